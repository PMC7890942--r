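#' Simulation configuration
#'
#' Defines the study conditions the synthetic data emulates: a scaled-down
#' genome, SV sites of each type with log-uniform lengths, three
#' populations genotyped under Hardy-Weinberg equilibrium at a shared
#' neutral frequency per site, an optional set of planted "selected"
#' deletions whose true frequency is elevated in the focal population, and
#' a panel of imperfect callers (false negatives, caller-private false
#' positives, Gaussian breakpoint jitter, genotyping errors).
#'
#' @param genome named integer vector of chromosome lengths in bp.
#' @param n_sites named vector: number of true sites per SV type.
#' @param svlen_range named list of `c(min, max)` length bounds per type;
#'   lengths are drawn log-uniformly.
#' @param populations named integer vector of diploid sample sizes; the
#'   first population is the focal one unless `focal` says otherwise.
#' @param focal focal population label.
#' @param af_range baseline allele-frequency bounds; each neutral site
#'   draws one true frequency, shared by all populations.
#' @param n_selected number of planted selected deletions.
#' @param selected_focal_af,selected_ref_af true frequencies at planted
#'   sites in the focal and in every reference population.
#' @param callers data frame with columns `name`, `fnr` (false-negative
#'   rate), `fpr_per_mb` (false positives per Mb of genome), `jitter_sd`
#'   (breakpoint noise sd in bp), `genotyping` (does the caller emit
#'   genotypes). The defaults model three genotyping callers and one
#'   non-genotyping caller with moderate error.
#' @param genotype_error per-genotype error rate of genotyping callers.
#' @param n_genes genes placed for annotation exercises.
#' @param seed RNG seed; a fixed seed makes every simulation product
#'   byte-identical across runs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(
    genome = setNames(rep(10e6, 18), paste0("chr", 1:18)),
    n_sites = c(DEL = 400, INS = 200, INV = 20, DUP = 50, TRA = 0),
    svlen_range = list(DEL = c(100, 10000), INS = c(50, 500),
                       INV = c(5000, 100000), DUP = c(5000, 100000)),
    populations = c(MS = 50, DU = 50, TB = 50),
    focal = names(populations)[1],
    af_range = c(0.05, 0.95),
    n_selected = 0,
    selected_focal_af = 0.9,
    selected_ref_af = 0.1,
    callers = data.frame(
      name = c("delly", "manta", "genomestrip", "breakdancer"),
      fnr = 0.2, fpr_per_mb = 0.5, jitter_sd = 30,
      genotyping = c(TRUE, TRUE, TRUE, FALSE),
      stringsAsFactors = FALSE),
    genotype_error = 0.02,
    n_genes = 200,
    seed = 1L) {
  stopifnot(all(genome > 0), all(n_sites >= 0),
            all(callers$fnr >= 0 & callers$fnr <= 1),
            all(callers$fpr_per_mb >= 0), all(callers$jitter_sd >= 0),
            genotype_error >= 0 && genotype_error <= 1,
            af_range[1] >= 0, af_range[2] <= 1, af_range[1] <= af_range[2],
            length(populations) >= 1, n_selected >= 0)
  if (n_selected > 0 && selected_focal_af == selected_ref_af) {
    stop("planted sites need selected_focal_af != selected_ref_af")
  }
  if (n_selected > n_sites["DEL"]) {
    stop("n_selected exceeds the number of deletion sites")
  }
  structure(list(genome = genome, n_sites = n_sites,
                 svlen_range = svlen_range, populations = populations,
                 focal = focal, af_range = af_range,
                 n_selected = n_selected,
                 selected_focal_af = selected_focal_af,
                 selected_ref_af = selected_ref_af,
                 callers = callers, genotype_error = genotype_error,
                 n_genes = n_genes, seed = as.integer(seed)),
            class = "sim_config")
}

config_popmap <- function(config) {
  sizes <- config$populations
  ids <- unlist(lapply(names(sizes), function(p)
    sprintf("%s_s%03d", p, seq_len(sizes[[p]]))))
  population_map(ids, rep(names(sizes), sizes), focal = config$focal)
}

rlogunif <- function(n, lo, hi) {
  round(exp(runif(n, log(lo), log(hi))))
}

# place n non-overlapping (same-type) intervals of the given lengths
place_intervals <- function(n, lens, genome, max_tries = 100L) {
  chroms <- names(genome)
  placed <- data.frame(chrom = character(), start = integer(),
                       end = integer(), svlen = integer(),
                       stringsAsFactors = FALSE)
  remaining <- as.integer(lens)
  for (tries in seq_len(max_tries)) {
    need <- length(remaining)
    if (need == 0L) break
    cc <- sample(chroms, need, replace = TRUE, prob = genome)
    room <- genome[cc] - remaining + 1
    if (any(room < 1)) stop("an SV is longer than its chromosome")
    st <- floor(runif(need, 1, room + 1))
    cand <- data.frame(chrom = cc, start = as.integer(st),
                       end = as.integer(st + remaining - 1L),
                       svlen = remaining, stringsAsFactors = FALSE)
    all_iv <- rbind(placed, cand)
    gr <- GenomicRanges::GRanges(all_iv$chrom,
                                 IRanges::IRanges(all_iv$start, all_iv$end))
    ov <- GenomicRanges::countOverlaps(gr, gr)
    keep_cand <- ov[seq.int(nrow(placed) + 1L, nrow(all_iv))] == 1L
    placed <- rbind(placed, cand[keep_cand, , drop = FALSE])
    remaining <- remaining[!keep_cand]
  }
  if (nrow(placed) < n) {
    stop("could not place ", n, " non-overlapping sites after ",
         max_tries, " rounds; genome too small")
  }
  rownames(placed) <- NULL
  placed
}

#' Simulate a ground-truth SV set with population structure
#'
#' Places the configured sites uniformly on the genome without same-type
#' overlap, draws one true alt-allele frequency per neutral site (shared by
#' all populations, so the true focal-vs-reference difference is zero) and
#' plants `n_selected` deletions whose true frequency is
#' `selected_focal_af` in the focal population and `selected_ref_af`
#' elsewhere. Per-sample genotypes are independent Hardy-Weinberg draws
#' from the population frequency (dosage ~ Binomial(2, f)).
#'
#' @param config a [sim_config].
#' @return list of class `sv_truth`: `svs` (an [sv_calls] table,
#'   caller `"truth"`, with the true genotypes as its `gt` column), `af`
#'   (true frequency matrix, sites x populations), `selected` (logical per
#'   site), `popmap`, `config`.
#' @export
simulate_truth <- function(config = sim_config()) {
  set.seed(config$seed)
  popmap <- config_popmap(config)
  types <- names(config$n_sites)[config$n_sites > 0]
  pieces <- lapply(types, function(tp) {
    n <- config$n_sites[[tp]]
    if (tp == "TRA") {
      cc <- sample(names(config$genome), n, replace = TRUE,
                   prob = config$genome)
      st <- floor(runif(n, 1, config$genome[cc]))
      mc <- sample(names(config$genome), n, replace = TRUE)
      mp <- floor(runif(n, 1, config$genome[mc]))
      return(data.frame(chrom = cc, start = as.integer(st),
                        end = as.integer(st), svtype = tp, svlen = 0L,
                        mate_chrom = mc, mate_pos = as.integer(mp),
                        stringsAsFactors = FALSE))
    }
    rg <- config$svlen_range[[tp]]
    lens <- rlogunif(n, rg[1], rg[2])
    iv <- place_intervals(n, lens, config$genome)
    if (tp == "INS") {
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$start,
                 svtype = tp, svlen = iv$svlen, mate_chrom = NA_character_,
                 mate_pos = NA_integer_, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = iv$chrom, start = iv$start, end = iv$end,
                 svtype = tp, svlen = iv$end - iv$start + 1L,
                 mate_chrom = NA_character_, mate_pos = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  svs <- do.call(rbind, pieces)
  o <- order(svs$chrom, svs$start, svs$svtype)
  svs <- svs[o, , drop = FALSE]
  n <- nrow(svs)
  ids <- sprintf("truth_%05d", seq_len(n))

  pops <- names(config$populations)
  af <- matrix(runif(n, config$af_range[1], config$af_range[2]),
               n, length(pops), dimnames = list(ids, pops))
  selected <- rep(FALSE, n)
  if (config$n_selected > 0) {
    del_idx <- which(svs$svtype == "DEL")
    sel <- sample(del_idx, config$n_selected)
    selected[sel] <- TRUE
    af[sel, ] <- config$selected_ref_af
    af[sel, config$focal] <- config$selected_focal_af
  }

  samples <- popmap$samples$sample_id
  gt <- matrix(NA_integer_, n, length(samples),
               dimnames = list(ids, samples))
  for (p in pops) {
    cols <- pop_samples(popmap, p)
    gt[, cols] <- rbinom(n * length(cols), 2L, rep(af[, p], length(cols)))
  }

  truth_svs <- sv_calls(chrom = svs$chrom, start = svs$start, end = svs$end,
                        svtype = svs$svtype, svlen = svs$svlen,
                        caller = "truth", id = ids, gt = gt,
                        mate_chrom = svs$mate_chrom,
                        mate_pos = svs$mate_pos)
  structure(list(svs = truth_svs, af = af, selected = selected,
                 popmap = popmap, config = config),
            class = "sv_truth")
}

#' @export
print.sv_truth <- function(x, ...) {
  cat("sv_truth:", nrow(x$svs), "true SVs,",
      sum(x$selected), "planted selected site(s)\n")
  print(x$popmap)
  invisible(x)
}

jitter_bp <- function(x, sd) {
  if (sd == 0) return(x)
  as.integer(x + round(rnorm(length(x), 0, sd)))
}

perturb_genotypes <- function(gt, error) {
  if (error == 0) return(gt)
  flip <- !is.na(gt) & matrix(runif(length(gt)) < error, nrow(gt))
  if (any(flip)) {
    shift <- sample(1:2, sum(flip), replace = TRUE)
    gt[flip] <- (gt[flip] + shift) %% 3L
  }
  gt
}

#' Simulate noisy per-caller call sets from a truth set
#'
#' Every caller reports each true site with probability `1 - fnr`; reported
#' breakpoints are the true ones plus independent rounded Gaussian noise at
#' each end (re-ordered if inverted). Caller-private false positives are
#' added at `fpr_per_mb` per Mb of genome, with types drawn in proportion
#' to the configured site counts and log-uniform lengths; being private,
#' they can never gain two-caller support downstream. Genotyping callers
#' copy the true genotypes with a per-genotype error rate; false-positive
#' genotypes are Hardy-Weinberg draws at a random baseline frequency.
#'
#' @param truth an `sv_truth` from [simulate_truth].
#' @param config a [sim_config]; defaults to the one inside `truth`.
#' @return named list of [sv_calls], one per configured caller.
#' @export
simulate_callsets <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  genome_mb <- sum(config$genome) / 1e6
  samples <- colnames(truth$svs$gt)
  types <- names(config$n_sites)[config$n_sites > 0]
  type_prob <- config$n_sites[types] / sum(config$n_sites[types])

  out <- list()
  for (k in seq_len(nrow(config$callers))) {
    cal <- config$callers[k, ]
    keep <- runif(nrow(truth$svs)) >= cal$fnr
    tp <- truth$svs[keep, , drop = FALSE]
    if (nrow(tp)) {
      s <- jitter_bp(tp$start, cal$jitter_sd)
      is_point <- tp$svtype %in% c("INS", "TRA")
      e <- ifelse(is_point, s, jitter_bp(tp$end, cal$jitter_sd))
      swap <- e < s & !is_point
      tmp <- s[swap]; s[swap] <- e[swap]; e[swap] <- tmp
      s <- pmax(s, 1L)
      e <- pmax(e, s)
      tp$start <- as.integer(s)
      tp$end <- as.integer(e)
      span <- tp$svtype %in% c("DEL", "INV", "DUP")
      tp$svlen[span] <- tp$end[span] - tp$start[span] + 1L
      tp$mate_pos <- ifelse(tp$svtype == "TRA",
                            pmax(1L, jitter_bp(tp$mate_pos, cal$jitter_sd)),
                            tp$mate_pos)
    }

    n_fp <- rpois(1, cal$fpr_per_mb * genome_mb)
    if (n_fp > 0) {
      fp_type <- sample(types, n_fp, replace = TRUE, prob = type_prob)
      fp <- do.call(rbind, lapply(seq_len(n_fp), function(i) {
        tpp <- fp_type[i]
        cc <- sample(names(config$genome), 1, prob = config$genome)
        if (tpp == "TRA") {
          st <- floor(runif(1, 1, config$genome[[cc]]))
          data.frame(chrom = cc, start = st, end = st, svtype = tpp,
                     svlen = 0L,
                     mate_chrom = sample(names(config$genome), 1),
                     mate_pos = floor(runif(1, 1, config$genome[[1]])),
                     stringsAsFactors = FALSE)
        } else {
          rg <- config$svlen_range[[tpp]]
          len <- rlogunif(1, rg[1], rg[2])
          st <- floor(runif(1, 1, max(2, config$genome[[cc]] - len)))
          data.frame(chrom = cc, start = st,
                     end = if (tpp == "INS") st else st + len - 1L,
                     svtype = tpp, svlen = len,
                     mate_chrom = NA_character_, mate_pos = NA_integer_,
                     stringsAsFactors = FALSE)
        }
      }))
      fp_af <- runif(n_fp, config$af_range[1], config$af_range[2])
      fp_gt <- matrix(rbinom(n_fp * length(samples), 2L,
                             rep(fp_af, length(samples))),
                      n_fp, length(samples),
                      dimnames = list(NULL, samples))
      fp_calls <- sv_calls(chrom = fp$chrom, start = fp$start, end = fp$end,
                           svtype = fp$svtype, svlen = pmax(fp$svlen, 0L),
                           caller = cal$name,
                           id = sprintf("%s_fp%04d", cal$name,
                                        seq_len(n_fp)),
                           gt = fp_gt, mate_chrom = fp$mate_chrom,
                           mate_pos = fp$mate_pos)
    } else {
      fp_calls <- empty_sv_calls(samples)
    }

    if (nrow(tp)) {
      tp$caller <- cal$name
      tp$id <- sprintf("%s_tp%05d", cal$name, seq_len(nrow(tp)))
    }
    calls <- rbind(tp, fp_calls)
    o <- order(calls$chrom, calls$start, calls$svtype)
    calls <- calls[o, , drop = FALSE]
    rownames(calls) <- NULL
    if (cal$genotyping) {
      calls$gt <- perturb_genotypes(calls$gt, config$genotype_error)
    } else {
      calls$gt <- NULL
    }
    out[[cal$name]] <- validate_sv_calls(calls)
  }
  out
}

#' Simulate gene models on the configured genome
#'
#' Places `n_genes` non-overlapping genes (log-uniform spans, 1-6 merged
#' exons each, random strand) for annotation exercises.
#'
#' @param config a [sim_config].
#' @return a [gene_models] object.
#' @export
simulate_genes <- function(config = sim_config()) {
  set.seed(config$seed + 2L)
  n <- config$n_genes
  lens <- rlogunif(n, 5000, 100000)
  iv <- place_intervals(n, lens, config$genome)
  ids <- sprintf("gene%04d", seq_len(n))
  genes <- data.frame(gene_id = ids, chrom = iv$chrom, start = iv$start,
                      end = iv$end,
                      strand = sample(c("+", "-"), n, replace = TRUE),
                      stringsAsFactors = FALSE)
  exons <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(1:6, 1)
    span <- genes$end[i] - genes$start[i] + 1L
    bounds <- sort(sample(seq_len(span), min(2 * k, span - 1)))
    st <- genes$start[i] + bounds[seq(1, length(bounds) - 1, by = 2)] - 1L
    en <- genes$start[i] + bounds[seq(2, length(bounds), by = 2)] - 1L
    data.frame(gene_id = ids[i], start = st, end = en,
               stringsAsFactors = FALSE)
  }))
  gene_models(genes, exons)
}

#' Write a complete simulation bundle to disk
#'
#' Emits one VCF per caller, the truth VCF (with true genotypes), the
#' population map TSV, a gene-model BED and a JSON manifest recording the
#' configuration and seed. With a fixed seed the bundle is byte-identical
#' across runs.
#'
#' @param truth an `sv_truth`.
#' @param callsets output of [simulate_callsets].
#' @param outdir output directory (created if needed).
#' @param genes optional [gene_models]; simulated from the config when
#'   `NULL`.
#' @return named list of written file paths, invisibly.
#' @export
write_simulation_bundle <- function(truth, callsets, outdir, genes = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create output directory ", outdir)
  if (is.null(genes)) genes <- simulate_genes(truth$config)
  paths <- list(truth = file.path(outdir, "truth.vcf"),
                popmap = file.path(outdir, "population_map.tsv"),
                genes = file.path(outdir, "genes.bed"),
                manifest = file.path(outdir, "manifest.json"))
  write_sv_vcf(truth$svs, paths$truth)
  write_population_map(truth$popmap, paths$popmap)
  write_gene_models_bed(genes, paths$genes)
  for (nm in names(callsets)) {
    paths[[paste0("caller_", nm)]] <- file.path(outdir,
                                                paste0(nm, ".vcf"))
    write_sv_vcf(callsets[[nm]], paths[[paste0("caller_", nm)]])
  }
  cfg <- truth$config
  cfg$svlen_range <- lapply(cfg$svlen_range, as.numeric)
  manifest <- list(config = cfg[setdiff(names(cfg), "callers")],
                   callers = cfg$callers,
                   files = lapply(paths, basename),
                   n_true_sites = nrow(truth$svs),
                   n_selected = sum(truth$selected))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}
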