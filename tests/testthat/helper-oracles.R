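# Independent oracles and small fixture builders shared across tests.
# The oracle code deliberately re-derives every rule from scratch (scalar
# arithmetic, explicit loops) so it shares no code path with the package.

# scalar match rule: reciprocal overlap > ro_min for spanning types,
# breakpoint window + length ratio for INS, dual-breakend window for TRA
oracle_match <- function(a, b, ro_min = 0.75, win = 100, ratio = 0.75) {
  if (a$chrom != b$chrom || a$svtype != b$svtype) return(FALSE)
  if (a$svtype %in% c("DEL", "INV", "DUP")) {
    o <- min(a$end, b$end) - max(a$start, b$start) + 1
    if (o <= 0) return(FALSE)
    ro <- min(o / (a$end - a$start + 1), o / (b$end - b$start + 1))
    return(ro > ro_min)
  }
  if (a$svtype == "INS") {
    return(abs(a$start - b$start) <= win &&
             min(a$svlen, b$svlen) / max(a$svlen, b$svlen) >= ratio)
  }
  identical(a$mate_chrom, b$mate_chrom) &&
    abs(a$start - b$start) <= win &&
    abs(a$mate_pos - b$mate_pos) <= win
}

# exhaustive pairwise match matrix + breadth-first connected components
oracle_components <- function(calls) {
  n <- nrow(calls)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        adj[i, j] <- oracle_match(calls[i, ], calls[j, ])
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (s in seq_len(n)) {
    if (comp[s] == 0L) {
      cid <- cid + 1L
      queue <- s
      while (length(queue)) {
        v <- queue[1]
        queue <- queue[-1]
        if (comp[v] == 0L) {
          comp[v] <- cid
          queue <- c(queue, which(adj[v, ] & comp == 0L))
        }
      }
    }
  }
  comp
}

# canonical partition representation for comparing clusterings
partition_sets <- function(membership) {
  unname(lapply(split(seq_along(membership), membership), sort)[
    order(vapply(split(seq_along(membership), membership),
                 min, integer(1)))])
}

# random small merge instance: up to max_n calls from 3 callers, mixed
# types, coordinates chosen so that partial overlaps are common
random_merge_instance <- function(max_n = 12) {
  n <- sample(2:max_n, 1)
  svtype <- sample(c("DEL", "INS", "INV", "DUP"), n, replace = TRUE)
  chrom <- sample(c("c1", "c2"), n, replace = TRUE)
  len <- ifelse(svtype == "INS",
                sample(60:400, n, replace = TRUE),
                sample(c(100, 500, 1000, 2000), n, replace = TRUE))
  start <- sample(1:3000, n, replace = TRUE)
  end <- ifelse(svtype == "INS", start, start + len - 1L)
  sv_calls(chrom = chrom, start = start, end = end, svtype = svtype,
           svlen = len,
           caller = sample(c("a", "b", "c"), n, replace = TRUE))
}

# noiseless caller panel used by identity tests
perfect_callers <- function(n = 3, genotyping = TRUE) {
  data.frame(name = letters[seq_len(n)], fnr = 0, fpr_per_mb = 0,
             jitter_sd = 0, genotyping = genotyping,
             stringsAsFactors = FALSE)
}

small_sim_config <- function(populations = c(MS = 10, DU = 10, TB = 10),
                             n_sites = c(DEL = 40, INS = 15, INV = 5,
                                         DUP = 5, TRA = 3), ...) {
  sim_config(genome = setNames(rep(2e6, 4), paste0("chr", 1:4)),
             n_sites = n_sites, populations = populations, n_genes = 30,
             ...)
}

# fast truth-level scan used by the calibration and power tests: neutral
# or planted deletion sites, genotypes straight from the simulator
truth_scan <- function(n_sites, n_selected, seed, n_per_pop = 50,
                       focal_af = 0.9, ref_af = 0.1) {
  cfg <- sim_config(
    n_sites = c(DEL = n_sites, INS = 0, INV = 0, DUP = 0, TRA = 0),
    populations = c(MS = n_per_pop, DU = n_per_pop, TB = n_per_pop),
    n_selected = n_selected, selected_focal_af = focal_af,
    selected_ref_af = ref_af, seed = seed)
  truth <- simulate_truth(cfg)
  scan <- run_scan(truth$svs, truth$svs$gt, truth$popmap)
  list(truth = truth, scan = scan)
}

# recovery of planted sites and the neutral flag rate from one such run
scan_rates <- function(ts) {
  sel_ids <- ts$truth$svs$id[ts$truth$selected]
  r <- ts$scan$results
  sig <- r$site[r$significant]
  scanned_neutral <- setdiff(r$site, sel_ids)
  c(recovery = if (length(sel_ids))
      mean(sel_ids %in% sig) else NA_real_,
    neutral_rate = mean(scanned_neutral %in% sig))
}

write_vcf_lines <- function(lines, ...) {
  path <- tempfile(fileext = ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
           '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
           '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="l">',
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="g">')
  writeLines(c(hdr, ..., lines), path)
  path
}
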