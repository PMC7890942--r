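#' Consensus genotype from per-caller genotype calls
#'
#' A genotype is accepted only when at least two callers assert it
#' identically; missing calls never count as agreement. When no genotype
#' reaches two concordant votes (including the case of a single non-missing
#' call) the consensus is missing.
#'
#' @param dosages integer vector of per-caller alt-allele dosages
#'   (0/1/2, `NA` = missing), one entry per caller.
#' @return a single dosage, or `NA` when no genotype wins two votes.
#' @export
consensus_genotype <- function(dosages) {
  d <- dosages[!is.na(dosages)]
  if (length(d) < 2L) return(NA_integer_)
  votes <- tabulate(d + 1L, nbins = 3L)
  win <- which(votes >= 2L)
  if (length(win) != 1L) return(NA_integer_)
  win - 1L
}

# per-site consensus over caller-level dosage rows (callers x samples)
vote_consensus <- function(caller_gt) {
  if (nrow(caller_gt) < 2L) {
    return(rep(NA_integer_, ncol(caller_gt)))
  }
  v0 <- colSums(caller_gt == 0L, na.rm = TRUE)
  v1 <- colSums(caller_gt == 1L, na.rm = TRUE)
  v2 <- colSums(caller_gt == 2L, na.rm = TRUE)
  votes <- rbind(v0, v1, v2)
  winners <- colSums(votes >= 2L)
  out <- max.col(t(votes), ties.method = "first") - 1L
  out[winners != 1L] <- NA_integer_
  as.integer(out)
}

#' Build the consensus genotype matrix for a merged SV map
#'
#' For every consensus site and sample, collects the genotypes the
#' genotyping callers' member calls carry and applies the two-concordant-
#' caller rule ([consensus_genotype]). A caller whose member calls at a
#' site disagree with each other for a sample contributes a missing vote;
#' samples with no member call at a site are missing.
#'
#' @param consensus an `sv_consensus` data frame from [merge_callsets]
#'   (its `calls` attribute supplies member genotypes).
#' @param popmap optional [population_map]; when given, every mapped sample
#'   must appear in at least one genotyping call set and the matrix columns
#'   are restricted to the mapped samples.
#' @return integer dosage matrix, rows = consensus site ids, columns =
#'   samples, class `sv_genotypes`.
#' @export
build_genotype_matrix <- function(consensus, popmap = NULL) {
  calls <- attr(consensus, "calls")
  if (is.null(calls) || is.null(calls$gt)) {
    stop("consensus object carries no genotyped member calls")
  }
  samples <- colnames(calls$gt)
  if (!is.null(popmap)) {
    absent <- setdiff(popmap$samples$sample_id, samples)
    if (length(absent)) {
      stop("sample '", absent[1], "' is absent from all genotyped call sets")
    }
    samples <- popmap$samples$sample_id
  }
  gmat <- matrix(NA_integer_, nrow(consensus), length(samples),
                 dimnames = list(consensus$id, samples))
  for (i in seq_len(nrow(consensus))) {
    idx <- consensus$members[[i]]
    sub <- calls$gt[idx, samples, drop = FALSE]
    caller <- calls$caller[idx]
    if (length(unique(caller)) < length(caller)) {
      # collapse duplicate members of one caller; conflicts become missing
      sub <- do.call(rbind, lapply(split(seq_along(idx), caller), function(k) {
        g <- sub[k, , drop = FALSE]
        one <- g[1, ]
        conflict <- apply(g, 2L, function(col) {
          u <- unique(col[!is.na(col)])
          length(u) > 1L
        })
        one[conflict] <- NA_integer_
        miss_all <- colSums(!is.na(g)) == 0L
        one[!conflict & !miss_all] <-
          apply(g[, !conflict & !miss_all, drop = FALSE], 2L,
                function(col) col[!is.na(col)][1])
        one
      }))
    }
    gmat[i, ] <- vote_consensus(sub)
  }
  structure(gmat, class = c("sv_genotypes", class(gmat)))
}

#' Per-population and pooled alt-allele frequencies
#'
#' At every site and for every population, the alt-allele frequency is
#' `(2 * n_hom_alt + n_het) / (2 * n_non_missing)`; missing genotypes are
#' excluded from the denominator. The pooled frequency (`af_all`) is
#' count-pooled over all samples of the focal and reference populations
#' jointly - allele counts are summed before dividing, so it equals the
#' sample-size-weighted combination of the population counts, not the mean
#' of the population frequencies. Populations with no non-missing genotype
#' at a site get `NaN` there.
#'
#' @param gmat dosage matrix (sites x samples), e.g. from
#'   [build_genotype_matrix] or a simulated truth set.
#' @param popmap a [population_map]; frequencies are computed for the focal
#'   and reference populations.
#' @return data frame of class `sv_freq`: `site`, then `af_<pop>` and
#'   `n_<pop>` (non-missing genotype count) per population, then `af_all`,
#'   `n_all` for the pooled samples.
#' @export
allele_frequencies <- function(gmat, popmap) {
  pops <- c(popmap$focal, popmap$references)
  out <- data.frame(site = rownames(gmat), stringsAsFactors = FALSE)
  pool_ac <- 0; pool_n <- 0
  for (p in pops) {
    cols <- pop_samples(popmap, p)
    sub <- gmat[, cols, drop = FALSE]
    nn <- rowSums(!is.na(sub))
    ac <- rowSums(sub, na.rm = TRUE)
    out[[paste0("af_", p)]] <- ac / (2 * nn)
    out[[paste0("n_", p)]] <- nn
    pool_ac <- pool_ac + ac
    pool_n <- pool_n + nn
  }
  out$af_all <- pool_ac / (2 * pool_n)
  out$n_all <- pool_n
  class(out) <- c("sv_freq", "data.frame")
  out
}

#' Write a genotype matrix as TSV (sites x samples, dosage coding)
#' @param gmat dosage matrix.
#' @param path output file.
#' @export
write_genotype_matrix <- function(gmat, path) {
  df <- data.frame(site = rownames(gmat), unclass(gmat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix written by [write_genotype_matrix]
#' @param path TSV file.
#' @return integer dosage matrix.
#' @export
read_genotype_matrix <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$site
  structure(m, class = c("sv_genotypes", class(m)))
}
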