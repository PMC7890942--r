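#' Pre-scan deletion filters
#'
#' Restricts a frequency table to the deletion sites eligible for the
#' selection scan: SV type `DEL`, length at most `max_len` (deletions over
#' 100 kb are removed by default), pooled alt-allele frequency at least
#' `min_freq` (rare sites below 0.01 are removed), and at least one
#' non-missing genotype in the focal and in every reference population.
#'
#' @param freq an `sv_freq` data frame from [allele_frequencies].
#' @param sites SV table (`id`, `chrom`, `start`, `end`, `svtype`, `svlen`)
#'   whose `id` matches `freq$site`; typically the `sv_consensus` map or a
#'   truth set's `svs`.
#' @param popmap a [population_map].
#' @param max_len maximum deletion length in bp (default 100,000).
#' @param min_freq minimum pooled frequency (default 0.01).
#' @return the filtered frequency table joined to the site coordinates.
#' @export
scan_filter <- function(freq, sites, popmap, max_len = 1e5,
                        min_freq = 0.01) {
  m <- match(freq$site, sites$id)
  if (anyNA(m)) stop("site '", freq$site[which(is.na(m))[1]],
                     "' absent from the SV table")
  joined <- cbind(
    freq,
    sites[m, c("chrom", "start", "end", "svtype", "svlen"), drop = FALSE]
  )
  rownames(joined) <- NULL
  pops <- c(popmap$focal, popmap$references)
  n_ok <- Reduce(`&`, lapply(pops, function(p) joined[[paste0("n_", p)]] > 0))
  keep <- joined$svtype == "DEL" &
    joined$svlen <= max_len &
    !is.na(joined$af_all) & joined$af_all >= min_freq &
    n_ok
  out <- joined[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Absolute allele-frequency difference (dAF)
#'
#' `dAF = | f_focal - mean(f_references) |`, the absolute difference
#' between the focal population's alt-allele frequency and the arithmetic
#' mean of the reference populations' frequencies. Always in \[0, 1\].
#'
#' @param f_focal focal-population frequencies (vector).
#' @param f_refs reference frequencies: a matrix with one column per
#'   reference population, or a vector (one site, or one reference).
#' @return numeric vector of dAF values.
#' @export
delta_af <- function(f_focal, f_refs) {
  f_refs <- as.matrix(f_refs)
  if (length(f_focal) == 1L && nrow(f_refs) > 1L) f_refs <- t(f_refs)
  abs(f_focal - rowMeans(f_refs))
}

#' Relative frequency difference (RFD)
#'
#' `RFD = (f_focal - mean(f_references)) / f_pooled`, the focal-vs-reference
#' frequency difference scaled by the pooled all-sample frequency. Positive
#' values indicate focal-population enrichment; the magnitude is unbounded
#' above by `1 / f_pooled`.
#'
#' @inheritParams delta_af
#' @param f_pool pooled (count-pooled, all samples) frequencies; must be
#'   positive, which the [scan_filter] minimum-frequency rule guarantees.
#' @return numeric vector of signed RFD values.
#' @export
rfd <- function(f_focal, f_refs, f_pool) {
  if (any(f_pool <= 0, na.rm = TRUE)) {
    stop("pooled frequency must be > 0 (apply scan_filter first)")
  }
  f_refs <- as.matrix(f_refs)
  if (length(f_focal) == 1L && nrow(f_refs) > 1L) f_refs <- t(f_refs)
  (f_focal - rowMeans(f_refs)) / f_pool
}

#' Flag the empirical top fraction of a distribution
#'
#' Uses the nearest-rank percentile: with `n` values and tail fraction `q`,
#' the cutoff is the `ceiling((1 - q) * n)`-th smallest value, and a value
#' is flagged iff it is strictly greater than the cutoff. Ties at the
#' cutoff are therefore not flagged, and a degenerate all-equal input flags
#' nothing.
#'
#' @param values numeric vector (no NAs).
#' @param fraction tail fraction, default 0.05 (the top 5 percent).
#' @return logical flags, with the cutoff in `attr(, "cutoff")`.
#' @export
empirical_top_fraction <- function(values, fraction = 0.05) {
  if (!length(values)) stop("empty value vector")
  if (anyNA(values)) stop("NA values in distribution")
  n <- length(values)
  if (n < 20L) {
    warning("fewer than 20 values; a ", fraction,
            " tail is poorly resolved")
  }
  cutoff <- sort(values)[ceiling((1 - fraction) * n)]
  structure(values > cutoff, cutoff = cutoff)
}

#' Scan deletion sites for selection signatures
#'
#' The scan computes dAF ([delta_af]) and RFD ([rfd]) at every eligible
#' deletion site ([scan_filter]), flags the empirical top `fraction` of
#' each statistic over the same filtered site set
#' ([empirical_top_fraction]), and calls a site a selection signature only
#' when it lies in both tails.
#'
#' @param sites SV table (consensus map or truth `svs`) with `id`, `chrom`,
#'   `start`, `end`, `svtype`, `svlen`.
#' @param gmat dosage matrix (sites x samples), rownames matching
#'   `sites$id`.
#' @param popmap a [population_map] with at least two reference
#'   populations.
#' @param fraction tail fraction for both statistics (default 0.05).
#' @param max_len,min_freq passed to [scan_filter].
#' @return an object of class `sv_scan`: a list with `results` (one row
#'   per scanned site: coordinates, frequencies, `delta_af`, `rfd`,
#'   `pass_daf`, `pass_rfd`, `significant`), `cutoffs`, the population
#'   roles, and bookkeeping counts.
#' @seealso [build_regions] to aggregate significant sites,
#'   [plot.sv_scan] for a genome-wide RFD plot.
#' @export
run_scan <- function(sites, gmat, popmap, fraction = 0.05,
                     max_len = 1e5, min_freq = 0.01) {
  if (length(popmap$references) < 2L) {
    stop("the scan needs at least 2 reference populations (got ",
         length(popmap$references), ")")
  }
  freq <- allele_frequencies(gmat, popmap)
  res <- scan_filter(freq, sites, popmap, max_len = max_len,
                     min_freq = min_freq)
  f_focal <- res[[paste0("af_", popmap$focal)]]
  f_refs <- as.matrix(res[paste0("af_", popmap$references)])
  res$delta_af <- delta_af(f_focal, f_refs)
  res$rfd <- rfd(f_focal, f_refs, res$af_all)
  daf_flags <- empirical_top_fraction(res$delta_af, fraction)
  rfd_flags <- empirical_top_fraction(res$rfd, fraction)
  res$pass_daf <- as.logical(daf_flags)
  res$pass_rfd <- as.logical(rfd_flags)
  res$significant <- res$pass_daf & res$pass_rfd
  structure(
    list(results = res,
         cutoffs = c(delta_af = attr(daf_flags, "cutoff"),
                     rfd = attr(rfd_flags, "cutoff")),
         fraction = fraction,
         focal = popmap$focal, references = popmap$references,
         n_input = nrow(freq), n_scanned = nrow(res)),
    class = "sv_scan"
  )
}

#' @export
print.sv_scan <- function(x, ...) {
  cat("Deletion selection scan -", x$focal, "vs",
      paste(x$references, collapse = "+"), "\n")
  cat(sprintf("  sites: %d input, %d scanned after filters\n",
              x$n_input, x$n_scanned))
  cat(sprintf("  top-%g%% cutoffs: dAF > %.4f, RFD > %.4f\n",
              100 * x$fraction, x$cutoffs["delta_af"], x$cutoffs["rfd"]))
  cat(sprintf("  significant (both tails): %d site(s)\n",
              sum(x$results$significant)))
  invisible(x)
}

#' @export
summary.sv_scan <- function(object, ...) {
  r <- object$results
  out <- list(
    n_scanned = nrow(r),
    n_pass_daf = sum(r$pass_daf),
    n_pass_rfd = sum(r$pass_rfd),
    n_significant = sum(r$significant),
    delta_af = summary(r$delta_af),
    rfd = summary(r$rfd),
    cutoffs = object$cutoffs
  )
  class(out) <- "summary.sv_scan"
  out
}

#' @export
print.summary.sv_scan <- function(x, ...) {
  cat(sprintf("scanned %d sites: %d pass dAF, %d pass RFD, %d significant\n",
              x$n_scanned, x$n_pass_daf, x$n_pass_rfd, x$n_significant))
  cat("dAF distribution:\n"); print(x$delta_af)
  cat("RFD distribution:\n"); print(x$rfd)
  invisible(x)
}

#' Genome-wide RFD plot of a selection scan
#'
#' Manhattan-style plot of per-site RFD values along the genome with the
#' top-fraction cutoff drawn and significant (both-statistic) sites
#' highlighted.
#'
#' @param x an `sv_scan` object.
#' @param ... further arguments passed to [graphics::plot].
#' @export
plot.sv_scan <- function(x, ...) {
  r <- x$results
  chroms <- unique(r$chrom)
  off <- setNames(c(0, cumsum(vapply(chroms, function(cc)
    max(r$end[r$chrom == cc]), numeric(1))))[seq_along(chroms)], chroms)
  pos <- off[r$chrom] + r$start
  graphics::plot(pos, r$rfd, pch = 16, cex = 0.5,
                 col = ifelse(r$significant, "firebrick",
                              c("grey40", "grey65")[1 + match(r$chrom, chroms) %% 2]),
                 xlab = "genome position", ylab = "RFD", xaxt = "n", ...)
  graphics::axis(1, at = off + diff(c(off, max(pos))) / 2, labels = chroms,
                 las = 2, cex.axis = 0.7)
  graphics::abline(h = x$cutoffs["rfd"], lty = 2, col = "steelblue")
  invisible(x)
}

#' Aggregate significant sites into selection regions
#'
#' Significant sites on one chromosome are sorted and chained: consecutive
#' sites whose gap (bases strictly between one site's end and the next
#' site's start) is at most `join_gap` fall in one region, whose span is
#' the envelope of its member sites. Sites on different chromosomes are
#' never joined.
#'
#' @param scan an `sv_scan` object (or its `results` data frame).
#' @param join_gap maximum inter-site gap in bp (default 100,000).
#' @return data frame of class `sv_regions`: `chrom`, `start`, `end`,
#'   `n_sites` and a `sites` list-column of member site ids.
#' @export
build_regions <- function(scan, join_gap = 1e5) {
  r <- if (inherits(scan, "sv_scan")) scan$results else scan
  sig <- r[r$significant, , drop = FALSE]
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), n_sites = integer(),
                    stringsAsFactors = FALSE)
  out$sites <- list()
  for (cc in unique(sig$chrom)) {
    s <- sig[sig$chrom == cc, , drop = FALSE]
    s <- s[order(s$start, s$end), , drop = FALSE]
    grp <- cumsum(c(1L, (s$start[-1] - cummax(s$end)[-nrow(s)] - 1L) > join_gap))
    for (g in split(seq_len(nrow(s)), grp)) {
      out <- rbind(out, data.frame(
        chrom = cc, start = min(s$start[g]), end = max(s$end[g]),
        n_sites = length(g),
        sites = I(list(s$site[g])), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  class(out) <- c("sv_regions", "data.frame")
  out
}

#' Write scan results as TSV
#' @param scan an `sv_scan` object.
#' @param path output file.
#' @export
write_scan_results <- function(scan, path) {
  write.table(scan$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write selection regions as BED (0-based half-open) plus a TSV gene list
#' @param regions an `sv_regions` data frame, optionally with a
#'   `genes` column from [genes_in_regions].
#' @param path output BED path.
#' @export
write_regions_bed <- function(regions, path) {
  name <- vapply(regions$sites, paste, character(1), collapse = ",")
  df <- data.frame(regions$chrom, regions$start - 1L, regions$end, name)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
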