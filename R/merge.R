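#' Merge parameters
#'
#' @param ro_min minimum reciprocal overlap for spanning types; two calls
#'   match only when their reciprocal overlap is strictly greater than this
#'   (default 0.75, i.e. the ">75%" rule).
#' @param ins_window maximum breakpoint distance (bp) for insertion and
#'   translocation matching.
#' @param ins_len_ratio minimum min/max insertion-length ratio.
#' @param min_support minimum number of distinct callers for a consensus
#'   record (default 2).
#' @return a list of class `merge_params`.
#' @export
merge_params <- function(ro_min = 0.75, ins_window = 100L,
                         ins_len_ratio = 0.75, min_support = 2L) {
  stopifnot(ro_min >= 0, ro_min <= 1, ins_window >= 0,
            ins_len_ratio >= 0, ins_len_ratio <= 1, min_support >= 1)
  structure(list(ro_min = ro_min, ins_window = as.integer(ins_window),
                 ins_len_ratio = ins_len_ratio,
                 min_support = as.integer(min_support)),
            class = "merge_params")
}

#' Reciprocal overlap of two spanning SV calls
#'
#' For 1-based inclusive intervals the reciprocal overlap is
#' `min(O/len_a, O/len_b)` with `O` the shared length in bp (0 when the
#' intervals are disjoint) and `len = end - start + 1`. Calls on different
#' chromosomes or of different types have reciprocal overlap 0 by
#' definition. All arguments recycle, so the function is vectorised over
#' pairs.
#'
#' @param a,b single-row `sv_calls` data frames, or lists/data frames with
#'   `chrom`, `start`, `end`, `svtype` fields.
#' @return fraction(s) in \[0, 1\].
#' @export
reciprocal_overlap <- function(a, b) {
  same <- a$chrom == b$chrom & a$svtype == b$svtype
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start) + 1L)
  ro <- pmin(ov / (a$end - a$start + 1), ov / (b$end - b$start + 1))
  ifelse(same, ro, 0)
}

#' Do two calls describe the same SV?
#'
#' Spanning types (DEL/INV/DUP) match when reciprocal overlap exceeds
#' `ro_min`. Insertions, being point-like, match when their positions are
#' within `ins_window` bp and their length ratio (min/max) is at least
#' `ins_len_ratio`. Translocations match when both breakends are within
#' `ins_window` bp on the same chromosome pair. Calls of different type or
#' chromosome never match.
#'
#' @inheritParams reciprocal_overlap
#' @param params a [merge_params] list.
#' @return logical vector.
#' @export
sv_matches <- function(a, b, params = merge_params()) {
  same <- a$chrom == b$chrom & a$svtype == b$svtype
  type <- ifelse(same, a$svtype, "NONE")
  out <- logical(length(type))
  sp <- type %in% c("DEL", "INV", "DUP")
  if (any(sp)) out[sp] <- reciprocal_overlap(a, b)[sp] > params$ro_min
  ins <- type == "INS"
  if (any(ins)) {
    d <- abs(a$start - b$start)
    ratio <- pmin(a$svlen, b$svlen) / pmax(a$svlen, b$svlen)
    out[ins] <- d[ins] <= params$ins_window &
      ratio[ins] >= params$ins_len_ratio
  }
  tra <- type == "TRA"
  if (any(tra)) {
    out[tra] <- (a$mate_chrom == b$mate_chrom &
                   abs(a$start - b$start) <= params$ins_window &
                   abs(a$mate_pos - b$mate_pos) <= params$ins_window)[tra]
  }
  out
}

# candidate matching pairs (i, j) within one (chrom, svtype) partition
partition_pairs <- function(calls, params) {
  n <- nrow(calls)
  if (n < 2L) return(NULL)
  type <- calls$svtype[1]
  if (type %in% c("DEL", "INV", "DUP")) {
    ir <- IRanges::IRanges(calls$start, calls$end)
    hit <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(hit); j <- S4Vectors::subjectHits(hit)
  } else if (type == "INS") {
    ir <- IRanges::IRanges(calls$start, calls$start + params$ins_window)
    hit <- IRanges::findOverlaps(ir, drop.self = TRUE, drop.redundant = TRUE)
    i <- S4Vectors::queryHits(hit); j <- S4Vectors::subjectHits(hit)
  } else {                               # TRA: partitions are small
    cmb <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    i <- cmb[, 1]; j <- cmb[, 2]
  }
  if (!length(i)) return(NULL)
  keep <- sv_matches(calls[i, , drop = FALSE], calls[j, , drop = FALSE],
                     params)
  if (!any(keep)) return(NULL)
  cbind(i[keep], j[keep])
}

#' Cluster calls into putative same-SV groups
#'
#' Within each (chromosome, SV type) partition, calls are vertices and
#' [sv_matches] pairs are edges; clusters are the connected components of
#' that graph (single linkage, the behaviour of standard SV mergers).
#' Chaining is therefore possible: A-B and B-C matching places A and C in
#' one cluster even if they do not match each other directly.
#'
#' @param calls an [sv_calls] data frame (any mix of callers).
#' @param params a [merge_params] list.
#' @return integer vector of cluster ids, one per call; every call belongs
#'   to exactly one cluster.
#' @export
cluster_calls <- function(calls, params = merge_params()) {
  n <- nrow(calls)
  if (n == 0L) return(integer())
  part <- paste(calls$chrom, calls$svtype, sep = "\r")
  membership <- integer(n)
  offset <- 0L
  for (idx in split(seq_len(n), part)) {
    sub <- calls[idx, , drop = FALSE]
    pairs <- partition_pairs(sub, params)
    if (is.null(pairs)) {
      comp <- seq_along(idx)
    } else {
      g <- igraph::graph_from_edgelist(pairs, directed = FALSE)
      g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
      comp <- igraph::components(g)$membership
    }
    membership[idx] <- comp + offset
    offset <- offset + max(comp)
  }
  membership
}

med_floor <- function(x) as.integer(floor(median(x)))

#' Resolve one cluster to a consensus record
#'
#' A cluster becomes a consensus SV only when at least `min_support`
#' distinct callers contributed to it (duplicate calls from one caller
#' count once toward support but all contribute to the medians). Breakpoints
#' are the medians of the member starts and ends; an even-sized median takes
#' the floor of the midpoint so coordinates stay integral. `svlen` is
#' recomputed as `end - start + 1` for spanning types and is the median
#' member length for insertions.
#'
#' @param members an [sv_calls] data frame, all same chrom and svtype.
#' @param params a [merge_params] list.
#' @return a one-row consensus data frame, or `NULL` when support is
#'   insufficient.
#' @export
resolve_consensus <- function(members, params = merge_params()) {
  callers <- sort(unique(members$caller))
  if (length(callers) < params$min_support) return(NULL)
  type <- members$svtype[1]
  start <- med_floor(members$start)
  end <- med_floor(members$end)
  svlen <- switch(type,
                  INS = med_floor(members$svlen),
                  TRA = 0L,
                  end - start + 1L)
  data.frame(chrom = members$chrom[1], start = start, end = end,
             svtype = type, svlen = svlen,
             callers = paste(callers, collapse = ","),
             n_callers = length(callers),
             mate_chrom = members$mate_chrom[1],
             mate_pos = if (type == "TRA") med_floor(members$mate_pos)
                        else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Apply the per-type size filters
#'
#' Keeps deletions and insertions longer than 50 bp and shorter than 10 Mb,
#' inversions and duplications shorter than 10 Mb, and all translocations.
#' Bounds are strict (a 50-bp deletion is removed).
#'
#' @param svs consensus (or raw) SV data frame with `svtype`, `svlen`.
#' @return the surviving subset, attributes preserved.
#' @export
apply_size_filters <- function(svs) {
  keep <- rep(TRUE, nrow(svs))
  indel <- svs$svtype %in% c("DEL", "INS")
  keep[indel] <- svs$svlen[indel] > 50 & svs$svlen[indel] < 1e7
  big <- svs$svtype %in% c("INV", "DUP")
  keep[big] <- svs$svlen[big] < 1e7
  subset_consensus(svs, keep)
}

subset_consensus <- function(svs, keep) {
  out <- svs[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (a in c("calls", "genotyping_callers")) {
    attr(out, a) <- attr(svs, a)
  }
  class(out) <- class(svs)
  out
}

#' Merge multi-caller call sets into a consensus SV map
#'
#' The complete consensus procedure: pool the call sets, cluster within
#' (chromosome, type) partitions by the reciprocal-overlap rule
#' ([cluster_calls]), keep clusters detected by two or more callers with
#' median breakpoints ([resolve_consensus]), then apply the per-type size
#' filters ([apply_size_filters]). Output is sorted by (chrom, start) and
#' is invariant to the order of the input calls.
#'
#' @param callsets a named list of [sv_calls] data frames, one per caller
#'   (at least two); names override the `caller` column when present.
#' @param params a [merge_params] list.
#' @param size_filter apply [apply_size_filters] (default `TRUE`).
#' @return a data frame of class `sv_consensus` with columns `id`, `chrom`,
#'   `start`, `end`, `svtype`, `svlen`, `callers`, `n_callers`, a
#'   `members` list-column of indices into the pooled input calls, and the
#'   pooled calls themselves in `attr(, "calls")` (used downstream for
#'   consensus genotyping).
#' @export
merge_callsets <- function(callsets, params = merge_params(),
                           size_filter = TRUE) {
  if (length(callsets) < 2L) stop("need call sets from at least 2 callers")
  if (is.null(names(callsets)) || any(!nzchar(names(callsets)))) {
    names(callsets) <- vapply(callsets, function(cs)
      if (nrow(cs)) cs$caller[1] else "caller", character(1))
  }
  callsets <- Map(function(cs, nm) { if (nrow(cs)) cs$caller <- nm; cs },
                  callsets, names(callsets))
  samples <- sort(unique(unlist(lapply(callsets, function(cs)
    colnames(cs$gt)))))
  genotyping <- names(callsets)[vapply(callsets, function(cs)
    !is.null(cs$gt), logical(1))]
  calls <- do.call(rbind, lapply(callsets, function(cs) {
    if (length(samples)) {
      gt <- matrix(NA_integer_, nrow(cs), length(samples),
                   dimnames = list(NULL, samples))
      if (!is.null(cs$gt)) gt[, colnames(cs$gt)] <- cs$gt
      cs$gt <- gt
    }
    cs
  }))
  rownames(calls) <- NULL

  membership <- cluster_calls(calls, params)
  groups <- split(seq_len(nrow(calls)), membership)
  rows <- lapply(groups, function(idx)
    resolve_consensus(calls[idx, , drop = FALSE], params))
  ok <- !vapply(rows, is.null, logical(1))
  cons <- do.call(rbind, rows[ok])
  if (is.null(cons)) {
    cons <- data.frame(chrom = character(), start = integer(),
                       end = integer(), svtype = character(),
                       svlen = integer(), callers = character(),
                       n_callers = integer(), mate_chrom = character(),
                       mate_pos = integer(), stringsAsFactors = FALSE)
    members <- list()
  } else {
    members <- unname(groups[ok])
  }
  o <- order(cons$chrom, cons$start, cons$svtype)
  cons <- cons[o, , drop = FALSE]
  members <- members[o]
  cons$id <- sprintf("consensus_%05d", seq_len(nrow(cons)))
  cons$members <- members
  rownames(cons) <- NULL
  cons <- cons[, c("id", "chrom", "start", "end", "svtype", "svlen",
                   "callers", "n_callers", "mate_chrom", "mate_pos",
                   "members")]
  attr(cons, "calls") <- calls
  attr(cons, "genotyping_callers") <- genotyping
  class(cons) <- c("sv_consensus", "data.frame")
  if (size_filter) cons <- apply_size_filters(cons)
  cons
}

#' @export
print.sv_consensus <- function(x, ...) {
  cat("sv_consensus:", nrow(x), "merged SVs\n")
  if (nrow(x)) {
    print(table(type = x$svtype, callers = x$n_callers))
  }
  invisible(x)
}

#' Per-type summary of a consensus SV map
#'
#' Counts and length statistics per SV type, plus length histograms binned
#' at 100 bp for deletions and 10 bp for insertions.
#'
#' @param object an `sv_consensus` data frame.
#' @param ... unused.
#' @return a list with `counts` (per-type data frame) and `length_hist`
#'   (named list of binned count tables), classed for printing.
#' @export
summary.sv_consensus <- function(object, ...) {
  counts <- do.call(rbind, lapply(split(object, object$svtype), function(d) {
    data.frame(svtype = d$svtype[1], n = nrow(d),
               mean_len = mean(d$svlen), median_len = median(d$svlen))
  }))
  rownames(counts) <- NULL
  hist_of <- function(type, bin) {
    len <- object$svlen[object$svtype == type]
    if (!length(len)) return(NULL)
    table(bin * (len %/% bin))
  }
  structure(list(counts = counts,
                 length_hist = list(DEL = hist_of("DEL", 100L),
                                    INS = hist_of("INS", 10L))),
            class = "summary.sv_consensus")
}

#' @export
print.summary.sv_consensus <- function(x, ...) {
  print(x$counts)
  invisible(x)
}
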