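#' @importFrom stats median rbinom rnorm rpois runif quantile setNames
#' @importFrom utils read.table write.table head
NULL

SV_TYPES <- c("DEL", "INS", "INV", "DUP", "TRA")

#' Construct a table of structural-variant calls
#'
#' The package represents a call set as a plain `data.frame` (class
#' `sv_calls`) with one row per call and columns `id`, `chrom`, `start`,
#' `end`, `svtype`, `svlen`, `caller`, `mate_chrom`, `mate_pos`. Coordinates
#' are 1-based inclusive (VCF convention). For insertions `end == start` and
#' `svlen` is the inserted-sequence length; for translocations the second
#' breakend lives in `mate_chrom`/`mate_pos` and `svlen` is 0. Per-sample
#' genotypes, when present, are stored in a matrix column `gt` holding the
#' alt-allele dosage (0 = hom ref, 1 = het, 2 = hom alt, `NA` = missing),
#' one column per sample; a matrix column subsets with the rows, so ordinary
#' `data.frame` row indexing keeps calls and genotypes aligned.
#'
#' @param chrom chromosome names.
#' @param start,end 1-based inclusive breakpoints.
#' @param svtype one of `"DEL"`, `"INS"`, `"INV"`, `"DUP"`, `"TRA"`.
#' @param svlen length in bp (absolute value is stored).
#' @param caller caller identifier, recycled.
#' @param id record identifiers; autogenerated when `NULL`.
#' @param gt optional dosage matrix (rows = calls, named columns = samples).
#' @param mate_chrom,mate_pos second breakend, TRA records only.
#' @return a validated `sv_calls` data frame.
#' @export
sv_calls <- function(chrom, start, end, svtype, svlen,
                     caller = "unknown", id = NULL,
                     gt = NULL, mate_chrom = NA_character_,
                     mate_pos = NA_integer_) {
  n <- length(chrom)
  if (is.null(id)) id <- sprintf("%s_sv%05d", rep_len(caller, n), seq_len(n))
  df <- data.frame(
    id = as.character(id),
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    svtype = as.character(svtype),
    svlen = as.integer(abs(as.numeric(svlen))),
    caller = rep_len(as.character(caller), n),
    mate_chrom = rep_len(as.character(mate_chrom), n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    stringsAsFactors = FALSE
  )
  if (!is.null(gt)) {
    gt <- as.matrix(gt)
    stopifnot(nrow(gt) == n, !is.null(colnames(gt)))
    storage.mode(gt) <- "integer"
    df$gt <- gt
  }
  validate_sv_calls(df)
}

validate_sv_calls <- function(df) {
  bad <- !df$svtype %in% SV_TYPES
  if (any(bad)) {
    stop("unknown svtype '", df$svtype[which(bad)[1]],
         "' in record ", which(bad)[1])
  }
  if (any(df$start < 1L)) {
    stop("start < 1 in record ", which(df$start < 1L)[1])
  }
  span <- df$svtype %in% c("DEL", "INV", "DUP")
  if (any(span & df$end < df$start)) {
    stop("end < start in record ", which(span & df$end < df$start)[1])
  }
  sized <- df$svtype %in% c("DEL", "INS", "INV", "DUP")
  if (any(sized & df$svlen <= 0L)) {
    stop("svlen <= 0 in record ", which(sized & df$svlen <= 0L)[1])
  }
  if (!is.null(df$gt) && any(!(df$gt %in% c(0L, 1L, 2L, NA)))) {
    stop("genotype dosages must be 0, 1, 2 or NA")
  }
  class(df) <- unique(c("sv_calls", class(df)))
  df
}

empty_sv_calls <- function(samples = NULL) {
  df <- sv_calls(character(), integer(), integer(), character(), integer())
  if (!is.null(samples)) {
    df$gt <- matrix(NA_integer_, 0, length(samples),
                    dimnames = list(NULL, samples))
  }
  df
}

#' Construct a sample-to-population map
#'
#' @param sample_id sample identifiers (must be unique).
#' @param population population label per sample.
#' @param focal label of the focal population (the one scanned for
#'   selection signatures).
#' @param references labels of the reference populations; defaults to every
#'   non-focal population in the map. The selection scan requires at least
#'   two of them.
#' @return an object of class `population_map`: a list with elements
#'   `samples` (data frame), `focal`, `references`.
#' @export
population_map <- function(sample_id, population, focal, references = NULL) {
  sample_id <- as.character(sample_id)
  population <- as.character(population)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample id: ", sample_id[duplicated(sample_id)][1])
  }
  pops <- unique(population)
  if (!focal %in% pops) stop("focal population '", focal, "' has no samples")
  if (is.null(references)) references <- setdiff(pops, focal)
  if (focal %in% references) stop("focal population cannot also be a reference")
  missing_ref <- setdiff(references, pops)
  if (length(missing_ref)) {
    stop("reference population '", missing_ref[1], "' has no samples")
  }
  structure(
    list(
      samples = data.frame(sample_id = sample_id, population = population,
                           stringsAsFactors = FALSE),
      focal = focal,
      references = references
    ),
    class = "population_map"
  )
}

#' @export
print.population_map <- function(x, ...) {
  tab <- table(x$samples$population)
  cat("population map:", nrow(x$samples), "samples,",
      length(tab), "populations\n")
  cat("  focal:", x$focal, sprintf("(n=%d)\n", tab[[x$focal]]))
  cat("  references:",
      paste(sprintf("%s (n=%d)", x$references, tab[x$references]),
            collapse = ", "), "\n")
  invisible(x)
}

pop_samples <- function(popmap, pops) {
  popmap$samples$sample_id[popmap$samples$population %in% pops]
}

#' @export
print.sv_calls <- function(x, ...) {
  cat("sv_calls:", nrow(x), "calls from",
      length(unique(x$caller)), "caller(s)")
  if (!is.null(x$gt)) cat(";", ncol(x$gt), "genotyped samples")
  cat("\n")
  if (nrow(x)) {
    print(table(x$svtype))
  }
  invisible(x)
}
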