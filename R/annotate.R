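REGION_CLASSES <- c("exonic", "intronic", "upstream_1kb", "downstream_1kb",
                    "intergenic")

#' Classify SVs relative to gene models
#'
#' Each SV interval gets exactly one class by fixed precedence:
#' `exonic` (intersects an exon of any gene) > `intronic` (intersects a
#' gene span but no exon) > `upstream_1kb` > `downstream_1kb` (within
#' `flank` bp of a gene span, strand-aware: upstream is 5' of the gene) >
#' `intergenic`. Interval intersection is closed-interval, so a 1-bp
#' overlap counts. The gene contributing the winning class is reported;
#' when several genes tie, the first by coordinate order.
#'
#' @param svs SV table with `chrom`, `start`, `end` (consensus map,
#'   `sv_calls`, or scan results with `site` coordinates).
#' @param genes a [gene_models] object.
#' @param flank near-gene window in bp (default 1000).
#' @return data frame with one row per SV: `class` (factor over the five
#'   classes) and `gene_id` (`NA` for intergenic).
#' @export
classify_sv <- function(svs, genes, flank = 1000L) {
  sv_gr <- GenomicRanges::GRanges(svs$chrom,
                                  IRanges::IRanges(svs$start, svs$end))
  exons <- attr(genes, "exons")
  gchrom <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  exon_gr <- GenomicRanges::GRanges(gchrom,
                                    IRanges::IRanges(exons$start, exons$end))
  gene_gr <- genes_granges(genes)

  n <- nrow(svs)
  cls <- rep("intergenic", n)
  gid <- rep(NA_character_, n)

  open <- rep(TRUE, n)
  assign_hits <- function(hits, ids, label) {
    q <- S4Vectors::queryHits(hits)
    first <- !duplicated(q) & open[q]
    cls[q[first]] <<- label
    gid[q[first]] <<- ids[S4Vectors::subjectHits(hits)[first]]
    open[q] <<- FALSE
  }

  hits <- GenomicRanges::findOverlaps(sv_gr, exon_gr, ignore.strand = TRUE)
  assign_hits(hits, exons$gene_id, "exonic")
  hits <- GenomicRanges::findOverlaps(sv_gr, gene_gr, ignore.strand = TRUE)
  assign_hits(hits, genes$gene_id, "intronic")

  minus <- genes$strand == "-"
  up_start <- ifelse(minus, genes$end + 1L, pmax(1L, genes$start - flank))
  up_end <- ifelse(minus, genes$end + flank, genes$start - 1L)
  ok <- up_end >= up_start
  up_gr <- GenomicRanges::GRanges(genes$chrom[ok],
                                  IRanges::IRanges(up_start[ok], up_end[ok]))
  hits <- GenomicRanges::findOverlaps(sv_gr, up_gr, ignore.strand = TRUE)
  assign_hits(hits, genes$gene_id[ok], "upstream_1kb")

  dn_start <- ifelse(minus, pmax(1L, genes$start - flank), genes$end + 1L)
  dn_end <- ifelse(minus, genes$start - 1L, genes$end + flank)
  ok <- dn_end >= dn_start
  dn_gr <- GenomicRanges::GRanges(genes$chrom[ok],
                                  IRanges::IRanges(dn_start[ok], dn_end[ok]))
  hits <- GenomicRanges::findOverlaps(sv_gr, dn_gr, ignore.strand = TRUE)
  assign_hits(hits, genes$gene_id[ok], "downstream_1kb")

  data.frame(class = factor(cls, levels = REGION_CLASSES), gene_id = gid,
             stringsAsFactors = FALSE)
}

#' Class-distribution summary of an annotated SV set
#' @param classes the `class` column from [classify_sv].
#' @return data frame with counts and percentages per region class.
#' @export
class_distribution <- function(classes) {
  tab <- table(classes)
  data.frame(class = names(tab), n = as.integer(tab),
             percent = round(100 * as.integer(tab) / sum(tab), 2),
             stringsAsFactors = FALSE)
}

#' Genes overlapped by selection regions
#'
#' Attaches to each region the distinct ids of genes whose spans intersect
#' the region interval (closed-interval, 1 bp suffices).
#'
#' @param regions an `sv_regions` data frame from [build_regions].
#' @param genes a [gene_models] object.
#' @return `regions` with added columns `genes` (list of gene ids) and
#'   `n_genes`; the number of distinct genes covered across all regions is
#'   in `attr(, "n_distinct_genes")`.
#' @export
genes_in_regions <- function(regions, genes) {
  reg_gr <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start,
                                                    regions$end))
  hits <- GenomicRanges::findOverlaps(reg_gr, genes_granges(genes),
                                      ignore.strand = TRUE)
  per_reg <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                   factor(S4Vectors::queryHits(hits),
                          levels = seq_len(nrow(regions))))
  regions$genes <- I(lapply(per_reg, function(g) sort(unique(g))))
  regions$n_genes <- vapply(regions$genes, length, integer(1))
  attr(regions, "n_distinct_genes") <-
    length(unique(unlist(regions$genes)))
  regions
}
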