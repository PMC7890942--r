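#' Gene models
#'
#' Gene models are held as a data frame of class `gene_models` with columns
#' `gene_id`, `chrom`, `start`, `end` (1-based inclusive), `strand`
#' (`"+"`/`"-"`), `biotype`, plus an `exons` attribute: a data frame
#' (`gene_id`, `start`, `end`) of per-gene exon intervals, merged so that
#' no two exons of one gene overlap.
#'
#' @param genes data frame with the columns above.
#' @param exons optional exon data frame; when `NULL` each gene's full span
#'   counts as a single exon.
#' @return a `gene_models` data frame.
#' @export
gene_models <- function(genes, exons = NULL) {
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(genes))) {
    stop("gene table must have columns: ", paste(need, collapse = ", "))
  }
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (is.null(genes$strand)) genes$strand <- "+"
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  if (is.null(genes$biotype)) genes$biotype <- "protein_coding"
  if (any(genes$end < genes$start)) stop("gene with end < start")
  if (is.null(exons)) {
    exons <- data.frame(gene_id = genes$gene_id, start = genes$start,
                        end = genes$end, stringsAsFactors = FALSE)
  }
  exons <- merge_exons(exons, genes)
  genes <- genes[order(genes$chrom, genes$start),
                 c("gene_id", "chrom", "start", "end", "strand", "biotype")]
  rownames(genes) <- NULL
  structure(genes, exons = exons,
            class = c("gene_models", "data.frame"))
}

# union of exon intervals per gene, clipped to the gene span
merge_exons <- function(exons, genes) {
  if (nrow(exons) == 0L) return(exons)
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  span <- genes[match(exons$gene_id, genes$gene_id), ]
  if (anyNA(span$start)) stop("exon with unknown gene_id")
  if (any(exons$start < span$start | exons$end > span$end)) {
    stop("exon outside its gene span")
  }
  pieces <- lapply(split(exons, exons$gene_id), function(e) {
    r <- IRanges::reduce(IRanges::IRanges(e$start, e$end))
    data.frame(gene_id = e$gene_id[1], start = IRanges::start(r),
               end = IRanges::end(r), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Read gene models from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package's 1-based
#' inclusive coordinates on read; a BED line `chr1 999 2000 geneA` becomes a
#' gene spanning 1000-2000. BED has no exon structure, so each gene's span
#' is its single exon. GFF3 input (1-based inclusive) contributes `gene`
#' features and their `exon` descendants (resolved through `mRNA`/
#' `transcript` parents); overlapping exons of a gene are merged.
#'
#' @param path a `.bed`, `.gff3` or `.gff` file.
#' @param format `"auto"` (from extension), `"bed"` or `"gff3"`.
#' @return a [gene_models] data frame.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed(\\.gz)?$", path)) "bed"
              else if (grepl("\\.gff3?(\\.gz)?$", path)) "gff3"
              else stop("cannot infer format of '", path,
                        "'; pass format=\"bed\" or \"gff3\"")
  }
  if (format == "bed") {
    gr <- rtracklayer::import(path, format = "BED")
    if (is.null(gr$name)) gr$name <- sprintf("gene%05d", seq_along(gr))
    genes <- data.frame(
      gene_id = gr$name,
      chrom = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr),   # rtracklayer already 1-based
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
    return(gene_models(genes))
  }
  gr <- rtracklayer::import(path, format = "GFF3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  gid <- as.character(md$ID)
  is_gene <- type == "gene"
  if (!any(is_gene)) stop("no gene features in ", path)
  genes <- data.frame(
    gene_id = gid[is_gene],
    chrom = as.character(GenomicRanges::seqnames(gr))[is_gene],
    start = GenomicRanges::start(gr)[is_gene],
    end = GenomicRanges::end(gr)[is_gene],
    strand = as.character(GenomicRanges::strand(gr))[is_gene],
    biotype = if (!is.null(md$biotype)) as.character(md$biotype)[is_gene]
              else "protein_coding",
    stringsAsFactors = FALSE
  )
  # transcripts map exons up to their gene
  parent <- vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))
  tx <- type %in% c("mRNA", "transcript")
  tx2gene <- setNames(parent[tx], gid[tx])
  is_exon <- type == "exon"
  if (any(is_exon)) {
    owner <- parent[is_exon]
    via_tx <- owner %in% names(tx2gene)
    owner[via_tx] <- tx2gene[owner[via_tx]]
    if (any(!owner %in% genes$gene_id)) {
      stop("exon with unresolvable gene parent at GFF3 record ",
           which(is_exon)[which(!owner %in% genes$gene_id)[1]])
    }
    exons <- data.frame(gene_id = owner,
                        start = GenomicRanges::start(gr)[is_exon],
                        end = GenomicRanges::end(gr)[is_exon],
                        stringsAsFactors = FALSE)
  } else exons <- NULL
  gene_models(genes, exons)
}

#' Write gene models as BED4+strand
#' @param genes a [gene_models] object.
#' @param path output `.bed` path (0-based half-open on disk).
#' @export
write_gene_models_bed <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                   0L, genes$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand, gene_id = genes$gene_id)
}
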