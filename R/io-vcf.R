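GT_TO_DOSAGE <- c("0/0" = 0L, "0|0" = 0L,
                  "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
                  "1/1" = 2L, "1|1" = 2L)

gt_string_to_dosage <- function(gt) {
  out <- unname(GT_TO_DOSAGE[gt])
  out[is.na(gt) | grepl("\\.", gt)] <- NA_integer_
  out
}

dosage_to_gt_string <- function(d) {
  c("0/0", "0/1", "1/1")[d + 1L] -> s
  s[is.na(d)] <- "./."
  s
}

#' Read structural-variant calls from a VCF file
#'
#' Parses a VCF 4.x file whose records carry `SVTYPE` (and `END`/`SVLEN` for
#' non-translocation types) in INFO. When `END` is absent for a spanning
#' record it is reconstructed as `POS + |SVLEN| - 1`. `SVLEN` may be signed
#' (deletions are conventionally negative); the absolute value is stored.
#' `GT` fields, when present, become the dosage matrix column (`0/0` -> 0,
#' `0/1` or `1/0` -> 1, `1/1` -> 2, any `.` allele -> missing). Records with
#' an unknown `SVTYPE` are skipped with a warning; multi-allelic records are
#' rejected because the downstream model treats every site as biallelic.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param caller caller identifier attached to every record; defaults to the
#'   file name without extension.
#' @return an [sv_calls] data frame.
#' @export
read_sv_vcf <- function(path, caller = NULL) {
  if (is.null(caller)) caller <- sub("\\.vcf(\\.gz)?$", "", basename(path))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  if (nrow(fix) == 0L) {
    samples <- colnames(vcf@gt)
    samples <- samples[samples != "FORMAT"]
    return(empty_sv_calls(if (length(samples)) samples else NULL))
  }
  alt <- fix[, "ALT"]
  if (any(grepl(",", alt))) {
    stop("multi-allelic SV record at line-record ",
         which(grepl(",", alt))[1], "; sites must be biallelic")
  }
  svtype <- vcfR::extract.info(vcf, "SVTYPE")
  if (any(is.na(svtype))) {
    stop("record ", which(is.na(svtype))[1], " has no SVTYPE")
  }
  known <- svtype %in% SV_TYPES
  if (!all(known)) {
    warning("skipping ", sum(!known), " record(s) with unknown SVTYPE (",
            paste(unique(svtype[!known]), collapse = ", "), ")")
  }
  pos <- as.integer(fix[, "POS"])
  end <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  svlen <- suppressWarnings(as.numeric(vcfR::extract.info(vcf, "SVLEN")))
  chr2 <- vcfR::extract.info(vcf, "CHR2")
  id <- fix[, "ID"]
  id[is.na(id) | id == "."] <- sprintf("%s_rec%05d", caller,
                                       which(is.na(id) | id == "."))

  span <- svtype %in% c("DEL", "INV", "DUP")
  need_end <- span & is.na(end)
  if (any(need_end & is.na(svlen))) {
    stop("record ", which(need_end & is.na(svlen))[1],
         " lacks both END and SVLEN")
  }
  end[need_end] <- pos[need_end] + abs(svlen[need_end]) - 1L
  svlen[span] <- end[span] - pos[span] + 1L

  is_ins <- svtype == "INS"
  if (any(is_ins & is.na(svlen))) {
    stop("INS record ", which(is_ins & is.na(svlen))[1], " lacks SVLEN")
  }
  end[is_ins] <- pos[is_ins]

  is_tra <- svtype == "TRA"
  mate_chrom <- rep(NA_character_, length(pos))
  mate_pos <- rep(NA_integer_, length(pos))
  if (any(is_tra)) {
    if (any(is_tra & is.na(chr2))) {
      stop("TRA record ", which(is_tra & is.na(chr2))[1], " lacks CHR2")
    }
    mate_chrom[is_tra] <- chr2[is_tra]
    mate_pos[is_tra] <- end[is_tra]
    end[is_tra] <- pos[is_tra]
    svlen[is_tra] <- 0L
  }

  gt <- NULL
  if (!is.null(vcf@gt) && ncol(vcf@gt) > 1L) {
    gts <- vcfR::extract.gt(vcf, element = "GT")
    gt <- matrix(gt_string_to_dosage(gts), nrow = nrow(gts),
                 dimnames = list(NULL, colnames(gts)))
  }

  keep <- which(known)
  sv_calls(chrom = fix[keep, "CHROM"], start = pos[keep], end = end[keep],
           svtype = svtype[keep], svlen = svlen[keep],
           caller = caller, id = id[keep],
           gt = if (is.null(gt)) NULL else gt[keep, , drop = FALSE],
           mate_chrom = mate_chrom[keep], mate_pos = mate_pos[keep])
}

#' Write structural-variant calls to a VCF file
#'
#' Emits a minimal VCF 4.2 file with symbolic ALT alleles and `SVTYPE`,
#' `END`, `SVLEN` INFO fields (`SVLEN` negative for deletions, VCF
#' convention). Consensus records additionally carry `SUPP_CALLERS` (the
#' comma-separated supporting caller set) and `NCALLERS`. Genotypes, when
#' the call set carries them, are written as a `GT` FORMAT column per
#' sample. `read_sv_vcf()` of the written file reproduces the call set
#' field for field.
#'
#' @param calls an [sv_calls] or [merge_callsets()] consensus data frame,
#'   sorted by (chrom, start).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sv_vcf <- function(calls, path) {
  if (nrow(calls)) {
    o <- order(calls$chrom, calls$start)
    if (!identical(o, seq_len(nrow(calls)))) {
      stop("calls must be sorted by (chrom, start) before writing")
    }
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=svpopscan",
    '##ALT=<ID=DEL,Description="Deletion">',
    '##ALT=<ID=INS,Description="Insertion">',
    '##ALT=<ID=INV,Description="Inversion">',
    '##ALT=<ID=DUP,Description="Duplication">',
    '##ALT=<ID=TRA,Description="Translocation">',
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=SVLEN,Number=1,Type=Integer,Description="SV length">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Mate chromosome (TRA)">',
    '##INFO=<ID=SUPP_CALLERS,Number=.,Type=String,Description="Supporting callers">',
    '##INFO=<ID=NCALLERS,Number=1,Type=Integer,Description="Number of distinct supporting callers">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'
  )
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_gt <- !is.null(calls$gt)
  if (has_gt) cols <- c(cols, "FORMAT", colnames(calls$gt))
  lines <- c(hdr, paste(cols, collapse = "\t"))
  if (nrow(calls)) {
    is_tra <- calls$svtype == "TRA"
    end_field <- ifelse(is_tra, calls$mate_pos, calls$end)
    svlen_field <- ifelse(calls$svtype == "DEL", -calls$svlen, calls$svlen)
    info <- sprintf("SVTYPE=%s;END=%d;SVLEN=%d",
                    calls$svtype, end_field, svlen_field)
    info[is_tra] <- sprintf("%s;CHR2=%s", info[is_tra],
                            calls$mate_chrom[is_tra])
    if (!is.null(calls$callers)) {
      info <- sprintf("%s;SUPP_CALLERS=%s;NCALLERS=%d",
                      info, calls$callers, calls$n_callers)
    }
    rec <- paste(calls$chrom, calls$start, calls$id, "N",
                 sprintf("<%s>", calls$svtype), ".", "PASS", info,
                 sep = "\t")
    if (has_gt) {
      gts <- apply(calls$gt, 1L,
                   function(d) paste(dosage_to_gt_string(d), collapse = "\t"))
      rec <- paste(rec, "GT", gts, sep = "\t")
    }
    lines <- c(lines, rec)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a sample-to-population map from TSV
#'
#' @param path TSV file with a header and columns `sample_id`, `population`.
#' @inheritParams population_map
#' @return a [population_map].
#' @export
read_population_map <- function(path, focal, references = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("sample_id", "population")
  if (!all(need %in% names(df))) {
    stop("population map must have columns: ", paste(need, collapse = ", "))
  }
  population_map(df$sample_id, df$population, focal, references)
}

#' Write a population map to TSV
#' @param popmap a [population_map].
#' @param path output file.
#' @export
write_population_map <- function(popmap, path) {
  write.table(popmap$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
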