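# brute-force per-base classifier: paints the chromosome with the class
# masks and applies the precedence exonic > intronic > upstream >
# downstream > intergenic to each SV interval
oracle_classify <- function(svs, genes, L, flank = 1000) {
  exons <- attr(genes, "exons")
  rng <- function(a, b) if (b < a) integer() else seq.int(a, b)
  exon_mask <- logical(L); gene_mask <- logical(L)
  up_mask <- logical(L); dn_mask <- logical(L)
  for (i in seq_len(nrow(genes))) {
    gene_mask[genes$start[i]:genes$end[i]] <- TRUE
    before <- rng(max(1, genes$start[i] - flank), genes$start[i] - 1)
    after <- rng(genes$end[i] + 1, min(L, genes$end[i] + flank))
    if (genes$strand[i] == "+") { up <- before; dn <- after }
    else { up <- after; dn <- before }
    if (length(up)) up_mask[up] <- TRUE
    if (length(dn)) dn_mask[dn] <- TRUE
  }
  for (i in seq_len(nrow(exons))) {
    exon_mask[exons$start[i]:exons$end[i]] <- TRUE
  }
  vapply(seq_len(nrow(svs)), function(i) {
    iv <- svs$start[i]:svs$end[i]
    if (any(exon_mask[iv])) "exonic"
    else if (any(gene_mask[iv])) "intronic"
    else if (any(up_mask[iv])) "upstream_1kb"
    else if (any(dn_mask[iv])) "downstream_1kb"
    else "intergenic"
  }, character(1))
}

one_gene <- function(strand = "+") {
  gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", start = 10000L, end = 20000L,
               strand = strand),
    data.frame(gene_id = "g1", start = c(10000L, 19000L),
               end = c(11000L, 20000L)))
}

sv_at <- function(start, end) {
  data.frame(chrom = "chr1", start = start, end = end)
}

test_that("classification follows the fixed precedence", {
  g <- one_gene()
  # wholly inside the intron between the two exons
  expect_equal(as.character(classify_sv(sv_at(12000L, 12140L), g)$class),
               "intronic")
  # 1 bp of exon overlap wins over the intronic stretch
  expect_equal(as.character(classify_sv(sv_at(11000L, 12000L), g)$class),
               "exonic")
  # 5 kb from the gene: intergenic
  expect_equal(as.character(classify_sv(sv_at(25001L, 25500L), g)$class),
               "intergenic")
  # 500 bp before the start of a + gene is upstream; after the end, downstream
  expect_equal(as.character(classify_sv(sv_at(9400L, 9500L), g)$class),
               "upstream_1kb")
  expect_equal(as.character(classify_sv(sv_at(20500L, 20600L), g)$class),
               "downstream_1kb")
  # strand awareness: on a - gene the same flanks swap roles
  gm <- one_gene("-")
  expect_equal(as.character(classify_sv(sv_at(9400L, 9500L), gm)$class),
               "downstream_1kb")
  expect_equal(as.character(classify_sv(sv_at(20500L, 20600L), gm)$class),
               "upstream_1kb")
  # exactly 1000 bp away still counts, 1001 does not
  expect_equal(as.character(classify_sv(sv_at(9000L, 9000L), g)$class),
               "upstream_1kb")
  expect_equal(as.character(classify_sv(sv_at(8999L, 8999L), g)$class),
               "intergenic")
})

test_that("every SV receives exactly one class", {
  g <- one_gene()
  svs <- sv_at(seq(8000L, 22000L, by = 500L),
               seq(8000L, 22000L, by = 500L) + 200L)
  cls <- classify_sv(svs, g)$class
  expect_false(anyNA(cls))
  expect_true(all(as.character(cls) %in%
                    c("exonic", "intronic", "upstream_1kb",
                      "downstream_1kb", "intergenic")))
})

test_that("classification matches the per-base oracle on random layouts", {
  set.seed(61)
  L <- 100000L
  for (rep in 1:5) {
    n_genes <- 6
    gs <- sort(sample(seq(1000L, L - 6000L), n_genes))
    genes_df <- data.frame(
      gene_id = sprintf("g%d", seq_len(n_genes)), chrom = "chr1",
      start = gs, end = pmin(gs + sample(1500:4000, n_genes), L),
      strand = sample(c("+", "-"), n_genes, replace = TRUE))
    exons_df <- do.call(rbind, lapply(seq_len(n_genes), function(i) {
      st <- sort(sample(genes_df$start[i]:genes_df$end[i], 4))
      data.frame(gene_id = genes_df$gene_id[i],
                 start = st[c(1, 3)],
                 end = pmin(st[c(1, 3)] + 200L, genes_df$end[i]))
    }))
    g <- gene_models(genes_df, exons_df)
    st <- sample(seq_len(L - 500L), 120)
    svs <- sv_at(st, st + sample(50:400, 120, replace = TRUE))
    got <- as.character(classify_sv(svs, g)$class)
    want <- oracle_classify(svs, g, L)
    expect_equal(got, want)
  }
})

test_that("class histograms agree with the oracle on a simulated bundle", {
  cfg <- small_sim_config(seed = 67)
  truth <- simulate_truth(cfg)
  genes <- simulate_genes(cfg)
  svs <- truth$svs[truth$svs$svtype != "TRA", ]
  got <- as.character(classify_sv(svs, genes)$class)
  exons <- attr(genes, "exons")
  want <- unlist(lapply(split(seq_len(nrow(svs)), svs$chrom), function(idx) {
    cc <- svs$chrom[idx[1]]
    on_cc <- genes$chrom == cc
    sub <- gene_models(as.data.frame(genes)[on_cc, ],
                       exons[exons$gene_id %in% genes$gene_id[on_cc], ])
    oracle_classify(svs[idx, , drop = FALSE], sub, L = cfg$genome[[cc]])
  }))
  lv <- c("exonic", "intronic", "upstream_1kb", "downstream_1kb",
          "intergenic")
  expect_equal(table(factor(got, lv)), table(factor(want, lv)))
})

test_that("regions collect the distinct genes they intersect", {
  genes <- gene_models(data.frame(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    start = c(1000L, 8000L, 50000L), end = c(2000L, 9000L, 60000L),
    strand = "+"))
  reg <- data.frame(chrom = "chr1", start = c(500L, 30000L, 60000L),
                    end = c(9500L, 40000L, 60500L))
  reg$sites <- list("s1", "s2", "s3")
  class(reg) <- c("sv_regions", "data.frame")
  out <- genes_in_regions(reg, genes)
  expect_equal(out$genes[[1]], c("gA", "gB"))   # two whole genes
  expect_equal(out$n_genes[2], 0L)              # gene desert
  expect_equal(out$genes[[3]], "gC")            # 1 bp overlap suffices
  expect_equal(attr(out, "n_distinct_genes"), 3L)
})
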