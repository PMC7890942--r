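test_that("dAF is the absolute focal-vs-mean-reference difference", {
  expect_equal(delta_af(0.9, c(0.1, 0.1)), 0.8)
  expect_equal(delta_af(0.4, c(0.4, 0.4)), 0)
  expect_equal(delta_af(0.0, c(0.5, 0.7)), 0.6)
  # vectorised over sites
  refs <- rbind(c(0.1, 0.1), c(0.5, 0.7))
  expect_equal(delta_af(c(0.9, 0.0), refs), c(0.8, 0.6))
})

test_that("RFD scales the signed difference by the pooled frequency", {
  # equal sizes, focal 0.6 vs refs 0.2/0.2: pooled 1/3, RFD 1.2
  expect_equal(rfd(0.6, c(0.2, 0.2), 1 / 3), 1.2)
  expect_equal(rfd(0.4, c(0.4, 0.4), 0.4), 0)
  expect_equal(rfd(0.0, c(0.3, 0.3), 0.2), -1.5)
  expect_error(rfd(0.5, c(0.5, 0.5), 0), "scan_filter")
})

test_that("dAF stays in [0,1] and RFD sign tracks the focal shift", {
  set.seed(37)
  f_focal <- runif(10000)
  f_refs <- cbind(runif(10000), runif(10000))
  f_pool <- (f_focal + f_refs[, 1] + f_refs[, 2]) / 3
  f_pool <- pmax(f_pool, 0.01)
  d <- delta_af(f_focal, f_refs)
  r <- rfd(f_focal, f_refs, f_pool)
  expect_true(all(d >= 0 & d <= 1))
  expect_true(all(sign(r) == sign(f_focal - rowMeans(f_refs))))
  expect_equal(abs(r) > 0, d > 0)
})

test_that("the top-fraction rule uses the nearest-rank percentile with strict >", {
  flags <- empirical_top_fraction(1:100)
  expect_equal(which(flags), 96:100)
  expect_equal(attr(flags, "cutoff"), 95)

  flags20 <- empirical_top_fraction(1:20)
  expect_equal(which(flags20), 20L)

  expect_warning(empirical_top_fraction(1:19), "20")  # small-sample warning
  expect_warning(none <- empirical_top_fraction(rep(3, 15)))
  expect_false(any(none))                    # degenerate ties flag nothing
  expect_error(empirical_top_fraction(numeric()), "empty")
})

test_that("scan filters keep only eligible deletion sites", {
  sites <- data.frame(
    id = sprintf("s%d", 1:6),
    chrom = "chr1", start = 1000L * (1:6), end = 1000L * (1:6) + 10L,
    svtype = c("DEL", "DEL", "DEL", "DUP", "DEL", "DEL"),
    svlen = c(5000, 150000, 5000, 5000, 100000, 100001))
  freq <- data.frame(site = sites$id,
                     af_MS = 0.5, n_MS = 10,
                     af_DU = 0.5, n_DU = 10,
                     af_TB = 0.5, n_TB = c(10, 10, 10, 10, 10, 10),
                     af_all = c(0.5, 0.5, 0.009, 0.5, 0.5, 0.5),
                     n_all = 30)
  pm <- population_map(c("m", "d", "t"), c("MS", "DU", "TB"), focal = "MS")
  out <- scan_filter(freq, sites, pm)
  # s2 too long, s3 too rare, s4 not a deletion, s6 one bp over 100 kb
  expect_setequal(out$site, c("s1", "s5"))

  freq$n_TB <- c(10, 10, 10, 10, 0, 10)   # s5 loses its last TB genotype
  out2 <- scan_filter(freq, sites, pm)
  expect_equal(out2$site, "s1")
})

test_that("significance demands both statistics, not either", {
  # 40 sites: one huge dAF with weak RFD, one the reverse, one strong both
  n <- 40
  ids <- sprintf("s%02d", 1:n)
  sites <- data.frame(id = ids, chrom = "chr1",
                      start = 10000L * (1:n), end = 10000L * (1:n) + 500L,
                      svtype = "DEL", svlen = 500)
  af_ms <- rep(0.30, n); af_du <- rep(0.30, n); af_tb <- rep(0.30, n)
  af_ms[1] <- 0.95; af_du[1] <- 0.90; af_tb[1] <- 0.10  # big dAF, small RFD
  af_ms[2] <- 0.052; af_du[2] <- 0.001; af_tb[2] <- 0.001 # big RFD, small dAF
  af_ms[3] <- 0.90; af_du[3] <- 0.05; af_tb[3] <- 0.05  # big both
  jitter <- seq(0, 0.004, length.out = n)
  af_du <- af_du + jitter                                # break ties
  freq <- data.frame(site = ids, af_MS = af_ms, n_MS = 50,
                     af_DU = af_du, n_DU = 50, af_TB = af_tb, n_TB = 50,
                     af_all = (af_ms + af_du + af_tb) / 3, n_all = 150)
  pm <- population_map(c("m", "d", "t"), c("MS", "DU", "TB"), focal = "MS")
  filtered <- scan_filter(freq, sites, pm)
  f_refs <- as.matrix(filtered[c("af_DU", "af_TB")])
  d <- delta_af(filtered$af_MS, f_refs)
  r <- rfd(filtered$af_MS, f_refs, filtered$af_all)
  pass_d <- empirical_top_fraction(d)
  pass_r <- empirical_top_fraction(r)
  expect_true(pass_d[1] && !pass_r[1])
  expect_true(pass_r[2] && !pass_d[2])
  expect_true(pass_d[3] && pass_r[3])
})

test_that("run_scan intersects the two top tails", {
  ts <- truth_scan(n_sites = 400, n_selected = 8, seed = 43)
  r <- ts$scan$results
  expect_true(all(r$significant == (r$pass_daf & r$pass_rfd)))
  expect_lte(sum(r$significant), min(sum(r$pass_daf), sum(r$pass_rfd)))
  expect_lte(sum(r$pass_daf), floor(0.05 * nrow(r)))
  expect_lte(sum(r$pass_rfd), floor(0.05 * nrow(r)))
})

test_that("reference labels are exchangeable in dAF and a focal relabel is too", {
  ts <- truth_scan(n_sites = 500, n_selected = 0, seed = 47)
  fr <- allele_frequencies(ts$truth$svs$gt, ts$truth$popmap)
  d1 <- delta_af(fr$af_MS, as.matrix(fr[c("af_DU", "af_TB")]))
  d2 <- delta_af(fr$af_MS, as.matrix(fr[c("af_TB", "af_DU")]))
  expect_identical(d1, d2)
  # neutral equal-size populations: relabelling the focal population leaves
  # the dAF distribution statistically exchangeable
  d3 <- delta_af(fr$af_DU, as.matrix(fr[c("af_MS", "af_TB")]))
  expect_lt(abs(mean(d1) - mean(d3)), 5 * sd(c(d1, d3)) / sqrt(length(d1)))
})

test_that("regions chain nearby significant sites and respect chromosomes", {
  res <- data.frame(
    site = sprintf("s%d", 1:5),
    chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    start = c(1000L, 2500L, 400000L, 1000L, 500000L),
    end = c(2000L, 3000L, 401000L, 2000L, 501000L),
    significant = c(TRUE, TRUE, TRUE, TRUE, TRUE))
  reg <- build_regions(res, join_gap = 1e5)
  expect_equal(nrow(reg), 4L)
  r1 <- reg[reg$chrom == "chr1" & reg$start == 1000L, ]
  expect_equal(r1$end, 3000L)          # 500 bp gap joined
  expect_equal(r1$n_sites, 2L)
  expect_true(all(reg$end >= reg$start))
  # a single significant site spans exactly itself
  single <- build_regions(res[3, ], join_gap = 1e5)
  expect_equal(c(single$start, single$end), c(400000L, 401000L))
  # chr1 and chr2 sites at identical coordinates never merge
  expect_equal(sum(reg$chrom == "chr2"), 2L)
})

test_that("planted selected deletions are recovered above the neutral rate", {
  rates <- scan_rates(truth_scan(n_sites = 1000, n_selected = 20, seed = 53))
  expect_gt(rates["recovery"], rates["neutral_rate"])
  expect_gt(rates["recovery"], 0.5)
})

test_that("scan result tables and region BED files round-trip sensibly", {
  ts <- truth_scan(n_sites = 300, n_selected = 10, seed = 59)
  path <- tempfile(fileext = ".tsv")
  write_scan_results(ts$scan, path)
  back <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(back), nrow(ts$scan$results))
  expect_equal(back$delta_af, ts$scan$results$delta_af)

  reg <- build_regions(ts$scan)
  if (nrow(reg)) {
    bed <- tempfile(fileext = ".bed")
    write_regions_bed(reg, bed)
    raw <- read.table(bed, sep = "\t")
    expect_equal(raw[[2]], reg$start - 1L)   # BED is 0-based half-open
    expect_equal(raw[[3]], reg$end)
  }
})
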