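test_that("methylation windows classify on a strict 40% cutoff", {
  meth <- data.frame(chrom = "chr1",
                     start = c(0L, 100L, 200L, 300L),
                     end = c(100L, 200L, 300L, 400L),
                     value = c(50, 40, 45, NA))
  mr <- methylated_regions(meth)
  # 50% methylated; exactly 40% is unmethylated; NA (no CG) unmethylated;
  # adjacent windows of the same state merge
  expect_equal(mr$methylated$start, c(0L, 200L))
  expect_equal(mr$methylated$end, c(100L, 300L))
  expect_equal(mr$unmethylated$start, c(100L, 300L))
  expect_equal(mr$unmethylated$end, c(200L, 400L))
  meth2 <- meth; meth2$start[2] <- 50L
  expect_error(methylated_regions(meth2), "multiples of 100")
  meth3 <- meth; meth3$value[1] <- 120
  expect_error(methylated_regions(meth3), "0, 100")
  # adjacent methylated windows merge into one interval
  meth4 <- data.frame(chrom = "chr1", start = c(0L, 100L),
                      end = c(100L, 200L), value = c(60, 70))
  expect_equal(nrow(methylated_regions(meth4)$methylated), 1)
})

test_that("pericentromere = centromere plus clipped flanks", {
  cen <- interval_track(data.frame(chrom = c("chr1", "chr2"),
                                   start = c(100e6, 10e6),
                                   end = c(105e6, 15e6)))
  lens <- c(chr1 = 300e6, chr2 = 100e6)
  p <- pericentromere(cen, lens, flank = 40e6)
  expect_equal(p$start, c(60e6, 0))        # chr2 clipped at 0
  expect_equal(p$end, c(145e6, 55e6))
  p0 <- pericentromere(cen, lens, flank = 0)
  expect_equal(p0$start, cen$start)
  expect_equal(p0$end, cen$end)
  expect_error(pericentromere(cen, c(lens, chr3 = 50e6)),
               "without a centromere")
})

test_that("SNP-in-interval membership uses the half-open convention", {
  snps <- data.frame(chrom = "chr1", pos = c(100L, 150L),
                     ref = "A", alt = "C", id = NA)
  expect_equal(snps_in_track(snps, interval_track(
    data.frame(chrom = "chr1", start = 99, end = 100))), c(TRUE, FALSE))
  expect_equal(snps_in_track(snps, interval_track(
    data.frame(chrom = "chr1", start = 100, end = 200))),
    c(FALSE, TRUE))
  st <- stratify_snps(snps, interval_track(
    data.frame(chrom = "chr1", start = 99, end = 100)))
  expect_equal(nrow(st$inside) + nrow(st$outside), nrow(snps))
})

test_that("interval algebra: merge-then-stratify = stratify-then-merge", {
  sim <- small_sim()
  panel <- small_panel()
  raw <- data.frame(chrom = "chr1",
                    start = c(1000L, 1500L, 4000L),
                    end = c(2000L, 2500L, 5000L))
  merged <- interval_track(raw, merge = TRUE)
  m1 <- snps_in_track(panel$snps, merged)
  m2 <- snps_in_track(panel$snps, raw[1, , drop = FALSE]) |
    snps_in_track(panel$snps, raw[2, , drop = FALSE]) |
    snps_in_track(panel$snps, raw[3, , drop = FALSE])
  expect_identical(m1, m2)
})

test_that("stratified [AT]-difference recovers the planted region effects", {
  sim <- small_sim()
  panel <- small_panel()
  in_peri <- snps_in_track(panel$snps, sim$peri)
  res <- stratified_at_difference(panel$geno, panel$snps, panel$groups,
                                  list(all = rep(TRUE, nrow(panel$snps)),
                                       peri = in_peri, arm = !in_peri,
                                       empty = rep(FALSE,
                                                   nrow(panel$snps))))
  # whole-set stratum equals the global group difference
  at <- compute_at(panel$geno, panel$snps)
  gs <- group_separation(at$at, panel$groups)
  expect_equal(res$at_diff[res$stratum == "all"], gs$difference,
               tolerance = 1e-12)
  # planted pericentromeric excess
  expect_gt(res$at_diff[res$stratum == "peri"],
            res$at_diff[res$stratum == "arm"])
  expect_false(res$defined[res$stratum == "empty"])
})

test_that("rate correlations behave and detect the planted coupling", {
  tr <- data.frame(chrom = "chr1", start = (0:9) * 100L,
                   end = (1:10) * 100L, at_diff = seq(0.01, 0.1, by = 0.01))
  rate_same <- interval_track(data.frame(chrom = tr$chrom, start = tr$start,
                                         end = tr$end,
                                         value = tr$at_diff))
  expect_equal(rate_correlation(tr, rate_same)$r, 1)
  rate_neg <- rate_same; rate_neg$value <- -rate_neg$value
  expect_equal(rate_correlation(tr, rate_neg)$r, -1)
  # affine rescaling leaves the correlation unchanged
  rate_aff <- rate_same; rate_aff$value <- 3 * rate_aff$value + 5
  expect_equal(rate_correlation(tr, rate_aff)$r, 1)
  # fewer than 3 complete pairs is flagged undefined
  short <- tr[1:2, ]
  expect_false(rate_correlation(short, rate_same)$defined)

  # planted: low recombination in the pericentromere, where delta is doubled
  sim <- small_sim()
  panel <- small_panel()
  wat <- windowed_at(panel$geno, panel$snps, sim$lens,
                     window = 5e4, step = 5e4, min_snps = 20)
  wd <- windowed_at_difference(wat, panel$groups)
  wd0 <- data.frame(chrom = wd$chrom, start = wd$start - 1L, end = wd$end,
                    at_diff = wd$at_diff)
  rc <- rate_correlation(wd0, sim$recomb)
  expect_true(all(rc$r < 0))
})

test_that("windowed MAF is flat when allele frequencies are flat", {
  snps <- data.frame(chrom = "chr1", pos = 10L * (1:50),
                     ref = "A", alt = "G", id = NA)
  geno <- rbind(matrix(0L, 5, 50), matrix(1L, 5, 50))  # MAF 0.5 everywhere
  win <- make_windows(c(chr1 = 1000L), window = 250, step = 250)
  wm <- windowed_maf(geno, snps, win)
  expect_equal(wm$mean_maf[!wm$masked],
               rep(0.5, sum(!wm$masked)))
  expect_true(all(wm$masked[wm$n_snps == 0]))
  # planted: depressed MAF inside the pericentromere
  sim <- small_sim()
  panel <- small_panel()
  win2 <- make_windows(sim$lens, window = 5e4, step = 5e4)
  wm2 <- windowed_maf(panel$geno, panel$snps, win2)
  p <- sim$peri[1, ]
  mid <- (wm2$start + wm2$end) / 2
  in_peri <- mid >= p$start & mid < p$end
  expect_lt(mean(wm2$mean_maf[in_peri & !wm2$masked]),
            mean(wm2$mean_maf[!in_peri & !wm2$masked]))
})
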