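test_that("substitution types are unordered allele pairs", {
  expect_equal(classify_substitution("C", "T"), "C/T")
  expect_equal(classify_substitution("T", "C"), "C/T")
  expect_equal(classify_substitution(c("G", "A"), c("T", "G")),
               c("G/T", "A/G"))
})

test_that("common filter applies the MAF and missing-rate thresholds", {
  snps <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L, 40L),
                     ref = "A", alt = "G", id = NA)
  n <- 100
  geno <- cbind(
    c(rep(1L, 4), rep(0L, 96)),                       # MAF 0.04 -> drop
    c(rep(1L, 50), rep(0L, 25), rep(NA, 25)),         # 25% missing -> drop
    c(rep(1L, 45), rep(0L, 45), rep(NA, 10)),         # 50/50, 10% miss -> keep
    c(rep(1L, 5), rep(0L, 95))                        # MAF exactly 0.05 -> keep
  )
  out <- filter_common(snps, geno)
  expect_equal(out$kept, c(FALSE, FALSE, TRUE, TRUE))
  # monomorphic dropped; emptied result warns instead of erroring
  expect_warning(filter_common(snps[1, , drop = FALSE],
                               matrix(0L, n, 1)), "removed")
})

test_that("[AT] is the fraction of carried alleles that are A or T", {
  snps <- data.frame(chrom = "chr1", pos = c(1L, 2L, 3L, 4L) * 10L,
                     ref = c("A", "T", "G", "C"),
                     alt = c("G", "C", "A", "T"), id = NA)
  geno <- toy_matrix(list(c(0L, 0L, 0L, 0L),   # A T G C -> 0.5
                          c(1L, 1L, 1L, 1L),   # G C A T -> 0.5
                          c(0L, 0L, 1L, 1L)))  # A T A T -> 1.0
  bc <- compute_at(geno, snps)
  expect_equal(bc$at, c(0.5, 0.5, 1.0))
  expect_equal(bc$A + bc$C + bc$G + bc$T, rep(1, 3), tolerance = 1e-12)

  # missing calls shrink the denominator
  snps10 <- data.frame(chrom = "chr1", pos = 10L * (1:10),
                       ref = c("A", "A", "T", "T", "G", "G", "C", "C",
                               "A", "G"),
                       alt = c("G", "G", "C", "C", "A", "A", "T", "T",
                               "G", "A"), id = NA)
  calls <- c(rep(0L, 8), NA, NA)
  bc10 <- compute_at(toy_matrix(list(calls)), snps10)
  expect_equal(bc10$at, 0.5)
  expect_equal(bc10$n_sites, 8)
  # zero non-missing sites -> flagged undefined
  bc0 <- compute_at(toy_matrix(list(rep(NA_integer_, 10))), snps10)
  expect_false(bc0$defined)
  expect_true(is.na(bc0$at))
})

test_that("per-type composition matches a hand tally and decomposes [AT]", {
  # one site per substitution type, hand-countable
  snps <- data.frame(chrom = "chr1", pos = 10L * (1:6),
                     ref = c("A", "A", "A", "C", "C", "G"),
                     alt = c("C", "G", "T", "G", "T", "T"), id = NA)
  geno <- toy_matrix(list(c(0L, 1L, 1L, 0L, 1L, 1L)))  # A G T C T T
  ct <- composition_by_type(geno, snps)
  ct1 <- ct[ct$accession == "acc1", ]
  # conditional fractions: each type has exactly 1 site here
  expect_equal(ct1$share, rep(1 / 6, 6))
  expect_equal(ct1$at[ct1$type == "C/T"], 1)   # carries T
  expect_equal(ct1$at[ct1$type == "A/C"], 1)   # carries A
  expect_equal(ct1$at[ct1$type == "C/G"], 0)   # carries C
  # decomposition: sum over types of share x conditional [AT] = overall [AT]
  overall <- compute_at(geno, snps)$at
  expect_equal(sum(ct1$share * ct1$at), overall, tolerance = 1e-9)

  # absent type flagged
  snps2 <- snps[snps$ref != "C" | snps$alt != "G", ]
  geno2 <- geno[, c(1:3, 5:6), drop = FALSE]
  ct2 <- composition_by_type(geno2, snps2)
  expect_false(ct2$defined[ct2$type == "C/G"])
})

test_that("per-type decomposition holds on the simulated panel", {
  panel <- small_panel()
  idx <- 1:10
  geno <- panel$geno[idx, , drop = FALSE]
  overall <- compute_at(geno, panel$snps)
  ct <- composition_by_type(geno, panel$snps)
  for (a in overall$accession) {
    sub <- ct[ct$accession == a & ct$defined, ]
    expect_equal(sum(sub$share * sub$at), overall$at[overall$accession == a],
                 tolerance = 1e-9)
  }
})

test_that("windowed [AT] is consistent with the global value", {
  panel <- small_panel()
  sim <- small_sim()
  wat <- windowed_at(panel$geno, panel$snps, sim$lens,
                     window = 1e5, step = 1e5, min_snps = 1)
  expect_false(any(wat$windows$masked))
  # SNP-weighted mean of tiling windows equals the global [AT] exactly
  global <- compute_at(panel$geno, panel$snps)$at
  # per accession the weights are its own non-missing counts per window
  for (j in c(1, 75, 150)) {
    w_counts <- vapply(seq_len(nrow(wat$windows)), function(w) {
      sel <- panel$snps$pos >= wat$windows$start[w] &
        panel$snps$pos <= wat$windows$end[w]
      sum(!is.na(panel$geno[j, sel]))
    }, numeric(1))
    expect_equal(sum(wat$at[, j] * w_counts) / sum(w_counts), global[j],
                 tolerance = 1e-12)
  }
  # low-coverage windows are masked, not dropped
  wat2 <- windowed_at(panel$geno, panel$snps, sim$lens,
                      window = 1e5, step = 1e5, min_snps = 1e6)
  expect_true(all(wat2$windows$masked))
  expect_equal(nrow(wat2$windows), nrow(wat$windows))
  expect_error(windowed_at(panel$geno, panel$snps, sim$lens,
                           window = 0, step = 1e5), "positive")
})

test_that("a planted high-AT region is the windowed-track maximum", {
  cfg <- sim_config(n_chrom = 1, chrom_length = 5e5, n_genes = 0,
                    pericentromere_flank = 1e5, n_common_snps = 8000,
                    peri_delta_mult = 1,
                    hotspot = list(chrom = "chr1", start = 0L, end = 5e4L,
                                   mult = 6),
                    seed = 99)
  sim <- simulate_genome(cfg)
  panel <- simulate_common_panel(cfg, sim)
  wat <- windowed_at(panel$geno, panel$snps, sim$lens,
                     window = 5e4, step = 5e4, min_snps = 10)
  wd <- windowed_at_difference(wat, panel$groups)
  expect_equal(which.max(wd$at_diff), 1L)
})

test_that("group separation reports difference, test statistic and p-value", {
  groups <- factor(rep(c("wild", "landrace"), each = 5),
                   levels = c("wild", "landrace", "improved"))
  expect_equal(group_separation(rep(0.4, 10), groups)$p.value, 1)
  expect_equal(group_separation(rep(0.4, 10), groups)$difference, 0)

  set.seed(1)
  at <- c(rnorm(5, 0.38, 1e-4), rnorm(5, 0.41, 1e-4))
  gs <- group_separation(at, groups)
  expect_equal(gs$difference, 0.03, tolerance = 0.01)
  expect_lt(gs$p.value, 1e-6)
  gsw <- group_separation(at, groups, test = "wilcoxon")
  expect_lt(gsw$p.value, 0.05)
  expect_error(group_separation(at[-(1:4)], groups[-(1:4)]), "at least 2")
})

test_that("outputs are invariant to permuting accessions and sites", {
  panel <- small_panel()
  idx_acc <- sample(nrow(panel$geno))
  idx_site <- sample(nrow(panel$snps))
  bc1 <- compute_at(panel$geno, panel$snps)
  bc2 <- compute_at(panel$geno[idx_acc, idx_site],
                    panel$snps[idx_site, ])
  expect_equal(bc2$at[order(idx_acc)], bc1$at)
  gs1 <- group_separation(bc1$at, panel$groups)
  gs2 <- group_separation(bc2$at, panel$groups[idx_acc])
  expect_equal(gs1$difference, gs2$difference)
  expect_equal(gs1$p.value, gs2$p.value)
})
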