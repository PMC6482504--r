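test_that("polarization keeps matching outgroup alleles only", {
  snps <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L),
                     ref = c("C", "C", "G"), alt = c("T", "T", "A"),
                     id = NA)
  pol <- suppressMessages(polarize(snps, c("C", "G", NA)))
  expect_equal(nrow(pol), 1)
  expect_equal(pol$ancestral, "C")
  expect_equal(pol$derived, "T")
  excl <- attr(pol, "exclusions")
  expect_equal(unname(excl["missing_outgroup"]), 1)
  expect_equal(unname(excl["outgroup_matches_neither"]), 1)
  # outgroup matching alt polarizes the other way
  pol2 <- polarize(snps[1, ], "T")
  expect_equal(pol2$ancestral, "T")
  expect_equal(pol2$derived, "C")
})

test_that("private-set calling follows the printed definitions", {
  # 9 accessions, 3 per group; ancestral = ref at all sites
  groups <- factor(rep(c("wild", "landrace", "improved"), each = 3),
                   levels = c("wild", "landrace", "improved"))
  snps <- data.frame(chrom = "chr1", pos = 10L * (1:6), ref = "C",
                     alt = "T", id = NA, ancestral = "C", derived = "T")
  geno <- cbind(
    c(0L, 1L, 0L, 0L, 0L, 0L, 0L, 0L, 0L),  # seg wild only -> PW
    c(0L, 0L, 0L, 0L, 1L, 0L, 1L, 0L, 0L),  # seg landrace+improved -> PD only
    c(0L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),  # seg landrace only -> PL (and PD)
    c(1L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 0L),  # seg wild and landrace -> none
    c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 0L),  # seg improved only -> PI (and PD)
    c(NA, NA, NA, 0L, 1L, 0L, 0L, 0L, 0L)   # wild all missing -> unassignable
  )
  cp <- call_private(geno, groups, snps)
  expect_equal(cp$PW, 1L)
  expect_setequal(cp$PD, c(2L, 3L, 5L))
  expect_equal(cp$PL, 3L)
  expect_equal(cp$PI, 5L)
  expect_equal(cp$unassignable, 6L)
  expect_equal(unname(cp$overlap["PD_only"]), 1L)
  # call-rate floor: fixation needs >= 80% calls in the fixed group
  geno2 <- cbind(c(0L, 1L, 0L, NA, NA, 0L, 0L, 0L, 0L))
  cp2 <- call_private(geno2, groups, snps[1, ], min_call_rate = 0.8)
  expect_length(cp2$PW, 0)  # landrace call rate 1/3 < 0.8
  cp3 <- call_private(geno2, groups, snps[1, ], min_call_rate = 0.3)
  expect_equal(cp3$PW, 1L)
})

test_that("mutation typing strand-collapses to pyrimidine ancestral bases", {
  g <- c(chr1 = "ATCGA", chr2 = "ACGAT", chr3 = "CAAAT")
  mt <- function(genome, pos, chrom, anc, der) {
    s <- data.frame(chrom = chrom, pos = as.integer(pos), ref = anc,
                    alt = der, id = NA, ancestral = anc, derived = der)
    mutation_type(s, genome)
  }
  expect_equal(mt(g, 3, "chr1", "C", "T"), "TCG>TTG")
  expect_equal(mt(g, 3, "chr2", "G", "A"), "TCG>TTG")  # CGA>CAA collapsed
  expect_equal(mt(g, 3, "chr3", "A", "C"), "TTT>TGT")  # AAA>ACA collapsed
  expect_length(mutation_classes96(), 96)
})

test_that("typing a mutation and its reverse complement gives one class", {
  sim <- small_sim()
  priv <- small_private()
  snps <- priv$PW$snps[1:200, ]
  cls <- mutation_type(snps, sim$genome)
  # rebuild each mutation on an explicit reverse-complement chromosome
  g1 <- sim$genome[["chr1"]]
  L <- nchar(g1)
  rc_genome <- c(chr1 = revcomp(g1))
  rc_snps <- data.frame(chrom = "chr1", pos = L - snps$pos + 1L,
                        ref = chartr("ACGT", "TGCA", snps$ref),
                        alt = chartr("ACGT", "TGCA", snps$alt), id = NA,
                        ancestral = chartr("ACGT", "TGCA", snps$ancestral),
                        derived = chartr("ACGT", "TGCA", snps$derived))
  cls_rc <- mutation_type(rc_snps, rc_genome)
  expect_identical(cls, cls_rc)
})

test_that("spectrum counts conserve: input = typed + excluded", {
  sim <- small_sim()
  priv <- small_private()
  sp <- mutation_spectrum96(priv$PL$snps, sim$genome)
  expect_equal(sp$total + sp$excluded, nrow(priv$PL$snps))
  expect_equal(sum(sp$counts), sp$total)
  expect_equal(sum(sp$freq), 1)
})

test_that("spectrum comparison reproduces the hand-computed 2x2 chi-square", {
  mk <- function(counts, total) {
    cts <- setNames(integer(96), mutation_classes96())
    cts["TCG>TTG"] <- counts
    cts["TTT>TGT"] <- total - counts
    list(counts = cts, freq = cts / total, total = total)
  }
  cmp <- compare_spectra(mk(30, 1000), mk(20, 1000))
  row <- cmp[cmp$class == "TCG>TTG", ]
  # Pearson chi-square on [[30, 970], [20, 980]]:
  # 2000 * (30*980 - 970*20)^2 / (1000 * 1000 * 50 * 1950)
  expect_equal(row$chisq, 2000 * 1e8 / 9.75e10, tolerance = 1e-12)
  expect_equal(row$fold_difference, 0.5)
  # identical spectra: all chisq 0, all defined fold differences 0
  cmp0 <- compare_spectra(mk(30, 1000), mk(30, 1000))
  expect_true(all(cmp0$chisq == 0))
  expect_true(all(cmp0$fold_difference[cmp0$fold_defined] == 0))
  # swapping sets keeps chisq and maps d -> -d/(1+d)
  cmp_sw <- compare_spectra(mk(20, 1000), mk(30, 1000))
  expect_equal(cmp_sw$chisq, cmp$chisq)
  d <- row$fold_difference
  expect_equal(cmp_sw$fold_difference[cmp_sw$class == "TCG>TTG"],
               -d / (1 + d))
  # zero frequency in the reference set flags the fold difference
  expect_false(cmp$fold_defined[cmp$class == "ACA>AGA"])
  expect_true(is.na(cmp$fold_difference[cmp$class == "ACA>AGA"]))
})

test_that("UV-frequency bins cover the set in blocks of consecutive SNPs", {
  sim <- small_sim()
  priv <- small_private()
  snps <- priv$PD$snps[1:2500, ]
  bins <- bin_uv_frequencies(snps, sim$genome, bin_size = 1000)
  expect_equal(nrow(bins), 3)
  expect_equal(bins$n_snps, c(1000L, 1000L, 500L))
  expect_equal(bins$partial, c(FALSE, FALSE, TRUE))
  expect_true(all(bins$f_TCG >= 0 & bins$f_TCG <= 1))
  # empty set gives an empty table
  expect_equal(nrow(bin_uv_frequencies(snps[0, ], sim$genome)), 0)
  # PD bin-mean f(TCG->T) exceeds PW bin-mean (planted excess)
  bd <- bin_uv_frequencies(priv$PD$snps, sim$genome)
  bw <- bin_uv_frequencies(priv$PW$snps, sim$genome)
  expect_gt(mean(bd$f_TCG), mean(bw$f_TCG))
})
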