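# Hand-built two-gene toy genome with known codons.
toy_annotation <- function() {
  chrT <- paste(rep("A", 200), collapse = "")
  substr(chrT, 31, 42) <- "ATGGCTTACGGG"  # codons ATG GCT TAC GGG
  chrM <- paste(rep("A", 200), collapse = "")
  substr(chrM, 85, 90) <- "AGCCAT"        # revcomp spliced starts ATG GCT
  genome <- c(chrT = chrT, chrM = chrM)
  feats <- rbind(
    data.frame(type = c("gene", "mRNA"), chrom = "chrT", start = 21L,
               end = 160L, strand = "+", phase = NA_integer_,
               id = c("gplus", "gplus.t"),
               parent = c(NA, "gplus")),
    data.frame(type = c("exon", "exon"), chrom = "chrT",
               start = c(21L, 101L), end = c(80L, 160L), strand = "+",
               phase = NA_integer_, id = NA, parent = "gplus.t"),
    data.frame(type = c("CDS", "CDS"), chrom = "chrT",
               start = c(31L, 101L), end = c(80L, 131L), strand = "+",
               phase = c(0L, 1L), id = NA, parent = "gplus.t"),
    data.frame(type = c("five_prime_UTR", "three_prime_UTR"),
               chrom = "chrT", start = c(21L, 132L), end = c(30L, 160L),
               strand = "+", phase = NA_integer_, id = NA,
               parent = "gplus.t"),
    data.frame(type = c("gene", "mRNA", "exon", "CDS"), chrom = "chrM",
               start = c(21L, 21L, 21L, 31L), end = c(100L, 100L, 100L, 90L),
               strand = "-", phase = c(NA, NA, NA, 0L),
               id = c("gminus", "gminus.t", NA, NA),
               parent = c(NA, "gminus", "gminus.t", "gminus.t")))
  list(genome = genome, models = build_gene_models(feats))
}

toy_snp <- function(chrom, pos, alt, genome) {
  data.frame(chrom = chrom, pos = as.integer(pos),
             ref = genome_base(genome, chrom, pos), alt = alt, id = NA)
}

test_that("CDS effects follow the genetic code", {
  toy <- toy_annotation()
  cls <- function(chrom, pos, alt) {
    as.character(classify_sites(toy_snp(chrom, pos, alt, toy$genome),
                                toy$models, toy$genome))
  }
  expect_equal(cls("chrT", 36, "C"), "synonymous")    # GCT -> GCC (Ala)
  expect_equal(cls("chrT", 39, "A"), "other_genic")   # TAC -> TAA (stop gain)
  expect_equal(cls("chrT", 40, "A"), "missense")      # GGG -> AGG (Gly->Arg)
  expect_equal(cls("chrT", 31, "G"), "other_genic")   # ATG -> GTG (start loss)
  # minus-strand gene: spliced codon 2 is GCT; genomic 85 A->G gives GCC
  expect_equal(cls("chrM", 85, "G"), "synonymous")
  expect_equal(toy$models$genes$tss[toy$models$genes$id == "gminus"], 100L)
})

test_that("UTR, splice, intron, proximal and intergenic follow precedence", {
  toy <- toy_annotation()
  cls <- function(chrom, pos, alt, ...) {
    as.character(classify_sites(toy_snp(chrom, pos, alt, toy$genome),
                                toy$models, toy$genome, ...))
  }
  expect_equal(cls("chrT", 25, "C"), "utr")
  expect_equal(cls("chrT", 81, "C"), "other_genic")   # splice, 1st intron bp
  expect_equal(cls("chrT", 100, "C"), "other_genic")  # splice, last intron bp
  expect_equal(cls("chrT", 90, "C"), "intronic")
  expect_equal(cls("chrT", 10, "C"), "gene_proximal") # 11 bp 5' of TSS 21
  expect_equal(cls("chrT", 10, "C", proximal_dist = 5), "intergenic")
  expect_equal(cls("chrT", 190, "C"), "intergenic")
  # minus-strand gene: upstream is to the right of TSS = 100
  expect_equal(cls("chrM", 110, "C"), "gene_proximal")
  expect_error(cls("chrX", 10, "C"), "undeclared")
})

test_that("classification agrees with the brute-force translation oracle", {
  sim <- small_sim()
  panel <- small_panel()
  idx <- seq(1, nrow(panel$snps), by = 13)[1:250]
  snps <- panel$snps[idx, ]
  got <- as.character(classify_sites(snps, sim$models, sim$genome))
  want <- oracle_classify(snps, sim$models, sim$genome)
  expect_identical(got, want)
})

test_that("labels are invariant under reverse-complementing the genome", {
  sim <- small_sim()
  panel <- small_panel()
  idx <- seq(1, nrow(panel$snps), by = 29)
  snps <- panel$snps[idx, ]
  fwd <- as.character(classify_sites(snps, sim$models, sim$genome))

  L <- unname(sim$lens["chr1"])
  flip_genome <- setNames(revcomp(sim$genome), names(sim$genome))
  feats <- sim$feats
  new_start <- L - feats$end + 1L
  feats$end <- L - feats$start + 1L
  feats$start <- new_start
  feats$strand <- ifelse(feats$strand == "+", "-", "+")
  flip_models <- build_gene_models(feats)
  flip_snps <- data.frame(chrom = snps$chrom, pos = L - snps$pos + 1L,
                          ref = chartr("ACGT", "TGCA", snps$ref),
                          alt = chartr("ACGT", "TGCA", snps$alt), id = NA)
  o <- order(flip_snps$pos)
  rev_cls <- as.character(classify_sites(flip_snps[o, ], flip_models,
                                         flip_genome))
  expect_identical(rev_cls[order(o)], fwd)
})

test_that("genic/non-genic partition is complete and disjoint", {
  sim <- small_sim()
  panel <- small_panel()
  cls <- classify_sites(panel$snps, sim$models, sim$genome)
  p <- partition_sets(cls)
  expect_equal(sum(p$genic) + sum(p$non_genic), nrow(panel$snps))
  expect_false(any(p$genic & p$non_genic))
  # degenerate case: everything intergenic
  p0 <- partition_sets(factor(rep("intergenic", 5),
                              levels = levels(cls)))
  expect_equal(sum(p0$genic), 0)
})

test_that("balanced subsampling matches sizes and is seeded", {
  reps <- balanced_subsample(1:10, 1:100, n_reps = 5, seed = 1)
  expect_length(reps, 5)
  expect_true(all(vapply(reps, function(r) length(r$genic) == 10 &&
                           length(r$non_genic) == 10, logical(1))))
  reps2 <- balanced_subsample(1:10, 1:100, n_reps = 5, seed = 1)
  expect_identical(reps, reps2)
  expect_error(balanced_subsample(integer(0), 1:10, seed = 1), "non-empty")
})

test_that("subsampled non-genic [AT]-difference exceeds genic (planted)", {
  sim <- small_sim()
  panel <- small_panel()
  cls <- classify_sites(panel$snps, sim$models, sim$genome)
  p <- partition_sets(cls)
  reps <- balanced_subsample(p$genic, p$non_genic, n_reps = 20, seed = 8)
  diffs <- vapply(reps, function(r) {
    d <- function(idx) {
      at <- compute_at(panel$geno[, idx, drop = FALSE],
                       panel$snps[idx, , drop = FALSE])$at
      mean(at[panel$groups != "wild"]) - mean(at[panel$groups == "wild"])
    }
    d(r$non_genic) - d(r$genic)
  }, numeric(1))
  expect_gt(mean(diffs), 0)
})
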