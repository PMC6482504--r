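# Where does the [AT]-increase live? Classify SNPs into the seven genomic
# annotation sets, form the genic/non-genic partition, stratify the
# [AT]-difference by pericentromere, TE, selective-sweep and methylation
# status, and correlate the windowed [AT]-difference with the recombination
# rate per chromosome.

source("analysis/00_config.R")

genome <- read_genome_fasta(sim_path("genome.fa"))
models <- read_gene_models(sim_path("genes.gff3"))
groups_tab <- read_group_table(sim_path("groups.tsv"))
study <- read_vcf_genotypes(sim_path("snps.vcf"), groups_tab)
fc <- filter_common(study$snps, study$geno)
snps <- fc$snps; geno <- fc$geno; groups <- study$groups

centromeres <- read_bed_track(sim_path("centromeres.bed"))
peri <- pericentromere(centromeres, chrom_lengths(genome),
                       flank = study_config()$pericentromere_flank)
te <- read_bed_track(sim_path("te.bed"))
sweeps <- read_bed_track(sim_path("sweeps.bed"))
meth <- read_numeric_track(sim_path("methylation.tsv"))
mr <- methylated_regions(meth)

cls <- classify_sites(snps, models, genome)
freq <- table(cls) / length(cls)
write_tsv(data.frame(class = names(freq), share = as.numeric(freq)),
          res_path("annotation_class_shares.tsv"))
message("annotation shares: ",
        paste(names(freq), sprintf("%.3f", freq), collapse = ", "))

parts <- partition_sets(cls)
strata <- list(
  all = rep(TRUE, nrow(snps)),
  genic = parts$genic,
  non_genic = parts$non_genic,
  pericentromere = snps_in_track(snps, peri),
  arms = !snps_in_track(snps, peri),
  te = snps_in_track(snps, te),
  non_te = !snps_in_track(snps, te),
  sweep = snps_in_track(snps, sweeps),
  non_sweep = !snps_in_track(snps, sweeps),
  methylated = snps_in_track(snps, mr$methylated),
  unmethylated = snps_in_track(snps, mr$unmethylated))
sad <- stratified_at_difference(geno, snps, groups, strata)
write_tsv(sad, res_path("at_by_region.tsv"))
show <- function(s) sprintf("%s %.4f", s,
                            sad$at_diff[sad$stratum == s])
message("[AT]-difference by stratum: ",
        paste(vapply(c("genic", "non_genic", "pericentromere", "arms",
                       "te", "sweep"), show, character(1)),
              collapse = ", "))

# equal-size genic/non-genic subsamples (the SNP-number control)
reps <- balanced_subsample(parts$genic, parts$non_genic, n_reps = 100,
                           seed = STUDY_SEED)
sub_diff <- vapply(reps, function(r) {
  d <- function(idx) {
    at <- compute_at(geno[, idx, drop = FALSE], snps[idx, , drop = FALSE])$at
    mean(at[groups != "wild"]) - mean(at[groups == "wild"])
  }
  c(genic = d(r$genic), non_genic = d(r$non_genic))
}, numeric(2))
message(sprintf(
  "balanced subsamples (n = %d x 100): genic diff %.4f, non-genic diff %.4f",
  length(reps[[1]]$genic), mean(sub_diff["genic", ]),
  mean(sub_diff["non_genic", ])))

# windowed [AT]-difference vs recombination rate, per chromosome
recomb <- read_numeric_track(sim_path("recomb.tsv"))
w <- study_config()$recomb_window
wat <- windowed_at(geno, snps, chrom_lengths(genome), window = w,
                   step = w, min_snps = 50)
wd <- windowed_at_difference(wat, groups)
wd0 <- data.frame(chrom = wd$chrom, start = wd$start - 1L, end = wd$end,
                  at_diff = wd$at_diff)
rc <- rate_correlation(wd0, recomb)
write_tsv(rc, res_path("recombination_correlation.tsv"))
message("[AT]-difference vs recombination rate: ",
        paste(sprintf("%s r = %.2f (p = %.2g)", rc$chrom, rc$r, rc$p.value),
              collapse = "; "))

# windowed MAF (pericentromeric depression)
wm <- windowed_maf(geno, snps, make_windows(chrom_lengths(genome), w, w))
write_tsv(wm, res_path("maf_windows.tsv"))
mid <- (wm$start + wm$end) / 2
in_peri <- snps_in_track(data.frame(chrom = wm$chrom, pos = round(mid),
                                    ref = "A", alt = "C"), peri)
message(sprintf("mean window MAF: pericentromere %.3f vs arms %.3f",
                mean(wm$mean_maf[in_peri], na.rm = TRUE),
                mean(wm$mean_maf[!in_peri], na.rm = TRUE)))
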