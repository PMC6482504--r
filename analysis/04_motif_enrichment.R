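# Trinucleotide motif enrichment around the common SNPs: the 96-class motif
# spectrum against the empirical 95th-percentile null from randomly
# resampled flanking sites, enrichment calls, and the frequencies of the
# four solar-UV-signature motifs conditional on genic/non-genic,
# pericentromeric and methylation strata.

source("analysis/00_config.R")

genome <- read_genome_fasta(sim_path("genome.fa"))
models <- read_gene_models(sim_path("genes.gff3"))
groups_tab <- read_group_table(sim_path("groups.tsv"))
study <- read_vcf_genotypes(sim_path("snps.vcf"), groups_tab)
fc <- filter_common(study$snps, study$geno)
snps <- fc$snps

obs <- motif_spectrum(snps, genome)
null95 <- null_spectrum(snps, genome, n_reps = 100, flank = 1000,
                        seed = STUDY_SEED)
enr <- call_enrichment(obs, null95)
write_tsv(enr, res_path("motif_enrichment.tsv"))

message("classified SNPs: ", attr(obs, "n_classified"),
        " (", attr(obs, "n_excluded"), " excluded at chromosome ends)")
message("mean motif frequency: ", sprintf("%.4f", mean(obs)),
        " (expected 1/96 = 0.0104); enriched motifs: ", sum(enr$enriched))
uv_rows <- enr[enr$uv, ]
message("UV-signature motifs:")
for (i in seq_len(nrow(uv_rows))) {
  message(sprintf("  %-10s observed %.4f null95 %.4f ratio %.3f%s",
                  uv_rows$motif[i], uv_rows$observed[i], uv_rows$null95[i],
                  uv_rows$ratio[i],
                  if (uv_rows$enriched[i]) " (enriched)" else ""))
}

# conditional UV-motif frequencies by stratum
centromeres <- read_bed_track(sim_path("centromeres.bed"))
peri <- pericentromere(centromeres, chrom_lengths(genome),
                       flank = study_config()$pericentromere_flank)
mr <- methylated_regions(read_numeric_track(sim_path("methylation.tsv")))
cls <- classify_sites(snps, models, genome)
parts <- partition_sets(cls)
in_peri <- snps_in_track(snps, peri)
in_meth <- snps_in_track(snps, mr$methylated)
strata <- list(genic = parts$genic, non_genic = parts$non_genic,
               pericentromere = in_peri, arms = !in_peri,
               methylated = in_meth, unmethylated = !in_meth)
cf <- conditional_uv_frequencies(snps, genome, strata)
write_tsv(cf, res_path("uv_motifs_by_stratum.tsv"))
uv <- uv_motifs()$motif
tot <- rowSums(cf[, uv])
message("summed UV-motif frequency by stratum: ",
        paste(sprintf("%s %.4f", cf$stratum, tot), collapse = ", "))

# the planted UV excess lives in the domesticated-private sets: the same
# machinery on PD shows the four UV-signature motifs as the top ratios
pd <- read_vcf_genotypes(sim_path("private_PD.vcf"), groups_tab)
obs_pd <- motif_spectrum(pd$snps, genome)
null_pd <- null_spectrum(pd$snps, genome, n_reps = 100, flank = 1000,
                         seed = STUDY_SEED + 1)
enr_pd <- call_enrichment(obs_pd, null_pd)
write_tsv(enr_pd, res_path("motif_enrichment_PD.tsv"))
top4 <- enr_pd[order(-enr_pd$ratio), ][1:4, ]
message("PD private set, top-ratio motifs: ",
        paste(sprintf("%s %.2f%s", top4$motif, top4$ratio,
                      ifelse(top4$uv, "*", "")), collapse = ", "),
        "  (* = solar-UV signature)")

meth_pd <- snps_in_track(pd$snps, mr$methylated)
cf_pd <- conditional_uv_frequencies(pd$snps, genome,
                                    list(methylated = meth_pd,
                                         unmethylated = !meth_pd))
message("PD summed UV-motif frequency: methylated ",
        sprintf("%.4f", rowSums(cf_pd[, uv]))[1], " vs unmethylated ",
        sprintf("%.4f", rowSums(cf_pd[, uv]))[2])
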