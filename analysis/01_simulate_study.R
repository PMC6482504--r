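# Generate the synthetic study: genome, gene models, region tracks,
# methylation and recombination tracks, the common three-population SNP
# panel with its planted [AT]-difference, and the four population-private
# SNP sets with their planted UV-signature mutation excess. Everything is
# written to standard formats so the downstream scripts exercise the same
# IO paths a real study would.

source("analysis/00_config.R")

cfg <- study_config()
message("simulating genome (", cfg$n_chrom, " x ",
        round(cfg$chrom_length / 1e6), " Mb, seed ", cfg$seed, ") ...")
sim <- simulate_genome(cfg)
panel <- simulate_common_panel(cfg, sim)
priv <- simulate_private_sets(cfg, sim)

write_sim_study(sim, panel, priv, SIM_DIR)

# designate a quarter of the genes as UV-damage-repair related; in this
# synthetic study no causal link to the [AT] phenotype is planted, so the
# downstream enrichment scan is a null demonstration
set.seed(cfg$seed)
uv_ids <- sort(sample(sim$models$genes$id,
                      max(10, round(0.25 * nrow(sim$models$genes)))))
write_tsv(data.frame(gene = uv_ids), sim_path("uv_genes.tsv"))

message("common SNPs:   ", nrow(panel$snps))
message("private sets:  ",
        paste(vapply(c("PW", "PD", "PL", "PI"),
                     function(l) paste0(l, "=", nrow(priv[[l]]$snps)),
                     character(1)), collapse = ", "))
message("genes: ", nrow(sim$models$genes), " (", length(uv_ids),
        " designated UV-related)")
message("study written to ", SIM_DIR)
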