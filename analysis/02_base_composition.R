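# Genome-wide [AT] per accession: group separation between wild and
# domesticated accessions, the substitution-type decomposition, and the
# moving-window [AT] track along the chromosomes. Mirrors the whole-genome
# view a resequencing study starts from.

source("analysis/00_config.R")

genome <- read_genome_fasta(sim_path("genome.fa"))
groups_tab <- read_group_table(sim_path("groups.tsv"))
study <- read_vcf_genotypes(sim_path("snps.vcf"), groups_tab)
validate_study(study$snps, study$geno, study$groups, genome)

fc <- filter_common(study$snps, study$geno)
message("common filter (MAF >= 5%, missing <= 20%): kept ",
        sum(fc$kept), "/", length(fc$kept), " sites")

bc <- compute_at(fc$geno, fc$snps)
write_tsv(cbind(bc, group = as.character(study$groups)),
          res_path("at_per_accession.tsv"))

gs <- group_separation(bc$at, study$groups)
message(sprintf(
  "mean [AT]: wild %.4f, domesticated %.4f; difference %.4f (Welch p = %.3g)",
  gs$mean_wild, gs$mean_domesticated, gs$difference, gs$p.value))

for (g in c("wild", "landrace", "improved")) {
  message(sprintf("  %-9s mean [AT] %.4f (SD %.4f)", g,
                  mean(bc$at[study$groups == g]),
                  sd(bc$at[study$groups == g])))
}

# substitution-type view: type shares and per-type group contrast
type <- classify_substitution(fc$snps$ref, fc$snps$alt)
shares <- table(type) / length(type)
message("substitution-type shares: ",
        paste(names(shares), sprintf("%.3f", shares), collapse = ", "))
ct <- composition_by_type(fc$geno, fc$snps)
ct$group <- as.character(study$groups)[match(ct$accession, bc$accession)]
type_summary <- do.call(rbind, lapply(split(ct, ct$type), function(d) {
  data.frame(type = d$type[1],
             share = mean(d$share, na.rm = TRUE),
             at_wild = mean(d$at[d$group == "wild"], na.rm = TRUE),
             at_dom = mean(d$at[d$group != "wild"], na.rm = TRUE))
}))
type_summary$at_diff <- type_summary$at_dom - type_summary$at_wild
write_tsv(type_summary, res_path("at_by_substitution_type.tsv"))
message("largest per-type [AT]-difference: ",
        type_summary$type[which.max(type_summary$at_diff)],
        sprintf(" (%.4f)", max(type_summary$at_diff)))

# moving-window track (window/step scaled to the 5-Mb chromosomes)
wat <- windowed_at(fc$geno, fc$snps, chrom_lengths(genome),
                   window = 5e5, step = 4e5, min_snps = 100)
wd <- windowed_at_difference(wat, study$groups)
write_tsv(wd, res_path("at_windows.tsv"))
message("windowed [AT]-difference range: ",
        sprintf("%.4f .. %.4f", min(wd$at_diff, na.rm = TRUE),
                max(wd$at_diff, na.rm = TRUE)))
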