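# Mutation spectra of population-private variation: polarize each private
# set with the outgroup alleles, verify the privacy definitions against the
# genotypes, type mutations into the 96 strand-collapsed classes, compare
# the domesticated-private spectra with the wild-private spectrum
# (fold difference and Pearson chi-square), and summarise the per-bin
# f(TCG->T) / f(CCG->T) variation.

source("analysis/00_config.R")

genome <- read_genome_fasta(sim_path("genome.fa"))
groups_tab <- read_group_table(sim_path("groups.tsv"))

sets <- list()
for (lab in c("PW", "PD", "PL", "PI")) {
  study <- read_vcf_genotypes(sim_path(paste0("private_", lab, ".vcf")),
                              groups_tab)
  outgroup <- read.table(sim_path(paste0("outgroup_", lab, ".tsv")),
                         header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  pol <- polarize(study$snps, outgroup)
  cp <- call_private(study$geno, study$groups, pol)
  message(lab, ": ", nrow(pol), " polarized SNPs, ",
          length(cp[[lab]]), " verified ", lab, "-private")
  sets[[lab]] <- list(snps = pol, geno = study$geno,
                      groups = study$groups)
}

spectra <- lapply(sets, function(s) mutation_spectrum96(s$snps, genome))
spec_tab <- data.frame(class = mutation_classes96())
for (lab in names(spectra)) spec_tab[[lab]] <- spectra[[lab]]$freq
write_tsv(spec_tab, res_path("private_spectra.tsv"))

for (lab in c("PD", "PL", "PI")) {
  cmp <- compare_spectra(spectra[[lab]], spectra$PW)
  write_tsv(cmp, res_path(paste0("spectrum_", lab, "_vs_PW.tsv")))
  top <- cmp[order(-cmp$chisq), ][1:3, ]
  message(lab, " vs PW, top chi-square classes: ",
          paste(sprintf("%s (chi2 %.1f, fold %+.2f)", top$class, top$chisq,
                        top$fold_difference), collapse = ", "))
}

message(sprintf("f(TCG->T): PW %.4f, PD %.4f, PL %.4f, PI %.4f",
                spectra$PW$freq["TCG>TTG"], spectra$PD$freq["TCG>TTG"],
                spectra$PL$freq["TCG>TTG"], spectra$PI$freq["TCG>TTG"]))

bins <- do.call(rbind, lapply(names(sets), function(lab) {
  b <- bin_uv_frequencies(sets[[lab]]$snps, genome, bin_size = 1000)
  if (nrow(b)) b$set <- lab
  b
}))
write_tsv(bins, res_path("uv_bins.tsv"))
agg <- tapply(bins$f_TCG, bins$set, mean)
message("bin-mean f(TCG->T): ",
        paste(sprintf("%s %.4f", names(agg), agg), collapse = ", "))
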