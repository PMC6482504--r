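# Shared settings for the analysis workflow. The synthetic study emulates a
# three-population (wild / landrace / improved) resequencing panel on a
# 10-Mb genome: 50 accessions per group, 50,000 common SNPs with a planted
# wild-vs-domesticated [AT]-difference of 0.034, and 20,000 SNPs per
# population-private set with a 1.5-fold planted excess of PyCG->PyTG
# (solar-UV-signature) mutations in the domesticated-private sets.

library(atgenome)

STUDY_SEED <- 1

study_config <- function() sim_config(seed = STUDY_SEED)

# big generated inputs live under scratch/ (regenerated on demand);
# summary tables the scripts produce go under results/
SIM_DIR <- "scratch/sim"
RESULTS_DIR <- "results"

dir.create(SIM_DIR, showWarnings = FALSE, recursive = TRUE)
dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)

res_path <- function(f) file.path(RESULTS_DIR, f)
sim_path <- function(f) file.path(SIM_DIR, f)
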