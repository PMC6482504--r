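# Shared small synthetic study, built once per test run.

.fixtures <- new.env(parent = emptyenv())

small_cfg <- function() {
  sim_config(n_chrom = 1, chrom_length = 5e5, n_genes = 40,
             pericentromere_flank = 1e5, n_common_snps = 4000,
             n_private_snps = 3000, recomb_window = 5e4, seed = 42)
}

small_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_genome(small_cfg())
  .fixtures$sim
}

small_panel <- function() {
  if (is.null(.fixtures$panel)) {
    .fixtures$panel <- simulate_common_panel(small_cfg(), small_sim())
  }
  .fixtures$panel
}

small_private <- function() {
  if (is.null(.fixtures$private)) {
    .fixtures$private <- simulate_private_sets(small_cfg(), small_sim())
  }
  .fixtures$private
}

# a tiny hand-buildable genotype matrix: calls coded 0/1/NA
toy_matrix <- function(calls, accessions = NULL) {
  m <- do.call(rbind, calls)
  rownames(m) <- accessions %||% paste0("acc", seq_len(nrow(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a
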