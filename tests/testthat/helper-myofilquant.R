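# Shared fixtures for the suite: load the peptide table once and provide a
# compact untreated-only simulation used by the recovery tests.

fx <- study_peptides()

# Simulate only untreated runs for a relative-abundance / truncation design
# (treated runs are not needed for those quantities).
sim_untreated_runs <- function(truth, seed, n_replicates = 3,
                               groups = truth$groups$group) {
  design <- tidyr::expand_grid(group = groups,
                               replicate = seq_len(n_replicates))
  design$treated <- FALSE
  design$run_seed <- as.integer(seed) + seq_len(nrow(design))
  design$cset <- purrr::pmap(
    list(design$group, design$replicate, design$run_seed),
    function(g, r, s) {
      simulate_lcms_run(truth, g, FALSE, r, s, fixture = fx)
    }
  )
  design
}

# A noiseless ground truth with given per-group occupancies, reused by the
# oracle tests.
noiseless_truth <- function(...) {
  ground_truth(..., loading_sigma = 0, noise_cv = 0)
}
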