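# Small in-code fixtures shared across test files.

toy_design <- function(n_rep = 3L) {
  ip_design(
    sample_id = c(sprintf("IgG_MLS_r%d", 1:n_rep),
                  sprintf("BRG1_MLS_r%d", 1:n_rep),
                  sprintf("DDIT3_MLS_r%d", 1:n_rep)),
    ip_target = rep(c("IgG", "BRG1", "DDIT3"), each = n_rep),
    cell_context = "MLS",
    replicate = rep(1:n_rep, 3))
}

toy_matrix <- function(proteins, design, value = 1) {
  m <- matrix(value, nrow = length(proteins), ncol = nrow(design),
              dimnames = list(proteins, design$sample_id))
  attr(m, "provenance") <- "imputed"
  m
}

# a fast small simulation config used across tests
small_sim <- function(seed = 1, n_proteins = 300, ...) {
  simulate_ip_experiment(ip_sim_config(n_proteins = n_proteins, seed = seed,
                                       ...))
}

# run the filter -> intersect -> normalize -> compare chain on a simulation
run_comparison <- function(sim, a = c("DDIT3", "MLS"), b = c("BRG1", "MLS"),
                           bait = "BRG1", thresholds = ip_thresholds(),
                           log_scale = FALSE) {
  imp <- impute_lowest_detected(sim$matrix)
  fa <- igg_filter(imp, sim$design, a, thresholds$igg_fc_min)
  fb <- igg_filter(imp, sim$design, b, thresholds$igg_fc_min)
  shared <- intersect_for_comparison(fa$retained, fb$retained)
  norm <- bait_normalize(imp, sim$design, bait)
  cols_a <- sim$design$sample_id[!sim$design$is_control &
                                   sim$design$ip_target == a[1] &
                                   sim$design$cell_context == a[2]]
  cols_b <- sim$design$sample_id[!sim$design$is_control &
                                   sim$design$ip_target == b[1] &
                                   sim$design$cell_context == b[2]]
  differential_enrichment(norm[shared, cols_a, drop = FALSE],
                          norm[shared, cols_b, drop = FALSE],
                          thresholds = thresholds, log_scale = log_scale)
}
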