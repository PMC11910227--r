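# Shared fixtures, all generated in code. Cohorts are cached per test run.

.cohort_cache <- new.env(parent = emptyenv())

# The default study conditions: 8 participants, 3 planted responders.
get_default_cohort <- function() {
  if (is.null(.cohort_cache$default)) {
    .cohort_cache$default <- simulate_cohort(sim_config(seed = 1))
  }
  .cohort_cache$default
}

# All planted effects switched off: a fully null paired cohort.
null_sim_config <- function(seed, ...) {
  sim_config(seed = seed,
             responder_ids = character(0),
             signature_effect = c(ifng = 1, cd274 = 1, sting = 1),
             tsg_promoter_delta = 0, tsg_expression_effect = 1,
             treg_relative_change = 0, cd8_relative_change = 0,
             cancer_relative_change = 0, fraction_jitter_sd = 0,
             dmr_delta = 0, promoter_decrease = 0, global_drift = 0,
             ...)
}

get_null_cohort <- function() {
  if (is.null(.cohort_cache$null)) {
    .cohort_cache$null <- simulate_cohort(null_sim_config(seed = 7))
  }
  .cohort_cache$null
}

# Scaled-down configuration for loops over many seeds.
small_config <- function(seed, ...) {
  sim_config(n_probes = 2200, n_genes = 600,
             n_reference_probes = 120, n_reference_overlap = 100,
             seed = seed, ...)
}

# Small wide beta tibble from a matrix of means plus beta noise.
beta_fixture <- function(mean_mat, precision = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- pmin(pmax(mean_mat, 1e-3), 1 - 1e-3)
  b <- matrix(stats::rbeta(length(mu), mu * precision, (1 - mu) * precision),
              nrow = nrow(mu), dimnames = dimnames(mu))
  tibble::as_tibble(b, rownames = "probe_id")
}

# Minimal sample sheet for n participants.
sheet_fixture <- function(n, dose = NULL) {
  ids <- paste0("P", seq_len(n))
  tibble::tibble(
    sample_id = c(paste0(ids, "_b"), paste0(ids, "_t")),
    participant_id = rep(ids, 2),
    timepoint = rep(c("baseline", "on_treatment"), each = n),
    dose = rep(dose %||% rep("5day", n), 2))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
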