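#' Configuration for the synthetic paired-biopsy cohort
#'
#' Defines the study conditions emulated by [simulate_cohort()]: a small
#' trial cohort with paired baseline / on-treatment tumor biopsies across
#' two dose levels, a subset of participants carrying planted
#' "molecular responder" effects (immune signature upregulation, promoter
#' demethylation of silenced tumor-suppressor genes, regulatory-T-cell
#' depletion and CD8 T-cell infiltration), and realistic measurement noise
#' (beta-distributed methylation noise, hierarchical overdispersed counts).
#'
#' @param n_participants Number of participants (default 8; at least 2).
#' @param n_probes Number of CpG probes (default 20000).
#' @param n_genes Number of genes (default 5000).
#' @param responder_ids Participant labels carrying responder effects
#'   (default `c("P2", "P5", "P8")`, 3 of 8).
#' @param signature_effect Named multiplicative fold changes applied to the
#'   responder on-treatment expression of the signature gene groups:
#'   `ifng` (default 3.0), `cd274` (2.8), `sting` (1.8).
#' @param tsg_promoter_delta Additive beta change planted on responder
#'   on-treatment promoters of the reversed tumor-suppressor genes
#'   (default -0.30).
#' @param tsg_expression_effect Fold change planted on the reversed TSGs'
#'   responder on-treatment expression (default 3.0).
#' @param treg_relative_change Relative on-treatment change of the
#'   regulatory-T-cell fraction in responders (default -0.35).
#' @param cd8_relative_change Relative on-treatment change of the CD8 T-cell
#'   fraction in responders (default +0.5).
#' @param cancer_relative_change Relative on-treatment change of the cancer
#'   cell fraction in responders (default -0.1).
#' @param fraction_jitter_sd Log-scale standard deviation of the paired
#'   biological drift of all cell fractions between timepoints
#'   (default 0.03; set to 0 for a fully null cohort).
#' @param dmr_delta Additive beta change planted on the dedicated
#'   differentially-methylated-region probe clusters on treatment, in all
#'   participants (default -0.30).
#' @param promoter_decrease Relative decrease of promoter methylation
#'   planted on treatment for the participants in
#'   `promoter_decrease_ids` (default 0.15); this is the molecular marker
#'   driving the biologically-effective-dose rule.
#' @param promoter_decrease_ids Participants carrying the promoter decrease
#'   (default `c("P2", "P3", "P5", "P8")`: 3 of 5 at the 5-day dose, 1 of 3
#'   at the 10-day dose).
#' @param global_drift Small additive on-treatment beta drift; applied with
#'   negative sign to all participants except `drift_up_ids`, who get half
#'   of it upward (default 0.01, giving 6 of 8 participants a global
#'   methylation decrease).
#' @param drift_up_ids Participants drifting upward (default
#'   `c("P1", "P6")`).
#' @param beta_precision Concentration of the beta-distributed methylation
#'   noise around the target mean (default 50).
#' @param nb_dispersion Marginal negative-binomial dispersion of the counts
#'   across participants (default 0.1); within a participant the paired
#'   samples share the biological component, as in a paired RNA-seq design.
#' @param library_size_range Range of per-sample total read counts
#'   (default `c(1e6, 3e6)`).
#' @param n_reference_probes Signature CpGs in the full deconvolution
#'   reference (default 1197).
#' @param n_reference_overlap Reference CpGs measured in the cohort
#'   (default 933).
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the configuration.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 8,
                       n_probes = 20000,
                       n_genes = 5000,
                       responder_ids = c("P2", "P5", "P8"),
                       signature_effect = c(ifng = 3.0, cd274 = 2.8, sting = 1.8),
                       tsg_promoter_delta = -0.30,
                       tsg_expression_effect = 3.0,
                       treg_relative_change = -0.35,
                       cd8_relative_change = 0.5,
                       cancer_relative_change = -0.1,
                       fraction_jitter_sd = 0.03,
                       dmr_delta = -0.30,
                       promoter_decrease = 0.15,
                       promoter_decrease_ids = c("P2", "P3", "P5", "P8"),
                       global_drift = 0.01,
                       drift_up_ids = c("P1", "P6"),
                       beta_precision = 50,
                       nb_dispersion = 0.1,
                       library_size_range = c(1e6, 3e6),
                       n_reference_probes = 1197,
                       n_reference_overlap = 933,
                       seed = 1L) {
  if (n_participants < 2) abort("n_participants must be at least 2")
  participants <- paste0("P", seq_len(n_participants))
  if (!all(responder_ids %in% participants)) {
    abort("responder_ids must be a subset of the participant labels")
  }
  if (any(signature_effect <= 0) || tsg_expression_effect <= 0) {
    abort("fold-change effects must be positive")
  }
  if (treg_relative_change < -1 || cd8_relative_change < -1) {
    abort("relative fraction changes must be greater than -1")
  }
  if (beta_precision <= 0 || nb_dispersion < 0) {
    abort("beta_precision must be positive and nb_dispersion non-negative")
  }
  if (n_probes < 3 * n_genes + n_reference_overlap + 200) {
    abort("n_probes too small for the gene and reference layout")
  }
  cfg <- list(
    n_participants = n_participants, participants = participants,
    n_probes = n_probes, n_genes = n_genes,
    responder_ids = responder_ids,
    signature_effect = signature_effect,
    tsg_promoter_delta = tsg_promoter_delta,
    tsg_expression_effect = tsg_expression_effect,
    treg_relative_change = treg_relative_change,
    cd8_relative_change = cd8_relative_change,
    cancer_relative_change = cancer_relative_change,
    fraction_jitter_sd = fraction_jitter_sd,
    dmr_delta = dmr_delta,
    promoter_decrease = promoter_decrease,
    promoter_decrease_ids = intersect(promoter_decrease_ids, participants),
    global_drift = global_drift,
    drift_up_ids = intersect(drift_up_ids, participants),
    beta_precision = beta_precision,
    nb_dispersion = nb_dispersion,
    library_size_range = library_size_range,
    n_reference_probes = n_reference_probes,
    n_reference_overlap = n_reference_overlap,
    seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

cell_types <- function() {
  c("Fibroblasts", "Neutrophils", "CD4T", "CD8T", "Treg",
    "CD14", "CD19", "CD56", "Eosinophils", "Cancer")
}

#' Generate a cell-type methylation reference
#'
#' Builds a signature-CpG reference of mean beta values for the 10 cell
#' types resolved by methylome deconvolution (fibroblasts, neutrophils,
#' CD4+ T, CD8+ T, regulatory T, CD14 monocytes/macrophages, CD19 B cells,
#' CD56 NK cells, eosinophils, and cancer cells). Each probe is near-binary
#' across cell types (low ~0.1 or high ~0.9 with small jitter), giving a
#' between-cell-type beta spread well above 0.3 and a full-rank reference,
#' so noiseless mixtures invert uniquely.
#'
#' @param config A [sim_config()].
#' @return Wide tibble: `probe_id` plus one column per cell type.
#' @export
generate_reference <- function(config = sim_config()) {
  set.seed(config$seed + 1L)
  k <- length(cell_types())
  n <- config$n_reference_probes
  repeat {
    pattern <- matrix(sample(c(0, 1), n * k, replace = TRUE), nrow = n)
    # force every probe to discriminate (not all-equal across cell types)
    flat <- rowSums(pattern) %in% c(0, k)
    pattern[flat, 1] <- 1 - pattern[flat, 1]
    if (qr(pattern)$rank == k) break
  }
  jitter <- matrix(runif(n * k, -0.05, 0.05), nrow = n)
  ref <- 0.1 + 0.8 * pattern + jitter
  ref <- pmin(pmax(ref, 0.02), 0.98)
  colnames(ref) <- cell_types()
  dplyr::bind_cols(tibble(probe_id = sprintf("ref%06d", seq_len(n))),
                   as_tibble(ref))
}

#' Mix reference methylomes into bulk beta profiles
#'
#' Forward model for deconvolution: each sample's expected beta at a
#' signature probe is the fraction-weighted average of the reference
#' columns, `reference %*% t(fractions)`; the observed beta is drawn from a
#' beta distribution with that mean and concentration `precision` (an
#' infinite precision returns the expected values exactly).
#'
#' @param reference Wide reference tibble (`probe_id` + cell-type columns).
#' @param fractions Tibble with `sample_id` and one column per cell type;
#'   rows must sum to 1.
#' @param precision Beta-distribution concentration (default 50).
#' @return Wide beta tibble (`probe_id` + one column per sample).
#' @export
mix_methylomes <- function(reference, fractions, precision = 50) {
  R <- wide_to_matrix(reference, "probe_id")
  f <- wide_to_matrix(fractions, "sample_id")[, colnames(R), drop = FALSE]
  if (any(abs(rowSums(f) - 1) > 1e-6)) abort("fraction rows must sum to 1")
  mu <- R %*% t(f)
  if (is.infinite(precision)) {
    return(matrix_to_wide(mu, "probe_id"))
  }
  b <- rbeta_mean(mu, precision)
  matrix_to_wide(b, "probe_id")
}

# Beta draws parameterized by (mean, concentration), clipped away from {0,1}.
rbeta_mean <- function(mu, precision) {
  mu_c <- pmin(pmax(mu, 1e-3), 1 - 1e-3)
  out <- matrix(rbeta(length(mu_c), mu_c * precision, (1 - mu_c) * precision),
                nrow = nrow(mu_c), dimnames = dimnames(mu_c))
  pmin(pmax(out, 1e-6), 1 - 1e-6)
}

#' Simulate a complete synthetic paired-biopsy cohort
#'
#' Generates every substrate of the downstream pipeline: a probe-by-sample
#' beta matrix with annotation and per-sample QC (detection p, bead
#' counts), a gene-by-sample count matrix with gene lengths, the cell-type
#' deconvolution reference and the true mixing fractions, gene sets
#' (IFN-gamma, STING, M1/M2, antigen-processing, cancer-testis,
#' tumor-suppressor and GO-like collections), a synthetic tumor-vs-normal
#' promoter methylation compendium, clinical records (blood counts,
#' survival), immunohistochemistry intensity tables, and a truth record of
#' everything planted. Responder participants carry the planted effects on
#' their on-treatment samples; non-responders carry null effects.
#'
#' @param config A [sim_config()].
#' @return A list of class `synthetic_cohort`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  reference <- generate_reference(config)
  set.seed(config$seed)

  participants <- config$participants
  n_part <- length(participants)
  dose <- ifelse(seq_len(n_part) <= ceiling(n_part * 5 / 8), "5day", "10day")
  responders <- config$responder_ids

  sample_sheet <- tibble(
    sample_id = c(paste0(participants, "_baseline"), paste0(participants, "_on")),
    participant_id = rep(participants, 2),
    timepoint = rep(c("baseline", "on_treatment"), each = n_part),
    dose = rep(dose, 2)) |>
    dplyr::arrange(.data$participant_id, .data$timepoint)
  design <- as_paired_design(sample_sheet)
  samples <- sample_sheet$sample_id

  ## ---- genes, sets, lengths -------------------------------------------
  special <- c("IDO1", "CXCL10", "CXCL9", "HLA-DRA", "STAT1", "IFNG", "CD274")
  gene_ids <- c(special, sprintf("G%04d", seq_len(config$n_genes - length(special))))
  ifng_genes <- special[1:6]
  pool <- sample(setdiff(gene_ids, special))
  # set sizes follow the trial's printed list sizes, scaled down when the
  # simulated gene universe is smaller than the default
  scale_f <- min(1, length(pool) / 4993)
  sz <- function(k, lo = 4) max(lo, round(k * scale_f))
  take <- function(pool, n) list(set = pool[seq_len(n)], rest = pool[-seq_len(n)])
  st <- take(pool, sz(44)); sting_genes <- st$set
  st <- take(st$rest, sz(188)); m1_genes <- st$set
  st <- take(st$rest, sz(159)); m2_genes <- st$set
  st <- take(st$rest, sz(15)); apm_genes <- st$set
  st <- take(st$rest, sz(1019)); cta_genes <- st$set
  st <- take(st$rest, min(sz(1217), length(st$rest))); tsg_genes <- st$set
  hyper_tsgs <- sample(tsg_genes, min(268, length(tsg_genes)))
  reversal_tsgs <- sample(hyper_tsgs, min(20, length(hyper_tsgs)))

  go_size <- function() sample(seq(min(30, n_genes %/% 10),
                                   min(80, n_genes %/% 5)), 1)
  n_genes <- length(gene_ids)
  go_sets <- lapply(seq_len(40), function(i) sample(gene_ids, go_size()))
  names(go_sets) <- sprintf("GOBP_SET_%03d", seq_len(40))
  planted_set <- unique(c(reversal_tsgs,
                          sample(setdiff(gene_ids, reversal_tsgs), 30)))
  go_sets[["GOBP_DEMETHYLATION_RESPONSE"]] <- planted_set

  gene_sets <- list(ifng = ifng_genes, cd274 = "CD274", sting = sting_genes,
                    m1 = m1_genes, m2 = m2_genes, apm = apm_genes,
                    cta = cta_genes, tsg = tsg_genes)
  gene_sets <- c(gene_sets, go_sets)

  gene_lengths <- tibble(gene_id = gene_ids,
                         length_bp = round(runif(length(gene_ids), 500, 10000)))

  ## ---- probe layout ----------------------------------------------------
  n_genes <- length(gene_ids)
  n_intergenic <- config$n_probes - 3 * n_genes
  chroms <- paste0("chr", rep(1:22, length.out = n_genes))
  gene_chrom <- sort(chroms)
  gene_index_on_chrom <- stats::ave(seq_along(gene_chrom), gene_chrom,
                                    FUN = seq_along)
  gene_start <- 1e5 + (gene_index_on_chrom - 1) * 1e5
  gene_order <- order(gene_chrom, gene_start)
  gene_tab <- tibble(gene = gene_ids, chrom = gene_chrom, start = gene_start)

  promoter1 <- tibble(gene = gene_tab$gene, chrom = gene_tab$chrom,
                      pos = gene_tab$start + 50, region = "TSS200")
  promoter2 <- tibble(gene = gene_tab$gene, chrom = gene_tab$chrom,
                      pos = gene_tab$start + 300, region = "5UTR")
  body <- tibble(gene = gene_tab$gene, chrom = gene_tab$chrom,
                 pos = gene_tab$start + 1500, region = "Body")

  n_sig <- config$n_reference_overlap
  n_dmr_clusters <- 3
  dmr_probes_per_cluster <- 5
  n_sex <- 120
  n_fill <- n_intergenic - n_sig - n_dmr_clusters * dmr_probes_per_cluster - n_sex
  intergenic <- dplyr::bind_rows(
    tibble(gene = NA_character_, chrom = paste0("chr", rep(1:22, length.out = n_sig)),
           pos = 5e7 + 5e4 * seq_len(n_sig), region = "Other", kind = "signature"),
    tibble(gene = NA_character_,
           chrom = rep(paste0("chr", 1:n_dmr_clusters), each = dmr_probes_per_cluster),
           pos = 4.9e8 + rep(seq_len(n_dmr_clusters) * 1e5, each = dmr_probes_per_cluster) +
             rep(seq_len(dmr_probes_per_cluster) * 100, n_dmr_clusters),
           region = "Other", kind = "dmr"),
    tibble(gene = NA_character_,
           chrom = rep(c("chrX", "chrY"), length.out = n_sex),
           pos = 1e6 + 5e4 * seq_len(n_sex), region = "Other", kind = "sex"),
    tibble(gene = NA_character_, chrom = paste0("chr", rep(1:22, length.out = n_fill)),
           pos = 1.5e8 + 5e4 * seq_len(n_fill), region = "Other", kind = "filler"))

  ann <- dplyr::bind_rows(
    dplyr::mutate(promoter1, kind = "promoter"),
    dplyr::mutate(promoter2, kind = "promoter"),
    dplyr::mutate(body, kind = "body"),
    intergenic) |>
    dplyr::arrange(.data$chrom, .data$pos)
  n_probes <- nrow(ann)
  ann$probe_id <- sprintf("cg%08d", seq_len(n_probes))
  # the in-cohort signature probes take reference probe identities
  sig_idx <- which(ann$kind == "signature")
  overlap_ref_ids <- reference$probe_id[seq_len(n_sig)]
  ann$probe_id[sig_idx] <- overlap_ref_ids
  ann$cytoband <- paste0(sub("chr", "", ann$chrom),
                         ifelse(ann$pos < 1e8, "p11", "q22"))
  filler_idx <- which(ann$kind == "filler")
  ann$snp_flag <- FALSE
  ann$multimap_flag <- FALSE
  ann$snp_flag[sample(filler_idx, 50)] <- TRUE
  ann$multimap_flag[sample(setdiff(filler_idx, which(ann$snp_flag)), 50)] <- TRUE

  annotation <- ann[, c("probe_id", "chrom", "pos", "gene", "region",
                        "cytoband", "snp_flag", "multimap_flag")]

  ## ---- true cell fractions --------------------------------------------
  alpha <- c(Fibroblasts = 2, Neutrophils = 1, CD4T = 1.5, CD8T = 1.5,
             Treg = 1, CD14 = 1, CD19 = 0.5, CD56 = 0.5,
             Eosinophils = 0.3, Cancer = 8)
  base_f <- rdirichlet(n_part, alpha * 3)
  colnames(base_f) <- names(alpha)
  rownames(base_f) <- participants
  on_f <- base_f * matrix(exp(rnorm(n_part * 10, 0, config$fraction_jitter_sd)),
                          n_part)
  for (p in responders) {
    on_f[p, "Treg"] <- on_f[p, "Treg"] * (1 + config$treg_relative_change)
    on_f[p, "CD8T"] <- on_f[p, "CD8T"] * (1 + config$cd8_relative_change)
    on_f[p, "Cancer"] <- on_f[p, "Cancer"] * (1 + config$cancer_relative_change)
  }
  on_f <- on_f / rowSums(on_f)
  true_fractions <- dplyr::bind_rows(
    dplyr::bind_cols(tibble(sample_id = paste0(participants, "_baseline")),
                     as_tibble(base_f)),
    dplyr::bind_cols(tibble(sample_id = paste0(participants, "_on")),
                     as_tibble(on_f)))
  true_fractions <- true_fractions[match(samples, true_fractions$sample_id), ]

  ## ---- beta matrix -----------------------------------------------------
  base_mean <- numeric(n_probes)
  base_mean[ann$kind == "promoter"] <- rbeta(sum(ann$kind == "promoter"), 2, 8)
  base_mean[ann$kind == "body"] <- rbeta(sum(ann$kind == "body"), 5, 5)
  base_mean[ann$kind %in% c("filler", "sex")] <-
    runif(sum(ann$kind %in% c("filler", "sex")), 0.1, 0.9)
  base_mean[ann$kind == "dmr"] <- 0.5
  hyper_prom <- ann$kind == "promoter" & ann$gene %in% hyper_tsgs
  base_mean[hyper_prom] <- runif(sum(hyper_prom), 0.55, 0.7)

  mean_mat <- matrix(base_mean, n_probes, length(samples),
                     dimnames = list(ann$probe_id, samples))
  prom_idx <- ann$kind == "promoter"
  rev_prom <- ann$kind == "promoter" & ann$gene %in% reversal_tsgs
  dmr_idx <- ann$kind == "dmr"
  for (i in seq_len(n_part)) {
    p <- participants[i]
    s_on <- paste0(p, "_on")
    drift <- if (p %in% config$drift_up_ids) config$global_drift / 2 else
      -config$global_drift
    mean_mat[, s_on] <- mean_mat[, s_on] + drift
    if (p %in% config$promoter_decrease_ids) {
      mean_mat[prom_idx, s_on] <- mean_mat[prom_idx, s_on] *
        (1 - config$promoter_decrease)
    }
    # treatment-wide demethylated regions (all participants)
    mean_mat[dmr_idx, s_on] <- mean_mat[dmr_idx, s_on] + config$dmr_delta
    if (p %in% responders) {
      mean_mat[rev_prom, s_on] <- mean_mat[rev_prom, s_on] +
        config$tsg_promoter_delta
    }
  }
  mean_mat <- pmin(pmax(mean_mat, 0.02), 0.98)
  # signature probes: means come from the mixing model
  ref_m <- wide_to_matrix(reference, "probe_id")[overlap_ref_ids, , drop = FALSE]
  frac_m <- wide_to_matrix(true_fractions, "sample_id")[samples, colnames(ref_m)]
  mean_mat[sig_idx, ] <- ref_m %*% t(frac_m)
  beta_m <- rbeta_mean(mean_mat, config$beta_precision)
  beta <- matrix_to_wide(beta_m, "probe_id")

  ## ---- QC matrices -----------------------------------------------------
  dp <- matrix(runif(n_probes * length(samples), 1e-6, 5e-3),
               n_probes, length(samples), dimnames = list(ann$probe_id, samples))
  bc <- matrix(rpois(n_probes * length(samples), 12) + 3L,
               n_probes, length(samples), dimnames = list(ann$probe_id, samples))
  bad_dp <- sample(filler_idx, 60)
  dp[bad_dp, sample(length(samples), 2)] <- 0.5
  bad_bc <- sample(setdiff(filler_idx, bad_dp), 40)
  bc[bad_bc, sample(length(samples), 2)] <- 1L
  detection_p <- matrix_to_wide(dp, "probe_id")
  bead_count <- matrix_to_wide(bc, "probe_id")

  ## ---- counts ----------------------------------------------------------
  weight <- stats::rlnorm(n_genes, log(20), 1.2)
  names(weight) <- gene_ids
  boosted <- unique(c(special, sting_genes, reversal_tsgs))
  weight[boosted] <- pmax(weight[boosted], quantile(weight, 0.8))
  prob <- weight / sum(weight)

  phi <- config$nb_dispersion
  u <- if (phi > 0) {
    matrix(rgamma(n_genes * n_part, shape = 1 / phi, rate = 1 / phi), n_genes)
  } else {
    matrix(1, n_genes, n_part)
  }
  lib <- runif(length(samples), config$library_size_range[1],
               config$library_size_range[2])
  names(lib) <- samples

  eff <- matrix(1, n_genes, length(samples),
                dimnames = list(gene_ids, samples))
  planted_cta <- list()
  cta_carriers <- intersect(c("P8", "P5"), responders)
  cta_n <- c(12, 4)[seq_along(cta_carriers)]
  for (j in seq_along(cta_carriers)) {
    planted_cta[[cta_carriers[j]]] <- sample(cta_genes, cta_n[j])
  }
  for (p in responders) {
    s_on <- paste0(p, "_on")
    eff[ifng_genes, s_on] <- config$signature_effect[["ifng"]]
    eff["CD274", s_on] <- config$signature_effect[["cd274"]]
    eff[sting_genes, s_on] <- config$signature_effect[["sting"]]
    eff[reversal_tsgs, s_on] <- config$tsg_expression_effect
    if (!is.null(planted_cta[[p]])) {
      eff[planted_cta[[p]], s_on] <- 3.0
    }
  }
  counts_m <- matrix(0L, n_genes, length(samples),
                     dimnames = list(gene_ids, samples))
  part_of_sample <- match(sub("_(baseline|on)$", "", samples), participants)
  for (s in seq_along(samples)) {
    mu <- prob * u[, part_of_sample[s]] * lib[s] * eff[, s]
    counts_m[, s] <- rpois(n_genes, mu)
  }
  counts <- matrix_to_wide(counts_m, "gene_id")

  ## ---- tumor-vs-normal compendium -------------------------------------
  prom_ann <- annotation[annotation$region %in% c("TSS200", "5UTR") &
                           !is.na(annotation$gene), ]
  is_hyper <- prom_ann$gene %in% hyper_tsgs
  tumor_normal <- tibble(
    probe_id = prom_ann$probe_id, gene = prom_ann$gene,
    region = prom_ann$region,
    delta_beta = ifelse(is_hyper, runif(nrow(prom_ann), 0.12, 0.35),
                        rnorm(nrow(prom_ann), 0, 0.03)),
    fdr = ifelse(is_hyper, runif(nrow(prom_ann), 1e-6, 0.01),
                 runif(nrow(prom_ann), 0.05, 1)))

  ## ---- clinical + IHC --------------------------------------------------
  neut_base <- stats::rlnorm(n_part, log(7), 0.7)
  lymph_base <- stats::rlnorm(n_part, log(0.9), 0.4)
  neut_last <- neut_base * exp(rnorm(n_part, -0.25, 0.15))
  lymph_last <- lymph_base * exp(rnorm(n_part, 0.35, 0.15))
  rate0 <- log(2) / 10
  rate <- rate0 * ifelse(participants %in% responders, 0.4, 1)
  raw_t <- rexp(n_part, rate)
  clinical <- tibble(
    participant_id = participants, dose = dose,
    neutrophils_baseline = neut_base, lymphocytes_baseline = lymph_base,
    neutrophils_last = neut_last, lymphocytes_last = lymph_last,
    survival_months = pmin(raw_t, 24), event = as.integer(raw_t <= 24))

  ihc <- purrr::map_dfr(samples, function(s) {
    p <- sub("_(baseline|on)$", "", s)
    on <- grepl("_on$", s)
    hot <- on && p %in% responders
    purrr::map_dfr(c("CD8", "FOXP3"), function(marker) {
      probs <- if (marker == "CD8") {
        if (hot) c(0.3, 0.3, 0.25, 0.15) else c(0.55, 0.3, 0.1, 0.05)
      } else {
        if (hot) c(0.7, 0.2, 0.07, 0.03) else c(0.5, 0.3, 0.15, 0.05)
      }
      pct <- round_to_100(drop(rdirichlet(1, probs * 60)) * 100)
      tibble(sample_id = s, marker = marker,
             pct_intensity_0 = pct[1], pct_intensity_1 = pct[2],
             pct_intensity_2 = pct[3], pct_intensity_3 = pct[4])
    })
  })

  truth <- list(
    responders = responders,
    planted_dmrs = ann[dmr_idx, c("chrom", "pos")] |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(start = min(.data$pos), end = max(.data$pos),
                       n_probes = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(delta = config$dmr_delta),
    enriched_sets = "GOBP_DEMETHYLATION_RESPONSE",
    reversal_tsgs = reversal_tsgs,
    hyper_tsgs = hyper_tsgs,
    planted_cta = planted_cta,
    promoter_decrease_ids = config$promoter_decrease_ids,
    signature_effect = as.list(config$signature_effect))

  out <- list(config = config, sample_sheet = sample_sheet, design = design,
              beta = beta, detection_p = detection_p, bead_count = bead_count,
              annotation = annotation, counts = counts,
              gene_lengths = gene_lengths, gene_sets = gene_sets,
              reference = reference, true_fractions = true_fractions,
              tumor_normal = tumor_normal, clinical = clinical, ihc = ihc,
              truth = truth)
  class(out) <- "synthetic_cohort"
  out
}

# Round percentages to integers summing exactly to 100 (largest remainder).
round_to_100 <- function(x) {
  f <- floor(x)
  rem <- x - f
  short <- 100 - sum(f)
  if (short > 0) {
    add <- order(rem, decreasing = TRUE)[seq_len(short)]
    f[add] <- f[add] + 1
  }
  f
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic paired-biopsy cohort\n")
  cat("  participants:", x$config$n_participants,
      "(", length(x$truth$responders), "planted responders )\n")
  cat("  probes:", nrow(x$beta), " genes:", nrow(x$counts), "\n")
  invisible(x)
}
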