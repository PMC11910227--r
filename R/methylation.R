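#' Convert methylation beta values to M values and back
#'
#' The beta value at a CpG is the methylated fraction of total signal,
#' bounded in \[0, 1\]; the M value is its logit on the log2 scale,
#' `M = log2(beta / (1 - beta))`, which has more homoscedastic noise and is
#' the preferred scale for differential testing. Betas are clipped to
#' `[epsilon, 1 - epsilon]` before the transform so the log stays defined at
#' fully (un)methylated sites.
#'
#' @param beta Numeric vector, matrix or array of beta values in \[0, 1\].
#' @param epsilon Clipping offset applied before the logit (default `1e-6`).
#' @return `beta_to_m()` returns M values with the same shape as the input;
#'   `m_to_beta()` returns beta values in (0, 1).
#' @examples
#' beta_to_m(0.5) # 0
#' beta_to_m(0.8) # 2
#' m_to_beta(beta_to_m(0.3))
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort("beta values must lie in [0, 1]")
  }
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' @rdname beta_to_m
#' @param m Numeric M values.
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Probe-level quality-control filtering of a beta matrix
#'
#' Removes probes that fail the detection-p / bead-count rule in more than
#' `max_fail_fraction` of samples (strictly more than; a probe failing in
#' exactly that fraction is retained), probes flagged as overlapping a SNP or
#' aligning to multiple genomic locations, and probes on the X or Y
#' chromosome. A probe is counted under the first rule that removes it so the
#' removal log sums to the number of probes dropped.
#'
#' @param beta Wide tibble of beta values: `probe_id` column plus one numeric
#'   column per sample.
#' @param annotation Probe annotation with columns `probe_id`, `chrom`,
#'   `snp_flag`, `multimap_flag` (one row per probe in `beta`).
#' @param detection_p Wide tibble (same shape as `beta`) of per-sample
#'   detection p-values.
#' @param bead_count Wide tibble (same shape as `beta`) of per-sample bead
#'   counts.
#' @param max_fail_fraction Highest tolerated fraction of failing samples
#'   per probe (default 0.05).
#' @param detection_p_cut A sample fails a probe when its detection p exceeds
#'   this cutoff (default 0.01).
#' @param min_beads A sample fails a probe when its bead count is below this
#'   (default 3).
#' @return A list with `beta` (the filtered wide tibble) and `removal_log`
#'   (tibble of `reason`, `n`; reasons are `detection_bead`, `snp`,
#'   `multimap`, `sex_chromosome`).
#' @export
qc_filter_probes <- function(beta, annotation,
                             detection_p, bead_count,
                             max_fail_fraction = 0.05,
                             detection_p_cut = 0.01,
                             min_beads = 3) {
  for (col in c("probe_id", "chrom", "snp_flag", "multimap_flag")) {
    if (!col %in% names(annotation)) {
      abort(paste0("annotation is missing required column '", col, "'"))
    }
  }
  if (is.null(detection_p)) abort("missing QC input 'detection_p'")
  if (is.null(bead_count)) abort("missing QC input 'bead_count'")

  b <- wide_to_matrix(beta, "probe_id")
  ann <- annotation[match(rownames(b), annotation$probe_id), ]
  if (anyNA(ann$probe_id)) {
    abort("annotation does not cover every probe in the beta matrix")
  }
  dp <- wide_to_matrix(detection_p, "probe_id")[rownames(b), colnames(b), drop = FALSE]
  bc <- wide_to_matrix(bead_count, "probe_id")[rownames(b), colnames(b), drop = FALSE]

  fail <- (dp > detection_p_cut) | (bc < min_beads)
  fail_frac <- rowMeans(fail)

  reason <- rep(NA_character_, nrow(b))
  reason[is.na(reason) & fail_frac > max_fail_fraction] <- "detection_bead"
  reason[is.na(reason) & as.logical(ann$snp_flag)] <- "snp"
  reason[is.na(reason) & as.logical(ann$multimap_flag)] <- "multimap"
  reason[is.na(reason) & ann$chrom %in% c("chrX", "chrY", "X", "Y")] <- "sex_chromosome"

  keep <- is.na(reason)
  log <- tibble(reason = c("detection_bead", "snp", "multimap", "sex_chromosome")) |>
    dplyr::mutate(n = unname(vapply(.data$reason,
                                    function(r) sum(reason == r, na.rm = TRUE),
                                    integer(1))))
  list(beta = beta[keep, , drop = FALSE], removal_log = log)
}

#' Paired differential methylation at probe level
#'
#' Tests each probe for a within-participant change between baseline and
#' on-treatment samples. Testing is performed on M values; the reported
#' effect size `delta_beta` is the mean on-treatment minus baseline change on
#' the beta scale. With `moderated = TRUE` the per-probe variance is shrunk
#' with an empirical-Bayes moderated paired t-test (limma on the within-pair
#' M-value differences); otherwise an ordinary paired t-test is used.
#' P-values are Benjamini-Hochberg adjusted across all tested probes.
#' Probes whose within-pair differences have zero variance are flagged and
#' assigned p = 1.
#'
#' @param beta Wide beta tibble (`probe_id` + sample columns).
#' @param design Sample sheet or paired design (see [as_paired_design()]).
#' @param moderated Use empirical-Bayes variance moderation (default TRUE).
#' @param epsilon Clipping offset for the M transform.
#' @return Tibble with `probe_id`, `delta_beta`, `statistic`, `df`,
#'   `p_value`, `p_adjusted`, `zero_variance`.
#' @export
paired_dmp <- function(beta, design, moderated = TRUE, epsilon = 1e-6) {
  design <- ensure_design(design)
  if (nrow(design) < 2) abort("paired testing requires at least 2 pairs")
  b <- wide_to_matrix(beta, "probe_id")
  pm <- paired_matrices(b, design)
  delta_beta <- rowMeans(pm$on - pm$base)

  m_diff <- beta_to_m(pm$on, epsilon) - beta_to_m(pm$base, epsilon)
  n <- ncol(m_diff)
  zv <- row_sds(m_diff) == 0

  if (moderated) {
    fit <- limma::lmFit(m_diff, design = matrix(1, n, 1))
    # zero-variance probes are flagged and forced to p = 1 below, so the
    # shrinkage warning about them is redundant
    fit <- withCallingHandlers(
      limma::eBayes(fit),
      warning = function(w) {
        if (grepl("Zero sample variances", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    statistic <- fit$t[, 1]
    p <- fit$p.value[, 1]
    df <- rep(fit$df.total[1], length(p))
  } else {
    mu <- rowMeans(m_diff)
    s <- row_sds(m_diff)
    statistic <- mu / (s / sqrt(n))
    df <- rep(n - 1, length(mu))
    p <- 2 * pt(-abs(statistic), df = n - 1)
  }
  p[zv] <- 1
  statistic[zv] <- NA_real_
  tibble(probe_id = rownames(b),
         delta_beta = unname(delta_beta),
         statistic = unname(statistic),
         df = unname(df),
         p_value = unname(p),
         p_adjusted = p.adjust(unname(p), method = "BH"),
         zero_variance = unname(zv))
}

#' Per-gene promoter methylation change for each participant
#'
#' For every gene with at least one promoter probe (region class `TSS200` or
#' `5UTR` by default), returns the mean across its promoter probes of the
#' on-treatment minus baseline beta difference, separately per participant.
#' Genes without promoter probes are absent from the result (not reported as
#' zero).
#'
#' @inheritParams paired_dmp
#' @param annotation Probe annotation with `probe_id`, `gene`, `region`.
#' @param regions Region classes counted as promoter (default
#'   `c("TSS200", "5UTR")`).
#' @return Tibble with `participant_id`, `gene`, `delta_beta`, `n_probes`.
#' @export
promoter_delta <- function(beta, design, annotation,
                           regions = c("TSS200", "5UTR")) {
  design <- ensure_design(design)
  b <- wide_to_matrix(beta, "probe_id")
  ann <- annotation[match(rownames(b), annotation$probe_id), ]
  keep <- !is.na(ann$gene) & ann$gene != "" & ann$region %in% regions
  if (!any(keep)) {
    return(tibble(participant_id = character(), gene = character(),
                  delta_beta = double(), n_probes = integer()))
  }
  pm <- paired_matrices(b[keep, , drop = FALSE], design)
  d <- pm$on - pm$base
  colnames(d) <- design$participant_id
  long <- as_tibble(d, rownames = "probe_id") |>
    dplyr::mutate(gene = ann$gene[keep]) |>
    tidyr::pivot_longer(cols = -c("probe_id", "gene"),
                        names_to = "participant_id", values_to = "delta")
  long |>
    dplyr::group_by(.data$participant_id, .data$gene) |>
    dplyr::summarise(delta_beta = mean(.data$delta),
                     n_probes = dplyr::n(), .groups = "drop")
}

#' Standardized promoter probe-level methylation changes
#'
#' Computes the per-probe promoter beta difference (on-treatment minus
#' baseline) for each participant, then standardizes the differences to
#' Z-scores using the mean and standard deviation across all promoter CpGs of
#' that participant's comparison. This is the probe-level input to
#' [gene_level_z()].
#'
#' @inheritParams promoter_delta
#' @return Tibble with `participant_id`, `probe_id`, `gene`, `delta_beta`, `z`.
#' @export
promoter_probe_z <- function(beta, design, annotation,
                             regions = c("TSS200", "5UTR")) {
  design <- ensure_design(design)
  b <- wide_to_matrix(beta, "probe_id")
  ann <- annotation[match(rownames(b), annotation$probe_id), ]
  keep <- !is.na(ann$gene) & ann$gene != "" & ann$region %in% regions
  pm <- paired_matrices(b[keep, , drop = FALSE], design)
  d <- pm$on - pm$base
  colnames(d) <- design$participant_id
  as_tibble(d, rownames = "probe_id") |>
    dplyr::mutate(gene = ann$gene[keep]) |>
    tidyr::pivot_longer(cols = -c("probe_id", "gene"),
                        names_to = "participant_id", values_to = "delta_beta") |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::mutate(z = (.data$delta_beta - mean(.data$delta_beta)) /
                    sd(.data$delta_beta)) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "probe_id", "gene", "delta_beta", "z")
}

#' Combine probe-level Z-scores into gene-level Stouffer statistics
#'
#' For each gene (within each participant when a `participant_id` column is
#' present), the gene-level statistic is the sum of its CpG Z-scores divided
#' by the square root of the number of CpGs, with a two-sided standard-normal
#' p-value. Genes contribute only through the probes present in the input;
#' genes with no probes are simply absent.
#'
#' @param probe_z Tibble with columns `gene`, `z` and optionally
#'   `participant_id` (e.g. from [promoter_probe_z()]).
#' @return Tibble with (optionally `participant_id`,) `gene`, `z`,
#'   `n_cpgs`, `p_value`.
#' @export
gene_level_z <- function(probe_z) {
  for (col in c("gene", "z")) {
    if (!col %in% names(probe_z)) {
      abort(paste0("probe_z is missing column '", col, "'"))
    }
  }
  groups <- intersect(c("participant_id", "gene"), names(probe_z))
  probe_z |>
    dplyr::filter(!is.na(.data$gene), .data$gene != "") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(groups))) |>
    dplyr::summarise(z = sum(.data$z) / sqrt(dplyr::n()),
                     n_cpgs = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(p_value = 2 * pnorm(-abs(.data$z)))
}

#' Per-participant global methylation summary
#'
#' For each participant, summarizes the genome-wide on-treatment shift:
#' the mean beta change, the count and fraction of probes with a beta
#' decrease strictly greater than `decrease_cut`, the same fraction over
#' promoter CpGs when an annotation is supplied, and a `global_decrease`
#' flag (mean change below zero).
#'
#' @inheritParams paired_dmp
#' @param annotation Optional probe annotation (for the promoter fraction).
#' @param decrease_cut Beta decrease cutoff (default 0.25, i.e. a 25-point
#'   drop); the comparison is strict.
#' @param regions Promoter region classes.
#' @return Tibble with one row per participant.
#' @export
global_methylation_summary <- function(beta, design, annotation = NULL,
                                       decrease_cut = 0.25,
                                       regions = c("TSS200", "5UTR")) {
  design <- ensure_design(design)
  b <- wide_to_matrix(beta, "probe_id")
  pm <- paired_matrices(b, design)
  d <- pm$on - pm$base
  promoter <- NULL
  if (!is.null(annotation)) {
    ann <- annotation[match(rownames(b), annotation$probe_id), ]
    promoter <- !is.na(ann$gene) & ann$gene != "" & ann$region %in% regions
  }
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    di <- d[, i]
    out <- tibble(
      participant_id = design$participant_id[i],
      mean_change = mean(di),
      mean_promoter_base = if (is.null(promoter)) NA_real_ else
        mean(pm$base[promoter, i]),
      mean_promoter_on = if (is.null(promoter)) NA_real_ else
        mean(pm$on[promoter, i]),
      n_decreased = sum(di < -decrease_cut),
      frac_decreased = mean(di < -decrease_cut),
      frac_promoter_decreased = if (is.null(promoter)) NA_real_ else
        mean(di[promoter] < -decrease_cut),
      global_decrease = mean(di) < 0
    )
    out
  })
}

# Accept either a long sample sheet or an already-paired design.
ensure_design <- function(design) {
  if (all(c("baseline", "on_treatment", "participant_id") %in% names(design))) {
    return(design)
  }
  as_paired_design(design)
}
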