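#' Call molecular responders from paired signature fold changes
#'
#' A participant is a molecular responder when both the IFN-gamma signature
#' score and CD274 (PD-L1) expression increased more than `fc_cut`-fold on
#' treatment (strict inequalities, conjunction by default; a disjunction
#' variant is available).
#'
#' @param fc Tibble with columns `participant_id`, `ifng_fc`, `cd274_fc`.
#' @param fc_cut Fold-change cutoff (default 2, strict).
#' @param rule `"conjunction"` (default) or `"disjunction"`.
#' @return The input with an added logical `responder` column.
#' @export
call_molecular_responders <- function(fc, fc_cut = 2,
                                      rule = c("conjunction", "disjunction")) {
  rule <- match.arg(rule)
  for (col in c("participant_id", "ifng_fc", "cd274_fc")) {
    if (!col %in% names(fc)) abort(paste0("fc is missing column '", col, "'"))
  }
  op <- if (rule == "conjunction") `&` else `|`
  dplyr::mutate(as_tibble(fc),
                responder = op(.data$ifng_fc > fc_cut, .data$cd274_fc > fc_cut))
}

#' Assess the biologically effective dose rule per dose level
#'
#' A dose level meets the biologically-effective-dose (BED) definition when
#' at least `decrease_cut` (a 10% marker decrease by default) is achieved in
#' at least `participant_frac` (50% by default) of its evaluable
#' participants. Both thresholds are inclusive ("at least"), so a
#' participant decreasing by exactly 10% qualifies and a dose level with
#' exactly half its participants qualifying is met.
#'
#' @param marker_decreases Tibble with `participant_id`, `dose` and
#'   `decrease` (proportion decrease of the molecular marker from baseline
#'   to on-treatment; positive = decrease).
#' @param decrease_cut Qualifying marker decrease (default 0.10).
#' @param participant_frac Required fraction of qualifying participants
#'   (default 0.5).
#' @return Tibble with one row per dose: `dose`, `n_evaluable`,
#'   `n_qualifying`, `fraction`, `bed_met`.
#' @export
assess_bed <- function(marker_decreases, decrease_cut = 0.10,
                       participant_frac = 0.5) {
  for (col in c("participant_id", "dose", "decrease")) {
    if (!col %in% names(marker_decreases)) {
      abort(paste0("marker_decreases is missing column '", col, "'"))
    }
  }
  marker_decreases |>
    dplyr::group_by(.data$dose) |>
    dplyr::summarise(n_evaluable = dplyr::n(),
                     n_qualifying = sum(.data$decrease >= decrease_cut),
                     .groups = "drop") |>
    dplyr::mutate(fraction = .data$n_qualifying / .data$n_evaluable,
                  bed_met = .data$fraction >= participant_frac)
}

#' Tumor-suppressor genes hypermethylated in tumor versus normal
#'
#' From a tumor-versus-normal probe-level differential methylation table,
#' selects the tumor-suppressor genes with at least one promoter probe that
#' is hypermethylated in tumor: beta difference (tumor minus normal) of at
#' least `delta_cut` with FDR below `fdr_cut`. Only hypermethylation counts;
#' hypomethylated promoters do not qualify.
#'
#' @param tumor_vs_normal Tibble with `probe_id`, `gene`, `region`,
#'   `delta_beta` (tumor - normal) and `fdr`.
#' @param tsg_genes Character vector of tumor-suppressor gene symbols.
#' @param delta_cut Minimum beta difference (default 0.10, inclusive).
#' @param fdr_cut FDR cutoff (default 0.05, strict).
#' @param regions Promoter region classes.
#' @return Tibble with `gene`, `n_hyper_probes`, `max_delta`.
#' @export
tsg_hyper_dmps <- function(tumor_vs_normal, tsg_genes,
                           delta_cut = 0.10, fdr_cut = 0.05,
                           regions = c("TSS200", "5UTR")) {
  tumor_vs_normal |>
    dplyr::filter(.data$gene %in% tsg_genes,
                  .data$region %in% regions,
                  .data$delta_beta >= delta_cut,
                  .data$fdr < fdr_cut) |>
    dplyr::group_by(gene = .data$gene) |>
    dplyr::summarise(n_hyper_probes = dplyr::n(),
                     max_delta = max(.data$delta_beta), .groups = "drop")
}

#' Count reversed (demethylated and re-expressed) tumor-suppressor genes
#'
#' For each participant, counts the hypermethylated tumor-suppressor genes
#' whose promoter methylation decreased by strictly more than `meth_cut`
#' (promoter delta beta below `-meth_cut`) with a strictly greater than
#' `fc_cut`-fold increase in expression, and reports the mean promoter delta
#' over all evaluable hypermethylated TSGs.
#'
#' @param hyper_tsgs Character vector (or [tsg_hyper_dmps()] result) of
#'   hypermethylated TSGs.
#' @param promoter_deltas [promoter_delta()] table (`participant_id`,
#'   `gene`, `delta_beta`).
#' @param fc Gene-level paired fold-change table (`participant_id`,
#'   `gene_id`, `fc`).
#' @param meth_cut Promoter methylation decrease cutoff (default 0.25,
#'   strict).
#' @param fc_cut Expression fold-change cutoff (default 2, strict).
#' @return Tibble with `participant_id`, `n_reversed`, `n_evaluated`,
#'   `mean_promoter_delta`.
#' @export
tsg_reversal <- function(hyper_tsgs, promoter_deltas, fc,
                         meth_cut = 0.25, fc_cut = 2) {
  if (is.data.frame(hyper_tsgs)) hyper_tsgs <- hyper_tsgs$gene
  joined <- promoter_deltas |>
    dplyr::filter(.data$gene %in% hyper_tsgs) |>
    dplyr::inner_join(dplyr::select(fc, "participant_id",
                                    gene = "gene_id", "fc"),
                      by = c("participant_id", "gene"))
  joined |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_reversed = sum(.data$delta_beta < -meth_cut & .data$fc > fc_cut),
      n_evaluated = dplyr::n(),
      mean_promoter_delta = mean(.data$delta_beta),
      .groups = "drop")
}

#' Neutrophil-to-lymphocyte ratio
#'
#' `nlr()` divides absolute neutrophil counts by absolute lymphocyte counts
#' (element-wise); ratios with a zero lymphocyte count are returned as
#' missing with a warning. `nlr_summary()` summarizes a clinical table at
#' baseline and last cycle over the available records.
#'
#' @param neutrophils,lymphocytes Absolute cell counts (same units).
#' @return `nlr()` returns a numeric vector of ratios.
#' @export
nlr <- function(neutrophils, lymphocytes) {
  if (any(neutrophils < 0 | lymphocytes < 0, na.rm = TRUE)) {
    abort("cell counts must be non-negative")
  }
  zero <- !is.na(lymphocytes) & lymphocytes == 0
  if (any(zero)) {
    warn(paste0(sum(zero), " record(s) with zero lymphocyte count; NLR set to NA"))
  }
  out <- neutrophils / lymphocytes
  out[zero] <- NA_real_
  out
}

#' @rdname nlr
#' @param clinical Tibble with `neutrophils_baseline`,
#'   `lymphocytes_baseline`, `neutrophils_last`, `lymphocytes_last` (last
#'   cycle values may be missing).
#' @return `nlr_summary()` returns one row per timepoint with `n`, `mean`
#'   and `sd` of the NLR over available records.
#' @export
nlr_summary <- function(clinical) {
  base <- nlr(clinical$neutrophils_baseline, clinical$lymphocytes_baseline)
  last <- nlr(clinical$neutrophils_last, clinical$lymphocytes_last)
  summarize_one <- function(tp, x) {
    x <- x[!is.na(x)]
    tibble(timepoint = tp, n = length(x), mean = mean(x), sd = sd(x))
  }
  dplyr::bind_rows(summarize_one("baseline", base),
                   summarize_one("last_cycle", last))
}

#' Immunohistochemistry H-score
#'
#' The H-score weights the percentage of cells at each staining intensity:
#' `1 x (% intensity 1) + 2 x (% intensity 2) + 3 x (% intensity 3)`,
#' ranging from 0 (all cells unstained) to 300 (all cells at intensity 3).
#' Percentages must sum to 100 per record.
#'
#' @param ihc Tibble with columns `pct_intensity_0` .. `pct_intensity_3`.
#' @return The input with an added `h_score` column.
#' @export
h_score <- function(ihc) {
  cols <- paste0("pct_intensity_", 0:3)
  miss <- setdiff(cols, names(ihc))
  if (length(miss) > 0) {
    abort(paste0("ihc is missing column(s): ", paste(miss, collapse = ", ")))
  }
  total <- rowSums(as.matrix(ihc[cols]))
  if (any(abs(total - 100) > 1e-6)) {
    abort("intensity percentages must sum to 100 for every record")
  }
  dplyr::mutate(as_tibble(ihc),
                h_score = 1 * .data$pct_intensity_1 +
                  2 * .data$pct_intensity_2 +
                  3 * .data$pct_intensity_3)
}

#' Exact two-sided Wilcoxon rank-sum test
#'
#' Computes the two-sided rank-sum p-value by full enumeration of the
#' assignments of the (mid)ranks to the two groups whenever the number of
#' enumerated assignments is tractable; midranks handle ties. The permutation
#' distribution of the rank sum is symmetric, so the two-sided p-value is
#' the probability of a rank sum at least as far from its null mean as the
#' observed one. For larger samples without ties the exact distribution of
#' the Mann-Whitney statistic is used (combined n up to 30); beyond that, or
#' with ties that cannot be enumerated, a normal approximation with tie
#' correction is used and flagged.
#'
#' @param group_a,group_b Numeric vectors (both non-empty).
#' @param max_enumeration Largest number of rank assignments enumerated
#'   (default 2e6).
#' @return A list with `statistic` (rank sum of `group_a`), `p_value`, and
#'   `method` (`"enumeration"`, `"exact_distribution"` or
#'   `"normal_approximation"`).
#' @examples
#' wilcoxon_exact(c(3.5, 3.4, 3.6), c(0.8, 0.7, 0.9, 0.75, 0.85))$p_value # 2/56
#' @export
wilcoxon_exact <- function(group_a, group_b, max_enumeration = 2e6) {
  if (length(group_a) == 0 || length(group_b) == 0) {
    abort("both groups must be non-empty")
  }
  na <- length(group_a)
  nb <- length(group_b)
  n <- na + nb
  r <- rank(c(group_a, group_b)) # midranks for ties
  w_obs <- sum(r[seq_len(na)])
  mu <- na * mean(r)
  ties <- anyDuplicated(r) > 0

  if (choose(n, na) <= max_enumeration) {
    idx <- combn(n, na)
    w_all <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
    return(list(statistic = w_obs, p_value = p, method = "enumeration"))
  }
  if (!ties && n <= 30) {
    u_obs <- w_obs - na * (na + 1) / 2
    u_mu <- na * nb / 2
    lo <- floor(u_mu - abs(u_obs - u_mu) + 1e-9)
    hi <- ceiling(u_mu + abs(u_obs - u_mu) - 1e-9)
    p <- stats::pwilcox(lo, na, nb) +
      stats::pwilcox(hi - 1, na, nb, lower.tail = FALSE)
    return(list(statistic = w_obs, p_value = min(1, p),
                method = "exact_distribution"))
  }
  warn("sample too large for exact mode; using a normal approximation")
  sigma2 <- na * nb / (n * (n - 1)) * (sum(r^2) - n * mean(r)^2)
  z <- (w_obs - mu) / sqrt(sigma2)
  list(statistic = w_obs, p_value = 2 * pnorm(-abs(z)),
       method = "normal_approximation")
}

#' Kaplan-Meier survival summary
#'
#' Product-limit estimate of the survival function with Greenwood variance
#' and log-log 95% confidence limits (via the survival package). The median
#' is the first time at which the estimated survival drops to 0.5 or below;
#' when the curve never reaches 0.5 (e.g. heavy censoring) the median is
#' reported as missing.
#'
#' @param times Event or censoring times (non-negative).
#' @param events Event indicators (1 = event, 0 = censored).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `km_fit`: list with `table` (tibble of
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`, `lower`, `upper`),
#'   `median`, `n`, `n_events`, `conf_level` and the underlying `survfit`.
#' @export
km_curve <- function(times, events, conf_level = 0.95) {
  if (any(times < 0)) abort("survival times must be non-negative")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  tab <- summary(fit)$table
  med <- unname(tab["median"])
  out <- list(
    table = tibble(time = fit$time, n_risk = fit$n.risk,
                   n_event = fit$n.event, n_censor = fit$n.censor,
                   surv = fit$surv, lower = fit$lower, upper = fit$upper),
    median = if (is.na(med)) NA_real_ else med,
    n = unname(tab["records"]),
    n_events = unname(tab["events"]),
    conf_level = conf_level,
    survfit = fit)
  class(out) <- "km_fit"
  out
}

#' @rdname km_curve
#' @param km A `km_fit` object.
#' @param t Time at which to evaluate the survival rate.
#' @return `km_rate()` returns a one-row tibble with `time`, `surv`,
#'   `lower`, `upper`.
#' @export
km_rate <- function(km, t) {
  s <- summary(km$survfit, times = t, extend = TRUE)
  tibble(time = t, surv = s$surv, lower = s$lower, upper = s$upper)
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier fit:", x$n, "subjects,", x$n_events, "events\n")
  med <- if (is.na(x$median)) "not reached" else format(x$median, digits = 4)
  cat("Median survival:", med, "\n")
  invisible(x)
}
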