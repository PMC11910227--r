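#' Pipeline configuration
#'
#' Collects every stage toggle and threshold of the end-to-end analysis in
#' one place. Defaults are the conventional trial cutoffs: detection p 0.01,
#' 3 beads, 5% failing samples, FDR 0.05, 2-fold signature increase for the
#' responder call, 25% promoter methylation decrease with 2-fold
#' re-expression for tumor-suppressor reversal, and the 10%-decrease /
#' 50%-of-participants biologically-effective-dose rule.
#'
#' @param stages Character vector of stages to run, any of
#'   `"methylation"`, `"expression"`, `"deconvolution"`, `"enrichment"`,
#'   `"endpoints"`.
#' @param detection_p_cut,min_beads,max_fail_fraction Probe QC thresholds.
#' @param dmp_fdr FDR cutoff for differentially methylated probes.
#' @param dmr_max_gap_bp,dmr_min_probes,dmr_delta_cut,dmr_n_perm Region
#'   finder settings.
#' @param responder_fc_cut Fold-change cutoff of the molecular responder
#'   rule (both the IFN-gamma signature and CD274 must exceed it).
#' @param bed_decrease_cut,bed_participant_frac Biologically-effective-dose
#'   rule thresholds.
#' @param tsg_meth_cut,tsg_fc_cut Tumor-suppressor reversal thresholds.
#' @param tsg_delta_cut,tsg_fdr_cut Tumor-vs-normal hypermethylation rule.
#' @param enrichment_fdr Joint enrichment FDR cutoff.
#' @param score_offset Geometric-mean signature score offset (RPKM units).
#' @param seed Seed for the permutation stages.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(stages = c("methylation", "expression",
                                       "deconvolution", "enrichment",
                                       "endpoints"),
                            detection_p_cut = 0.01, min_beads = 3,
                            max_fail_fraction = 0.05,
                            dmp_fdr = 0.05,
                            dmr_max_gap_bp = 500, dmr_min_probes = 3,
                            dmr_delta_cut = 0.1, dmr_n_perm = 1000,
                            responder_fc_cut = 2,
                            bed_decrease_cut = 0.10,
                            bed_participant_frac = 0.5,
                            tsg_meth_cut = 0.25, tsg_fc_cut = 2,
                            tsg_delta_cut = 0.10, tsg_fdr_cut = 0.05,
                            enrichment_fdr = 0.05,
                            score_offset = 0.1,
                            seed = 1L) {
  cfg <- as.list(environment())
  known <- c("methylation", "expression", "deconvolution", "enrichment",
             "endpoints")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) abort(paste0("unknown stage(s): ", paste(bad, collapse = ", ")))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Validate pipeline inputs without running the analysis
#'
#' Checks matrix / annotation / sample-sheet consistency: beta values in
#' \[0, 1\] (out-of-range values are reported with probe and sample
#' coordinates), duplicate identifiers, annotation coverage of every probe,
#' and pairing completeness (each participant must have a baseline and an
#' on-treatment sample).
#'
#' @param beta Wide beta tibble.
#' @param counts Wide count tibble (optional).
#' @param annotation Probe annotation (optional).
#' @param sample_sheet Sample sheet (optional).
#' @return A tibble of issues (`check`, `detail`); zero rows when clean.
#' @export
validate_inputs <- function(beta, counts = NULL, annotation = NULL,
                            sample_sheet = NULL) {
  issues <- list()
  add <- function(check, detail) {
    issues[[length(issues) + 1]] <<- tibble(check = check, detail = detail)
  }
  if (anyDuplicated(beta$probe_id)) add("beta", "duplicate probe_id values")
  b <- as.matrix(beta[setdiff(names(beta), "probe_id")])
  bad <- which(b < 0 | b > 1, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    for (i in seq_len(min(nrow(bad), 10))) {
      add("beta_range",
          paste0("beta = ", signif(b[bad[i, 1], bad[i, 2]], 4), " at probe ",
                 beta$probe_id[bad[i, 1]], ", sample ",
                 colnames(b)[bad[i, 2]]))
    }
  }
  if (!is.null(annotation)) {
    uncovered <- setdiff(beta$probe_id, annotation$probe_id)
    if (length(uncovered) > 0) {
      add("annotation", paste0(length(uncovered),
                               " probe(s) without annotation rows"))
    }
  }
  if (!is.null(counts)) {
    cm <- as.matrix(counts[setdiff(names(counts), "gene_id")])
    if (any(cm < 0) || any(cm != round(cm))) {
      add("counts", "counts must be non-negative integers")
    }
  }
  if (!is.null(sample_sheet)) {
    res <- tryCatch({as_paired_design(sample_sheet); NULL},
                    error = function(e) conditionMessage(e))
    if (!is.null(res)) add("pairing", res)
    missing_beta <- setdiff(sample_sheet$sample_id, colnames(b))
    if (length(missing_beta) > 0) {
      add("samples", paste0("sample(s) in sheet absent from beta matrix: ",
                            paste(missing_beta, collapse = ", ")))
    }
  }
  if (length(issues) == 0) {
    return(tibble(check = character(), detail = character()))
  }
  dplyr::bind_rows(issues)
}

#' Run the full correlative biomarker pipeline
#'
#' Executes the enabled stages in dependency order on a
#' [simulate_cohort()] object or a fixture directory written with
#' `write_fixtures(..., include_reference = TRUE)`: probe QC and paired
#' differential methylation (probes, regions, promoter deltas, gene-level
#' Z), RPKM normalization and signature scoring, reference-based cell-type
#' deconvolution, directional gene-set enrichment on the methylation and
#' expression statistics, and the molecular endpoints (responder calls, the
#' biologically-effective-dose rule on the per-participant relative
#' promoter-methylation decrease, tumor-suppressor reversal counts,
#' neutrophil-to-lymphocyte ratio and Kaplan-Meier summaries). The report
#' is a deterministic function of the inputs and configuration.
#'
#' @param input A `synthetic_cohort` object or a fixture directory path.
#' @param config A [pipeline_config()].
#' @return A list of class `pipeline_report` with elements `parameters`,
#'   `stages`, `validation`, per-stage result tables and `endpoints`.
#' @export
run_pipeline <- function(input, config = pipeline_config()) {
  data <- if (inherits(input, "synthetic_cohort")) input else read_fixtures(input)
  checksums <- if (is.character(input)) {
    fls <- list.files(input, full.names = TRUE)
    tibble(file = basename(fls), md5 = unname(tools::md5sum(fls)))
  } else {
    tibble(file = character(), md5 = character())
  }
  report <- list(parameters = config, stages = character(),
                 input_checksums = checksums, warnings = character())
  class(report) <- "pipeline_report"

  validation <- validate_inputs(data$beta, data$counts, data$annotation,
                                data$sample_sheet)
  report$validation <- validation
  if (nrow(validation) > 0) {
    abort(paste0("input validation failed: ", validation$check[1], " - ",
                 validation$detail[1]))
  }
  design <- as_paired_design(data$sample_sheet)

  beta <- data$beta
  if ("methylation" %in% config$stages) {
    if (!is.null(data$detection_p) && !is.null(data$bead_count)) {
      qc <- qc_filter_probes(beta, data$annotation, data$detection_p,
                             data$bead_count,
                             max_fail_fraction = config$max_fail_fraction,
                             detection_p_cut = config$detection_p_cut,
                             min_beads = config$min_beads)
      beta <- qc$beta
      report$qc_removal_log <- qc$removal_log
    }
    report$dmp <- paired_dmp(beta, design)
    report$dmrs <- find_dmrs(beta, design, data$annotation,
                             max_gap_bp = config$dmr_max_gap_bp,
                             min_probes = config$dmr_min_probes,
                             delta_cut = config$dmr_delta_cut,
                             n_perm = config$dmr_n_perm, seed = config$seed)
    report$promoter_deltas <- promoter_delta(beta, design, data$annotation)
    report$gene_z <- gene_level_z(promoter_probe_z(beta, design, data$annotation))
    report$global_methylation <-
      global_methylation_summary(beta, design, data$annotation)
    report$stages <- c(report$stages, "methylation")
  }

  if ("expression" %in% config$stages) {
    expr <- rpkm(data$counts, data$gene_lengths)
    report$signature_fc <- dplyr::bind_rows(
      dplyr::mutate(paired_fold_change(expr, design, "signature",
                                       data$gene_sets$ifng,
                                       offset = config$score_offset),
                    signature = "ifng"),
      dplyr::mutate(paired_fold_change(expr, design, "signature",
                                       data$gene_sets$cd274,
                                       offset = config$score_offset),
                    signature = "cd274"),
      dplyr::mutate(paired_fold_change(expr, design, "signature",
                                       data$gene_sets$sting,
                                       offset = config$score_offset),
                    signature = "sting"))
    report$gene_fc <- paired_fold_change(expr, design, "gene",
                                         offset = config$score_offset)
    report$m1_m2 <- m1_m2_ratio_change(expr, data$gene_sets$m1,
                                       data$gene_sets$m2, design,
                                       offset = config$score_offset)
    report$stages <- c(report$stages, "expression")
  }

  if ("deconvolution" %in% config$stages && !is.null(data$reference)) {
    ref <- intersect_reference(data$reference, beta)
    fractions <- deconvolve(beta, ref)
    report$fractions <- fractions
    report$fraction_changes <- fraction_change(fractions, design)
    report$stages <- c(report$stages, "deconvolution")
  }

  if ("enrichment" %in% config$stages &&
      all(c("methylation", "expression") %in% report$stages)) {
    go_sets <- data$gene_sets[grepl("^GOBP_", names(data$gene_sets))]
    meth_cohort <- report$gene_z |>
      dplyr::group_by(gene = .data$gene) |>
      dplyr::summarise(z = sum(.data$z) / sqrt(dplyr::n()), .groups = "drop") |>
      dplyr::mutate(direction = sign(.data$z),
                    p_value = pmax(2 * pnorm(-abs(.data$z)), 1e-300))
    expr_stats <- expression_gene_stats(report$gene_fc)
    report$enrichment_meth <- directional_enrichment(
      dplyr::select(meth_cohort, "gene", "direction", "p_value"), go_sets)
    report$enrichment_expr <- directional_enrichment(expr_stats, go_sets)
    report$joint_enrichment <- joint_hypo_up(report$enrichment_meth,
                                             report$enrichment_expr,
                                             fdr_cut = config$enrichment_fdr)
    report$stages <- c(report$stages, "enrichment")
  }

  if ("endpoints" %in% config$stages && "expression" %in% report$stages) {
    sig_wide <- report$signature_fc |>
      dplyr::select("participant_id", "signature", "fc") |>
      tidyr::pivot_wider(names_from = "signature", values_from = "fc",
                         names_glue = "{signature}_fc")
    responders <- call_molecular_responders(sig_wide,
                                            fc_cut = config$responder_fc_cut)
    endpoints <- list(responders = responders)

    if ("methylation" %in% report$stages) {
      gm <- report$global_methylation
      decreases <- gm |>
        dplyr::mutate(decrease = (.data$mean_promoter_base -
                                    .data$mean_promoter_on) /
                        .data$mean_promoter_base) |>
        dplyr::select("participant_id", "decrease") |>
        dplyr::left_join(dplyr::select(design, "participant_id", "dose"),
                         by = "participant_id")
      endpoints$bed <- assess_bed(decreases,
                                  decrease_cut = config$bed_decrease_cut,
                                  participant_frac = config$bed_participant_frac)
      if (!is.null(data$tumor_normal)) {
        hyper <- tsg_hyper_dmps(data$tumor_normal, data$gene_sets$tsg,
                                delta_cut = config$tsg_delta_cut,
                                fdr_cut = config$tsg_fdr_cut)
        endpoints$tsg_reversal <- tsg_reversal(hyper, report$promoter_deltas,
                                               report$gene_fc,
                                               meth_cut = config$tsg_meth_cut,
                                               fc_cut = config$tsg_fc_cut)
      }
    }
    if (!is.null(data$clinical)) {
      endpoints$nlr <- nlr_summary(data$clinical)
      km <- km_curve(data$clinical$survival_months, data$clinical$event)
      endpoints$km <- list(median = km$median, n = km$n, events = km$n_events)
    }
    if (!is.null(data$ihc)) {
      endpoints$ihc <- h_score(data$ihc)
    }
    resp_ids <- responders$participant_id[responders$responder]
    ifng <- dplyr::filter(report$signature_fc, .data$signature == "ifng")
    if (length(resp_ids) > 0 && length(resp_ids) < nrow(ifng)) {
      w <- wilcoxon_exact(ifng$fc[ifng$participant_id %in% resp_ids],
                          ifng$fc[!ifng$participant_id %in% resp_ids])
      endpoints$responder_vs_rest_p <- w$p_value
    }
    report$endpoints <- endpoints
    report$stages <- c(report$stages, "endpoints")
  }
  report
}

# Cohort-level per-gene expression statistics for enrichment: paired t-test
# on log2 RPKM per gene, direction = sign of the mean paired log fold change.
expression_gene_stats <- function(gene_fc, offset = 0.1) {
  gene_fc |>
    dplyr::group_by(gene = .data$gene_id) |>
    dplyr::summarise(mean_lfc = mean(log2(.data$fc)),
                     se = sd(log2(.data$fc)) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop") |>
    dplyr::mutate(statistic = .data$mean_lfc / .data$se,
                  direction = sign(.data$mean_lfc),
                  p_value = ifelse(.data$se == 0, 1,
                                   2 * pt(-abs(.data$statistic), .data$n - 1))) |>
    dplyr::select("gene", "direction", "p_value")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report; stages run:", paste(x$stages, collapse = ", "), "\n")
  if (!is.null(x$endpoints$responders)) {
    r <- x$endpoints$responders
    cat("Molecular responders:",
        paste(r$participant_id[r$responder], collapse = ", "), "\n")
  }
  if (!is.null(x$endpoints$bed)) {
    b <- x$endpoints$bed
    met <- b$dose[b$bed_met]
    cat("BED met at dose level(s):",
        if (length(met)) paste(met, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}
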