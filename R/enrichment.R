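#' Directional logistic-regression gene-set enrichment
#'
#' For every gene set, fits a logistic regression of the binary set
#' membership indicator on the signed significance score
#' `s_g = direction_g * (-ln p_g)` over all genes in the statistics table,
#' and tests the slope with a Wald test (optionally a likelihood-ratio
#' test). A positive slope means set members are enriched among
#' significantly *up* genes (direction label `"up"`), a negative slope among
#' significantly *down* genes. Raw set p-values are Benjamini-Hochberg
#' adjusted across all tested sets. Sets falling outside
#' `[min_size, max_size]` after intersection with the statistics table are
#' skipped, as are degenerate sets containing all or none of the genes.
#'
#' The natural log of p is used for the score; the base only rescales the
#' slope, not its test.
#'
#' @param stats Tibble with columns `gene`, `direction` (-1, 0 or +1) and
#'   `p_value` in (0, 1].
#' @param sets Named list of character vectors (e.g. from [read_gmt()]);
#'   cytoband collections are expressed the same way with cytoband labels as
#'   set names.
#' @param min_size,max_size Set-size bounds after intersection (defaults 10
#'   and 500).
#' @param test `"wald"` (default) or `"lrt"`.
#' @return Tibble with `set`, `n_genes`, `slope`, `odds_ratio`, `direction`,
#'   `p_value`, `fdr`, sorted by p-value.
#' @export
directional_enrichment <- function(stats, sets, min_size = 10, max_size = 500,
                                   test = c("wald", "lrt")) {
  test <- match.arg(test)
  for (col in c("gene", "direction", "p_value")) {
    if (!col %in% names(stats)) abort(paste0("stats is missing column '", col, "'"))
  }
  if (any(stats$p_value <= 0 | stats$p_value > 1)) {
    abort("p_value must lie in (0, 1]")
  }
  genes <- stats$gene
  score <- stats$direction * (-log(stats$p_value))

  rows <- purrr::imap(sets, function(members, name) {
    member <- genes %in% members
    n <- sum(member)
    if (n < min_size || n > max_size) return(NULL)
    if (n == length(genes)) {
      inform(paste0("set '", name, "' contains every gene; skipped"))
      return(NULL)
    }
    fit <- suppressWarnings(glm(member ~ score, family = binomial()))
    cf <- summary(fit)$coefficients
    slope <- cf["score", "Estimate"]
    p <- if (test == "wald") {
      cf["score", "Pr(>|z|)"]
    } else {
      null_fit <- glm(member ~ 1, family = binomial())
      stats::pchisq(null_fit$deviance - fit$deviance, df = 1, lower.tail = FALSE)
    }
    tibble(set = name, n_genes = n, slope = slope,
           odds_ratio = exp(slope),
           direction = ifelse(slope >= 0, "up", "down"),
           p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(set = character(), n_genes = integer(), slope = double(),
                  odds_ratio = double(), direction = character(),
                  p_value = double(), fdr = double()))
  }
  out$fdr <- p.adjust(out$p_value, method = "BH")
  dplyr::arrange(out, .data$p_value)
}

#' Gene sets jointly hypomethylated and upregulated
#'
#' Intersects a methylation enrichment result with an expression enrichment
#' result over the same collection and keeps the sets that are significant
#' in both (FDR below `fdr_cut`) with methylation direction down and
#' expression direction up — the signature of demethylation-driven
#' re-expression. Returns an empty table (no error) when nothing qualifies.
#'
#' @param enr_meth,enr_expr [directional_enrichment()] results on the
#'   methylation and expression statistics.
#' @param fdr_cut FDR cutoff applied to both inputs (default 0.05).
#' @return Tibble with `set`, both FDRs, and `-log10(p)` columns for
#'   plotting.
#' @export
joint_hypo_up <- function(enr_meth, enr_expr, fdr_cut = 0.05) {
  joined <- dplyr::inner_join(
    dplyr::select(enr_meth, "set", meth_direction = "direction",
                  meth_p = "p_value", meth_fdr = "fdr"),
    dplyr::select(enr_expr, "set", expr_direction = "direction",
                  expr_p = "p_value", expr_fdr = "fdr"),
    by = "set")
  joined |>
    dplyr::filter(.data$meth_fdr < fdr_cut, .data$expr_fdr < fdr_cut,
                  .data$meth_direction == "down",
                  .data$expr_direction == "up") |>
    dplyr::mutate(neg_log10_p_meth = -log10(.data$meth_p),
                  neg_log10_p_expr = -log10(.data$expr_p)) |>
    dplyr::select("set", "meth_fdr", "expr_fdr",
                  "neg_log10_p_meth", "neg_log10_p_expr")
}

#' Build cytoband gene sets from a probe annotation
#'
#' Groups the genes of an annotation table by cytoband label, yielding a
#' collection usable with [directional_enrichment()] (cytoband labels as set
#' names).
#'
#' @param annotation Probe annotation with `gene` and `cytoband` columns.
#' @return Named list of gene vectors.
#' @export
cytoband_gene_sets <- function(annotation) {
  ann <- annotation[!is.na(annotation$gene) & annotation$gene != "" &
                      !is.na(annotation$cytoband), ]
  lapply(split(ann$gene, ann$cytoband), unique)
}
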