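#' RPKM normalization of a count matrix
#'
#' Computes reads per kilobase of transcript per million mapped reads:
#' `RPKM = count * 1e9 / (length_bp * library_size)`, where the library size
#' is the column sum of counts. The log2 view used downstream is
#' `log2(RPKM + pseudocount)`; the pseudocount is recorded on the result.
#'
#' @param counts Wide tibble of non-negative integer counts: `gene_id`
#'   column plus one column per sample.
#' @param gene_lengths Tibble with `gene_id` and `length_bp`, or a named
#'   numeric vector of lengths in base pairs.
#' @param pseudocount Offset used by [log2_rpkm()] (default 1).
#' @return A wide tibble of RPKM values (`gene_id` + sample columns) with
#'   the pseudocount stored in attribute `"pseudocount"`.
#' @examples
#' counts <- tibble::tibble(gene_id = "g1", s1 = 10L)
#' rpkm(counts, c(g1 = 1000)) # library 10 reads -> RPKM 1e6
#' @export
rpkm <- function(counts, gene_lengths, pseudocount = 1) {
  m <- wide_to_matrix(counts, "gene_id")
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (is.data.frame(gene_lengths)) {
    gene_lengths <- setNames(gene_lengths$length_bp, gene_lengths$gene_id)
  }
  len <- gene_lengths[rownames(m)]
  if (anyNA(len)) abort("gene lengths missing for some genes in the count matrix")
  if (any(len <= 0)) abort("gene lengths must be positive")
  lib <- colSums(m)
  if (any(lib == 0)) abort("zero library size for at least one sample")
  r <- m * 1e9 / (outer(unname(len), lib))
  out <- matrix_to_wide(r, "gene_id")
  attr(out, "pseudocount") <- pseudocount
  out
}

#' @rdname rpkm
#' @param expr RPKM tibble from [rpkm()].
#' @return `log2_rpkm()` returns the log2(RPKM + pseudocount) view.
#' @export
log2_rpkm <- function(expr, pseudocount = NULL) {
  pc <- pseudocount %||% attr(expr, "pseudocount") %||% 1
  m <- wide_to_matrix(expr, "gene_id")
  matrix_to_wide(log2(m + pc), "gene_id")
}

#' Geometric-mean signature score per sample
#'
#' The score of a sample is the geometric mean of `RPKM + offset` over the
#' signature genes present in the expression matrix:
#' `exp(mean(log(RPKM + offset)))`. Signature genes absent from the matrix
#' are dropped with a warning; if none are present the call errors. With
#' `offset = 0` the score is the plain geometric mean and is equivariant
#' under multiplicative rescaling of the input.
#'
#' @param expr RPKM tibble (`gene_id` + sample columns).
#' @param genes Character vector of signature gene identifiers.
#' @param offset Additive offset keeping the log defined at zero RPKM
#'   (default 0.1).
#' @return Tibble with `sample_id`, `score`, `n_genes`.
#' @export
signature_score <- function(expr, genes, offset = 0.1) {
  genes <- unique(genes)
  if (length(genes) == 0) abort("signature gene list is empty")
  m <- wide_to_matrix(expr, "gene_id")
  present <- intersect(genes, rownames(m))
  if (length(present) == 0) abort("no signature gene present in the expression matrix")
  if (length(present) < length(genes)) {
    warn(paste0(length(genes) - length(present),
                " signature gene(s) absent from the expression matrix"))
  }
  sub <- m[present, , drop = FALSE]
  score <- exp(colMeans(log(sub + offset)))
  tibble(sample_id = colnames(m), score = unname(score),
         n_genes = length(present))
}

#' Paired fold changes per participant
#'
#' Linear-scale on-treatment / baseline fold changes, computed per gene or
#' for a signature score. A small offset keeps ratios defined for genes with
#' zero baseline expression: `FC = (on + offset) / (base + offset)`.
#' Signature-level fold changes are ratios of the per-sample
#' [signature_score()] values (scores are already bounded away from zero by
#' the score offset, so no further offset is applied).
#'
#' @param expr RPKM tibble.
#' @param design Sample sheet or paired design.
#' @param level `"gene"` for per-gene fold changes or `"signature"`.
#' @param signature Character vector of signature genes (required when
#'   `level = "signature"`).
#' @param offset Offset for gene-level ratios and for the signature score.
#' @return For `level = "gene"`: tibble with `participant_id`, `gene_id`,
#'   `baseline`, `on_treatment`, `fc`. For `level = "signature"`: one row
#'   per participant with baseline/on-treatment scores and `fc`.
#' @export
paired_fold_change <- function(expr, design, level = c("gene", "signature"),
                               signature = NULL, offset = 0.1) {
  level <- match.arg(level)
  design <- ensure_design(design)
  if (level == "signature") {
    if (is.null(signature)) abort("signature genes must be supplied")
    sc <- signature_score(expr, signature, offset = offset)
    s <- setNames(sc$score, sc$sample_id)
    return(tibble(participant_id = design$participant_id,
                  baseline = unname(s[design$baseline]),
                  on_treatment = unname(s[design$on_treatment]),
                  fc = unname(s[design$on_treatment] / s[design$baseline])))
  }
  m <- wide_to_matrix(expr, "gene_id")
  pm <- paired_matrices(m, design)
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    tibble(participant_id = design$participant_id[i],
           gene_id = rownames(m),
           baseline = unname(pm$base[, i]),
           on_treatment = unname(pm$on[, i]),
           fc = unname((pm$on[, i] + offset) / (pm$base[, i] + offset)))
  })
}

#' M1/M2 macrophage polarization ratio
#'
#' Ratio of the geometric-mean signature scores of an M1 (pro-inflammatory)
#' and an M2 (anti-inflammatory) macrophage gene set per sample; a higher
#' ratio indicates M1-skewed polarization.
#'
#' @param expr RPKM tibble.
#' @param m1,m2 Character vectors of M1 / M2 signature genes.
#' @param offset Score offset.
#' @return Tibble with `sample_id`, `m1_score`, `m2_score`, `ratio`.
#' @export
m1_m2_ratio <- function(expr, m1, m2, offset = 0.1) {
  s1 <- signature_score(expr, m1, offset = offset)
  s2 <- signature_score(expr, m2, offset = offset)
  tibble(sample_id = s1$sample_id,
         m1_score = s1$score,
         m2_score = s2$score,
         ratio = s1$score / s2$score)
}

#' @rdname m1_m2_ratio
#' @param design Sample sheet or paired design.
#' @return `m1_m2_ratio_change()` returns one row per participant with the
#'   baseline and on-treatment ratios and their fold change.
#' @export
m1_m2_ratio_change <- function(expr, m1, m2, design, offset = 0.1) {
  design <- ensure_design(design)
  r <- m1_m2_ratio(expr, m1, m2, offset = offset)
  v <- setNames(r$ratio, r$sample_id)
  tibble(participant_id = design$participant_id,
         baseline = unname(v[design$baseline]),
         on_treatment = unname(v[design$on_treatment]),
         fc = unname(v[design$on_treatment] / v[design$baseline]))
}

#' Count upregulated genes of a set per participant
#'
#' Given gene-level paired fold changes, counts for each participant the
#' genes of a set with fold change strictly greater than `fc_cut`, and
#' reports the mean fold change over the set genes present in the table.
#'
#' @param fc Gene-level fold-change tibble from
#'   `paired_fold_change(level = "gene")`.
#' @param genes Character vector of set genes.
#' @param fc_cut Fold-change cutoff (strict; default 2).
#' @return Tibble with `participant_id`, `n_up`, `n_set_genes`, `mean_fc`.
#' @export
set_upregulation_count <- function(fc, genes, fc_cut = 2) {
  present <- intersect(unique(genes), unique(fc$gene_id))
  if (length(present) == 0) {
    warn("no set gene present in the fold-change table")
    return(dplyr::distinct(fc, .data$participant_id) |>
             dplyr::mutate(n_up = 0L, n_set_genes = 0L, mean_fc = NA_real_))
  }
  fc |>
    dplyr::filter(.data$gene_id %in% present) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(n_up = sum(.data$fc > fc_cut),
                     n_set_genes = dplyr::n(),
                     mean_fc = mean(.data$fc), .groups = "drop")
}
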