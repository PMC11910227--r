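# Internal helpers shared across modules.

# Wide tibble (one id column + one numeric column per sample) -> matrix.
wide_to_matrix <- function(df, id_col) {
  if (!id_col %in% names(df)) {
    abort(paste0("expected an id column named '", id_col, "'"))
  }
  value_cols <- setdiff(names(df), id_col)
  m <- as.matrix(df[value_cols])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[id_col]])
  if (anyDuplicated(rownames(m))) {
    abort(paste0("duplicate ids in column '", id_col, "'"))
  }
  m
}

matrix_to_wide <- function(m, id_col) {
  out <- as_tibble(m, rownames = id_col)
  out
}

#' Normalize a sample sheet into an explicit paired design
#'
#' Takes a long sample sheet (one row per sample) and returns one row per
#' participant with the baseline and on-treatment sample identifiers side by
#' side. Every participant must contribute exactly one sample per timepoint.
#'
#' @param sample_sheet Data frame with columns `sample_id`, `participant_id`
#'   and `timepoint` (values `"baseline"` / `"on_treatment"`); an optional
#'   `dose` column is carried through.
#' @return A tibble with columns `participant_id`, `baseline`, `on_treatment`
#'   (and `dose` when present), ordered by participant.
#' @export
as_paired_design <- function(sample_sheet) {
  need <- c("sample_id", "participant_id", "timepoint")
  miss <- setdiff(need, names(sample_sheet))
  if (length(miss) > 0) {
    abort(paste0("sample sheet is missing column(s): ", paste(miss, collapse = ", ")))
  }
  bad_tp <- setdiff(unique(sample_sheet$timepoint), c("baseline", "on_treatment"))
  if (length(bad_tp) > 0) {
    abort(paste0("unknown timepoint value(s): ", paste(bad_tp, collapse = ", ")))
  }
  if (anyDuplicated(sample_sheet$sample_id)) {
    abort("duplicate sample_id in sample sheet")
  }
  counts <- dplyr::count(sample_sheet, .data$participant_id, .data$timepoint)
  if (any(counts$n != 1)) {
    bad <- unique(counts$participant_id[counts$n != 1])
    abort(paste0("participant(s) with more than one sample per timepoint: ",
                 paste(bad, collapse = ", ")))
  }
  per_part <- dplyr::count(dplyr::distinct(sample_sheet,
                                           .data$participant_id, .data$timepoint),
                           .data$participant_id)
  incomplete <- per_part$participant_id[per_part$n != 2]
  if (length(incomplete) > 0) {
    abort(paste0("participant(s) missing a timepoint: ",
                 paste(incomplete, collapse = ", ")))
  }
  keep <- intersect(c("sample_id", "participant_id", "timepoint", "dose"),
                    names(sample_sheet))
  wide <- tidyr::pivot_wider(sample_sheet[keep],
                             names_from = "timepoint",
                             values_from = "sample_id")
  dplyr::arrange(wide, .data$participant_id)
}

# Extract aligned baseline / on-treatment matrices for a design.
paired_matrices <- function(m, design) {
  missing_samples <- setdiff(c(design$baseline, design$on_treatment), colnames(m))
  if (length(missing_samples) > 0) {
    abort(paste0("samples in design absent from matrix: ",
                 paste(missing_samples, collapse = ", ")))
  }
  list(base = m[, design$baseline, drop = FALSE],
       on = m[, design$on_treatment, drop = FALSE])
}

row_sds <- function(m) {
  n <- ncol(m)
  if (n < 2) return(rep(NA_real_, nrow(m)))
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (n - 1))
}

# Draw from a Dirichlet distribution (rows sum to exactly 1).
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = alpha), nrow = n, byrow = TRUE)
  x / rowSums(x)
}
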