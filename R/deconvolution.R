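#' Restrict a cell-type reference to the probes of a beta matrix
#'
#' Reference-based deconvolution can only use signature CpGs measured in the
#' data, so the reference is intersected with the probes present in the beta
#' matrix. To keep the per-sample least-squares problem well determined the
#' call errors when fewer than `10 x (number of cell types)` probes survive
#' the intersection.
#'
#' @param reference Wide tibble: `probe_id` column plus one mean-beta column
#'   per cell type.
#' @param beta Wide beta tibble (`probe_id` + sample columns).
#' @return The reference restricted to shared probes (row order preserved).
#' @export
intersect_reference <- function(reference, beta) {
  shared <- reference$probe_id %in% beta$probe_id
  k <- ncol(reference) - 1L
  if (sum(shared) < 10 * k) {
    abort(paste0("only ", sum(shared), " reference probes overlap the data; ",
                 "at least ", 10 * k, " are required for ", k, " cell types"))
  }
  reference[shared, , drop = FALSE]
}

#' Estimate cell-type fractions from bulk methylation profiles
#'
#' Solves, for every sample, for the mixing fractions of the reference
#' cell-type methylomes that best reproduce the observed bulk beta values at
#' the signature CpGs. The default method (`"cls"`) minimizes
#' `||R f - b||_2` subject to `f >= 0` and `sum(f) = 1` (a quadratic program
#' with the simplex constraint imposed exactly). The alternative
#' (`"nu_svr"`) follows the support-vector-regression tradition of
#' CIBERSORT-style deconvolution: a linear nu-SVR is fit for each
#' `nu in {0.25, 0.5, 0.75}`, the fit with the lowest RMSE is kept, negative
#' coefficients are clipped to zero and the remainder renormalized to sum
#' to one.
#'
#' @param beta Wide beta tibble restricted (or restrictable) to the
#'   reference probes.
#' @param reference Cell-type reference (ideally from
#'   [intersect_reference()]).
#' @param method `"cls"` (constrained least squares, default) or `"nu_svr"`.
#' @param nu_grid Candidate nu values for the SVR method.
#' @return A tibble of class `deconvolution_result`: `sample_id`, one
#'   fraction column per cell type, and `residual` (the per-sample residual
#'   norm `||R f - b||_2`). The method is stored in attribute `"method"`.
#' @export
deconvolve <- function(beta, reference, method = c("cls", "nu_svr"),
                       nu_grid = c(0.25, 0.5, 0.75)) {
  method <- match.arg(method)
  R <- wide_to_matrix(reference, "probe_id")
  b <- wide_to_matrix(beta, "probe_id")
  missing_probes <- setdiff(rownames(R), rownames(b))
  if (length(missing_probes) > 0) {
    abort(paste0("probe mismatch: ", length(missing_probes),
                 " reference probes absent from the beta matrix ",
                 "(run intersect_reference() first)"))
  }
  b <- b[rownames(R), , drop = FALSE]
  k <- ncol(R)

  fit_one <- function(y) {
    if (method == "cls") {
      f <- cls_simplex(R, y)
    } else {
      f <- svr_fractions(R, y, nu_grid)
    }
    resid <- sqrt(sum((R %*% f - y)^2))
    c(f, resid)
  }
  res <- t(apply(b, 2, fit_one))
  colnames(res) <- c(colnames(R), "residual")
  out <- dplyr::bind_cols(tibble(sample_id = colnames(b)), as_tibble(res))
  attr(out, "method") <- method
  class(out) <- c("deconvolution_result", class(out))
  out
}

# Nonnegative least squares on the probability simplex via quadratic
# programming; exact at the optimum (no post-hoc renormalization).
cls_simplex <- function(R, y) {
  k <- ncol(R)
  Dmat <- crossprod(R)
  # tiny ridge only if numerically singular
  if (rcond(Dmat) < 1e-12) Dmat <- Dmat + diag(1e-10, k)
  dvec <- crossprod(R, y)
  Amat <- cbind(rep(1, k), diag(k))
  bvec <- c(1, rep(0, k))
  sol <- quadprog::solve.QP(Dmat, dvec, Amat, bvec, meq = 1)
  f <- sol$solution
  f[f < 0 & f > -1e-12] <- 0
  f
}

svr_fractions <- function(R, y, nu_grid) {
  fits <- lapply(nu_grid, function(nu) {
    e1071::svm(x = R, y = y, type = "nu-regression", kernel = "linear",
               nu = nu, scale = FALSE)
  })
  rmse <- vapply(fits, function(f) sqrt(mean((stats::predict(f, R) - y)^2)),
                 double(1))
  best <- fits[[which.min(rmse)]]
  w <- drop(t(best$coefs) %*% best$SV)
  w[w < 0] <- 0
  if (sum(w) == 0) abort("nu-SVR produced an all-zero coefficient vector")
  w / sum(w)
}

#' Paired change in estimated cell-type fractions
#'
#' For each participant and cell type, the absolute change
#' (on-treatment minus baseline fraction) and the relative change
#' `(on - base) / base`; the relative change is reported as missing when the
#' baseline fraction is zero.
#'
#' @param fractions A [deconvolve()] result (or any tibble with `sample_id`
#'   and one column per cell type).
#' @param design Sample sheet or paired design.
#' @return Tibble with `participant_id`, `cell_type`, `baseline`,
#'   `on_treatment`, `abs_change`, `rel_change`.
#' @export
fraction_change <- function(fractions, design) {
  design <- ensure_design(design)
  keep <- setdiff(names(fractions), c("sample_id", "residual"))
  m <- wide_to_matrix(fractions[c("sample_id", keep)], "sample_id")
  base <- m[design$baseline, , drop = FALSE]
  on <- m[design$on_treatment, , drop = FALSE]
  purrr::map_dfr(seq_len(nrow(design)), function(i) {
    tibble(participant_id = design$participant_id[i],
           cell_type = colnames(m),
           baseline = unname(base[i, ]),
           on_treatment = unname(on[i, ]),
           abs_change = unname(on[i, ] - base[i, ]),
           rel_change = unname(ifelse(base[i, ] == 0, NA_real_,
                                      (on[i, ] - base[i, ]) / base[i, ])))
  })
}

#' @rdname fraction_change
#' @param changes Output of `fraction_change()`.
#' @return `fraction_change_summary()` returns the cohort mean absolute and
#'   relative change per cell type.
#' @export
fraction_change_summary <- function(changes) {
  changes |>
    dplyr::group_by(.data$cell_type) |>
    dplyr::summarise(mean_abs_change = mean(.data$abs_change),
                     mean_rel_change = mean(.data$rel_change, na.rm = TRUE),
                     n = dplyr::n(), .groups = "drop")
}
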