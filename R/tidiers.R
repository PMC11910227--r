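#' Tidy and glance methods
#'
#' Broom-style accessors: `tidy()` returns one row per estimated quantity,
#' `glance()` a one-row model summary.
#'
#' @param x A `km_fit` or `deconvolution_result` object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.km_fit <- function(x, ...) {
  x$table
}

#' @rdname tidiers
#' @export
glance.km_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, median = x$median,
         conf_level = x$conf_level)
}

#' @rdname tidiers
#' @export
tidy.deconvolution_result <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x),
                      cols = -c("sample_id", "residual"),
                      names_to = "cell_type", values_to = "fraction")
}

#' @rdname tidiers
#' @export
glance.deconvolution_result <- function(x, ...) {
  tibble(n_samples = nrow(x),
         n_cell_types = ncol(x) - 2L,
         mean_residual = mean(x$residual),
         method = attr(x, "method") %||% "cls")
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
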