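#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a 2PL calibration
#'
#' @param x A `neatlink_fit` from [fit_2pl()].
#' @param ... Unused.
#' @return The item bank tibble (one row per item with estimates and SEs).
#' @export
tidy.neatlink_fit <- function(x, ...) x$bank

#' @rdname tidy.neatlink_fit
#' @return For `glance()`: a one-row tibble with `log_likelihood`,
#'   `n_cycles`, `converged`, `n_items`, `n_examinees`, `n_excluded`.
#' @export
glance.neatlink_fit <- function(x, ...) {
  tibble(log_likelihood = x$loglik, n_cycles = x$n_cycles,
         converged = x$converged, n_items = nrow(x$bank),
         n_examinees = x$n_examinees, n_excluded = nrow(x$excluded))
}

#' Tidy a linking fit
#'
#' @param x A `neatlink_linking`.
#' @param ... Unused.
#' @return A tibble with one row per coefficient (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.neatlink_linking <- function(x, ...) {
  tibble(term = c("A", "B"), estimate = c(x$A, x$B),
         std.error = c(x$se_A, x$se_B))
}

#' @rdname tidy.neatlink_linking
#' @export
glance.neatlink_linking <- function(x, ...) {
  tibble(method = x$method, n_anchors = x$n_anchors,
         criterion = x$criterion, converged = x$converged)
}

#' Tidy a residual scan
#'
#' @param x A `neatlink_li` from [residual_scan()].
#' @param ... Unused.
#' @return The full cell table (`tidy`) or the one-row summary (`glance`).
#' @export
tidy.neatlink_li <- function(x, ...) x$cells

#' @rdname tidy.neatlink_li
#' @export
glance.neatlink_li <- function(x, ...) x$summary

#' Tidy an age-reference model
#'
#' @param x A `neatlink_refmodel`.
#' @param ... Unused.
#' @return Coefficients of the winning mean model (`tidy`) or a one-row
#'   model summary (`glance`).
#' @export
tidy.neatlink_refmodel <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @rdname tidy.neatlink_refmodel
#' @export
glance.neatlink_refmodel <- function(x, ...) {
  tibble(model_id = x$model_id, r_squared = x$r_squared,
         spread_model = x$spread_model, fit_n = x$fit_n,
         age_min = x$age_range[1], age_max = x$age_range[2])
}
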