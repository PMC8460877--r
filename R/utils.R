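#' @importFrom rlang abort warn .data :=
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join pull n row_number across all_of
#' @importFrom stats plogis qlogis qnorm pnorm dnorm optim uniroot lm coef
#'   residuals sd rnorm runif rbinom quantile pchisq setNames complete.cases
NULL

# round-half-up (the convention "values above the 0.50 decimal going up");
# base round() rounds half to even, which is not what score tables use
round_half_up <- function(x) floor(x + 0.5)

check_finite <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort(paste0("`", what, "` must be finite and numeric."), class = "neatlink_invalid_argument")
  }
  invisible(x)
}

check_scalar_prob <- function(x, what) {
  check_finite(x, what)
  if (length(x) != 1L || x <= 0 || x >= 1) {
    abort(paste0("`", what, "` must be a single value in (0, 1)."), class = "neatlink_invalid_argument")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

question_types <- function() c("LIT", "TC", "GAP", "SM")
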