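#' Scale linking between two calibrated forms
#'
#' Estimates the affine transformation \eqn{\theta_{to} = A\theta_{from} + B}
#' placing the from-form's parameter scale onto the to-form's, from the
#' anchor items' two sets of estimates. Under the transformation an item's
#' parameters map as \eqn{a^* = a/A}, \eqn{b^* = A b + B}.
#'
#' Four estimators:
#' \describe{
#'   \item{mean-sigma}{moments of anchor difficulties:
#'     \eqn{A = s(b_{to})/s(b_{from})} (sample SDs),
#'     \eqn{B = \bar b_{to} - A \bar b_{from}}.}
#'   \item{mean-mean}{\eqn{A = \bar a_{from}/\bar a_{to}}, same intercept
#'     formula.}
#'   \item{Haebara}{minimizes the weighted squared difference between the
#'     anchor item characteristic curves on the to-form scale, summed over
#'     items then nodes.}
#'   \item{Stocking--Lord}{same, but the difference of the anchor test
#'     characteristic curves (sum over items before squaring).}
#' }
#' The characteristic-curve criteria are minimized by Nelder--Mead from the
#' mean-sigma start, then polished with BFGS (criterion tolerance 1e-8,
#' non-symmetric classic definitions, loss on the to-form scale over the
#' grid's weights).
#'
#' @param anchors_from,anchors_to Anchor banks with matched `item_id`s
#'   (order-free; matched internally).
#' @param grid Quadrature grid (characteristic-curve methods).
#' @param method One of `"mean_mean"`, `"mean_sigma"`, `"haebara"`,
#'   `"stocking_lord"`.
#' @return A `neatlink_linking` object: list with `method`, `A`, `B`, `se_A`,
#'   `se_B` (`NA` until [linking_se()] fills them), `n_anchors`, `criterion`
#'   (characteristic-curve methods), `converged`.
#' @examples
#' pair <- generate_affine_pair(
#'   item_bank(paste0("an", 1:5), a = c(1, 1.2, 0.8, 1.5, 1.1),
#'             b = c(-1, -0.3, 0.2, 0.9, 1.4), is_anchor = TRUE),
#'   A = 0.9, B = -0.2)
#' link_forms(pair$anchors_from, pair$anchors_to, method = "stocking_lord")
#' @export
link_forms <- function(anchors_from, anchors_to,
                       method = c("stocking_lord", "haebara", "mean_sigma", "mean_mean"),
                       grid = ability_grid()) {
  method <- match.arg(method)
  m <- match_anchors(anchors_from, anchors_to)
  switch(method,
    mean_sigma = mean_sigma(m$from, m$to),
    mean_mean = mean_mean(m$from, m$to),
    haebara = cc_link(m$from, m$to, grid, symmetric_sum = FALSE, method = "haebara"),
    stocking_lord = cc_link(m$from, m$to, grid, symmetric_sum = TRUE, method = "stocking_lord"))
}

match_anchors <- function(anchors_from, anchors_to) {
  anchors_from <- validate_item_bank(anchors_from)
  anchors_to <- validate_item_bank(anchors_to)
  ids <- intersect(anchors_from$item_id, anchors_to$item_id)
  if (length(ids) < 2) {
    abort("Need at least 2 anchors with matched item_ids.",
          class = "neatlink_invalid_argument")
  }
  list(from = anchors_from[match(ids, anchors_from$item_id), ],
       to = anchors_to[match(ids, anchors_to$item_id), ])
}

new_linking <- function(method, A, B, n_anchors, criterion = NA_real_,
                        converged = TRUE) {
  if (!is.finite(A) || A <= 0) {
    abort("Linking produced a non-positive slope; anchors are degenerate.",
          class = "neatlink_degenerate_anchor")
  }
  structure(list(method = method, A = A, B = B, se_A = NA_real_, se_B = NA_real_,
                 n_anchors = n_anchors, criterion = criterion,
                 converged = converged),
            class = "neatlink_linking")
}

#' @rdname link_forms
#' @export
mean_sigma <- function(anchors_from, anchors_to) {
  m <- match_anchors(anchors_from, anchors_to)
  s_from <- sd(m$from$b); s_to <- sd(m$to$b)
  if (!is.finite(s_from) || s_from == 0) {
    abort("Anchor difficulties of the from-form have zero spread.",
          class = "neatlink_degenerate_anchor")
  }
  A <- s_to / s_from
  new_linking("mean_sigma", A, mean(m$to$b) - A * mean(m$from$b), nrow(m$from))
}

#' @rdname link_forms
#' @export
mean_mean <- function(anchors_from, anchors_to) {
  af <- validate_item_bank(anchors_from); at <- validate_item_bank(anchors_to)
  # a single matched anchor suffices for the moment formulas
  ids <- intersect(af$item_id, at$item_id)
  if (length(ids) < 1) abort("No matched anchors.", class = "neatlink_invalid_argument")
  f <- af[match(ids, af$item_id), ]; t_ <- at[match(ids, at$item_id), ]
  if (mean(t_$a) == 0) {
    abort("Mean anchor discrimination of the to-form is zero.",
          class = "neatlink_degenerate_anchor")
  }
  A <- mean(f$a) / mean(t_$a)
  new_linking("mean_mean", A, mean(t_$b) - A * mean(f$b), nrow(f))
}

cc_criterion <- function(par, from, to, nodes, w, symmetric_sum) {
  A <- par[1]; B <- par[2]
  if (A <= 0) return(1e10)
  p_to <- plogis(outer(to$a, nodes, "*") - outer(to$a * to$b, rep(1, length(nodes))))
  a_t <- from$a / A; b_t <- A * from$b + B
  p_tr <- plogis(outer(a_t, nodes, "*") - outer(a_t * b_t, rep(1, length(nodes))))
  if (symmetric_sum) {
    sum(w * colSums(p_to - p_tr)^2)        # TCC difference (Stocking--Lord)
  } else {
    sum(w * colSums((p_to - p_tr)^2))      # per-item ICC differences (Haebara)
  }
}

cc_link <- function(from, to, grid, symmetric_sum, method) {
  validate_grid(grid)
  start <- tryCatch({
    ms <- mean_sigma(from, to); c(ms$A, ms$B)
  }, error = function(e) c(1, 0))
  fn <- function(p) cc_criterion(p, from, to, grid$node, grid$weight, symmetric_sum)
  o1 <- optim(start, fn, method = "Nelder-Mead",
              control = list(reltol = 1e-12, maxit = 2000))
  o2 <- optim(o1$par, fn, method = "BFGS",
              control = list(reltol = 1e-12, maxit = 500))
  best <- if (o2$value <= o1$value) o2 else o1
  converged <- best$convergence == 0 && best$value <= fn(start) + 1e-8
  if (!converged) warn(paste0(method, " optimizer did not converge cleanly."))
  new_linking(method, best$par[1], best$par[2], nrow(from),
              criterion = best$value, converged = converged)
}

#' @export
print.neatlink_linking <- function(x, ...) {
  cat(sprintf("Linking (%s): A = %.5f (SE %s), B = %.5f (SE %s), %d anchors\n",
              x$method, x$A,
              ifelse(is.na(x$se_A), "NA", sprintf("%.5f", x$se_A)),
              x$B,
              ifelse(is.na(x$se_B), "NA", sprintf("%.5f", x$se_B)),
              x$n_anchors))
  invisible(x)
}

#' Rescale a bank with linking coefficients
#'
#' Applies \eqn{a^* = a/A}, \eqn{b^* = A b + B} to every item; metadata and
#' reliabilities are unchanged (reliability is scale-dependent only through
#' `a`, so it is recomputed when present). Item characteristic curves are
#' preserved at corresponding abilities:
#' \eqn{P(\theta; a, b) = P(A\theta + B; a/A, Ab + B)}.
#'
#' @param bank Item bank.
#' @param A,B Linking coefficients (`A > 0`), or a `neatlink_linking` passed
#'   as `A`.
#' @return The rescaled bank.
#' @examples
#' b <- item_bank("an1", a = 1.285143, b = 0.835929)
#' transform_parameters(b, A = 0.91536, B = -0.21297)[, c("a", "b")]
#' @export
transform_parameters <- function(bank, A, B = NULL) {
  if (inherits(A, "neatlink_linking")) { B <- A$B; A <- A$A }
  bank <- validate_item_bank(bank)
  check_finite(A, "A"); check_finite(B, "B")
  if (A <= 0) abort("`A` must be > 0.", class = "neatlink_invalid_argument")
  out <- mutate(bank, a = .data$a / A, b = A * .data$b + B)
  if (!is.null(out$reliability)) out$reliability <- item_reliability(out$a)
  if (!is.null(out$se_a)) out$se_a <- out$se_a / A
  if (!is.null(out$se_b)) out$se_b <- out$se_b * A
  out
}

#' Parametric-bootstrap standard errors for linking coefficients
#'
#' Resamples both anchor sets' parameter estimates from independent normal
#' distributions centered at the estimates with their standard errors,
#' re-solves the linking for each replicate, and reports the SDs of the
#' replicate coefficients. Deterministic given `seed`.
#'
#' @param anchors_from,anchors_to Anchor banks carrying `se_a`, `se_b`.
#' @param method Linking method (see [link_forms()]).
#' @param n_boot Number of replicates (default 500).
#' @param grid Quadrature grid.
#' @param seed Integer seed (default 1).
#' @return The `neatlink_linking` fit with `se_A`, `se_B` filled in and a
#'   `boot` tibble of replicate draws attached. If any required SE is
#'   missing, the fit is returned with `se_A = se_B = NA` and a warning
#'   (unavailable-SE result, not an error).
#' @export
linking_se <- function(anchors_from, anchors_to, method = "stocking_lord",
                       n_boot = 500, grid = ability_grid(), seed = 1L) {
  fit <- link_forms(anchors_from, anchors_to, method = method, grid = grid)
  m <- match_anchors(anchors_from, anchors_to)
  ses <- c(m$from$se_a, m$from$se_b, m$to$se_a, m$to$se_b)
  if (anyNA(ses)) {
    warn("Anchor standard errors unavailable; linking SEs not computed.")
    return(fit)
  }
  J <- nrow(m$from)
  draws <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_boot), function(r) {
      f <- m$from; t_ <- m$to
      f$a <- pmax(f$a + rnorm(J, 0, f$se_a), 1e-3)
      f$b <- f$b + rnorm(J, 0, f$se_b)
      t_$a <- pmax(t_$a + rnorm(J, 0, t_$se_a), 1e-3)
      t_$b <- t_$b + rnorm(J, 0, t_$se_b)
      res <- tryCatch(link_forms(f, t_, method = method, grid = grid),
                      error = function(e) NULL)
      if (is.null(res)) tibble(A = NA_real_, B = NA_real_)
      else tibble(A = res$A, B = res$B)
    })
  })
  ok <- complete.cases(draws)
  fit$se_A <- sd(draws$A[ok]); fit$se_B <- sd(draws$B[ok])
  fit$boot <- draws
  fit$n_boot <- n_boot
  fit
}

#' Table of linking coefficients by all four methods
#'
#' @inheritParams link_forms
#' @param se Compute bootstrap SEs (default `FALSE`).
#' @param n_boot,seed Bootstrap controls when `se = TRUE`.
#' @return A tibble with one row per method: `method`, `A`, `se_A`, `B`,
#'   `se_B`.
#' @export
linking_table <- function(anchors_from, anchors_to, grid = ability_grid(),
                          se = FALSE, n_boot = 500, seed = 1L) {
  methods <- c("mean_mean", "mean_sigma", "haebara", "stocking_lord")
  purrr::map_dfr(methods, function(mth) {
    fit <- if (se) linking_se(anchors_from, anchors_to, mth, n_boot, grid, seed)
           else link_forms(anchors_from, anchors_to, mth, grid)
    tibble(method = mth, A = fit$A, se_A = fit$se_A, B = fit$B, se_B = fit$se_B)
  })
}
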