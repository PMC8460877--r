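#' Model-expected counts for one item pair
#'
#' Under local independence, the expected count of response pattern
#' \eqn{(x, y)} for items \eqn{i, j} is the quadrature integral of the
#' product of the two item characteristic curves over the ability
#' distribution, times the sample size:
#' \eqn{E_{xy} = n \sum_k w_k P_i^x(1-P_i)^{1-x} P_j^y (1-P_j)^{1-y}}.
#' The four pattern counts sum to `n` by construction.
#'
#' @param bank Calibrated item bank.
#' @param pair Length-2 character, the two `item_id`s.
#' @param grid Quadrature grid.
#' @param n Sample size.
#' @return A tibble `pattern` (`"00", "01", "10", "11"`; first digit item 1 of
#'   `pair`), `expected`.
#' @export
expected_pair_counts <- function(bank, pair, grid = ability_grid(), n) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  if (n <= 0) abort("`n` must be positive.", class = "neatlink_invalid_argument")
  idx <- match(pair, bank$item_id)
  if (anyNA(idx)) {
    abort(paste0("Item(s) not in bank: ", paste(pair[is.na(idx)], collapse = ", ")),
          class = "neatlink_invalid_argument")
  }
  pi_ <- plogis(bank$a[idx[1]] * (grid$node - bank$b[idx[1]]))
  pj_ <- plogis(bank$a[idx[2]] * (grid$node - bank$b[idx[2]]))
  w <- grid$weight
  tibble(
    pattern = c("00", "01", "10", "11"),
    expected = n * c(sum(w * (1 - pi_) * (1 - pj_)), sum(w * (1 - pi_) * pj_),
                     sum(w * pi_ * (1 - pj_)), sum(w * pi_ * pj_)))
}

#' Standardized Pearson residual for a pattern cell
#'
#' \eqn{z = (O - E) / \sqrt{E (1 - E/n)}} — the observed count against its
#' binomial-model expectation and standard deviation.
#'
#' @param observed Observed count.
#' @param expected Expected count, in `(0, n)`.
#' @param n Total count for the pair.
#' @return The z value.
#' @examples
#' standardized_residual(30, 25, 100) # 1.1547
#' @export
standardized_residual <- function(observed, expected, n) {
  check_finite(observed, "observed"); check_finite(expected, "expected"); check_finite(n, "n")
  if (any(expected <= 0) || any(expected >= n)) {
    abort("`expected` must lie strictly between 0 and `n`.",
          class = "neatlink_undefined_residual")
  }
  (observed - expected) / sqrt(expected * (1 - expected / n))
}

#' Bonferroni-adjusted residual cutoff
#'
#' Divides the significance level by the number of items of the form and
#' returns the matching two-tailed standard-normal critical value. With 81
#' items at alpha 0.05 the adjusted level is about 0.0006 (z near |3.42|);
#' with 95 items, about 0.0005 (z near |3.47|).
#'
#' @param n_items Number of items on the form.
#' @param alpha Unadjusted two-tailed level (default 0.05).
#' @return A tibble `adjusted_alpha`, `z_cutoff`.
#' @export
bonferroni_cutoff <- function(n_items, alpha = 0.05) {
  if (n_items < 1) abort("`n_items` must be >= 1.", class = "neatlink_invalid_argument")
  check_scalar_prob(alpha, "alpha")
  adj <- alpha / n_items
  tibble(adjusted_alpha = adj, z_cutoff = qnorm(1 - adj / 2))
}

#' Bivariate residual scan of a form
#'
#' Computes the four standardized Pearson residual cells for every item pair
#' of a calibrated form — \eqn{4 \binom{J}{2}} cells — and summarizes their
#' distribution against the Bonferroni cutoff. Expected counts use the
#' marginal (quadrature-integrated) model probabilities. Cells whose expected
#' proportion falls outside `(1e-6, 1 - 1e-6)` are excluded from the summary
#' and counted as unusable.
#'
#' @param bank Calibrated item bank (columns matching the responses).
#' @param responses Response tibble.
#' @param grid Quadrature grid.
#' @param alpha Unadjusted significance level (default 0.05).
#' @return An object of class `neatlink_li`: list with `cells` (tibble
#'   `item_i`, `item_j`, `pattern`, `observed`, `expected`, `z`, `flagged`,
#'   `usable`) and `summary` (tibble `n_cells`, `n_usable`, `mean`, `sd`,
#'   `min`, `max`, `n_exceeding_cutoff`, `cutoff`, `adjusted_alpha`).
#' @export
residual_scan <- function(bank, responses, grid = ability_grid(), alpha = 0.05) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  rm_ <- response_matrix(responses)
  idx <- match(bank$item_id, rm_$item_ids)
  if (anyNA(idx)) abort("Bank items missing from responses.", class = "neatlink_invalid_argument")
  x <- rm_$x[, idx, drop = FALSE]
  n <- nrow(x); J <- ncol(x)
  if (J < 2) abort("Need at least two items.", class = "neatlink_invalid_argument")

  P <- plogis(outer(bank$a, grid$node, "*") - outer(bank$a * bank$b, rep(1, nrow(grid))))
  W <- grid$weight
  E11 <- n * (P %*% (W * t(P)))               # J x J
  Pm <- as.numeric(P %*% W)                   # marginal P(correct)
  E10 <- n * outer(Pm, rep(1, J)) - E11
  E01 <- n * outer(rep(1, J), Pm) - E11
  E00 <- n - E11 - E10 - E01

  O11 <- crossprod(x)
  O10 <- crossprod(x, 1 - x)
  O01 <- t(O10)
  O00 <- n - O11 - O10 - O01

  ut <- upper.tri(E11)
  ii <- row(E11)[ut]; jj <- col(E11)[ut]
  cells <- tibble(
    item_i = rep(bank$item_id[ii], 4),
    item_j = rep(bank$item_id[jj], 4),
    pattern = rep(c("00", "01", "10", "11"), each = sum(ut)),
    observed = c(O00[ut], O01[ut], O10[ut], O11[ut]),
    expected = c(E00[ut], E01[ut], E10[ut], E11[ut]))
  cells <- cells |>
    mutate(usable = .data$expected / n > 1e-6 & .data$expected / n < 1 - 1e-6,
           z = ifelse(.data$usable,
                      (.data$observed - .data$expected) /
                        sqrt(.data$expected * (1 - .data$expected / n)),
                      NA_real_))
  cut <- bonferroni_cutoff(J, alpha)
  cells$flagged <- !is.na(cells$z) & abs(cells$z) > cut$z_cutoff
  zu <- cells$z[cells$usable]
  summary <- tibble(
    n_cells = nrow(cells), n_usable = sum(cells$usable),
    mean = mean(zu), sd = sd(zu), min = min(zu), max = max(zu),
    n_exceeding_cutoff = sum(cells$flagged),
    cutoff = cut$z_cutoff, adjusted_alpha = cut$adjusted_alpha)
  structure(list(cells = cells, summary = summary, n = n, alpha = alpha),
            class = "neatlink_li")
}

#' @export
print.neatlink_li <- function(x, ...) {
  s <- x$summary
  cat("Local-independence residual scan\n")
  cat(sprintf("  %d cells (%d usable); z mean %.3f, sd %.3f, range [%.2f, %.2f]\n",
              s$n_cells, s$n_usable, s$mean, s$sd, s$min, s$max))
  cat(sprintf("  %d cell(s) beyond the Bonferroni cutoff |%.2f| (adjusted alpha %.2g)\n",
              s$n_exceeding_cutoff, s$cutoff, s$adjusted_alpha))
  invisible(x)
}

#' Export a residual scan
#'
#' Writes the full cell table as CSV and the summary as JSON.
#'
#' @param scan A `neatlink_li` object.
#' @param cells_path,summary_path Output paths (either may be `NULL`).
#' @return `scan`, invisibly.
#' @export
write_residual_scan <- function(scan, cells_path = NULL, summary_path = NULL) {
  if (!is.null(cells_path)) readr::write_csv(scan$cells, cells_path, na = "")
  if (!is.null(summary_path)) {
    jsonlite::write_json(as.list(scan$summary), summary_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(scan)
}
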