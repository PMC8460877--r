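#' Lord--Wingersky recursion
#'
#' Exact distribution of the number-correct score over independent Bernoulli
#' items, built by adding one item at a time. An empty probability vector
#' gives a point mass at score 0.
#'
#' @param p Vector of correct-response probabilities in \[0, 1\].
#' @return Numeric vector of length `length(p) + 1`, the probabilities of
#'   scores `0:length(p)` (nonnegative, summing to 1).
#' @examples
#' lord_wingersky(c(0.5, 0.5)) # 0.25 0.50 0.25
#' @export
lord_wingersky <- function(p) {
  if (length(p) == 0) return(1)
  check_finite(p, "p")
  if (any(p < 0 | p > 1)) abort("`p` must lie in [0, 1].", class = "neatlink_invalid_argument")
  dist <- 1
  for (pj in p) {
    dist <- c(dist * (1 - pj), 0) + c(0, dist * pj)
  }
  dist
}

#' Marginal (model-implied) raw-score distribution
#'
#' Integrates the conditional score distribution (Lord--Wingersky at each
#' node) over the ability distribution carried by the grid weights — the
#' synthetic-population distribution used by observed-score equating.
#'
#' @param bank Item bank on the scale of interest.
#' @param grid Quadrature grid; its weights are the population ability
#'   distribution (pass empirical weights for an EAP-based population).
#' @return A tibble `score` (0..n items), `probability` (sums to 1).
#' @export
marginal_score_distribution <- function(bank, grid = ability_grid()) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  n <- nrow(bank)
  out <- numeric(n + 1)
  for (k in seq_len(nrow(grid))) {
    p <- plogis(bank$a * (grid$node[k] - bank$b))
    out <- out + grid$weight[k] * lord_wingersky(p)
  }
  tibble(score = 0:n, probability = out)
}

#' Equipercentile mapping between two score distributions
#'
#' Percentile ranks use the midpoint (half-point continuization) convention
#' \eqn{PR(s) = F(s-1) + p(s)/2}; the inverse of the target distribution is
#' taken piecewise-linearly. A degenerate (point-mass) target maps every
#' score to that mass point, flagged in the `degenerate` attribute.
#'
#' @param dist_from,dist_to Score-distribution tibbles
#'   (`score`, `probability`) from [marginal_score_distribution()].
#' @return A tibble `score`, `equivalent` (clamped to \[0, n_to\]), with
#'   attribute `degenerate`.
#' @export
equipercentile <- function(dist_from, dist_to) {
  validate_score_dist(dist_from); validate_score_dist(dist_to)
  n_to <- max(dist_to$score)
  if (sum(dist_to$probability > 1e-12) == 1) {
    k <- dist_to$score[dist_to$probability > 1e-12]
    warn("Target score distribution is a point mass; all equivalents equal it.")
    out <- tibble(score = dist_from$score, equivalent = as.numeric(k))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  p_from <- dist_from$probability
  pr <- cumsum(p_from) - p_from / 2
  F_to <- cumsum(dist_to$probability)
  p_to <- dist_to$probability
  eq <- vapply(pr, function(q) {
    j <- which(F_to >= q - 1e-15)[1]
    if (is.na(j)) return(n_to + 0.5)
    # skip zero-mass scores: interpolate within the first score carrying mass
    while (p_to[j] <= 1e-15 && j < length(p_to)) j <- j + 1
    F_prev <- if (j == 1) 0 else F_to[j - 1]
    (j - 1) - 0.5 + (q - F_prev) / p_to[j]
  }, numeric(1))
  out <- tibble(score = dist_from$score, equivalent = pmin(pmax(eq, 0), n_to))
  attr(out, "degenerate") <- FALSE
  out
}

validate_score_dist <- function(d) {
  if (!is.data.frame(d) || !all(c("score", "probability") %in% names(d))) {
    abort("Score distribution needs columns `score`, `probability`.",
          class = "neatlink_invalid_argument")
  }
  if (any(d$probability < -1e-12) || abs(sum(d$probability) - 1) > 1e-10) {
    abort("Score probabilities must be nonnegative and sum to 1.",
          class = "neatlink_invalid_argument")
  }
  invisible(d)
}

#' IRT true-score equating
#'
#' For each interior integer raw score on the from-form, inverts the
#' from-form test characteristic curve (monotone; bracketed root finding,
#' tolerance 1e-9 in ability) and evaluates the to-form TCC at the same
#' ability. Endpoints map 0 to 0 and n_from to n_to by convention (the 2PL
#' TCC is invertible on the open score range; there is no guessing floor).
#'
#' @param bank_from,bank_to Banks already on a common scale (apply
#'   [transform_parameters()] first).
#' @return A `neatlink_equating` tibble: `score`, `equivalent`,
#'   `method = "TSE"`.
#' @export
true_score_equating <- function(bank_from, bank_to) {
  bank_from <- validate_item_bank(bank_from); bank_to <- validate_item_bank(bank_to)
  n_from <- nrow(bank_from); n_to <- nrow(bank_to)
  interior <- seq_len(n_from - 1)
  theta_s <- vapply(interior, function(s) {
    f <- function(t) test_characteristic_curve(bank_from, t) - s
    lo <- -10; hi <- 10
    while (f(lo) > 0) lo <- lo * 2
    while (f(hi) < 0) hi <- hi * 2
    uniroot(f, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
  eq <- c(0, test_characteristic_curve(bank_to, theta_s), n_to)
  new_equating(tibble(score = 0:n_from, equivalent = eq), "TSE")
}

#' IRT observed-score equating
#'
#' Computes both forms' marginal raw-score distributions over the same
#' population ability weights and maps scores by equipercentile equating.
#'
#' @inheritParams true_score_equating
#' @param grid Quadrature grid carrying the population ability weights.
#' @return A `neatlink_equating` tibble: `score`, `equivalent`,
#'   `method = "OSE"`.
#' @export
observed_score_equating <- function(bank_from, bank_to, grid = ability_grid()) {
  d_from <- marginal_score_distribution(bank_from, grid)
  d_to <- marginal_score_distribution(bank_to, grid)
  eq <- equipercentile(d_from, d_to)
  new_equating(tibble(score = eq$score, equivalent = eq$equivalent), "OSE")
}

new_equating <- function(tbl, method) {
  tbl$method <- method
  # monotone non-decreasing by construction; guard numerical wiggles
  tbl$equivalent <- cummax(tbl$equivalent)
  class(tbl) <- c("neatlink_equating", class(tbl))
  tbl
}

#' Apply an equating table to raw scores
#'
#' Linear interpolation between table rows (integer raw scores map exactly).
#'
#' @param table A `neatlink_equating` tibble.
#' @param score Raw score(s) on the from-form.
#' @return Equated score(s) on the to-form.
#' @export
apply_equating <- function(table, score) {
  stats::approx(table$score, table$equivalent, xout = score, rule = 2)$y
}

#' Write an equating table as CSV
#'
#' Columns `raw_score`, `equivalent`, `method`, `direction`, mirroring a
#' conversion table.
#'
#' @param table A `neatlink_equating` tibble.
#' @param path CSV path.
#' @param direction Label such as `"A_to_B"`.
#' @return `path`, invisibly.
#' @export
write_equating_table <- function(table, path, direction = "from_to_to") {
  readr::write_csv(tibble(raw_score = table$score, equivalent = table$equivalent,
                          method = table$method, direction = direction), path)
  invisible(path)
}
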