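#' The 44-model candidate set for the age--score mean function
#'
#' Fractional-polynomial candidates over powers
#' \{-2, -1, -0.5, 0 (log), 0.5, 1, 2, 3\}: the 8 one-term (FP1) models plus
#' the 36 unordered two-term (FP2) pairs including repeated powers — 44 in
#' all. Power 0 denotes `log(age)`; a repeated power `p` contributes both
#' `age^p` and `age^p * log(age)`. Plain linear is FP1(1), the quadratic is
#' FP2(1, 2), and cubic-type growth shapes are covered by pairs such as
#' FP2(2, 3); the inverse-squared family enters through power -2, including
#' the repeated pair FP2(-2, -2) whose mean function is
#' \eqn{\beta_0 + \beta_1 \mathrm{age}^{-2} + \beta_2 \mathrm{age}^{-2}\log(\mathrm{age})}.
#'
#' @return A tibble with `model_id`, `family` (`"FP1"`/`"FP2"`), `power1`,
#'   `power2` (`NA` for FP1), `label`.
#' @examples
#' nrow(candidate_models()) # 44
#' @export
candidate_models <- function() {
  powers <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
  fp1 <- tibble(family = "FP1", power1 = powers, power2 = NA_real_)
  pairs <- expand.grid(i = seq_along(powers), j = seq_along(powers))
  pairs <- pairs[pairs$i <= pairs$j, ]
  fp2 <- tibble(family = "FP2", power1 = powers[pairs$i], power2 = powers[pairs$j])
  out <- bind_rows(fp1, fp2)
  out$model_id <- sprintf("%s(%s)", out$family,
                          ifelse(is.na(out$power2),
                                 as.character(out$power1),
                                 paste(out$power1, out$power2, sep = ",")))
  out$label <- out$model_id
  out[, c("model_id", "family", "power1", "power2", "label")]
}

# one FP basis column; p = 0 means log(x)
fp_term <- function(x, p) if (p == 0) log(x) else x^p

# design matrix (no intercept column) for one candidate
fp_design <- function(age, family, p1, p2) {
  if (family == "FP1" || is.na(p2)) {
    m <- cbind(fp_term(age, p1))
    colnames(m) <- paste0("t1")
  } else if (p1 == p2) {
    m <- cbind(fp_term(age, p1), fp_term(age, p1) * log(age))
    colnames(m) <- c("t1", "t2")
  } else {
    m <- cbind(fp_term(age, p1), fp_term(age, p2))
    colnames(m) <- c("t1", "t2")
  }
  m
}

#' Fit age-specific reference intervals by fractional-polynomial search
#'
#' Fits every candidate mean model by least squares and keeps the one with
#' the highest R-squared. The spread is then modeled from the winner's
#' residuals: `"constant_sd"` (default) uses the residual SD; `"linear_sd"`
#' regresses absolute residuals on age and scales by \eqn{\sqrt{\pi/2}}
#' (normal-theory mean absolute deviation), giving an age-varying SD. The
#' percentile function is \eqn{q_p(\mathrm{age}) = \hat\mu(\mathrm{age}) +
#' z_p \hat\sigma(\mathrm{age})} with standard-normal multipliers.
#'
#' Candidates whose design matrix is degenerate on the data (collinear or
#' non-finite) are skipped with a warning.
#'
#' @param data Tibble with columns `age` (positive) and `score`.
#' @param candidates Candidate roster (default [candidate_models()]); editable
#'   configuration, not code.
#' @param spread `"constant_sd"` or `"linear_sd"`.
#' @param min_n Minimum observations (default 50).
#' @return A `neatlink_refmodel` object: `terms` (winning powers),
#'   `coefficients`, `r_squared`, `spread_model`, `fit_n`, `age_range`,
#'   `search` (tibble of all candidates' R-squared), plus prediction
#'   closures `mean_fn(age)` and `sd_fn(age)`.
#' @export
fit_reference <- function(data, candidates = candidate_models(),
                          spread = c("constant_sd", "linear_sd"), min_n = 50) {
  spread <- match.arg(spread)
  if (!is.data.frame(data) || !all(c("age", "score") %in% names(data))) {
    abort("`data` needs columns `age` and `score`.", class = "neatlink_invalid_argument")
  }
  data <- data[complete.cases(data[, c("age", "score")]), ]
  if (nrow(data) < min_n) {
    abort(sprintf("Need at least %d observations.", min_n),
          class = "neatlink_invalid_argument")
  }
  if (any(data$age <= 0)) abort("Ages must be positive.", class = "neatlink_invalid_argument")
  age <- data$age; score <- data$score
  tss <- sum((score - mean(score))^2)

  fits <- purrr::pmap(candidates, function(model_id, family, power1, power2, label) {
    X <- fp_design(age, family, power1, power2)
    if (any(!is.finite(X)) || qr(cbind(1, X))$rank < ncol(X) + 1) {
      warn(paste0("Skipping degenerate candidate ", model_id))
      return(list(model_id = model_id, r_squared = NA_real_, fit = NULL))
    }
    fit <- lm.fit(cbind(`(Intercept)` = 1, X), score)
    rss <- sum(fit$residuals^2)
    r2 <- if (tss > 0) 1 - rss / tss else 0
    list(model_id = model_id, r_squared = r2, fit = fit)
  })
  search <- tibble(model_id = purrr::map_chr(fits, "model_id"),
                   r_squared = purrr::map_dbl(fits, "r_squared")) |>
    left_join(candidates, by = "model_id") |>
    arrange(dplyr::desc(.data$r_squared))
  if (all(is.na(search$r_squared))) {
    abort("No candidate could be fitted.", class = "neatlink_invalid_argument")
  }
  best_id <- search$model_id[1]
  best <- fits[[which(purrr::map_chr(fits, "model_id") == best_id)]]
  spec <- candidates[candidates$model_id == best_id, ]
  coefs <- best$fit$coefficients
  resid <- best$fit$residuals

  if (spread == "constant_sd") {
    p_used <- length(coefs)
    sigma <- sqrt(sum(resid^2) / (length(resid) - p_used))
    spread_coefs <- c(intercept = sigma, slope = 0)
  } else {
    sfit <- lm(abs(resid) ~ age)
    spread_coefs <- coef(sfit) * sqrt(pi / 2)
    names(spread_coefs) <- c("intercept", "slope")
  }

  mean_fn <- local({
    fam <- spec$family; p1 <- spec$power1; p2 <- spec$power2; cf <- coefs
    function(age_new) as.numeric(cbind(1, fp_design(age_new, fam, p1, p2)) %*% cf)
  })
  sd_fn <- local({
    sc <- spread_coefs
    function(age_new) {
      s <- sc[["intercept"]] + sc[["slope"]] * age_new
      if (any(s < 0)) {
        abort("Spread model implies negative SD inside the age range.",
              class = "neatlink_invalid_argument")
      }
      s
    }
  })

  structure(list(model_id = best_id, family = spec$family,
                 terms = c(spec$power1, spec$power2),
                 coefficients = coefs, r_squared = best$r_squared,
                 spread_model = spread, spread_coefficients = spread_coefs,
                 fit_n = length(resid), age_range = range(age),
                 search = search, mean_fn = mean_fn, sd_fn = sd_fn),
            class = "neatlink_refmodel")
}

#' @export
print.neatlink_refmodel <- function(x, ...) {
  cat(sprintf("Age-reference model %s, R-squared %.3f (n = %d, ages %.1f-%.1f)\n",
              x$model_id, x$r_squared, x$fit_n, x$age_range[1], x$age_range[2]))
  cat("  spread:", x$spread_model, "\n")
  invisible(x)
}

#' Build an age-by-percentile norm table
#'
#' Tabulates \eqn{q_p(\mathrm{age})} at integer ages and the requested
#' percentile levels, rounded half-up (the only place rounding happens) and
#' clamped to \[0, `max_score`\]. Entries are non-decreasing along each row by
#' construction of the percentile function; refusal to extrapolate outside
#' the fitted age range is explicit.
#'
#' @param model A `neatlink_refmodel`.
#' @param ages Integer ages, within the fitted range.
#' @param levels Percentile levels (default `c(2.5, 10, 25, 50, 75, 90)`).
#' @param max_score Score ceiling for clamping (default 45).
#' @return A `neatlink_normtable` tibble: `age`, `level`, `entry`.
#' @export
norm_table <- function(model, ages, levels = c(2.5, 10, 25, 50, 75, 90),
                       max_score = 45) {
  if (!inherits(model, "neatlink_refmodel")) {
    abort("`model` must come from fit_reference().", class = "neatlink_invalid_argument")
  }
  # integer ages at the boundary of a continuous fitted range are allowed
  lo <- floor(model$age_range[1]); hi <- ceiling(model$age_range[2])
  if (any(ages < lo | ages > hi)) {
    abort(sprintf("Ages outside the fitted range [%.2f, %.2f]; refusing to extrapolate.",
                  model$age_range[1], model$age_range[2]),
          class = "neatlink_extrapolation")
  }
  if (any(levels <= 0 | levels >= 100)) {
    abort("Percentile levels must lie in (0, 100).", class = "neatlink_invalid_argument")
  }
  grid <- tidyr::expand_grid(age = ages, level = sort(levels))
  z <- qnorm(grid$level / 100)
  raw <- model$mean_fn(grid$age) + z * model$sd_fn(grid$age)
  grid$entry <- pmin(pmax(round_half_up(raw), 0), max_score)
  # enforce within-age ordering after clamping/rounding
  grid <- grid |>
    group_by(.data$age) |>
    mutate(entry = cummax(.data$entry)) |>
    ungroup()
  class(grid) <- c("neatlink_normtable", class(grid))
  attr(grid, "max_score") <- max_score
  grid
}

#' Norm table from a long or wide data frame
#'
#' Turns a published age-by-percentile table (wide: one column per level) into
#' the long `neatlink_normtable` form used by the lookup functions.
#'
#' @param df Wide data frame: column `age`, remaining columns named by
#'   percentile level (e.g. `"2.5"`, `"10"`, ...).
#' @param max_score Score ceiling associated with the table.
#' @return A `neatlink_normtable` tibble.
#' @export
as_norm_table <- function(df, max_score = 45) {
  long <- tidyr::pivot_longer(as_tibble(df), -"age", names_to = "level",
                              values_to = "entry")
  long$level <- as.numeric(long$level)
  long <- arrange(long, .data$age, .data$level)
  class(long) <- c("neatlink_normtable", class(long))
  attr(long, "max_score") <- max_score
  long
}

#' Published age norms for the reduced form
#'
#' The instrument's published reference-specific age-interval table for the
#' reduced form (scores on the B-R scale, percentiles generated with
#' observed-score equating): ages 7--11, levels 2.5/10/25/50/75/90.
#'
#' @return A `neatlink_normtable` tibble.
#' @export
published_norm_table <- function() {
  path <- system.file("extdata", "form_br_age_norms.csv", package = "neatlink")
  wide <- readr::read_csv(path, show_col_types = FALSE)
  names(wide) <- sub("^p", "", names(wide))
  as_norm_table(wide, max_score = 45)
}

#' Percentile band of a score at an age
#'
#' Returns the highest tabulated percentile level whose entry does not
#' exceed the score, together with the bracketing band (that level and the
#' next one up; scores below the lowest entry report the band below the
#' lowest level).
#'
#' @param table A `neatlink_normtable`.
#' @param age Integer age present in the table.
#' @param score Integer raw score.
#' @return A tibble `age`, `score`, `percentile` (`NA` when below the lowest
#'   entry), `band_low`, `band_high`.
#' @export
score_to_percentile_band <- function(table, age, score) {
  rows <- table[table$age == age, ]
  if (nrow(rows) == 0) {
    abort(sprintf("Age %s not present in the norm table.", age),
          class = "neatlink_invalid_argument")
  }
  rows <- arrange(rows, .data$level)
  at_or_below <- which(rows$entry <= score)
  if (length(at_or_below) == 0) {
    return(tibble(age = age, score = score, percentile = NA_real_,
                  band_low = 0, band_high = rows$level[1]))
  }
  i <- max(at_or_below)
  tibble(age = age, score = score, percentile = rows$level[i],
         band_low = rows$level[i],
         band_high = if (i < nrow(rows)) rows$level[i + 1] else 100)
}

#' Percentile lookup for a score reported on the other form
#'
#' Converts the raw score through an equating table, rounds half-up (values
#' above the .50 decimal go up), and looks the result up in the norm table.
#'
#' @param score Raw score on the other form.
#' @param equating_table A `neatlink_equating` tibble mapping that form onto
#'   the norm table's scale.
#' @param table A `neatlink_normtable`.
#' @param age Integer age.
#' @return As [score_to_percentile_band()], with an extra column
#'   `equated_score`.
#' @export
equated_norm_lookup <- function(score, equating_table, table, age) {
  eq <- apply_equating(equating_table, score)
  rounded <- round_half_up(eq)
  out <- score_to_percentile_band(table, age, rounded)
  out$equated_score <- eq
  out
}
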