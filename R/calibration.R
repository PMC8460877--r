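#' Coerce a response tibble to an internal 0/1 matrix
#'
#' Responses travel as a tibble with one row per examinee: `examinee_id`,
#' optionally `group_label`, then one 0/1/`NA` column per item. Omitted
#' responses within a taken form are scored incorrect (0) by convention, which
#' is how no-responses are scored in the instrument; set
#' `na_as_incorrect = FALSE` to keep them missing (they are then ignored by
#' the likelihood).
#'
#' @param responses Response tibble.
#' @param na_as_incorrect Score `NA` as 0 (default `TRUE`).
#' @return A list with the numeric matrix `x` (examinee x item), the
#'   observation-indicator matrix `obs`, `examinee_id` and `group_label`.
#' @keywords internal
response_matrix <- function(responses, na_as_incorrect = TRUE) {
  if (!is.data.frame(responses) || !"examinee_id" %in% names(responses)) {
    abort("`responses` must be a data frame with an `examinee_id` column.",
          class = "neatlink_invalid_argument")
  }
  meta <- intersect(c("examinee_id", "group_label"), names(responses))
  item_cols <- setdiff(names(responses), meta)
  if (length(item_cols) == 0) {
    abort("`responses` has no item columns.", class = "neatlink_invalid_argument")
  }
  if (anyDuplicated(responses$examinee_id)) {
    abort("Duplicate `examinee_id`.", class = "neatlink_invalid_argument")
  }
  x <- as.matrix(responses[item_cols])
  storage.mode(x) <- "double"
  bad <- x[!is.na(x)]
  if (any(bad != 0 & bad != 1)) {
    abort("Item responses must be 0, 1 or NA.", class = "neatlink_invalid_argument")
  }
  if (na_as_incorrect) x[is.na(x)] <- 0
  obs <- 1 - is.na(x)
  x[is.na(x)] <- 0
  list(x = x, obs = obs, examinee_id = as.character(responses$examinee_id),
       group_label = if ("group_label" %in% meta) as.character(responses$group_label)
                     else rep(NA_character_, nrow(x)),
       item_ids = item_cols)
}

# posterior over grid nodes per examinee, plus marginal log-likelihood
e_step <- function(x, obs, P, w) {
  logP <- log(P); log1P <- log1p(-P)
  ll <- (x * obs) %*% logP + ((1 - x) * obs) %*% log1P   # n x K
  ll <- sweep(ll, 2, log(w), `+`)
  m <- apply(ll, 1, max)
  post <- exp(ll - m)
  norm <- rowSums(post)
  list(post = post / norm, loglik = sum(log(norm) + m))
}

# M-step for one item by Fisher scoring on the expected complete-data
# log-likelihood, with step halving so the objective never decreases (keeps
# the outer EM monotone); returns updated (a, b)
m_step_item <- function(a, b, r, m, nodes, max_iter = 10, tol = 1e-8) {
  obj <- function(a_, b_) {
    p <- plogis(a_ * (nodes - b_))
    sum(r * log(p) + (m - r) * log1p(-p))
  }
  f0 <- obj(a, b)
  for (it in seq_len(max_iter)) {
    p <- plogis(a * (nodes - b))
    resid <- r - m * p
    g <- c(sum(resid * (nodes - b)), -a * sum(resid))
    wgt <- m * p * (1 - p)
    # expected information in (a, b)
    Iaa <- sum(wgt * (nodes - b)^2)
    Ibb <- a^2 * sum(wgt)
    Iab <- -a * sum(wgt * (nodes - b))
    det <- Iaa * Ibb - Iab^2
    if (!is.finite(det) || det <= 1e-12) break
    step <- c(Ibb * g[1] - Iab * g[2], -Iab * g[1] + Iaa * g[2]) / det
    # damp huge steps; keep a positive
    step <- pmax(pmin(step, 1), -1)
    moved <- FALSE
    for (h in 0:5) {
      a_new <- a + step[1] / 2^h; b_new <- b + step[2] / 2^h
      if (a_new < 1e-3) a_new <- 1e-3
      f_new <- obj(a_new, b_new)
      if (is.finite(f_new) && f_new >= f0) {
        moved <- abs(a_new - a) > tol || abs(b_new - b) > tol
        a <- a_new; b <- b_new; f0 <- f_new
        break
      }
    }
    if (!moved) break
  }
  c(a, b)
}

#' Fit the 2PL model by marginal maximum likelihood (Bock--Aitkin EM)
#'
#' Calibrates all items of one form against a fixed quadrature grid with a
#' standard-normal ability prior, which identifies the latent scale as mean 0,
#' SD 1. The M-step updates each item by Fisher scoring on the expected
#' complete-data log-likelihood. Standard errors come from the empirical
#' cross-product (outer product of per-examinee scores) approximation to the
#' observed information at convergence.
#'
#' Items observed all-correct or all-incorrect are unidentified and are
#' excluded before fitting (recorded in `$excluded`). Non-convergence within
#' `max_cycles` is flagged, not an error.
#'
#' @param responses Response tibble (see [response_matrix()]).
#' @param grid Quadrature grid from [ability_grid()].
#' @param form_id Form label stored in the fitted bank.
#' @param item_meta Optional tibble of item metadata (`item_id`, `text_id`,
#'   `question_type`, `is_anchor`) joined onto the fitted bank.
#' @param max_cycles,tol EM stopping rule: stop when the maximum absolute
#'   parameter change falls below `tol` (default 1e-4) or after `max_cycles`
#'   (default 500) cycles.
#' @param na_as_incorrect Score missing responses as incorrect (default).
#' @return An object of class `neatlink_fit`: a list with `bank` (item tibble
#'   with `a`, `b`, `se_a`, `se_b`, `reliability`), `eap` (per-examinee
#'   ability estimate and posterior SD), `loglik_trace`, `n_cycles`,
#'   `converged`, `excluded`, `n_examinees`.
#' @examples
#' study <- generate_neat_study(study_config(n_from = 150, n_to = 120, seed = 1))
#' fit <- fit_2pl(study$responses_from, max_cycles = 50)
#' head(tidy(fit))
#' @export
fit_2pl <- function(responses, grid = ability_grid(), form_id = "F",
                    item_meta = NULL, max_cycles = 500, tol = 1e-4,
                    na_as_incorrect = TRUE) {
  validate_grid(grid)
  rm_ <- response_matrix(responses, na_as_incorrect = na_as_incorrect)
  x <- rm_$x; obs <- rm_$obs
  if (ncol(x) < 2 || nrow(x) < 2) {
    abort("Need at least 2 items and 2 examinees.", class = "neatlink_invalid_argument")
  }
  # degenerate filter: all-0 or all-1 among observed entries, or all-missing
  n_obs <- colSums(obs)
  n_correct <- colSums(x * obs)
  degenerate <- n_obs == 0 | n_correct == 0 | n_correct == n_obs
  excluded <- tibble(item_id = rm_$item_ids[degenerate],
                     reason = ifelse(n_obs[degenerate] == 0, "all_missing", "degenerate"))
  if (any(degenerate)) {
    warn(paste0("Excluding ", sum(degenerate), " degenerate item(s): ",
                paste(rm_$item_ids[degenerate], collapse = ", ")))
    x <- x[, !degenerate, drop = FALSE]; obs <- obs[, !degenerate, drop = FALSE]
  }
  item_ids <- rm_$item_ids[!degenerate]
  J <- ncol(x)
  if (J < 2) abort("Fewer than 2 identifiable items remain.", class = "neatlink_invalid_argument")

  nodes <- grid$node; w <- grid$weight
  pbar <- pmin(pmax(colSums(x * obs) / colSums(obs), 0.02), 0.98)
  a <- rep(1, J); b <- -qlogis(pbar)
  trace <- numeric(0); converged <- FALSE; cycle <- 0
  repeat {
    cycle <- cycle + 1
    P <- plogis(outer(a, nodes, "*") - outer(a * b, rep(1, length(nodes))))
    es <- e_step(x, obs, P, w)
    trace <- c(trace, es$loglik)
    r <- t(x * obs) %*% es$post          # J x K expected corrects
    m <- t(obs) %*% es$post              # J x K expected attempts
    old <- c(a, b)
    for (j in seq_len(J)) {
      ab <- m_step_item(a[j], b[j], r[j, ], m[j, ], nodes)
      a[j] <- ab[1]; b[j] <- ab[2]
    }
    delta <- max(abs(c(a, b) - old))
    if (delta < tol) { converged <- TRUE; break }
    if (cycle >= max_cycles) break
  }

  # final posterior for EAP scores and standard errors
  P <- plogis(outer(a, nodes, "*") - outer(a * b, rep(1, length(nodes))))
  es <- e_step(x, obs, P, w)
  post <- es$post
  eap <- as.numeric(post %*% nodes)
  psd <- sqrt(pmax(as.numeric(post %*% nodes^2) - eap^2, 0))
  all_missing <- rowSums(obs) == 0
  eap_tbl <- tibble(examinee_id = rm_$examinee_id, group_label = rm_$group_label,
                    eap = ifelse(all_missing, NA_real_, eap),
                    psd = ifelse(all_missing, NA_real_, psd),
                    defined = !all_missing)

  se <- fit_2pl_se(x, obs, post, a, b, P, nodes)

  bank <- tibble(item_id = item_ids, form_id = form_id,
                 text_id = NA_character_, question_type = NA_character_,
                 is_anchor = FALSE, a = a, b = b,
                 se_a = se$se_a, se_b = se$se_b,
                 reliability = item_reliability(a))
  if (!is.null(item_meta)) {
    keep <- intersect(c("item_id", "text_id", "question_type", "is_anchor"), names(item_meta))
    bank <- bank |>
      select(-all_of(setdiff(keep, "item_id"))) |>
      left_join(item_meta[keep], by = "item_id") |>
      select(all_of(c("item_id", "form_id", "text_id", "question_type",
                      "is_anchor", "a", "b", "se_a", "se_b", "reliability")))
    bank$is_anchor[is.na(bank$is_anchor)] <- FALSE
  }

  structure(list(bank = bank, eap = eap_tbl, loglik_trace = trace,
                 loglik = trace[length(trace)], n_cycles = cycle,
                 converged = converged, excluded = excluded,
                 n_examinees = nrow(x), grid = grid),
            class = "neatlink_fit")
}

# empirical cross-product information; G[i, ] = posterior-expected score of
# examinee i w.r.t. (a_j, b_j) for all j
fit_2pl_se <- function(x, obs, post, a, b, P, nodes) {
  n <- nrow(x); J <- ncol(x)
  S1 <- (x * obs) - obs * (post %*% t(P))                         # sum_k post (x - P)
  S2 <- (x * obs) * as.numeric(post %*% nodes) - obs * (post %*% t(P * matrix(nodes, J, length(nodes), byrow = TRUE)))
  G <- matrix(0, n, 2 * J)
  G[, seq(1, 2 * J, 2)] <- S2 - sweep(S1, 2, b, `*`)              # d/da
  G[, seq(2, 2 * J, 2)] <- -sweep(S1, 2, a, `*`)                  # d/db
  info <- crossprod(G)
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, 2 * J))
  if (anyNA(se)) warn("Observed information singular; standard errors set to NA.")
  list(se_a = se[seq(1, 2 * J, 2)], se_b = se[seq(2, 2 * J, 2)])
}

#' @export
print.neatlink_fit <- function(x, ...) {
  cat("2PL marginal-ML calibration\n")
  cat(sprintf("  items: %d   examinees: %d\n", nrow(x$bank), x$n_examinees))
  cat(sprintf("  log-likelihood: %.3f after %d EM cycles (%s)\n",
              x$loglik, x$n_cycles,
              if (x$converged) "converged" else "NOT converged"))
  if (nrow(x$excluded)) cat("  excluded items:", paste(x$excluded$item_id, collapse = ", "), "\n")
  invisible(x)
}

#' Marginal log-likelihood of a bank on a response set
#'
#' Evaluates the 2PL marginal likelihood with the same quadrature used by
#' [fit_2pl()], e.g. to compare fitted versus generating parameters.
#'
#' @inheritParams fit_2pl
#' @param bank Item bank whose `a`, `b` are evaluated; columns must match the
#'   response item columns.
#' @return The marginal log-likelihood (a scalar).
#' @export
marginal_loglik <- function(bank, responses, grid = ability_grid(),
                            na_as_incorrect = TRUE) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  rm_ <- response_matrix(responses, na_as_incorrect = na_as_incorrect)
  idx <- match(bank$item_id, rm_$item_ids)
  if (anyNA(idx)) abort("Bank items missing from responses.", class = "neatlink_invalid_argument")
  x <- rm_$x[, idx, drop = FALSE]; obs <- rm_$obs[, idx, drop = FALSE]
  P <- plogis(outer(bank$a, grid$node, "*") - outer(bank$a * bank$b, rep(1, nrow(grid))))
  e_step(x, obs, P, grid$weight)$loglik
}

#' Expected a posteriori ability scores
#'
#' Posterior mean and SD of ability given each examinee's responses, under a
#' calibrated bank and the grid's prior weights.
#'
#' @param bank Calibrated item bank.
#' @param responses Response tibble; bank items must be among its columns.
#' @param grid Quadrature grid.
#' @param na_as_incorrect Score missing responses as incorrect (default).
#' @return A tibble `examinee_id`, `group_label`, `eap`, `psd`, `defined`
#'   (`FALSE`, with `NA` estimates, for examinees with no observed responses).
#' @export
eap_scores <- function(bank, responses, grid = ability_grid(),
                       na_as_incorrect = TRUE) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  rm_ <- response_matrix(responses, na_as_incorrect = na_as_incorrect)
  idx <- match(bank$item_id, rm_$item_ids)
  if (anyNA(idx)) {
    abort(paste0("Bank items not in responses: ",
                 paste(bank$item_id[is.na(idx)], collapse = ", ")),
          class = "neatlink_invalid_argument")
  }
  x <- rm_$x[, idx, drop = FALSE]; obs <- rm_$obs[, idx, drop = FALSE]
  P <- plogis(outer(bank$a, grid$node, "*") - outer(bank$a * bank$b, rep(1, nrow(grid))))
  post <- e_step(x, obs, P, grid$weight)$post
  eap <- as.numeric(post %*% grid$node)
  psd <- sqrt(pmax(as.numeric(post %*% grid$node^2) - eap^2, 0))
  all_missing <- rowSums(obs) == 0
  tibble(examinee_id = rm_$examinee_id, group_label = rm_$group_label,
         eap = ifelse(all_missing, NA_real_, eap),
         psd = ifelse(all_missing, NA_real_, psd),
         defined = !all_missing)
}

#' Yen's Q1 item-fit statistic
#'
#' Partitions examinees into `n_groups` equal-count ability groups and
#' contrasts the observed proportion correct with the model-expected
#' proportion per group:
#' \eqn{Q_1 = \sum_g n_g (O_g - E_g)^2 / (E_g (1 - E_g))},
#' referred to a chi-square with `n_groups - 2` degrees of freedom for the
#' 2PL (two item parameters). An RMSEA associated with the chi-square is
#' reported as \eqn{\sqrt{\max(Q_1 - df, 0) / (df \cdot n)}}.
#'
#' To keep the statistic calibrated, the item under test is held out of its
#' own evaluation: examinees are grouped by the EAP computed from the
#' remaining items, and the expected proportion is the posterior-expected
#' item probability under that leave-one-out posterior (plugging in a point
#' ability estimate that includes the item inflates the statistic badly).
#'
#' Items whose expected proportion correct is essentially 0 or 1 in some
#' group (outside `(eps, 1 - eps)`) are flagged `computable = FALSE`: the
#' sample's ability range does not cover the item's difficulty, so the
#' statistic is not trustworthy there.
#'
#' @param bank Calibrated bank.
#' @param responses Response tibble.
#' @param n_groups Number of ability groups (default 10 deciles).
#' @param eps Guard band for expected proportions (default 1e-3).
#' @param grid Quadrature grid.
#' @return A tibble per item: `item_id`, `chi_square`, `df`, `p_value`,
#'   `rmsea`, `computable`.
#' @export
yen_q1_fit <- function(bank, responses, n_groups = 10, eps = 1e-3,
                       grid = ability_grid()) {
  bank <- validate_item_bank(bank); validate_grid(grid)
  rm_ <- response_matrix(responses)
  n <- nrow(rm_$x)
  if (n < n_groups) {
    abort("Fewer examinees than ability groups.", class = "neatlink_invalid_argument")
  }
  idx <- match(bank$item_id, rm_$item_ids)
  if (anyNA(idx)) abort("Bank items missing from responses.", class = "neatlink_invalid_argument")
  x <- rm_$x[, idx, drop = FALSE]; obs <- rm_$obs[, idx, drop = FALSE]
  nodes <- grid$node; w <- grid$weight
  P <- plogis(outer(bank$a, nodes, "*") - outer(bank$a * bank$b, rep(1, length(nodes))))
  ll_total <- (x * obs) %*% log(P) + ((1 - x) * obs) %*% log1p(-P)
  ll_total <- sweep(ll_total, 2, log(w), `+`)
  df <- n_groups - 2L
  purrr::map_dfr(seq_len(ncol(x)), function(j) {
    contrib <- (x[, j] * obs[, j]) %*% t(log(P[j, ])) +
      ((1 - x[, j]) * obs[, j]) %*% t(log1p(-P[j, ]))
    llj <- ll_total - contrib
    m <- apply(llj, 1, max)
    postj <- exp(llj - m); postj <- postj / rowSums(postj)
    eapj <- as.numeric(postj %*% nodes)
    pexp <- as.numeric(postj %*% P[j, ])
    use <- obs[, j] == 1
    nj <- sum(use)
    grp <- ceiling(rank(eapj[use], ties.method = "first") * n_groups / nj)
    O <- tapply(x[use, j], grp, mean)
    E <- tapply(pexp[use], grp, mean)
    n_g <- tabulate(grp, n_groups)
    computable <- all(E > eps & E < 1 - eps)
    chi2 <- sum(n_g * (O - E)^2 / (E * (1 - E)))
    tibble(item_id = bank$item_id[j], chi_square = chi2, df = df,
           p_value = pchisq(chi2, df, lower.tail = FALSE),
           rmsea = sqrt(pmax(chi2 - df, 0) / (df * nj)),
           computable = computable)
  })
}

#' Read / write response matrices
#'
#' CSV layout: first column `examinee_id`, optional `group_label`, then one
#' 0/1/NA column per item.
#'
#' @param path CSV path.
#' @param responses Response tibble.
#' @return `read_responses()` returns the tibble; `write_responses()` returns
#'   `path` invisibly.
#' @export
read_responses <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  response_matrix(out) # validation only
  out
}

#' @rdname read_responses
#' @export
write_responses <- function(responses, path) {
  readr::write_csv(responses, path, na = "")
  invisible(path)
}
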