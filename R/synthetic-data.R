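#' Configuration of a synthetic NEAT study
#'
#' Describes a common-item nonequivalent groups (NEAT) data set: two groups of
#' examinees, each taking its own form plus a shared internal anchor block,
#' with ages correlated with ability. Defaults emulate the reduced
#' reading-comprehension study conditions: 427 and 321 examinees, 33 unique
#' items per form plus 9 anchors, ages 6--12 with mean 9.1 and SD 1.0.
#'
#' The latent scale convention: true item parameters live on the *to*-form's
#' (base) scale, where the to-group is N(`to_mean`, `to_sd`) = N(0, 1) by
#' default. `true_link = c(A, B)` is the from-form-to-to-form transformation
#' \eqn{\theta_{to} = A\theta_{from} + B}: the from-group, standard normal on
#' its own scale, is therefore N(B, A) on the base scale. Calibrating each
#' group separately and linking the from-form onto the to-form recovers
#' (A, B).
#'
#' @param n_from,n_to Group sizes (defaults 427 and 321).
#' @param items_from,items_to Per-form unique-item content layout: a tibble
#'   with `text_id`, `question_type`, `n`. Defaults to the reduced forms'
#'   layout ([reduced_form_layout()]); use [full_pool_layout()] for the
#'   original 81/95-item pools.
#' @param n_anchor Number of anchor items (default 9).
#' @param a_range Range of generating discriminations (uniform; default
#'   0.6--2.0).
#' @param b_range Range of generating difficulties (uniform; default
#'   -2.5 to 2.5).
#' @param true_link Length-2 numeric `c(A, B)`, the from-to-to scale relation.
#'   The default, `c(0.91536, -0.21297)`, is the mild nonequivalence the
#'   study's Stocking--Lord linking estimated between the two randomly
#'   assigned groups.
#' @param to_mean,to_sd Ability distribution of the to-group on the base
#'   scale.
#' @param age_range Integer age bounds (default 6--12).
#' @param age_mean,age_sd Age distribution (default 9.1, 1.0).
#' @param age_ability_cor Latent correlation between age and ability (default
#'   0.6: comprehension grows with age across the 2nd--5th grades).
#' @param seed Integer seed; every draw flows from it.
#' @return A `neatlink_config` list.
#' @export
study_config <- function(n_from = 427, n_to = 321,
                         items_from = reduced_form_layout("A"),
                         items_to = reduced_form_layout("B"),
                         n_anchor = 9,
                         a_range = c(0.6, 2.0), b_range = c(-2.5, 2.5),
                         true_link = c(0.91536, -0.21297),
                         to_mean = 0, to_sd = 1,
                         age_range = c(6L, 12L), age_mean = 9.1, age_sd = 1.0,
                         age_ability_cor = 0.6, seed = 1L) {
  cfg <- list(n_from = n_from, n_to = n_to, items_from = items_from,
              items_to = items_to, n_anchor = n_anchor, a_range = a_range,
              b_range = b_range, true_link = true_link, to_mean = to_mean,
              to_sd = to_sd, age_range = age_range, age_mean = age_mean,
              age_sd = age_sd, age_ability_cor = age_ability_cor,
              seed = as.integer(seed))
  problems <- validate_study_config(cfg)
  if (length(problems)) {
    abort(paste0("Invalid study config:\n", paste("-", problems, collapse = "\n")),
          class = "neatlink_invalid_argument")
  }
  structure(cfg, class = "neatlink_config")
}

validate_study_config <- function(cfg) {
  p <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) p <<- c(p, msg)
  chk(is.numeric(cfg$n_from) && cfg$n_from >= 1, "n_from must be a positive count")
  chk(is.numeric(cfg$n_to) && cfg$n_to >= 1, "n_to must be a positive count")
  chk(is.numeric(cfg$n_anchor) && cfg$n_anchor >= 1, "n_anchor must be >= 1")
  chk(is.data.frame(cfg$items_from) && all(c("text_id", "question_type", "n") %in% names(cfg$items_from)),
      "items_from must have text_id, question_type, n")
  chk(is.data.frame(cfg$items_to) && all(c("text_id", "question_type", "n") %in% names(cfg$items_to)),
      "items_to must have text_id, question_type, n")
  chk(is.numeric(cfg$true_link) && length(cfg$true_link) == 2 && cfg$true_link[1] > 0,
      "true_link must be c(A, B) with A > 0")
  chk(is.numeric(cfg$to_sd) && cfg$to_sd > 0, "to_sd must be > 0")
  chk(is.numeric(cfg$age_ability_cor) && abs(cfg$age_ability_cor) < 1,
      "age_ability_cor must lie in (-1, 1)")
  chk(is.numeric(cfg$a_range) && length(cfg$a_range) == 2 && all(cfg$a_range > 0),
      "a_range must be positive")
  chk(is.numeric(cfg$age_range) && length(cfg$age_range) == 2 && cfg$age_range[1] < cfg$age_range[2],
      "age_range must be increasing")
  p
}

#' Packaged content layouts
#'
#' `reduced_form_layout()` gives each reduced form's unique-item counts per
#' text and question type (33 items over 7 texts); `full_pool_layout()` gives
#' the original item pools (81 items for form A, 95 for form B), with
#' per-text totals reconciled to the published per-text sums;
#' `anchor_layout()` gives the 9-item anchor block (1 LIT, 6 TC, 1 GAP,
#' 1 SM).
#'
#' @param form `"A"` or `"B"`.
#' @return A tibble `text_id`, `question_type`, `n`.
#' @export
reduced_form_layout <- function(form = c("A", "B")) {
  form <- match.arg(form)
  counts <- list( # per text: LIT, TC, GAP, SM — identical for the two forms
    T1 = c(1, 1, 1, 1), T2 = c(1, 2, 1, 0), T3 = c(1, 2, 1, 1),
    T4 = c(0, 3, 2, 1), T5 = c(0, 3, 1, 0), T6 = c(0, 4, 0, 0),
    T7 = c(1, 3, 2, 0))
  layout_from_counts(counts)
}

#' @rdname reduced_form_layout
#' @export
full_pool_layout <- function(form = c("A", "B")) {
  form <- match.arg(form)
  counts <- if (form == "A") {
    list(T1 = c(2, 5, 1, 1), T2 = c(1, 6, 2, 2), T3 = c(1, 5, 3, 1),
         T4 = c(3, 5, 5, 2), T5 = c(2, 4, 4, 2), T6 = c(0, 6, 6, 2),
         T7 = c(1, 5, 2, 2))
  } else {
    list(T1 = c(2, 9, 2, 1), T2 = c(3, 4, 6, 1), T3 = c(3, 5, 4, 1),
         T4 = c(1, 10, 3, 2), T5 = c(1, 9, 3, 0), T6 = c(2, 12, 0, 0),
         T7 = c(1, 8, 2, 0))
  }
  layout_from_counts(counts)
}

#' @rdname reduced_form_layout
#' @export
anchor_layout <- function() {
  layout_from_counts(list(ANCHOR = c(1, 6, 1, 1)))
}

layout_from_counts <- function(counts) {
  purrr::map_dfr(names(counts), function(tx) {
    tibble(text_id = tx, question_type = question_types(), n = counts[[tx]])
  }) |> filter(.data$n > 0)
}

layout_size <- function(layout) sum(layout$n)

# draw a bank of items for one layout, parameters on the base scale
draw_bank <- function(layout, prefix, form_id, a_range, b_range, is_anchor = FALSE) {
  rows <- layout[rep(seq_len(nrow(layout)), layout$n), c("text_id", "question_type")]
  J <- nrow(rows)
  item_bank(
    item_id = sprintf("%s%02d", prefix, seq_len(J)),
    a = runif(J, a_range[1], a_range[2]),
    b = runif(J, b_range[1], b_range[2]),
    form_id = form_id, text_id = rows$text_id,
    question_type = rows$question_type, is_anchor = is_anchor)
}

simulate_responses <- function(bank, theta, examinee_id, group_label) {
  p <- plogis(sweep(outer(theta, bank$b, "-"), 2, bank$a, "*"))
  x <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
  colnames(x) <- bank$item_id
  dplyr::bind_cols(tibble(examinee_id = examinee_id, group_label = group_label),
                   as_tibble(x))
}

# ages on an integer range with a target latent (Gaussian-copula) correlation
draw_ages <- function(z_ability, rho, age_mean, age_sd, age_range) {
  n <- length(z_ability)
  z_age <- rho * z_ability + sqrt(1 - rho^2) * rnorm(n)
  age <- round_half_up(age_mean + age_sd * z_age)
  pmin(pmax(age, age_range[1]), age_range[2])
}

#' Generate a synthetic NEAT study
#'
#' Draws true item banks (anchors shared exactly between forms), group
#' abilities, ages correlated with ability, and Bernoulli responses from the
#' 2PL item characteristic curves. All randomness flows from `config$seed`;
#' identical configs give bit-identical output.
#'
#' @param config A [study_config()].
#' @return A `neatlink_study` list: `responses_from`, `responses_to` (response
#'   tibbles including anchor columns), `bank_from`, `bank_to` (true
#'   generating banks on each form's own scale), `bank_from_base` (the from
#'   bank expressed on the base/to scale), `examinees` (age, true ability on
#'   both scales, group), `config`.
#' @examples
#' study <- generate_neat_study(study_config(n_from = 80, n_to = 60, seed = 42))
#' dim(study$responses_from)
#' @export
generate_neat_study <- function(config = study_config()) {
  if (!inherits(config, "neatlink_config")) config <- do.call(study_config, config)
  A0 <- config$true_link[1]; B0 <- config$true_link[2]
  withr::with_seed(config$seed, {
    # banks on the base (to-form) scale
    anchors <- draw_bank(anchor_layout(), "AN", "ANCHOR", config$a_range,
                         c(-1.5, 1.5), is_anchor = TRUE)
    uniq_from <- draw_bank(config$items_from, "A", "A", config$a_range, config$b_range)
    uniq_to <- draw_bank(config$items_to, "B", "B", config$a_range, config$b_range)
    bank_from_base <- bind_rows(uniq_from, mutate(anchors, form_id = "A"))
    bank_to <- bind_rows(uniq_to, mutate(anchors, form_id = "B"))

    # abilities on the base scale
    z_from <- rnorm(config$n_from)
    z_to <- rnorm(config$n_to)
    theta_from_base <- B0 + A0 * z_from
    theta_to_base <- config$to_mean + config$to_sd * z_to

    ages <- draw_ages(c(z_from, z_to), config$age_ability_cor,
                      config$age_mean, config$age_sd, config$age_range)

    id_from <- sprintf("F%04d", seq_len(config$n_from))
    id_to <- sprintf("T%04d", seq_len(config$n_to))
    responses_from <- simulate_responses(bank_from_base, theta_from_base, id_from, "from")
    responses_to <- simulate_responses(bank_to, theta_to_base, id_to, "to")
  })
  # the from-form bank on its own calibrated scale (where its group is N(0,1))
  bank_from <- mutate(bank_from_base, a = .data$a * A0, b = (.data$b - B0) / A0)
  examinees <- tibble(
    examinee_id = c(sprintf("F%04d", seq_len(config$n_from)),
                    sprintf("T%04d", seq_len(config$n_to))),
    group = rep(c("from", "to"), c(config$n_from, config$n_to)),
    age = ages,
    theta_base = c(theta_from_base, theta_to_base),
    theta_own = c(z_from, (theta_to_base - config$to_mean) / config$to_sd))
  structure(list(responses_from = responses_from, responses_to = responses_to,
                 bank_from = bank_from, bank_to = bank_to,
                 bank_from_base = bank_from_base,
                 examinees = examinees, config = config),
            class = "neatlink_study")
}

#' Affinely related anchor sets for linking oracles
#'
#' Builds `anchors_to` as the exact image of `anchors_from` under the
#' from-to-to transformation (`a/A`, `A b + B`), optionally perturbed with
#' independent Gaussian noise — the construction under which every linking
#' method must recover `(A, B)`.
#'
#' @param bank Anchor bank (the `from` side).
#' @param A,B Transformation coefficients, `A > 0`.
#' @param noise_sd SD of independent Gaussian perturbation added to the
#'   transformed parameters (default 0, exact affinity).
#' @param seed Optional seed for the perturbation.
#' @return A list `anchors_from`, `anchors_to`.
#' @export
generate_affine_pair <- function(bank, A, B, noise_sd = 0, seed = NULL) {
  bank <- validate_item_bank(bank)
  if (!is.numeric(A) || A <= 0) abort("`A` must be > 0.", class = "neatlink_invalid_argument")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.", class = "neatlink_invalid_argument")
  to <- mutate(bank, a = .data$a / A, b = A * .data$b + B)
  if (noise_sd > 0) {
    perturb <- function() {
      to$a <<- pmax(to$a + rnorm(nrow(to), 0, noise_sd), 0.05)
      to$b <<- to$b + rnorm(nrow(to), 0, noise_sd)
    }
    if (is.null(seed)) perturb() else withr::with_seed(seed, perturb())
  }
  list(anchors_from = bank, anchors_to = to)
}

#' Synthetic age--score data for reference-interval fitting
#'
#' Ages uniform on a range; scores are a mean function of age plus Gaussian
#' noise, truncated to \[0, `max_score`\] and rounded to integers.
#'
#' @param n Number of observations.
#' @param age_range Length-2 numeric.
#' @param mean_function Function of age giving the expected score.
#' @param sd Noise SD (>= 0).
#' @param max_score Upper truncation bound (default 45).
#' @param seed Integer seed.
#' @return A tibble `age`, `score`.
#' @export
generate_age_score_data <- function(n, age_range = c(6, 12),
                                    mean_function = function(age) 2 * age,
                                    sd = 3, max_score = 45, seed = 1L) {
  if (n <= 0) abort("`n` must be positive.", class = "neatlink_invalid_argument")
  if (sd < 0) abort("`sd` must be >= 0.", class = "neatlink_invalid_argument")
  withr::with_seed(seed, {
    age <- runif(n, age_range[1], age_range[2])
    score <- mean_function(age) + rnorm(n, 0, sd)
  })
  score <- round_half_up(pmin(pmax(score, 0), max_score))
  tibble(age = age, score = score)
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Emits the response CSVs, the item-metadata CSV, the examinee table, and a
#' ground-truth bundle (true banks, true link, config echo) as JSON.
#'
#' @param study A `neatlink_study`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_responses(study$responses_from, file.path(dir, "responses_from.csv"))
  write_responses(study$responses_to, file.path(dir, "responses_to.csv"))
  write_item_bank(study$bank_from, file.path(dir, "true_bank_from.csv"))
  write_item_bank(study$bank_to, file.path(dir, "true_bank_to.csv"))
  readr::write_csv(study$examinees, file.path(dir, "examinees.csv"))
  truth <- list(true_link = list(A = study$config$true_link[1],
                                 B = study$config$true_link[2]),
                config = unclass(study$config)[c("n_from", "n_to", "n_anchor",
                                                 "seed", "age_ability_cor")])
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
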