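test_that("study configs are validated with all violations listed", {
  expect_s3_class(study_config(), "neatlink_config")
  err <- expect_error(study_config(n_from = -5, to_sd = 0, age_ability_cor = 2),
                      class = "neatlink_invalid_argument")
  msg <- conditionMessage(err)
  expect_match(msg, "n_from")
  expect_match(msg, "to_sd")
  expect_match(msg, "age_ability_cor")
})

test_that("generation is bit-identical under the same seed", {
  s1 <- generate_neat_study(study_config(n_from = 60, n_to = 50, seed = 7))
  s2 <- generate_neat_study(study_config(n_from = 60, n_to = 50, seed = 7))
  expect_identical(s1$responses_from, s2$responses_from)
  expect_identical(s1$responses_to, s2$responses_to)
  expect_identical(s1$bank_from, s2$bank_from)
  s3 <- generate_neat_study(study_config(n_from = 60, n_to = 50, seed = 8))
  expect_false(identical(s1$responses_from, s3$responses_from))
})

test_that("anchor items share generating parameters across forms exactly", {
  study <- generate_neat_study(study_config(n_from = 40, n_to = 40, seed = 9))
  af <- dplyr::filter(study$bank_from_base, is_anchor) |> dplyr::arrange(item_id)
  at <- dplyr::filter(study$bank_to, is_anchor) |> dplyr::arrange(item_id)
  expect_identical(af$a, at$a)
  expect_identical(af$b, at$b)
})

test_that("the default study carries the published design dimensions", {
  study <- generate_neat_study(study_config(seed = 2))
  expect_equal(nrow(study$responses_from), 427)
  expect_equal(nrow(study$responses_to), 321)
  # 33 unique + 9 anchors per form
  expect_equal(ncol(study$responses_from) - 2, 42)
  expect_equal(ncol(study$responses_to) - 2, 42)
  expect_equal(sum(study$bank_from$is_anchor), 9)
  ages <- study$examinees$age
  expect_true(all(ages >= 6 & ages <= 12))
  # ages correlate positively with ability (configured rank correlation 0.6)
  expect_gt(cor(study$examinees$age, study$examinees$theta_own, method = "spearman"), 0.3)
})

test_that("group ability distributions encode the true link construction", {
  study <- generate_neat_study(study_config(n_from = 20000, n_to = 20000, seed = 10,
                                            true_link = c(0.8, -0.3)))
  ex <- study$examinees
  from_base <- ex$theta_base[ex$group == "from"]
  expect_equal(mean(from_base), -0.3, tolerance = 0.03)
  expect_equal(sd(from_base), 0.8, tolerance = 0.03)
  to_base <- ex$theta_base[ex$group == "to"]
  expect_equal(mean(to_base), 0, tolerance = 0.03)
  expect_equal(sd(to_base), 1, tolerance = 0.03)
  # the from-form's own-scale bank is the inverse image of the base bank
  tr <- transform_parameters(study$bank_from, 0.8, -0.3)
  expect_equal(tr$a, study$bank_from_base$a, tolerance = 1e-12)
  expect_equal(tr$b, study$bank_from_base$b, tolerance = 1e-12)
})

test_that("observed proportions correct match quadrature expectations in
           aggregate at study scale", {
  study <- generate_neat_study(study_config(seed = 12))
  grid <- ability_grid(201)
  # from-group abilities on the base scale are N(B, A)
  A0 <- study$config$true_link[1]; B0 <- study$config$true_link[2]
  w <- dnorm((grid$node - B0) / A0); w <- w / sum(w)
  p_exp <- vapply(seq_len(nrow(study$bank_from_base)), function(j) {
    sum(w * plogis(study$bank_from_base$a[j] * (grid$node - study$bank_from_base$b[j])))
  }, numeric(1))
  obs <- colMeans(study$responses_from[study$bank_from_base$item_id])
  n <- nrow(study$responses_from)
  se <- sqrt(p_exp * (1 - p_exp) / n)
  within3 <- abs(obs - p_exp) <= 3 * se
  expect_gte(mean(within3), 0.95)
})

test_that("affine pairs feed the linking oracle and perturbation stays local", {
  pair0 <- generate_affine_pair(toy_anchors(), A = 1, B = 0)
  expect_equal(pair0$anchors_from$a, pair0$anchors_to$a)
  expect_equal(pair0$anchors_from$b, pair0$anchors_to$b)
  fit <- link_forms(pair0$anchors_from, pair0$anchors_to, "haebara")
  expect_equal(fit$A, 1, tolerance = 1e-4)

  # noisy perturbation: recovered A within 0.1 of truth in >= 90% of replicates
  hits <- vapply(1:100, function(r) {
    pair <- generate_affine_pair(toy_anchors(), A = 1.1, B = 0.2,
                                 noise_sd = 0.05, seed = 3000 + r)
    fit_r <- link_forms(pair$anchors_from, pair$anchors_to, "stocking_lord")
    abs(fit_r$A - 1.1) <= 0.1
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("age-score generation is deterministic with regression-consistent slope", {
  d1 <- generate_age_score_data(750, mean_function = function(a) 4 + 2.5 * a,
                                sd = 2, seed = 33)
  d2 <- generate_age_score_data(750, mean_function = function(a) 4 + 2.5 * a,
                                sd = 2, seed = 33)
  expect_identical(d1, d2)
  fit <- lm(score ~ age, data = d1)
  se <- summary(fit)$coefficients["age", "Std. Error"]
  expect_lte(abs(coef(fit)["age"] - 2.5), 3 * se + 0.2)
  # zero noise: score is a deterministic (rounded) function of age
  d0 <- generate_age_score_data(100, sd = 0, seed = 34)
  expect_equal(d0$score, floor(2 * d0$age + 0.5))
})

test_that("studies round-trip to disk in the pipeline formats", {
  study <- generate_neat_study(study_config(n_from = 30, n_to = 25, seed = 14))
  dir <- withr::local_tempdir()
  write_study(study, dir)
  back <- read_responses(file.path(dir, "responses_from.csv"))
  expect_equal(nrow(back), 30)
  truth <- jsonlite::fromJSON(file.path(dir, "ground_truth.json"))
  expect_equal(truth$true_link$A, study$config$true_link[1])
  bank <- read_item_bank(file.path(dir, "true_bank_to.csv"))
  expect_equal(nrow(bank), nrow(study$bank_to))
})
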