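simulate_flat <- function(bank, theta, seed) {
  withr::with_seed(seed, {
    p <- plogis(sweep(outer(theta, bank$b, "-"), 2, bank$a, "*"))
    x <- matrix(rbinom(length(p), 1, p), nrow(p), ncol(p))
  })
  colnames(x) <- bank$item_id
  dplyr::bind_cols(tibble::tibble(examinee_id = sprintf("e%05d", seq_along(theta))),
                   tibble::as_tibble(x))
}

test_that("MML-EM recovers generating parameters at n = 2000, 40 items", {
  withr::with_seed(11, {
    bank <- item_bank(sprintf("i%02d", 1:40), a = runif(40, 0.8, 2.0),
                      b = runif(40, -2.5, 2.5))
    theta <- rnorm(2000)
  })
  fit <- fit_2pl(simulate_flat(bank, theta, 12))
  expect_true(fit$converged)
  expect_lt(mean(abs(fit$bank$b - bank$b)), 0.15)
  expect_gt(cor(fit$bank$a, bank$a), 0.9)
  # the fitted parameters must beat the truth on the fitted sample's own
  # marginal likelihood (same quadrature)
  resp <- simulate_flat(bank, theta, 12)
  expect_gte(marginal_loglik(fit$bank, resp), marginal_loglik(bank, resp) - 1e-6)
})

test_that("an ability-independent coin-flip item gets near-zero discrimination", {
  withr::with_seed(21, {
    bank <- item_bank(sprintf("i%02d", 1:20), a = runif(20, 0.8, 2), b = rnorm(20))
    theta <- rnorm(2000)
    resp <- simulate_flat(bank, theta, 22)
    resp$coin <- rbinom(2000, 1, 0.5)
  })
  fit <- fit_2pl(resp)
  expect_lt(abs(fit$bank$a[fit$bank$item_id == "coin"]), 0.2)
})

test_that("EM log-likelihood trace is monotone and the scale is identified", {
  pf <- parallel_fits()
  for (side in c("from", "to")) {
    trace <- pf[[side]]$loglik_trace
    expect_true(all(diff(trace) > -1e-8))
  }
  # mean EAP of the calibration sample pinned to 0 (prior identification)
  expect_lt(abs(mean(pf$from$eap$eap)), 0.05)
  expect_lt(abs(mean(pf$to$eap$eap)), 0.05)
})

test_that("difficulty recovery improves with sample size (seeds 1-5)", {
  mae <- function(n, seed) {
    withr::with_seed(seed, {
      bank <- item_bank(sprintf("i%02d", 1:20), a = runif(20, 0.8, 2),
                        b = runif(20, -2, 2))
      theta <- rnorm(n)
    })
    fit <- fit_2pl(simulate_flat(bank, theta, seed + 1000))
    mean(abs(fit$bank$b - bank$b))
  }
  for (seed in 1:5) {
    expect_lte(mae(4000, seed), mae(500, seed))
  }
})

test_that("degenerate items are excluded with a warning, not fitted", {
  withr::with_seed(31, {
    bank <- item_bank(sprintf("i%02d", 1:10), a = runif(10, 0.8, 2), b = rnorm(10))
    resp <- simulate_flat(bank, rnorm(300), 32)
  })
  resp$always1 <- 1
  expect_warning(fit <- fit_2pl(resp), "degenerate")
  expect_false("always1" %in% fit$bank$item_id)
  expect_equal(fit$excluded$item_id, "always1")
})

test_that("EAP scoring is monotone in raw score and matches direct quadrature", {
  bank <- item_bank(c("i1", "i2"), a = c(1.2, 0.9), b = c(-0.3, 0.6))
  grid <- ability_grid(21)
  resp <- tibble::tibble(examinee_id = c("lo", "hi"), i1 = c(0, 1), i2 = c(0, 1))
  eap <- eap_scores(bank, resp, grid)
  expect_lt(eap$eap[1], eap$eap[2])
  # direct summation oracle for the all-correct pattern
  lik <- plogis(1.2 * (grid$node + 0.3)) * plogis(0.9 * (grid$node - 0.6))
  post <- lik * grid$weight / sum(lik * grid$weight)
  expect_equal(eap$eap[2], sum(post * grid$node), tolerance = 1e-12)
  expect_true(all(eap$psd > 0))
  expect_error(eap_scores(bank[0, ], resp, grid), class = "neatlink_invalid_argument")
})

test_that("examinees with no observed responses get undefined EAP", {
  bank <- item_bank(c("i1", "i2"), a = c(1, 1), b = c(0, 0))
  resp <- tibble::tibble(examinee_id = c("e1", "e2"), i1 = c(1, NA), i2 = c(0, NA))
  eap <- eap_scores(bank, resp, na_as_incorrect = FALSE)
  expect_true(eap$defined[1])
  expect_false(eap$defined[2])
  expect_true(is.na(eap$eap[2]))
})

test_that("Yen Q1 is zero at perfect fit, flags uncoverable items, rejects at
           the nominal rate under the null", {
  pf <- parallel_fits()
  bank <- pf$from$bank
  # an item far too easy for the sample: expected proportions ~1 everywhere
  easy <- bank
  easy$b[1] <- -12
  resp <- pf$study$responses_from
  fitq <- yen_q1_fit(easy, resp)
  expect_false(fitq$computable[1])
  expect_equal(fitq$df[1], 8)
  expect_equal(fitq$rmsea, sqrt(pmax(fitq$chi_square - fitq$df, 0) /
                                  (fitq$df * nrow(resp))), tolerance = 1e-12)

  # Monte-Carlo null calibration: each replicate is simulated from the model,
  # refitted, and tested with its own fitted bank - the way the statistic is
  # used in practice (its df correction presumes estimated item parameters)
  withr::with_seed(41, {
    bank15 <- item_bank(sprintf("i%02d", 1:15), a = runif(15, 0.8, 1.8),
                        b = runif(15, -1.5, 1.5))
    rejections <- vapply(1:150, function(r) {
      resp_r <- simulate_flat(bank15, rnorm(1500), seed = 7000 + r)
      fit_r <- fit_2pl(resp_r)
      q <- yen_q1_fit(fit_r$bank, resp_r)
      q$p_value[7] < 0.05   # one pre-chosen mid-difficulty item
    }, logical(1))
  })
  rate <- mean(rejections)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.10)
})

test_that("Yen Q1 demands enough examinees for the deciles", {
  bank <- item_bank(c("i1", "i2"), a = c(1, 1), b = c(0, 0))
  resp <- tibble::tibble(examinee_id = paste0("e", 1:5),
                         i1 = c(0, 1, 0, 1, 1), i2 = c(1, 1, 0, 0, 1))
  expect_error(yen_q1_fit(bank, resp), class = "neatlink_invalid_argument")
})

test_that("response matrices round-trip through CSV", {
  resp <- tibble::tibble(examinee_id = c("e1", "e2"), group_label = "g",
                         i1 = c(1, 0), i2 = c(NA, 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(resp, path)
  back <- read_responses(path)
  expect_equal(back$i1, resp$i1)
  expect_true(is.na(back$i2[1]))
})
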