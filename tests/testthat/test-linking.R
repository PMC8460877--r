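test_that("moment methods match closed forms", {
  f <- item_bank(c("a1", "a2"), a = c(1, 1), b = c(0, 1), is_anchor = TRUE)
  t_ <- item_bank(c("a1", "a2"), a = c(1, 1), b = c(1, 3), is_anchor = TRUE)
  ms <- mean_sigma(f, t_)
  expect_equal(ms$A, 2); expect_equal(ms$B, 1)
  idm <- mean_sigma(f, f)
  expect_equal(idm$A, 1); expect_equal(idm$B, 0)
  aff <- generate_affine_pair(toy_anchors(), A = 0.9, B = -0.2)
  ms2 <- mean_sigma(aff$anchors_from, aff$anchors_to)
  expect_equal(ms2$A, 0.9, tolerance = 1e-12)
  expect_equal(ms2$B, -0.2, tolerance = 1e-12)

  mm <- mean_mean(f, f)
  expect_equal(mm$A, 1); expect_equal(mm$B, 0)
  t2 <- dplyr::mutate(f, a = a / 2, b = 2 * b + 1)
  mm2 <- mean_mean(f, t2)
  expect_equal(mm2$A, 2); expect_equal(mm2$B, 1)
  single <- mean_mean(item_bank("x", a = 1, b = 0), item_bank("x", a = 0.5, b = 1))
  expect_equal(single$A, 2); expect_equal(single$B, 1)

  degen <- item_bank(c("a1", "a2"), a = c(1, 1), b = c(0.5, 0.5), is_anchor = TRUE)
  expect_error(mean_sigma(degen, t_), class = "neatlink_degenerate_anchor")
})

test_that("characteristic-curve methods recover exact affine relations over a
           grid of coefficients (all four methods, 1e-4)", {
  anchors <- toy_anchors()
  for (A0 in c(0.7, 0.91536, 1, 1.3, 1.7)) {
    for (B0 in c(-0.4, 0, 0.5)) {
      pair <- generate_affine_pair(anchors, A = A0, B = B0)
      for (mth in c("mean_mean", "mean_sigma", "haebara", "stocking_lord")) {
        fit <- link_forms(pair$anchors_from, pair$anchors_to, method = mth)
        expect_equal(fit$A, A0, tolerance = 1e-4)
        expect_equal(fit$B, B0, tolerance = 1e-4)
      }
    }
  }
})

test_that("identical anchor sets give the identity transformation", {
  anchors <- toy_anchors()
  for (mth in c("haebara", "stocking_lord")) {
    fit <- link_forms(anchors, anchors, method = mth)
    expect_equal(fit$A, 1, tolerance = 1e-6)
    expect_equal(fit$B, 0, tolerance = 1e-6)
  }
})

test_that("the optimized criterion never exceeds its mean-sigma start", {
  pair <- generate_affine_pair(toy_anchors(), A = 1.2, B = 0.3, noise_sd = 0.08,
                               seed = 81)
  grid <- ability_grid()
  for (mth in c("haebara", "stocking_lord")) {
    fit <- link_forms(pair$anchors_from, pair$anchors_to, method = mth)
    ms <- mean_sigma(pair$anchors_from, pair$anchors_to)
    start_val <- neatlink:::cc_criterion(c(ms$A, ms$B), pair$anchors_from,
                                         pair$anchors_to, grid$node, grid$weight,
                                         symmetric_sum = mth == "stocking_lord")
    expect_lte(fit$criterion, start_val + 1e-10)
  }
})

test_that("parameter transformation matches the printed worked example and
           preserves item characteristic curves", {
  bank <- item_bank("anchor1", a = 1.285143, b = 0.835929)
  out <- transform_parameters(bank, A = 0.91536, B = -0.21297)
  expect_equal(out$a, 1.403976, tolerance = 1e-6)
  expect_equal(out$b, 0.5522, tolerance = 1e-4)
  ident <- transform_parameters(bank, 1, 0)
  expect_equal(ident$a, bank$a); expect_equal(ident$b, bank$b)
  expect_error(transform_parameters(bank, -1, 0), class = "neatlink_invalid_argument")
  # ICC invariance: P(theta; a, b) = P(A theta + B; a/A, A b + B)
  theta <- seq(-3, 3, by = 0.5)
  A <- 0.83; B <- 0.41
  tr <- transform_parameters(toy_anchors(), A, B)
  for (j in seq_len(nrow(tr))) {
    expect_equal(icc(toy_anchors()$a[j], toy_anchors()$b[j], theta),
                 icc(tr$a[j], tr$b[j], A * theta + B), tolerance = 1e-12)
  }
})

test_that("on noisy parallel-form calibrations the two characteristic-curve
           methods agree and the link round-trips", {
  pf <- parallel_fits()
  af <- dplyr::filter(pf$from$bank, is_anchor)
  at <- dplyr::filter(pf$to$bank, is_anchor)
  hb <- link_forms(af, at, "haebara")
  sl <- link_forms(af, at, "stocking_lord")
  expect_lt(abs(hb$A - sl$A), 0.05)
  fwd <- link_forms(af, at, "stocking_lord")
  bwd <- link_forms(at, af, "stocking_lord")
  expect_lt(abs(fwd$A * bwd$A - 1), 0.05)
  expect_lt(abs(bwd$A * fwd$B + bwd$B), 0.05)
})

test_that("bootstrap linking SEs are deterministic, vanish with zero input SE,
           and scale with the input SEs", {
  anchors <- toy_anchors()
  pair <- generate_affine_pair(anchors, A = 0.95, B = -0.1)
  f0 <- dplyr::mutate(pair$anchors_from, se_a = 0, se_b = 0)
  t0 <- dplyr::mutate(pair$anchors_to, se_a = 0, se_b = 0)
  fit0 <- linking_se(f0, t0, method = "mean_sigma", n_boot = 50, seed = 5)
  expect_equal(fit0$se_A, 0); expect_equal(fit0$se_B, 0)

  f1 <- dplyr::mutate(pair$anchors_from, se_a = 0.1, se_b = 0.1)
  t1 <- dplyr::mutate(pair$anchors_to, se_a = 0.1, se_b = 0.1)
  fit1 <- linking_se(f1, t1, method = "mean_sigma", n_boot = 2000, seed = 5)
  fit1b <- linking_se(f1, t1, method = "mean_sigma", n_boot = 2000, seed = 5)
  expect_identical(fit1$se_A, fit1b$se_A)
  f2 <- dplyr::mutate(f1, se_a = 0.2, se_b = 0.2)
  t2 <- dplyr::mutate(t1, se_a = 0.2, se_b = 0.2)
  fit2 <- linking_se(f2, t2, method = "mean_sigma", n_boot = 2000, seed = 5)
  ratio <- fit2$se_A / fit1$se_A
  expect_gte(ratio, 1.6); expect_lte(ratio, 2.4)

  # missing SEs: result returned with NA SEs and a warning, not an error
  expect_warning(fitna <- linking_se(pair$anchors_from, pair$anchors_to,
                                     method = "mean_sigma", n_boot = 10),
                 "unavailable")
  expect_true(is.na(fitna$se_A))
})

test_that("tidy and glance expose linking results as tibbles", {
  fit <- link_forms(toy_anchors(), toy_anchors(), "stocking_lord")
  td <- tidy(fit)
  expect_equal(td$term, c("A", "B"))
  expect_equal(td$estimate, c(1, 0), tolerance = 1e-6)
  gl <- glance(fit)
  expect_equal(gl$method, "stocking_lord")
  expect_equal(gl$n_anchors, 9)
})
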