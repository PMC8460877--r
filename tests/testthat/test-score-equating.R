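test_that("Lord-Wingersky equals exhaustive enumeration up to 12 items", {
  expect_equal(lord_wingersky(c(0.5, 0.5)), c(0.25, 0.5, 0.25))
  expect_equal(lord_wingersky(c(1, 1, 1)), c(0, 0, 0, 1))
  expect_equal(lord_wingersky(numeric(0)), 1)
  withr::with_seed(91, {
    for (n in c(3, 7, 12)) {
      p <- runif(n)
      expect_equal(lord_wingersky(p), enumerate_score_dist(p), tolerance = 1e-12)
    }
  })
  expect_error(lord_wingersky(c(0.5, 1.2)), class = "neatlink_invalid_argument")
})

test_that("marginal score distribution integrates to 1 with the TCC as mean", {
  withr::local_seed(1234)
  one <- item_bank("i1", a = 1, b = 0)
  grid <- ability_grid()  # symmetric nodes and weights about 0
  d1 <- marginal_score_distribution(one, grid)
  expect_equal(d1$probability[d1$score == 1], 0.5, tolerance = 1e-6)

  bank <- item_bank(paste0("i", 1:8), a = runif(8, 0.5, 2), b = rnorm(8))
  d <- marginal_score_distribution(bank, grid)
  expect_equal(sum(d$probability), 1, tolerance = 1e-10)
  expect_true(all(d$probability >= 0))
  expect_equal(sum(d$score * d$probability),
               sum(grid$weight * test_characteristic_curve(bank, grid$node)),
               tolerance = 1e-8)
})

test_that("marginal score distribution matches a Monte-Carlo oracle", {
  withr::with_seed(101, {
    bank <- item_bank(paste0("i", 1:5), a = runif(5, 0.6, 1.8), b = runif(5, -1, 1))
    theta <- rnorm(1e5)
    p <- plogis(sweep(outer(theta, bank$b, "-"), 2, bank$a, "*"))
    scores <- rowSums(matrix(rbinom(length(p), 1, p), nrow(p), ncol(p)))
  })
  emp <- tabulate(scores + 1, 6) / 1e5
  d <- marginal_score_distribution(bank, ability_grid(201))
  mc_se <- sqrt(emp * (1 - emp) / 1e5)
  expect_true(all(abs(d$probability - emp) <= 3 * mc_se + 1e-4))
})

test_that("true-score equating is the identity on itself, monotone, and lower
           against a uniformly harder form", {
  withr::local_seed(1234)
  bank <- item_bank(paste0("i", 1:12), a = runif(12, 0.7, 1.8), b = runif(12, -1.5, 1.5))
  self_eq <- true_score_equating(bank, bank)
  expect_equal(self_eq$equivalent, self_eq$score, tolerance = 1e-6)
  harder <- dplyr::mutate(bank, b = b + 0.5)
  eq <- true_score_equating(bank, harder)
  inner <- eq$score > 0 & eq$score < 12
  expect_true(all(eq$equivalent[inner] < eq$score[inner]))
  expect_true(all(diff(eq$equivalent) >= 0))
  expect_equal(eq$equivalent[1], 0)
  expect_equal(eq$equivalent[13], 12)
})

test_that("equipercentile behaves on identity, shift and degenerate cases", {
  withr::local_seed(1234)
  bank <- item_bank(paste0("i", 1:10), a = runif(10, 0.7, 1.6), b = rnorm(10))
  d <- marginal_score_distribution(bank)
  ident <- equipercentile(d, d)
  expect_true(all(abs(ident$equivalent - ident$score) < 0.51))

  # a +2 shift of the same shape maps close to s + 2
  shifted <- tibble::tibble(score = 0:12,
                            probability = c(0, 0, d$probability))
  eqs <- equipercentile(d, shifted)
  mid <- eqs$score >= 1 & eqs$score <= 9
  expect_true(all(abs(eqs$equivalent[mid] - (eqs$score[mid] + 2)) < 0.51))

  point <- tibble::tibble(score = 0:5, probability = c(0, 0, 0, 1, 0, 0))
  expect_warning(eqd <- equipercentile(d, point), "point mass")
  expect_true(all(eqd$equivalent == 3))
  expect_true(attr(eqd, "degenerate"))
})

test_that("observed-score self-equating stays within the continuization bound
           and respects score-range boundaries", {
  withr::local_seed(1234)
  bank <- item_bank(paste0("i", 1:15), a = runif(15, 0.6, 1.9), b = runif(15, -2, 2))
  eq <- observed_score_equating(bank, bank)
  expect_true(all(abs(eq$equivalent - eq$score) < 0.51))
  expect_gte(eq$equivalent[1], 0); expect_lt(eq$equivalent[1], 1)
  expect_gt(eq$equivalent[16], 14); expect_lte(eq$equivalent[16], 15)
})

test_that("OSE and TSE agree almost perfectly on linked parallel forms", {
  pf <- parallel_fits()
  af <- dplyr::filter(pf$from$bank, is_anchor)
  at <- dplyr::filter(pf$to$bank, is_anchor)
  sl <- link_forms(af, at, "stocking_lord")
  from_on_to <- transform_parameters(pf$from$bank, sl)
  tse <- true_score_equating(from_on_to, pf$to$bank)
  ose <- observed_score_equating(from_on_to, pf$to$bank)
  expect_gt(cor(tse$equivalent, ose$equivalent), 0.99)
  expect_true(all(diff(tse$equivalent) >= 0))
  expect_true(all(diff(ose$equivalent) >= 0))

  # symmetry: composing with the reverse equating returns near the identity;
  # the equipercentile (OSE) map is only evaluated where the score
  # distribution carries real mass - its clamped extreme tails are not
  # symmetric by construction
  bwd <- link_forms(at, af, "stocking_lord")
  to_on_from <- transform_parameters(pf$to$bank, bwd)
  tse_rev <- true_score_equating(to_on_from, pf$from$bank)
  rt_tse <- apply_equating(tse_rev, tse$equivalent)
  expect_true(all(abs(rt_tse - tse$score) <= 0.75))

  ose_rev <- observed_score_equating(to_on_from, pf$from$bank)
  d_from <- marginal_score_distribution(from_on_to)
  pr <- cumsum(d_from$probability) - d_from$probability / 2
  interior <- pr >= 0.005 & pr <= 0.995
  rt_ose <- apply_equating(ose_rev, ose$equivalent)
  expect_true(all(abs(rt_ose[interior] - ose$score[interior]) <= 0.75))
})

test_that("equating tables export with direction metadata", {
  withr::local_seed(1234)
  bank <- item_bank(paste0("i", 1:6), a = rep(1, 6), b = seq(-1, 1.5, 0.5))
  eq <- true_score_equating(bank, bank)
  path <- withr::local_tempfile(fileext = ".csv")
  write_equating_table(eq, path, direction = "A_to_B")
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$raw_score, 0:6)
  expect_equal(unique(back$direction), "A_to_B")
  expect_equal(unique(back$method), "TSE")
})
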