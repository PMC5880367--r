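test_that("BIC and AIC match their formulas", {
  fake <- structure(
    list(loglik = -100, effective_params = 5, n = 90,
         spec = lcm_spec(2), n_free_params = 9, n_boundary_params = 4),
    class = "lcm_fit"
  )
  ic <- lcm_ic(fake)
  expect_equal(ic$bic, 200 + 5 * log(90), tolerance = 1e-10)
  expect_equal(ic$aic, 210)

  # same loglik, one extra parameter: BIC difference is exactly log(n)
  fake2 <- fake
  fake2$effective_params <- 6
  expect_equal(lcm_ic(fake2)$bic - ic$bic, log(90), tolerance = 1e-12)
})

test_that("model comparison flags the lowest BIC and breaks ties by parsimony", {
  dat <- simulate_lcm_data(lcm_preset("study"), seed = 31,
                           n_per_group = c(50, 50, 50, 50))
  fits <- lapply(1:3, function(K) fit_lcm(dat, K, n_restarts = 10, seed = K))
  tab <- lcm_compare(fits)
  expect_equal(sum(tab$selected), 1)
  expect_equal(tab$n_classes[tab$selected], tab$n_classes[which.min(tab$bic)])

  # exact tie: the smaller model must win
  f_small <- fits[[1]]; f_big <- fits[[2]]
  f_big$loglik <- f_small$loglik
  f_big$effective_params <- f_small$effective_params
  tie <- lcm_compare(list(f_big, f_small))
  expect_true(tie$selected[tie$n_classes == 1])
})

test_that("likelihood-ratio test computes G2, df, and the chi-square tail", {
  dat <- simulate_lcm_data(lcm_preset("age_logit"), seed = 41,
                           n_per_group = c(40, 40, 40, 40))
  f0 <- fit_lcm(dat, 3, "none", n_restarts = 10, seed = 1)
  f1 <- fit_lcm(dat, 3, "membership", n_restarts = 10, seed = 2)
  lr <- lcm_lr_test(f0, f1)
  # adding age on membership to a 3-class model frees one slope per
  # non-reference class
  expect_equal(lr$df, 2L)
  expect_equal(lr$g2, 2 * (f1$loglik - f0$loglik), tolerance = 1e-10)
  expect_gte(lr$g2, 0)

  # identical log-likelihoods give g2 = 0, p = 1
  f1b <- f1; f1b$loglik <- f0$loglik
  lr0 <- lcm_lr_test(f0, f1b)
  expect_equal(lr0$g2, 0)
  expect_equal(lr0$p_value, 1)

  # closed-form tail at df 2: p = exp(-g2/2)
  expect_equal(stats::pchisq(10, 2, lower.tail = FALSE), exp(-5),
               tolerance = 1e-12)

  expect_error(lcm_lr_test(f1, f0), "covariate")
  f2 <- fit_lcm(dat, 2, n_restarts = 5, seed = 3)
  expect_error(lcm_lr_test(f2, f1), "same number of classes")
})

test_that("G2 statistic matches hand computation and the multinomial form", {
  # J=1, 10 zeros and 30 ones against p = 0.5
  d <- make_response_data(matrix(rep(c(0, 1), c(10, 30)), 40, 1))
  fit <- fit_lcm(d, 1, n_restarts = 1, seed = 1)
  fit$params <- lcm_params(pi = 1, prob = matrix(0.5, 1, 1))
  g <- lcm_g2(fit, d)
  expect_equal(g$g2, 2 * (30 * log(1.5) + 10 * log(0.5)), tolerance = 1e-9)

  # saturated agreement gives G2 = 0 (and the unobserved-pattern term drops)
  fit$params <- lcm_params(pi = 1, prob = matrix(0.75, 1, 1))
  expect_equal(lcm_g2(fit, d)$g2, 0, tolerance = 1e-9)

  # covariate-free G2 equals the classical multinomial statistic
  for (seed in 1:20) {
    dat <- random_instance(seed, n = 40, J = 3)
    f <- suppressWarnings(fit_lcm(dat, 1 + seed %% 2, n_restarts = 5, seed = seed))
    expect_equal(lcm_g2(f, dat)$g2, multinomial_g2(f, dat), tolerance = 1e-6)
  }
})

test_that("G2 df is the pattern cells minus effective parameters, floored at 0", {
  dat <- simulate_lcm_data(lcm_preset("one_class"), seed = 10)
  f <- fit_lcm(dat, 1, n_restarts = 3, seed = 1)
  expect_equal(lcm_g2(f, dat)$df, (2^4 - 1) - f$effective_params)
})

test_that("bootstrap p-value respects the add-one counting rule", {
  dat <- simulate_lcm_data(lcm_preset("one_class"), seed = 2,
                           n_per_group = c(20, 20, 20, 20))
  fit <- fit_lcm(dat, 1, n_restarts = 3, seed = 1)
  gof <- lcm_bootstrap_gof(fit, dat, B = 19, seed = 5)
  expect_gte(gof$p_value, 1 / 20)
  expect_lte(gof$p_value, 1)
  expect_length(gof$bootstrap_g2, 19)
  expect_equal(gof$p_value,
               (1 + sum(gof$bootstrap_g2 >= gof$g2_observed)) / 20)

  # p is monotone non-increasing in the observed statistic for a fixed
  # bootstrap sample
  p_at <- function(g2obs) (1 + sum(gof$bootstrap_g2 >= g2obs)) / 20
  obs <- sort(c(gof$g2_observed, gof$bootstrap_g2))
  expect_true(all(diff(vapply(obs, p_at, numeric(1))) <= 0))

  # an observed statistic of zero can never be beaten
  expect_equal(p_at(0), 1)

  # reproducible given the seed
  gof2 <- lcm_bootstrap_gof(fit, dat, B = 19, seed = 5)
  expect_identical(gof$bootstrap_g2, gof2$bootstrap_g2)
})
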