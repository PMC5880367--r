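test_that("log-likelihood matches hand-computed mixture values", {
  # uniform one-class model: 8 Bernoulli(0.5) terms
  d1 <- make_response_data(matrix(c(1, 0, 1, 0, 1, 1, 0, 0), 2, 4))
  p1 <- lcm_params(pi = 1, prob = matrix(0.5, 1, 4))
  expect_equal(lcm_loglik(d1, lcm_spec(1), p1), 8 * log(0.5), tolerance = 1e-10)

  # perfect one-class fit to constant data
  d2 <- make_response_data(matrix(c(1, 1, 0, 0), 2, 2))
  p2 <- lcm_params(pi = 1, prob = matrix(c(1, 0), 1, 2))
  expect_equal(lcm_loglik(d2, lcm_spec(1), p2), 0, tolerance = 1e-8)

  # two-class mixture, one subject: log(0.5 * 0.81 + 0.5 * 0.01)
  d3 <- make_response_data(matrix(c(1, 1), 1, 2))
  p3 <- lcm_params(pi = c(0.5, 0.5),
                   prob = matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2, byrow = TRUE))
  expect_equal(lcm_loglik(d3, lcm_spec(2), p3), log(0.41), tolerance = 1e-9)

  expect_error(lcm_loglik(d3, lcm_spec(3), p3), "classes")
})

test_that("E-step responsibilities follow Bayes rule and normalize", {
  d <- make_response_data(matrix(c(1, 1), 1, 2))
  # single class: posterior exactly 1
  p1 <- lcm_params(pi = 1, prob = matrix(0.6, 1, 2))
  expect_equal(as.numeric(lcm_estep(d, lcm_spec(1), p1)), 1)

  # identical classes with equal priors: exact symmetry
  p2 <- lcm_params(pi = c(0.5, 0.5), prob = matrix(0.7, 2, 2))
  expect_equal(as.numeric(lcm_estep(d, lcm_spec(2), p2)), c(0.5, 0.5))

  # hand Bayes rule on the mixture from the log-likelihood test
  p3 <- lcm_params(pi = c(0.5, 0.5),
                   prob = matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2, byrow = TRUE))
  expect_equal(as.numeric(lcm_estep(d, lcm_spec(2), p3)),
               c(0.405, 0.005) / 0.41, tolerance = 1e-9)
})

test_that("posterior rows sum to one across random instances", {
  for (seed in 1:20) {
    dat <- random_instance(seed)
    K <- sample(1:3, 1)
    set.seed(seed)
    pm <- matrix(runif(K * 3, 0.1, 0.9), K, 3)
    w <- rgamma(K, 1); w <- w / sum(w)
    post <- lcm_estep(dat, lcm_spec(K), lcm_params(pi = w, prob = pm))
    expect_lt(max(abs(rowSums(post) - 1)), 1e-10)
  }
})

test_that("M-step reproduces weighted-mean closed forms", {
  # all mass on class 1: item means and degenerate weights
  Y <- matrix(c(1, 0, 1, 1, 0, 0), 3, 2)
  d <- make_response_data(Y)
  post <- cbind(rep(1, 3), rep(0, 3))
  prev <- lcm_params(pi = c(0.5, 0.5), prob = matrix(0.5, 2, 2))
  up <- lcm_mstep(d, lcm_spec(2), post, prev)
  expect_equal(up$prob[1, ], colMeans(Y), ignore_attr = TRUE)
  expect_equal(up$pi, c(1, 0))

  # fractional weights: p = (0.8 * 1 + 0.2 * 0) / (0.8 + 0.2)
  d2 <- make_response_data(matrix(c(1, 0), 2, 1))
  post2 <- cbind(c(0.8, 0.2), c(0.2, 0.8))
  prev2 <- lcm_params(pi = c(0.5, 0.5), prob = matrix(0.5, 2, 1))
  up2 <- lcm_mstep(d2, lcm_spec(2), post2, prev2)
  expect_equal(up2$prob[1, 1], 0.8, tolerance = 1e-12)
  expect_equal(up2$prob[2, 1], 0.2, tolerance = 1e-12)
})

test_that("membership M-step finds no age slope when responsibilities ignore age", {
  set.seed(42)
  n <- 200
  d <- make_response_data(matrix(rbinom(n * 2, 1, 0.5), n, 2),
                          age = runif(n, 24, 72))
  post <- cbind(rep(0.6, n), rep(0.4, n))
  prev <- lcm_params(pi = c(0.5, 0.5), prob = matrix(0.5, 2, 2),
                     age_center = mean(d$age_months),
                     age_scale = stats::sd(d$age_months))
  up <- lcm_mstep(d, lcm_spec(2, "membership"), post, prev)
  expect_lt(abs(up$beta), 1e-4)
  expect_equal(up$pi[1], 0.6, tolerance = 1e-4)
})

test_that("EM log-likelihood is non-decreasing across random instances", {
  worst <- Inf
  for (seed in 1:100) {
    dat <- random_instance(seed, n = 10 + seed %% 8, J = 2 + seed %% 2)
    K <- 1 + seed %% 3
    fit <- suppressWarnings(
      fit_lcm(dat, K, n_restarts = 1, seed = seed, max_iter = 200)
    )
    if (fit$iterations > 1) worst <- min(worst, min(diff(fit$loglik_trace)))
  }
  expect_gte(worst, -1e-8)
})

test_that("EM attains the optimum found by a direct numerical maximizer", {
  for (seed in c(3, 17)) {
    dat <- random_instance(seed, n = 30, J = 3)
    for (K in 1:2) {
      fit <- fit_lcm(dat, K, n_restarts = 10, seed = 1)
      oracle <- direct_max_loglik(dat, K)
      expect_equal(fit$loglik, oracle, tolerance = 1e-4)
    }
  }
})

test_that("one-class EM recovers observed item means in closed form", {
  dat <- random_instance(8, n = 25, J = 3)
  fit <- fit_lcm(dat, 1, n_restarts = 3, seed = 2)
  expect_equal(fit$params$prob[1, ], colMeans(response_matrix(dat)),
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("log-likelihood is exactly invariant to class relabeling", {
  dat <- random_instance(5, n = 15, J = 3)
  pm <- matrix(runif(9, 0.1, 0.9), 3, 3)
  pi <- c(0.5, 0.3, 0.2)
  base <- lcm_loglik(dat, lcm_spec(3), lcm_params(pi = pi, prob = pm))
  perm <- c(3, 1, 2)
  permuted <- lcm_loglik(dat, lcm_spec(3),
                         lcm_params(pi = pi[perm], prob = pm[perm, ]))
  expect_identical(base, permuted)
})

test_that("EM fits are reproducible given a seed and ordered by class size", {
  dat <- simulate_lcm_data(lcm_preset("study"), seed = 21)
  f1 <- fit_lcm(dat, 2, n_restarts = 5, seed = 7)
  f2 <- fit_lcm(dat, 2, n_restarts = 5, seed = 7)
  expect_identical(f1$loglik, f2$loglik)
  expect_identical(f1$params$prob, f2$params$prob)
  expect_true(all(diff(f1$params$pi) <= 1e-12))
})

test_that("overfitting more classes than patterns warns but still fits", {
  d <- make_response_data(matrix(c(1, 1, 0, 0), 2, 2))
  expect_warning(fit <- fit_lcm(d, 3, n_restarts = 2, seed = 1),
                 "distinct response patterns")
  expect_s3_class(fit, "lcm_fit")
})

test_that("modal classification breaks ties toward the lower class index", {
  dat <- make_response_data(matrix(c(1, 1), 1, 2))
  fit <- fit_lcm(dat, 1, n_restarts = 1, seed = 1)
  fit$posteriors <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(lcm_classify(fit), 1L)
  fit$posteriors <- matrix(c(0.05, 0.9, 0.05), 1, 3)
  expect_equal(lcm_classify(fit), 2L)
})

test_that("the all-or-none pattern is assigned to the boundary class", {
  # under the selected-model parameters, pattern (0,0,1,1) has zero
  # likelihood in classes 1 and 2, so its posterior concentrates on class 3
  d <- make_response_data(matrix(c(0, 0, 1, 1), 1, 4))
  params <- lcm_params(pi = c(0.567, 0.300, 0.133), prob = table2_probs())
  post <- lcm_estep(d, lcm_spec(3), params)
  expect_equal(as.numeric(post), c(0, 0, 1), tolerance = 1e-8)
})

test_that("effective parameter counting follows the boundary-adjustment rule", {
  # interior one-class fit: 4 free, none at boundary
  dat <- simulate_lcm_data(lcm_preset("one_class"), seed = 4)
  f1 <- fit_lcm(dat, 1, n_restarts = 3, seed = 1)
  counts <- lcm_effective_params(f1)
  expect_equal(counts$n_free, 4)
  expect_equal(counts$n_boundary, 0)
  expect_equal(counts$effective, 4)

  # the selected-model response matrix carries 8 boundary probabilities
  f1$spec <- lcm_spec(3)
  f1$params <- lcm_params(pi = study_proportions(), prob = table2_probs())
  counts <- lcm_effective_params(f1, boundary_tol = 1e-3)
  expect_equal(counts$n_free, 2 + 12)
  expect_equal(counts$n_boundary, 8)
  expect_equal(counts$effective, 6)

  # an empty class surrenders its response-parameter row
  f1$spec <- lcm_spec(2)
  f1$params <- lcm_params(pi = c(1, 0), prob = matrix(0.5, 2, 4))
  counts <- lcm_effective_params(f1)
  expect_equal(counts$n_free, 1 + 2 * 4 - 4)
  expect_equal(counts$n_boundary, 1)
})

test_that("class alignment undoes label switching", {
  truth <- table2_probs()
  shuffled <- truth[c(2, 3, 1), ]
  perm <- align_classes(shuffled, truth)
  expect_equal(shuffled[perm, ], truth, ignore_attr = TRUE)
})
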