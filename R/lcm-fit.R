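#' Fit a latent class model by EM with random restarts
#'
#' Alternates [lcm_estep()] and [lcm_mstep()] from `n_restarts` random
#' starting points and keeps the restart with the highest log-likelihood.
#' Within each run the log-likelihood is non-decreasing; a run stops when the
#' increase falls below `tol` or after `max_iter` iterations. Age enters the
#' covariate models after centering and scaling by the sample mean and
#' standard deviation; the scaling constants are stored with the parameters
#' so coefficients can be reported per month.
#'
#' Fitted classes are relabeled in order of decreasing class proportion
#' (evaluated at the mean age), so class 1 is always the largest group.
#'
#' @param data A [response_data] tibble.
#' @param n_classes Number of latent classes K.
#' @param covariate Where age enters: `"none"`, `"membership"`, `"response"`.
#' @param n_restarts Number of random starts (default 20). Start values draw
#'   response probabilities from uniform(0.2, 0.8) and class weights from a
#'   symmetric Dirichlet. For covariate models the starts are screened with
#'   short EM runs and the three most promising continued to convergence.
#' @param tol Convergence tolerance on the log-likelihood increase.
#' @param max_iter Maximum EM iterations per restart (default 5000: runs
#'   that approach boundary estimates gain likelihood geometrically slowly,
#'   and covariate-free fits cost almost nothing per iteration because EM
#'   operates on the collapsed response-pattern counts).
#' @param seed Master seed; per-restart sub-seeds are derived from it
#'   deterministically, so the fit is reproducible.
#' @param boundary_tol Tolerance used to count boundary parameters, see
#'   [lcm_effective_params()].
#' @return An object of class `lcm_fit` with elements `spec`, `params`,
#'   `loglik`, `posteriors`, `classification`, `n_free_params`,
#'   `n_boundary_params`, `effective_params`, `converged`, `restarts_run`,
#'   `best_restart_seed`, `loglik_trace` (best restart) and `data`.
#' @examples
#' dat <- simulate_lcm_data(lcm_preset("study"), seed = 7)
#' fit <- fit_lcm(dat, n_classes = 3, n_restarts = 5, seed = 1)
#' glance(fit)
#' @export
fit_lcm <- function(data, n_classes, covariate = c("none", "membership", "response"),
                    n_restarts = 20, tol = 1e-8, max_iter = 5000, seed = 1,
                    boundary_tol = 1e-3) {
  covariate <- match.arg(covariate)
  spec <- lcm_spec(n_classes, covariate)
  stopifnot(n_restarts >= 1, tol > 0)
  Y <- response_matrix(data)
  n <- nrow(Y); J <- ncol(Y); K <- spec$n_classes

  n_patterns <- length(unique(pattern_key(Y)))
  if (K > n_patterns) {
    warn(paste0("Requested ", K, " classes but the data contain only ",
                n_patterns, " distinct response patterns; the fit may overfit."))
  }

  age_center <- mean(data$age_months)
  age_scale <- stats::sd(data$age_months)
  if (!is.finite(age_scale) || age_scale == 0) age_scale <- 1

  z <- standardize_age(data$age_months, age_center, age_scale)

  # without a covariate the likelihood depends on the data only through the
  # response-pattern counts, so EM runs on the (at most 2^J) unique patterns
  collapse <- spec$covariate == "none"
  if (collapse) {
    keys <- pattern_key(Y)
    ukeys <- unique(keys)
    idx <- match(keys, ukeys)
    Yr <- Y[match(ukeys, keys), , drop = FALSE]
    wr <- as.numeric(tabulate(idx, nbins = length(ukeys)))
    zr <- numeric(nrow(Yr))
  } else {
    Yr <- Y; wr <- NULL; zr <- z
  }

  restart_seeds <- derive_seeds(seed, n_restarts)
  best <- NULL
  if (collapse) {
    for (r in seq_len(n_restarts)) {
      start <- init_params(K, J, restart_seeds[r], age_center, age_scale)
      run <- em_run_collapsed(Yr, wr, start$pi, start$prob, tol, max_iter,
                              age_center, age_scale)
      if (is.null(best) || run$loglik > best$loglik) {
        best <- run
        best$seed <- restart_seeds[r]
      }
    }
  } else {
    # covariate fits are costly per iteration, so restarts are screened
    # with short runs and only the most promising continued to convergence
    # (the usual emEM strategy)
    stage1 <- min(200L, max_iter)
    runs <- lapply(seq_len(n_restarts), function(r) {
      start <- init_params(K, J, restart_seeds[r], age_center, age_scale)
      em_single_run(Yr, zr, spec, start, tol = tol, max_iter = stage1)
    })
    lls <- vapply(runs, function(x) x$loglik, numeric(1))
    deepen <- utils::head(order(lls, decreasing = TRUE),
                          max(1L, min(3L, n_restarts)))
    for (r in deepen) {
      run <- runs[[r]]
      if (!run$converged && max_iter > stage1) {
        cont <- em_single_run(Yr, zr, spec, run$params, tol = tol,
                              max_iter = max_iter - stage1)
        cont$trace <- c(run$trace, cont$trace)
        cont$iterations <- run$iterations + cont$iterations
        run <- cont
      }
      if (is.null(best) || run$loglik > best$loglik) {
        best <- run
        best$seed <- restart_seeds[r]
      }
    }
  }

  if (collapse) best$posteriors <- best$posteriors[idx, , drop = FALSE]
  best <- reorder_classes(best, spec)
  counts <- effective_param_counts(spec, best$params, boundary_tol)

  fit <- structure(
    list(
      spec = spec, params = best$params, loglik = best$loglik,
      posteriors = best$posteriors,
      classification = max.col(best$posteriors, ties.method = "first"),
      n = n, trials = response_trials(data),
      n_free_params = counts$n_free, n_boundary_params = counts$n_boundary,
      effective_params = counts$effective,
      converged = best$converged, iterations = best$iterations,
      restarts_run = n_restarts, best_restart_seed = best$seed,
      loglik_trace = best$trace, boundary_tol = boundary_tol,
      tol = tol, max_iter = max_iter,
      master_seed = seed, data = data
    ),
    class = "lcm_fit"
  )
  fit
}

init_params <- function(K, J, seed, age_center, age_scale) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  w <- rgamma(K, shape = 1)
  pi <- w / sum(w)
  prob <- matrix(runif(K * J, 0.2, 0.8), K, J)
  lcm_params(pi = pi, prob = prob,
             alpha = if (K > 1L) log(pi[-1] / pi[1]) else numeric(0),
             beta = numeric(max(K - 1L, 0L)),
             gamma = qlogis(prob), delta = matrix(0, K, J),
             age_center = age_center, age_scale = age_scale)
}

# tight EM loop for covariate-free models on collapsed pattern counts:
# identical updates to estep_mat/mstep_mat, specialized to avoid per-
# iteration parameter-object construction
em_run_collapsed <- function(Y, w, pi, prob, tol, max_iter,
                             age_center, age_scale) {
  S <- nrow(Y); K <- length(pi); n <- sum(w)
  Y0 <- 1 - Y
  ll_old <- -Inf
  trace <- numeric(max_iter)
  converged <- FALSE
  it <- 0L
  post <- NULL
  while (it < max_iter) {
    it <- it + 1L
    P <- prob
    P[P < PROB_EPS] <- PROB_EPS
    P[P > 1 - PROB_EPS] <- 1 - PROB_EPS
    LP <- Y %*% t(log(P)) + Y0 %*% t(log1p(-P)) +
      rep(log(pi), each = S)
    M <- LP[, 1L]
    if (K > 1L) for (k in 2L:K) M <- pmax.int(M, LP[, k])
    lse <- M + log(rowSums(exp(LP - M)))
    ll <- sum(w * lse)
    trace[it] <- ll
    post <- exp(LP - lse)
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    W <- post * w
    ws <- colSums(W)
    live <- ws >= 1e-8
    newprob <- crossprod(W[, live, drop = FALSE], Y) / ws[live]
    newprob[newprob < 0] <- 0
    newprob[newprob > 1] <- 1
    prob[live, ] <- newprob
    pi <- ws / n
  }
  params <- lcm_params(pi = pi, prob = prob,
                       age_center = age_center, age_scale = age_scale)
  list(params = params, posteriors = post, loglik = trace[it],
       trace = trace[seq_len(it)], converged = converged, iterations = it)
}

em_single_run <- function(Y, z, spec, params, tol, max_iter, w = NULL) {
  ll_old <- -Inf
  trace <- numeric(max_iter)
  converged <- FALSE
  post <- NULL
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    post <- estep_mat(Y, z, spec, params, w = w)
    ll <- attr(post, "loglik")
    trace[it] <- ll
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    params <- mstep_mat(Y, z, spec, post, params, w = w)
  }
  list(params = params, posteriors = post, loglik = trace[it],
       trace = trace[seq_len(it)], converged = converged, iterations = it)
}

# relabel classes by decreasing proportion at the mean age
reorder_classes <- function(run, spec) {
  K <- spec$n_classes
  if (K == 1L) return(run)
  p <- run$params
  ord <- order(p$pi, decreasing = TRUE)
  if (identical(ord, seq_len(K))) return(run)
  eta <- c(0, p$alpha)[ord]
  zeta <- c(0, p$beta)[ord]
  run$params <- lcm_params(
    pi = p$pi[ord], prob = p$prob[ord, , drop = FALSE],
    alpha = (eta - eta[1])[-1], beta = (zeta - zeta[1])[-1],
    gamma = p$gamma[ord, , drop = FALSE], delta = p$delta[ord, , drop = FALSE],
    age_center = p$age_center, age_scale = p$age_scale
  )
  run$posteriors <- run$posteriors[, ord, drop = FALSE]
  run
}

#' Modal class assignment
#'
#' Assigns each subject to the class with the highest posterior
#' responsibility; ties go to the lower class index.
#'
#' @param fitted An [fit_lcm()] result.
#' @return Integer vector of class labels, length n.
#' @export
lcm_classify <- function(fitted) {
  stopifnot(inherits(fitted, "lcm_fit"))
  max.col(fitted$posteriors, ties.method = "first")
}

#' Boundary-adjusted effective parameter count
#'
#' Counts freely estimated parameters as (K-1) membership terms (doubled
#' when age acts on membership) plus K*J response terms (doubled when age
#' acts on responses), then subtracts parameters estimated at the boundary:
#' fitted response probabilities within `boundary_tol` of 0 or 1, and class
#' proportions within `boundary_tol` of 0 (an empty class also surrenders its
#' row of response parameters from the free count). The resulting effective
#' count is the penalty dimension used for BIC/AIC.
#'
#' @param fitted An `lcm_fit` object.
#' @param boundary_tol Positive tolerance, at most 0.01.
#' @return A one-row tibble with `n_free`, `n_boundary`, `effective`.
#' @export
lcm_effective_params <- function(fitted, boundary_tol = 1e-3) {
  stopifnot(inherits(fitted, "lcm_fit"))
  counts <- effective_param_counts(fitted$spec, fitted$params, boundary_tol)
  tibble::tibble(n_free = counts$n_free, n_boundary = counts$n_boundary,
                 effective = counts$effective)
}

effective_param_counts <- function(spec, params, boundary_tol = 1e-3) {
  stopifnot(boundary_tol > 0, boundary_tol <= 0.01)
  K <- spec$n_classes
  J <- n_items(params)
  memb_mult <- 1L + (spec$covariate == "membership")
  resp_mult <- 1L + (spec$covariate == "response")
  n_free <- (K - 1L) * memb_mult + K * J * resp_mult

  empty <- which(params$pi < boundary_tol)
  n_free <- n_free - length(empty) * J * resp_mult
  live <- setdiff(seq_len(K), empty)
  p_live <- params$prob[live, , drop = FALSE]
  n_boundary <- length(empty) +
    sum(p_live < boundary_tol | p_live > 1 - boundary_tol)
  list(n_free = n_free, n_boundary = n_boundary,
       effective = max(n_free - n_boundary, 0L))
}

#' @export
print.lcm_fit <- function(x, digits = 3, ...) {
  cat("<lcm_fit> ", x$spec$n_classes, " class(es), covariate = ",
      x$spec$covariate, "\n", sep = "")
  cat("  n = ", x$n, ", logLik = ", format(x$loglik, digits = 7),
      ", effective parameters = ", x$effective_params,
      " (", x$n_free_params, " free - ", x$n_boundary_params, " boundary)\n",
      sep = "")
  cat("  class proportions (at mean age): ",
      paste(round(x$params$pi, digits), collapse = ", "), "\n", sep = "")
  cat("  response probabilities (at mean age):\n")
  m <- round(x$params$prob, digits)
  dimnames(m) <- list(paste0("class", seq_len(nrow(m))), x$trials)
  print(m)
  invisible(x)
}

#' Match fitted classes to reference classes
#'
#' Finds the permutation of fitted classes minimizing the total absolute
#' difference between fitted and reference response-probability rows —
#' the standard remedy for label switching when scoring parameter recovery.
#'
#' @param fitted_probs,reference_probs K-by-J response-probability matrices.
#' @return Integer permutation `perm` such that `fitted_probs[perm, ]` is
#'   aligned with `reference_probs`.
#' @export
align_classes <- function(fitted_probs, reference_probs) {
  fitted_probs <- as.matrix(fitted_probs)
  reference_probs <- as.matrix(reference_probs)
  stopifnot(dim(fitted_probs) == dim(reference_probs))
  K <- nrow(fitted_probs)
  perms <- all_permutations(K)
  cost <- vapply(perms, function(p) {
    sum(abs(fitted_probs[p, , drop = FALSE] - reference_probs))
  }, numeric(1))
  perms[[which.min(cost)]]
}

#' Serialize a fitted model to JSON
#'
#' Writes the model specification, both parameter blocks, the log-likelihood,
#' parameter counts and the fitting seed to a JSON file.
#'
#' @param fitted An `lcm_fit` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lcm_json <- function(fitted, path) {
  stopifnot(inherits(fitted, "lcm_fit"))
  payload <- list(
    package = "blicketlca",
    version = as.character(utils::packageVersion("blicketlca")),
    spec = unclass(fitted$spec),
    parameters = list(
      class_proportions = fitted$params$pi,
      membership_intercepts = fitted$params$alpha,
      membership_slopes = fitted$params$beta,
      response_probs = fitted$params$prob,
      response_logit_intercepts = fitted$params$gamma,
      response_logit_slopes = fitted$params$delta,
      age_center = fitted$params$age_center,
      age_scale = fitted$params$age_scale
    ),
    loglik = fitted$loglik,
    n = fitted$n,
    n_free_params = fitted$n_free_params,
    n_boundary_params = fitted$n_boundary_params,
    effective_params = fitted$effective_params,
    converged = fitted$converged,
    restarts_run = fitted$restarts_run,
    master_seed = fitted$master_seed
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
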