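#' Information criteria for a fitted latent class model
#'
#' BIC = -2 logLik + k log(n) and AIC = -2 logLik + 2k, where k is the
#' boundary-adjusted effective parameter count. Model selection across
#' different numbers of classes uses the lowest BIC; AIC is computed and
#' reported but not used to select.
#'
#' @param fitted An `lcm_fit` object.
#' @param n Sample size (defaults to the fitted n).
#' @return A one-row tibble with `loglik`, `effective_params`, `n`, `bic`,
#'   `aic`.
#' @export
lcm_ic <- function(fitted, n = fitted$n) {
  stopifnot(inherits(fitted, "lcm_fit"), n >= 1)
  k <- fitted$effective_params
  tibble::tibble(
    loglik = fitted$loglik, effective_params = k, n = as.integer(n),
    bic = -2 * fitted$loglik + k * log(n),
    aic = -2 * fitted$loglik + 2 * k
  )
}

#' Compare a set of fitted latent class models
#'
#' Produces the goodness-of-fit comparison table: per model the
#' log-likelihood, free/boundary/effective parameter counts, BIC and AIC.
#' The lowest-BIC model is flagged as selected; BIC ties break toward fewer
#' classes (parsimony).
#'
#' @param fits A list of `lcm_fit` objects on the same data.
#' @return A tibble with one row per model and a logical `selected` column.
#' @export
lcm_compare <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "lcm_fit")))
  tab <- purrr::map_dfr(fits, function(f) {
    dplyr::bind_cols(
      tibble::tibble(n_classes = f$spec$n_classes, covariate = f$spec$covariate,
                     n_free = f$n_free_params, n_boundary = f$n_boundary_params),
      lcm_ic(f)
    )
  })
  ord <- order(tab$bic, tab$n_classes, tab$n_free)
  tab$selected <- seq_len(nrow(tab)) == ord[1L]
  tab[c("n_classes", "covariate", "loglik", "n_free", "n_boundary",
        "effective_params", "n", "bic", "aic", "selected")]
}

#' Likelihood-ratio test for nested covariate models
#'
#' Compares a latent class model against the same-K model extended with
#' covariate terms: G2 = 2 (logLik_extended - logLik_nested), df = the
#' number of covariate coefficients added (difference in free parameter
#' counts), p from the upper chi-square tail. A significant test favors the
#' extended model.
#'
#' @param nested,extended `lcm_fit` objects on the same data with the same
#'   number of classes; `extended` must add covariate terms absent from
#'   `nested`.
#' @return A one-row tibble with `g2`, `df`, `p_value`.
#' @export
lcm_lr_test <- function(nested, extended) {
  stopifnot(inherits(nested, "lcm_fit"), inherits(extended, "lcm_fit"))
  if (nested$spec$n_classes != extended$spec$n_classes) {
    abort("Nested comparison requires the same number of classes.")
  }
  rank0 <- covariate_rank(nested$spec$covariate)
  rank1 <- covariate_rank(extended$spec$covariate)
  if (rank0 != 0 || rank1 == 0) {
    abort("`extended` must add covariate terms to a covariate-free `nested` model.")
  }
  g2 <- 2 * (extended$loglik - nested$loglik)
  if (g2 < -1e-6) {
    abort(paste0("Extended model fits worse than the nested one (G2 = ",
                 format(g2), "); its fit likely failed. Increase restarts."))
  }
  g2 <- max(g2, 0)
  # df counts the covariate coefficients the extension adds, from the model
  # structure itself (boundary or empty-class adjustments do not change how
  # many coefficients were freed)
  K <- extended$spec$n_classes
  J <- length(extended$trials)
  df <- if (extended$spec$covariate == "membership") K - 1L else K * J
  tibble::tibble(g2 = g2, df = as.integer(df),
                 p_value = pchisq(g2, df = df, lower.tail = FALSE))
}

covariate_rank <- function(covariate) as.integer(covariate != "none")

#' Pattern-frequency G-squared fit statistic
#'
#' Tabulates observed counts over all 2^J response patterns and compares
#' them with the expected counts under the fitted model, `E_s = sum_i
#' Pr(pattern s | x_i)` (covariate models marginalize over the empirical
#' age distribution). `G2 = 2 sum_(O_s > 0) O_s log(O_s / E_s)`; unobserved
#' patterns contribute zero. The nominal df is `(2^J - 1) - effective
#' parameters`, floored at 0 with a warning; with sparse pattern tables the
#' bootstrap p from [lcm_bootstrap_gof()] is the operative fit measure, not
#' the chi-square tail.
#'
#' @param fitted An `lcm_fit` object.
#' @param data The [response_data] the statistic is evaluated on (defaults to
#'   the fitted data).
#' @return A one-row tibble with `g2`, `df`, `p_value` (chi-square tail, for
#'   reference only when cells are sparse).
#' @export
lcm_g2 <- function(fitted, data = fitted$data) {
  stopifnot(inherits(fitted, "lcm_fit"))
  Y <- response_matrix(data)
  J <- ncol(Y)
  if (J > 12) abort("Pattern enumeration limited to 12 trials.")
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), J)))[, J:1, drop = FALSE]
  colnames(patterns) <- colnames(Y)
  keys <- pattern_key(patterns)
  obs <- table(factor(pattern_key(Y), levels = keys))
  O <- as.numeric(obs)

  E <- expected_pattern_counts(fitted, data, patterns)
  bad <- which(O > 0 & E == 0)
  if (length(bad) > 0L) {
    abort(paste0("Observed pattern ", keys[bad[1L]],
                 " has expected count 0 under the fitted model."))
  }
  pos <- O > 0
  g2 <- 2 * sum(O[pos] * log(O[pos] / E[pos]))
  df_nominal <- (2^J - 1) - fitted$effective_params
  if (df_nominal < 0) {
    warn("Nominal G2 df is negative after boundary adjustment; floored at 0. Use the bootstrap p-value.")
  }
  df <- max(df_nominal, 0L)
  tibble::tibble(g2 = g2, df = as.integer(df),
                 p_value = pchisq(g2, df = df, lower.tail = FALSE))
}

# expected count of each pattern, summed over subjects' ages
expected_pattern_counts <- function(fitted, data, patterns) {
  spec <- fitted$spec
  params <- fitted$params
  z <- standardize_age(data$age_months, params$age_center, params$age_scale)
  n <- length(z)
  K <- spec$n_classes
  S <- nrow(patterns)
  PI <- class_prob_matrix(params, spec, z) # n x K
  E <- numeric(S)
  for (k in seq_len(K)) {
    P <- item_prob_matrix(params, spec, z, k) # n x J, unclipped
    for (s in seq_len(S)) {
      y <- patterns[s, ]
      lik <- rep(1, n)
      for (j in seq_along(y)) {
        lik <- lik * (if (y[j] == 1) P[, j] else 1 - P[, j])
      }
      E[s] <- E[s] + sum(PI[, k] * lik)
    }
  }
  E
}

#' Parametric-bootstrap p-value for the G-squared statistic
#'
#' Simulates `B` replicate datasets from the fitted model (keeping each
#' subject's observed age), refits the same model specification with the
#' same restart policy to each, and recomputes the replicate G-squared.
#' The p-value uses the add-one rule `(1 + #{G2_b >= G2_obs}) / (B + 1)`,
#' so it is never exactly zero. Replicates whose refit does not converge
#' (or yields a degenerate pattern table) are redrawn with a fresh sub-seed.
#'
#' @param fitted An `lcm_fit` object.
#' @param data The observed [response_data] (defaults to the fitted data).
#' @param B Number of bootstrap replicates (default 1000; 99 is enough for
#'   testing).
#' @param seed Master seed for the bootstrap; replicate sub-seeds are derived
#'   from it.
#' @return An object of class `lcm_gof`: list with `g2_observed`,
#'   `df_reported`, `n_bootstrap`, `bootstrap_g2`, `p_value`, `n_redraws`.
#' @export
lcm_bootstrap_gof <- function(fitted, data = fitted$data, B = 1000, seed = 1) {
  stopifnot(inherits(fitted, "lcm_fit"), B >= 1)
  obs <- lcm_g2(fitted, data)
  seeds <- derive_seeds(seed, 2L * B + 10L) # spare seeds for redraws
  boot <- numeric(B)
  used <- 0L
  redraws <- 0L
  for (b in seq_len(B)) {
    repeat {
      used <- used + 1L
      if (used > length(seeds)) {
        abort("Exhausted bootstrap sub-seeds; refits keep failing.")
      }
      g2b <- tryCatch({
        rep_data <- simulate_from_fit(fitted, data, seed = seeds[used])
        rep_fit <- fit_lcm(rep_data, n_classes = fitted$spec$n_classes,
                           covariate = fitted$spec$covariate,
                           n_restarts = fitted$restarts_run,
                           seed = seeds[used],
                           tol = fitted$tol %||% 1e-8,
                           max_iter = fitted$max_iter %||% 5000,
                           boundary_tol = fitted$boundary_tol)
        if (!rep_fit$converged) abort("replicate fit did not converge")
        lcm_g2(rep_fit, rep_data)$g2
      }, error = function(e) NA_real_)
      if (!is.na(g2b)) break
      redraws <- redraws + 1L
    }
    boot[b] <- g2b
  }
  p <- (1 + sum(boot >= obs$g2)) / (B + 1)
  structure(
    list(g2_observed = obs$g2, df_reported = obs$df, n_bootstrap = B,
         bootstrap_g2 = boot, p_value = p, n_redraws = redraws),
    class = "lcm_gof"
  )
}

#' @export
print.lcm_gof <- function(x, ...) {
  cat("<lcm_gof> G2 = ", format(x$g2_observed, digits = 4),
      " (df = ", x$df_reported, "), parametric-bootstrap p = ",
      format(x$p_value, digits = 3), " (B = ", x$n_bootstrap, ")\n", sep = "")
  invisible(x)
}

# simulate a replicate dataset from a fitted model, keeping observed ages
simulate_from_fit <- function(fitted, data, seed) {
  params <- fitted$params
  spec <- fitted$spec
  z <- standardize_age(data$age_months, params$age_center, params$age_scale)
  n <- length(z)
  J <- n_items(params)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  PI <- class_prob_matrix(params, spec, z)
  cls <- vapply(seq_len(n), function(i) {
    sample.int(spec$n_classes, 1L, prob = PI[i, ])
  }, integer(1))
  Y <- matrix(0, n, J)
  for (k in unique(cls)) {
    idx <- which(cls == k)
    P <- item_prob_matrix(params, spec, z[idx], k)
    Y[idx, ] <- rbinom(length(idx) * J, 1, as.vector(P))
  }
  out <- tibble::tibble(subject_id = paste0("boot", seq_len(n)),
                        age_months = data$age_months)
  if ("age_group" %in% names(data)) out$age_group <- data$age_group
  out <- dplyr::bind_cols(out, tibble::as_tibble(`colnames<-`(Y, response_trials(data))))
  response_data(out, trials = response_trials(data))
}
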