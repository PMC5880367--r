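#' @importFrom generics tidy glance augment
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
generics::augment

#' Tidy a fitted latent class model
#'
#' One row per parameter: class proportions (at the mean age), response
#' probabilities per class and trial, and — when present — membership and
#' response age coefficients. Age slopes are reported both on the
#' standardized scale used in fitting and back-transformed per month.
#'
#' @param x An `lcm_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term`, `class`, `trial`, `estimate`,
#'   `per_month`.
#' @export
tidy.lcm_fit <- function(x, ...) {
  p <- x$params
  K <- x$spec$n_classes
  J <- length(x$trials)
  out <- list(
    tibble::tibble(term = "class_proportion", class = seq_len(K),
                   trial = NA_character_, estimate = p$pi,
                   per_month = NA_real_),
    tibble::tibble(term = "response_prob",
                   class = rep(seq_len(K), times = J),
                   trial = rep(x$trials, each = K),
                   estimate = as.vector(p$prob), per_month = NA_real_)
  )
  if (x$spec$covariate == "membership" && K > 1L) {
    out <- c(out, list(
      tibble::tibble(term = "membership_intercept", class = 2:K,
                     trial = NA_character_, estimate = p$alpha,
                     per_month = NA_real_),
      tibble::tibble(term = "membership_age_slope", class = 2:K,
                     trial = NA_character_, estimate = p$beta,
                     per_month = p$beta / p$age_scale)
    ))
  }
  if (x$spec$covariate == "response") {
    out <- c(out, list(
      tibble::tibble(term = "response_age_slope",
                     class = rep(seq_len(K), times = J),
                     trial = rep(x$trials, each = K),
                     estimate = as.vector(p$delta),
                     per_month = as.vector(p$delta) / p$age_scale)
    ))
  }
  dplyr::bind_rows(out)
}

#' Glance at a fitted latent class model
#'
#' @param x An `lcm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with the fit summary: sample size, model
#'   dimensions, log-likelihood, parameter counts, BIC, AIC, convergence.
#' @export
glance.lcm_fit <- function(x, ...) {
  ic <- lcm_ic(x)
  tibble::tibble(
    n = x$n, n_classes = x$spec$n_classes, covariate = x$spec$covariate,
    loglik = x$loglik, n_free = x$n_free_params,
    n_boundary = x$n_boundary_params, effective_params = x$effective_params,
    bic = ic$bic, aic = ic$aic, converged = x$converged,
    restarts = x$restarts_run
  )
}

#' Augment response data with posteriors and modal classes
#'
#' @param x An `lcm_fit` object.
#' @param data The data to augment (defaults to the fitted data).
#' @param ... Unused.
#' @return The data tibble with `.class` (modal assignment) and one
#'   `.posterior_k` column per class.
#' @export
augment.lcm_fit <- function(x, data = x$data, ...) {
  out <- tibble::as_tibble(data)
  out$.class <- lcm_classify(x)
  post <- x$posteriors
  colnames(post) <- paste0(".posterior_", seq_len(ncol(post)))
  dplyr::bind_cols(out, tibble::as_tibble(post))
}

#' Tidy a goodness-of-fit bootstrap result
#'
#' @param x An `lcm_gof` object.
#' @param ... Unused.
#' @return A one-row tibble with `g2_observed`, `df_reported`,
#'   `n_bootstrap`, `p_value`, `n_redraws`.
#' @export
tidy.lcm_gof <- function(x, ...) {
  tibble::tibble(g2_observed = x$g2_observed, df_reported = x$df_reported,
                 n_bootstrap = x$n_bootstrap, p_value = x$p_value,
                 n_redraws = x$n_redraws)
}

#' Tidy a study report
#'
#' Returns the model-comparison table of the four-step analysis.
#'
#' @param x A `study_report` object.
#' @param ... Unused.
#' @return The comparison tibble.
#' @export
tidy.study_report <- function(x, ...) x$comparison

#' Glance at a study report
#'
#' @param x A `study_report` object.
#' @param ... Unused.
#' @return One-row tibble summarizing the selected model and the headline
#'   tests.
#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    selected_classes = x$selected$spec$n_classes,
    selected_covariate = x$selected$spec$covariate,
    lr_g2 = x$lr_test$g2, lr_df = x$lr_test$df, lr_p = x$lr_test$p_value,
    strategy_preferred = x$strategy_preferred,
    g2 = x$g2$g2, g2_df = x$g2$df,
    bootstrap_p = if (!is.null(x$gof)) x$gof$p_value else NA_real_
  )
}
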