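#' Run the four-step strategy-variability analysis
#'
#' Reproduces the full analysis pipeline on a binary response dataset:
#' \enumerate{
#'   \item Fit latent class models with 1 to `max_classes` classes and no
#'     covariate; select K* by lowest BIC (ties toward fewer classes).
#'   \item Extend the K*-class model with age: on class membership when
#'     K* >= 2 (the concomitant-variable model), otherwise on the response
#'     probabilities (the only age extension a one-class model admits);
#'     test the extension with a likelihood-ratio test.
#'   \item Fit the one-class model with age on the response probabilities
#'     (accuracy-growth alternative) and compare its BIC with the step-2
#'     model's BIC.
#'   \item For the selected model, report the response-probability table,
#'     the pattern G-squared with a parametric-bootstrap p-value, modal
#'     class assignments, and the strategy-by-age-group summary.
#' }
#'
#' @param data A [response_data] tibble with at least two trials.
#' @param max_classes Largest number of classes fit in step 1 (default 4).
#' @param n_restarts Random EM restarts per fit (default 20).
#' @param seed Master seed governing all fits and the bootstrap.
#' @param bootstrap_B Bootstrap replicates for the goodness-of-fit p-value
#'   (default 1000); set `bootstrap = FALSE` to skip the bootstrap.
#' @param bootstrap Whether to run the parametric bootstrap in step 4.
#' @param alpha Significance level used to phrase the step-2 conclusion.
#' @param max_iter EM iteration cap per restart. The pipeline default is
#'   deliberately generous because every step must actually converge:
#'   candidate models with more classes than the data support approach
#'   their optimum along a flat ridge and need tens of thousands of (cheap,
#'   pattern-collapsed) iterations.
#' @return An object of class `study_report`: list with the per-step fits,
#'   the model-comparison table (`comparison`), the step-2 `lr_test`, the
#'   step-3 BIC contrast (`accuracy_vs_strategy`), the `selected` fit, the
#'   response-probability table, the `gof` result (when bootstrapped),
#'   modal `classification` and `class_by_age`.
#' @examples
#' \donttest{
#' dat <- simulate_lcm_data(lcm_preset("study"), seed = 3)
#' rep <- run_variability_analysis(dat, n_restarts = 5, seed = 1,
#'                                 bootstrap = FALSE)
#' rep$comparison
#' }
#' @export
run_variability_analysis <- function(data, max_classes = 4, n_restarts = 20,
                                     seed = 1, bootstrap_B = 1000,
                                     bootstrap = TRUE, alpha = 0.05,
                                     max_iter = 50000) {
  stopifnot(inherits(data, "response_data"))
  if (length(response_trials(data)) < 2L) {
    abort("At least two trials are required after screening.")
  }
  seeds <- derive_seeds(seed, max_classes + 3L)

  # step 1: 1..max_classes, no covariate, BIC selection
  step1_fits <- purrr::map(seq_len(max_classes), function(K) {
    fit <- fit_lcm(data, n_classes = K, covariate = "none",
                   n_restarts = n_restarts, seed = seeds[K],
                   max_iter = max_iter)
    if (!fit$converged) abort(paste0("Step 1: the ", K, "-class fit did not converge."))
    fit
  })
  step1_tab <- lcm_compare(step1_fits)
  k_star <- step1_tab$n_classes[step1_tab$selected]

  # step 2: age extension of the K* model + LRT
  step2_covariate <- if (k_star >= 2L) "membership" else "response"
  step2_fit <- fit_lcm(data, n_classes = k_star, covariate = step2_covariate,
                       n_restarts = n_restarts, seed = seeds[max_classes + 1L],
                       max_iter = max_iter)
  if (!step2_fit$converged) abort("Step 2: the covariate fit did not converge.")
  lr <- lcm_lr_test(step1_fits[[k_star]], step2_fit)

  # step 3: accuracy-growth alternative (1 class, age on responses)
  if (k_star == 1L) {
    step3_fit <- step2_fit
  } else {
    step3_fit <- fit_lcm(data, n_classes = 1, covariate = "response",
                         n_restarts = n_restarts,
                         seed = seeds[max_classes + 2L],
                         max_iter = max_iter)
    if (!step3_fit$converged) abort("Step 3: the accuracy-growth fit did not converge.")
  }
  age_model <- if (lr$p_value < alpha) step2_fit else step1_fits[[k_star]]
  step3_tab <- lcm_compare(list(age_model, step3_fit))
  strategy_preferred <- step3_tab$selected[1L] ||
    identical(step3_fit, age_model)

  selected <- if (step3_tab$selected[1L]) age_model else step3_fit

  comparison <- lcm_compare(c(step1_fits, list(step2_fit),
                              if (k_star > 1L) list(step3_fit)))

  # step 4: fit quality and strategy-by-age profile of the selected model
  gof <- if (bootstrap) {
    lcm_bootstrap_gof(selected, data, B = bootstrap_B,
                      seed = seeds[max_classes + 3L])
  } else {
    NULL
  }
  g2_tab <- lcm_g2(selected, data)
  labels <- lcm_classify(selected)
  class_by_age <- if ("age_group" %in% names(data)) {
    class_by_age_summary(labels, data$age_group)
  } else {
    NULL
  }
  probs <- selected$params$prob
  dimnames(probs) <- list(paste0("class", seq_len(nrow(probs))),
                          response_trials(data))

  structure(
    list(
      step1_fits = step1_fits, step1_table = step1_tab, k_star = k_star,
      step2_fit = step2_fit, step2_covariate = step2_covariate, lr_test = lr,
      step3_fit = step3_fit, accuracy_vs_strategy = step3_tab,
      strategy_preferred = strategy_preferred,
      selected = selected, comparison = comparison,
      response_probs = probs, g2 = g2_tab, gof = gof,
      classification = labels,
      class_sizes = as.integer(table(factor(labels, levels = seq_len(selected$spec$n_classes)))),
      class_by_age = class_by_age,
      alpha = alpha, seed = seed
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, digits = 2, ...) {
  cat("Strategy-variability analysis\n")
  cat("=============================\n\n")
  cat("Step 1 - number of strategies (BIC selection):\n")
  print(as.data.frame(x$step1_table), digits = 7, row.names = FALSE)
  cat("  -> ", x$k_star, " class(es) selected\n\n", sep = "")
  cat("Step 2 - age and strategy use (covariate on ", x$step2_covariate,
      "):\n", sep = "")
  cat("  LRT: G2 = ", format(x$lr_test$g2, digits = 4), ", df = ",
      x$lr_test$df, ", p = ", format.pval(x$lr_test$p_value, digits = 3),
      "\n\n", sep = "")
  cat("Step 3 - strategy use vs accuracy growth (BIC):\n")
  print(as.data.frame(x$accuracy_vs_strategy), digits = 7, row.names = FALSE)
  cat("  -> ", if (x$strategy_preferred) "strategy-use" else "accuracy-growth",
      " model preferred\n\n", sep = "")
  cat("Step 4 - selected model (", x$selected$spec$n_classes, " class(es), covariate = ",
      x$selected$spec$covariate, ")\n", sep = "")
  cat("Response probabilities:\n")
  print(round(x$response_probs, digits))
  cat("Class sizes (modal assignment): ",
      paste(x$class_sizes, collapse = ", "), "\n", sep = "")
  cat("Fit: G2 = ", format(x$g2$g2, digits = 4), " (df = ", x$g2$df, ")",
      sep = "")
  if (!is.null(x$gof)) {
    cat(", parametric-bootstrap p = ", format(x$gof$p_value, digits = 3),
        " (B = ", x$gof$n_bootstrap, ")", sep = "")
  }
  cat("\n")
  if (!is.null(x$class_by_age)) {
    cat("\nStrategy percentages by age group:\n")
    wide <- tidyr::pivot_wider(x$class_by_age[c("age_group", "class", "percent")],
                               names_from = "class", values_from = "percent",
                               names_prefix = "class")
    print(as.data.frame(wide), digits = 3, row.names = FALSE)
  }
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits the analysis as machine-readable JSON plus the human-readable text
#' rendering of the report.
#'
#' @param report A `study_report` from [run_variability_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  stopifnot(inherits(report, "study_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  payload <- list(
    comparison = report$comparison,
    k_star = report$k_star,
    lr_test = report$lr_test,
    accuracy_vs_strategy = report$accuracy_vs_strategy,
    strategy_preferred = report$strategy_preferred,
    selected = list(n_classes = report$selected$spec$n_classes,
                    covariate = report$selected$spec$covariate,
                    loglik = report$selected$loglik,
                    effective_params = report$selected$effective_params),
    response_probs = report$response_probs,
    class_sizes = report$class_sizes,
    g2 = report$g2,
    gof = if (!is.null(report$gof)) {
      report$gof[c("g2_observed", "df_reported", "n_bootstrap", "p_value",
                   "n_redraws")]
    },
    class_by_age = report$class_by_age,
    seed = report$seed
  )
  jsonlite::write_json(payload, file.path(dir, "study_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       dataframe = "rows")
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "study_report.txt"))
  invisible(dir)
}
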