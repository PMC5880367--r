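#' Specify a latent class model
#'
#' A model is defined by the number of latent classes K and where the age
#' covariate enters: nowhere (`"none"`), in the class-membership
#' probabilities through a multinomial logit (`"membership"`, the
#' concomitant-variable model; requires K >= 2), or in the per-class
#' response probabilities through a logistic link (`"response"`).
#'
#' @param n_classes Positive integer number of latent classes.
#' @param covariate One of `"none"`, `"membership"`, `"response"`.
#' @return An object of class `lcm_spec`.
#' @export
lcm_spec <- function(n_classes, covariate = c("none", "membership", "response")) {
  covariate <- match.arg(covariate)
  if (!is.numeric(n_classes) || length(n_classes) != 1L || n_classes < 1 ||
      n_classes != round(n_classes)) {
    abort("`n_classes` must be a positive integer.")
  }
  n_classes <- as.integer(n_classes)
  if (covariate == "membership" && n_classes < 2L) {
    abort("A membership covariate requires at least 2 classes.")
  }
  structure(list(n_classes = n_classes, covariate = covariate),
            class = "lcm_spec")
}

#' @export
print.lcm_spec <- function(x, ...) {
  cat("<lcm_spec> ", x$n_classes, " class(es), covariate = ", x$covariate,
      "\n", sep = "")
  invisible(x)
}

#' Bundle latent class model parameters
#'
#' Holds the two parameter blocks of a binary-response latent class model:
#' class-membership probabilities (`pi`, with multinomial-logit intercepts
#' and age slopes `alpha`/`beta` against class 1 when the covariate acts on
#' membership) and per-class response probabilities (`prob`, a K-by-J matrix,
#' with logit intercepts and age slopes `gamma`/`delta` when the covariate
#' acts on responses). Age slopes are expressed on the standardized-age scale
#' recorded in `age_center`/`age_scale`.
#'
#' @param pi Length-K class proportions (evaluated at the mean age).
#' @param prob K-by-J response probabilities (evaluated at the mean age).
#' @param alpha,beta Length-(K-1) membership intercepts and age slopes
#'   (reference class 1); `beta` is all zero unless the covariate acts on
#'   membership.
#' @param gamma,delta K-by-J logit-scale response intercepts and age slopes;
#'   `delta` is all zero unless the covariate acts on responses.
#' @param age_center,age_scale Centering/scaling constants (months) applied
#'   to age before it enters either linear predictor.
#' @return An object of class `lcm_params`.
#' @export
lcm_params <- function(pi, prob, alpha = NULL, beta = NULL,
                       gamma = NULL, delta = NULL,
                       age_center = 0, age_scale = 1) {
  prob <- as.matrix(prob)
  K <- length(pi)
  stopifnot(nrow(prob) == K)
  if (abs(sum(pi) - 1) > 1e-8 || any(pi < -1e-12)) {
    abort("`pi` must be a probability vector summing to 1.")
  }
  if (any(prob < -1e-12 | prob > 1 + 1e-12)) {
    abort("`prob` entries must lie in [0, 1].")
  }
  prob[] <- pmin(pmax(prob, 0), 1)
  pi <- pmax(pi, 0)
  pi <- pi / sum(pi)
  if (is.null(alpha)) alpha <- if (K > 1L) log(pi[-1] / pi[1]) else numeric(0)
  if (is.null(beta)) beta <- numeric(max(K - 1L, 0L))
  if (is.null(gamma)) gamma <- qlogis(prob)
  if (is.null(delta)) delta <- matrix(0, K, ncol(prob))
  structure(
    list(pi = as.numeric(pi), prob = prob,
         alpha = as.numeric(alpha), beta = as.numeric(beta),
         gamma = as.matrix(gamma), delta = as.matrix(delta),
         age_center = age_center, age_scale = age_scale),
    class = "lcm_params"
  )
}

n_items <- function(params) ncol(params$prob)

standardize_age <- function(age, center, scale) (age - center) / scale

# class-membership probabilities per subject: n x K
class_prob_matrix <- function(params, spec, z) {
  K <- spec$n_classes
  n <- length(z)
  if (spec$covariate == "membership") {
    eta <- cbind(0, matrix(params$alpha, n, K - 1L, byrow = TRUE) +
                   outer(z, params$beta))
    row_softmax(eta)
  } else {
    matrix(params$pi, n, K, byrow = TRUE)
  }
}

# response probabilities for one class across subjects: n x J
item_prob_matrix <- function(params, spec, z, class) {
  J <- n_items(params)
  n <- length(z)
  if (spec$covariate == "response") {
    plogis(matrix(params$gamma[class, ], n, J, byrow = TRUE) +
             outer(z, params$delta[class, ]))
  } else {
    matrix(params$prob[class, ], n, J, byrow = TRUE)
  }
}

# n x K matrix of log Pr(y_i | class c, age_i); probabilities clipped
class_loglik_matrix <- function(Y, params, spec, z) {
  n <- nrow(Y); K <- spec$n_classes
  out <- matrix(0, n, K)
  if (spec$covariate == "response") {
    for (k in seq_len(K)) {
      P <- clip_prob(item_prob_matrix(params, spec, z, k))
      out[, k] <- rowSums(Y * log(P) + (1 - Y) * log1p(-P))
    }
  } else {
    P <- clip_prob(params$prob)
    out <- Y %*% t(log(P)) + (1 - Y) %*% t(log1p(-P))
  }
  out
}

check_dims <- function(data, spec, params) {
  J <- length(response_trials(data))
  if (n_items(params) != J) {
    abort(paste0("Parameter block has ", n_items(params),
                 " items but data has ", J, " trials."))
  }
  if (length(params$pi) != spec$n_classes) {
    abort(paste0("Parameter block has ", length(params$pi),
                 " classes but spec requests ", spec$n_classes, "."))
  }
}

#' Log-likelihood of a latent class model
#'
#' Evaluates `sum_i log sum_c pi_c(x_i) prod_j p_cj(x_i)^y_ij
#' (1 - p_cj(x_i))^(1 - y_ij)` with a numerically stable log-sum over
#' classes. Response probabilities are floored at 1e-10 away from 0/1 inside
#' the evaluation only.
#'
#' @param data A [response_data] tibble.
#' @param spec An [lcm_spec].
#' @param params An [lcm_params] whose dimensions match `spec` and the data.
#' @return The log-likelihood. If some subject has probability exactly zero
#'   under every class (possible only through zero mixing weights), returns
#'   `-Inf` with the offending subjects recorded in
#'   `attr(, "degenerate_subjects")`.
#' @export
lcm_loglik <- function(data, spec, params) {
  check_dims(data, spec, params)
  Y <- response_matrix(data)
  z <- standardize_age(data$age_months, params$age_center, params$age_scale)
  ll <- class_loglik_matrix(Y, params, spec, z)
  lpi <- log(class_prob_matrix(params, spec, z))
  lse <- row_lse(ll + lpi)
  if (any(lse == -Inf)) {
    out <- -Inf
    attr(out, "degenerate_subjects") <- which(lse == -Inf)
    return(out)
  }
  sum(lse)
}

#' Posterior class responsibilities (E step)
#'
#' Bayes-rule responsibilities `Pr(class c | y_i, x_i)` for each subject;
#' each row sums to 1.
#'
#' @inheritParams lcm_loglik
#' @return An n-by-K matrix of posterior probabilities.
#' @export
lcm_estep <- function(data, spec, params) {
  check_dims(data, spec, params)
  Y <- response_matrix(data)
  z <- standardize_age(data$age_months, params$age_center, params$age_scale)
  estep_mat(Y, z, spec, params)
}

# matrix-level E step used inside the EM loop (avoids tibble round-trips);
# w holds per-row multiplicities when rows are collapsed response patterns
estep_mat <- function(Y, z, spec, params, w = NULL) {
  lp <- class_loglik_matrix(Y, params, spec, z) +
    log(class_prob_matrix(params, spec, z))
  lse <- row_lse(lp)
  if (any(lse == -Inf)) {
    bad <- which(lse == -Inf)
    abort(paste0(
      "Zero total probability for subject(s) ", paste(head(bad, 5L), collapse = ", "),
      " under the supplied parameters."
    ))
  }
  post <- exp(lp - lse)
  attr(post, "loglik") <- if (is.null(w)) sum(lse) else sum(w * lse)
  post
}

#' Update parameters from responsibilities (M step)
#'
#' Maximizes the expected complete-data log-likelihood given posterior class
#' responsibilities. Without a covariate this is closed form (posterior-
#' weighted means); with a membership covariate the multinomial-logit
#' coefficients are found by BFGS with an analytic gradient; with a response
#' covariate each class-item cell is a posterior-weighted logistic regression
#' of the item on standardized age.
#'
#' @inheritParams lcm_loglik
#' @param posteriors n-by-K responsibility matrix with unit row sums.
#' @param prev An [lcm_params] supplying warm starts for the covariate
#'   optimizations and fallback values for degenerate classes (posterior
#'   weight below 1e-8, which are flagged in `attr(, "degenerate_classes")`).
#' @return Updated [lcm_params].
#' @export
lcm_mstep <- function(data, spec, posteriors, prev) {
  Y <- response_matrix(data)
  z <- standardize_age(data$age_months, prev$age_center, prev$age_scale)
  mstep_mat(Y, z, spec, posteriors, prev)
}

# matrix-level M step used inside the EM loop; w holds row multiplicities
# when rows are collapsed response patterns (covariate-free models only)
mstep_mat <- function(Y, z, spec, posteriors, prev, w = NULL) {
  n <- nrow(Y); J <- ncol(Y); K <- spec$n_classes
  stopifnot(ncol(posteriors) == K, nrow(posteriors) == n)
  W <- if (is.null(w)) posteriors else posteriors * w
  n <- if (is.null(w)) n else sum(w)
  wsum <- colSums(W)
  degenerate <- which(wsum < 1e-8)

  # response block
  if (spec$covariate == "response") {
    gamma <- prev$gamma; delta <- prev$delta
    for (k in setdiff(seq_len(K), degenerate)) {
      for (j in seq_len(J)) {
        coefs <- weighted_logistic(z, Y[, j], W[, k],
                                   c(prev$gamma[k, j], prev$delta[k, j]))
        gamma[k, j] <- coefs[1]; delta[k, j] <- coefs[2]
      }
    }
    prob <- plogis(gamma) # evaluated at the mean age (z = 0)
  } else {
    prob <- prev$prob
    ok <- setdiff(seq_len(K), degenerate)
    prob[ok, ] <- (t(W[, ok, drop = FALSE]) %*% Y) / wsum[ok]
    prob[] <- pmin(pmax(prob, 0), 1) # guard float overshoot of weighted means
    gamma <- qlogis(prob)
    delta <- matrix(0, K, J)
  }

  # membership block
  if (spec$covariate == "membership") {
    th <- fit_weighted_multinomial(z, W, prev$alpha, prev$beta)
    alpha <- th$alpha; beta <- th$beta
    pi <- as.numeric(row_softmax(matrix(c(0, alpha), 1, K))) # at z = 0
  } else {
    pi <- wsum / n
    alpha <- if (K > 1L) log(pi[-1] / pi[1]) else numeric(0)
    beta <- numeric(max(K - 1L, 0L))
  }

  out <- lcm_params(pi = pi, prob = prob, alpha = alpha, beta = beta,
                    gamma = gamma, delta = delta,
                    age_center = prev$age_center, age_scale = prev$age_scale)
  if (length(degenerate) > 0L) attr(out, "degenerate_classes") <- degenerate
  out
}

# posterior-weighted logistic regression of y on z; returns c(intercept, slope)
weighted_logistic <- function(z, y, w, start) {
  if (sum(w) < 1e-8) return(start)
  fit <- suppressWarnings(
    glm.fit(x = cbind(1, z), y = y, weights = w, family = binomial(),
            control = list(maxit = 100))
  )
  co <- fit$coefficients
  if (anyNA(co)) co[is.na(co)] <- 0
  co
}

# maximize sum_ic W_ic log softmax_c(alpha_c + beta_c z_i) over alpha, beta.
# The objective is concave, so a damped Newton iteration with the analytic
# Hessian converges in a handful of steps (warm-started from the previous
# M step); coefficients are capped to keep softmax probabilities finite.
fit_weighted_multinomial <- function(z, W, alpha0, beta0,
                                     grad_tol = 1e-8, max_steps = 10) {
  K <- ncol(W); n <- nrow(W)
  m <- K - 1L
  eta_of <- function(th) {
    cbind(0, matrix(th[seq_len(m)], n, m, byrow = TRUE) +
            outer(z, th[(m + 1L):(2L * m)]))
  }
  # local log-sum-exp: the reference column pins eta at 0, so no row can
  # be all -Inf and the general guard is unnecessary
  lse_of <- function(eta) {
    mx <- eta[, 1L]
    for (k in 2L:K) mx <- pmax.int(mx, eta[, k])
    mx + log(rowSums(exp(eta - mx)))
  }
  nll <- function(th) {
    eta <- eta_of(th)
    -sum(W * (eta - lse_of(eta)))
  }
  th <- c(alpha0, beta0)
  th[!is.finite(th)] <- 0
  f <- nll(th)
  for (step in seq_len(max_steps)) {
    P <- row_softmax(eta_of(th))
    D <- P - W
    g <- c(colSums(D)[-1L], colSums(z * D)[-1L])
    if (max(abs(g)) < grad_tol) break
    # Hessian blocks: sum_i s_i P_ic (1[c=d] - P_id), s in {1, z, z^2}
    H <- matrix(0, 2L * m, 2L * m)
    for (c in seq_len(m)) {
      Pc <- P[, c + 1L]
      for (d in seq_len(c)) {
        Pd <- P[, d + 1L]
        cross <- Pc * ((c == d) - Pd)
        h1 <- sum(cross); hz <- sum(z * cross); hz2 <- sum(z * z * cross)
        H[c, d] <- H[d, c] <- h1
        H[c, m + d] <- H[m + d, c] <- hz
        H[d, m + c] <- H[m + c, d] <- hz
        H[m + c, m + d] <- H[m + d, m + c] <- hz2
      }
    }
    dir <- tryCatch(solve(H + diag(1e-10, 2L * m), g),
                    error = function(e) g) # fall back to gradient
    # backtracking line search on the concave objective
    stepsize <- 1
    repeat {
      th_new <- th - stepsize * dir
      th_new <- pmin(pmax(th_new, -30), 30)
      f_new <- nll(th_new)
      if (f_new <= f + 1e-12 || stepsize < 1e-8) break
      stepsize <- stepsize / 2
    }
    if (f - f_new < 1e-12 && max(abs(g)) < 1e-4) {
      th <- th_new
      break
    }
    th <- th_new
    f <- f_new
  }
  list(alpha = th[seq_len(m)], beta = th[(m + 1L):(2L * m)])
}
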