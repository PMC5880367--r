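# shared fixtures and independent oracles

table2_probs <- function() {
  matrix(c(1, 0.67, 0.94, 1,
           0.48, 0.33, 1, 0,
           0, 0, 1, 1),
         nrow = 3, byrow = TRUE)
}

study_proportions <- function() c(51, 27, 12) / 90

# wrap a bare 0/1 matrix as a response_data tibble
make_response_data <- function(Y, age = NULL, age_group = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  colnames(Y) <- paste0("trial", seq_len(ncol(Y)))
  df <- tibble::tibble(
    subject_id = paste0("s", seq_len(n)),
    age_months = if (is.null(age)) rep(48, n) else age
  )
  if (!is.null(age_group)) df$age_group <- age_group
  response_data(dplyr::bind_cols(df, tibble::as_tibble(Y)))
}

# random small response dataset for property tests
random_instance <- function(seed, n = 12, J = 3) {
  set.seed(seed)
  Y <- matrix(rbinom(n * J, 1, runif(1, 0.2, 0.8)), n, J)
  make_response_data(Y, age = runif(n, 24, 72))
}

# independent oracle: maximize the covariate-free mixture likelihood
# directly with optim over an unconstrained parametrization, from many
# random starts -- never touches the EM path
direct_max_loglik <- function(data, K, n_starts = 30, seed = 99) {
  Y <- response_matrix(data)
  J <- ncol(Y)
  nll <- function(th) {
    if (K > 1) {
      pi <- exp(c(0, th[1:(K - 1)]))
      pi <- pi / sum(pi)
      pm <- matrix(plogis(th[K:length(th)]), K, J)
    } else {
      pi <- 1
      pm <- matrix(plogis(th), 1, J)
    }
    # mixture likelihood written out directly (independent of the package's
    # evaluation path); pm is interior so no clipping is needed
    A <- Y %*% t(log(pm)) + (1 - Y) %*% t(log1p(-pm))
    -sum(log(exp(A) %*% pi))
  }
  npar <- (K - 1) + K * J
  set.seed(seed)
  best <- Inf
  for (s in seq_len(n_starts)) {
    st <- stats::rnorm(npar, 0, 1.5)
    opt <- try(stats::optim(st, nll, method = "BFGS",
                            control = list(maxit = 500, reltol = 1e-13)),
               silent = TRUE)
    if (!inherits(opt, "try-error") && opt$value < best) best <- opt$value
  }
  -best
}

# brute-force Fisher oracle: enumerate every table with the observed
# margins via binomial coefficients and sum the probabilities of tables no
# more probable than the observed one
fisher_bruteforce <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || (n - c1) == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[match(a, support)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# classical multinomial G2 from raw pattern frequencies (covariate-free
# cross-check for lcm_g2)
multinomial_g2 <- function(fit, data) {
  Y <- response_matrix(data)
  J <- ncol(Y)
  patterns <- as.matrix(expand.grid(rep(list(c(0, 1)), J)))
  key <- function(m) apply(m, 1, paste0, collapse = "")
  O <- as.numeric(table(factor(key(Y), levels = key(patterns))))
  pi <- fit$params$pi
  pm <- fit$params$prob
  probs <- vapply(seq_len(nrow(patterns)), function(s) {
    y <- patterns[s, ]
    sum(vapply(seq_along(pi), function(k) {
      pi[k] * prod(pm[k, ]^y * (1 - pm[k, ])^(1 - y))
    }, numeric(1)))
  }, numeric(1))
  E <- nrow(Y) * probs
  pos <- O > 0
  2 * sum(O[pos] * log(O[pos] / E[pos]))
}
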