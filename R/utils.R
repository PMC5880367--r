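#' @importFrom rlang abort warn inform %||%
#' @importFrom stats plogis qlogis pchisq dhyper phyper pnorm qnorm runif rbinom
#' @importFrom stats rgamma optim glm.fit binomial setNames
#' @importFrom utils head
NULL

# probability floor used inside likelihood evaluation only; stored estimates
# are never clipped so boundary counting sees true 0/1
PROB_EPS <- 1e-10

clip_prob <- function(p) {
  p[p < PROB_EPS] <- PROB_EPS
  p[p > 1 - PROB_EPS] <- 1 - PROB_EPS
  p
}

# row-wise log-sum-exp without apply(); x is n x K with small K
row_lse <- function(x) {
  m <- x[, 1L]
  K <- ncol(x)
  if (K > 1L) for (k in 2L:K) m <- pmax(m, x[, k])
  m[!is.finite(m)] <- 0 # all -Inf rows: lse is -Inf via log(0) below
  lse <- m + log(rowSums(exp(x - m)))
  lse[apply_all_neginf(x)] <- -Inf
  lse
}

apply_all_neginf <- function(x) {
  out <- x[, 1L] == -Inf
  K <- ncol(x)
  if (K > 1L) for (k in 2L:K) out <- out & (x[, k] == -Inf)
  out
}

# softmax over rows of an n x K linear-predictor matrix
row_softmax <- function(eta) {
  m <- eta[, 1L]
  K <- ncol(eta)
  if (K > 1L) for (k in 2L:K) m <- pmax(m, eta[, k])
  ex <- exp(eta - m)
  ex / rowSums(ex)
}

# all permutations of 1:k (k <= 5 in practice)
all_permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    rest <- all_permutations(k - 1L)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(k), i)[p])))
  }
  out
}

# deterministic sub-seed derivation from a master seed (kept below 2^31)
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

pattern_key <- function(mat) apply(mat, 1L, paste0, collapse = "")
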