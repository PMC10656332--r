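## Independent oracles used across the suite.  All of them deliberately
## avoid the package's Fisher-scoring path and margin bookkeeping.

## Expand a sparse table into one respondent row per observation.
obs_matrix <- function(tab) {
  tab$patterns[rep(seq_len(nrow(tab$patterns)), tab$counts), , drop = FALSE]
}

## Coefficient alpha straight from raw observations, divisor N.
oracle_alpha <- function(tab) {
  x <- obs_matrix(tab)
  N <- nrow(x)
  S <- stats::cov(x) * (N - 1) / N
  J <- ncol(x)
  (J / (J - 1)) * (1 - sum(diag(S)) / sum(S))
}

## H_j coefficients by brute-force counting over the dense table, items in
## the order given: for the ordered pair (i, j), i before j, the
## Guttman-error cell is {i = 0, j = 1}.
oracle_hj <- function(tab) {
  n <- as_dense(tab)
  J <- tab$J
  pat <- index_to_pattern(seq_along(n) - 1, tab$cats)
  N <- sum(n)
  m1 <- vapply(seq_len(J), function(j) sum(n[pat[, j] == 1]), numeric(1))
  m0 <- N - m1
  H <- numeric(J)
  for (j in seq_len(J)) {
    num <- den <- 0
    for (i in seq_len(J)) {
      if (i < j) {
        num <- num + sum(n[pat[, i] == 0 & pat[, j] == 1])
        den <- den + m0[i] * m1[j]
      } else if (i > j) {
        num <- num + sum(n[pat[, j] == 0 & pat[, i] == 1])
        den <- den + m0[j] * m1[i]
      }
    }
    H[j] <- 1 - N * num / den
  }
  H
}

## General-purpose constrained maximizer of the multinomial likelihood over
## the probability simplex: augmented Lagrangian on N * softmax(z), inner
## BFGS.  Returns fitted frequencies and G2.  Only for small supports.
oracle_constrained_fit <- function(model, tab, support = c("full", "observed"),
                                   sweeps = 40, seed = 1) {
  support <- match.arg(support)
  stab <- if (support == "full") cmmael:::full_support_table(tab) else tab
  n <- stab$counts
  N <- stab$N
  S <- length(n)
  At <- cmmael:::margin_matrix(model, stab)
  gf <- function(m) tryCatch(cmmael:::constraints_eval(model, At, m, N)$g,
                             error = function(e) NULL)
  obj <- function(z, lam, rho) {
    m <- exp(z - max(z)); m <- N * m / sum(m)
    g <- gf(m)
    if (is.null(g)) return(1e8)
    -sum(n[n > 0] * log(m[n > 0])) + sum(lam * g) + rho / 2 * sum(g^2)
  }
  set.seed(seed)
  z <- stats::rnorm(S, sd = 0.1)
  lam <- numeric(model$D)
  rho <- 10
  for (k in seq_len(sweeps)) {
    o <- stats::optim(z, obj, lam = lam, rho = rho, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-15))
    z <- o$par
    m <- exp(z - max(z)); m <- N * m / sum(m)
    g <- gf(m)
    if (is.null(g)) break
    lam <- lam + rho * g
    rho <- min(rho * 2, 1e8)
  }
  m <- exp(z - max(z)); m <- N * m / sum(m)
  g <- gf(m)
  list(m = m, G2 = 2 * sum(n[n > 0] * log(n[n > 0] / m[n > 0])),
       max_g = if (is.null(g)) Inf else max(abs(g)))
}

## Random dense small tables (all cells positive) for oracle comparisons.
random_dense_table <- function(J, seed, min_count = 1L, lambda = 8) {
  set.seed(seed)
  L <- 2^J
  counts <- stats::rpois(L, lambda) + min_count
  sparse_table(index_to_pattern(seq_len(L) - 1, rep(2L, J)),
               counts = counts, cats = rep(2L, J))
}

## Numeric ICC integral: expected item mean under the 2PL with N(0,1) trait.
oracle_2pl_mean <- function(a, b) {
  stats::integrate(function(t) stats::plogis(a * (t - b)) * stats::dnorm(t),
                   -Inf, Inf)$value
}
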