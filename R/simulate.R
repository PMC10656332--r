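#' Sample response patterns from a two-parameter logistic IRT model
#'
#' Draws a latent trait `theta ~ N(0, 1)` per respondent and dichotomous
#' item responses with success probability
#' `P(X_j = 1 | theta) = 1 / (1 + exp(-a_j (theta - b_j)))`, the
#' two-parameter logistic model (2PL).  Used to construct base tables for
#' null-population construction.
#'
#' @param a discrimination parameters (positive, recycled to `J`).
#' @param b location (difficulty) parameters; `J = length(b)`.
#' @param n number of respondents.
#' @param seed integer seed (draws are deterministic given it).
#' @return a [sparse_table()] of the sampled patterns.
#' @examples
#' tab <- twopl_sample(1.5, b = c(-1, 0, 1), n = 200, seed = 1)
#' @export
twopl_sample <- function(a, b, n, seed = NULL) {
  J <- length(b)
  a <- rep_len(a, J)
  if (any(a <= 0)) stop("discriminations must be positive", call. = FALSE)
  if (n < 1) stop("need at least one respondent", call. = FALSE)
  x <- with_seed(seed, {
    theta <- stats::rnorm(n)
    p <- stats::plogis(outer(theta, b, "-") * rep(a, each = n))
    matrix(as.integer(stats::runif(n * J) < p), n, J)
  })
  sparse_table(x, cats = rep(2L, J))
}

#' Construct a null population satisfying a CMM exactly
#'
#' Fits the model to a base table (ML for small tables, MAEL for large
#' ones) and uses the fitted probabilities `pi = m_hat / N` as the data
#' generating distribution.  By construction the population satisfies the
#' model constraints to solver tolerance, so samples from it realize the
#' null hypothesis of the model regardless of how the base table was
#' produced.
#'
#' @param model a [cmm_model()].
#' @param base a [sparse_table()] of base data (e.g. from
#'   [twopl_sample()]; 1000 patterns by default in the study drivers).
#' @param method `"MAEL"` or `"ML"`.
#' @param seed seed for the augmentation draws.
#' @param control a [cmm_control()].
#' @return an object of class `cmm_population`: list with `patterns`,
#'   `cats`, `pi` (probabilities over the support) and the underlying `fit`.
#' @export
build_population <- function(model, base, method = c("MAEL", "ML"),
                             seed = NULL, control = cmm_control()) {
  method <- match.arg(method)
  fit <- cmm_fit(model, base, method = method, seed = seed, control = control)
  if (!fit$converged)
    stop("population construction failed: model fit did not converge",
         call. = FALSE)
  pi <- fit$m_hat / fit$N
  keep <- pi > 0
  pi <- pi[keep] / sum(pi[keep])
  structure(list(patterns = fit$support$patterns[keep, , drop = FALSE],
                 cats = fit$support$cats, pi = pi, model = model, fit = fit),
            class = "cmm_population")
}

#' @export
print.cmm_population <- function(x, ...) {
  cat(sprintf("Population model on %d support cells (J = %d)\n",
              length(x$pi), ncol(x$patterns)))
  invisible(x)
}

#' Randomly zero out population cells
#'
#' Sets a uniformly random `ceiling(U * |support|)` subset of the population
#' probabilities to zero and rescales the rest to sum to one, creating
#' unobservable response patterns.  The thinned population need no longer
#' satisfy the model constraints, so it is used only for convergence
#' studies, not for Type I error or bias.
#'
#' @param pop a `cmm_population`.
#' @param U fraction of cells to zero, `0 <= U < 1`.
#' @param seed integer seed.
#' @return a thinned `cmm_population`.
#' @export
thin_zeros <- function(pop, U, seed = NULL) {
  stopifnot(inherits(pop, "cmm_population"))
  if (U < 0 || U >= 1) stop("U must lie in [0, 1)", call. = FALSE)
  if (U == 0) return(pop)
  S <- length(pop$pi)
  k <- ceiling(U * S)
  drop <- with_seed(seed, sample.int(S, k))
  pi <- pop$pi
  pi[drop] <- 0
  if (sum(pi) <= 0)
    stop("thinning removed all probability mass", call. = FALSE)
  keep <- pi > 0
  structure(list(patterns = pop$patterns[keep, , drop = FALSE],
                 cats = pop$cats, pi = pi[keep] / sum(pi[keep]),
                 model = pop$model, fit = pop$fit),
            class = "cmm_population")
}

#' Draw a multinomial sample from a population model
#'
#' @param pop a `cmm_population`.
#' @param N sample size.
#' @param seed integer seed.
#' @return a [sparse_table()] of the positive sampled cells.
#' @export
sample_population <- function(pop, N, seed = NULL) {
  cnt <- with_seed(seed, as.numeric(stats::rmultinom(1, N, pop$pi)))
  keep <- cnt > 0
  sparse_table(pop$patterns[keep, , drop = FALSE], counts = cnt[keep],
               cats = pop$cats)
}

default_2pl_items <- function(J) {
  list(a = rep(1.5, J),
       b = if (J == 1) 0 else seq(-1.5, 1.5, length.out = J))
}

build_family_model <- function(family, J, criterion = NULL) {
  switch(family,
         mean = mean_model(J),
         alpha = alpha_model(J, criterion %||% 0.8),
         hj = suppressWarnings(hj_model(J, criterion %||% 0.3)),
         stop("unknown model family: ", family, call. = FALSE))
}

#' Type I error study under a self-constructed null population
#'
#' Builds one null population for the requested model family (2PL base data
#' of `base_n` patterns, constraints imposed exactly via
#' [build_population()]), draws `replications` multinomial samples of size
#' `N`, fits each by MAEL (fresh augmentation seed per replication) and
#' records the rejection rate of the `G2` test at the nominal level, the
#' convergence rate and, for the equality-of-means model, bias and standard
#' deviation of the parameter estimate (the overall mean item score).
#' Non-converged replications count as non-rejections and are reported
#' separately through the convergence rate.
#'
#' @param family `"mean"`, `"alpha"` or `"hj"`.
#' @param J number of items.
#' @param N sample size per replication.
#' @param replications number of Monte-Carlo replications.
#' @param seed master seed; per-replication seeds are derived from it.
#' @param criterion model criterion (defaults: alpha 0.8, hj 0.3).
#' @param level nominal Type I error rate (default 0.05).
#' @param base_n base-table size for population construction (default 1000).
#' @param control a [cmm_control()].
#' @return a one-row `data.frame` (class `cmm_study`): family, `J`, `N`,
#'   `method`, `replications`, `converged`, `convergence_rate`,
#'   `rejection_rate`, `mc_se` (Monte-Carlo SE of the rejection rate),
#'   `beta_true`, `beta_bias`, `beta_sd`.
#' @export
run_type1_study <- function(family = c("mean", "alpha", "hj"), J, N,
                            replications = 1000L, seed = 1L,
                            criterion = NULL, level = 0.05, base_n = 1000L,
                            control = cmm_control()) {
  family <- match.arg(family)
  model <- build_family_model(family, J, criterion)
  seeds <- with_seed(seed, sample.int(2^31 - 2, replications + 2L))

  items <- default_2pl_items(J)
  base <- twopl_sample(items$a, items$b, base_n, seed = seeds[1L])
  pop <- build_population(model, base,
                          method = if (prod(base$cats) <= 4096) "ML"
                                   else "MAEL",
                          seed = seeds[2L], control = control)

  ## true parameter for the mean model: overall mean item score of pi
  beta_true <- NA_real_
  if (family == "mean")
    beta_true <- mean(vapply(seq_len(J), function(j)
      sum(pop$pi[pop$patterns[, j] == 1L]), numeric(1)))

  reject <- conv <- logical(replications)
  betah <- rep(NA_real_, replications)
  for (r in seq_len(replications)) {
    tab <- sample_population(pop, N, seed = seeds[r + 2L])
    fit <- tryCatch(
      cmm_fit(model, tab, method = "MAEL", seed = seeds[r + 2L],
              control = control),
      cmm_error = function(e) NULL, error = function(e) NULL)
    if (!is.null(fit) && fit$converged) {
      conv[r] <- TRUE
      reject[r] <- is.finite(fit$p_value) && fit$p_value < level
      if (family == "mean" && !is.null(fit$mean_score))
        betah[r] <- fit$mean_score
    }
  }

  rate <- mean(reject)
  out <- data.frame(
    family = family, J = J, N = N, method = "MAEL",
    replications = replications, converged = sum(conv),
    convergence_rate = mean(conv), rejection_rate = rate,
    mc_se = sqrt(rate * (1 - rate) / replications),
    beta_true = beta_true,
    beta_bias = if (family == "mean") mean(betah, na.rm = TRUE) - beta_true
                else NA_real_,
    beta_sd = if (family == "mean") stats::sd(betah, na.rm = TRUE)
              else NA_real_)
  class(out) <- c("cmm_study", "data.frame")
  out
}

#' Convergence-rate study across estimation methods
#'
#' For each experimental cell (method by zero-cell fraction `U`), builds a
#' null population, thins it with [thin_zeros()], draws samples of size `N`
#' and fits the family model by the requested method, classifying each
#' replication as converged, first-order problem, second-order problem or
#' other non-convergence.  For the alpha family the criterion is the sample
#' alpha plus 0.2 and for the H_j family the mean of the sample `H_j`
#' values (both clamped to (0.01, 0.99)), so that the fitted criterion is
#' always attainable in principle.
#'
#' @param config list (or path to a YAML file, see [read_study_config()])
#'   with fields `family`, `J`, `N`, `U` (vector of fractions), `methods`
#'   (subset of ML/MEL/MAEL), `replications`, `seed`, and optionally
#'   `base_n`, `criterion`.
#' @param control a [cmm_control()].
#' @return a `data.frame` with one row per experimental cell: convergence
#'   rate and failure-type rates.
#' @export
run_convergence_study <- function(config, control = cmm_control()) {
  if (is.character(config)) config <- read_study_config(config)
  need <- c("family", "J", "N", "U", "methods", "replications", "seed")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("study config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  family <- config$family
  J <- config$J; N <- config$N
  base_n <- config$base_n %||% 1000L
  reps <- config$replications

  seeds <- with_seed(config$seed,
                     sample.int(2^31 - 2, 2L + length(config$U) +
                                  reps * length(config$U)))
  model0 <- build_family_model(family, J, config$criterion)
  items <- default_2pl_items(J)
  base <- twopl_sample(items$a, items$b, base_n, seed = seeds[1L])
  pop0 <- build_population(model0, base,
                           method = if (prod(base$cats) <= 4096) "ML"
                                    else "MAEL",
                           seed = seeds[2L], control = control)

  rows <- list()
  si <- 2L
  for (ui in seq_along(config$U)) {
    U <- config$U[ui]
    si <- si + 1L
    pop <- thin_zeros(pop0, U, seed = seeds[si])
    tally <- array(0L, dim = c(length(config$methods), 4L),
                   dimnames = list(config$methods,
                                   c("converged", "first_order",
                                     "second_order", "nonconverged")))
    for (r in seq_len(reps)) {
      rs <- seeds[2L + length(config$U) + (ui - 1L) * reps + r]
      tab <- sample_population(pop, N, seed = rs)
      model <- sample_criterion_model(family, J, tab, config$criterion)
      if (is.null(model)) next   # degenerate sample; counts as nonconvergence
      for (meth in config$methods) {
        out <- classify_fit(model, tab, meth, rs, control)
        tally[meth, out] <- tally[meth, out] + 1L
      }
    }
    for (meth in config$methods)
      rows[[length(rows) + 1L]] <- data.frame(
        family = family, J = J, N = N, U = U, method = meth,
        replications = reps,
        convergence_rate = tally[meth, "converged"] / reps,
        first_order_rate = tally[meth, "first_order"] / reps,
        second_order_rate = tally[meth, "second_order"] / reps,
        nonconvergence_rate = tally[meth, "nonconverged"] / reps)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cmm_study", "data.frame")
  out
}

## sample-dependent criterion for the convergence study
sample_criterion_model <- function(family, J, tab, criterion = NULL) {
  tryCatch({
    if (family == "alpha" && is.null(criterion)) {
      cr <- min(max(cmm_alpha(tab) + 0.2, 0.01), 0.99)
      alpha_model(J, cr)
    } else if (family == "hj" && is.null(criterion)) {
      cr <- min(max(mean(cmm_hj(tab)), 0.01), 0.99)
      suppressWarnings(hj_model(J, cr))
    } else build_family_model(family, J, criterion)
  }, error = function(e) NULL)
}

classify_fit <- function(model, tab, method, seed, control) {
  fit <- tryCatch(
    cmm_fit(model, tab, method = method, seed = seed, control = control),
    cmm_first_order_error = function(e) "first_order",
    cmm_second_order_error = function(e) "second_order",
    cmm_augmentation_error = function(e) "nonconverged",
    error = function(e) "nonconverged")
  if (is.character(fit)) return(fit)
  if (fit$converged) "converged" else "nonconverged"
}

#' Read a study configuration from YAML
#'
#' Valid keys: `family`, `J`, `cats`, `N`, `U`, `methods`, `replications`,
#' `seed`, `base_n`, `criterion`, `level`.  `seed` is mandatory so that
#' every study is reproducible.
#'
#' @param file path to the YAML file.
#' @return a named list.
#' @export
read_study_config <- function(file) {
  cfg <- yaml::read_yaml(file)
  valid <- c("family", "J", "cats", "N", "U", "methods", "replications",
             "seed", "base_n", "criterion", "level", "kind")
  bad <- setdiff(names(cfg), valid)
  if (length(bad))
    stop("invalid study config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$seed))
    stop("study config must set a seed (studies are reproducible by policy)",
         call. = FALSE)
  cfg
}

#' @export
print.cmm_study <- function(x, ...) {
  cat("CMM simulation study results:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}
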