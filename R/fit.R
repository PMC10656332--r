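#' Solver control parameters
#'
#' @param max_iter maximum Fisher-scoring iterations (default 1000).
#' @param tol_g convergence tolerance on the constraint residual, relative to
#'   `N`: converged when `max|g~(m)| < tol_g * N`.
#' @param tol_m convergence tolerance on the step, relative to `N`.
#' @param floor_frac expected frequencies are floored at `floor_frac * N` so
#'   that the diagonal weight matrix stays invertible.
#' @param boundary_frac cells with fitted frequency below
#'   `boundary_frac * N` are flagged as boundary cells (the step-halved
#'   iterates decay geometrically towards zero, so boundary optima stall
#'   slightly above the hard floor).
#' @param cap full-table materialization cap (cells); ML refuses larger
#'   tables.
#' @param augment_cap maximum number of cells support augmentation may add
#'   (default `50 * D + 100`).
#' @param restarts random restarts used by the heuristic first-order-problem
#'   check for nonlinear links.
#' @return a list of class `cmm_control`.
#' @export
cmm_control <- function(max_iter = 1000L, tol_g = 1e-8, tol_m = 1e-8,
                        floor_frac = 1e-12, boundary_frac = 1e-6, cap = 1e7,
                        augment_cap = NULL, restarts = 5L) {
  structure(list(max_iter = as.integer(max_iter), tol_g = tol_g, tol_m = tol_m,
                 floor_frac = floor_frac, boundary_frac = boundary_frac,
                 cap = cap, augment_cap = augment_cap,
                 restarts = as.integer(restarts)),
            class = "cmm_control")
}

cmm_error <- function(class, message, ...) {
  structure(class = c(class, "cmm_error", "error", "condition"),
            list(message = message, call = sys.call(-1), ...))
}

#' Fit a categorical marginal model
#'
#' Maximizes the multinomial log-likelihood `sum_i n_i log m_i` subject to
#' the model constraints `g(m) = 0` and the total-count constraint
#' `sum_i m_i = N`, over one of three supports:
#'
#' * `"ML"` — all `prod(cats)` cells of the table (guarded by the
#'   materialization cap);
#' * `"MEL"` — only the cells with positive observed count (zero cells are
#'   treated as structural zeroes);
#' * `"MAEL"` — the observed cells plus an augmentation of well-chosen
#'   zero-count cells (see [augment_support()]), which repairs the first- and
#'   second-order estimation problems MEL runs into on sparse tables.
#'
#' The solver is Aitchison-Silvey/Lang-style Fisher scoring on the
#' Lagrangian with step halving: at iterate `m`, with `G~` the constraint
#' Jacobian extended by the total-count row, it solves
#' `(G~ D_m G~') lambda = g~(m) + G~ (n - m)` and moves towards the candidate
#' `m+ = n - D_m G~' lambda`, halving the step until the iterate stays above
#' the frequency floor and an l1-penalized likelihood merit does not worsen.
#' Starting values are uniform, `m_i = N / |support|`.
#'
#' @param model a [cmm_model()] (or one of the builders' models).
#' @param data a [sparse_table()], or a respondent-by-item score matrix.
#' @param method `"MAEL"` (default), `"ML"` or `"MEL"`.
#' @param augment augmentation level for MAEL: `"second"` (default; covers
#'   model margins and their pairwise covariance margins, then adds random
#'   cells until the constraint covariance has full rank), `"first"` (margin
#'   coverage only) or `"none"`.
#' @param extra_cells additional random zero cells appended to the
#'   augmentation.
#' @param augment_cells explicit augmentation: a pattern matrix (or vector
#'   of pattern strings) of zero-count cells to add to the support instead
#'   of the automatic plan.
#' @param seed integer seed controlling the (seeded, replayable) random
#'   augmentation draws.
#' @param start optional starting values for the expected frequencies:
#'   a vector over the support, either positional or named by pattern
#'   string (e.g. from a reloaded fit report).  Default: uniform.
#' @param control a [cmm_control()] list.
#' @return an object of class `cmm_fit`; see Details.  Components include
#'   the fitted expected frequencies `m_hat` over `support`, Lagrange
#'   multipliers `lambda` (the `D` constraints plus the total-count
#'   constraint), `G2`, `X2`, `df`, `p_value`, `beta`/`beta_se` (models with
#'   a design matrix), `mean_score` (equality-of-means model),
#'   `iterations`, `converged`, `boundary_cells` and the `augmentation`
#'   plan.  If a positive count faces a floored expected frequency, `G2` is
#'   `Inf` and the floored (truncation-dependent) value is kept in
#'   `G2_truncated`.
#' @section Estimation problems: if the scoring equations are singular the
#'   fit signals a classed error: `cmm_first_order_error` when the constraint
#'   set has no solution on the support (the empty-set problem), otherwise
#'   `cmm_second_order_error` (constraint covariance not estimable —
#'   augmenting the support usually repairs this).
#' @examples
#' tab <- example_tables()$three_items
#' fit <- cmm_fit(mean_model(3), tab, method = "ML")
#' fit$G2        # 2.6107
#' round(fit$m_hat, 3)
#' @export
cmm_fit <- function(model, data, method = c("MAEL", "ML", "MEL"),
                    augment = c("second", "first", "none"), extra_cells = 0L,
                    augment_cells = NULL, seed = NULL, start = NULL,
                    control = cmm_control()) {
  method <- match.arg(method)
  augment <- match.arg(augment)
  if (!inherits(data, "sparse_table")) data <- sparse_table(data)
  stopifnot(inherits(model, "cmm_model"))
  if (model$J != data$J)
    stop("model and data disagree on the number of variables", call. = FALSE)
  model <- hj_resolve_order(model, data)

  plan <- NULL
  if (method == "ML") {
    stab <- full_support_table(data, control$cap)
  } else {
    ## observed support only
    keep <- data$counts > 0
    stab <- sparse_table(data$patterns[keep, , drop = FALSE],
                         counts = data$counts[keep], cats = data$cats)
    if (method == "MAEL" && !is.null(augment_cells)) {
      if (is.character(augment_cells))
        augment_cells <- string_to_pattern(augment_cells, data$J)
      plan <- structure(
        list(added = augment_cells, level = "manual", seed = seed,
             coverage_report = data.frame(
               pattern = pattern_to_string(augment_cells, data$cats),
               reason = "user-specified")),
        class = "cmm_augmentation")
      stab <- apply_augmentation(stab, plan)
    } else if (method == "MAEL" && augment != "none") {
      plan <- augment_support(stab, model, seed = seed, level = augment,
                              extra = extra_cells, control = control)
      stab <- apply_augmentation(stab, plan)
    }
  }

  res <- fit_support(model, stab, control, start = start)
  res$model <- model
  res$method <- method
  res$augmentation <- plan
  res$seed <- seed
  res
}

apply_augmentation <- function(stab, plan) {
  if (is.null(plan) || nrow(plan$added) == 0L) return(stab)
  sparse_table(rbind(stab$patterns, plan$added),
               counts = c(stab$counts, numeric(nrow(plan$added))),
               cats = stab$cats,
               augmented = c(stab$augmented, rep(TRUE, nrow(plan$added))))
}

## core constrained maximizer over a fixed support
fit_support <- function(model, stab, control = cmm_control(), start = NULL) {
  At <- margin_matrix(model, stab)
  n <- stab$counts
  N <- stab$N
  S <- length(n)
  D <- model$D
  floor_m <- control$floor_frac * N
  tol_g <- control$tol_g * N
  tol_m <- control$tol_m * N

  gtilde <- function(m) {
    ev <- constraints_eval(model, At, m, N)
    list(g = c(ev$g, sum(m) - N), G = rbind(ev$G, 1), ev = ev)
  }
  loglik <- function(m) sum(n[n > 0] * log(m[n > 0]))

  if (is.null(start)) {
    m <- rep(N / S, S)               # uniform starting values
  } else {
    if (!is.null(names(start))) {
      key <- pattern_to_string(stab$patterns, stab$cats)
      start <- start[match(key, names(start))]
    }
    if (length(start) != S || anyNA(start))
      stop("`start` must cover every support cell", call. = FALSE)
    m <- pmax(as.numeric(start), floor_m)
  }
  cur <- gtilde(m)
  converged <- FALSE
  iter <- 0L
  prev_step <- NULL
  ll_prev <- loglik(m)
  ll_flat <- 0L
  for (iter in seq_len(control$max_iter)) {
    V <- cur$G %*% (m * t(cur$G))
    lambda <- tryCatch(solve(V, cur$g + as.numeric(cur$G %*% (n - m))),
                       error = function(e) NULL)
    if (is.null(lambda)) {
      ## singular scoring equations: report the sharper of the two
      ## estimation problems
      fo <- detect_first_order_problem(model, stab, control = control)
      if (identical(fo, "present"))
        stop(cmm_error("cmm_first_order_error",
                       paste0("first-order estimation problem (empty-set ",
                              "problem): the constraints have no solution ",
                              "on this support")))
      stop(cmm_error("cmm_second_order_error",
                     paste0("second-order estimation problem: singular ",
                            "constraint covariance on this support; ",
                            "consider MAEL estimation with support ",
                            "augmentation")))
    }
    mplus <- n - m * as.numeric(t(cur$G) %*% lambda)
    dir <- mplus - m
    w <- 2 * max(1, max(abs(lambda)))
    merit0 <- -loglik(m) + w * sum(abs(cur$g))
    ## halve the initial step when the direction reverses, which collapses
    ## the period-2 limit cycles the full scoring step can fall into
    s <- if (!is.null(prev_step) && sum(dir * prev_step) < 0) 0.5 else 1
    repeat {
      mnew <- pmax(m + s * dir, floor_m)
      nxt <- tryCatch(gtilde(mnew), error = function(e) NULL)
      if (!is.null(nxt)) {
        merit1 <- -loglik(mnew) + w * sum(abs(nxt$g))
        if (merit1 <= merit0 + 1e-10 * (abs(merit0) + 1)) break
      }
      s <- s / 2
      if (s < 2^-30) break
    }
    if (is.null(nxt)) break                     # link undefined along the path
    step <- max(abs(mnew - m))
    prev_step <- mnew - m
    m <- mnew; cur <- nxt
    ll_now <- loglik(m)
    ll_flat <- if (abs(ll_now - ll_prev) < 1e-9 * (abs(ll_now) + 1))
      ll_flat + 1L else 0L
    ll_prev <- ll_now
    if (max(abs(cur$g)) < tol_g) {
      ## either the iterates have settled, or only likelihood-neutral
      ## zero-count cells are still decaying towards the boundary
      if (step < tol_m || ll_flat >= 3L) { converged <- TRUE; break }
    }
    if (s < 2^-30) break                        # stalled
  }

  zero_tol <- control$boundary_frac * N
  boundary <- which(m <= zero_tol)
  gof <- goodness_of_fit(n, m, D, zero_tol = zero_tol)

  beta <- beta_se <- mean_score <- NULL
  if (!is.null(model$Z)) {
    beta <- beta_from_margins(model, stab, m)
    mean_score <- attr(beta, "mean_score")
    attr(beta, "mean_score") <- NULL
    beta_se <- tryCatch(
      beta_se_compute(model, At, m, N),
      error = function(e) NULL)
  }

  structure(
    list(model = model, method = NA_character_, support = stab, n = n,
         m_hat = m, lambda = lambda, G2 = gof$G2, X2 = gof$X2,
         G2_truncated = gof$G2_truncated, df = D, p_value = gof$p,
         beta = beta, beta_se = beta_se, mean_score = mean_score,
         iterations = iter, converged = converged,
         max_g = max(abs(cur$g)), boundary_cells = boundary,
         N = N, control = control, augmentation = NULL, seed = NULL),
    class = "cmm_fit")
}

#' Goodness-of-fit statistics
#'
#' Likelihood-ratio and Pearson statistics comparing observed counts to
#' fitted expected frequencies on a common support:
#' `G2 = 2 sum_{n_i > 0} n_i log(n_i / m_i)` (with `0 log 0 = 0`) and
#' `X2 = sum_{m_i > 0} (n_i - m_i)^2 / m_i`, referred to a chi-square
#' distribution with `df` degrees of freedom.  A positive count facing a
#' zero (floored) expected frequency makes `G2` infinite; the value computed
#' at the floor is returned as `G2_truncated`.
#'
#' @param n observed counts over the support.
#' @param m_hat fitted expected frequencies (same support, same total).
#' @param df degrees of freedom (number of model constraints).
#' @param zero_tol boundary threshold below which `m_hat` counts as zero.
#' @return list with `G2`, `X2`, `p` (upper-tail probability) and
#'   `G2_truncated` (non-`NULL` only when `G2` is infinite).
#' @export
goodness_of_fit <- function(n, m_hat, df, zero_tol = 1e-6 * sum(n)) {
  if (any(n < 0) || any(m_hat < 0))
    stop("negative counts or expected frequencies", call. = FALSE)
  floor_m <- 1e-12 * sum(n)
  pos <- n > 0
  zero_exp <- pos & (m_hat <= zero_tol)
  G2_raw <- 2 * sum(n[pos] * log(n[pos] / pmax(m_hat[pos], floor_m)))
  if (any(zero_exp)) {
    warning("positive observed count with boundary-zero expected frequency; ",
            "G2 is infinite (truncated value retained)", call. = FALSE)
    G2 <- Inf
    G2_truncated <- G2_raw
  } else {
    G2 <- max(G2_raw, 0)
    G2_truncated <- NULL
  }
  pos_m <- m_hat > zero_tol
  X2 <- sum((n[pos_m] - m_hat[pos_m])^2 / m_hat[pos_m])
  p <- stats::pchisq(G2, df, lower.tail = FALSE)
  list(G2 = G2, X2 = X2, p = p, G2_truncated = G2_truncated)
}

## delta-method asymptotic covariance of beta-hat.
## Cov(m-hat) = D - D G~'(G~ D G~')^{-1} G~ D with G~ the model-constraint
## Jacobian extended by the total-count row; with only the total-count row
## this is the multinomial covariance D - m m'/N.
beta_se_compute <- function(model, At, m, N) {
  ev <- constraints_eval(model, At, m, N)
  Gt <- rbind(ev$G, 1)
  V <- Gt %*% (m * t(Gt))
  DG <- m * t(Gt)                      # D_m G~'
  Cov <- diag(m) - DG %*% solve(V, t(DG))
  Z <- model$Z
  Jf <- model$f_jac(ev$u, N)
  Jbeta <- solve(crossprod(Z), crossprod(Z, Jf)) %*% At
  se <- sqrt(pmax(diag(Jbeta %*% Cov %*% t(Jbeta)), 0))
  if (model$type == "mean")
    attr(se, "mean_score_se") <- se / (sqrt(model$J) * N)
  se
}

#' Standard errors of the model parameter
#'
#' Delta-method standard errors of `beta = (Z'Z)^{-1} Z' f(A'm)` at the
#' fitted expected frequencies, based on the constrained asymptotic
#' covariance of `m`-hat (Aitchison-Silvey/Lang theory).
#'
#' @param fit a converged [cmm_fit()] result for a model carrying `Z`.
#' @return numeric vector of standard errors; for the equality-of-means
#'   model the SE of the overall mean item score is attached as attribute
#'   `"mean_score_se"`.
#' @export
beta_se <- function(fit) {
  stopifnot(inherits(fit, "cmm_fit"))
  if (is.null(fit$model$Z))
    stop("model has no design matrix Z; beta is not defined", call. = FALSE)
  if (!fit$converged)
    stop("fit did not converge; standard errors unavailable", call. = FALSE)
  At <- margin_matrix(fit$model, fit$support)
  tryCatch(beta_se_compute(fit$model, At, fit$m_hat, fit$N),
           error = function(e)
             stop(cmm_error("cmm_second_order_error",
                            paste0("singular constraint covariance at the ",
                                   "fit; standard errors unavailable"))))
}
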