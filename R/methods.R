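#' @export
print.cmm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("CMM fit (%s): model \"%s\", %d support cells, N = %g\n",
              x$method, x$model$name, length(x$m_hat), x$N))
  if (!x$converged)
    cat("  ** did not converge (", x$iterations, " iterations, max |g| = ",
        format(x$max_g, digits = 3), ") **\n", sep = "")
  g2 <- if (is.finite(x$G2)) format(round(x$G2, digits))
        else sprintf("Inf (truncated %.2f)", x$G2_truncated)
  cat(sprintf("  G2 = %s, X2 = %s, df = %d, p = %s\n",
              g2, format(round(x$X2, digits)), x$df,
              format.pval(x$p_value, digits = digits)))
  if (!is.null(x$beta)) {
    cat("  beta =", paste(format(round(x$beta, digits)), collapse = ", "))
    if (!is.null(x$beta_se))
      cat("  (SE ", paste(format(round(x$beta_se, digits)), collapse = ", "),
          ")", sep = "")
    cat("\n")
    if (!is.null(x$mean_score))
      cat("  overall mean item score =", format(round(x$mean_score, digits)),
          "\n")
  }
  if (length(x$boundary_cells))
    cat("  boundary cells:",
        paste(pattern_to_string(
          x$support$patterns[x$boundary_cells, , drop = FALSE],
          x$support$cats), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.cmm_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.cmm_fit")
}

#' @export
print.summary.cmm_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nIterations:", f$iterations,
      " converged:", f$converged,
      " max |g|:", format(f$max_g, digits = 3), "\n")
  cat("Lagrange multipliers:",
      paste(format(round(f$lambda, digits)), collapse = ", "), "\n")
  df <- as.data.frame(f$support)
  df$observed <- f$n
  df$fitted <- round(f$m_hat, digits)
  df$augmented <- NULL
  cat("\nFitted expected frequencies:\n")
  print(utils::head(df[, c("pattern", "observed", "fitted")], 25L),
        row.names = FALSE)
  if (nrow(df) > 25L) cat("  ...", nrow(df) - 25L, "more cells\n")
  invisible(x)
}

#' @export
coef.cmm_fit <- function(object, ...) {
  ev <- evaluate_constraints(object$model, object$support, object$m_hat,
                             object$N)
  fv <- ev$f
  names(fv) <- switch(object$model$type,
                      alpha = "alpha",
                      hj = paste0("H", seq_along(fv)),
                      mean = paste0("f", seq_along(fv)),
                      NULL)
  fv
}

#' @export
fitted.cmm_fit <- function(object, ...) {
  stats::setNames(object$m_hat,
                  pattern_to_string(object$support$patterns,
                                    object$support$cats))
}

#' @export
residuals.cmm_fit <- function(object, type = c("pearson", "raw"), ...) {
  type <- match.arg(type)
  r <- object$n - object$m_hat
  if (type == "pearson")
    r <- r / sqrt(pmax(object$m_hat, object$control$floor_frac * object$N))
  stats::setNames(r, names(fitted(object)))
}

#' @export
logLik.cmm_fit <- function(object, ...) {
  pos <- object$n > 0
  ll <- sum(object$n[pos] * log(object$m_hat[pos] / object$N)) +
    lgamma(object$N + 1) - sum(lgamma(object$n[pos] + 1))
  structure(ll, df = length(object$m_hat) - 1L - object$df,
            nobs = object$N, class = "logLik")
}

#' Simulate tables from a fitted model
#'
#' Draws multinomial samples of size `N` from the fitted probabilities
#' `m_hat / N` over the fit's support.
#'
#' @param object a [cmm_fit()] result.
#' @param nsim number of tables.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of [sparse_table()] objects (length `nsim`).
#' @export
simulate.cmm_fit <- function(object, nsim = 1, seed = NULL, ...) {
  pi <- object$m_hat / sum(object$m_hat)
  with_seed(seed, lapply(seq_len(nsim), function(i) {
    cnt <- as.numeric(stats::rmultinom(1, object$N, pi))
    keep <- cnt > 0
    sparse_table(object$support$patterns[keep, , drop = FALSE],
                 counts = cnt[keep], cats = object$support$cats)
  }))
}

#' @export
plot.cmm_fit <- function(x, ...) {
  graphics::plot(sqrt(x$m_hat), sqrt(x$n),
                 xlab = expression(sqrt(fitted)),
                 ylab = expression(sqrt(observed)),
                 main = sprintf("%s fit: G2 = %s, df = %d", x$method,
                                format(round(x$G2, 3)), x$df), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}
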