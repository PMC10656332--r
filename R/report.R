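#' Write and read machine-readable fit reports
#'
#' Serializes a [cmm_fit()] result to JSON: model descriptor, method,
#' support sizes (observed cells `L_star` and total support `L_dagger`),
#' fitted expected frequencies as a pattern-to-value map, multipliers, fit
#' statistics, parameter estimates, convergence diagnostics and seed.
#' Infinite `G2` is encoded as the string `"Inf"`.
#'
#' @param fit a `cmm_fit`.
#' @param file output path.
#' @return invisibly, `file`.
#' @export
write_fit_report <- function(fit, file) {
  stopifnot(inherits(fit, "cmm_fit"))
  m <- fit$model
  pat <- pattern_to_string(fit$support$patterns, fit$support$cats)
  report <- list(
    model = list(name = m$name, link = m$link, J = m$J,
                 cats = as.integer(m$cats),
                 D = m$D, criterion = m$criterion),
    method = fit$method,
    N = fit$N,
    L_star = sum(fit$n > 0),
    L_dagger = length(fit$m_hat),
    m_hat = stats::setNames(as.list(fit$m_hat), pat),
    observed = stats::setNames(as.list(fit$n), pat),
    lambda = fit$lambda,
    G2 = if (is.finite(fit$G2)) fit$G2 else "Inf",
    G2_truncated = fit$G2_truncated,
    X2 = fit$X2, df = fit$df, p_value = fit$p_value,
    beta = fit$beta, beta_se = as.numeric(fit$beta_se),
    mean_score = fit$mean_score,
    iterations = fit$iterations, converged = fit$converged,
    boundary_cells = as.list(pat[fit$boundary_cells]),
    seed = fit$seed)
  jsonlite::write_json(report, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(file)
}

#' @rdname write_fit_report
#' @export
read_fit_report <- function(file) {
  rep <- jsonlite::read_json(file, simplifyVector = TRUE)
  if (identical(rep$G2, "Inf")) rep$G2 <- Inf
  rep
}
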