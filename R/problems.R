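#' Detect the first-order (empty-set) estimation problem
#'
#' The first-order estimation problem occurs when the constraint set
#' `{m >= 0, sum m = N, g(m) = 0}` has no solution on the given support, so
#' the (augmented) empirical likelihood cannot be maximized at all.  For
#' linear (identity-link) models this is decided exactly by linear
#' programming; for nonlinear links the check is heuristic: constraints whose
#' Jacobian vanishes identically on the support while `g` stays away from
#' zero are certainly infeasible, and otherwise a penalized feasibility
#' search from several random starts is used, so the status may come back
#' `"undetermined"`.
#'
#' @param model a [cmm_model()].
#' @param table a [sparse_table()] whose support is examined.
#' @param N total count (defaults to `table$N`).
#' @param control a [cmm_control()]; `restarts` sets the number of random
#'   starts for the nonlinear heuristic.
#' @return `"absent"`, `"present"` or `"undetermined"`.
#' @examples
#' shift <- cmm_model(
#'   margins = list(list(vars = 1, values = 0), list(vars = 2, values = 1)),
#'   J = 2, B_t = matrix(c(0, 0, 1, -1), 2, 2)[2, , drop = FALSE])
#' @export
detect_first_order_problem <- function(model, table, N = NULL,
                                       control = cmm_control()) {
  stopifnot(inherits(model, "cmm_model"), inherits(table, "sparse_table"))
  model <- hj_resolve_order(model, table)
  if (is.null(N)) N <- table$N
  At <- margin_matrix(model, table)
  S <- ncol(At)

  if (isTRUE(model$linear)) {
    ## g(m) = G m - criterion with constant G
    G <- (model$B_t %*% model$f_jac(numeric(nrow(At)), N)) %*% At
    A3 <- rbind(G, rep(1, S))
    b3 <- c(model$criterion, N)
    ## identically-zero constraint rows: trivially satisfied or infeasible
    zr <- apply(abs(A3), 1L, max) < 1e-12
    if (any(zr & abs(b3) > 1e-9)) return("present")
    A3 <- A3[!zr, , drop = FALSE]; b3 <- b3[!zr]
    ## drop linearly dependent rows (after checking they are consistent)
    if (nrow(A3) > 1L) {
      if (qr(cbind(A3, b3))$rank > qr(A3)$rank) return("present")
      qa <- qr(t(A3))
      keep <- sort(qa$pivot[seq_len(qa$rank)])
      A3 <- A3[keep, , drop = FALSE]; b3 <- b3[keep]
    }
    neg <- b3 < 0
    A3[neg, ] <- -A3[neg, , drop = FALSE]
    b3[neg] <- -b3[neg]
    ## redundant bound row guards boot::simplex against single-row input
    sol <- tryCatch(boot::simplex(a = numeric(S),
                                  A1 = matrix(1, 1, S), b1 = 2 * N,
                                  A3 = A3, b3 = b3,
                                  n.iter = 50 * (S + nrow(A3))),
                    error = function(e) NULL)
    if (is.null(sol)) return("undetermined")
    return(if (sol$solved == -1) "present" else if (sol$solved == 1)
      "absent" else "undetermined")
  }

  ## nonlinear links ----------------------------------------------------
  eval_g <- function(m) constraints_eval(model, At, m, N)
  ## short-circuit: identically-flat constraints that are off target
  probe <- replicate(3, {
    m <- stats::runif(S); m <- N * m / sum(m)
    ev <- tryCatch(eval_g(m), error = function(e) NULL)
    if (is.null(ev)) NULL else ev
  }, simplify = FALSE)
  probe <- Filter(Negate(is.null), probe)
  if (length(probe) >= 2) {
    flat_off <- vapply(seq_len(model$D), function(k) {
      all(vapply(probe, function(ev)
        max(abs(ev$G[k, ])) < 1e-10 && abs(ev$g[k]) > 1e-4, logical(1)))
    }, logical(1))
    if (any(flat_off)) return("present")
  }

  ## penalized feasibility search over N * softmax(z)
  obj <- function(z) {
    m <- exp(z - max(z)); m <- N * m / sum(m)
    ev <- tryCatch(eval_g(m), error = function(e) NULL)
    if (is.null(ev)) return(1e6)
    sum(ev$g^2)
  }
  best <- Inf
  for (r in seq_len(max(1L, control$restarts))) {
    z0 <- stats::rnorm(S, sd = if (r == 1) 0 else 1)
    opt <- tryCatch(stats::optim(z0, obj, method = "BFGS",
                                 control = list(maxit = 400)),
                    error = function(e) NULL)
    if (!is.null(opt)) best <- min(best, opt$value)
    if (best < 1e-12) break
  }
  if (!is.finite(best)) return("undetermined")
  if (sqrt(best) < 1e-5) "absent"
  else if (sqrt(best) > 1e-3) "present"
  else "undetermined"
}

#' Detect the second-order estimation problem
#'
#' The second-order estimation problem occurs when the support is too small
#' to estimate the covariance matrix of the constraint statistics: the
#' multinomial covariance of `g(n)`,
#' `V = G (D_m - m m'/N) G'` with `G` the constraint Jacobian restricted to
#' the support, is rank-deficient.  `V` is evaluated at the uniform
#' distribution over the support (`m_i = N / |support|`); rank deficiency is
#' declared when the smallest eigenvalue falls below `tol` times the
#' largest.
#'
#' A first-order problem implies a second-order problem; absence of the
#' second-order problem implies the first-order problem is absent too.
#'
#' @param model a [cmm_model()].
#' @param table a [sparse_table()].
#' @param tol relative eigenvalue tolerance (default `1e-10`).
#' @return `"present"` or `"absent"`.
#' @export
detect_second_order_problem <- function(model, table, tol = 1e-10) {
  stopifnot(inherits(model, "cmm_model"), inherits(table, "sparse_table"))
  model <- hj_resolve_order(model, table)
  N <- table$N
  At <- margin_matrix(model, table)
  S <- ncol(At)
  m <- rep(N / S, S)
  ev <- tryCatch(constraints_eval(model, At, m, N),
                 error = function(e) NULL)
  if (is.null(ev)) return("present")   # link degenerate at the uniform point
  Gm <- as.numeric(ev$G %*% m)
  V <- ev$G %*% (m * t(ev$G)) - tcrossprod(Gm) / N
  lam <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (max(lam) <= 0) return("present")
  if (min(lam) / max(lam) < tol) "present" else "absent"
}

#' Augment an empirical-likelihood support
#'
#' Chooses zero-observed-count cells to add to a sparse table's support so
#' that MAEL estimation avoids the first- and second-order estimation
#' problems.  At level `"first"`, every cell of every marginal distribution
#' the model constrains (all score combinations over each margin's variable
#' subset, not only the cells appearing in the constraint) that has no
#' contributing support cell receives one uniformly random full pattern
#' consistent with it.  At level `"second"`, the bivariate distributions of
#' all pairs of constrained variables (the covariance margins) are covered
#' the same way, and additional random zero cells are then drawn until the
#' constraint-covariance rank test ([detect_second_order_problem()]) passes,
#' up to a cap of `50 * D + 100` added cells (configurable via
#' [cmm_control()]).  The plan is deterministic given `seed`.
#'
#' @param table a [sparse_table()] of observed cells.
#' @param model a [cmm_model()].
#' @param seed integer seed for the random draws.
#' @param level `"first"` or `"second"`.
#' @param extra that many further random zero cells appended at the end.
#' @param control a [cmm_control()].
#' @return an object of class `cmm_augmentation`: list with `added` (pattern
#'   matrix, possibly 0 rows), `level`, `seed` and `coverage_report` (one
#'   row per added cell: which margin cell requested it).
#' @export
augment_support <- function(table, model, seed = NULL,
                            level = c("second", "first"), extra = 0L,
                            control = cmm_control()) {
  level <- match.arg(level)
  stopifnot(inherits(table, "sparse_table"), inherits(model, "cmm_model"))
  model <- hj_resolve_order(model, table)
  cats <- table$cats
  J <- table$J
  L <- prod(cats)
  cap <- if (is.null(control$augment_cap)) 50L * model$D + 100L
         else control$augment_cap

  keys <- pattern_to_string(table$patterns, cats)
  added <- matrix(0L, 0L, J)
  reason <- character(0)

  room_left <- function() nrow(table$patterns) + nrow(added) < L
  random_cell <- function(fix_vars = integer(0), fix_vals = integer(0)) {
    for (try in seq_len(1000L)) {
      p <- vapply(seq_len(J), function(j) sample.int(cats[j], 1L) - 1L,
                  integer(1))
      p[fix_vars] <- fix_vals
      key <- pattern_to_string(p, cats)
      if (!(key %in% keys)) return(p)
    }
    NULL
  }
  add_cell <- function(p, why) {
    added <<- rbind(added, p)
    keys <<- c(keys, pattern_to_string(p, cats))
    reason <<- c(reason, why)
  }

  cover_distribution <- function(vars, why) {
    combos <- expand.grid(lapply(cats[vars], function(cj) 0:(cj - 1L)),
                          KEEP.OUT.ATTRS = FALSE)
    for (r in seq_len(nrow(combos))) {
      vals <- as.integer(combos[r, ])
      covered <- any(margin_mask(table$patterns, vars, vals)) ||
        (nrow(added) > 0 && any(margin_mask(added, vars, vals)))
      if (!covered && room_left() && nrow(added) < cap) {
        p <- random_cell(vars, vals)
        if (!is.null(p))
          add_cell(p, sprintf("%s (%s)", why,
                              paste0(vars, "=", vals, collapse = ",")))
      }
    }
  }

  ## distinct variable subsets the model's margins live on
  subsets <- unique(lapply(model$margins, `[[`, "vars"))

  with_seed(seed, {
    ## level "first": cover every cell of every constrained marginal
    ## distribution (including the complement cells the reduced binary
    ## margin sets leave implicit)
    for (vars in subsets) cover_distribution(vars, "margin cell")

    ## level "second": cover the covariance margins -- the joint bivariate
    ## distributions of all pairs of constrained variables (the covariance
    ## of two observed margins is a function of their joint margin) -- then
    ## add random cells until the covariance rank test passes
    if (level == "second") {
      cvars <- sort(unique(unlist(subsets)))
      if (length(cvars) > 1L) {
        for (i in seq_len(length(cvars) - 1L))
          for (k in seq.int(i + 1L, length(cvars)))
            cover_distribution(c(cvars[i], cvars[k]), "covariance margin")
      }
      batch <- max(1L, ceiling(model$D / 10))
      repeat {
        aug <- apply_augmentation(table, list(added = added))
        if (detect_second_order_problem(model, aug) == "absent") break
        if (nrow(added) >= cap || !room_left()) {
          stop(cmm_error("cmm_augmentation_error",
                         paste0("support augmentation cap reached (",
                                cap, " cells) with the constraint ",
                                "covariance still rank-deficient"),
                         coverage_report = reason))
        }
        for (b in seq_len(batch)) {
          if (!room_left()) break
          p <- random_cell()
          if (is.null(p)) break
          add_cell(p, "covariance rank")
        }
      }
    }

    ## extras
    for (e in seq_len(extra)) {
      if (!room_left()) break
      p <- random_cell()
      if (!is.null(p)) add_cell(p, "extra")
    }
  })

  rownames(added) <- NULL
  structure(list(added = added, level = level, seed = seed,
                 coverage_report = if (nrow(added) > 0)
                   data.frame(pattern = pattern_to_string(added, cats),
                              reason = reason, stringsAsFactors = FALSE)
                 else data.frame(pattern = character(0),
                                 reason = character(0))),
            class = "cmm_augmentation")
}

#' @export
print.cmm_augmentation <- function(x, ...) {
  cat(sprintf("Support augmentation plan (level %s): %d cell%s added\n",
              x$level, nrow(x$added), if (nrow(x$added) == 1L) "" else "s"))
  if (nrow(x$added) > 0) print(utils::head(x$coverage_report, 10L))
  invisible(x)
}
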