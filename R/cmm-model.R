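#' Categorical marginal model specification
#'
#' A categorical marginal model (CMM) constrains marginal functions of the
#' expected-frequency vector `m` of a multinomial contingency table:
#' `g(m) = B' f(A'm) - c = 0`, where `A'm` picks marginal cells out of the
#' table, `f` is a smooth link with analytic Jacobian, `B'` is a full-row-rank
#' constraint matrix and `c` a criterion vector.  The joint dependence of the
#' variables is left unmodelled; the only distributional assumption is
#' multinomial sampling of the cell counts.
#'
#' `cmm_model()` builds a custom model from its parts; [mean_model()],
#' [alpha_model()] and [hj_model()] build the model families used for
#' equality-of-means / marginal-homogeneity testing, Cronbach's alpha
#' benchmark testing and Mokken scalability-coefficient testing.
#'
#' @param margins list of marginal cells, each a `list(vars = , values = )`
#'   with 1-based variable indices and fixed scores (the rows of `A'`).
#' @param J number of variables.
#' @param cats per-variable category counts (scalar recycled).
#' @param B_t constraint matrix `B'` (`D x K` where `K = length(f(u))`),
#'   full row rank.
#' @param criterion numeric vector of length `D` subtracted inside the
#'   constraint, so `g(m) = B' f(A'm) - criterion`.
#' @param f_fun,f_jac for custom links: `f_fun(u, N)` returns the length-`K`
#'   link value at margin vector `u`; `f_jac(u, N)` its `K x M` Jacobian.
#'   Defaults to the identity.
#' @param Z optional design matrix (orthogonal complement of `B`, full column
#'   rank) used to recover the model parameter `beta = (Z'Z)^{-1} Z' f(A'm)`.
#' @param name model label.
#' @return an object of class `cmm_model` with components `name`, `type`,
#'   `J`, `cats`, `margins`, `B_t`, `Z`, `criterion`, `D` and link functions.
#' @examples
#' ## marginal homogeneity of two binary items, written by hand
#' mh <- cmm_model(
#'   margins = list(list(vars = 1, values = 1), list(vars = 2, values = 1)),
#'   J = 2, B_t = matrix(c(1, -1), 1, 2))
#' mh
#' @export
cmm_model <- function(margins, J, cats = 2, B_t, criterion = NULL,
                      f_fun = NULL, f_jac = NULL, Z = NULL,
                      name = "custom") {
  cats <- check_cats(cats, J)
  margins <- lapply(margins, function(sp) {
    vars <- as.integer(sp$vars); vals <- as.integer(sp$values)
    if (length(vars) != length(vals) || anyDuplicated(vars) ||
        any(vars < 1L) || any(vars > J))
      stop("invalid marginal cell specification", call. = FALSE)
    if (any(vals < 0L) || any(vals >= cats[vars]))
      stop("marginal-cell score out of range", call. = FALSE)
    o <- order(vars)
    list(vars = vars[o], values = vals[o])
  })
  B_t <- as.matrix(B_t)
  D <- nrow(B_t)
  if (D > 0 && qr(B_t)$rank < D)
    stop("B_t must have full row rank", call. = FALSE)
  if (is.null(criterion)) criterion <- numeric(D)
  if (length(criterion) != D)
    stop("criterion must have one entry per constraint", call. = FALSE)
  linear <- is.null(f_fun)
  if (is.null(f_fun)) {
    if (ncol(B_t) != length(margins))
      stop("identity link: B_t needs one column per marginal cell",
           call. = FALSE)
    f_fun <- function(u, N) u
    f_jac <- function(u, N) diag(length(u))
  }
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (qr(Z)$rank < ncol(Z)) stop("Z must have full column rank", call. = FALSE)
    if (D > 0 && max(abs(B_t %*% Z)) > 1e-8)
      stop("Z must satisfy B'Z = 0", call. = FALSE)
  }
  structure(
    list(name = name, type = "custom", J = J, cats = cats, margins = margins,
         B_t = B_t, Z = Z, criterion = criterion, D = D, linear = linear,
         f_fun = f_fun, f_jac = f_jac,
         link = if (linear) "identity" else "custom", link_data = NULL),
    class = "cmm_model")
}

#' @export
print.cmm_model <- function(x, ...) {
  cat(sprintf("CMM \"%s\": %d constraint%s (link: %s) on %d marginal cells, J = %d\n",
              x$name, x$D, if (x$D == 1L) "" else "s", x$link,
              length(x$margins), x$J))
  if (!is.null(x$criterion) && any(x$criterion != 0))
    cat("  criterion:", paste(format(x$criterion), collapse = ", "), "\n")
  invisible(x)
}

uni_margins <- function(J, cats) {
  out <- list()
  for (j in seq_len(J))
    for (x in seq_len(cats[j] - 1L))
      out[[length(out) + 1L]] <- list(vars = j, values = x)
  out
}

#' Equality-of-means (marginal homogeneity) model
#'
#' The "Mean" model constrains the `J` item means to be equal,
#' `E(X_1) = ... = E(X_J)`, via the successive-difference constraint matrix
#' on the mean numerators `sum_x x * m^j_x`; for binary items these are just
#' the univariate margins `m^j_1` and the model is marginal homogeneity of
#' the item margins.  The model has `J - 1` degrees of freedom, and carries
#' the normalized constant design column `Z = 1/sqrt(J)` so that the scalar
#' parameter `beta = sum_j f_j / sqrt(J)` (the common mean numerator scaled
#' by `sqrt(J)`) is recoverable; the overall mean item score
#' `sum_j f_j / (J N)` is reported alongside.
#'
#' @param J number of items (>= 2).
#' @param cats per-item category counts (scalar recycled; default binary).
#' @return a `cmm_model`.
#' @examples
#' mean_model(3)
#' @export
mean_model <- function(J, cats = 2) {
  if (J < 2) stop("the equality-of-means model needs J >= 2 items", call. = FALSE)
  cats <- check_cats(cats, J)
  margins <- uni_margins(J, cats)
  M <- length(margins)
  ## W maps margin cells to the J mean numerators sum_x x m^j_x
  W <- matrix(0, J, M)
  for (i in seq_len(M))
    W[margins[[i]]$vars, i] <- margins[[i]]$values
  B_t <- -diff(diag(J))         # successive differences m_j - m_{j+1}, (J-1) x J
  m <- structure(
    list(name = "Mean", type = "mean", J = J, cats = cats, margins = margins,
         B_t = B_t, Z = matrix(1 / sqrt(J), J, 1), criterion = numeric(J - 1),
         D = J - 1L, linear = TRUE,
         f_fun = NULL, f_jac = NULL, link = "mean", link_data = list(W = W)),
    class = "cmm_model")
  m$f_fun <- function(u, N) as.numeric(W %*% u)
  m$f_jac <- function(u, N) W
  m
}

#' Cronbach's alpha benchmark model
#'
#' Constrains coefficient alpha, computed from the first- and second-order
#' marginal moments of the items, to equal a benchmark value:
#' `alpha(m) - criterion = 0`, a CMM with one degree of freedom.  Covariances
#' use divisor `N` (the maximum-likelihood convention of the multinomial
#' framework), not `N - 1`.
#'
#' For binary items the margin set is reduced to the cells `{j = 1}` and
#' `{j = 1, k = 1}`; complements are recovered as `m^j_0 = N - m^j_1`, which
#' halves the margin rows without changing any value.
#'
#' @param J number of items (>= 2).
#' @param criterion benchmark value in (0, 1).
#' @param cats per-item category counts.
#' @return a `cmm_model`.
#' @seealso [alpha_from_margins()], [cmm_alpha()]
#' @export
alpha_model <- function(J, criterion = 0.8, cats = 2) {
  if (J < 2) stop("alpha needs J >= 2 items", call. = FALSE)
  if (criterion <= 0 || criterion >= 1)
    stop("alpha criterion must lie in (0, 1)", call. = FALSE)
  cats <- check_cats(cats, J)
  margins <- uni_margins(J, cats)
  uni <- do.call(rbind, lapply(seq_along(margins), function(i)
    c(i, margins[[i]]$vars, margins[[i]]$values)))
  biv <- NULL
  for (j in seq_len(J - 1L)) for (k in seq.int(j + 1L, J))
    for (x in seq_len(cats[j] - 1L)) for (y in seq_len(cats[k] - 1L)) {
      margins[[length(margins) + 1L]] <- list(vars = c(j, k), values = c(x, y))
      biv <- rbind(biv, c(length(margins), j, k, x, y))
    }
  link_data <- list(J = J, uni = uni, biv = biv)
  m <- structure(
    list(name = "Alpha", type = "alpha", J = J, cats = cats, margins = margins,
         B_t = matrix(1, 1, 1), Z = NULL, criterion = criterion, D = 1L,
         linear = FALSE,
         f_fun = NULL, f_jac = NULL, link = "alpha", link_data = link_data),
    class = "cmm_model")
  m$f_fun <- function(u, N) alpha_from_margins(u, J, cats, N, link_data)
  m$f_jac <- function(u, N) alpha_jacobian(u, J, cats, N, link_data)
  m
}

alpha_moments <- function(u, J, N, ld) {
  mu <- q <- numeric(J)
  for (r in seq_len(nrow(ld$uni))) {
    j <- ld$uni[r, 2L]; x <- ld$uni[r, 3L]
    mu[j] <- mu[j] + x * u[ld$uni[r, 1L]] / N
    q[j] <- q[j] + x^2 * u[ld$uni[r, 1L]] / N
  }
  cc <- matrix(0, J, J)
  for (r in seq_len(nrow(ld$biv))) {
    j <- ld$biv[r, 2L]; k <- ld$biv[r, 3L]
    cc[j, k] <- cc[j, k] + ld$biv[r, 4L] * ld$biv[r, 5L] * u[ld$biv[r, 1L]] / N
  }
  sjj <- q - mu^2
  S1 <- sum(sjj)
  S2 <- S1
  for (j in seq_len(J - 1L)) for (k in seq.int(j + 1L, J))
    S2 <- S2 + 2 * (cc[j, k] - mu[j] * mu[k])
  list(mu = mu, S1 = S1, S2 = S2)
}

#' Coefficient alpha from marginal cell values
#'
#' Computes item means, variances and covariances from univariate and
#' bivariate marginal frequencies (divisor `N`) and returns
#' `alpha = (J/(J-1)) (1 - sum_j sigma_jj / sum_jk sigma_jk)`.
#'
#' @param u numeric vector of marginal cell values, ordered as in the margin
#'   list of [alpha_model()] (all univariate cells, then all bivariate cells).
#' @param J,cats,N test length, category counts, total count.
#' @param link_data internal margin bookkeeping; supplied automatically when
#'   called through a model.
#' @return coefficient alpha (scalar).
#' @examples
#' cmm_alpha(example_tables()$three_items)   # 0.3675...
#' @export
alpha_from_margins <- function(u, J, cats = 2, N, link_data = NULL) {
  cats <- check_cats(cats, J)
  if (is.null(link_data)) link_data <- alpha_model(J, 0.5, cats)$link_data
  mo <- alpha_moments(u, J, N, link_data)
  if (mo$S2 <= 0)
    stop("degenerate total-score variance: sum of item covariances <= 0",
         call. = FALSE)
  (J / (J - 1)) * (1 - mo$S1 / mo$S2)
}

alpha_jacobian <- function(u, J, cats, N, ld) {
  mo <- alpha_moments(u, J, N, ld)
  if (mo$S2 <= 0)
    stop("degenerate total-score variance in alpha Jacobian", call. = FALSE)
  dS1 <- dS2 <- numeric(length(u))
  mu <- mo$mu
  for (r in seq_len(nrow(ld$uni))) {
    i <- ld$uni[r, 1L]; j <- ld$uni[r, 2L]; x <- ld$uni[r, 3L]
    dS1[i] <- x^2 / N - 2 * mu[j] * x / N
    dS2[i] <- dS1[i] - 2 * (x / N) * (sum(mu) - mu[j])
  }
  for (r in seq_len(nrow(ld$biv))) {
    i <- ld$biv[r, 1L]
    dS2[i] <- 2 * ld$biv[r, 4L] * ld$biv[r, 5L] / N
  }
  R <- J / (J - 1)
  matrix(R * (mo$S1 * dS2 - dS1 * mo$S2) / mo$S2^2, nrow = 1L)
}

#' Mokken item-scalability (H_j) model
#'
#' Constrains every item-scalability coefficient `H_j` of a set of
#' dichotomous items to a researcher-specified lower bound:
#' `H_j(m) - criterion = 0` for `j = 1..J`, a CMM with `J` degrees of
#' freedom.  `H_j` is 1 minus the ratio of observed to
#' expected-under-independence Guttman errors for the item pairs involving
#' item `j`; the Guttman-error cell for an ordered pair `(i, j)` (item `i`
#' before item `j`) is `{i = 0, j = 1}`.
#'
#' By default items are taken in the order given, which reproduces sample
#' values computed by applying the defining formula to the items as listed;
#' `item_order = "popularity"` instead re-sorts items in ascending order of
#' sample popularity (the textbook convention), and an integer permutation
#' gives explicit control.
#'
#' @param J number of dichotomous items (>= 2).
#' @param criterion lower-bound value in (0, 1).
#' @param item_order `NULL` (given order), `"popularity"`, or an integer
#'   permutation of `1:J` listing items from least to most popular.
#' @param cats must be all 2; polytomous items are not supported.
#' @return a `cmm_model`.  For `J = 2` the two constraints are algebraically
#'   identical; the duplicate is detected and collapsed to `D = 1` with a
#'   warning.
#' @seealso [hj_from_margins()], [cmm_hj()]
#' @export
hj_model <- function(J, criterion = 0.3, item_order = NULL, cats = 2) {
  if (J < 2) stop("H_j needs J >= 2 items", call. = FALSE)
  cats <- check_cats(cats, J)
  if (any(cats != 2L))
    stop("the H_j model supports dichotomous items only", call. = FALSE)
  if (criterion <= 0 || criterion >= 1)
    stop("H_j criterion must lie in (0, 1)", call. = FALSE)
  order_spec <- item_order
  if (is.numeric(item_order) &&
      !identical(sort(as.integer(item_order)), seq_len(J)))
    stop("item_order must be a permutation of 1:J", call. = FALSE)

  margins <- uni_margins(J, cats)               # {j = 1}, j = 1..J
  pair_rows <- NULL                              # filled once order is known
  link_data <- list(J = J, order_spec = order_spec)

  D <- if (J == 2L) 1L else J
  B_t <- if (J == 2L) matrix(c(1, 0), 1, 2) else diag(J)
  if (J == 2L)
    warning("J = 2: the two H constraints are identical; collapsed to D = 1",
            call. = FALSE)

  m <- structure(
    list(name = "Hj", type = "hj", J = J, cats = cats, margins = margins,
         B_t = B_t, Z = NULL, criterion = rep(criterion, D), D = D,
         linear = FALSE,
         f_fun = NULL, f_jac = NULL, link = "hj", link_data = link_data),
    class = "cmm_model")
  m <- hj_finalize_order(m, order = if (is.numeric(order_spec))
    as.integer(order_spec) else seq_len(J))
  m
}

## fixes the item order (permutation least -> most popular) and appends the
## Guttman-error margin cells {earlier = 0, later = 1} for ordered pairs
hj_finalize_order <- function(model, order) {
  J <- model$J
  margins <- uni_margins(J, model$cats)
  pair_idx <- matrix(0L, J, J)  # pair_idx[p, q]: margin index of E_{pq}, p < q positions
  for (p in seq_len(J - 1L)) for (q in seq.int(p + 1L, J)) {
    i <- order[p]; j <- order[q]
    margins[[length(margins) + 1L]] <-
      list(vars = sort(c(i, j)),
           values = if (i < j) c(0L, 1L) else c(1L, 0L))
    pair_idx[p, q] <- length(margins)
  }
  model$margins <- margins
  model$link_data$order <- order
  model$link_data$pair_idx <- pair_idx
  ld <- model$link_data
  model$f_fun <- function(u, N) hj_from_margins(u, J, N, link_data = ld)
  model$f_jac <- function(u, N) hj_jacobian(u, J, N, ld)
  model
}

hj_parts <- function(u, J, N, ld) {
  u1 <- u[seq_len(J)][ld$order]           # positive margins by position
  u0 <- N - u1
  num <- den <- numeric(J)
  for (p in seq_len(J)) {
    qs_before <- seq_len(p - 1L)
    qs_after <- if (p < J) seq.int(p + 1L, J) else integer(0)
    num[p] <- sum(u[ld$pair_idx[qs_before, p]]) + sum(u[ld$pair_idx[p, qs_after]])
    den[p] <- sum(u0[qs_before]) * u1[p] + u0[p] * sum(u1[qs_after])
  }
  list(u1 = u1, u0 = u0, num = num, den = den)
}

#' Item-scalability coefficients from marginal cell values
#'
#' Computes the vector of `H_j` coefficients from the positive univariate
#' margins `m^j_1` and the Guttman-error pair margins, via
#' `H_j = 1 - N * (observed errors) / (expected errors under independence)`.
#'
#' @param u margin vector ordered as in [hj_model()]: the `J` cells
#'   `{j = 1}` in item order, then the error cells for ordered pairs.
#' @param J,N number of items, total count.
#' @param item_order integer permutation (least to most popular); default the
#'   given order.
#' @param link_data internal bookkeeping, supplied automatically through a
#'   model.
#' @return numeric vector of length `J`, indexed by original item.
#' @examples
#' cmm_hj(example_tables()$three_items)  # 0.231, 0.164, 0.055
#' @export
hj_from_margins <- function(u, J, N, item_order = NULL, link_data = NULL) {
  if (is.null(link_data)) {
    order <- if (is.null(item_order)) seq_len(J) else as.integer(item_order)
    mdl <- suppressWarnings(hj_model(J, 0.5))
    link_data <- hj_finalize_order(mdl, order)$link_data
  }
  pp <- hj_parts(u, J, N, link_data)
  if (any(pp$den <= 0))
    stop("degenerate H_j margins: zero expected-error denominator",
         call. = FALSE)
  H <- 1 - N * pp$num / pp$den
  out <- numeric(J)
  out[link_data$order] <- H
  out
}

hj_jacobian <- function(u, J, N, ld) {
  pp <- hj_parts(u, J, N, ld)
  if (any(pp$den <= 0))
    stop("degenerate H_j margins in Jacobian", call. = FALSE)
  Jm <- matrix(0, J, length(u))    # rows indexed by position, remapped below
  for (p in seq_len(J)) {
    qs_before <- seq_len(p - 1L)
    qs_after <- if (p < J) seq.int(p + 1L, J) else integer(0)
    dden <- N * pp$num[p] / pp$den[p]^2
    ## error-cell derivatives
    for (q in qs_before) Jm[p, ld$pair_idx[q, p]] <- -N / pp$den[p]
    for (q in qs_after) Jm[p, ld$pair_idx[p, q]] <- -N / pp$den[p]
    ## positive-margin derivatives (u columns are in original item order)
    dd_dp <- sum(pp$u0[qs_before]) - sum(pp$u1[qs_after])
    Jm[p, ld$order[p]] <- Jm[p, ld$order[p]] + dden * dd_dp
    for (q in qs_before)
      Jm[p, ld$order[q]] <- Jm[p, ld$order[q]] + dden * (-pp$u1[p])
    for (q in qs_after)
      Jm[p, ld$order[q]] <- Jm[p, ld$order[q]] + dden * pp$u0[p]
  }
  ## remap rows from position to original item index
  out <- matrix(0, J, length(u))
  out[ld$order, ] <- Jm
  out
}

#' Convenience coefficients from a table
#'
#' `cmm_alpha()` and `cmm_hj()` compute coefficient alpha and the `H_j`
#' vector directly from a [sparse_table()] (or respondent score matrix),
#' using observed counts as the margin weights.
#'
#' @param x a `sparse_table` or integer score matrix.
#' @param item_order for `cmm_hj()`: as in [hj_model()].
#' @return `cmm_alpha()`: a scalar; `cmm_hj()`: a length-`J` vector.
#' @export
cmm_alpha <- function(x) {
  if (!inherits(x, "sparse_table")) x <- sparse_table(x)
  model <- alpha_model(x$J, 0.5, x$cats)
  u <- margin_values(model, x)
  alpha_from_margins(u, x$J, x$cats, x$N, model$link_data)
}

#' @rdname cmm_alpha
#' @export
cmm_hj <- function(x, item_order = NULL) {
  if (!inherits(x, "sparse_table")) x <- sparse_table(x)
  if (any(x$cats != 2L)) stop("H_j is defined for dichotomous items", call. = FALSE)
  model <- hj_resolve_order(suppressWarnings(hj_model(x$J, 0.5,
                                                      item_order = item_order)),
                            x)
  u <- margin_values(model, x)
  hj_from_margins(u, x$J, x$N, link_data = model$link_data)
}

## resolve "popularity" ordering against a data table
hj_resolve_order <- function(model, table) {
  spec <- model$link_data$order_spec
  if (identical(spec, "popularity")) {
    pop <- vapply(seq_len(model$J), function(j)
      margin_value(table, j, 1L), numeric(1))
    hj_finalize_order(model, order(pop))
  } else model
}

## M x S margin matrix (rows of A' restricted to the support columns)
margin_matrix <- function(model, table) {
  pat <- table$patterns
  S <- nrow(pat)
  At <- matrix(0, length(model$margins), S)
  for (i in seq_along(model$margins)) {
    sp <- model$margins[[i]]
    At[i, margin_mask(pat, sp$vars, sp$values)] <- 1
  }
  At
}

## all margin values A'm for a model at weights m (defaults to counts)
margin_values <- function(model, table, m = NULL) {
  if (is.null(m)) m <- table$counts
  as.numeric(margin_matrix(model, table) %*% m)
}

#' Evaluate model constraints and their Jacobian on a support
#'
#' Computes `g(m) = B' f(A'm) - criterion` and the Jacobian
#' `G = B' (df/du) A'` restricted to the support columns of `table`.
#'
#' @param model a `cmm_model`.
#' @param table a [sparse_table()] providing the support.
#' @param m weights over the support (defaults to the observed counts).
#' @param N total count (defaults to `table$N`).
#' @return list with `g` (length `D`), `G` (`D x S` Jacobian), `f` (link
#'   value) and `u` (margin values).
#' @examples
#' tab <- example_tables()$three_items
#' evaluate_constraints(mean_model(3), tab)$g   # (-10, 5)
#' @export
evaluate_constraints <- function(model, table, m = NULL, N = NULL) {
  stopifnot(inherits(model, "cmm_model"), inherits(table, "sparse_table"))
  if (table$J != model$J)
    stop("table and model disagree on the number of variables", call. = FALSE)
  model <- hj_resolve_order(model, table)
  if (is.null(m)) m <- table$counts
  if (is.null(N)) N <- table$N
  At <- margin_matrix(model, table)
  ev <- constraints_eval(model, At, m, N)
  ev
}

## internal: evaluation against a prebuilt margin matrix
constraints_eval <- function(model, At, m, N) {
  u <- as.numeric(At %*% m)
  fv <- model$f_fun(u, N)
  g <- as.numeric(model$B_t %*% fv) - model$criterion
  Jf <- model$f_jac(u, N)
  G <- (model$B_t %*% Jf) %*% At
  list(g = g, G = G, f = fv, u = u)
}

#' Model parameter from marginal functions
#'
#' Recovers `beta = (Z'Z)^{-1} Z' f(A'm)` for models that carry a design
#' matrix `Z`.  For the equality-of-means model the returned value also
#' carries the overall mean item score `sum_j f_j / (J N)` as attribute
#' `"mean_score"`.
#'
#' @param model a `cmm_model` with non-`NULL` `Z`.
#' @param table a [sparse_table()].
#' @param m weights over the support (defaults to observed counts).
#' @return numeric vector `beta`.
#' @export
beta_from_margins <- function(model, table, m = NULL) {
  if (is.null(model$Z))
    stop("model has no design matrix Z (constraint-only model); ",
         "beta is not defined", call. = FALSE)
  if (is.null(m)) m <- table$counts
  N <- table$N
  u <- margin_values(model, table, m)
  fv <- model$f_fun(u, N)
  Z <- model$Z
  beta <- as.numeric(solve(crossprod(Z), crossprod(Z, fv)))
  if (model$type == "mean")
    attr(beta, "mean_score") <- sum(fv) / (model$J * N)
  beta
}

#' Write and read model specifications as YAML
#'
#' Serializes the built-in model families (and identity-link custom models)
#' to a small YAML document: name, link, `J`, `cats`, criterion, item order,
#' and for custom models the dense `B_t` and margin cells.  Custom models
#' with user-supplied link functions cannot be serialized.
#'
#' @param model a `cmm_model`.
#' @param file path to write to / read from.
#' @return `read_model_yaml()` returns a `cmm_model`.
#' @export
write_model_yaml <- function(model, file) {
  doc <- list(name = model$name, link = model$link, J = model$J,
              cats = as.integer(model$cats))
  if (model$type == "alpha") doc$criterion <- model$criterion
  if (model$type == "hj") {
    doc$criterion <- model$criterion[1L]
    doc$item_order <- model$link_data$order
  }
  if (model$type == "custom") {
    doc$criterion <- model$criterion
    doc$B_t <- apply(model$B_t, 1L, as.numeric, simplify = FALSE)
    doc$margins <- lapply(model$margins, function(sp)
      list(vars = as.integer(sp$vars), values = as.integer(sp$values)))
  }
  yaml::write_yaml(doc, file)
  invisible(file)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(file) {
  doc <- yaml::read_yaml(file)
  switch(doc$link,
    mean = mean_model(doc$J, doc$cats),
    alpha = alpha_model(doc$J, doc$criterion, doc$cats),
    hj = suppressWarnings(
      hj_model(doc$J, doc$criterion,
               item_order = if (!is.null(doc$item_order))
                 as.integer(doc$item_order) else NULL,
               cats = doc$cats)),
    identity = ,
    custom = cmm_model(doc$margins, doc$J, doc$cats,
                       B_t = do.call(rbind, doc$B_t),
                       criterion = doc$criterion, name = doc$name),
    stop("unknown link in model file: ", doc$link, call. = FALSE))
}
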