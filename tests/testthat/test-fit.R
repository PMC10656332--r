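eq10_mhat <- c(20.000, 14.397, 8.060, 11.695, 0.000, 19.755, 26.092, 30.000)

test_that("ML fit of marginal homogeneity reproduces the worked solution", {
  tab <- example_tables()$three_items
  fit <- cmm_fit(mean_model(3), tab, method = "ML")
  expect_true(fit$converged)
  expect_equal(round(fit$m_hat, 3), eq10_mhat)
  expect_equal(fit$G2, 2.6107, tolerance = 1e-4)
  expect_equal(fit$df, 2L)
  expect_equal(fit$p_value, 0.2711, tolerance = 1e-3)
  expect_equal(sum(fit$m_hat), 130)
  expect_equal(as.numeric(fit$beta), 131.37, tolerance = 1e-3)
  expect_equal(fit$mean_score, 0.5834, tolerance = 1e-3)
})

test_that("MEL over the observed support matches the ML fit here", {
  tab <- example_tables()$three_items
  ml <- cmm_fit(mean_model(3), tab, method = "ML")
  mel <- cmm_fit(mean_model(3), tab, method = "MEL")
  expect_true(mel$converged)
  expect_equal(length(mel$m_hat), 7L)
  expect_equal(mel$G2, 2.611, tolerance = 1e-3)
  ## identical fitted values on the observed cells
  expect_equal(mel$m_hat, ml$m_hat[ml$n > 0], tolerance = 1e-6)
})

test_that("a table already satisfying the constraints is left untouched", {
  sat <- sparse_table(index_to_pattern(0:7, rep(2L, 3)),
                      counts = c(10, 5, 5, 10, 5, 10, 10, 5))
  expect_equal(evaluate_constraints(mean_model(3), sat)$g, c(0, 0))
  fit <- cmm_fit(mean_model(3), sat, method = "ML")
  expect_equal(fit$m_hat, sat$counts, tolerance = 1e-8)
  expect_equal(fit$G2, 0, tolerance = 1e-10)
  expect_equal(fit$p_value, 1)
})

test_that("the H-benchmark model fit agrees with an independent optimizer", {
  tab <- example_tables()$three_items
  fit <- cmm_fit(suppressWarnings(hj_model(3, 0.3)), tab, method = "ML")
  expect_true(fit$converged)
  expect_equal(fit$df, 3L)
  ## value confirmed by the augmented-Lagrangian oracle and by the printed
  ## upper-tail probability 0.0023 of the chi-square(3) reference
  expect_equal(fit$G2, 14.4882, tolerance = 1e-4)
  expect_equal(round(fit$p_value, 4), 0.0023)
  orc <- oracle_constrained_fit(suppressWarnings(hj_model(3, 0.3)), tab)
  expect_lt(orc$max_g, 1e-7)
  expect_equal(fit$G2, orc$G2, tolerance = 1e-3)
})

test_that("extreme two-cell data reproduce the degenerate-fit chain", {
  two <- example_tables()$two_cell
  ml <- cmm_fit(mean_model(3), two, method = "ML")
  expect_equal(ml$G2, 180.22, tolerance = 1e-3)
  expect_equal(round(ml$m_hat, 3), c(0, 32.5, 0, 32.5, 32.5, 0, 32.5, 0))

  ## five-cell augmented support: all bivariate margins contribute
  m5 <- cmm_fit(mean_model(3), two, method = "MAEL",
                augment_cells = c("000", "011", "101"))
  expect_equal(m5$G2, 232.92, tolerance = 1e-2)
  expect_equal(round(m5$m_hat, 3), c(0, 54.167, 32.5, 21.667, 21.667),
               tolerance = 1e-3)
  ## closed form: G2 = 130 (log 2 + log 3)
  expect_equal(m5$G2, 130 * (log(2) + log(3)), tolerance = 1e-4)

  ## single-cell augmentation leads to a boundary optimum with infinite G2
  m3 <- suppressWarnings(cmm_fit(mean_model(3), two, method = "MAEL",
                                 augment_cells = "011"))
  expect_identical(m3$G2, Inf)
  expect_true(length(m3$boundary_cells) >= 1L)
  expect_true(is.finite(m3$G2_truncated))
  ## fitted mass concentrates on the two feasible cells
  expect_equal(sort(m3$m_hat, decreasing = TRUE)[1:2], c(65, 65),
               tolerance = 1e-3)

  ## monotone support chain: the ML value is the best achievable
  expect_lte(ml$G2, m5$G2)
})

test_that("ML and MEL pipelines coincide exactly on dense tables", {
  for (s in 1:4) {
    rt <- random_dense_table(3, seed = 400 + s)
    ml <- cmm_fit(mean_model(3), rt, method = "ML")
    mel <- cmm_fit(mean_model(3), rt, method = "MEL")
    mael <- cmm_fit(mean_model(3), rt, method = "MAEL", seed = s)
    expect_identical(ml$m_hat, mel$m_hat)
    expect_identical(ml$G2, mel$G2)
    ## empty augmentation plan: MAEL is the same pipeline as MEL
    expect_equal(nrow(mael$augmentation$added), 0L)
    expect_identical(mael$m_hat, mel$m_hat)
  }
})

test_that("the solver matches the independent optimizer on random tables", {
  cases <- list()
  for (s in 1:4) {
    rt <- random_dense_table(3, seed = 500 + s)
    cases[[length(cases) + 1]] <- list(model = mean_model(3), tab = rt)
    a <- cmm_alpha(rt)
    if (a > 0.07 && a < 0.93)
      cases[[length(cases) + 1]] <-
        list(model = alpha_model(3, a - 0.05), tab = rt)
    h <- mean(cmm_hj(rt))
    if (h > 0.07 && h < 0.93)
      cases[[length(cases) + 1]] <-
        list(model = suppressWarnings(hj_model(3, h - 0.05)), tab = rt)
  }
  expect_gte(length(cases), 6)
  for (cs in cases) {
    fit <- cmm_fit(cs$model, cs$tab, method = "ML")
    orc <- oracle_constrained_fit(cs$model, cs$tab)
    expect_true(fit$converged)
    expect_lt(orc$max_g, 1e-6)
    expect_equal(fit$G2, orc$G2, tolerance = 1e-3)
  }
})

test_that("converged fits satisfy the constraints and the stationarity law", {
  tab <- example_tables()$three_items
  fits <- list(cmm_fit(mean_model(3), tab, method = "ML"),
               cmm_fit(alpha_model(3, 0.45), tab, method = "ML"),
               cmm_fit(suppressWarnings(hj_model(3, 0.25)), tab,
                       method = "MEL"))
  for (fit in fits) {
    expect_true(fit$converged)
    expect_equal(sum(fit$m_hat), fit$N, tolerance = 1e-6)
    ev <- evaluate_constraints(fit$model, fit$support, fit$m_hat, fit$N)
    expect_lt(max(abs(ev$g)), 1e-6)
    ## Lagrangian stationarity n_i/m_i - mu - (G' lambda)_i = 0 off the
    ## boundary, with mu = 1 the multiplier of the total-count constraint
    ## in the scoring parameterization
    Gt <- rbind(ev$G, 1)
    interior <- fit$m_hat > 1e-4 * fit$N
    resid <- fit$n[interior] / fit$m_hat[interior] - 1 -
      as.numeric(t(Gt) %*% fit$lambda)[interior]
    expect_lt(max(abs(resid)), 1e-5)
  }
})

test_that("goodness-of-fit handles boundary and exact-fit edges", {
  gof <- goodness_of_fit(c(5, 5), c(5, 5), df = 1)
  expect_equal(gof$G2, 0)
  expect_equal(gof$X2, 0)
  expect_equal(gof$p, 1)
  ## the five-cell degenerate fit in closed form
  gof5 <- goodness_of_fit(c(0, 0, 65, 0, 65),
                          c(0, 54.167, 32.5, 21.67, 21.67), df = 2)
  expect_equal(gof5$G2, 2 * 65 * (log(2) + log(3)), tolerance = 1e-3)
  expect_warning(bad <- goodness_of_fit(c(5, 5), c(10 - 1e-9, 1e-9), df = 1),
                 "infinite")
  expect_identical(bad$G2, Inf)
  expect_equal(bad$p, 0)
  expect_error(goodness_of_fit(c(-1, 2), c(1, 1), df = 1), "negative")
})

test_that("a reloaded fit report restarts the solver at its fixed point", {
  tab <- example_tables()$three_items
  fit <- cmm_fit(mean_model(3), tab, method = "ML")
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, f)
  rep <- read_fit_report(f)
  expect_equal(rep$G2, fit$G2, tolerance = 1e-10)
  expect_equal(rep$L_star, 7)
  expect_equal(rep$L_dagger, 8)
  refit <- cmm_fit(mean_model(3), tab, method = "ML",
                   start = unlist(rep$m_hat))
  expect_lte(refit$iterations, 2L)
  expect_equal(refit$G2, fit$G2, tolerance = 1e-6)
})

test_that("infinite-G2 reports encode and decode cleanly", {
  two <- example_tables()$two_cell
  m3 <- suppressWarnings(cmm_fit(mean_model(3), two, method = "MAEL",
                                 augment_cells = "011"))
  f <- withr::local_tempfile(fileext = ".json")
  write_fit_report(m3, f)
  rep <- read_fit_report(f)
  expect_identical(rep$G2, Inf)
  expect_true(is.finite(rep$G2_truncated))
  expect_true(length(rep$boundary_cells) >= 1)
})

test_that("standard errors: saturated closed form and Monte-Carlo agreement", {
  ## saturated single-margin model: SE of a binary margin is the
  ## multinomial closed form sqrt(m (N - m) / N)
  sat <- cmm_model(margins = list(list(vars = 1, values = 1)), J = 2,
                   B_t = matrix(0, 0, 1), Z = matrix(1, 1, 1),
                   name = "one-margin")
  rt <- random_dense_table(2, seed = 33)
  fit <- cmm_fit(sat, rt, method = "ML")
  m1 <- margin_value(rt, 1, 1)
  expect_equal(as.numeric(fit$beta_se), sqrt(m1 * (rt$N - m1) / rt$N),
               tolerance = 1e-6)

  ## delta-method SE vs the SD of the estimate over seeded replications
  set.seed(77)
  J <- 4; N <- 400
  pop_tab <- twopl_sample(1.5, c(-1, -0.3, 0.3, 1), 1000, seed = 5)
  pop <- build_population(mean_model(J), pop_tab, method = "ML", seed = 6)
  bh <- se_an <- numeric(300)
  for (r in 1:300) {
    tab <- sample_population(pop, N, seed = 1000 + r)
    f <- cmm_fit(mean_model(J), tab, method = "ML")
    bh[r] <- f$mean_score
    se_an[r] <- attr(f$beta_se, "mean_score_se")
  }
  expect_lt(abs(mean(se_an) - sd(bh)) / sd(bh), 0.15)
})
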