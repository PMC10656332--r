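eq9_matrix <- rbind(c(0, 0, -1, -1, 1, 1, 0, 0),
                    c(0, -1, 0, -1, 1, 0, 1, 0))

test_that("the equality-of-means model reproduces the dense constraint matrix", {
  tab <- example_tables()$three_items
  model <- mean_model(3)
  expect_equal(model$D, 2L)
  full <- cmmael:::full_support_table(tab)
  ev <- evaluate_constraints(model, full)
  ## the successive-difference rows span the same constraint space as the
  ## printed dense matrix (whose second row is the a-c difference), and the
  ## first rows coincide exactly
  expect_equal(unname(ev$G[1, ]), eq9_matrix[1, ])
  expect_equal(qr(rbind(ev$G, eq9_matrix))$rank, 2L)
  ## Jacobian of an identity-link model is constant in m
  ev2 <- evaluate_constraints(model, full, m = runif(8, 1, 10))
  expect_equal(ev2$G, ev$G)
  ## observed margins 70, 80, 75 give g = (-10, 5)
  expect_equal(evaluate_constraints(model, tab)$g, c(-10, 5))
  ## the fitted vector satisfies marginal homogeneity
  mhat <- c(20.000, 14.397, 8.060, 11.695, 0.000, 19.755, 26.092, 30.000)
  expect_lt(max(abs(cmmael:::constraints_eval(model,
    cmmael:::margin_matrix(model, full), mhat, 130)$g)), 1e-3)
  ## smallest case: one constraint
  expect_equal(mean_model(2)$D, 1L)
  expect_error(mean_model(1), "J >= 2")
})

test_that("model builders emit consistent B, Z and margin sets", {
  for (model in list(mean_model(3), mean_model(5, cats = 3))) {
    expect_equal(qr(model$B_t)$rank, model$D)
    expect_lt(max(abs(model$B_t %*% model$Z)), 1e-12)
    BZ <- cbind(t(model$B_t), model$Z)
    expect_equal(qr(BZ)$rank, ncol(BZ))          # (B Z) square nonsingular
  }
  am <- alpha_model(3, 0.8)
  expect_equal(am$D, 1L)
  ## reduced binary margin set: {j=1} and {j=1,k=1}
  expect_equal(length(am$margins), 3 + 3)
  expect_error(alpha_model(3, 1.2), "\\(0, 1\\)")
  hm <- suppressWarnings(hj_model(4, 0.3))
  expect_equal(hm$D, 4L)
  expect_equal(length(hm$margins), 4 + 6)
  expect_error(hj_model(3, 0.3, cats = 3), "dichotomous")
  expect_error(alpha_model(1, 0.5), "J >= 2")
})

test_that("alpha matches a raw-observation covariance oracle", {
  tab <- example_tables()$three_items
  expect_equal(cmm_alpha(tab), oracle_alpha(tab), tolerance = 1e-12)
  expect_equal(round(cmm_alpha(tab), 4), 0.3675)
  for (s in 1:6) {
    rt <- random_dense_table(4, seed = 100 + s)
    expect_equal(cmm_alpha(rt), oracle_alpha(rt), tolerance = 1e-10)
  }
  ## two parallel items (variance v, covariance v) give alpha = 1
  par2 <- sparse_table(rbind(c(0L, 0L), c(1L, 1L)), counts = c(5, 5))
  expect_equal(cmm_alpha(par2), 1)
  ## zero covariance gives alpha = 0
  ind2 <- sparse_table(index_to_pattern(0:3, c(2, 2)), counts = c(4, 4, 4, 4))
  expect_equal(cmm_alpha(ind2), 0)
  ## degenerate total variance errors
  flat <- sparse_table(rbind(c(0L, 1L), c(1L, 0L)), counts = c(5, 5))
  expect_error(cmm_alpha(flat), "degenerate")
})

test_that("H coefficients match the printed values and a brute-force oracle", {
  tab <- example_tables()$three_items
  expect_equal(round(cmm_hj(tab), 3), c(0.231, 0.164, 0.055))
  expect_equal(cmm_hj(tab), oracle_hj(tab), tolerance = 1e-12)
  for (s in 1:6) {
    rt <- random_dense_table(4, seed = 200 + s)
    expect_equal(cmm_hj(rt), oracle_hj(rt), tolerance = 1e-10)
  }
  ## empty Guttman-error cell forces H = 1
  expect_equal(cmm_hj(example_tables()$perfect_guttman), c(1, 1))
  ## independence margins force H = 0
  ind2 <- sparse_table(index_to_pattern(0:3, c(2, 2)), counts = c(4, 4, 4, 4))
  expect_equal(cmm_hj(ind2), c(0, 0))
})

test_that("J = 2 duplicate H constraints are collapsed with a warning", {
  expect_warning(m2 <- hj_model(2, 0.3), "collapsed")
  expect_equal(m2$D, 1L)
  ## the two H coefficients are one function: identical values everywhere
  for (s in 1:4) {
    rt <- random_dense_table(2, seed = 300 + s)
    H <- cmm_hj(rt)
    expect_equal(H[1], H[2], tolerance = 1e-12)
  }
})

test_that("analytic Jacobians agree with central finite differences", {
  tab <- example_tables()$three_items
  full <- cmmael:::full_support_table(tab)
  models <- list(mean_model(3), alpha_model(3, 0.5),
                 suppressWarnings(hj_model(3, 0.4)))
  set.seed(11)
  for (model in models) {
    At <- cmmael:::margin_matrix(model, full)
    for (rep in 1:3) {
      m <- runif(8, 0.5, 2); m <- 130 * m / sum(m)
      ev <- cmmael:::constraints_eval(model, At, m, 130)
      num <- matrix(0, model$D, 8)
      for (i in 1:8) {
        h <- 1e-6 * m[i]
        mp <- m; mp[i] <- m[i] + h
        mm <- m; mm[i] <- m[i] - h
        num[, i] <- (cmmael:::constraints_eval(model, At, mp, 130)$g -
                     cmmael:::constraints_eval(model, At, mm, 130)$g) / (2 * h)
      }
      expect_lt(max(abs(ev$G - num)) / max(abs(num), 1), 1e-5)
    }
  }
})

test_that("beta recovers the design-projected link value", {
  tab <- example_tables()$three_items
  model <- mean_model(3)
  ## at the marginal-homogeneity fit each margin is 75.847
  mhat <- c(20.000, 14.397, 8.060, 11.695, 0.000, 19.755, 26.092, 30.000)
  full <- cmmael:::full_support_table(tab)
  b <- beta_from_margins(model, full, mhat)
  expect_equal(as.numeric(b), 3 * 75.847 / sqrt(3), tolerance = 1e-3)
  expect_equal(attr(b, "mean_score"), 75.847 / 130, tolerance = 1e-4)
  ## all item means exactly one half: overall mean score one half
  half <- sparse_table(index_to_pattern(c(0, 7), rep(2L, 3)), counts = c(5, 5))
  bh <- beta_from_margins(mean_model(3), half)
  expect_equal(attr(bh, "mean_score"), 0.5)
  ## constant link value k: beta = k * sqrt(dim) under the constant design
  const <- beta_from_margins(mean_model(4),
                             sparse_table(index_to_pattern(c(0, 15), rep(2L, 4)),
                                          counts = c(6, 6)))
  expect_equal(as.numeric(const), 6 * sqrt(4))
  expect_error(beta_from_margins(alpha_model(3, 0.5), tab), "no design")
})

test_that("models serialize to YAML and back", {
  dir <- withr::local_tempdir()
  models <- list(mean_model(4), alpha_model(5, 0.8),
                 suppressWarnings(hj_model(3, 0.3, item_order = c(2, 1, 3))))
  for (model in models) {
    f <- file.path(dir, paste0(model$name, ".yaml"))
    write_model_yaml(model, f)
    back <- suppressWarnings(read_model_yaml(f))
    expect_equal(back$D, model$D)
    expect_equal(back$criterion, model$criterion)
    expect_equal(back$margins, model$margins)
  }
  ## custom identity-link models round-trip through dense B_t
  cust <- cmm_model(list(list(vars = 1, values = 1), list(vars = 2, values = 1)),
                    J = 2, B_t = matrix(c(1, -1), 1, 2), name = "shift")
  f <- file.path(dir, "cust.yaml")
  write_model_yaml(cust, f)
  back <- read_model_yaml(f)
  expect_equal(back$B_t, cust$B_t)
  rt2 <- random_dense_table(2, seed = 9)
  expect_equal(evaluate_constraints(back, rt2)$g,
               evaluate_constraints(cust, rt2)$g, tolerance = 1e-12)
})
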