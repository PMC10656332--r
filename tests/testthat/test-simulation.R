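test_that("2PL sampling matches the item characteristic curve integral", {
  a <- c(1.5, 1.5, 1.5, 1.5)
  b <- c(-1, -0.3, 0.3, 1)
  tab <- twopl_sample(a, b, 4e4, seed = 12)
  means <- colSums(tab$patterns * tab$counts) / tab$N
  ## means decrease in difficulty
  expect_true(all(diff(means) < 0))
  for (j in 1:4) {
    mu <- oracle_2pl_mean(a[j], b[j])
    mc_se <- sqrt(mu * (1 - mu) / tab$N)
    expect_lt(abs(means[j] - mu), 3 * mc_se)
  }
  ## determinism given the seed
  expect_identical(twopl_sample(a, b, 100, seed = 4)$counts,
                   twopl_sample(a, b, 100, seed = 4)$counts)
  expect_error(twopl_sample(-1, 0, 10), "positive")
})

test_that("null populations satisfy their model constraints exactly", {
  base <- twopl_sample(1.5, c(-1, -0.3, 0.3, 1), 1000, seed = 3)
  fams <- list(mean_model(4), alpha_model(4, 0.8),
               suppressWarnings(hj_model(4, 0.3)))
  for (model in fams) {
    pop <- build_population(model, base, method = "ML", seed = 5)
    ptab <- sparse_table(pop$patterns, counts = pmax(round(1000 * pop$pi), 0),
                         cats = pop$cats,
                         augmented = round(1000 * pop$pi) == 0)
    ev <- evaluate_constraints(model, ptab, m = 1000 * pop$pi, N = 1000)
    expect_lt(max(abs(ev$g)), 1e-6 * 1000)
    expect_equal(sum(pop$pi), 1, tolerance = 1e-12)
    expect_true(all(pop$pi >= 0))
  }
  ## MAEL-built population for a table too large to materialize
  items <- 40
  base40 <- twopl_sample(1.5, seq(-1.5, 1.5, length.out = items), 500,
                         seed = 8)
  pop40 <- build_population(suppressWarnings(hj_model(items, 0.3)), base40,
                            method = "MAEL", seed = 9)
  H <- hj_from_margins(
    cmmael:::margin_values(suppressWarnings(hj_model(items, 0.3)),
                           sparse_table(pop40$patterns,
                                        counts = rep(1, length(pop40$pi)),
                                        cats = pop40$cats),
                           m = 500 * pop40$pi),
    items, 500)
  expect_lt(max(abs(H - 0.3)), 1e-6)
})

test_that("thinning zeroes the requested fraction and renormalizes", {
  base <- twopl_sample(1.5, c(-1, -0.3, 0.3, 1), 2000, seed = 21)
  pop <- build_population(mean_model(4), base, method = "ML", seed = 22)
  expect_identical(thin_zeros(pop, 0), pop)
  S <- length(pop$pi)
  th <- thin_zeros(pop, 0.75, seed = 23)
  expect_equal(length(th$pi), S - ceiling(0.75 * S))
  expect_equal(sum(th$pi), 1)
  ## samples from the thinned population stay inside its support
  tab <- sample_population(th, 200, seed = 24)
  keys <- pattern_to_string(th$patterns, th$cats)
  expect_true(all(pattern_to_string(tab$patterns, tab$cats) %in% keys))
  expect_error(thin_zeros(pop, 1), "U must")
})

test_that("multinomial sampling recovers the population distribution", {
  base <- twopl_sample(1.5, c(-0.5, 0.5), 500, seed = 31)
  pop <- build_population(mean_model(2), base, method = "ML", seed = 32)
  tab <- sample_population(pop, 5e4, seed = 33)
  ## chi-square goodness of fit of the sampled frequencies against pi
  idx <- match(tab$index, pattern_index(pop$patterns, pop$cats))
  exp_counts <- 5e4 * pop$pi[idx]
  X2 <- sum((tab$counts - exp_counts)^2 / exp_counts)
  expect_lt(X2, qchisq(0.999, df = length(pop$pi) - 1))
})

test_that("the study drivers return sane, reproducible summaries", {
  r <- run_type1_study("mean", J = 4, N = 250, replications = 80, seed = 55)
  expect_s3_class(r, "data.frame")
  expect_equal(r$replications, 80)
  expect_gte(r$convergence_rate, 0.9)
  expect_true(r$rejection_rate >= 0 && r$rejection_rate <= 0.25)
  expect_lt(abs(r$beta_bias), 4 * r$beta_sd / sqrt(80) + 1e-3)
  r2 <- run_type1_study("mean", J = 4, N = 250, replications = 80, seed = 55)
  expect_identical(r$rejection_rate, r2$rejection_rate)

  cfg <- list(family = "mean", J = 4, N = 50, U = c(0, 0.75),
              methods = c("ML", "MEL", "MAEL"), replications = 40, seed = 77)
  cv <- suppressWarnings(run_convergence_study(cfg))
  expect_equal(nrow(cv), 6L)
  expect_true(all(cv$convergence_rate >= 0 & cv$convergence_rate <= 1))
  ## sparse-support regime: empirical likelihood breaks down, the augmented
  ## variant does not, plain likelihood is unaffected
  mel75 <- cv$convergence_rate[cv$U == 0.75 & cv$method == "MEL"]
  mael75 <- cv$convergence_rate[cv$U == 0.75 & cv$method == "MAEL"]
  ml75 <- cv$convergence_rate[cv$U == 0.75 & cv$method == "ML"]
  expect_gte(mael75, 0.9)
  expect_gte(ml75, 0.9)
  expect_lt(mel75, mael75 - 0.25)
  ## dense regime: all methods essentially always converge
  expect_true(all(cv$convergence_rate[cv$U == 0] >= 0.95))
})

test_that("study configurations are validated", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(family = "mean", J = 4, N = 250, U = 0,
                        methods = "MAEL", replications = 10, seed = 1), f)
  expect_type(read_study_config(f), "list")
  yaml::write_yaml(list(family = "mean", J = 4, N = 250, U = 0,
                        methods = "MAEL", replications = 10), f)
  expect_error(read_study_config(f), "seed")
  yaml::write_yaml(list(family = "mean", J = 4, bogus = 1, seed = 1), f)
  expect_error(read_study_config(f), "bogus")
  expect_error(run_convergence_study(list(family = "mean", seed = 1)),
               "missing keys")
})
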