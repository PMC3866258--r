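test_that("pseudo-log-likelihood matches the per-cell conditional product", {
  fc <- feature_config(1)
  zero <- crf_params(fc)
  inst22 <- protein_rna_instance("AC", "GU", matrix(0.1, 2, 2),
                                 matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(pseudo_log_likelihood(zero, fc, inst22), 4 * log(0.5))

  for (fam in 1:3) {
    fc_k <- feature_config(fam, grouping_scheme(4))
    inst <- small_instance(40 + fam, Np = 3, Nr = 3)
    pars <- random_params(fc_k, fam)
    L <- pseudo_log_likelihood(pars, fc_k, inst)
    expect_lte(L, 0)
    slow <- sum(vapply(1:3, function(i) {
      sum(vapply(1:3, function(j) {
        local_conditional(pars, fc_k, inst, inst$r, i, j, log_p = TRUE)
      }, 0))
    }, 0))
    expect_equal(L, slow, tolerance = 1e-10)
  }
  unlabeled <- protein_rna_instance("AC", "GU", matrix(0, 2, 2))
  expect_error(pseudo_log_likelihood(zero, fc, unlabeled), "contact grid")
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(55)
  for (k in 1:8) {
    fam <- sample(1:3, 1)
    fc <- feature_config(fam, grouping_scheme(sample(c(2, 8), 1)))
    inst <- small_instance(200 + k, Np = sample(2:4, 1), Nr = sample(2:5, 1))
    theta <- rnorm(fc$f_dim + fc$g_dim, 0, 0.5)
    pars <- crf_params(fc, theta[seq_len(fc$f_dim)], theta[-seq_len(fc$f_dim)])
    g <- pll_gradient(pars, fc, inst)
    ga <- c(g$w_f, g$w_g)
    gn <- fd_gradient(fc, list(inst), theta)
    expect_lt(max(abs(ga - gn) / pmax(1, abs(ga))), 1e-5)
  }
})

test_that("gradients are additive over instances and balanced at zero", {
  fc <- feature_config(1)
  i1 <- small_instance(61)
  i2 <- small_instance(62)
  pars <- random_params(fc, 6)
  g12 <- pll_gradient(pars, fc, list(i1, i2))
  g1 <- pll_gradient(pars, fc, i1)
  g2 <- pll_gradient(pars, fc, i2)
  expect_equal(g12$w_f, g1$w_f + g2$w_f, tolerance = 1e-12)
  expect_equal(g12$w_g, g2$w_g + g1$w_g, tolerance = 1e-12)

  # at theta = 0 the conditional is uniform, so the expected feature term is
  # the state-average: with a half/half label grid the constant coordinates
  # of the f-block cancel exactly
  inst_bal <- protein_rna_instance("AC", "GU", matrix(0.3, 2, 2),
                                   matrix(c(1L, 0L, 0L, 1L), 2, 2))
  g0 <- pll_gradient(crf_params(fc), fc, inst_bal)
  expect_equal(g0$w_f[1], 0, tolerance = 1e-12)  # r-indicator coordinate
  expect_equal(g0$w_f[3], 0, tolerance = 1e-12)  # rbar-indicator coordinate
})

test_that("the lasso objective subtracts the L1 norm", {
  fc <- feature_config(1)
  inst <- small_instance(63)
  pars <- crf_params(fc, c(1, -2, 0.5, 0), c(1, -1, 0, 0, 2, 0, 0, -0.5))
  L <- pseudo_log_likelihood(pars, fc, inst)
  expect_equal(crf_objective(pars, fc, inst, C = 0), L)
  expect_equal(crf_objective(pars, fc, inst, C = 1), L - 8)
  expect_equal(crf_objective(pars, fc, inst, C = 2.5), L - 2.5 * 8)
  zero <- crf_params(fc)
  expect_equal(crf_objective(zero, fc, inst, C = 100),
               pseudo_log_likelihood(zero, fc, inst))
})

test_that("fitting recovers planted coupling and respects the lasso", {
  fc <- feature_config(1)
  train <- lapply(1:4, function(k) {
    small_instance(300 + k, Np = 8, Nr = 10, n_pairs = 80,
                   density = 0.2, coupling = 0.9)
  })
  fit <- crf_fit(train, fc, training_config())
  expect_true(attr(fit, "converged"))
  # MI lowers the energy of the contact state relative to the non-contact
  # state: the log-odds of r=1 increase with m
  expect_lt(fit$w_f[2] - fit$w_f[4], 0)
  # high-MI cell scores above low-MI cell under the fitted model
  p <- score_grid(fit, fc, train[[1]], conditioning = train[[1]]$r * 0L)
  expect_gt(cor(as.vector(train[[1]]$m), as.vector(p)), 0)

  # gradient at the optimum is below tolerance
  g <- pll_gradient(fit, fc, train)
  expect_lt(max(abs(c(g$w_f, g$w_g))), 1e-5 * max(1, max(abs(c(fit$w_f, fit$w_g)))) * 10)

  # C above the largest gradient coordinate at zero: exact zero solution
  g0 <- pll_gradient(crf_params(fc), fc, train)
  C_big <- 1.05 * max(abs(c(g0$w_f, g0$w_g)))
  fit0 <- crf_fit(train, fc, training_config(lasso_C = C_big))
  expect_identical(fit0$w_f, numeric(4))
  expect_identical(fit0$w_g, numeric(8))

  # the penalized optimum has a smaller L1 norm than the unpenalized one
  fitC <- crf_fit(train, fc, training_config(lasso_C = 1))
  expect_lte(sum(abs(fitC$w_f)) + sum(abs(fitC$w_g)),
             sum(abs(fit$w_f)) + sum(abs(fit$w_g)) + 1e-8)

  # the optimizer trace is non-decreasing in the penalized objective
  expect_true(all(diff(attr(fitC, "trace")) >= -1e-10))
})

test_that("no random restart improves on the deterministic fit", {
  fc <- feature_config(1)
  train <- list(small_instance(71, Np = 5, Nr = 6, n_pairs = 40))
  base <- crf_fit(train, fc, training_config(gradient_tolerance = 1e-7))
  best <- attr(base, "objective")
  set.seed(99)
  for (k in 1:10) {
    start <- crf_params(fc, rnorm(4, 0, 2), rnorm(8, 0, 2))
    fit_k <- crf_fit(train, fc,
                     training_config(gradient_tolerance = 1e-7,
                                     initial_params = start))
    expect_lt(attr(fit_k, "objective"), best + 1e-6)
  }
})

test_that("parameters round-trip through JSON", {
  fc <- feature_config(2, grouping_scheme(8))
  pars <- random_params(fc, 8)
  f <- withr::local_tempfile(fileext = ".json")
  write_params_json(pars, f)
  back <- read_params_json(f)
  expect_equal(back$w_f, pars$w_f, tolerance = 1e-12)
  expect_equal(back$w_g, pars$w_g, tolerance = 1e-12)
  expect_equal(back$config$family, 2L)
  expect_equal(back$config$grouping$group_count, 8L)
})
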