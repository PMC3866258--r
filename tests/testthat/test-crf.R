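test_that("feature dimensions follow the family and grouping", {
  # ungrouped label indicator has length 20 x 4 = 80
  fc3 <- feature_config(3, grouping_scheme(20))
  expect_equal(length(feature_f(fc3, 1, a_i = "A", b_j = "A")), 160L)
  expect_equal(fc3$G4, 80L)

  fc1 <- feature_config(1)
  expect_equal(c(fc1$f_dim, fc1$g_dim), c(4L, 8L))
  for (G in c(2, 4, 8, 10, 15, 20)) {
    fc2 <- feature_config(2, grouping_scheme(G))
    expect_equal(fc2$f_dim, 2L * (G * 4L) * 2L)
    expect_equal(fc2$g_dim, 2L * 2L * (G * 4L) * 2L)
    fc3g <- feature_config(3, grouping_scheme(G))
    expect_equal(fc3g$f_dim, 2L * G * 4L)
    expect_equal(fc3g$g_dim, 4L * G * 4L)
  }
  expect_equal(feature_config(2, grouping_scheme(20))$f_dim, 320L)
  expect_equal(feature_config(2, grouping_scheme(20))$g_dim, 640L)
})

test_that("local features match their explicit Kronecker forms", {
  fc1 <- feature_config(1)
  expect_equal(feature_f(fc1, 1, 0.5), c(1, 0.5, 0, 0))
  expect_equal(feature_f(fc1, 0, 0.5), c(0, 0, 1, 0.5))
  expect_equal(feature_g(fc1, 1, 0, 0.3), c(0, 0, 1, 0.3, 0, 0, 0, 0))
  expect_equal(feature_g(fc1, 0, 0, 0), c(0, 0, 0, 0, 0, 0, 1, 0))

  # family 3, two residue classes: one-hot lands in the rbar block
  g2 <- grouping_scheme(2)
  fc3 <- feature_config(3, g2)
  v <- feature_f(fc3, 0, a_i = "M", b_j = "A")  # M in class 0, base A
  expect_equal(which(v == 1), fc3$G4 + 1L)
  expect_equal(sum(v != 0), 1L)

  # all families and states agree with independently built Kronecker
  # products over random observations
  set.seed(13)
  for (fam in 1:3) {
    for (G in c(2, 8, 20)) {
      fc <- feature_config(fam, grouping_scheme(G))
      for (k in 1:5) {
        a <- sample(AA20, 2)
        b <- sample(RNA4, 2)
        m <- rnorm(2)
        for (r1 in 0:1) {
          expect_equal(feature_f(fc, r1, m[1], a[1], b[1]),
                       kron_feature_f(fc, r1, m[1], a[1], b[1]))
          for (r2 in 0:1) {
            expect_equal(feature_g(fc, r1, r2, m[2], a[2], b[2]),
                         kron_feature_g(fc, r1, r2, m[2], a[2], b[2]))
          }
        }
      }
    }
  }
})

test_that("features are 2-sparse (1-sparse for labels-only) one-hot blocks", {
  set.seed(3)
  for (fam in 1:3) {
    fc <- feature_config(fam, grouping_scheme(8))
    nnz <- if (fam == 3L) 1L else 2L
    for (k in 1:10) {
      f <- feature_f(fc, sample(0:1, 1), rnorm(1), sample(AA20, 1), sample(RNA4, 1))
      g <- feature_g(fc, sample(0:1, 1), sample(0:1, 1), rnorm(1),
                     sample(AA20, 1), sample(RNA4, 1))
      expect_lte(sum(f != 0), nnz)
      expect_lte(sum(g != 0), nnz)
    }
  }
  expect_error(feature_f(feature_config(2), 1, 0.1, "Z", "A"), "residue")
  expect_error(feature_f(feature_config(2), 1, 0.1, "A", "T"), "base")
})

test_that("grid neighborhoods truncate at boundaries in fixed order", {
  expect_equal(grid_neighbors(3, 3, 5, 5),
               list(c(2L, 3L), c(4L, 3L), c(3L, 2L), c(3L, 4L)))
  expect_equal(grid_neighbors(1, 1, 5, 5), list(c(2L, 1L), c(1L, 2L)))
  expect_equal(grid_neighbors(1, 1, 1, 1), list())
  expect_equal(length(grid_neighbors(1, 3, 2, 5)), 3L)
})

test_that("local potential matches an independent oracle and is linear", {
  inst <- small_instance(21)
  r <- inst$r
  for (fam in 1:3) {
    fc <- feature_config(fam, grouping_scheme(8))
    pars <- random_params(fc, 100 + fam)
    for (i in c(1, 2, 4)) {
      for (j in c(1, 3, 5)) {
        expect_equal(local_potential(pars, fc, inst, r, i, j),
                     oracle_potential(pars, fc, inst, r, i, j),
                     tolerance = 1e-12)
      }
    }
    # zero parameters give zero potential
    expect_equal(local_potential(crf_params(fc), fc, inst, r, 2, 2), 0)
    # linearity in the parameters
    pars2 <- crf_params(fc, 2.5 * pars$w_f, 2.5 * pars$w_g)
    expect_equal(local_potential(pars2, fc, inst, r, 2, 3),
                 2.5 * local_potential(pars, fc, inst, r, 2, 3),
                 tolerance = 1e-10)
  }
  # family 1 picking a single coordinate
  fc1 <- feature_config(1)
  p1 <- crf_params(fc1, c(1, 0, 0, 0), numeric(8))
  r1 <- r; r1[1, 1] <- 1L
  expect_equal(local_potential(p1, fc1, inst, r1, 1, 1), 1)
})

test_that("local conditionals are normalized logistic probabilities", {
  inst <- small_instance(22)
  fc <- feature_config(1)
  zero <- crf_params(fc)
  expect_equal(local_conditional(zero, fc, inst, inst$r, 1, 1, state = 0), 0.5)
  expect_equal(local_conditional(zero, fc, inst, inst$r, 1, 1, state = 1), 0.5)

  # U(1) - U(0) = ln 3  =>  Pr(1) = 1/4; realized with w_f = (ln3, 0, 0, 0)
  p3 <- crf_params(fc, c(log(3), 0, 0, 0), numeric(8))
  expect_equal(local_conditional(p3, fc, inst, inst$r, 2, 2, state = 1), 0.25)

  set.seed(77)
  for (k in 1:100) {
    fam <- sample(1:3, 1)
    fc_k <- feature_config(fam, grouping_scheme(sample(c(2, 8, 20), 1)))
    pars <- random_params(fc_k, k, sd = 1)
    i <- sample(nrow(inst$r), 1)
    j <- sample(ncol(inst$r), 1)
    p0 <- local_conditional(pars, fc_k, inst, inst$r, i, j, state = 0)
    p1 <- local_conditional(pars, fc_k, inst, inst$r, i, j, state = 1)
    expect_equal(p0 + p1, 1, tolerance = 1e-12)
  }
})

test_that("one-class residue grouping collapses family 2 onto family 1", {
  g1 <- new_grouping("1", paste(AA20, collapse = ""))
  fc2 <- feature_config(2, g1)
  fc1 <- feature_config(1)
  set.seed(4)
  for (k in 1:10) {
    r <- sample(0:1, 1)
    m <- rnorm(1)
    a <- sample(AA20, 1)
    b <- sample(RNA4, 1)
    f2 <- feature_f(fc2, r, m, a, b)
    f1 <- feature_f(fc1, r, m)
    # extract the base-specific block: entries collapse onto family 1
    bi <- match(b, RNA4) - 1L
    idx <- c(bi * 2 + 1:2, 8 + bi * 2 + 1:2)
    expect_equal(f2[idx], f1)
    expect_equal(sum(f2[-idx] != 0), 0L)
  }
})
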