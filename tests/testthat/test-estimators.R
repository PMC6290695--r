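test_that("moment estimators match hand arithmetic and the analytic CV", {
  m <- estimate_moments(c(1, 2, 3))
  expect_equal(m$mean, 2)
  expect_equal(m$variance, 1)
  expect_equal(m$sd, 1)
  expect_equal(m$cv, 50)

  cst <- estimate_moments(rep(4, 10))
  expect_equal(cst$variance, 0)
  expect_equal(cst$cv, 0)

  z <- estimate_moments(c(-1, 1))
  expect_false(z$cv_defined)
  expect_true(is.na(z$cv))

  set.seed(1)
  x <- rnorm(1e5, 10, 2)
  expect_equal(estimate_moments(x)$cv, 20, tolerance = 0.5 / 20)
})

test_that("aleatory variance recovers the noise variance of an additive toy", {
  # deterministic model: reseeding changes nothing
  x <- runif(100)
  expect_equal(aleatory_variance(x, x)$variance, 0)

  set.seed(42)
  M <- 1e5
  xx <- runif(M)
  sig <- 0.7
  fA <- xx + rnorm(M, 0, sig)
  fR <- xx + rnorm(M, 0, sig)
  est <- aleatory_variance(fA, fR)
  expect_equal(est$variance, sig^2, tolerance = 0.05)
  expect_equal(est$sd_bound, sqrt(est$variance))
  expect_error(aleatory_variance(1:3, 1:4), "mismatch")
})

test_that("the Jensen bound dominates the nested-MC conditional sd", {
  # x-dependent noise amplitude: f = x + (1 + x) * xi
  set.seed(7)
  sig <- 0.5
  M <- 2e4
  xx <- runif(M)
  fA <- xx + (1 + xx) * rnorm(M, 0, sig)
  fR <- xx + (1 + xx) * rnorm(M, 0, sig)
  bound <- aleatory_variance(fA, fR)$sd_bound
  # nested double-loop: E_x[ sd(f | x) ]
  direct <- mean(vapply(seq_len(200), function(k) {
    x1 <- runif(1)
    sd(x1 + (1 + x1) * rnorm(500, 0, sig))
  }, numeric(1)))
  expect_gte(bound, direct * 0.98)
  # analytic check: E[(1+x)] sigma vs sqrt(E[(1+x)^2]) sigma
  expect_equal(direct, 1.5 * sig, tolerance = 0.05)
  expect_equal(bound, sqrt(7 / 3) * sig, tolerance = 0.05)
})

test_that("first-order indices recover the additive-model variance shares", {
  set.seed(11)
  M <- 2e4
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M, seed_root = 5)
  y <- evaluate_design(d, function(x, seed) x["x1"] + 2 * x["x2"])
  bl <- isruq:::split_blocks(d, y)
  s1 <- first_order_index(as.numeric(bl$A), as.numeric(bl$FO[[1]]))
  s2 <- first_order_index(as.numeric(bl$A), as.numeric(bl$FO[[2]]))
  expect_equal(s1$index, 20, tolerance = 2 / 20)
  expect_equal(s2$index, 80, tolerance = 2 / 80)
  # additive model: totals equal first orders within MC error
  t1 <- total_index(as.numeric(bl$A), as.numeric(bl$TO[[1]]))
  t2 <- total_index(as.numeric(bl$A), as.numeric(bl$TO[[2]]))
  expect_equal(t1$index, 20, tolerance = 2 / 20)
  expect_equal(t2$index, 80, tolerance = 2 / 80)
  # and first orders sum to ~100%
  expect_equal(s1$index + s2$index, 100, tolerance = 0.03)
})

test_that("first-order index of an inert input is ~0 and zero variance is flagged", {
  set.seed(2)
  M <- 5e3
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M, seed_root = 9)
  y <- evaluate_design(d, function(x, seed) 3 * x["x2"])
  bl <- isruq:::split_blocks(d, y)
  expect_equal(first_order_index(as.numeric(bl$A),
                                 as.numeric(bl$FO[[1]]))$index,
               0, tolerance = 3)
  cst <- first_order_index(rep(1, 10), rep(1, 10))
  expect_false(cst$defined)
  expect_true(is.na(cst$index))
})

test_that("Ishigami indices match the closed-form decomposition", {
  ref <- ishigami_indices()
  M <- 5e4
  sp <- parameter_space(c("u1", "u2", "u3"), c(0, 0, 0), c(1, 1, 1))
  d <- build_design(sp, M, seed_root = 21)
  y <- evaluate_design(d, function(x, seed) ishigami(x))
  bl <- isruq:::split_blocks(d, y)
  a <- as.numeric(bl$A)
  expect_equal(first_order_index(a, as.numeric(bl$FO[[1]]))$index, ref$S1,
               tolerance = 3 / ref$S1)
  expect_equal(first_order_index(a, as.numeric(bl$FO[[2]]))$index, ref$S2,
               tolerance = 3 / ref$S2)
  s3 <- first_order_index(a, as.numeric(bl$FO[[3]]))$index
  expect_lt(abs(s3 - ref$S3), 3)
  expect_equal(total_index(a, as.numeric(bl$TO[[3]]))$index, ref$ST3,
               tolerance = 3 / ref$ST3)
  expect_equal(var(a), ref$total_variance, tolerance = 0.05)
})

test_that("total index of a pure-noise model approaches 100% for every input", {
  set.seed(3)
  M <- 2e4
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M, seed_root = 13)
  y <- evaluate_design(d, function(x, seed) {
    set.seed(seed)
    rnorm(1)
  })
  bl <- isruq:::split_blocks(d, y)
  for (i in 1:2)
    expect_equal(total_index(as.numeric(bl$A),
                             as.numeric(bl$TO[[i]]))$index,
                 100, tolerance = 0.05)
})

test_that("Saltelli first-order estimates agree with a double-loop oracle", {
  f <- function(u) u[1] + u[2]^2 + u[1] * u[2]
  set.seed(17)
  oracle <- vapply(1:2, function(i)
    double_loop_first_order(f, i, 2, n_outer = 300, n_inner = 300),
    numeric(1))
  M <- 2e4
  sp <- parameter_space(c("u1", "u2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M, seed_root = 31)
  y <- evaluate_design(d, function(x, seed) f(x))
  bl <- isruq:::split_blocks(d, y)
  for (i in 1:2)
    expect_equal(first_order_index(as.numeric(bl$A),
                                   as.numeric(bl$FO[[i]]))$index,
                 oracle[i], tolerance = 6 / oracle[i])
})

test_that("bootstrap reproduces the CLT standard error and shrinks with M", {
  cst <- bootstrap_estimate(list(A = rep(2, 50)), function(b) mean(b$A),
                            K = 200)
  expect_equal(cst$sd, 0)

  set.seed(5)
  x <- rnorm(1000)
  b <- bootstrap_estimate(list(A = x), function(bl) mean(bl$A), K = 10000)
  expect_equal(b$sd, 1 / sqrt(1000), tolerance = 0.10)

  # error bar shrinks roughly like 1/sqrt(M)
  set.seed(6)
  sds <- vapply(c(100, 400, 1600), function(M) {
    bootstrap_estimate(list(A = rnorm(M)), function(bl) mean(bl$A),
                       K = 2000)$sd
  }, numeric(1))
  expect_equal(sds[1] / sds[2], 2, tolerance = 0.3)
  expect_equal(sds[2] / sds[3], 2, tolerance = 0.3)
})

test_that("the vectorised campaign bootstrap agrees with the generic resampler", {
  set.seed(8)
  M <- 200
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M, seed_root = 2)
  y <- evaluate_design(d, function(x, seed) {
    set.seed(seed)
    x["x1"] + 2 * x["x2"] + rnorm(1, 0, 0.3)
  })
  blm <- isruq:::split_blocks(d, y)
  bl <- list(A = as.numeric(blm$A), A_RESEED = as.numeric(blm$A_RESEED),
             FO = lapply(blm$FO, as.numeric), TO = lapply(blm$TO, as.numeric))
  set.seed(99)
  fast <- isruq:::bootstrap_report(bl, K = 4000, n_inputs = 2)
  gen_blocks <- list(A = bl$A, R = bl$A_RESEED, F1 = bl$FO[[1]])
  set.seed(99)
  slow_mean <- bootstrap_estimate(gen_blocks, function(b) mean(b$A), K = 4000)
  expect_equal(fast$mean[["mean"]], slow_mean$mean, tolerance = 0.02)
  expect_equal(fast$mean[["sd"]], slow_mean$sd, tolerance = 0.15)
  slow_al <- bootstrap_estimate(gen_blocks,
                                function(b) mean((b$A - b$R)^2) / 2, K = 4000)
  expect_equal(fast$aleatory_variance[["mean"]], slow_al$mean,
               tolerance = 0.05)
})
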