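test_that("pair force follows the Hertz/adhesion/tether law", {
  p <- mechanics_params()
  mk <- function(d) list(a = list(position = c(0, 0), radius = 0.015),
                         b = list(position = c(d, 0), radius = 0.015))
  # independent scalar evaluation of the chosen law
  scalar_law <- function(d, R = 0.03) {
    del <- R - d
    if (del > 0) return(p$hertz_stiffness * del^1.5 -
                          p$adhesion_coefficient * p$hertz_stiffness * del)
    s <- -del
    if (s >= p$tether_range) return(0)
    if (s <= p$tether_range / 2) return(-p$tether_stiffness * s)
    -p$tether_stiffness * (p$tether_range - s)
  }
  # exact contact boundary: zero force
  ab <- mk(0.03)
  expect_equal(pair_force(ab$a, ab$b, p), c(0, 0))
  # overlap 0.001: matches the scalar oracle
  ab <- mk(0.029)
  f <- pair_force(ab$a, ab$b, p)
  expect_equal(f[1], -scalar_law(0.029), tolerance = 1e-12)
  expect_equal(f[2], 0)
  # the Hertz component alone at overlap delta is k_h * delta^1.5
  p0 <- mechanics_params(adhesion_coefficient = 1e-12)
  f0 <- pair_force(ab$a, ab$b, p0)
  expect_equal(abs(f0[1]), p$hertz_stiffness * 0.001^1.5, tolerance = 1e-6)
  # tether region and beyond
  ab <- mk(0.033)
  expect_equal(pair_force(ab$a, ab$b, p)[1], -scalar_law(0.033),
               tolerance = 1e-12)
  ab <- mk(0.05)
  expect_equal(pair_force(ab$a, ab$b, p), c(0, 0))
  # Newton's third law
  ab <- mk(0.028)
  expect_equal(pair_force(ab$a, ab$b, p), -pair_force(ab$b, ab$a, p))
  # coincident centers
  expect_error(pair_force(ab$a, ab$a, p), "degenerate")
})

test_that("internal forces sum to zero over a random population", {
  p <- mechanics_params()
  set.seed(4)
  st <- make_tissue(runif(60, 0, 0.3), runif(60, 0, 0.3))
  f <- isruq:::tissue_forces(st, p)
  expect_equal(sum(f$fx), 0, tolerance = 1e-10)
  expect_equal(sum(f$fy), 0, tolerance = 1e-10)
})

test_that("binned neighbour search matches an all-pairs oracle", {
  p <- mechanics_params()
  set.seed(9)
  n <- 40
  st <- make_tissue(runif(n, 0, 0.2), runif(n, 0, 0.2))
  f <- isruq:::tissue_forces(st, p)
  # all-pairs reference in R
  fx <- fy <- numeric(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    fij <- pair_force(list(position = c(st$x[i], st$y[i]), radius = st$radius[i]),
                      list(position = c(st$x[j], st$y[j]), radius = st$radius[j]),
                      p)
    fx[i] <- fx[i] + fij[1]; fy[i] <- fy[i] + fij[2]
    fx[j] <- fx[j] - fij[1]; fy[j] <- fy[j] - fij[2]
  }
  expect_equal(f$fx, fx, tolerance = 1e-12)
  expect_equal(f$fy, fy, tolerance = 1e-12)
})

test_that("equilibration satisfies the two-body closed form and its contracts", {
  p <- mechanics_params()
  # isolated agent: unchanged
  st <- make_tissue(0.1, 0.1)
  st1 <- equilibrate(st, p)
  expect_equal(st1$x, st$x)
  expect_equal(st1$y, st$y)
  # two overlapping agents relax to separation R - a^2 (closed-form root
  # of k_h d^1.5 = a k_h d), to 1e-8 mm at a tight tolerance
  tight <- mechanics_params(equilibration_tolerance = 1e-7,
                            max_equilibration_iters = 200000)
  st <- make_tissue(c(0, 0.025), c(0, 0))
  st2 <- equilibrate(st, tight)
  expect_true(attr(st2, "converged"))
  sep <- abs(diff(st2$x))
  expect_lt(abs(sep - (0.03 - tight$adhesion_coefficient^2)), 1e-8)
  # post-equilibration separation at least contact distance minus the
  # adhesive overlap
  expect_gte(sep, 0.03 - tight$adhesion_coefficient^2 - 1e-8)
  # all agents fixed: returned unchanged
  st <- make_tissue(c(0, 0.02), c(0, 0))
  st3 <- equilibrate(st, p, fixed_ids = c(1L, 2L))
  expect_equal(st3$x, st$x)
  # idempotence: a second call moves nothing appreciably
  st4 <- equilibrate(st2, tight)
  expect_lt(max(abs(st4$x - st2$x), abs(st4$y - st2$y)), 1e-6)
  # horizontally constrained agents keep their x
  st <- make_tissue(c(0, 0.02), c(0, 0.01),
                    constrained_x = c(TRUE, FALSE))
  st5 <- equilibrate(st, p)
  expect_equal(st5$x[1], 0)
  expect_error(equilibrate(st, p, fixed_ids = 99L), "subset")
})

test_that("overload removal honours thresholds, chain strain and strut immunity", {
  p <- mechanics_params()
  # all loads below thresholds: nothing happens
  st <- make_tissue(c(0, 0.03, 0.06), c(0, 0, 0))
  out <- remove_overloaded(st, p)
  expect_equal(out$removed_ids, integer(0))
  expect_equal(out$state$id, st$id)
  # infinite thresholds: nothing removed even under heavy overlap
  pinf <- mechanics_params(smc_stress_threshold = 1e12,
                           iel_stress_threshold = 1e12,
                           iel_strain_threshold = 1e12)
  st <- make_tissue(c(0, 0.01), c(0, 0)) # deep overlap
  expect_equal(remove_overloaded(st, pinf)$removed_ids, integer(0))
  # a single stretched IEL link removes exactly its agents
  st <- make_tissue(c(0, 0.05), c(0, 0), kind = c(2L, 2L))
  st$iel_links <- cbind(1L, 2L)
  st$iel_rest <- 0.03
  out <- remove_overloaded(st, mechanics_params(iel_strain_threshold = 0.5))
  expect_setequal(out$removed_ids, c(1L, 2L)) # both ends exceed 66% strain
  expect_equal(out$state$removed_count, 2L)
  # strut agents are never removed
  st <- make_tissue(c(0, 0.01), c(0, 0), kind = c(3L, 3L))
  expect_equal(remove_overloaded(st, mechanics_params(
    smc_stress_threshold = 1e-9, iel_stress_threshold = 1e-9))$removed_ids,
    integer(0))
})

test_that("stent deployment is deterministic and damages the wall near the strut", {
  cfg <- coarse_config()
  s <- initialize_vessel(cfg)
  p <- cfg$mechanics
  # zero depth: geometry essentially unchanged, no removals
  s0 <- deploy_stent(s, 0, 4, p)
  expect_equal(s0$removed_count, 0L)
  expect_lt(max(abs(s0$x - s$x), abs(s0$y - s$y)), 1e-3)
  # nominal depth: IEL ruptured, and only in the strut neighbourhood
  s1 <- deploy_stent(s, 0.110, cfg$deploy_steps, p)
  gone <- setdiff(s$id[s$kind == 2L], s1$id[s1$kind == 2L])
  expect_gt(length(gone), 0)
  gx <- s$x[match(gone, s$id)]
  expect_true(all(abs(gx - cfg$vessel_length / 2) < 0.2))
  # removal exposes SMCs to the flow at the rupture site
  lat <- rasterize(s1, cfg$flow$spacing, attr(s, "bbox"),
                   inflate = cfg$flow$spacing / 2)
  fl <- solve_flow(lat, cfg$flow, 0.48e-3)
  w <- wall_shear_stress(fl, lat, s1)
  w <- w[!(as.integer(names(w)) %in% s1$id[s1$clamped])]
  expect_gt(length(w), 0)
  # determinism: bit-identical repeat
  s2 <- deploy_stent(s, 0.110, cfg$deploy_steps, p)
  expect_identical(s1$x, s2$x)
  expect_identical(s1$y, s2$y)
  expect_identical(s1$id, s2$id)
  # deeper deployment never heals damage: depth 0 removes the least
  expect_gte(s1$removed_count, s0$removed_count)
  expect_error(deploy_stent(s, 10, 4, p), "destroy")
})

test_that("deeper deployment removes at least as many agents (full resolution)", {
  cfg <- sim_config()
  s <- initialize_vessel(cfg)
  counts <- vapply(c(0, 0.09, 0.11, 0.13), function(d)
    deploy_stent(s, d, cfg$deploy_steps, cfg$mechanics)$removed_count,
    numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[1], 0)
  expect_gt(counts[3], 0)
})
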