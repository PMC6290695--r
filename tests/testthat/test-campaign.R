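# Build an in-memory isr_campaign from a design and an output function,
# bypassing the disk layout (used to validate the analysis layer against
# analytic stubs).
stub_campaign <- function(design, f, n_times = 1, snapshots = NULL,
                          restenosis = NULL) {
  y <- evaluate_design(design, f)
  area <- matrix(rep(as.numeric(y), n_times), ncol = n_times)
  n_runs <- nrow(design$runs)
  if (is.null(snapshots))
    snapshots <- replicate(n_runs, matrix(FALSE, 2, 2), simplify = FALSE)
  if (is.null(restenosis)) restenosis <- rep(FALSE, n_runs)
  structure(list(design = design, dir = NULL, times = seq_len(n_times),
                 area = area, width = area, coverage = area,
                 snapshots = snapshots, restenosis = restenosis,
                 original_lumen_area = pi / 4),
            class = "isr_campaign")
}

test_that("campaign generation writes the design and one config per run", {
  dir <- tempfile("camp")
  cfg <- tiny_config()
  sp <- default_parameter_space()
  d <- generate_campaign(cfg, sp, M = 2, seed_root = 5, dir = dir)
  expect_equal(nrow(d$runs), 16)
  expect_equal(length(list.files(file.path(dir, "runs"))), 16)
  expect_true(file.exists(file.path(dir, "design.csv")))
  # regeneration is refused without overwrite, idempotent with it
  expect_error(generate_campaign(cfg, sp, 2, 5, dir), "overwrite")
  before <- readBin(file.path(dir, "design.csv"), "raw",
                    file.size(file.path(dir, "design.csv")))
  generate_campaign(cfg, sp, 2, 5, dir, overwrite = TRUE)
  after <- readBin(file.path(dir, "design.csv"), "raw",
                   file.size(file.path(dir, "design.csv")))
  expect_identical(before, after)
  unlink(dir, recursive = TRUE)
})

test_that("campaign execution is resumable and worker-count invariant", {
  cfg <- tiny_config(total_days = 1.5)
  sp <- default_parameter_space()
  dir1 <- tempfile("camp1")
  generate_campaign(cfg, sp, M = 1, seed_root = 3, dir = dir1)
  run_campaign(dir1, workers = 1)
  res1 <- collect_campaign(dir1)
  dir2 <- tempfile("camp2")
  generate_campaign(cfg, sp, M = 1, seed_root = 3, dir = dir2)
  run_campaign(dir2, workers = 2)
  res2 <- collect_campaign(dir2)
  expect_identical(res1$area, res2$area)
  expect_identical(res1$snapshots, res2$snapshots)
  # resumability: wiping one run's status re-executes only that run
  rid <- res1$design$runs$run_id[2]
  unlink(file.path(dir1, "runs", rid, "status.json"))
  expect_equal(run_campaign(dir1, workers = 1), 1, ignore_attr = TRUE)
  res1b <- collect_campaign(dir1)
  expect_identical(res1b$area, res1$area)
  expect_error(run_campaign(tempfile()), "not a generated campaign")
  # missing runs are named when collecting an incomplete campaign
  unlink(file.path(dir1, "runs", rid, "status.json"))
  expect_error(collect_campaign(dir1), rid)
  unlink(dir1, recursive = TRUE); unlink(dir2, recursive = TRUE)
})

test_that("analysis flags degenerate outputs and isolates a single active input", {
  sp <- default_parameter_space()
  d <- build_design(sp, M = 64, seed_root = 11)
  # constant stub: zero variances, undefined indices
  camp <- stub_campaign(d, function(x, seed) 1.0)
  rep0 <- analyze_campaign(camp, K = 100)
  expect_equal(unname(rep0$estimates[1, "variance"]), 0)
  expect_true(is.na(rep0$estimates[1, "S_regen_time"]))
  expect_equal(unname(rep0$estimates[1, "aleatory_variance"]), 0)
  # deterministic, linear in deployment depth only
  camp1 <- stub_campaign(d, function(x, seed) x[["deployment_depth"]])
  rep1 <- analyze_campaign(camp1, K = 200)
  expect_equal(unname(rep1$estimates[1, "S_deployment_depth"]), 100, tolerance = 0.05)
  expect_equal(unname(rep1$estimates[1, "ST_deployment_depth"]), 100, tolerance = 0.05)
  expect_lt(abs(rep1$estimates[1, "S_flow_velocity"]), 5)
  expect_lt(abs(rep1$estimates[1, "ST_regen_time"]), 5)
  expect_equal(unname(rep1$estimates[1, "aleatory_variance"]), 0)
})

test_that("analysis decomposes an additive stochastic stub correctly", {
  sp <- parameter_space(c("x1", "x2"), c(0, 0), c(1, 1))
  d <- build_design(sp, M = 4000, seed_root = 17)
  camp <- stub_campaign(d, function(x, seed) {
    set.seed(seed)
    x[["x1"]] + 2 * x[["x2"]] + rnorm(1, 0, sqrt(1 / 12))
  })
  rep <- analyze_campaign(camp, K = 300)
  # variance bookkeeping: 1/12 + 4/12 + 1/12 = 6/12
  expect_equal(unname(rep$estimates[1, "variance"]), 0.5, tolerance = 0.05)
  expect_equal(unname(rep$estimates[1, "aleatory_variance"]) /
                 unname(rep$estimates[1, "variance"]), 1 / 6, tolerance = 0.25)
  expect_equal(unname(rep$estimates[1, "S_x1"]), 100 / 6, tolerance = 0.15)
  expect_equal(unname(rep$estimates[1, "S_x2"]), 400 / 6, tolerance = 0.1)
  # bootstrap error bars are reported for every quantity
  expect_true(all(is.finite(rep$bootstrap_sd[1, ])))
  s <- summary(rep)
  expect_true(all(c("estimate", "bootstrap_sd") %in% names(s)))
})

test_that("presence probability averages snapshot stacks sitewise", {
  m1 <- matrix(c(TRUE, FALSE, TRUE, FALSE), 2, 2)
  # single run: exact 0/1 field
  f1 <- presence_probability(list(m1))
  expect_true(all(f1$values %in% c(0, 1)))
  # duplicated identical runs change nothing
  f2 <- presence_probability(list(m1, m1, m1))
  expect_equal(f2$values, f1$values)
  # complementary masks average to one half everywhere
  f3 <- presence_probability(list(m1, !m1))
  expect_true(all(f3$values == 0.5))
  expect_error(presence_probability(list(m1, matrix(TRUE, 3, 3))),
               "mismatch")
})

test_that("spatial sensitivity maps equal sitewise scalar estimators", {
  sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 1))
  d <- build_design(sp, M = 16, seed_root = 23)
  n_runs <- nrow(d$runs)
  dims <- c(3, 2)
  # random boolean stacks, one bit per site per run, seeded by run
  snaps <- lapply(seq_len(n_runs), function(k) {
    set.seed(d$runs$seed[k] %% 1000 + k)
    matrix(runif(prod(dims)) < 0.5 + 0.4 * (d$runs$a[k] - 0.5), dims[1], dims[2])
  })
  camp <- stub_campaign(d, function(x, seed) 0, snapshots = snaps)
  maps <- spatial_sensitivity_maps(camp)
  expect_equal(dim(maps$variance$values), dims)
  expect_equal(dim(maps$fosi_a$values), dims)
  # oracle: recompute each site with the scalar estimators in a loop
  y <- t(vapply(snaps, function(m) as.numeric(m), numeric(prod(dims))))
  for (site in seq_len(prod(dims))) {
    bl <- isruq:::split_blocks(d, y[, site])
    a <- as.numeric(bl$A)
    if (var(a) > 0) {
      expect_equal(maps$variance$values[site], var(a))
      expect_equal(maps$fosi_a$values[site],
                   first_order_index(a, as.numeric(bl$FO[[1]]))$index)
      expect_equal(maps$tsi_b$values[site],
                   total_index(a, as.numeric(bl$TO[[2]]))$index)
      expect_equal(maps$aleatory$values[site],
                   aleatory_variance(a, as.numeric(bl$A_RESEED))$variance)
    } else {
      expect_true(is.na(maps$variance$values[site]))
    }
  }
})

test_that("restenosis probability carries a Wilson interval", {
  sp <- parameter_space("x", 0, 1)
  d <- build_design(sp, M = 25, seed_root = 2)
  camp <- stub_campaign(d, function(x, seed) x[["x"]],
                        restenosis = rep(c(TRUE, FALSE), c(30, 70)))
  rep <- analyze_campaign(camp, K = 100)
  expect_equal(rep$restenosis_probability, 0.3)
  ci <- rep$restenosis_ci
  expect_lt(ci[1], 0.3)
  expect_gt(ci[2], 0.3)
  expect_equal(unname(ci[1]), 0.2189, tolerance = 0.01) # Wilson 95% for 30/100
  expect_equal(unname(ci[2]), 0.3972, tolerance = 0.01)
})
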