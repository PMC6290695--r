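# Shared fixtures: tiny tissue states, analytic test models and
# brute-force oracles used across the suite.

# A bare tissue state from coordinate vectors (all SMC unless stated).
make_tissue <- function(x, y, radius = 0.015, kind = NULL,
                        constrained_x = NULL, clamped = NULL) {
  n <- length(x)
  if (is.null(kind)) kind <- rep(1L, n)
  structure(list(
    id = seq_len(n), kind = as.integer(kind), x = as.numeric(x),
    y = as.numeric(y), radius = rep_len(radius, n),
    bio_state = ifelse(kind == 1L, 1L, NA_integer_),
    covered = ifelse(kind == 1L, FALSE, NA),
    activated = rep(FALSE, n), was_exposed = rep(FALSE, n),
    clock = rep(0, n), duration = rep(NA_real_, n),
    constrained_x = if (is.null(constrained_x)) rep(FALSE, n) else constrained_x,
    clamped = if (is.null(clamped)) rep(FALSE, n) else clamped,
    iel_links = NULL, iel_rest = NULL,
    domain_length = if (n > 0) max(x) + 1 else 1, time = 0,
    removed_count = 0L,
    next_id = n + 1L
  ), class = "isr_tissue")
}

# Ishigami function on [-pi, pi]^3 and its closed-form Sobol decomposition.
ishigami <- function(u, a = 7, b = 0.1) {
  x <- -pi + 2 * pi * u
  sin(x[1]) + a * sin(x[2])^2 + b * x[3]^4 * sin(x[1])
}
ishigami_indices <- function(a = 7, b = 0.1) {
  v1 <- 0.5 * (1 + b * pi^4 / 5)^2
  v2 <- a^2 / 8
  v13 <- b^2 * pi^8 * (1 / 18 - 1 / 50)
  v <- v1 + v2 + v13
  list(S1 = v1 / v * 100, S2 = v2 / v * 100, S3 = 0,
       ST1 = (v1 + v13) / v * 100, ST2 = v2 / v * 100,
       ST3 = v13 / v * 100, total_variance = v)
}

# Brute-force double-loop Monte Carlo first-order index (percent) of
# input i for a deterministic function f(u) on the unit cube.
double_loop_first_order <- function(f, i, n_dims, n_outer = 200,
                                    n_inner = 200) {
  cond_means <- vapply(seq_len(n_outer), function(k) {
    xi <- runif(1)
    mean(vapply(seq_len(n_inner), function(j) {
      u <- runif(n_dims)
      u[i] <- xi
      f(u)
    }, numeric(1)))
  }, numeric(1))
  tot <- vapply(seq_len(n_outer * 4), function(k) f(runif(n_dims)),
                numeric(1))
  var(cond_means) / var(tot) * 100
}

# Brute-force star discrepancy of 2-D points via anchored boxes with
# corners on the point coordinates.
star_discrepancy_2d <- function(pts) {
  xs <- sort(unique(c(pts[, 1], 1)))
  ys <- sort(unique(c(pts[, 2], 1)))
  n <- nrow(pts)
  worst <- 0
  for (xx in xs) {
    inx <- pts[, 1] < xx
    cnt <- vapply(ys, function(yy) sum(inx & pts[, 2] < yy), numeric(1))
    worst <- max(worst, max(abs(cnt / n - xx * ys)))
  }
  worst
}

# Small campaign configuration used by engine/campaign tests: very short
# runs so the suite stays fast.
tiny_config <- function(total_days = 4, ...) {
  coarse_config(total_days = total_days, ...)
}


# straight channel lattice: walls `wall` nodes thick, interior fluid
channel_lattice <- function(nx, ny_fluid, spacing, wall = 2L) {
  ny <- ny_fluid + 2L * wall
  solid <- matrix(FALSE, nx, ny)
  solid[, seq_len(wall)] <- TRUE
  solid[, ny - seq_len(wall) + 1L] <- TRUE
  owner <- matrix(NA_integer_, nx, ny)
  owner[solid] <- 1L
  structure(list(spacing = spacing, origin = c(0, 0), nx = nx, ny = ny,
                 solid = solid, owner = owner), class = "isr_lattice")
}
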