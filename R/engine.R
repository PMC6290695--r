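#' Simulation configuration
#'
#' Geometry, scenario, growth, mechanics and flow settings for one vessel
#' simulation. Defaults describe a small healthy porcine coronary segment:
#' 1.5 mm long, 1 mm lumen, a tunica media of five SMC layers plus an
#' internal elastic lamina, and a square bare-metal stent strut per wall.
#'
#' @param vessel_length mm.
#' @param lumen_diameter mm (channel height between the IEL surfaces).
#' @param media_layers number of SMC layers per wall.
#' @param cell_radius agent radius, mm.
#' @param deployment_depth nominal strut deployment depth, mm.
#' @param deploy_steps stepwise deployment increments.
#' @param strut_size square strut side, mm.
#' @param scenario an `isr_schedule`.
#' @param growth an `isr_growth_params`.
#' @param mechanics an `isr_mechanics_params`.
#' @param flow an `isr_flow_params`.
#' @param reynolds Reynolds number defining the nominal flow velocity.
#' @param total_days simulated duration after deployment, days.
#' @param snapshot_days times (days) at which lattice snapshots are kept;
#'   the final time is always included.
#' @param master_seed default RNG seed for [run_simulation()].
#' @return an `isr_config`.
#' @export
sim_config <- function(vessel_length = 1.5, lumen_diameter = 1.0,
                       media_layers = 5, cell_radius = 0.015,
                       deployment_depth = 0.110, deploy_steps = 10,
                       strut_size = 0.09,
                       scenario = scenario_schedule("S1", 19),
                       growth = growth_params(),
                       mechanics = mechanics_params(),
                       flow = flow_params(),
                       reynolds = 120,
                       total_days = 30,
                       snapshot_days = NULL,
                       master_seed = 1L) {
  stopifnot(vessel_length > 0, lumen_diameter > 0, media_layers >= 1,
            cell_radius > 0, deployment_depth >= 0, strut_size > 0,
            total_days > 0)
  if (is.null(snapshot_days))
    snapshot_days <- unique(c(seq(0, total_days, by = 7)[-1], total_days))
  structure(list(vessel_length = vessel_length,
                 lumen_diameter = lumen_diameter,
                 media_layers = as.integer(media_layers),
                 cell_radius = cell_radius,
                 deployment_depth = deployment_depth,
                 deploy_steps = as.integer(deploy_steps),
                 strut_size = strut_size,
                 scenario = scenario, growth = growth,
                 mechanics = mechanics, flow = flow,
                 reynolds = reynolds,
                 total_days = total_days,
                 snapshot_days = snapshot_days,
                 master_seed = as.integer(master_seed)),
            class = "isr_config")
}

#' Build the initial vessel tissue state
#'
#' Two walls, each `media_layers` staggered rows of SMCs plus an aligned
#' innermost IEL row, separated by the lumen; one square strut per wall
#' sits in the lumen touching the IEL surface. Construction is fully
#' deterministic (cell-cycle durations are drawn only on activation).
#'
#' @param config an `isr_config`.
#' @return an `isr_tissue`.
#' @export
initialize_vessel <- function(config) {
  stopifnot(inherits(config, "isr_config"))
  r <- config$cell_radius
  L <- config$vessel_length
  D <- config$lumen_diameter
  nl <- config$media_layers
  # in-plane pitch at the adhesive two-body equilibrium (overlap a^2), so
  # the constructed lattice starts close to mechanical equilibrium
  p <- 2 * r - config$mechanics$adhesion_coefficient^2
  dy <- sqrt(3) / 2 * p
  if (L < 6 * r || D < 4 * r)
    stop("geometry inconsistent: cells of radius ", r, " do not fit")

  ids <- integer(0); kind <- integer(0); x <- numeric(0); y <- numeric(0)
  nid <- 1L
  add_row <- function(ycen, offset, what) {
    xs <- seq(r + offset, L - r, by = p)
    xs <- xs + (L - r - max(xs) - (min(xs) - r)) / 2 # symmetric margins
    n <- length(xs)
    ids <<- c(ids, nid + seq_len(n) - 1L)
    nid <<- nid + n
    kind <<- c(kind, rep(KIND[[what]], n))
    x <<- c(x, xs)
    y <<- c(y, rep(ycen, n))
    invisible(NULL)
  }
  # bottom wall: SMC rows outside-in, then IEL
  outer_ids <- integer(0)
  for (k in seq_len(nl)) {
    add_row(r + (k - 1) * dy, (k %% 2) * p / 2, "SMC")
    if (k == 1) outer_ids <- ids
  }
  y_iel_b <- r + nl * dy
  add_row(y_iel_b, 0, "IEL")
  iel_b_ids <- ids[kind == KIND[["IEL"]]]
  # top wall mirrored
  y_iel_t <- y_iel_b + D + 2 * r
  add_row(y_iel_t, 0, "IEL")
  iel_t_ids <- setdiff(ids[kind == KIND[["IEL"]]], iel_b_ids)
  for (k in seq_len(nl)) {
    n_before <- length(ids)
    add_row(y_iel_t + k * dy, (k %% 2) * p / 2, "SMC")
    if (k == nl) outer_ids <- c(outer_ids, ids[(n_before + 1):length(ids)])
  }

  # square struts: a grid of fine strut agents (half the cell radius, so
  # the strut surface is smoother than the tissue it indents), the outer
  # row touching the IEL disks. The two struts are staggered by a
  # quarter cell pitch in opposite directions; real stent struts are not
  # perfectly opposed, and the stagger keeps the two walls from
  # rupturing in lock-step.
  rs <- r / 2
  ns <- max(2L, as.integer(round(config$strut_size / (2 * rs))))
  sx0 <- (seq_len(ns) - (ns + 1) / 2) * 2 * rs
  strut_rows_b <- y_iel_b + r + rs + (seq_len(ns) - 1) * 2 * rs
  strut_rows_t <- y_iel_t - r - rs - (seq_len(ns) - 1) * 2 * rs
  strut_idx <- integer(0)
  for (side in c("b", "t")) {
    rows <- if (side == "b") strut_rows_b else strut_rows_t
    sx <- L / 2 + sx0 + (if (side == "b") -p / 4 else p / 4)
    for (yy in rows) {
      n <- length(sx)
      ids <- c(ids, nid + seq_len(n) - 1L)
      nid <- nid + n
      kind <- c(kind, rep(KIND[["STRUT"]], n))
      x <- c(x, sx)
      y <- c(y, rep(yy, n))
    }
  }

  n <- length(ids)
  outer_row <- ids %in% outer_ids
  state <- structure(list(
    id = ids, kind = kind, x = x, y = y,
    radius = ifelse(kind == KIND[["STRUT"]], rs, r),
    bio_state = ifelse(kind == KIND[["SMC"]], BIO[["CONTRACTILE"]], NA_integer_),
    covered = ifelse(kind == KIND[["SMC"]], FALSE, NA),
    activated = rep(FALSE, n),
    was_exposed = rep(FALSE, n),
    clock = rep(0, n),
    duration = rep(NA_real_, n),
    constrained_x = x < 3 * r | x > L - 3 * r,
    # edge columns are clamped (the segment continues into the unstented
    # artery) and so is the outermost SMC row of each wall, which rests
    # on the stiffer outer vessel layers; this backing is what localizes
    # the stent indentation instead of translating the free-floating wall
    clamped = (x < 3 * r | x > L - 3 * r) | outer_row,
    iel_links = NULL, iel_rest = NULL,
    domain_length = L, time = 0, removed_count = 0L,
    next_id = nid
  ), class = "isr_tissue")

  # IEL chain links between consecutive agents of each row
  link <- function(row_ids) {
    ord <- row_ids[order(state$x[match(row_ids, state$id)])]
    if (length(ord) < 2) return(NULL)
    cbind(ord[-length(ord)], ord[-1])
  }
  links <- rbind(link(iel_b_ids), link(iel_t_ids))
  state$iel_links <- links
  state$iel_rest <- rep(p, nrow(links))

  # lattice bounding box ends at the clamped outer-row centers: the
  # outer half of those rows (and anything beyond) is never fluid
  wall_h <- nl * dy + 2 * r # outer SMC surface to IEL inner surface
  attr(state, "bbox") <- c(0, L, r, y_iel_t + nl * dy)
  attr(state, "lumen_mid") <- (y_iel_b + y_iel_t) / 2
  attr(state, "media_thickness") <- wall_h
  # settle the lattice (deterministic): row re-centering leaves small
  # residual tether forces at the row ends
  equilibrate(state, config$mechanics)
}

#' @export
print.isr_tissue <- function(x, ...) {
  tb <- table(factor(names(KIND)[x$kind], levels = names(KIND)))
  cat("tissue state:", length(x$id), "agents (",
      paste(names(tb), tb, sep = "=", collapse = ", "), ")\n")
  cat("time:", x$time / 24, "days; removed:", x$removed_count, "\n")
  invisible(x)
}

#' Mean lumen width of a lattice
#'
#' Per column, the lumen width is the length of the largest contiguous run
#' of fluid nodes times the spacing; the mean over all columns is
#' returned (0 for a fully solid lattice).
#'
#' @param lat an `isr_lattice`.
#' @return mean width, mm.
#' @export
mean_lumen_width <- function(lat) {
  stopifnot(inherits(lat, "isr_lattice"))
  runs <- apply(!lat$solid, 1, largest_fluid_run)
  mean(runs[2, ]) * lat$spacing
}

#' Neointimal cross-sectional area from the mean lumen width
#'
#' The lumen is treated as a circle with the measured mean width as its
#' diameter; the neointimal area is the baseline post-stenting lumen area
#' minus the current circle area, floored at zero.
#'
#' @param width mean lumen width, mm.
#' @param baseline_lumen_area initial post-stenting lumen area, mm^2.
#' @return neointimal area, mm^2.
#' @export
neointimal_area <- function(width, baseline_lumen_area) {
  stopifnot(all(width >= 0))
  pmax(0, baseline_lumen_area - pi * (width / 2)^2)
}

#' Restenosis criterion
#'
#' TRUE iff the neointimal area strictly exceeds 50% of the original
#' cross-sectional lumen area.
#'
#' @param final_area neointimal area, mm^2.
#' @param original_lumen_area pre-stenting lumen area, mm^2.
#' @return logical.
#' @export
restenosis_flag <- function(final_area, original_lumen_area) {
  stopifnot(all(final_area >= 0), all(original_lumen_area >= 0))
  final_area > 0.5 * original_lumen_area
}

#' Run one in-stent restenosis simulation
#'
#' Deploys the stent, records the baseline post-stenting lumen area, then
#' advances the coupled model (flow and wall shear stress, biological
#' state update, stochastic re-endothelialization, cell cycling and
#' mitosis) for `total_days`. Identical (config, inputs, seed) give
#' bit-identical trajectories.
#'
#' @param config an `isr_config`.
#' @param inputs named list or vector overriding the uncertain inputs:
#'   `flow_velocity` (m/s), `deployment_depth` (mm), `regen_time` (days).
#'   Missing entries fall back to the config.
#' @param seed integer RNG seed for the run's single stochastic stream.
#' @return an `isr_trajectory`: time series of neointimal area, mean
#'   lumen width and endothelium coverage, lattice snapshots, and the
#'   restenosis flag.
#' @export
run_simulation <- function(config, inputs = list(), seed = config$master_seed) {
  stopifnot(inherits(config, "isr_config"))
  inputs <- as.list(inputs)
  velocity <- inputs$flow_velocity %||%
    reynolds_velocity(config$reynolds, config$flow$viscosity,
                      config$flow$density, config$lumen_diameter * 1e-3)
  depth <- inputs$deployment_depth %||% config$deployment_depth
  sched <- config$scenario
  if (!is.null(inputs$regen_time))
    sched <- scenario_schedule(sched$scenario, inputs$regen_time,
                               min(sched$fast_recovery_time,
                                   inputs$regen_time / 2),
                               sched$fast_recovery_degree)
  gp <- config$growth
  mech <- config$mechanics
  fp <- config$flow
  # growth-phase relaxation: overlaps introduced by single divisions are
  # local, so a looser tolerance and iteration cap suffice (residual
  # stress relaxes further on subsequent steps)
  mech_relax <- mech
  mech_relax$equilibration_tolerance <- 10 * mech$equilibration_tolerance
  mech_relax$max_equilibration_iters <-
    min(mech$max_equilibration_iters, 120L)
  set.seed(as.integer(seed))

  state <- initialize_vessel(config)
  bbox <- attr(state, "bbox")
  state <- deploy_stent(state, depth, config$deploy_steps, mech)
  attr(state, "bbox") <- bbox

  lat <- rasterize(state, fp$spacing, bbox, inflate = fp$spacing / 2)
  w0 <- mean_lumen_width(lat)
  baseline_area <- pi * (w0 / 2)^2
  original_area <- pi * (config$lumen_diameter / 2)^2
  flux <- velocity * config$lumen_diameter * 1e-3 # constant, m^2/s

  step_h <- gp$step
  n_steps <- ceiling(config$total_days * 24 / step_h)
  times <- numeric(n_steps + 1)
  area <- width <- coverage <- numeric(n_steps + 1)
  times[1] <- 0; width[1] <- w0; area[1] <- 0; coverage[1] <- 0
  snapshots <- list()
  snap_due <- sort(unique(c(config$snapshot_days, config$total_days)))
  closed <- FALSE

  for (k in seq_len(n_steps)) {
    t_days <- (k - 1) * step_h / 24
    dt_days <- step_h / 24
    flow <- tryCatch(solve_flow(lat, fp, flux),
                     isr_lumen_closed = function(e) NULL)
    if (is.null(flow)) { closed <- TRUE }
    if (!closed) {
      wss <- wall_shear_stress(flow, lat, state)
      # clamped boundary cells are not part of the modelled biology
      bdry <- state$id[state$clamped]
      wss <- wss[!(as.integer(names(wss)) %in% bdry)]
      exposed <- as.integer(names(wss))
      is_exp <- state$id %in% exposed & state$kind == KIND[["SMC"]]
      state$activated[is_exp] <- TRUE
      state$was_exposed[is_exp] <- TRUE
      state <- update_cell_states(state, wss, gp)
      fresh <- which(state$bio_state == BIO[["SYNTHETIC"]] &
                       state$kind == KIND[["SMC"]] & is.na(state$duration))
      if (length(fresh) > 0)
        state$duration[fresh] <- sample_cycle_duration(length(fresh), gp)
      state <- endothelium_update(state, sched, t_days, dt_days, exposed)
      state <- attempt_mitosis(state, gp, mech_relax)
      state$time <- k * step_h
      lat <- rasterize(state, fp$spacing, bbox, inflate = fp$spacing / 2)
    }
    times[k + 1] <- k * step_h / 24
    if (closed) {
      width[k + 1] <- 0
      area[k + 1] <- baseline_area
      coverage[k + 1] <- coverage[k]
    } else {
      width[k + 1] <- mean_lumen_width(lat)
      area[k + 1] <- neointimal_area(width[k + 1], baseline_area)
      smc <- state$kind == KIND[["SMC"]] & state$activated
      coverage[k + 1] <- if (any(smc)) mean(state$covered[smc]) else 0
    }
    t_next <- k * step_h / 24
    if (length(snap_due) > 0 && t_next + 1e-9 >= snap_due[1]) {
      snapshots[[sprintf("day_%05.1f", snap_due[1])]] <-
        list(day = snap_due[1], solid = lat$solid)
      snap_due <- snap_due[-1]
    }
  }
  # snapshots still pending (closure or rounding): hold the final mask
  for (d in snap_due)
    snapshots[[sprintf("day_%05.1f", d)]] <- list(day = d, solid = lat$solid)

  final_area <- area[n_steps + 1]
  structure(list(times = times, neointimal_area = area,
                 mean_lumen_width = width, coverage = coverage,
                 baseline_lumen_area = baseline_area,
                 original_lumen_area = original_area,
                 snapshots = snapshots,
                 restenosis = closed || restenosis_flag(final_area, original_area),
                 closed = closed,
                 inputs = list(flow_velocity = velocity,
                               deployment_depth = depth,
                               regen_time = sched$total_recovery_time),
                 seed = as.integer(seed),
                 spacing = fp$spacing),
            class = "isr_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.isr_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat("restenosis trajectory:", round(x$times[n], 1), "days,",
      "final neointimal area", signif(x$neointimal_area[n], 3), "mm^2\n")
  cat("baseline post-stent lumen area", signif(x$baseline_lumen_area, 3),
      "mm^2; restenosis:", x$restenosis, "\n")
  invisible(x)
}

#' @export
plot.isr_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$neointimal_area, type = "l",
                 xlab = "time (days)", ylab = "neointimal area (mm^2)", ...)
  graphics::abline(h = 0.5 * x$original_lumen_area, lty = 2)
  invisible(x)
}

#' Desk-scale campaign configuration
#'
#' A coarsened vessel for uncertainty-quantification campaigns: larger
#' cells (22.5 um radius), a shorter segment, a coarser lattice and an
#' 8-hour cell step, so that one 16-day run takes seconds instead of
#' minutes. Mechanical removal thresholds are rescaled by the Hertzian
#' contact-force factor (r/0.015)^1.5 so the deployment damage pattern is
#' consistent with the full-resolution geometry.
#'
#' @param scenario an `isr_schedule`.
#' @param total_days simulated duration, days.
#' @param ... further overrides passed to [sim_config()].
#' @return an `isr_config`.
#' @export
coarse_config <- function(scenario = scenario_schedule("S1", 19),
                          total_days = 25, ...) {
  r <- 0.0225
  fac <- (r / 0.015)^1.5
  defaults <- list(vessel_length = 1.2, cell_radius = r, strut_size = 0.09,
                   scenario = scenario,
                   growth = growth_params(step = 8),
                   mechanics = mechanics_params(smc_stress_threshold = 2.0 * fac,
                                                iel_stress_threshold = 2.0 * fac),
                   flow = flow_params(spacing = 0.02),
                   total_days = total_days, deploy_steps = 8)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}
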