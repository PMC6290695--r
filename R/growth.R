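#' Re-endothelialization scenario schedule
#'
#' Target endothelium coverage c(t). Scenario 1: fast partial recovery to
#' `fast_recovery_degree` (default 59%) at `fast_recovery_time` (default
#' 3 days), then linear to full coverage at the total recovery time T.
#' Scenario 2: linear from zero to full coverage over [0, T]. T is the
#' model's uncertain regeneration-time input (15-23 days).
#'
#' @param scenario "S1" or "S2".
#' @param total_recovery_time T, days.
#' @param fast_recovery_time days (Scenario 1 only).
#' @param fast_recovery_degree fraction (Scenario 1 only).
#' @return an `isr_schedule`.
#' @export
#' @examples
#' coverage_target(scenario_schedule("S1", 19), 3)  # 0.59
scenario_schedule <- function(scenario = c("S1", "S2"),
                              total_recovery_time,
                              fast_recovery_time = 3,
                              fast_recovery_degree = 0.59) {
  scenario <- match.arg(scenario)
  stopifnot(total_recovery_time > 0,
            fast_recovery_time > 0, fast_recovery_time < total_recovery_time,
            fast_recovery_degree >= 0, fast_recovery_degree <= 1)
  structure(list(scenario = scenario,
                 total_recovery_time = total_recovery_time,
                 fast_recovery_time = fast_recovery_time,
                 fast_recovery_degree = fast_recovery_degree),
            class = "isr_schedule")
}

#' Target endothelium coverage at a time
#'
#' @param sched an `isr_schedule`.
#' @param t time in days (>= 0; vectorised).
#' @return coverage fraction in [0, 1], clamped at 1 for t >= T.
#' @export
coverage_target <- function(sched, t) {
  stopifnot(inherits(sched, "isr_schedule"))
  if (any(t < 0)) stop("coverage is undefined for negative time")
  T <- sched$total_recovery_time
  if (sched$scenario == "S2") return(pmin(1, t / T))
  t1 <- sched$fast_recovery_time
  c1 <- sched$fast_recovery_degree
  ifelse(t <= t1, c1 * t / t1,
         pmin(1, c1 + (1 - c1) * (t - t1) / (T - t1)))
}

#' Stochastic update of endothelium coverage
#'
#' Each uncovered flow-exposed SMC becomes covered independently with
#' probability p = max(0, (c(t+dt) - c(t)) / (1 - c(t))) (p = 1 once
#' c(t) = 1), so that the expected covered fraction of an always-exposed
#' cohort tracks the target curve exactly. Coverage is never revoked.
#' Uses R's global RNG stream.
#'
#' @param state an `isr_tissue`.
#' @param sched an `isr_schedule`.
#' @param t current time, days.
#' @param dt step, days (> 0).
#' @param exposed_ids ids of flow-exposed SMCs (default: all SMCs).
#' @return the updated `isr_tissue`.
#' @export
endothelium_update <- function(state, sched, t, dt,
                               exposed_ids = state$id[state$kind == KIND[["SMC"]]]) {
  stopifnot(inherits(state, "isr_tissue"), dt > 0)
  c0 <- coverage_target(sched, t)
  c1 <- coverage_target(sched, t + dt)
  p <- if (c0 >= 1) 1 else max(0, (c1 - c0) / (1 - c0))
  cand <- which(state$id %in% exposed_ids &
                  state$kind == KIND[["SMC"]] & !state$covered)
  if (length(cand) > 0 && p > 0)
    state$covered[cand] <- runif(length(cand)) < p
  state
}

#' Cell growth parameters
#'
#' @param cycle_mean mean SMC cell-cycle duration, hours.
#' @param cycle_sd cell-cycle standard deviation, hours.
#' @param wss_no_threshold wall shear stress (Pa) above which an
#'   endothelium-covered SMC is nitric-oxide inhibited. The default (1 Pa)
#'   sits well below the unobstructed plane-Poiseuille wall value
#'   (11.52 Pa at the nominal flow): covered cells are then inhibited on
#'   the open lumen and in most recirculating recesses, so that the
#'   re-endothelialization scenario — not the flow pattern — controls
#'   when growth stops.
#' @param contact_neighbor_limit an SMC with at least this many contact
#'   neighbours is contact inhibited.
#' @param step cell-model time step, hours.
#' @return an `isr_growth_params`.
#' @export
growth_params <- function(cycle_mean = 32, cycle_sd = 2,
                          wss_no_threshold = 1.0,
                          contact_neighbor_limit = 5,
                          step = 1) {
  stopifnot(cycle_mean > 0, cycle_sd >= 0, step > 0,
            contact_neighbor_limit >= 0, wss_no_threshold >= 0)
  structure(list(cycle_mean = cycle_mean, cycle_sd = cycle_sd,
                 wss_no_threshold = wss_no_threshold,
                 contact_neighbor_limit = contact_neighbor_limit,
                 step = step),
            class = "isr_growth_params")
}

#' Sample SMC cell-cycle durations
#'
#' Draws from Normal(cycle_mean, cycle_sd) truncated to strictly positive
#' values (at the defaults, 32 +/- 2 h, the truncation is negligible).
#' Uses R's global RNG stream.
#'
#' @param n number of draws.
#' @param params an `isr_growth_params`.
#' @return numeric vector of durations, hours.
#' @export
sample_cycle_duration <- function(n = 1, params = growth_params()) {
  out <- rnorm(n, params$cycle_mean, params$cycle_sd)
  bad <- which(out <= 0)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), params$cycle_mean, params$cycle_sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Update SMC biological states
#'
#' An SMC is CONTACT_INHIBITED iff its contact-neighbour count reaches
#' the limit; else NO_INHIBITED iff it is endothelium-covered and its
#' wall shear stress is at or above the threshold; otherwise SYNTHETIC if
#' it has been activated (exposed by IEL rupture, or descended from an
#' activated cell), else CONTRACTILE. Inhibited cells' cycle clocks pause
#' (the clock only advances for SYNTHETIC cells, in [attempt_mitosis()]).
#'
#' @param state an `isr_tissue`.
#' @param wss named numeric vector: WSS in Pa for flow-adjacent SMC ids.
#' @param params an `isr_growth_params`.
#' @return the updated `isr_tissue`.
#' @export
update_cell_states <- function(state, wss, params) {
  stopifnot(inherits(state, "isr_tissue"), inherits(params, "isr_growth_params"))
  smc <- state$kind == KIND[["SMC"]]
  if (!any(smc)) return(state)
  w <- wss[as.character(state$id)]
  w[is.na(w)] <- -Inf  # no flow adjacency: never NO-inhibited
  # neighbour = center distance < 1.3*(ri+rj): wide enough to count packed
  # neighbours in imperfectly relaxed tissue; a flat free surface cell
  # keeps ~4 neighbours, interior and concave cells reach the limit
  nb <- neighbor_counts_cpp(state$x, state$y, state$radius, 1.3)
  ct_inh <- smc & nb >= params$contact_neighbor_limit
  no_inh <- smc & !ct_inh & state$covered & w >= params$wss_no_threshold
  syn <- smc & !no_inh & !ct_inh & state$activated
  ctr <- smc & !no_inh & !ct_inh & !state$activated
  state$bio_state[no_inh] <- BIO[["NO_INHIBITED"]]
  state$bio_state[ct_inh] <- BIO[["CONTACT_INHIBITED"]]
  state$bio_state[syn] <- BIO[["SYNTHETIC"]]
  state$bio_state[ctr] <- BIO[["CONTRACTILE"]]
  state
}

#' Advance cell cycles and perform mitosis
#'
#' Every SYNTHETIC SMC advances its cycle clock by the model step; a cell
#' reaching its cycle duration divides: the daughter is placed at a
#' uniformly random angle at a distance of one radius, both cells draw
#' fresh cycle durations and reset their clocks, and a mechanical
#' relaxation resolves the overlap. Daughters inherit activation and start
#' uncovered. Uses R's global RNG stream.
#'
#' @param state an `isr_tissue`.
#' @param params an `isr_growth_params`.
#' @param mech an `isr_mechanics_params` for the post-division relaxation.
#' @return the updated `isr_tissue`.
#' @export
attempt_mitosis <- function(state, params, mech = mechanics_params()) {
  stopifnot(inherits(state, "isr_tissue"), inherits(params, "isr_growth_params"))
  syn <- which(state$bio_state == BIO[["SYNTHETIC"]] &
                 state$kind == KIND[["SMC"]])
  if (length(syn) == 0) return(state)
  state$clock[syn] <- state$clock[syn] + params$step
  divide <- syn[state$clock[syn] >= state$duration[syn]]
  if (length(divide) == 0) return(state)
  for (i in divide) {
    ang <- runif(1, 0, 2 * pi)
    r <- state$radius[i]
    nid <- state$next_id
    state$next_id <- nid + 1L
    state$id <- c(state$id, nid)
    state$kind <- c(state$kind, KIND[["SMC"]])
    state$x <- c(state$x, state$x[i] + r * cos(ang))
    state$y <- c(state$y, state$y[i] + r * sin(ang))
    state$radius <- c(state$radius, r)
    state$bio_state <- c(state$bio_state, BIO[["SYNTHETIC"]])
    state$covered <- c(state$covered, FALSE)
    state$activated <- c(state$activated, TRUE)
    state$was_exposed <- c(state$was_exposed, FALSE)
    state$clock <- c(state$clock, 0)
    state$duration <- c(state$duration, sample_cycle_duration(1, params))
    state$constrained_x <- c(state$constrained_x, FALSE)
    state$clamped <- c(state$clamped, FALSE)
    state$clock[i] <- 0
    state$duration[i] <- sample_cycle_duration(1, params)
  }
  equilibrate(state, mech)
}
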