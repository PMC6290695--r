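# Agent kinds and biological states are stored as integer codes inside the
# tissue state for speed; these constants are the single source of truth.
KIND <- c(SMC = 1L, IEL = 2L, STRUT = 3L)
BIO <- c(CONTRACTILE = 1L, SYNTHETIC = 2L, NO_INHIBITED = 3L,
         CONTACT_INHIBITED = 4L)

#' Mechanical interaction parameters
#'
#' Pairwise force law between agents: Hertzian repulsion
#' F = k_h * overlap^(3/2) with a linear adhesive correction
#' -a * k_h * overlap inside contact (giving a stable equilibrium overlap
#' of a^2 mm for an isolated pair), and a Hookean extracellular-matrix
#' tether for gaps up to `tether_range` (linearly tapered over the outer
#' half of the range so the force is continuous at the cutoff). Agents
#' sustaining excessive contact stress (sum of contact-force magnitudes),
#' or for IEL agents excessive chain strain, are removed during stent
#' deployment.
#'
#' Stress/strain thresholds and stiffnesses are not published for the
#' original model; the defaults here are calibrated once so that a nominal
#' 110 micrometre deployment ruptures the IEL near the strut while a zero
#' depth deployment removes nothing.
#'
#' @param hertz_stiffness contact stiffness, force/mm^1.5.
#' @param adhesion_coefficient dimensionless adhesive correction.
#' @param tether_stiffness Hookean tether stiffness, force/mm.
#' @param tether_range tether reach beyond contact, mm.
#' @param smc_stress_threshold removal threshold for SMC contact stress.
#' @param iel_stress_threshold removal threshold for IEL contact stress.
#' @param iel_strain_threshold removal threshold for IEL chain strain
#'   (relative extension of the link to a chain neighbour).
#' @param equilibration_tolerance residual-force convergence tolerance.
#' @param max_equilibration_iters iteration cap for the relaxation.
#' @return an `isr_mechanics_params` list.
#' @export
mechanics_params <- function(hertz_stiffness = 1e4,
                             adhesion_coefficient = 0.017,
                             tether_stiffness = 20,
                             tether_range = 0.015,
                             smc_stress_threshold = 2.0,
                             iel_stress_threshold = 2.0,
                             iel_strain_threshold = 0.45,
                             equilibration_tolerance = 5e-4,
                             max_equilibration_iters = 4000) {
  p <- list(hertz_stiffness = hertz_stiffness,
            adhesion_coefficient = adhesion_coefficient,
            tether_stiffness = tether_stiffness,
            tether_range = tether_range,
            smc_stress_threshold = smc_stress_threshold,
            iel_stress_threshold = iel_stress_threshold,
            iel_strain_threshold = iel_strain_threshold,
            equilibration_tolerance = equilibration_tolerance,
            max_equilibration_iters = max_equilibration_iters)
  if (any(unlist(p[1:8]) <= 0) || max_equilibration_iters < 1)
    stop("all mechanical stiffnesses, thresholds and tolerances must be > 0")
  structure(p, class = "isr_mechanics_params")
}

#' Pairwise force between two agents
#'
#' Force exerted on agent `a` by agent `b`; the force on `b` is the exact
#' negation. See [mechanics_params()] for the force law.
#'
#' @param a,b agents: lists with `position` (length-2, mm) and `radius` (mm).
#' @param params an `isr_mechanics_params`.
#' @return length-2 numeric force vector on `a`.
#' @export
#' @examples
#' p <- mechanics_params()
#' a <- list(position = c(0, 0), radius = 0.015)
#' b <- list(position = c(0.029, 0), radius = 0.015)
#' pair_force(a, b, p)
pair_force <- function(a, b, params) {
  stopifnot(inherits(params, "isr_mechanics_params"))
  pair_force_cpp(a$position[1], a$position[2], b$position[1], b$position[2],
                 a$radius, b$radius,
                 params$hertz_stiffness, params$adhesion_coefficient,
                 params$tether_stiffness, params$tether_range)
}

# All forces + contact stress on a tissue state (internal). IEL chain
# links act as Hookean springs with stiffness = tether_stiffness.
tissue_forces <- function(state, params) {
  lk <- chain_indices(state)
  forces_cpp(state$x, state$y, state$radius,
             state$kind == KIND[["STRUT"]],
             lk$i1, lk$i2, lk$rest, params$tether_stiffness,
             params$hertz_stiffness, params$adhesion_coefficient,
             params$tether_stiffness, params$tether_range)
}

# 0-based index pairs + rest lengths of the live IEL chain links.
chain_indices <- function(state) {
  if (is.null(state$iel_links) || nrow(state$iel_links) == 0)
    return(list(i1 = integer(), i2 = integer(), rest = numeric()))
  i1 <- match(state$iel_links[, 1], state$id)
  i2 <- match(state$iel_links[, 2], state$id)
  keep <- !is.na(i1) & !is.na(i2)
  list(i1 = i1[keep] - 1L, i2 = i2[keep] - 1L, rest = state$iel_rest[keep])
}

#' Relax a tissue state to mechanical equilibrium
#'
#' Overdamped iterative relaxation until the largest residual force on a
#' free agent drops below `equilibration_tolerance` or the iteration cap
#' is reached (non-convergence is flagged, not fatal). Agents listed in
#' `fixed_ids` do not move; agents flagged as edge cells are constrained
#' horizontally.
#'
#' @param state an `isr_tissue`.
#' @param params an `isr_mechanics_params`.
#' @param fixed_ids ids of agents to hold fixed (strut agents are always
#'   held in addition).
#' @return the relaxed `isr_tissue`; attribute `converged` reports the
#'   outcome, `max_resid` the final residual.
#' @export
equilibrate <- function(state, params, fixed_ids = integer()) {
  stopifnot(inherits(state, "isr_tissue"),
            inherits(params, "isr_mechanics_params"))
  if (length(state$id) == 0) return(state)
  if (!all(fixed_ids %in% state$id))
    stop("fixed_ids must be a subset of agent ids")
  fixed <- state$id %in% fixed_ids | state$kind == KIND[["STRUT"]] |
    (if (is.null(state$clamped)) FALSE else state$clamped)
  lk <- chain_indices(state)
  res <- equilibrate_cpp(state$x, state$y, state$radius, fixed,
                         state$constrained_x & !fixed,
                         state$kind == KIND[["STRUT"]],
                         lk$i1, lk$i2, lk$rest, params$tether_stiffness,
                         params$hertz_stiffness, params$adhesion_coefficient,
                         params$tether_stiffness, params$tether_range,
                         params$equilibration_tolerance,
                         as.integer(params$max_equilibration_iters))
  state$x <- res$x
  state$y <- res$y
  attr(state, "converged") <- res$converged
  attr(state, "max_resid") <- res$max_resid
  state
}

# Per-agent contact stress and (for IEL) chain strain.
agent_loads <- function(state, params) {
  f <- tissue_forces(state, params)
  strain <- rep(NA_real_, length(state$id))
  if (!is.null(state$iel_links) && nrow(state$iel_links) > 0) {
    i1 <- match(state$iel_links[, 1], state$id)
    i2 <- match(state$iel_links[, 2], state$id)
    keep <- !is.na(i1) & !is.na(i2)
    if (any(keep)) {
      i1 <- i1[keep]; i2 <- i2[keep]
      rest <- state$iel_rest[keep]
      d <- sqrt((state$x[i1] - state$x[i2])^2 + (state$y[i1] - state$y[i2])^2)
      s <- (d - rest) / rest
      for (k in seq_along(i1)) {
        strain[i1[k]] <- max(strain[i1[k]], s[k], na.rm = TRUE)
        strain[i2[k]] <- max(strain[i2[k]], s[k], na.rm = TRUE)
      }
    }
  }
  list(stress = f$stress, strain = strain)
}

#' Remove mechanically overloaded agents
#'
#' SMC agents are removed when their contact stress exceeds the SMC
#' threshold; IEL agents when their stress exceeds the IEL threshold or
#' the relative extension of a link to a chain neighbour exceeds the
#' strain threshold. Strut agents are never removed.
#'
#' @param state an `isr_tissue`.
#' @param params an `isr_mechanics_params`.
#' @return list(state, removed_ids).
#' @export
remove_overloaded <- function(state, params) {
  stopifnot(inherits(state, "isr_tissue"),
            inherits(params, "isr_mechanics_params"))
  if (length(state$id) == 0)
    return(list(state = state, removed_ids = integer()))
  loads <- agent_loads(state, params)
  smc <- state$kind == KIND[["SMC"]] & loads$stress > params$smc_stress_threshold
  iel <- state$kind == KIND[["IEL"]] &
    (loads$stress > params$iel_stress_threshold |
       (!is.na(loads$strain) & loads$strain > params$iel_strain_threshold))
  drop <- smc | iel
  # clamped boundary agents carry artificial constraint stress: exempt
  if (!is.null(state$clamped)) drop <- drop & !state$clamped
  removed <- state$id[drop]
  state <- drop_agents(state, removed)
  list(state = state, removed_ids = removed)
}

# Remove agents by id, keeping IEL chain bookkeeping consistent.
drop_agents <- function(state, ids) {
  if (length(ids) == 0) return(state)
  keep <- !(state$id %in% ids)
  for (fld in c("id", "kind", "x", "y", "radius", "bio_state", "covered",
                "activated", "was_exposed", "clock", "duration",
                "constrained_x", "clamped"))
    if (!is.null(state[[fld]])) state[[fld]] <- state[[fld]][keep]
  if (!is.null(state$iel_links) && nrow(state$iel_links) > 0) {
    lk <- !(state$iel_links[, 1] %in% ids) & !(state$iel_links[, 2] %in% ids)
    state$iel_links <- state$iel_links[lk, , drop = FALSE]
    state$iel_rest <- state$iel_rest[lk]
  }
  state$removed_count <- state$removed_count + sum(!keep)
  state
}

#' Deploy the stent by stepwise strut displacement
#'
#' Moves each strut outward into its wall in `n_steps` equal increments;
#' after each increment the tissue is relaxed to equilibrium and
#' overloaded agents are removed. Deployment is deterministic.
#'
#' @param state an `isr_tissue` containing strut agents.
#' @param depth total outward strut displacement, mm (>= 0).
#' @param n_steps number of equal increments (>= 1).
#' @param params an `isr_mechanics_params`.
#' @return the post-deployment `isr_tissue`.
#' @export
deploy_stent <- function(state, depth, n_steps = 10, params = mechanics_params()) {
  stopifnot(inherits(state, "isr_tissue"), depth >= 0, n_steps >= 1)
  media <- attr(state, "media_thickness")
  if (!is.null(media) && depth >= media)
    stop("deployment depth ", depth, " mm would destroy the full media (",
         media, " mm)")
  strut <- state$kind == KIND[["STRUT"]]
  if (!any(strut) || depth == 0) {
    state <- equilibrate(state, params)
    return(state)
  }
  # struts above the lumen midline deploy upward, below deploy downward
  midline <- attr(state, "lumen_mid")
  if (is.null(midline)) midline <- mean(range(state$y))
  dirn <- ifelse(state$y[strut] > midline, 1, -1)
  inc <- depth / n_steps
  for (s in seq_len(n_steps)) {
    strut <- state$kind == KIND[["STRUT"]]
    state$y[strut] <- state$y[strut] + dirn * inc
    state <- equilibrate(state, params)
    state <- remove_overloaded(state, params)$state
  }
  state
}
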