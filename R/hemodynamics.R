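#' Mean flow velocity from a Reynolds number
#'
#' U = Re * mu / (rho * D). At the nominal configuration (Re = 120,
#' mu = 4 mPa s, rho = 1000 kg/m^3, D = 1 mm) this gives 0.48 m/s.
#'
#' @param Re Reynolds number (> 0).
#' @param mu dynamic viscosity, Pa s (> 0).
#' @param rho density, kg/m^3 (> 0).
#' @param D lumen diameter (channel height), m (> 0).
#' @return mean velocity, m/s.
#' @export
#' @examples
#' reynolds_velocity(120, 0.004, 1000, 0.001)  # 0.48
reynolds_velocity <- function(Re, mu, rho, D) {
  if (any(c(Re, mu, rho, D) <= 0))
    stop("Re, mu, rho and D must all be positive")
  Re * mu / (rho * D)
}

#' Flow model parameters
#'
#' @param viscosity dynamic viscosity, Pa s.
#' @param density kg/m^3.
#' @param spacing lattice spacing, mm.
#' @param mode "lubrication" (per-column Poiseuille at the local gap,
#'   cheap campaign default) or "lbm" (D2Q9 lattice-Boltzmann reference).
#' @param tol relative convergence tolerance (lbm).
#' @param max_iter iteration cap (lbm).
#' @param lattice_u target mean lattice velocity (lbm Mach control).
#' @return an `isr_flow_params`.
#' @export
flow_params <- function(viscosity = 0.004, density = 1000, spacing = 0.01,
                        mode = c("lubrication", "lbm"), tol = 1e-6,
                        max_iter = 200000, lattice_u = 0.05) {
  mode <- match.arg(mode)
  stopifnot(viscosity > 0, density > 0, spacing > 0, tol > 0)
  structure(list(viscosity = viscosity, density = density, spacing = spacing,
                 mode = mode, tol = tol, max_iter = max_iter,
                 lattice_u = lattice_u),
            class = "isr_flow_params")
}

#' Rasterize a tissue state onto a uniform lattice
#'
#' A node is solid iff its center lies within any agent disk; each solid
#' node also records the id of the nearest covering agent (its owner).
#'
#' @param state an `isr_tissue` (an empty state gives an all-fluid mask).
#' @param spacing lattice spacing, mm.
#' @param bbox optional c(xmin, xmax, ymin, ymax) in mm; defaults to the
#'   state's stored bounding box.
#' @param inflate radius inflation, mm (default 0: a node is solid exactly
#'   when its center lies in a disk). The simulation engine rasterizes
#'   with `inflate = spacing/2` so that the sub-node throats between
#'   touching cells do not read as fluid channels.
#' @return an `isr_lattice`: spacing, origin, nx, ny, `solid` (nx x ny
#'   logical matrix) and `owner` (integer matrix, NA on fluid nodes).
#' @export
rasterize <- function(state, spacing, bbox = NULL, inflate = 0) {
  stopifnot(spacing > 0, inflate >= 0)
  if (is.null(bbox)) bbox <- attr(state, "bbox")
  if (is.null(bbox)) {
    if (length(state$id) == 0) stop("empty state needs an explicit bbox")
    pad <- max(state$radius)
    bbox <- c(min(state$x) - pad, max(state$x) + pad,
              min(state$y) - pad, max(state$y) + pad)
  }
  nx <- max(1L, as.integer(ceiling((bbox[2] - bbox[1]) / spacing)))
  ny <- max(1L, as.integer(ceiling((bbox[4] - bbox[3]) / spacing)))
  xs <- bbox[1] + (seq_len(nx) - 0.5) * spacing
  ys <- bbox[3] + (seq_len(ny) - 0.5) * spacing
  solid <- matrix(FALSE, nx, ny)
  owner <- matrix(NA_integer_, nx, ny)
  best <- matrix(Inf, nx, ny)
  for (k in seq_along(state$id)) {
    r <- state$radius[k] + inflate
    ix <- which(xs >= state$x[k] - r & xs <= state$x[k] + r)
    iy <- which(ys >= state$y[k] - r & ys <= state$y[k] + r)
    if (length(ix) == 0 || length(iy) == 0) next
    d2 <- outer((xs[ix] - state$x[k])^2, (ys[iy] - state$y[k])^2, `+`)
    inside <- d2 <= r * r
    if (!any(inside)) next
    sub_best <- best[ix, iy, drop = FALSE]
    take <- inside & d2 < sub_best
    solid[ix, iy][inside] <- TRUE
    owner[ix, iy][take] <- state$id[k]
    best[ix, iy][take] <- d2[take]
  }
  structure(list(spacing = spacing, origin = c(bbox[1], bbox[3]),
                 nx = nx, ny = ny, solid = solid, owner = owner),
            class = "isr_lattice")
}

# Lumen gap in a logical fluid column: the largest contiguous fluid run
# bounded by solid on both sides (the lumen proper). Falls back to the
# largest run overall when no interior run exists (e.g. an all-fluid
# column), and returns c(0, 0) when fully solid.
largest_fluid_run <- function(fluid) {
  r <- rle(fluid)
  if (!any(r$values)) return(c(0L, 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  interior <- runs[starts[runs] > 1 & ends[runs] < length(fluid)]
  cand <- if (length(interior) > 0) interior else runs
  best <- cand[which.max(r$lengths[cand])]
  c(starts[best], r$lengths[best])
}

#' Solve steady flow through the lattice
#'
#' Plane channel flow at fixed volumetric flux per unit depth
#' (`target_flux`, m^2/s): either a quasi-1D lubrication solution
#' (per-column Poiseuille profile over the local lumen gap; the campaign
#' default) or the D2Q9 BGK lattice-Boltzmann reference with half-way
#' bounce-back walls and a flux-scaled parabolic inlet. The inlet profile
#' is rescaled on every solve so the flux stays at `target_flux` as the
#' lumen narrows.
#'
#' @param lat an `isr_lattice`.
#' @param params an `isr_flow_params`.
#' @param target_flux volumetric flux per unit depth, m^2/s.
#' @return an `isr_flow`: velocity matrices `ux`, `uy` (m/s), the lattice,
#'   flux, and solver diagnostics.
#' @export
solve_flow <- function(lat, params, target_flux) {
  stopifnot(inherits(lat, "isr_lattice"), inherits(params, "isr_flow_params"),
            target_flux >= 0)
  dx <- lat$spacing * 1e-3 # m
  # flow domain: fluid connected to the lumen at the inlet; isolated
  # interstices inside the tissue do not carry flow
  seed <- largest_fluid_run(!lat$solid[1, ])
  if (seed[2] == 0) stop_lumen_closed()
  conn <- flood_fill_cpp(lat$solid, 1L, as.integer(seed[1] + seed[2] %/% 2))
  eff <- lat
  eff$solid <- !conn
  gaps <- apply(conn, 1, largest_fluid_run)
  if (any(gaps[2, ] == 0))
    stop_lumen_closed()
  lat <- eff
  if (params$mode == "lubrication") {
    ux <- matrix(0, lat$nx, lat$ny)
    for (i in seq_len(lat$nx)) {
      st <- gaps[1, i]; len <- gaps[2, i]
      h <- len * dx
      yy <- (seq_len(len) - 0.5) / len # relative position across the gap
      ux[i, st:(st + len - 1L)] <- 6 * (target_flux / h) * yy * (1 - yy)
      # connected side pockets (recirculation zones) see a reduced wall
      # shear, ~10% of the local main-lumen value: seed their nodes with
      # the matching near-wall velocity so the finite-difference WSS
      # extraction reports it
      col <- conn[i, ]
      col[st:(st + len - 1L)] <- FALSE
      if (any(col)) {
        tau_main <- 6 * params$viscosity * target_flux / h^2
        u_eps <- 0.1 * tau_main * (dx / 2) / params$viscosity
        ux[i, col] <- u_eps
      }
    }
    return(structure(list(ux = ux, uy = matrix(0, lat$nx, lat$ny),
                          lattice = lat, target_flux = target_flux,
                          viscosity = params$viscosity,
                          density = params$density,
                          mode = "lubrication", converged = TRUE,
                          iters = 0L),
                     class = "isr_flow"))
  }
  # --- LBM mode ---
  st <- gaps[1, 1]; len <- gaps[2, 1]
  h_in <- len * dx
  u_mean_phys <- target_flux / h_in
  u_lat_mean <- params$lattice_u
  dt <- u_lat_mean * dx / u_mean_phys
  nu_lat <- (params$viscosity / params$density) * dt / dx^2
  tau <- 3 * nu_lat + 0.5
  cu <- dx / dt # velocity conversion, m/s per lattice unit
  u_in <- numeric(lat$ny)
  yy <- (seq_len(len) - 0.5) / len
  prof <- 6 * yy * (1 - yy)
  prof <- prof * len / sum(prof) # discrete flux exactly matches the mean
  u_in[st:(st + len - 1L)] <- u_lat_mean * prof
  res <- lbm_solve_cpp(lat$solid, u_in, tau, params$tol,
                       as.integer(params$max_iter), 50L)
  structure(list(ux = res$ux * cu, uy = res$uy * cu, rho = res$rho,
                 lattice = lat,
                 target_flux = target_flux, viscosity = params$viscosity,
                 density = params$density, mode = "lbm",
                 converged = res$converged, iters = res$iters, tau = tau),
            class = "isr_flow")
}

stop_lumen_closed <- function() {
  stop(structure(class = c("isr_lumen_closed", "error", "condition"),
                 list(message = "lumen fully occluded: no fluid path remains",
                      call = NULL)))
}

#' Wall shear stress on flow-adjacent SMCs
#'
#' For each fluid node adjacent to a solid node, the local WSS is
#' mu * |u_t| / (spacing/2): a one-sided finite difference of the
#' tangential velocity at the interface (the wall sits half a spacing
#' beyond the first fluid node). Values are averaged over each owning
#' SMC's interface nodes; SMCs with no fluid-adjacent node are absent
#' from the map.
#'
#' @param field an `isr_flow`.
#' @param lat an `isr_lattice` (defaults to the field's lattice).
#' @param state an `isr_tissue`; only SMC owners are reported.
#' @return named numeric vector, Pa, names = SMC agent ids.
#' @export
wall_shear_stress <- function(field, lat = field$lattice, state) {
  stopifnot(inherits(field, "isr_flow"), inherits(lat, "isr_lattice"))
  dx <- lat$spacing * 1e-3
  mu <- field$viscosity
  S <- lat$solid
  Fm <- !S
  # neighbour matrix at offset (di, dj), filled outside the domain
  shift_mat <- function(M, di, dj, fill) {
    out <- matrix(fill, nrow(M), ncol(M))
    si <- seq_len(nrow(M)) + di
    sj <- seq_len(ncol(M)) + dj
    oi <- which(si >= 1 & si <= nrow(M))
    oj <- which(sj >= 1 & sj <= ncol(M))
    out[oi, oj] <- M[si[oi], sj[oj]]
    out
  }
  smc_ids <- state$id[state$kind == KIND[["SMC"]]]
  owners <- integer(0); taus <- numeric(0)
  for (d in list(c(0, -1), c(0, 1), c(-1, 0), c(1, 0))) {
    nbS <- shift_mat(S, d[1], d[2], FALSE)
    sel <- Fm & nbS
    if (!any(sel)) next
    nbOwn <- shift_mat(lat$owner, d[1], d[2], NA_integer_)
    ut <- if (d[2] != 0) field$ux else field$uy # tangential component
    own <- nbOwn[sel]
    tau <- mu * abs(ut[sel]) / (dx / 2)
    keep <- !is.na(own) & own %in% smc_ids
    owners <- c(owners, own[keep])
    taus <- c(taus, tau[keep])
  }
  if (length(owners) == 0) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(taus, owners, mean)
  stats::setNames(as.numeric(out), names(out))
}
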