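#' Generate a campaign directory from a Saltelli design
#'
#' Builds the design, writes `design.csv` and one JSON config per run
#' under `runs/<run_id>/config.json`, each embedding the run's uncertain
#' inputs and seed. Regeneration with the same arguments is idempotent
#' (byte-identical design table).
#'
#' @param base_config an `isr_config` shared by all runs.
#' @param space an `isr_space` over the uncertain inputs (names must be
#'   `flow_velocity`, `deployment_depth`, `regen_time` for the restenosis
#'   model).
#' @param M base sample size (M(2n+2) runs).
#' @param seed_root integer root seed.
#' @param dir campaign directory to create.
#' @param overwrite refuse to reuse an existing directory unless TRUE.
#' @return the `isr_design`, invisibly; side effect: the campaign layout.
#' @export
generate_campaign <- function(base_config, space, M, seed_root, dir,
                              overwrite = FALSE) {
  stopifnot(inherits(base_config, "isr_config"), inherits(space, "isr_space"))
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop("campaign directory ", dir, " exists; use overwrite = TRUE")
  design <- build_design(space, M, seed_root)
  dir.create(file.path(dir, "runs"), recursive = TRUE, showWarnings = FALSE)
  write.csv(design$runs, file.path(dir, "design.csv"), row.names = FALSE)
  meta <- list(M = M, n = space$n, seed_root = seed_root,
               names = space$names, min = space$min, max = space$max)
  jsonlite::write_json(meta, file.path(dir, "campaign.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS_config <- serialize_config(base_config)
  jsonlite::write_json(saveRDS_config, file.path(dir, "base_config.json"),
                       auto_unbox = TRUE, digits = NA)
  for (k in seq_len(nrow(design$runs))) {
    rd <- file.path(dir, "runs", design$runs$run_id[k])
    dir.create(rd, showWarnings = FALSE)
    x <- as.list(design$runs[k, space$names])
    jsonlite::write_json(list(run_id = design$runs$run_id[k],
                              inputs = x, seed = design$runs$seed[k]),
                         file.path(rd, "config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(design)
}

# Config (de)serialization: flat JSON-able list.
serialize_config <- function(cfg) {
  list(vessel_length = cfg$vessel_length, lumen_diameter = cfg$lumen_diameter,
       media_layers = cfg$media_layers, cell_radius = cfg$cell_radius,
       deployment_depth = cfg$deployment_depth,
       deploy_steps = cfg$deploy_steps, strut_size = cfg$strut_size,
       scenario = unclass(cfg$scenario), growth = unclass(cfg$growth),
       mechanics = unclass(cfg$mechanics), flow = unclass(cfg$flow),
       reynolds = cfg$reynolds, total_days = cfg$total_days,
       snapshot_days = cfg$snapshot_days, master_seed = cfg$master_seed)
}

deserialize_config <- function(lst) {
  sim_config(vessel_length = lst$vessel_length,
             lumen_diameter = lst$lumen_diameter,
             media_layers = lst$media_layers,
             cell_radius = lst$cell_radius,
             deployment_depth = lst$deployment_depth,
             deploy_steps = lst$deploy_steps,
             strut_size = lst$strut_size,
             scenario = do.call(scenario_schedule, lst$scenario),
             growth = do.call(growth_params, lst$growth),
             mechanics = do.call(mechanics_params, lst$mechanics),
             flow = do.call(flow_params, lst$flow),
             reynolds = lst$reynolds,
             total_days = lst$total_days,
             snapshot_days = lst$snapshot_days,
             master_seed = lst$master_seed)
}

#' Read a simulation configuration from a JSON file
#' @param path JSON file written by [write_config()] or by hand.
#' @return an `isr_config`.
#' @export
read_config <- function(path) {
  deserialize_config(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Write a simulation configuration to JSON
#' @param config an `isr_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(serialize_config(config), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Execute the runs of a generated campaign
#'
#' Runs every design row through [run_simulation()]. Completed runs
#' (status.json present) are skipped, so an interrupted campaign resumes.
#' Runs are independent with self-contained seeds: the collected results
#' are identical for any worker count or execution order.
#'
#' @param dir campaign directory.
#' @param workers number of parallel worker processes.
#' @return invisibly, the number of runs executed now.
#' @export
run_campaign <- function(dir, workers = 1) {
  design_path <- file.path(dir, "design.csv")
  if (!file.exists(design_path)) stop("not a generated campaign: ", dir)
  runs <- read.csv(design_path, stringsAsFactors = FALSE)
  if (nrow(runs) == 0) stop("empty campaign: no runs in design")
  base <- read_config(file.path(dir, "base_config.json"))
  meta <- jsonlite::read_json(file.path(dir, "campaign.json"),
                              simplifyVector = TRUE)
  todo <- runs$run_id[!file.exists(file.path(dir, "runs", runs$run_id,
                                             "status.json"))]
  one <- function(rid) {
    rd <- file.path(dir, "runs", rid)
    cfgj <- jsonlite::read_json(file.path(rd, "config.json"),
                                simplifyVector = TRUE)
    ok <- TRUE; msg <- ""
    tr <- tryCatch(run_simulation(base, cfgj$inputs, cfgj$seed),
                   error = function(e) { ok <<- FALSE; msg <<- conditionMessage(e); NULL })
    if (ok) {
      write.csv(data.frame(time = tr$times, area = tr$neointimal_area,
                           width = tr$mean_lumen_width,
                           coverage = tr$coverage),
                file.path(rd, "trajectory.csv"), row.names = FALSE)
      last <- tr$snapshots[[length(tr$snapshots)]]
      write_mask(last$solid, file.path(rd, "snapshot_final.csv"))
      jsonlite::write_json(list(status = "done", restenosis = tr$restenosis,
                                closed = tr$closed,
                                baseline_lumen_area = tr$baseline_lumen_area,
                                original_lumen_area = tr$original_lumen_area),
                           file.path(rd, "status.json"),
                           auto_unbox = TRUE, digits = NA)
    } else {
      jsonlite::write_json(list(status = "failed", message = msg),
                           file.path(rd, "status.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    ok
  }
  if (length(todo) > 0) {
    if (workers > 1) {
      parallel::mclapply(todo, one, mc.cores = workers,
                         mc.preschedule = FALSE)
    } else {
      lapply(todo, one)
    }
  }
  invisible(length(todo))
}

# Boolean lattice mask <-> compact CSV (0/1 integer grid, one row per x).
write_mask <- function(mask, path) {
  utils::write.table(matrix(as.integer(mask), nrow(mask), ncol(mask)),
                     path, sep = ",", row.names = FALSE, col.names = FALSE)
}
read_mask <- function(path) {
  m <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(m) <- NULL
  m != 0
}

#' Collect the results of a completed campaign
#'
#' @param dir campaign directory.
#' @return an `isr_campaign`: the design, shared time grid, run-by-time
#'   area/width/coverage matrices, the final snapshot stack and per-run
#'   status. Errors (naming the runs) if any run is missing or failed.
#' @export
collect_campaign <- function(dir) {
  runs <- read.csv(file.path(dir, "design.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "campaign.json"),
                              simplifyVector = TRUE)
  space <- parameter_space(meta$names, meta$min, meta$max)
  design <- build_design(space, meta$M, meta$seed_root)
  status_paths <- file.path(dir, "runs", runs$run_id, "status.json")
  missing <- runs$run_id[!file.exists(status_paths)]
  if (length(missing) > 0)
    stop("incomplete campaign; missing runs: ",
         paste(head(missing, 5), collapse = ", "),
         if (length(missing) > 5) " ..." else "")
  st <- lapply(status_paths, jsonlite::read_json, simplifyVector = TRUE)
  failed <- runs$run_id[vapply(st, function(s) s$status != "done", TRUE)]
  if (length(failed) > 0)
    stop("failed runs: ", paste(head(failed, 5), collapse = ", "))
  trajs <- lapply(runs$run_id, function(rid)
    read.csv(file.path(dir, "runs", rid, "trajectory.csv")))
  times <- trajs[[1]]$time
  area <- t(vapply(trajs, function(tr) tr$area, numeric(length(times))))
  width <- t(vapply(trajs, function(tr) tr$width, numeric(length(times))))
  coverage <- t(vapply(trajs, function(tr) tr$coverage,
                       numeric(length(times))))
  snaps <- lapply(runs$run_id, function(rid)
    read_mask(file.path(dir, "runs", rid, "snapshot_final.csv")))
  dims <- unique(t(vapply(snaps, dim, integer(2))))
  if (nrow(dims) != 1) stop("snapshot dimension mismatch across runs")
  structure(list(design = design, dir = dir, times = times, area = area,
                 width = width, coverage = coverage,
                 snapshots = snaps,
                 restenosis = vapply(st, function(s) isTRUE(s$restenosis), TRUE),
                 original_lumen_area = st[[1]]$original_lumen_area),
            class = "isr_campaign")
}

# Wilson score interval for a binomial proportion.
wilson_interval <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  den <- 1 + z^2 / n
  mid <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, mid - half), upper = min(1, mid + half))
}

#' Analyze a campaign: uncertainty and sensitivity over time
#'
#' At every time point, computes the mean, variance, standard deviation
#' and coefficient of variation of the neointimal area; the aleatory
#' variance and its Jensen standard-deviation bound; and the first-order
#' and total Sobol sensitivity indices per uncertain input — each with a
#' bootstrap mean and standard deviation over K paired row resamples.
#' Also reports the final-time area density and the restenosis
#' probability with a Wilson 95% interval.
#'
#' @param result an `isr_campaign`.
#' @param K bootstrap replicates (study default 10000).
#' @param output run-by-time matrix to analyze (default: neointimal area).
#' @return an `isr_uq_report`.
#' @export
analyze_campaign <- function(result, K = 10000, output = result$area) {
  stopifnot(inherits(result, "isr_campaign"))
  design <- result$design
  n <- design$n
  nt <- ncol(output)
  blocks_all <- split_blocks(design, output)
  nm_in <- design$space$names
  cols <- c("mean", "variance", "sd", "cv", "aleatory_variance",
            paste0("S_", nm_in), paste0("ST_", nm_in))
  est <- matrix(NA_real_, nt, length(cols),
                dimnames = list(NULL, cols))
  boot_mean <- boot_sd <- est
  for (tix in seq_len(nt)) {
    bl <- list(A = blocks_all$A[, tix], A_RESEED = blocks_all$A_RESEED[, tix],
               FO = lapply(blocks_all$FO, function(m) m[, tix]),
               TO = lapply(blocks_all$TO, function(m) m[, tix]))
    mom <- estimate_moments(bl$A)
    alv <- aleatory_variance(bl$A, bl$A_RESEED)
    est[tix, "mean"] <- mom$mean
    est[tix, "variance"] <- mom$variance
    est[tix, "sd"] <- mom$sd
    est[tix, "cv"] <- mom$cv
    est[tix, "aleatory_variance"] <- alv$variance
    for (i in seq_len(n)) {
      est[tix, paste0("S_", nm_in[i])] <-
        first_order_index(bl$A, bl$FO[[i]])$index
      est[tix, paste0("ST_", nm_in[i])] <-
        total_index(bl$A, bl$TO[[i]])$index
    }
    br <- bootstrap_report(bl, K, n)
    boot_mean[tix, "mean"] <- br$mean["mean"]
    boot_sd[tix, "mean"] <- br$mean["sd"]
    boot_mean[tix, "variance"] <- br$variance["mean"]
    boot_sd[tix, "variance"] <- br$variance["sd"]
    boot_mean[tix, "sd"] <- br$sd["mean"]
    boot_sd[tix, "sd"] <- br$sd["sd"]
    boot_mean[tix, "cv"] <- br$cv["mean"]
    boot_sd[tix, "cv"] <- br$cv["sd"]
    boot_mean[tix, "aleatory_variance"] <- br$aleatory_variance["mean"]
    boot_sd[tix, "aleatory_variance"] <- br$aleatory_variance["sd"]
    for (i in seq_len(n)) {
      boot_mean[tix, paste0("S_", nm_in[i])] <- br$first_order[[i]]["mean"]
      boot_sd[tix, paste0("S_", nm_in[i])] <- br$first_order[[i]]["sd"]
      boot_mean[tix, paste0("ST_", nm_in[i])] <- br$total[[i]]["mean"]
      boot_sd[tix, paste0("ST_", nm_in[i])] <- br$total[[i]]["sd"]
    }
  }
  final <- blocks_all$A[, nt]
  dens <- if (var(final) > 0) density(final) else NULL
  n_rest <- sum(result$restenosis)
  n_runs <- length(result$restenosis)
  report <- structure(list(
    times = result$times, estimates = est,
    bootstrap_mean = boot_mean, bootstrap_sd = boot_sd,
    inputs = nm_in, K = K,
    aleatory_sd_bound = sqrt(pmax(est[, "aleatory_variance"], 0)),
    final_area = final, final_density = dens,
    restenosis_probability = n_rest / n_runs,
    restenosis_ci = wilson_interval(n_rest, n_runs)),
    class = "isr_uq_report")
  report
}

#' @export
print.isr_uq_report <- function(x, ...) {
  nt <- length(x$times)
  cat("uncertainty/sensitivity report over", nt, "time points;",
      "K =", x$K, "bootstrap replicates\n")
  cat(sprintf("final time: mean %.4g, sd %.4g (CV %.3g%%), aleatory sd bound <= %.4g\n",
              x$estimates[nt, "mean"], x$estimates[nt, "sd"],
              x$estimates[nt, "cv"], x$aleatory_sd_bound[nt]))
  for (nm in x$inputs)
    cat(sprintf("  %s: S = %.3g%% (+/- %.2g), ST = %.3g%% (+/- %.2g)\n", nm,
                x$estimates[nt, paste0("S_", nm)],
                x$bootstrap_sd[nt, paste0("S_", nm)],
                x$estimates[nt, paste0("ST_", nm)],
                x$bootstrap_sd[nt, paste0("ST_", nm)]))
  cat(sprintf("restenosis probability: %.3g [%.3g, %.3g]\n",
              x$restenosis_probability, x$restenosis_ci[1], x$restenosis_ci[2]))
  invisible(x)
}

#' @export
summary.isr_uq_report <- function(object, ...) {
  nt <- length(object$times)
  data.frame(quantity = colnames(object$estimates),
             estimate = object$estimates[nt, ],
             bootstrap_mean = object$bootstrap_mean[nt, ],
             bootstrap_sd = object$bootstrap_sd[nt, ],
             row.names = NULL)
}

#' @export
plot.isr_uq_report <- function(x, which = c("bands", "cv", "indices"), ...) {
  which <- match.arg(which)
  t <- x$times
  e <- x$estimates
  if (which == "bands") {
    graphics::plot(t, e[, "mean"], type = "l", xlab = "time (days)",
                   ylab = "neointimal area (mm^2)", ...)
    graphics::lines(t, e[, "mean"] + e[, "sd"], lty = 2, col = 2)
    graphics::lines(t, pmax(0, e[, "mean"] - e[, "sd"]), lty = 2, col = 2)
    graphics::lines(t, e[, "mean"] + x$aleatory_sd_bound, lty = 3, col = 4)
    graphics::lines(t, pmax(0, e[, "mean"] - x$aleatory_sd_bound), lty = 3,
                    col = 4)
  } else if (which == "cv") {
    graphics::plot(t, e[, "cv"], type = "l", xlab = "time (days)",
                   ylab = "CV (%)", ...)
    rel_al <- sqrt(pmax(e[, "aleatory_variance"], 0)) /
      abs(e[, "mean"]) * 100
    graphics::lines(t, rel_al, col = 4)
  } else {
    graphics::matplot(t, e[, paste0("S_", x$inputs), drop = FALSE],
                      type = "l", lty = 1, xlab = "time (days)",
                      ylab = "first-order index (%)", ...)
    graphics::legend("topleft", legend = x$inputs, col = seq_along(x$inputs),
                     lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write the analysis products of a campaign to disk
#'
#' Writes `analysis/moments.csv`, `analysis/sobol.csv` and
#' `analysis/summary.json` under the campaign directory.
#'
#' @param report an `isr_uq_report`.
#' @param dir campaign directory.
#' @return invisibly, the analysis directory.
#' @export
write_report <- function(report, dir) {
  ad <- file.path(dir, "analysis")
  dir.create(ad, showWarnings = FALSE)
  base_cols <- c("mean", "variance", "sd", "cv", "aleatory_variance")
  mom <- data.frame(time = report$times, report$estimates[, base_cols],
                    aleatory_sd_bound = report$aleatory_sd_bound)
  write.csv(mom, file.path(ad, "moments.csv"), row.names = FALSE)
  si_cols <- setdiff(colnames(report$estimates), base_cols)
  sob <- data.frame(time = report$times, report$estimates[, si_cols],
                    check.names = FALSE)
  for (cc in si_cols) {
    sob[[paste0(cc, "_boot_sd")]] <- report$bootstrap_sd[, cc]
  }
  write.csv(sob, file.path(ad, "sobol.csv"), row.names = FALSE)
  nt <- length(report$times)
  jsonlite::write_json(list(
    final_time = report$times[nt],
    mean = report$estimates[nt, "mean"],
    sd = report$estimates[nt, "sd"],
    cv = report$estimates[nt, "cv"],
    aleatory_sd_bound = report$aleatory_sd_bound[nt],
    first_order = as.list(report$estimates[nt, paste0("S_", report$inputs)]),
    total = as.list(report$estimates[nt, paste0("ST_", report$inputs)]),
    restenosis_probability = report$restenosis_probability,
    restenosis_ci = as.list(report$restenosis_ci),
    K = report$K), file.path(ad, "summary.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(ad)
}

#' Per-site presence probability over a snapshot stack
#'
#' @param snapshots list of equal-dimension boolean lattice masks.
#' @return an `isr_field`: per-site mean of the stack (fraction of runs in
#'   which the site was solid).
#' @export
presence_probability <- function(snapshots) {
  stopifnot(length(snapshots) >= 1)
  dims <- unique(t(vapply(snapshots, dim, integer(2))))
  if (nrow(dims) != 1) stop("snapshot dimension mismatch")
  acc <- Reduce(`+`, lapply(snapshots, function(m) m * 1))
  structure(list(values = acc / length(snapshots), kind = "presence"),
            class = "isr_field")
}

#' Spatial sensitivity maps at the final time
#'
#' Treats each lattice site's presence indicator (solid in the final
#' snapshot) as the model output and applies the variance, aleatory,
#' first-order and total-index estimators sitewise over the Saltelli
#' design. Sites whose base-block output has zero variance are masked NA.
#'
#' @param result an `isr_campaign` with one snapshot per run.
#' @return named list of `isr_field`s: `variance`, `aleatory`, and
#'   `fosi_<input>` / `tsi_<input>` per uncertain input.
#' @export
spatial_sensitivity_maps <- function(result) {
  stopifnot(inherits(result, "isr_campaign"))
  design <- result$design
  dims <- dim(result$snapshots[[1]])
  nsite <- prod(dims)
  Y <- t(vapply(result$snapshots, function(m) as.numeric(m),
                numeric(nsite))) # runs x sites
  bl <- split_blocks(design, Y)
  A <- bl$A; Rr <- bl$A_RESEED
  M <- nrow(A)
  mA <- colMeans(A)
  vA <- (colMeans(A^2) - mA^2) * M / (M - 1)
  mask <- vA > 0
  as_field <- function(v, kind) {
    v[!mask] <- NA_real_
    structure(list(values = matrix(v, dims[1], dims[2]), kind = kind),
              class = "isr_field")
  }
  out <- list(variance = as_field(vA, "variance"),
              aleatory = as_field(colMeans((A - Rr)^2) / 2,
                                  "aleatory_variance"))
  for (i in seq_len(design$n)) {
    nm <- design$space$names[i]
    Fi <- bl$FO[[i]]; Ti <- bl$TO[[i]]
    pv_fo <- colMeans(A * Fi) - mA * colMeans(Fi)
    pv_to <- colMeans((A - Ti)^2) / 2
    out[[paste0("fosi_", nm)]] <- as_field(pv_fo / vA * 100, "FOSI")
    out[[paste0("tsi_", nm)]] <- as_field(pv_to / vA * 100, "TSI")
  }
  out
}

#' Write spatial fields as CSV grids
#' @param maps named list of `isr_field`s (from
#'   [spatial_sensitivity_maps()] or [presence_probability()]).
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_maps <- function(maps, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(maps, "isr_field")) maps <- list(field = maps)
  for (nm in names(maps))
    utils::write.table(maps[[nm]]$values, file.path(dir, paste0(nm, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' @export
print.isr_field <- function(x, ...) {
  cat("spatial field (", x$kind, "): ", nrow(x$values), " x ",
      ncol(x$values), " sites, range ",
      paste(signif(range(x$values, na.rm = TRUE), 3), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}
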