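#' Scenario presets
#'
#' Named configurations of the growth study:
#' * `baseline` — soft matrix (E_ECM = 1.0 kPa), closed oxygen domain (RBC),
#'   overlapping phenotype switch, constant permeability, 5 days.
#' * `subtumor` — stiff matrix (E_ECM = 2.5 kPa) with permanent oxygen
#'   supply (PSBC); the regime in which a distant proliferative rim detaches
#'   from the core.
#' * `variable_permeability` — baseline plus the strain-dependent
#'   pore-stretch permeability factor.
#' * `stiff_switch` — baseline under the strict go-or-grow dichotomy.
#' * `rigid_rbc` — stiff matrix (2.5 kPa) with a closed oxygen domain; the
#'   control in which no distant rim forms and proliferation dies out.
#'
#' @param name One of `"baseline"`, `"subtumor"`, `"variable_permeability"`,
#'   `"stiff_switch"`, `"rigid_rbc"`.
#' @return A list with `name`, `overrides` (parameter overrides) and `t_end`
#'   (days).
#' @export
scenario_preset <- function(name) {
  presets <- list(
    baseline = list(E_ECM = 1000, oxygen_bc = "RBC", switch_mode = "overlap",
                    permeability_mode = "constant"),
    subtumor = list(E_ECM = 2500, oxygen_bc = "PSBC", switch_mode = "overlap",
                    permeability_mode = "constant"),
    variable_permeability = list(E_ECM = 1000, oxygen_bc = "RBC",
                                 switch_mode = "overlap",
                                 permeability_mode = "strain"),
    stiff_switch = list(E_ECM = 1000, oxygen_bc = "RBC",
                        switch_mode = "stiff",
                        permeability_mode = "constant"),
    rigid_rbc = list(E_ECM = 2500, oxygen_bc = "RBC", switch_mode = "overlap",
                     permeability_mode = "constant")
  )
  if (!name %in% names(presets)) {
    stop("unknown scenario: ", name, " (expected one of ",
         paste(names(presets), collapse = ", "), ")", call. = FALSE)
  }
  list(name = name, overrides = presets[[name]], t_end = 5)
}

#' Initial state of the growth simulation
#'
#' A sharp spheroid of proliferative cells (`C_p = C_init` for `r <= R0`,
#' zero outside; no hypoxic or necrotic cells), uniform oxygen at `n0`, and
#' a relaxed matrix (`u = 0`), with the mechanical state solved once for the
#' initial concentration profile.
#'
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()]; defaults to the grid implied by `params`.
#' @return A `sim_state` list: `t`, `C_p`, `C_m`, `C_n`, `C_tot`, `n_ox`,
#'   `mech`.
#' @export
initialize_state <- function(params, grid = NULL) {
  if (is.null(grid)) grid <- radial_grid(params$R_dom, params$dr)
  if (params$R0 >= params$R_dom) {
    stop("invalid configuration: R0 must be smaller than R_dom",
         call. = FALSE)
  }
  C_p <- ifelse(grid$r <= params$R0 + 1e-12, params$C_init, 0)
  C_m <- numeric(grid$n)
  C_n <- numeric(grid$n)
  n_ox <- rep(params$n0, grid$n)
  state <- list(t = 0, C_p = C_p, C_m = C_m, C_n = C_n,
                C_tot = C_p + C_m + C_n, n_ox = n_ox,
                mech = solve_mechanics(C_p, params, grid))
  class(state) <- "sim_state"
  state
}

#' One full operator-split time step
#'
#' Split order per step: (1) quasi-static mechanics solve for the current
#' concentration profile, (2) flux-corrected advection with the resulting
#' drift velocity, (3) random-motility diffusion, (4) explicit phenotype
#' sources, (5) oxygen diffusion and uptake.
#'
#' @param state A `sim_state` (see [initialize_state()]).
#' @param dt Time step, day.
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @return The advanced `sim_state`.
#' @export
step_state <- function(state, dt, params, grid) {
  mech <- solve_mechanics(state$C_tot, params, grid)
  fields <- cell_transport_step(
    list(C_p = state$C_p, C_m = state$C_m, C_n = state$C_n),
    mech$v_D, state$n_ox, dt, params, grid
  )
  n_ox <- oxygen_step(state$n_ox, fields$C_p, fields$C_m, dt, params, grid)
  out <- list(t = state$t + dt, C_p = fields$C_p, C_m = fields$C_m,
              C_n = fields$C_n, C_tot = fields$C_tot, n_ox = n_ox,
              mech = mech)
  attr(out, "clamped_mass") <- attr(fields, "clamped_mass")
  class(out) <- "sim_state"
  out
}

#' Run a growth scenario
#'
#' Integrates the model from the sharp initial spheroid to `t_end`, storing
#' snapshots at a fixed cadence (plus `t = 0` and the final time).  The
#' model is fully deterministic: identical configurations produce identical
#' trajectories.  If any field turns non-finite the run aborts with a
#' warning and returns the trajectory up to the last valid snapshot.
#'
#' @param scenario A preset name (see [scenario_preset()]) or `NULL` to run
#'   `params` as given.
#' @param params A [sim_params()] object; scenario overrides are applied on
#'   top of it.
#' @param t_end End time, days (default: the scenario's, else 5).
#' @param snapshot_every Snapshot cadence, days (default 0.1).
#' @param snapshot_times Extra exact times to record (default
#'   `c(0.2, 0.3, 0.5, 1, 2, 3, 5)` clipped to `t_end`).
#' @param track_center Logical; record the centre oxygen value at every step
#'   (used for hypoxia-onset timing).
#' @return A `sim_run` object: `params`, `grid`, `snapshots` (list of
#'   `sim_state`), `times`, `meta` (dt, dr, scenario, clamp diagnostics,
#'   optional per-step centre oxygen trace).
#' @export
run_scenario <- function(scenario = "baseline", params = sim_params(),
                         t_end = NULL, snapshot_every = 0.1,
                         snapshot_times = c(0.2, 0.3, 0.5, 1, 2, 3, 5),
                         track_center = TRUE) {
  scen_name <- "custom"
  if (!is.null(scenario)) {
    preset <- scenario_preset(scenario)
    scen_name <- preset$name
    ov <- preset$overrides
    keep <- setdiff(names(unclass(params)),
                    c(names(ov), "K_ECM", "M0", "D_p", "h_m_flag"))
    args <- c(unclass(params)[keep], ov)
    params <- do.call(sim_params, args)
    if (is.null(t_end)) t_end <- preset$t_end
  }
  if (is.null(t_end)) t_end <- 5
  grid <- radial_grid(params$R_dom, params$dr)
  dt <- params$dt
  n_steps <- as.integer(round(t_end / dt))
  if (abs(n_steps * dt - t_end) > 1e-9) {
    stop("t_end must be a multiple of dt", call. = FALSE)
  }
  snap_steps <- unique(sort(c(
    as.integer(round(seq(0, t_end, by = snapshot_every) / dt)),
    as.integer(round(snapshot_times[snapshot_times <= t_end] / dt)),
    n_steps
  )))

  state <- initialize_state(params, grid)
  snapshots <- vector("list", length(snap_steps))
  times <- snap_steps * dt
  si <- 1L
  if (snap_steps[1] == 0L) {
    snapshots[[1]] <- state
    si <- 2L
  }
  center_ox <- if (track_center) numeric(n_steps) else NULL
  clamped_total <- 0
  aborted <- FALSE
  for (i in seq_len(n_steps)) {
    state <- step_state(state, dt, params, grid)
    state$t <- i * dt  # exact, avoids drift in accumulated sums
    cm <- attr(state, "clamped_mass")
    if (!is.null(cm) && is.finite(cm)) clamped_total <- clamped_total + cm
    if (track_center) center_ox[i] <- state$n_ox[1]
    if (!all(is.finite(state$C_tot)) || !all(is.finite(state$n_ox)) ||
        !all(is.finite(state$mech$sigma_tot))) {
      warning(sprintf("instability detected at t = %.4f day; aborting with last valid snapshot",
                      state$t), call. = FALSE)
      aborted <- TRUE
      break
    }
    if (si <= length(snap_steps) && i == snap_steps[si]) {
      snapshots[[si]] <- state
      si <- si + 1L
    }
  }
  keep <- !vapply(snapshots, is.null, logical(1))
  run <- structure(
    list(params = params, grid = grid, snapshots = snapshots[keep],
         times = times[keep],
         meta = list(scenario = scen_name, dt = dt, dr = params$dr,
                     t_end = t_end, n_steps = n_steps,
                     clamped_cell_mass = clamped_total,
                     aborted = aborted,
                     center_ox = center_ox,
                     center_ox_times = if (track_center)
                       seq_len(n_steps) * dt else NULL)),
    class = "sim_run"
  )
  run
}

#' @export
print.sim_run <- function(x, ...) {
  cat(sprintf("<sim_run> scenario '%s': %d snapshots to t = %.3g day (dr = %.3g mm, dt = %.3g day)%s\n",
              x$meta$scenario, length(x$snapshots),
              max(x$times), x$meta$dr, x$meta$dt,
              if (isTRUE(x$meta$aborted)) " [ABORTED]" else ""))
  invisible(x)
}

#' Extract the snapshot closest to a requested time
#'
#' @param run A `sim_run`.
#' @param t Requested time, day.
#' @param tol Maximum allowed |t - snapshot time| (default half the cadence).
#' @return The `sim_state` snapshot.
#' @export
snapshot_at <- function(run, t, tol = 0.05) {
  i <- which.min(abs(run$times - t))
  if (abs(run$times[i] - t) > tol + 1e-12) {
    stop(sprintf("no snapshot within %.3g day of t = %.3g", tol, t),
         call. = FALSE)
  }
  run$snapshots[[i]]
}

#' Convert a snapshot to a data frame of radial profiles
#'
#' @param state A `sim_state`.
#' @param grid The run's [radial_grid()].
#' @return A data frame with columns `r_mm`, `C_p`, `C_m`, `C_n`, `C_tot`,
#'   `n_ox`, `u_mm`, `eps_v`, `sigma_C`, `sigma_ECM`, `sigma_tot`, `v_D`.
#' @export
snapshot_profiles <- function(state, grid) {
  data.frame(
    r_mm = grid$r, C_p = state$C_p, C_m = state$C_m, C_n = state$C_n,
    C_tot = state$C_tot, n_ox = state$n_ox, u_mm = state$mech$u,
    eps_v = state$mech$eps_v, sigma_C = state$mech$sigma_C,
    sigma_ECM = state$mech$sigma_ECM, sigma_tot = state$mech$sigma_tot,
    v_D = state$mech$v_D
  )
}

#' Write a trajectory to disk
#'
#' One CSV of radial profiles per snapshot (`snapshot_<t>.csv`) plus a
#' `manifest.json` with the configuration, grid and run metadata.
#'
#' @param run A `sim_run`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_run <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(run$snapshots)) {
    f <- file.path(dir, sprintf("snapshot_t%07.3f.csv", run$times[i]))
    utils::write.csv(snapshot_profiles(run$snapshots[[i]], run$grid), f,
                     row.names = FALSE)
  }
  manifest <- list(
    package = "gliosphere",
    scenario = run$meta$scenario,
    t_end = run$meta$t_end, dt = run$meta$dt, dr = run$meta$dr,
    n_nodes = run$grid$n,
    snapshot_times = run$times,
    aborted = isTRUE(run$meta$aborted),
    clamped_cell_mass = run$meta$clamped_cell_mass,
    params = unclass(run$params)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Time at which the spheroid centre first turns hypoxic
#'
#' First simulation time at which the centre-node oxygen concentration drops
#' below the hypoxia threshold `xi_h`, read from the per-step centre-oxygen
#' trace of a run.
#'
#' @param run A `sim_run` created with `track_center = TRUE`.
#' @return Time in days (`NA` if the centre never turns hypoxic).
#' @export
hypoxia_onset_time <- function(run) {
  trace <- run$meta$center_ox
  if (is.null(trace)) {
    stop("run was created without track_center = TRUE", call. = FALSE)
  }
  i <- which(trace < run$params$xi_h)
  if (!length(i)) return(NA_real_)
  run$meta$center_ox_times[i[1]]
}
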