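#' Outermost radius at which a profile crosses a threshold
#'
#' Scans the radial profile from the outer border inwards and returns the
#' linearly interpolated radius of the outermost downward crossing of the
#' threshold (the density isoline radius).  Returns `NA_real_` when the
#' profile never attains the threshold (a valid "not attained" result, not
#' an error).
#'
#' @param profile Non-negative radial profile (e.g. total cell density).
#' @param threshold Threshold value, same units as `profile`.
#' @param grid A [radial_grid()].
#' @return Radius in mm, or `NA_real_`.
#' @export
isoline_radius <- function(profile, threshold, grid) {
  stopifnot(length(profile) == grid$n)
  above <- profile >= threshold
  if (!any(above)) return(NA_real_)
  i <- max(which(above))
  if (i == grid$n) return(grid$R_dom)
  # interpolate between the last node above and the first below
  f1 <- profile[i]; f2 <- profile[i + 1]
  if (f1 == f2) return(grid$r[i])
  grid$r[i] + (f1 - threshold) / (f1 - f2) * grid$dr
}

#' Track a density isoline through a trajectory
#'
#' @param run A `sim_run`.
#' @param threshold Density threshold, cells/mm^3.
#' @param field Which profile to track (default total density).
#' @return A data frame with columns `t` (day) and `r_outer` (mm, `NA` where
#'   the threshold is not attained).
#' @export
isoline_track <- function(run, threshold, field = "C_tot") {
  r_outer <- vapply(run$snapshots, function(s)
    isoline_radius(s[[field]], threshold, run$grid), numeric(1))
  data.frame(t = run$times, r_outer = r_outer)
}

#' Mean outward speed of an isoline over a time window
#'
#' `(r_outer(t1) - r_outer(t0)) / (t1 - t0)` from an isoline track.
#'
#' @param track A data frame from [isoline_track()].
#' @param t0,t1 Window limits, day (must both be in the track, `t1 > t0`).
#' @return Speed in mm/day.
#' @export
invasion_speed <- function(track, t0, t1) {
  if (!is.finite(t0) || !is.finite(t1) || t1 <= t0) {
    stop("invalid argument: need t1 > t0", call. = FALSE)
  }
  pick <- function(tt) {
    i <- which.min(abs(track$t - tt))
    if (abs(track$t[i] - tt) > 1e-6 + 1e-9 * abs(tt)) {
      stop(sprintf("time %.4g day is not in the track", tt), call. = FALSE)
    }
    track$r_outer[i]
  }
  (pick(t1) - pick(t0)) / (t1 - t0)
}

#' Central density fold change
#'
#' Ratio of the centre-node total cell density at time `t` to the initial
#' concentration `C_init`.
#'
#' @param run A `sim_run`.
#' @param t Time, day.
#' @return Dimensionless fold change.
#' @export
central_fold_change <- function(run, t) {
  s <- snapshot_at(run, t)
  s$C_tot[1] / run$params$C_init
}

#' Detect proliferative rims (off-centre local maxima)
#'
#' Finds local maxima of a profile at `r > 0` whose prominence (peak height
#' above the higher of the two flanking minima, walking outwards until the
#' profile rises again or the domain ends) exceeds `min_prominence`.
#'
#' @param profile Non-negative radial profile (typically `C_p`).
#' @param grid A [radial_grid()].
#' @param min_prominence Minimum prominence, same units as `profile`.
#' @return A data frame with columns `r` (mm) and `peak` (profile value),
#'   sorted by radius; zero rows when no rim qualifies.
#' @export
detect_rims <- function(profile, grid, min_prominence = 0) {
  n <- grid$n
  stopifnot(length(profile) == n)
  peaks <- which(diff(sign(diff(profile))) < 0) + 1L
  peaks <- peaks[peaks > 1L]
  if (!length(peaks)) {
    return(data.frame(r = numeric(0), peak = numeric(0)))
  }
  prom <- vapply(peaks, function(i) {
    h <- profile[i]
    left <- if (i > 1) min(profile[1:(i - 1)][cummax_rev_ok(profile, i, -1L)])
            else h
    right <- if (i < n) min(profile[(i + 1):n][cummax_rev_ok(profile, i, 1L)])
             else h
    h - max(left, right)
  }, numeric(1))
  keep <- prom >= min_prominence & prom > 0
  data.frame(r = grid$r[peaks[keep]], peak = profile[peaks[keep]])
}

# helper: walking from peak i in direction dir, flag the positions up to the
# point where the profile climbs back above the peak (the prominence window)
cummax_rev_ok <- function(profile, i, dir) {
  idx <- if (dir < 0) (i - 1):1 else (i + 1):length(profile)
  stopbar <- profile[idx] > profile[i]
  if (any(stopbar)) {
    k <- which(stopbar)[1] - 1L
    out <- rep(FALSE, length(idx))
    if (k >= 1L) out[seq_len(k)] <- TRUE
  } else {
    out <- rep(TRUE, length(idx))
  }
  if (dir < 0) rev(out) else out
}

#' Hypoxic fraction of a radial band
#'
#' Volume-weighted fraction of hypoxic among live (non-necrotic) cells over
#' a radial band: `sum(w C_m) / sum(w (C_p + C_m))`.  Necrotic cells are
#' excluded from the denominator by default because the quantity concerns
#' the go/grow split of the live population; `include_necrotic = TRUE`
#' reports the variant with `C_n` in the denominator.
#'
#' @param state A `sim_state` snapshot.
#' @param band Numeric length-2 radius interval, mm.
#' @param grid A [radial_grid()].
#' @param include_necrotic Logical (default `FALSE`).
#' @return Fraction in `[0, 1]`, or `NA_real_` when the band holds no cells.
#' @export
rim_hypoxic_fraction <- function(state, band, grid,
                                 include_necrotic = FALSE) {
  stopifnot(length(band) == 2L, band[1] <= band[2])
  if (band[1] < 0 || band[2] > grid$R_dom) {
    stop("band must lie within the domain", call. = FALSE)
  }
  sel <- grid$r >= band[1] & grid$r <= band[2]
  w <- grid$w[sel]
  num <- sum(w * state$C_m[sel])
  den <- sum(w * (state$C_p[sel] + state$C_m[sel] +
                    if (include_necrotic) state$C_n[sel] else 0))
  if (den <= 0) return(NA_real_)
  num / den
}

#' Locate the main proliferative rim band of a run
#'
#' Identifies the outermost local maximum of the proliferative profile
#' inside the core (at the reference time, default day 2) and freezes a
#' radial band of the given half-width around it, for re-use at later
#' times.  The core edge is taken as the outermost radius where total
#' density exceeds `core_threshold`.
#'
#' @param run A `sim_run`.
#' @param t_ref Reference time, day (default 2).
#' @param half_width Band half-width, mm (default 0.05).
#' @param core_threshold Core-edge density, cells/mm^3 (default 4e4).
#' @return Numeric length-2 band, mm.
#' @export
main_rim_band <- function(run, t_ref = 2, half_width = 0.05,
                          core_threshold = 4e4) {
  s <- snapshot_at(run, t_ref)
  core_edge <- isoline_radius(s$C_tot, core_threshold, run$grid)
  if (is.na(core_edge)) core_edge <- run$grid$R_dom
  rims <- detect_rims(s$C_p, run$grid,
                      min_prominence = 0.01 * max(s$C_p))
  rims <- rims[rims$r <= core_edge + 1e-9, , drop = FALSE]
  centre <- if (nrow(rims)) max(rims$r) else {
    # monotone profile: use the maximum of C_p inside the core
    run$grid$r[which.max(ifelse(run$grid$r <= core_edge, s$C_p, -Inf))]
  }
  c(max(0, centre - half_width), min(run$grid$R_dom, centre + half_width))
}

#' Summary metrics of a run
#'
#' Isoline tracks at the standard thresholds plus headline observables
#' (hypoxia onset, day-1 invasive-zone displacement, day-3 central fold
#' change, rim inventory per snapshot).
#'
#' @param run A `sim_run`.
#' @param thresholds Isoline thresholds, cells/mm^3.
#' @return A list with `tracks` (long data frame of isoline radii),
#'   `summary` (named list of headline numbers) and `rims` (data frame of
#'   off-centre proliferative maxima per snapshot).
#' @export
run_metrics <- function(run, thresholds = c(4e2, 4e3, 4e4, 8e4, 1.6e5)) {
  tracks <- do.call(rbind, lapply(thresholds, function(th) {
    tr <- isoline_track(run, th)
    tr$threshold <- th
    tr
  }))
  rims <- do.call(rbind, lapply(seq_along(run$snapshots), function(i) {
    s <- run$snapshots[[i]]
    rr <- detect_rims(s$C_p, run$grid, min_prominence = 0.01 * max(s$C_p))
    if (!nrow(rr)) return(NULL)
    rr$t <- run$times[i]
    rr
  }))
  t_max <- max(run$times)
  summ <- list(
    hypoxia_onset_day = if (!is.null(run$meta$center_ox))
      hypoxia_onset_time(run) else NA_real_,
    iz_displacement_day1_mm = if (t_max >= 1)
      isoline_radius(snapshot_at(run, 1)$C_tot, 4e2, run$grid) -
        run$params$R0 else NA_real_,
    central_fold_day3 = if (t_max >= 3) central_fold_change(run, 3)
      else NA_real_
  )
  list(tracks = tracks, summary = summ, rims = rims)
}
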