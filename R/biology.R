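#' Smooth oxygen switch factors
#'
#' Smooth (tanh) approximations of the step functions triggering phenotype
#' transitions at the hypoxia threshold `xi_h` and the necrosis threshold
#' `xi_n`:
#' `h_pm = (1 - tanh((n - xi_h)/lambda))/2`, `h_mp = 1 - h_pm`,
#' `h_nec = (1 - tanh((n - xi_n)/lambda))/2`.
#' `h_pm` gates the proliferative-to-hypoxic switch, `h_mp` the reverse, and
#' `h_nec` the hypoxic-to-necrotic switch; all lie in (0, 1) and
#' `h_pm + h_mp == 1` identically.
#'
#' @param n_ox Oxygen concentration(s), mg/L (vectorised).
#' @param params A [sim_params()] object.
#' @return A list with `h_pm`, `h_mp`, `h_nec`.
#' @export
switch_factors <- function(n_ox, params) {
  h_pm <- (1 - tanh((n_ox - params$xi_h) / params$lambda_switch)) / 2
  h_nec <- (1 - tanh((n_ox - params$xi_n) / params$lambda_switch)) / 2
  list(h_pm = h_pm, h_mp = 1 - h_pm, h_nec = h_nec)
}

#' Phenotype source terms
#'
#' Reaction terms of the three-phenotype balance: logistic,
#' oxygen-modulated proliferation of the proliferative (and, in the
#' overlapping switch mode, hypoxic) population, phenotype transitions gated
#' by the smooth switch factors, and necrosis of hypoxic cells:
#' \deqn{S_p = (C_p/\tau_p)(1 - C_{tot}/C_q)(n/n_{max})
#'       - h_{pm} C_p/\tau_{pm} + h_{mp} C_m/\tau_{mp}}
#' \deqn{S_m = h_m (C_m/\tau_m)(1 - C_{tot}/C_q)(n/n_{max})
#'       + h_{pm} C_p/\tau_{pm} - h_{mp} C_m/\tau_{mp} - h_{nec} C_m/\tau_n}
#' \deqn{S_n = h_{nec} C_m/\tau_n}
#' Transitions cancel pairwise, so the total source reduces to the two
#' proliferation terms; necrotic mass only grows.  The logistic factor is
#' clamped at zero on transient overshoot (`C_tot > C_q` causes no death).
#'
#' @param C_p,C_m,C_n Phenotype concentration profiles, cells/mm^3.
#' @param n_ox Oxygen profile, mg/L.
#' @param params A [sim_params()] object.
#' @return A list with `S_p`, `S_m`, `S_n` in cells/(mm^3 day).
#' @export
phenotype_sources <- function(C_p, C_m, C_n, n_ox, params) {
  C_tot <- C_p + C_m + C_n
  h <- switch_factors(n_ox, params)
  logi <- pmax(0, 1 - C_tot / params$C_q) * (n_ox / params$n_max)
  t_pm <- h$h_pm * C_p / params$tau_pm
  t_mp <- h$h_mp * C_m / params$tau_mp
  t_nec <- h$h_nec * C_m / params$tau_n
  S_p <- C_p / params$tau_p * logi - t_pm + t_mp
  S_m <- params$h_m_flag * C_m / params$tau_m * logi + t_pm - t_mp - t_nec
  list(S_p = S_p, S_m = S_m, S_n = t_nec)
}

#' One oxygen transport-and-uptake step
#'
#' Crank-Nicolson diffusion of oxygen followed by explicit uptake
#' `-(alpha_p C_p + alpha_m C_m) dt`, clamped at zero from below.  Under the
#' closed-domain boundary condition (`RBC`) the border is zero-flux; under
#' permanent supply (`PSBC`) the border node is held at `n0`.
#'
#' @param n_ox Oxygen profile, mg/L.
#' @param C_p,C_m Live phenotype concentration profiles, cells/mm^3.
#' @param dt Time step, day.
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @return The updated oxygen profile.
#' @export
oxygen_step <- function(n_ox, C_p, C_m, dt, params, grid) {
  if (identical(params$oxygen_bc, "PSBC")) {
    n_new <- diffuse_cn(n_ox, params$D_ox, dt, grid, bc = "dirichlet",
                        bc_value = params$n0)
  } else {
    n_new <- diffuse_cn(n_ox, params$D_ox, dt, grid, bc = "no_flux")
  }
  n_new <- n_new - (params$alpha_p * C_p + params$alpha_m * C_m) * dt
  n_new <- pmax(n_new, 0)
  if (identical(params$oxygen_bc, "PSBC")) n_new[grid$n] <- params$n0
  n_new
}

#' One cell transport step (advection + diffusion + sources)
#'
#' Advances the three phenotype fields by one split step: shared-velocity
#' flux-corrected advection (sub-cycled if the CFL condition requires),
#' Crank-Nicolson random-motility diffusion with phenotype-specific
#' diffusivities (`D_n = 0` — necrotic cells are inert), then an explicit
#' Euler source update, with negative round-off clamped at zero.  All cell
#' boundaries are zero-flux.
#'
#' @param fields A list with `C_p`, `C_m`, `C_n` profiles, cells/mm^3.
#' @param v_D Shared drift velocity profile, mm/day.
#' @param n_ox Oxygen profile, mg/L (for the source terms).
#' @param dt Time step, day.
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @param sources Logical; set `FALSE` to run pure transport.
#' @return The updated `fields` list (with `C_tot` refreshed).
#' @export
cell_transport_step <- function(fields, v_D, n_ox, dt, params, grid,
                                sources = TRUE) {
  C_p <- fields$C_p; C_m <- fields$C_m; C_n <- fields$C_n

  v_face <- (v_D[-1] + v_D[-length(v_D)]) / 2
  cfl <- max(abs(v_face)) * dt / grid$dr
  n_sub <- max(1L, ceiling(cfl / 0.45))
  if (n_sub > 1000L) {
    stop(sprintf("cell_transport_step: CFL sub-cycling exceeds limit (needed %d sub-steps)",
                 n_sub), call. = FALSE)
  }
  dts <- dt / n_sub
  for (k in seq_len(n_sub)) {
    C_p <- advect_fct(C_p, v_D, dts, grid)
    C_m <- advect_fct(C_m, v_D, dts, grid)
    C_n <- advect_fct(C_n, v_D, dts, grid)
  }

  if (params$D_p > 0) C_p <- diffuse_cn(C_p, params$D_p, dt, grid)
  if (params$D_m > 0) C_m <- diffuse_cn(C_m, params$D_m, dt, grid)

  if (sources) {
    S <- phenotype_sources(C_p, C_m, C_n, n_ox, params)
    C_p <- C_p + S$S_p * dt
    C_m <- C_m + S$S_m * dt
    C_n <- C_n + S$S_n * dt
  }
  # clamp negative round-off; record the (signed) mass the clamp adds
  clamped <- -radial_integral(pmin(C_p, 0) + pmin(C_m, 0) + pmin(C_n, 0), grid)
  C_p <- pmax(C_p, 0)
  C_m <- pmax(C_m, 0)
  C_n <- pmax(C_n, 0)
  out <- list(C_p = C_p, C_m = C_m, C_n = C_n, C_tot = C_p + C_m + C_n)
  attr(out, "clamped_mass") <- clamped
  out
}
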