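#' Intercellular stress with adhesion
#'
#' Stress in the cell aggregate as a function of total cell concentration:
#' `sigma_C = gamma(C) * K_C0 * (C/C_eq - 1)` with the adhesion factor
#' `gamma` equal to 1 above the equilibrium concentration (linear repulsive
#' branch), proportional to `(C - C_inf)^2` between the detachment cut-off
#' `C_inf` and `C_eq` (adhesive traction branch, calibrated on the cell-cell
#' force-distance curve), and 0 below `C_inf` where cells no longer sense
#' each other.  The 27/4 normalisation makes the global minimum of the
#' stress exactly `-sigma_att`, attained at `C = (2 C_eq + C_inf)/3`.
#' Both branch boundaries evaluate to zero, so the law is continuous.
#'
#' @param C_tot Total cell concentration(s), cells/mm^3 (vectorised).
#' @param params A [sim_params()] object.
#' @return Stress in Pa (positive = compression/repulsion, negative =
#'   traction/adhesion).
#' @export
intercellular_stress <- function(C_tot, params) {
  gam <- adhesion_gamma(C_tot, params)
  gam * params$K_C0 * (C_tot / params$C_eq - 1)
}

adhesion_gamma <- function(C_tot, params) {
  gam <- numeric(length(C_tot))
  hi <- C_tot >= params$C_eq
  mid <- !hi & C_tot >= params$C_inf
  gam[hi] <- 1
  gam[mid] <- (27 / 4) * (params$sigma_att / params$K_C0) * params$C_eq *
    (C_tot[mid] - params$C_inf)^2 / (params$C_eq - params$C_inf)^3
  gam
}

#' Strains and stresses in the matrix from a displacement profile
#'
#' Computes the strain components `eps_rr = du/dr` (centred differences,
#' one-sided at the ends) and `eps_tt = u/r` (with the symmetry limit
#' `eps_tt(0) = du/dr(0)`), the dilatation `eps_v = eps_rr + 2 eps_tt`, and
#' the matrix stress components
#' `sigma_rr = K_ECM/(1+nu) * ((1-nu) eps_rr + 2 nu eps_tt)` and
#' `sigma_tt = K_ECM/(1+nu) * (nu eps_rr + eps_tt)`, with the mean matrix
#' stress `sigma_ECM = (2 sigma_tt + sigma_rr)/3`.
#'
#' The constitutive prefactor `K_ECM/(1+nu)` is the model's printed form;
#' `params$ecm_prefactor = "standard"` switches to the textbook Lame form
#' `E/((1+nu)(1-2nu))` for sensitivity runs.
#'
#' @param u Displacement profile, mm, with `u[1] = 0` at the centre.
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @return A list with `eps_rr`, `eps_tt`, `eps_v`, `sigma_rr`, `sigma_tt`,
#'   `sigma_ECM`.
#' @export
ecm_stress <- function(u, params, grid) {
  stopifnot(length(u) == grid$n)
  eps_rr <- radial_gradient(u, grid)
  eps_tt <- c(eps_rr[1], u[-1] / grid$r[-1])
  eps_v <- eps_rr + 2 * eps_tt
  pref <- if (identical(params$ecm_prefactor, "standard")) {
    params$E_ECM / ((1 + params$nu_ECM) * (1 - 2 * params$nu_ECM))
  } else {
    params$K_ECM / (1 + params$nu_ECM)
  }
  nu <- params$nu_ECM
  sigma_rr <- pref * ((1 - nu) * eps_rr + 2 * nu * eps_tt)
  sigma_tt <- pref * (nu * eps_rr + eps_tt)
  list(eps_rr = eps_rr, eps_tt = eps_tt, eps_v = eps_v,
       sigma_rr = sigma_rr, sigma_tt = sigma_tt,
       sigma_ECM = (2 * sigma_tt + sigma_rr) / 3)
}

#' Iso-strain composite total stress
#'
#' Volume-fraction weighted mixture of the two constituent stresses:
#' `sigma_tot = (1 - C_tot/C_max) sigma_ECM + (C_tot/C_max) sigma_C`.
#' Concentrations are clipped to `[0, C_max]` (with a warning on overshoot)
#' so the mixture always lies pointwise between the two constituents.
#'
#' @param sigma_C Intercellular stress profile, Pa.
#' @param sigma_ECM Matrix stress profile, Pa.
#' @param C_tot Total cell concentration profile, cells/mm^3.
#' @param params A [sim_params()] object.
#' @return Total stress profile, Pa.
#' @export
total_stress <- function(sigma_C, sigma_ECM, C_tot, params) {
  if (any(C_tot < 0) || any(C_tot > params$C_max)) {
    warning("total_stress: C_tot outside [0, C_max]; clipping for the mixture",
            call. = FALSE)
    C_tot <- pmin(pmax(C_tot, 0), params$C_max)
  }
  phi <- C_tot / params$C_max
  (1 - phi) * sigma_ECM + phi * sigma_C
}

#' Stress-gradient drift velocity
#'
#' `v_D = -M_eff * d(sigma_tot)/dr`, the common hydrostatic drift of all
#' cell phenotypes.  In `constant` permeability mode `M_eff = M0`; in
#' `strain` mode the pore-stretch factor applies,
#' `M_eff = M0 * max(0, 1 - eps_v/3)^2`, so matrix compression closes pores
#' and slows cells while tension opens them.  The centre velocity is pinned
#' to zero by symmetry.
#'
#' @param sigma_tot Total stress profile, Pa.
#' @param eps_v Matrix dilatation profile (used in `strain` mode).
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @return Velocity profile, mm/day.
#' @export
drift_velocity <- function(sigma_tot, eps_v, params, grid) {
  grad <- radial_gradient(sigma_tot, grid)
  M_eff <- if (identical(params$permeability_mode, "strain")) {
    params$M0 * pmax(0, 1 - eps_v / 3)^2
  } else {
    params$M0
  }
  v <- -M_eff * grad
  v[1] <- 0
  v
}

#' Full quasi-static mechanics solve
#'
#' One mechanical equilibrium solve for a given total cell concentration
#' profile: intercellular stress, volumetric strain source, displacement
#' boundary-value problem, matrix strains/stresses, iso-strain total stress
#' and drift velocity.  Re-run every transport step (quasi-static growth
#' assumption).
#'
#' The volumetric source is `delta_v = (1/K_ECM) d(sigma_C)/dr` by direct
#' differencing of the stress profile; `params$delta_v_form =
#' "gamma_outside"` instead uses the approximated form
#' `gamma K_C0 / K_ECM * d(C_tot/C_eq)/dr` with the adhesion factor outside
#' the derivative.
#'
#' @param C_tot Total cell concentration profile, cells/mm^3.
#' @param params A [sim_params()] object.
#' @param grid A [radial_grid()].
#' @return A `mechanical_state` list: `u`, `eps_rr`, `eps_tt`, `eps_v`,
#'   `sigma_C`, `sigma_rr`, `sigma_tt`, `sigma_ECM`, `sigma_tot`, `v_D`,
#'   `phi_c`.
#' @export
solve_mechanics <- function(C_tot, params, grid) {
  sigma_C <- intercellular_stress(C_tot, params)
  delta_v <- if (identical(params$delta_v_form, "gamma_outside")) {
    adhesion_gamma(C_tot, params) * params$K_C0 / params$K_ECM *
      radial_gradient(C_tot / params$C_eq, grid)
  } else {
    radial_gradient(sigma_C, grid) / params$K_ECM
  }
  u <- solve_displacement(delta_v, params$nu_ECM, grid)
  ecm <- ecm_stress(u, params, grid)
  C_clip <- pmin(pmax(C_tot, 0), params$C_max)
  sigma_tot <- total_stress(sigma_C, ecm$sigma_ECM, C_clip, params)
  v_D <- drift_velocity(sigma_tot, ecm$eps_v, params, grid)
  structure(
    list(u = u, eps_rr = ecm$eps_rr, eps_tt = ecm$eps_tt, eps_v = ecm$eps_v,
         sigma_C = sigma_C, sigma_rr = ecm$sigma_rr, sigma_tt = ecm$sigma_tt,
         sigma_ECM = ecm$sigma_ECM, sigma_tot = sigma_tot, v_D = v_D,
         phi_c = C_clip / params$C_max),
    class = "mechanical_state"
  )
}
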