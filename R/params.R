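#' Maximum packing concentration from single-cell volume
#'
#' Theoretical upper cut-off of cell density: the reciprocal of the volume of
#' a single cell, i.e. the concentration at which cells fill all space with
#' no fluid or matrix in between.  For a typical glioma cell volume of
#' 1200 um^3 this evaluates to about 8.3e5 cells/mm^3.
#'
#' @param V_cell Single-cell volume in um^3.
#' @return Concentration in cells/mm^3.
#' @export
#' @examples
#' max_packing_concentration(1200)  # ~8.3e5
max_packing_concentration <- function(V_cell) {
  if (!is.numeric(V_cell) || length(V_cell) != 1L || !is.finite(V_cell) ||
      V_cell <= 0) {
    stop("invalid parameter: V_cell must be a positive finite volume (um^3)",
         call. = FALSE)
  }
  1e9 / V_cell  # 1e9 um^3 per mm^3
}

#' Concentration corresponding to a uniform intercellular spacing
#'
#' Under a uniform cubic arrangement with centre-to-centre spacing `r` the
#' number density is 1/r^3.  Used to translate characteristic separations of
#' the cell-cell force-distance curve (the detachment cut-off at ~33 um and
#' the maximum-attraction separation at ~16.2 um) into the concentrations
#' C_inf and C_att of the intercellular stress law.
#'
#' @param r Centre-to-centre spacing in um.
#' @return Concentration in cells/mm^3.
#' @export
#' @examples
#' concentration_from_spacing(33)    # ~2.8e4  (cut-off C_inf)
#' concentration_from_spacing(16.2)  # ~2.35e5 (max attraction C_att)
concentration_from_spacing <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0) {
    stop("invalid parameter: spacing r must be a positive finite length (um)",
         call. = FALSE)
  }
  1e9 / r^3
}

#' Maximum contractile (adhesion) stress of a cell aggregate
#'
#' Peak traction a cell can exert on its neighbourhood: the peak cell-cell
#' attraction force times the number of touching neighbours, spread over the
#' cell surface.  With f_max = 430 pN, 12 neighbours (the sphere kissing
#' number) and S_cell = 550 um^2 this gives ~10 Pa.
#'
#' @param f_max Peak attraction force per cell pair, pN.
#' @param n_neighbors Number of interacting neighbours.
#' @param S_cell Cell surface area, um^2.
#' @return Stress in Pa.
#' @export
max_contractile_stress <- function(f_max, n_neighbors, S_cell) {
  if (!is.numeric(f_max) || length(f_max) != 1L || !is.finite(f_max) ||
      f_max < 0) {
    stop("invalid parameter: f_max must be a non-negative force (pN)",
         call. = FALSE)
  }
  if (!is.numeric(n_neighbors) || length(n_neighbors) != 1L ||
      !is.finite(n_neighbors) || n_neighbors <= 0) {
    stop("invalid parameter: n_neighbors must be positive", call. = FALSE)
  }
  if (!is.numeric(S_cell) || length(S_cell) != 1L || !is.finite(S_cell) ||
      S_cell <= 0) {
    stop("invalid parameter: S_cell must be a positive area (um^2)",
         call. = FALSE)
  }
  # pN/um^2 = 1e-12 N / 1e-12 m^2 = Pa
  n_neighbors * f_max / S_cell
}

#' Cell mobility from matrix permeability and cell viscosity
#'
#' Darcy-type mobility M = k/mu converted to the internal unit system
#' (mm^2 per Pa per day).  The paper's reference values k = 1e-12 m^2 and
#' mu = 300 Pa s give M = 2.9e-4 mm^2/(Pa day).
#'
#' @param k Matrix permeability, m^2.
#' @param mu Dynamic viscosity of the cell phase, Pa s.
#' @return Mobility in mm^2/(Pa day).
#' @export
mobility_from_permeability <- function(k, mu) {
  if (!is.numeric(k) || length(k) != 1L || is.na(k) || k <= 0) {
    stop("invalid parameter: permeability k must be positive (m^2)",
         call. = FALSE)
  }
  if (!is.numeric(mu) || length(mu) != 1L || is.na(mu) || mu <= 0) {
    stop("invalid parameter: viscosity mu must be positive (Pa s)",
         call. = FALSE)
  }
  # m^2/(Pa s) -> mm^2/(Pa day): 1e6 mm^2/m^2 * 86400 s/day
  (k / mu) * 1e6 * 86400
}

#' Bulk modulus from Young's modulus and Poisson ratio
#'
#' K = E / (3 (1 - 2 nu)).  Diverges at the incompressible limit nu = 0.5,
#' which is rejected.
#'
#' @param E Young's modulus, Pa.
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @return Bulk modulus in Pa.
#' @export
#' @examples
#' bulk_modulus_from_young(500, 0.13)  # ~225 Pa (soft collagen)
#' bulk_modulus_from_young(300, 0.4)   # 500 Pa (cell aggregate)
bulk_modulus_from_young <- function(E, nu) {
  if (!is.numeric(E) || length(E) != 1L || !is.finite(E) || E <= 0) {
    stop("invalid parameter: E must be a positive modulus (Pa)", call. = FALSE)
  }
  if (!is.numeric(nu) || length(nu) != 1L || !is.finite(nu) || nu < 0 ||
      nu >= 0.5) {
    stop("invalid parameter: nu must lie in [0, 0.5) (incompressible limit excluded)",
         call. = FALSE)
  }
  E / (3 * (1 - 2 * nu))
}

#' Simulation parameters
#'
#' Builds the full parameter set of the two-constituent spheroid growth
#' model: geometry and packing of the cell phase, the adhesion stress law,
#' matrix elasticity and permeability, phenotype kinetics and oxygen
#' transport, initial conditions and scenario switches.  Defaults are the
#' model's reference glioma parameterisation; every field can be overridden
#' by name.
#'
#' Internal unit system: mm, day, Pa, mg/L, cells/mm^3.  Concentration and
#' length arguments quoted in other units in the literature are converted by
#' the helper derivations (see [max_packing_concentration()],
#' [mobility_from_permeability()], [bulk_modulus_from_young()]).
#'
#' The scenario switches couple fields: `switch_mode = "stiff"` enforces the
#' strict go-or-grow dichotomy (D_p = 0, no hypoxic proliferation,
#' h_m_flag = 0); `switch_mode = "overlap"` allows reduced levels of both
#' (D_p = D_m/10, h_m_flag = 1).
#'
#' @param ... Named overrides of any parameter field.
#' @return An object of class `sim_params` (a validated named list).
#' @export
#' @examples
#' p <- sim_params()
#' p$C_max
#' p2 <- sim_params(E_ECM = 2500, oxygen_bc = "PSBC")
sim_params <- function(...) {
  V_cell <- 1200                               # um^3
  C_max  <- max_packing_concentration(V_cell)  # cells/mm^3
  E_ECM  <- 1000                               # Pa, baseline assumption
  nu_ECM <- 0.13
  D_m    <- 2.0e-2                             # mm^2/day
  n0     <- 4.0                                # mg/L
  p <- list(
    V_cell    = V_cell,
    C_max     = C_max,
    C_eq      = 3.5e5,
    C_inf     = 2.8e4,
    C_att     = 2.35e5,
    sigma_att = 10,
    K_C0      = 500,
    E_ECM     = E_ECM,
    nu_ECM    = nu_ECM,
    K_ECM     = bulk_modulus_from_young(E_ECM, nu_ECM),
    k0        = 1e-12,                         # m^2
    mu_cell   = 300,                           # Pa s
    M0        = mobility_from_permeability(1e-12, 300),
    D_p       = D_m / 10,
    D_m       = D_m,
    D_ox      = 86.4,
    alpha_p   = 1.38e-2,
    alpha_m   = 1.38e-2 / 5,
    xi_h      = 1.0,
    xi_n      = 0.8,
    lambda_switch = 1.0,
    tau_p     = 1.0,                           # day
    tau_m     = 2.0,
    tau_pm    = 1 / 24,
    tau_mp    = 4.0,
    tau_n     = 32 / 24,
    h_m_flag  = 1,
    C_q       = C_max,
    n0        = n0,
    n_max     = n0,
    R0        = 0.25,                          # mm
    C_init    = 7.0e4,
    R_dom     = 1.5,                           # mm
    dr        = 5e-3,                          # mm
    dt        = 2e-4,                          # day
    oxygen_bc = "RBC",
    switch_mode = "overlap",
    permeability_mode = "constant",
    delta_v_form = "exact",
    ecm_prefactor = "as_printed"
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == "")) {
      stop("all parameter overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides

    # derived fields follow their sources unless explicitly pinned
    if (("V_cell" %in% names(overrides)) && !("C_max" %in% names(overrides))) {
      p$C_max <- max_packing_concentration(p$V_cell)
    }
    if (any(c("E_ECM", "nu_ECM") %in% names(overrides)) &&
        !("K_ECM" %in% names(overrides))) {
      p$K_ECM <- bulk_modulus_from_young(p$E_ECM, p$nu_ECM)
    }
    if (any(c("k0", "mu_cell") %in% names(overrides)) &&
        !("M0" %in% names(overrides))) {
      p$M0 <- mobility_from_permeability(p$k0, p$mu_cell)
    }
    if (("C_max" %in% names(overrides)) && !("C_q" %in% names(overrides))) {
      p$C_q <- p$C_max
    }
    if (("n0" %in% names(overrides)) && !("n_max" %in% names(overrides))) {
      p$n_max <- p$n0
    }
  }

  # the switch mode pins motility/proliferation of the two live phenotypes
  if (identical(p$switch_mode, "stiff")) {
    if (!("D_p" %in% names(overrides)))      p$D_p <- 0
    if (!("h_m_flag" %in% names(overrides))) p$h_m_flag <- 0
  } else if (identical(p$switch_mode, "overlap")) {
    if (!("D_p" %in% names(overrides)))      p$D_p <- p$D_m / 10
    if (!("h_m_flag" %in% names(overrides))) p$h_m_flag <- 1
  }

  class(p) <- "sim_params"
  validate_params(p)
  p
}

#' Validate a simulation parameter set
#'
#' Checks every structural invariant of the parameter set (concentration
#' ordering, elastic-constant ranges, threshold ordering, geometry, scenario
#' switch consistency) and fails with a named error for the first violated
#' constraint.
#'
#' @param p A `sim_params` object or compatible named list.
#' @return `p`, invisibly, if valid.
#' @export
validate_params <- function(p) {
  fail <- function(name, msg) {
    stop(sprintf("invalid parameters [%s]: %s", name, msg), call. = FALSE)
  }
  num_pos <- function(field, allow_zero = FALSE) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) ||
        (if (allow_zero) v < 0 else v <= 0)) {
      fail(field, paste0("must be a ", if (allow_zero) "non-negative"
                         else "positive", " finite number"))
    }
  }
  for (f in c("V_cell", "C_max", "C_eq", "C_inf", "C_att", "K_C0", "E_ECM",
              "K_ECM", "k0", "mu_cell", "M0", "tau_p", "tau_m",
              "tau_pm", "tau_mp", "tau_n", "C_q", "n0", "n_max", "R0",
              "C_init", "R_dom", "dr", "dt", "lambda_switch")) {
    num_pos(f)
  }
  for (f in c("sigma_att", "D_p", "D_m", "D_ox", "alpha_p", "alpha_m", "xi_h",
              "xi_n")) {
    num_pos(f, allow_zero = TRUE)
  }
  if (!(p$C_inf < p$C_att)) fail("concentration_order", "requires C_inf < C_att")
  if (!(p$C_att < p$C_eq))  fail("concentration_order", "requires C_att < C_eq")
  if (!(p$C_eq < p$C_q))    fail("concentration_order", "requires C_eq < C_q")
  if (!(p$C_q <= p$C_max))  fail("concentration_order", "requires C_q <= C_max")
  if (!(p$nu_ECM > 0 && p$nu_ECM < 0.5)) {
    fail("nu_ECM", "must lie strictly inside (0, 0.5)")
  }
  if (!(p$xi_n < p$xi_h)) fail("oxygen_thresholds", "requires xi_n < xi_h")
  if (!(p$xi_h < p$n0))   fail("oxygen_thresholds", "requires xi_h < n0")
  if (!(p$R0 < p$R_dom))  fail("geometry", "requires R0 < R_dom")
  if (!(p$dr < p$R0))     fail("geometry", "requires dr < R0")
  if (!p$oxygen_bc %in% c("RBC", "PSBC")) {
    fail("oxygen_bc", "must be 'RBC' or 'PSBC'")
  }
  if (!p$switch_mode %in% c("stiff", "overlap")) {
    fail("switch_mode", "must be 'stiff' or 'overlap'")
  }
  if (!p$permeability_mode %in% c("constant", "strain")) {
    fail("permeability_mode", "must be 'constant' or 'strain'")
  }
  if (!p$delta_v_form %in% c("exact", "gamma_outside")) {
    fail("delta_v_form", "must be 'exact' or 'gamma_outside'")
  }
  if (!p$ecm_prefactor %in% c("as_printed", "standard")) {
    fail("ecm_prefactor", "must be 'as_printed' or 'standard'")
  }
  if (identical(p$switch_mode, "stiff") &&
      (p$D_p != 0 || p$h_m_flag != 0)) {
    fail("switch_mode", "stiff mode requires D_p = 0 and h_m_flag = 0")
  }
  if (!p$h_m_flag %in% c(0, 1)) fail("h_m_flag", "must be 0 or 1")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params> two-constituent spheroid growth model\n")
  cat(sprintf("  cells : C_eq %.3g, C_inf %.3g, C_att %.3g, C_max %.3g cells/mm^3\n",
              x$C_eq, x$C_inf, x$C_att, x$C_max))
  cat(sprintf("  stress: sigma_att %.3g Pa, K_C0 %.3g Pa; ECM E %.3g Pa, nu %.3g (K %.4g Pa)\n",
              x$sigma_att, x$K_C0, x$E_ECM, x$nu_ECM, x$K_ECM))
  cat(sprintf("  drift : M0 %.3g mm^2/(Pa day), permeability %s\n",
              x$M0, x$permeability_mode))
  cat(sprintf("  oxygen: D %.3g mm^2/day, n0 %.3g mg/L, xi_h %.3g, xi_n %.3g, BC %s\n",
              x$D_ox, x$n0, x$xi_h, x$xi_n, x$oxygen_bc))
  cat(sprintf("  switch: %s (D_p %.3g, h_m %d)\n",
              x$switch_mode, x$D_p, as.integer(x$h_m_flag)))
  cat(sprintf("  domain: R0 %.3g mm, R_dom %.3g mm, dr %.3g mm, dt %.3g day\n",
              x$R0, x$R_dom, x$dr, x$dt))
  invisible(x)
}

#' Read simulation parameters from a configuration file
#'
#' The configuration format is flat YAML key/value pairs whose keys are the
#' `sim_params` field names, with an optional `scenario:` key naming a preset
#' (see [scenario_preset()]) applied before the explicit overrides.  Unknown
#' keys are errors.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `sim_params` object.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) {
    stop("configuration file not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  if (!is.list(cfg)) stop("configuration must be a key/value mapping",
                          call. = FALSE)
  base <- list()
  if (!is.null(cfg$scenario)) {
    base <- scenario_preset(cfg$scenario)$overrides
    cfg$scenario <- NULL
  }
  # explicit keys win over the scenario preset
  base[names(cfg)] <- cfg
  do.call(sim_params, base)
}
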