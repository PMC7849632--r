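#' Crank-Nicolson step for spherical diffusion
#'
#' Advances `df/dt = (1/r^2) d/dr (D r^2 df/dr)` by one time step with the
#' Crank-Nicolson scheme in conservative finite-volume form.  The centre is
#' a symmetry boundary; the outer border is either zero-flux (`no_flux`,
#' under which the weighted total `sum(w*f)` is conserved to round-off) or
#' held at a fixed value (`dirichlet`).
#'
#' @param field Radial profile on the grid nodes.
#' @param D Diffusivity, mm^2/day (non-negative).
#' @param dt Time step, day.
#' @param grid A [radial_grid()].
#' @param bc `"no_flux"` or `"dirichlet"`.
#' @param bc_value Boundary value for the Dirichlet case.
#' @return The updated profile.
#' @export
diffuse_cn <- function(field, D, dt, grid, bc = c("no_flux", "dirichlet"),
                       bc_value = NA_real_) {
  bc <- match.arg(bc)
  stopifnot(length(field) == grid$n)
  if (!all(is.finite(field))) stop("diffuse_cn: field must be finite",
                                   call. = FALSE)
  if (!is.finite(D) || D < 0) stop("diffuse_cn: D must be >= 0", call. = FALSE)
  if (!is.finite(dt) || dt <= 0) stop("diffuse_cn: dt must be > 0",
                                      call. = FALSE)
  if (D == 0 && bc == "no_flux") return(field)
  if (bc == "dirichlet" && !is.finite(bc_value)) {
    stop("diffuse_cn: dirichlet boundary needs a finite bc_value",
         call. = FALSE)
  }
  cn_diffuse_step(as.numeric(field), D, dt, grid$w, grid$S_face, grid$dr,
                  if (bc == "dirichlet") 1L else 0L,
                  if (bc == "dirichlet") bc_value else 0)
}

#' Flux-corrected transport step for spherical advection
#'
#' Advances `df/dt + (1/r^2) d(r^2 v f)/dr = 0` by one conservative
#' flux-corrected transport step: donor-cell low-order transport plus a
#' Zalesak-limited centred antidiffusive correction.  Face velocities are
#' arithmetic means of the node velocities; flux through the centre and the
#' outer border is identically zero, so `sum(w*f)` is conserved to
#' round-off.  The limiter guarantees non-negative output from non-negative
#' input and no new local extrema beyond the low-order transported bounds.
#'
#' The CFL condition `max |v| dt / dr <= 0.5` is enforced; callers that need
#' larger steps must sub-cycle (see [cell_transport_step()]).
#'
#' @param field Non-negative radial profile.
#' @param v Node velocities, mm/day.
#' @param dt Time step, day.
#' @param grid A [radial_grid()].
#' @return The updated profile.
#' @export
advect_fct <- function(field, v, dt, grid) {
  stopifnot(length(field) == grid$n, length(v) == grid$n)
  if (!is.finite(dt) || dt <= 0) stop("advect_fct: dt must be > 0",
                                      call. = FALSE)
  v_face <- (v[-1] + v[-length(v)]) / 2
  cfl <- max(abs(v_face)) * dt / grid$dr
  if (cfl > 0.5 + 1e-12) {
    stop(sprintf("advect_fct: CFL violation (max |v| dt/dr = %.3g > 0.5); sub-cycle the step",
                 cfl), call. = FALSE)
  }
  if (all(v_face == 0)) return(field)
  fct_advect_step(as.numeric(field), v_face, dt, grid$w, grid$S_face)
}

#' Quasi-static displacement boundary-value solve
#'
#' Solves the spherically symmetric displacement equation
#' `d/dr[(1/r^2) d(r^2 u)/dr] = ((1+nu)/(1-nu)) delta_v`
#' with regularity `u(0) = 0` and a fixed outer border `u(R_dom) = 0`,
#' discretised by a symmetric second-order scheme and solved as a
#' tridiagonal system.  `delta_v` is the volumetric strain source produced
#' by the expanding cell aggregate inside the matrix.
#'
#' @param delta_v Source profile (1/mm) on the grid nodes.
#' @param nu Poisson ratio of the matrix, in `[0, 0.5)`.
#' @param grid A [radial_grid()].
#' @return Displacement profile `u` in mm.
#' @export
solve_displacement <- function(delta_v, nu, grid) {
  stopifnot(length(delta_v) == grid$n)
  if (!all(is.finite(delta_v))) {
    stop("solve_displacement: delta_v must be finite", call. = FALSE)
  }
  if (!is.finite(nu) || nu < 0 || nu >= 0.5) {
    stop("solve_displacement: nu must lie in [0, 0.5)", call. = FALSE)
  }
  n <- grid$n
  dr <- grid$dr
  r <- grid$r
  rhs <- (1 + nu) / (1 - nu) * delta_v

  a <- numeric(n); b <- numeric(n); c <- numeric(n); d <- numeric(n)
  # u(0) = 0 and u(R_dom) = 0
  b[1] <- 1; d[1] <- 0
  b[n] <- 1; d[n] <- 0
  i <- 2:(n - 1)
  ri <- r[i]
  # u'' + 2 u'/r - 2 u/r^2 = rhs, symmetric second-order stencil
  a[i] <- 1 / dr^2 - 1 / (ri * dr)
  b[i] <- -2 / dr^2 - 2 / ri^2
  c[i] <- 1 / dr^2 + 1 / (ri * dr)
  d[i] <- rhs[i]
  thomas_solve(a, b, c, d)
}
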