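p0 <- sim_params()

test_that("switch factors sit at 1/2 on their thresholds and saturate away from them", {
  h <- switch_factors(p0$xi_h, p0)
  expect_equal(h$h_pm, 0.5)
  expect_equal(h$h_mp, 0.5)
  expect_equal(switch_factors(p0$xi_n, p0)$h_nec, 0.5)
  h_hi <- switch_factors(p0$xi_h + 10 * p0$lambda_switch, p0)
  expect_lt(h_hi$h_pm, 1e-8)
  expect_gt(h_hi$h_mp, 1 - 1e-8)
  # complementarity holds for every oxygen level
  n <- seq(0, 10, by = 0.05)
  hh <- switch_factors(n, p0)
  expect_equal(hh$h_pm + hh$h_mp, rep(1, length(n)))
  expect_true(all(unlist(hh) > 0 & unlist(hh) < 1))
})

test_that("phenotype sources conserve cells through transitions", {
  expect_equal(unlist(phenotype_sources(0, 0, 0, 2, p0)), c(S_p = 0, S_m = 0, S_n = 0))

  # at carrying capacity the proliferation terms vanish and the transition
  # terms cancel pairwise
  S <- phenotype_sources(p0$C_q / 2, p0$C_q / 4, p0$C_q / 4, 2, p0)
  expect_equal(S$S_p + S$S_m + S$S_n, 0, tolerance = 1e-10)

  # total source equals the proliferation terms alone for arbitrary states
  set.seed(11)
  for (k in 1:5) {
    C_p <- runif(1, 0, 5e5); C_m <- runif(1, 0, 5e5); C_n <- runif(1, 0, 2e5)
    n_ox <- runif(1, 0, 5)
    S <- phenotype_sources(C_p, C_m, C_n, n_ox, p0)
    C_tot <- C_p + C_m + C_n
    growth <- (C_p / p0$tau_p + p0$h_m_flag * C_m / p0$tau_m) *
      max(0, 1 - C_tot / p0$C_q) * (n_ox / p0$n_max)
    expect_equal(S$S_p + S$S_m + S$S_n, growth, tolerance = 1e-10)
    expect_gte(S$S_n, 0)  # necrotic mass never decreases
  }

  # with proliferation switched off the sources are purely redistributive
  p_slow <- sim_params(tau_p = 1e9, tau_m = 1e9)
  S2 <- phenotype_sources(3e5, 1e5, 1e4, 0.9, p_slow)
  expect_equal(S2$S_p + S2$S_m + S2$S_n, 0, tolerance = 1e-3)
})

test_that("stiff switch silences hypoxic proliferation and proliferative motility", {
  ps <- sim_params(switch_mode = "stiff")
  S <- phenotype_sources(0, 1e5, 0, 4, ps)
  # no proliferation of hypoxic cells: S_m has only transition/necrosis terms
  h <- switch_factors(4, ps)
  expect_equal(S$S_m, -h$h_mp * 1e5 / ps$tau_mp - h$h_nec * 1e5 / ps$tau_n)
  expect_equal(ps$D_p, 0)
})

test_that("oxygen uptake follows the closed-form linear decay when diffusion is off", {
  p <- sim_params(D_ox = 0)
  g <- radial_grid(p$R_dom, p$dr)
  C_p <- rep(7e4, g$n)
  C_m <- rep(0, g$n)
  n_ox <- rep(p$n0, g$n)
  dt <- 1e-4
  for (k in 1:40) n_ox <- oxygen_step(n_ox, C_p, C_m, dt, p, g)
  # local depletion rate alpha_p * C_p = 966 mg/(L day): n = n0 - 966 t
  expect_equal(n_ox, rep(p$n0 - 1.38e-2 * 7e4 * 0.004, g$n),
               tolerance = 1e-10)
  # the clamp stops the decay at zero (n0/966 = 0.0041 day to exhaustion)
  for (k in 1:100) n_ox <- oxygen_step(n_ox, C_p, C_m, dt, p, g)
  expect_true(all(n_ox >= 0))
  expect_equal(max(n_ox), 0)
})

test_that("oxygen boundary conditions behave as closed-domain vs permanent supply", {
  g <- radial_grid(1, 0.01)
  p_rbc <- sim_params(R_dom = 1, dr = 0.01)
  p_ps <- sim_params(R_dom = 1, dr = 0.01, oxygen_bc = "PSBC")
  C_p <- ifelse(g$r < 0.25, 7e4, 0)
  C_m <- rep(0, g$n)
  n1 <- rep(p_rbc$n0, g$n)
  n2 <- n1
  for (k in 1:50) {
    n1 <- oxygen_step(n1, C_p, C_m, 2e-4, p_rbc, g)
    n2 <- oxygen_step(n2, C_p, C_m, 2e-4, p_ps, g)
  }
  # closed domain: total oxygen strictly decreases; no cells, no change
  expect_lt(radial_integral(n1, g), p_rbc$n0 * sum(g$w))
  expect_equal(oxygen_step(rep(2, g$n), C_m, C_m, 1e-3, p_rbc, g),
               rep(2, g$n))
  # permanent supply pins the border node after every step
  expect_equal(n2[g$n], p_ps$n0)
  expect_gt(radial_integral(n2, g), radial_integral(n1, g))
})

test_that("cell transport conserves total mass when sources are off", {
  p <- sim_params()
  g <- radial_grid(p$R_dom, p$dr)
  fields <- list(C_p = ifelse(g$r < 0.25, 7e4, 0),
                 C_m = 1e4 * exp(-(g$r / 0.3)^2),
                 C_n = rep(0, g$n))
  v <- -0.5 * sin(pi * g$r / g$R_dom)  # inward sweep, zero at both borders
  m0 <- radial_integral(fields$C_p + fields$C_m + fields$C_n, g)
  for (k in 1:25) {
    fields <- cell_transport_step(fields, v, rep(4, g$n), 2e-4, p, g,
                                  sources = FALSE)
  }
  m1 <- radial_integral(fields$C_p + fields$C_m + fields$C_n, g)
  expect_equal(m1, m0, tolerance = 1e-8)
  expect_true(all(fields$C_p >= 0 & fields$C_m >= 0 & fields$C_n >= 0))
  expect_equal(fields$C_tot, fields$C_p + fields$C_m + fields$C_n)
})

test_that("well-oxygenated uniform growth is exponential with rate 1/tau_p", {
  # high oxygen keeps the hypoxic leak negligible; uniform fields make
  # transport a no-op, so the closed-form C_p(t) = C_p(0) exp(t/tau_p) holds
  p <- sim_params(switch_mode = "stiff", n0 = 20, xi_h = 1, xi_n = 0.8)
  g <- radial_grid(p$R_dom, 0.05)
  fields <- list(C_p = rep(100, g$n), C_m = rep(0, g$n), C_n = rep(0, g$n))
  v0 <- rep(0, g$n)
  n_ox <- rep(p$n_max, g$n)
  dt <- 1e-3
  for (k in 1:1000) {
    fields <- cell_transport_step(fields, v0, n_ox, dt, p, g)
  }
  expect_equal(fields$C_p[1], 100 * exp(1), tolerance = 0.01)
  expect_true(all(abs(fields$C_p - fields$C_p[1]) < 1e-8))
})

test_that("sub-cycling honours the CFL contract instead of failing", {
  p <- sim_params()
  g <- radial_grid(1, 0.01)
  fields <- list(C_p = exp(-(g$r / 0.3)^2), C_m = rep(0, g$n),
                 C_n = rep(0, g$n))
  v <- rep(-40, g$n)  # CFL = 0.8 at dt = 2e-4: needs sub-cycling
  v[1] <- 0
  m0 <- radial_integral(fields$C_p, g)
  out <- cell_transport_step(fields, v, rep(4, g$n), 2e-4, p, g,
                             sources = FALSE)
  expect_equal(radial_integral(out$C_p, g), m0, tolerance = 1e-8)
})
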