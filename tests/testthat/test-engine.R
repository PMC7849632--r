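test_that("initialisation places a sharp proliferative spheroid in fresh matrix", {
  p <- sim_params()
  g <- radial_grid(p$R_dom, p$dr)
  st <- initialize_state(p, g)
  expect_equal(st$t, 0)
  # inside/outside the initial radius
  expect_true(all(st$C_p[g$r <= p$R0] == p$C_init))
  expect_true(all(st$C_p[g$r > p$R0 + 1e-9] == 0))
  # proliferative cells only at t = 0
  expect_true(all(st$C_m == 0))
  expect_true(all(st$C_n == 0))
  expect_true(all(st$n_ox == p$n0))
  # total initial cell count ~ C_init * (4/3) pi R0^3 (one-node-wide step
  # puts the discrete count within half a shell of the continuum value)
  expect_equal(radial_integral(st$C_p, g), p$C_init * 4 / 3 * pi * p$R0^3,
               tolerance = 0.035)
  expect_error(sim_params(R0 = 2), "geometry")
})

test_that("a fully degenerate configuration is a fixed point of the step", {
  # cells below the adhesion cut-off, no motility, no uptake, no kinetics
  p <- sim_params(switch_mode = "stiff", D_m = 0, alpha_p = 0, alpha_m = 0,
                  tau_p = 1e9, tau_m = 1e9, tau_pm = 1e9, tau_mp = 1e9,
                  tau_n = 1e9, C_init = 2e4)
  g <- radial_grid(p$R_dom, p$dr)
  st <- initialize_state(p, g)
  st2 <- step_state(st, p$dt, p, g)
  expect_equal(st2$C_p, st$C_p)
  expect_equal(st2$C_m, st$C_m)
  expect_equal(st2$C_n, st$C_n)
  expect_equal(st2$n_ox, st$n_ox)
  expect_equal(max(abs(st2$mech$v_D)), 0)
})

test_that("no necrosis occurs while the domain is well oxygenated", {
  p <- sim_params()
  g <- radial_grid(p$R_dom, p$dr)
  st <- initialize_state(p, g)
  st2 <- step_state(st, p$dt, p, g)
  expect_equal(radial_integral(st2$C_n, g), 0, tolerance = 1e-6)
})

test_that("trajectories are deterministic and snapshots strictly ordered", {
  r1 <- run_scenario(NULL, sim_params(), t_end = 0.02,
                     snapshot_every = 0.01, snapshot_times = numeric(0))
  r2 <- run_scenario(NULL, sim_params(), t_end = 0.02,
                     snapshot_every = 0.01, snapshot_times = numeric(0))
  expect_identical(r1$snapshots, r2$snapshots)
  expect_true(all(diff(r1$times) > 0))
  expect_equal(r1$times, c(0, 0.01, 0.02))
})

test_that("early traction phase keeps the intercellular stress non-positive", {
  # below C_eq everywhere, the stress law only produces adhesion traction
  run <- run_scenario("baseline", t_end = 0.3)
  s <- snapshot_at(run, 0.3)
  expect_lte(max(s$mech$sigma_C), 0)
  expect_lt(min(s$mech$sigma_C), 0)  # and it is genuinely active
})

test_that("closed-domain oxygen is non-increasing; permanent supply pins the border", {
  rbc <- run_scenario(NULL, sim_params(), t_end = 0.05,
                      snapshot_every = 0.01, snapshot_times = numeric(0))
  ox <- vapply(rbc$snapshots, function(s) radial_integral(s$n_ox, rbc$grid),
               numeric(1))
  expect_true(all(diff(ox) <= 1e-9))
  ps <- run_scenario(NULL, sim_params(oxygen_bc = "PSBC"), t_end = 0.05,
                     snapshot_every = 0.01, snapshot_times = numeric(0))
  for (s in ps$snapshots) expect_equal(s$n_ox[ps$grid$n], ps$params$n0)
})

test_that("necrotic mass is monotonically non-decreasing along a run", {
  run <- run_scenario(NULL, sim_params(xi_h = 3.5, xi_n = 3.2), t_end = 0.3,
                      snapshot_every = 0.05, snapshot_times = numeric(0))
  necro <- vapply(run$snapshots, function(s) radial_integral(s$C_n, run$grid),
                  numeric(1))
  expect_true(all(diff(necro) >= -1e-9))
  expect_gt(necro[length(necro)], 0)  # raised thresholds force some necrosis
})

test_that("halving the time step leaves the short-horizon profile essentially unchanged", {
  p1 <- sim_params()
  p2 <- sim_params(dt = 1e-4)
  r1 <- run_scenario(NULL, p1, t_end = 0.2, snapshot_every = 0.2,
                     snapshot_times = numeric(0), track_center = FALSE)
  r2 <- run_scenario(NULL, p2, t_end = 0.2, snapshot_every = 0.2,
                     snapshot_times = numeric(0), track_center = FALSE)
  f1 <- snapshot_at(r1, 0.2)$C_tot
  f2 <- snapshot_at(r2, 0.2)$C_tot
  rel <- sqrt(radial_integral((f1 - f2)^2, r1$grid) /
                radial_integral(f2^2, r1$grid))
  expect_lt(rel, 0.01)
})

test_that("scenario presets carry the documented switches", {
  sc <- scenario_preset("subtumor")
  expect_equal(sc$overrides$E_ECM, 2500)
  expect_equal(sc$overrides$oxygen_bc, "PSBC")
  expect_equal(sc$t_end, 5)
  expect_equal(scenario_preset("variable_permeability")$overrides$permeability_mode,
               "strain")
  expect_equal(scenario_preset("stiff_switch")$overrides$switch_mode, "stiff")
  expect_error(scenario_preset("warp_drive"), "unknown scenario")
})

test_that("runs serialise to per-snapshot CSV plus a JSON manifest", {
  run <- run_scenario(NULL, sim_params(), t_end = 0.01,
                      snapshot_every = 0.01, snapshot_times = numeric(0))
  dir <- file.path(tempdir(), "gliosphere-run")
  write_run(run, dir)
  files <- list.files(dir)
  expect_true("manifest.json" %in% files)
  expect_length(grep("^snapshot_.*csv$", files), length(run$snapshots))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$scenario, "custom")
  expect_equal(man$params$C_eq, 3.5e5)
  prof <- utils::read.csv(file.path(dir, grep("snapshot", files, value = TRUE)[1]))
  expect_named(prof, c("r_mm", "C_p", "C_m", "C_n", "C_tot", "n_ox", "u_mm",
                       "eps_v", "sigma_C", "sigma_ECM", "sigma_tot", "v_D"))
  unlink(dir, recursive = TRUE)
})

test_that("snapshot lookup and hypoxia-onset guards work", {
  run <- run_scenario(NULL, sim_params(), t_end = 0.02,
                      snapshot_every = 0.01, snapshot_times = numeric(0),
                      track_center = FALSE)
  expect_error(snapshot_at(run, 0.5), "no snapshot")
  expect_error(hypoxia_onset_time(run), "track_center")
  run2 <- run_scenario(NULL, sim_params(), t_end = 0.02,
                       snapshot_every = 0.01, snapshot_times = numeric(0))
  expect_true(is.na(hypoxia_onset_time(run2)))  # too early to be hypoxic
})
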