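# shared fixtures for the kernel and model tests

small_grid <- function(R_dom = 1, dr = 0.01) radial_grid(R_dom, dr)

# radial fundamental solution of the 3D heat equation (total mass 1)
heat_kernel_radial <- function(r, t, D) {
  (4 * pi * D * t)^(-3 / 2) * exp(-r^2 / (4 * D * t))
}

# deterministic "adversarial" non-negative profile: spikes, zeros, plateaus
spiky_profile <- function(n, seed) {
  set.seed(seed)
  f <- runif(n)^3 * sample(c(0, 1, 10), n, replace = TRUE)
  f[sample(n, n %/% 5)] <- 0
  f
}

# minimal sim_run wrapper so metrics helpers can be tested on synthetic
# profiles without running the engine
fake_run <- function(snapshots, times, grid, params) {
  structure(list(params = params, grid = grid, snapshots = snapshots,
                 times = times, meta = list(scenario = "synthetic")),
            class = "sim_run")
}
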