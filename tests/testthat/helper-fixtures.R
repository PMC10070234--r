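# shared fixtures: small systems and grids that keep the suite fast

# coarse grid: 1024 points x 2 fs -> Nyquist ~8300 cm^-1, resolution ~16 cm^-1
coarse_grid <- function() spectrum_grid(n_t = 1024, dt_fs = 2)

# minimal vibronic model: Qy + Qx + coupling mode, no intramolecular modes
minimal_vibronic_params <- function(alpha = 750) {
  monomer_params(states = electronic_states(c("Qy", "Qx")),
                 modes = mode_catalog(numeric(), numeric()),
                 vc = vc_mode(1500, alpha, max_quanta = 4))
}

# two-level electronic pigment (Qy only, no vibrations at all)
electronic_params <- function() {
  monomer_params(states = electronic_states("Qy"),
                 modes = mode_catalog(numeric(), numeric()),
                 vc = vc_mode(1500, 0, max_quanta = 0))
}

# random mode catalog for property tests
random_catalog <- function(n, seed) {
  set.seed(seed)
  mode_catalog(sort(runif(n, 50, 1600)), runif(n, 0.001, 0.1))
}

wscp_dimer <- function(variant = "vibronic", cfg = default_config("wscp")) {
  build_system(cfg, "dimer", variant)
}

expect_close <- function(x, y, tol) expect_lt(max(abs(x - y)), tol)

normalize_rnd <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

cos_angle <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
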