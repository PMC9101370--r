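# shared fixtures, built once per test run

.cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, .cache)) assign(name, force(expr), .cache)
  get(name, .cache)
}

default_met <- function() {
  micromet(t_air = 25, wind = 2.5, pressure = 1010, e_a = 15, s_dn = 800,
           z_u = 3, z_t = 3, h_c = 0.3)
}

small_scene <- function(seed = 3) {
  scene_spec(extent = c(16, 16), res = 1, seed = seed)
}

# forward-modelled 16x16 scene shared across tests
small_forward <- function() cached("small_forward", forward_fluxes(small_scene()))

# simulated 60 s flight over a 40x40 m scene
small_flight <- function() {
  cached("small_flight", {
    sp <- scene_spec(extent = c(40, 40), res = 0.5, seed = 5)
    dir <- file.path(tempdir(), "etmap-test-flight")
    list(scene = sp, out = simulate_flight(sp, dir, duration = 60))
  })
}

gray_scale <- function() cached("gray_scale", make_color_scale())

expect_same_values <- function(a, b, tol = 1e-12) {
  expect_true(max(abs(a - b), na.rm = TRUE) <= tol)
}
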