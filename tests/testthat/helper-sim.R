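# shared fixtures, built in code

# small noise-free configuration for fast deterministic scans
quiet_cfg <- function(n_lines = 6, seed = 1, ...) {
  acquisition_config(n_lines = n_lines, seed = seed,
                     sensor = sensor_model(read_noise_sigma = 0), ...)
}

# seeded random absorbance cube (values uniform in [0, amax])
random_absorbance_cube <- function(seed, lines = 8, samples = 8,
                                   grid = default_grid(), amax = 3) {
  set.seed(seed)
  vals <- array(runif(lines * samples * length(grid$centers), 0, amax),
                c(lines, samples, length(grid$centers)))
  pushbroom:::new_hyper_cube(vals, grid, array(TRUE, dim(vals)),
                             kind = "absorbance")
}

# reflectance cube with constant spectrum `spec` at every pixel
constant_cube <- function(spec, lines = 2, samples = 3,
                          grid = default_grid(), kind = "reflectance") {
  vals <- array(rep(spec, each = lines * samples),
                c(lines, samples, length(spec)))
  pushbroom:::new_hyper_cube(vals, grid, array(TRUE, dim(vals)), kind = kind)
}

# known projective map used across registration tests
example_homography <- function() {
  matrix(c(0.9, 0.05, 10,
           -0.03, 1.1, 5,
           1e-4, -5e-5, 1), 3, 3, byrow = TRUE)
}
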