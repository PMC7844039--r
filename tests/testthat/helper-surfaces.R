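# fixture builders shared across test files

rough <- function(map) roughness_surface(map)

# small random GRF roughness surface
grf_surf <- function(nx = 16, ny = 16, sq = 0.5, corr_len = 2, seed = 1,
                     dx = 0.5, dy = 0.5) {
  rough(gaussian_random_field(nx, ny, dx, dy, sq = sq, corr_len = corr_len,
                              seed = seed))
}

sinusoid_surf <- function(A = 1, lam = 10, nx = 640, ny = 64, dx = 0.15625,
                          dy = 0.5) {
  # dx chosen to give 64 samples per period so discrete moments match the
  # continuous closed forms well inside 0.5%
  rough(analytic_surface("sinusoid", list(amplitude = A, wavelength = lam),
                         nx = nx, ny = ny, dx = dx, dy = dy))
}

checkerboard_surf <- function(h = 0.3, nx = 64, ny = 64) {
  rough(analytic_surface("checkerboard", list(height = h), nx = nx, ny = ny,
                         dx = 0.5, dy = 0.5))
}

uniform_surf <- function(a = 0.5, nx = 256, ny = 256, seed = 2) {
  rough(analytic_surface("uniform_noise", list(a = a, seed = seed),
                         nx = nx, ny = ny, dx = 0.5, dy = 0.5))
}
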