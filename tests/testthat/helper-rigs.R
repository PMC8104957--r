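# Shared fixtures: poses, rigs, and error metrics used across test files.

rotation_error_deg <- function(R1, R2) {
  acos(pmin(1, pmax(-1, (sum(diag(t(R1) %*% R2)) - 1) / 2))) * 180 / pi
}

random_rotation <- function() {
  rotation_from_euler(runif(1, -180, 180), runif(1, -89, 89), runif(1, -180, 180))
}

random_pose <- function(scale = 1) {
  pose(runif(3, -scale, scale), random_rotation())
}

random_unit_directions <- function(n) {
  m <- matrix(rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# A frontoparallel display 0.2 m ahead subtending 90 x 90 degrees.
frontal_display <- function(nx = 128, ny = 128, distance = 0.2) {
  display_spec("front", pose(c(0, 0, distance)),
               width = 2 * distance, height = 2 * distance,
               resolution_x = nx, resolution_y = ny)
}

test_observer <- function() observer_spec()
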