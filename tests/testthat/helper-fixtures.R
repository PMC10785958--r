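# Shared fixtures: random rigid transforms and small synthetic fields.

# uniform random rotation via QR of a Gaussian matrix (det-corrected)
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_rigid <- function(from = "a", to = "b", t_scale = 50) {
  rigid_transform(random_rotation(), runif(3, -t_scale, t_scale),
                  from = from, to = to)
}

# brute-force 4x4 homogeneous product oracle
dense_product <- function(...) Reduce(`%*%`, lapply(list(...), as_matrix4))

# small pressure field on a given grid from an array
as_field <- function(arr, grid, frequency = 401e3, axis = c(0, 0, 1)) {
  structure(list(rms_pressure = arr, grid = grid, frequency = frequency,
                 axis = axis), class = "pressure_field")
}

# small grid helper
small_grid <- function(n = 16, h = 1) sim_grid_spec(rep(n, 3), h)
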