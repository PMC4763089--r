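# Internal geometry helpers.
#
# Conventions used throughout the package:
#  * arena coordinates (x, y) in mm; x runs along image columns, y along rows,
#    pixel (r, c) has its center at x = (c - 0.5) * pixel_size,
#    y = (r - 0.5) * pixel_size;
#  * an angle phi denotes the direction (cos phi, sin phi);
#  * the "right-hand" normal of a direction phi is (sin phi, -cos phi); the
#    curvature sign and the egocentric lateral axis both use it;
#  * angles are wrapped to (-pi, pi].

# wrap angle(s) to (-pi, pi]
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

unit_vec <- function(phi) c(cos(phi), sin(phi))

right_normal <- function(phi) c(sin(phi), -cos(phi))

# signed z-component of the 2D cross product a x b
cross2 <- function(ax, ay, bx, by) ax * by - ay * bx

# Points of a constant-curvature midline. `center` is the s = 0 point,
# `phi` the tangent direction there, `kappa` signed (positive: center of
# curvature on the right of the heading). Returns a matrix with columns x, y.
arc_points <- function(center, phi, kappa, s) {
  t_hat <- unit_vec(phi)
  if (abs(kappa) < 1e-9) {
    cbind(center[1] + s * t_hat[1], center[2] + s * t_hat[2])
  } else {
    r_hat <- right_normal(phi)
    cc <- center + r_hat / kappa           # center of curvature
    v0 <- center - cc
    cbind(
      cc[1] + cos(kappa * s) * v0[1] + sin(kappa * s) * t_hat[1] / kappa,
      cc[2] + cos(kappa * s) * v0[2] + sin(kappa * s) * t_hat[2] / kappa
    )
  }
}

# trapezoidal integral
trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# deterministic 31-bit sub-seed derived from a base seed and a stream label,
# so that scheduling / kinematics / noise randomness are independent streams
sub_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p, "|"))) h <- (h * 131 + ch) %% 2147483629
  }
  as.integer(h)
}

# evaluate code with a local RNG state seeded from (seed, stream labels)
with_stream <- function(seed, ..., code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(sub_seed(seed, ...))
  force(code)
}
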