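# Independent oracles and generators used across the suite.  These are written
# in plain base R against textbook formulas (quaternion product, quaternion
# rotation matrix) and never call the package's own composition routines.

quat_from_axis_angle <- function(axis, angle_rad) {
  c(cos(angle_rad / 2), sin(angle_rad / 2) * axis / sqrt(sum(axis^2)))
}

quat_mul <- function(p, q) {
  c(p[1] * q[1] - sum(p[2:4] * q[2:4]),
    p[1] * q[2:4] + q[1] * p[2:4] +
      c(p[3] * q[4] - p[4] * q[3],
        p[4] * q[2] - p[2] * q[4],
        p[2] * q[3] - p[3] * q[2]))
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

rv_to_quat <- function(r) {
  n <- sqrt(sum(r^2))
  if (n < 1e-15) return(c(1, 0, 0, 0))
  quat_from_axis_angle(r / n, 2 * atan(n))
}

quat_to_rv <- function(q) {
  if (q[1] < 0) q <- -q
  q[2:4] / q[1]
}

# oracle composition of two rotation vectors through quaternion products
oracle_rv_compose <- function(outer, inner) {
  quat_to_rv(quat_mul(rv_to_quat(outer), rv_to_quat(inner)))
}

random_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-3) return(v / n)
  }
}

random_rv <- function(max_angle_deg = 150) {
  tan(pi / 180 * stats::runif(1, 0, max_angle_deg) / 2) * random_unit3()
}

expect_vec_equal <- function(actual, expected, tol = 1e-12) {
  expect_lt(max(abs(actual - expected)), tol)
}

ref_rr1 <- function() tan(pi / 180 * 26.56 / 2) * c(0.4901, 0, -0.8727)
ref_rr2 <- function() tan(pi / 180 * 16.35 / 2) * c(0.8161, 0, -0.5782)
ref_rr12 <- function() c(0.00152, -0.01410, 0.11920)
ref_rl12 <- function() c(0.00640, -0.01728, 0.14412)
ref_F1 <- function() c(15, 29.56, 7.72)
ref_F2 <- function() c(10, 49.56, 12.72)

local_text_file <- function(content, ext = ".yaml") {
  path <- tempfile(fileext = ext)
  writeLines(content, path)
  path
}
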