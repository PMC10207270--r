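# Internal 3D geometry kernels shared by the builder and the detector.
# All coordinates are orthogonal angstroms; angles in degrees at the API
# surface, radians internally.

vnorm <- function(v) sqrt(sum(v * v))

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at vertex b of the triple a-b-c, in degrees
#'
#' Colinear triples are handled through clamping of the cosine, so degenerate
#' geometry yields exactly 0 or 180 rather than NaN.
#' @param a,b,c numeric 3-vectors (angstroms).
#' @return angle in degrees in [0, 180].
#' @keywords internal
#' @noRd
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  nu <- vnorm(u)
  nv <- vnorm(v)
  if (nu == 0 || nv == 0) stop("angle_deg: coincident atoms")
  cosang <- sum(u * v) / (nu * nv)
  acos(min(1, max(-1, cosang))) * 180 / pi
}

# Torsion a-b-c-d in degrees, IUPAC sign convention (cis = 0).
torsion_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Natural-extension (NeRF) placement: position atom D given the three
# previous atoms a-b-c, the c-D bond length, the b-c-D angle and the
# a-b-c-D torsion. Degrees in, angstroms out.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d_local <- c(-bond * cos(ang),
               bond * sin(ang) * cos(tor),
               -bond * sin(ang) * sin(tor))
  bc <- c - b
  bc <- bc / vnorm(bc)
  ab <- b - a
  n <- vcross(ab, bc)
  nn <- vnorm(n)
  if (nn < 1e-10) {
    # a-b-c colinear: any perpendicular frame serves; pick one deterministically
    ref <- if (abs(bc[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- vcross(ref, bc)
    nn <- vnorm(n)
  }
  n <- n / nn
  m <- vcross(n, bc)
  c + d_local[1L] * bc + d_local[2L] * m + d_local[3L] * n
}

# Rigid transform helpers used by invariance tests and the ensemble code.
rotation_matrix <- function(axis, theta_deg) {
  axis <- axis / vnorm(axis)
  th <- theta_deg * pi / 180
  ct <- cos(th)
  st <- sin(th)
  x <- axis[1L]; y <- axis[2L]; z <- axis[3L]
  matrix(c(ct + x * x * (1 - ct),     x * y * (1 - ct) - z * st, x * z * (1 - ct) + y * st,
           y * x * (1 - ct) + z * st, ct + y * y * (1 - ct),     y * z * (1 - ct) - x * st,
           z * x * (1 - ct) - y * st, z * y * (1 - ct) + x * st, ct + z * z * (1 - ct)),
         nrow = 3L, byrow = TRUE)
}
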