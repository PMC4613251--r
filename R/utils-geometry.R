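# Internal 3-vector helpers shared by the chromophore, builder and
# interaction code. Everything works on plain numeric length-3 vectors.

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) {
    rlang::abort("cannot normalize a (near) zero vector",
                 class = "dipolecd_degenerate_geometry")
  }
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Angle a-b-c in degrees.
vangle <- function(a, b, c) {
  u <- vunit(a - b)
  v <- vunit(c - b)
  rad2deg(acos(max(-1, min(1, sum(u * v)))))
}

# Signed torsion a-b-c-d in degrees, IUPAC sign convention.
vtorsion <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, vunit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  rad2deg(atan2(-y, x))
}

# Natural-extension reference frame placement: position atom d bonded to c,
# with bond length |c-d|, angle b-c-d and torsion a-b-c-d (degrees).
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- deg2rad(angle)
  tor <- deg2rad(torsion)
  d_local <- bond * c(-cos(ang), sin(ang) * cos(tor), sin(ang) * sin(tor))
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- vcross(n, bc)
  rot <- cbind(bc, m, n)
  c(rot %*% d_local) + c
}

# Rotation matrices used by the z-y-z Euler reconstruction.
rot_z <- function(phi) {
  cp <- cos(phi); sp <- sin(phi)
  matrix(c(cp, sp, 0, -sp, cp, 0, 0, 0, 1), 3L, 3L)
}

rot_y <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, 0, -st, 0, 1, 0, st, 0, ct), 3L, 3L)
}
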