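# small linear-algebra helpers shared by the synthetic generator and the
# detector-geometry utilities

# direct lattice basis as columns (a along x, b in xy plane)
direct_basis <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  al <- cell[["alpha"]] * pi / 180
  be <- cell[["beta"]] * pi / 180
  ga <- cell[["gamma"]] * pi / 180
  v <- cell_volume(cell)
  cx <- cc * cos(be)
  cy <- cc * (cos(al) - cos(be) * cos(ga)) / sin(ga)
  cz <- v / (a * b * sin(ga))
  matrix(c(a, 0, 0,
           b * cos(ga), b * sin(ga), 0,
           cx, cy, cz), 3, 3)
}

# reciprocal basis as columns: x* = recip_basis %*% c(h,k,l), Angstrom^-1
recip_basis <- function(cell) {
  t(solve(direct_basis(cell)))
}

# rotation matrix about unit axis u by angle phi (radians), Rodrigues form
rot_about_axis <- function(u, phi) {
  u <- u / sqrt(sum(u^2))
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(phi) * K + (1 - cos(phi)) * (K %*% K)
}

# z-y-z Euler rotation
euler_rotation <- function(angles) {
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(angles[1]) %*% ry(angles[2]) %*% rz(angles[3])
}

# in-plane rotation (spindle) axis for an azimuth in degrees, ccw from +x
axis_vector <- function(azimuth_deg) {
  a <- azimuth_deg * pi / 180
  c(cos(a), sin(a), 0)
}
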