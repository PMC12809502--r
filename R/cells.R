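#' Construct a unit cell
#'
#' A unit cell is stored as a named numeric vector of the six lattice
#' parameters with class `"unit_cell"`. Lengths are in Angstrom, angles in
#' degrees. The metric tensor must be positive definite (i.e. the six numbers
#' must describe a realisable lattice).
#'
#' @param a,b,c Cell edges in Angstrom, all `> 0`.
#' @param alpha,beta,gamma Cell angles in degrees, each in `(0, 180)`.
#' @return An object of class `unit_cell`.
#' @examples
#' uc <- unit_cell(10, 12, 15, 90, 101.5, 90)
#' cell_volume(uc)
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  p <- c(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma)
  if (any(!is.finite(p))) stop("unit cell parameters must be finite")
  if (any(p[1:3] <= 0)) stop("cell edges must be positive")
  if (any(p[4:6] <= 0) || any(p[4:6] >= 180))
    stop("cell angles must lie in (0, 180) degrees")
  uc <- structure(p, class = "unit_cell")
  G <- cell_metric(uc)
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("cell parameters do not define a positive-definite metric")
  uc
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell: a=%.4f b=%.4f c=%.4f  alpha=%.3f beta=%.3f gamma=%.3f  V=%.2f A^3\n",
              x[["a"]], x[["b"]], x[["c"]],
              x[["alpha"]], x[["beta"]], x[["gamma"]], cell_volume(x)))
  invisible(x)
}

#' Real-space metric tensor of a cell
#'
#' @param cell A [unit_cell()].
#' @return 3x3 symmetric matrix of dot products of the cell basis vectors
#'   (Angstrom^2).
#' @export
cell_metric <- function(cell) {
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]]  * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  matrix(c(a * a,      a * b * cg, a * cc * cb,
           a * b * cg, b * b,      b * cc * ca,
           a * cc * cb, b * cc * ca, cc * cc), 3, 3)
}

#' Cell volume
#'
#' Closed-form triclinic volume from the six parameters.
#'
#' @param cell A [unit_cell()].
#' @return Volume in Angstrom^3.
#' @export
cell_volume <- function(cell) {
  ca <- cos(cell[["alpha"]] * pi / 180)
  cb <- cos(cell[["beta"]]  * pi / 180)
  cg <- cos(cell[["gamma"]] * pi / 180)
  arg <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  cell[["a"]] * cell[["b"]] * cell[["c"]] * sqrt(max(arg, 0))
}

#' Reciprocal metric tensor
#'
#' @param cell A [unit_cell()].
#' @return 3x3 matrix G* such that 1/d^2 = h' G* h for Miller index column h.
#' @export
cell_reciprocal_metric <- function(cell) {
  solve(cell_metric(cell))
}

#' Resolution of Miller indices
#'
#' @param hkl Integer matrix with one (h,k,l) row per reflection (a length-3
#'   vector is treated as one reflection).
#' @param cell A [unit_cell()].
#' @return d-spacings in Angstrom (Inf for (0,0,0)).
#' @export
d_spacing <- function(hkl, cell) {
  hkl <- as_hkl_matrix(hkl)
  Gs <- cell_reciprocal_metric(cell)
  inv_d2 <- rowSums((hkl %*% Gs) * hkl)
  ifelse(inv_d2 <= 0, Inf, 1 / sqrt(inv_d2))
}

as_hkl_matrix <- function(hkl) {
  if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
  storage.mode(hkl) <- "double"
  if (ncol(hkl) != 3) stop("hkl must have three columns")
  hkl
}

#' Niggli-reduce a unit cell
#'
#' Reduces the cell to its Niggli form via the Krivy-Gruber algorithm, so
#' that alternative axis choices describing the same lattice map to one
#' canonical parameter set. Used by cell-similarity clustering.
#'
#' @param cell A [unit_cell()].
#' @param eps Relative stability tolerance of the comparisons.
#' @return The reduced cell as a `unit_cell`.
#' @references Krivy, I. & Gruber, B. (1976). Acta Cryst. A32, 297-298.
#' @export
niggli_reduce <- function(cell, eps = 1e-5) {
  # characteristic (A, B, C, xi, eta, zeta) = (a.a, b.b, c.c, 2b.c, 2a.c, 2a.b)
  a <- cell[["a"]]; b <- cell[["b"]]; cc <- cell[["c"]]
  A <- a^2; B <- b^2; C <- cc^2
  xi   <- 2 * b * cc * cos(cell[["alpha"]] * pi / 180)
  eta  <- 2 * a * cc * cos(cell[["beta"]]  * pi / 180)
  zeta <- 2 * a * b  * cos(cell[["gamma"]] * pi / 180)
  e <- eps * max(A, B, C)

  for (iter in 1:100) {
    changed <- FALSE
    # step 1: order A <= B
    if (A > B + e || (abs(A - B) <= e && abs(xi) > abs(eta) + e)) {
      tmp <- A; A <- B; B <- tmp
      tmp <- xi; xi <- eta; eta <- tmp
      changed <- TRUE
    }
    # step 2: order B <= C
    if (B > C + e || (abs(B - C) <= e && abs(eta) > abs(zeta) + e)) {
      tmp <- B; B <- C; C <- tmp
      tmp <- eta; eta <- zeta; zeta <- tmp
      next
    }
    # steps 3/4: all angle terms strictly acute (Type I) or all non-acute (Type II)
    if (xi * eta * zeta > 0) {
      xi <- abs(xi); eta <- abs(eta); zeta <- abs(zeta)
    } else {
      xi <- -abs(xi); eta <- -abs(eta); zeta <- -abs(zeta)
    }
    # step 5
    if (abs(xi) > B + e || (abs(xi - B) <= e && 2 * eta < zeta - e) ||
        (abs(xi + B) <= e && zeta < -e)) {
      s <- if (xi > 0) 1 else -1
      C <- B + C - s * xi
      eta <- eta - s * zeta
      xi <- xi - 2 * s * B
      next
    }
    # step 6
    if (abs(eta) > A + e || (abs(eta - A) <= e && 2 * xi < zeta - e) ||
        (abs(eta + A) <= e && zeta < -e)) {
      s <- if (eta > 0) 1 else -1
      C <- A + C - s * eta
      xi <- xi - s * zeta
      eta <- eta - 2 * s * A
      next
    }
    # step 7
    if (abs(zeta) > A + e || (abs(zeta - A) <= e && 2 * xi < eta - e) ||
        (abs(zeta + A) <= e && eta < -e)) {
      s <- if (zeta > 0) 1 else -1
      B <- A + B - s * zeta
      xi <- xi - s * eta
      zeta <- zeta - 2 * s * A
      next
    }
    # step 8
    if (xi + eta + zeta + A + B < -e ||
        (abs(xi + eta + zeta + A + B) <= e && 2 * (A + eta) + zeta > e)) {
      C <- A + B + C + xi + eta + zeta
      xi <- 2 * B + xi + zeta
      eta <- 2 * A + eta + zeta
      next
    }
    if (!changed) break
  }

  an <- sqrt(A); bn <- sqrt(B); cn <- sqrt(C)
  clamp1 <- function(x) pmin(1, pmax(-1, x))
  unit_cell(an, bn, cn,
            acos(clamp1(xi   / (2 * bn * cn))) * 180 / pi,
            acos(clamp1(eta  / (2 * an * cn))) * 180 / pi,
            acos(clamp1(zeta / (2 * an * bn))) * 180 / pi)
}
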