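laue_names <- c("-1", "2/m", "mmm", "4/m", "4/mmm",
                "-3", "-3m1", "-31m", "6/m", "6/mmm", "m-3", "m-3m")

# generator matrices act on Miller index column vectors: h' = M %*% h
.gen <- list(
  inv   = -diag(3),
  two_x = diag(c(1, -1, -1)),
  two_y = diag(c(-1, 1, -1)),
  two_z = diag(c(-1, -1, 1)),
  four_z  = matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE),
  three_c = matrix(c(0, 1, 0, -1, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
  two_hex_110  = matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE),
  two_hex_m110 = matrix(c(0, -1, 0, -1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE),
  three_111 = matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
)

.laue_generators <- list(
  "-1"    = list(),
  "2/m"   = list(.gen$two_y),
  "mmm"   = list(.gen$two_x, .gen$two_y),
  "4/m"   = list(.gen$four_z),
  "4/mmm" = list(.gen$four_z, .gen$two_x),
  "-3"    = list(.gen$three_c),
  "-3m1"  = list(.gen$three_c, .gen$two_hex_110),
  "-31m"  = list(.gen$three_c, .gen$two_hex_m110),
  "6/m"   = list(.gen$three_c, .gen$two_z),
  "6/mmm" = list(.gen$three_c, .gen$two_z, .gen$two_hex_110),
  "m-3"   = list(.gen$three_111, .gen$two_x, .gen$two_z),
  "m-3m"  = list(.gen$three_111, .gen$four_z)
)

.close_group <- function(gens) {
  ops <- list(diag(3))
  key <- function(m) paste(as.integer(round(m)), collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  queue <- ops
  while (length(queue)) {
    m <- queue[[1]]; queue <- queue[-1]
    for (g in gens) {
      p <- m %*% g
      k <- key(p)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        ops[[length(ops) + 1]] <- p
        queue[[length(queue) + 1]] <- p
      }
    }
  }
  lapply(ops, function(m) { storage.mode(m) <- "integer"; m })
}

.laue_cache <- new.env(parent = emptyenv())

#' Laue group operators
#'
#' Returns the full operator set (integer 3x3 matrices acting on Miller
#' indices) of one of the 11 Laue classes; both trigonal settings -3m1 and
#' -31m are offered (hexagonal axes). The set always contains the Friedel
#' inversion, so anomalous pairs merge.
#'
#' @param name Laue class name, one of `"-1"`, `"2/m"`, `"mmm"`, `"4/m"`,
#'   `"4/mmm"`, `"-3"`, `"-3m1"`, `"-31m"`, `"6/m"`, `"6/mmm"`, `"m-3"`,
#'   `"m-3m"`.
#' @param centering Lattice centering letter (`P`, `A`, `B`, `C`, `I`, `F`,
#'   `R`), used for systematic-extinction filtering downstream.
#' @return An object of class `laue_group`: list with `name`, `operators`
#'   (list of integer matrices, closed under composition, containing -I) and
#'   `centering`.
#' @export
laue_operators <- function(name, centering = "P") {
  if (!name %in% laue_names)
    stop("unknown Laue class: ", name, " (supported: ",
         paste(laue_names, collapse = ", "), ")")
  if (!centering %in% c("P", "A", "B", "C", "I", "F", "R"))
    stop("unknown centering: ", centering)
  ck <- paste0("g", match(name, laue_names))
  if (is.null(.laue_cache[[ck]])) {
    gens <- c(.laue_generators[[name]], list(.gen$inv))
    .laue_cache[[ck]] <- .close_group(gens)
  }
  structure(list(name = name, operators = .laue_cache[[ck]],
                 centering = centering),
            class = "laue_group")
}

#' @export
print.laue_group <- function(x, ...) {
  cat(sprintf("Laue group %s (%d operators, centering %s)\n",
              x$name, length(x$operators), x$centering))
  invisible(x)
}

.spacegroup_centering <- local({
  cent <- rep("P", 230)
  cent[c(5, 8, 9, 12, 15, 20, 21, 35, 36, 37, 63, 64, 65, 66, 67, 68)] <- "C"
  cent[c(38, 39, 40, 41)] <- "A"
  cent[c(22, 42, 43, 69, 70, 196, 202, 203, 209, 210, 216, 219,
         225, 226, 227, 228)] <- "F"
  cent[c(23, 24, 44, 45, 46, 71, 72, 73, 74, 79, 80, 82, 87, 88, 97, 98,
         107, 108, 109, 110, 119, 120, 121, 122, 139, 140, 141, 142,
         197, 199, 204, 206, 211, 214, 217, 220, 229, 230)] <- "I"
  cent[c(146, 148, 155, 160, 161, 166, 167)] <- "R"
  cent
})

.spacegroup_laue <- function(sg) {
  if (sg >= 1 && sg <= 2) return("-1")
  if (sg <= 15)  return("2/m")
  if (sg <= 74)  return("mmm")
  if (sg <= 88)  return("4/m")
  if (sg <= 142) return("4/mmm")
  if (sg <= 148) return("-3")
  if (sg <= 167) {
    if (sg %in% c(149, 151, 153, 157, 159, 162, 163)) return("-31m")
    return("-3m1")
  }
  if (sg <= 176) return("6/m")
  if (sg <= 194) return("6/mmm")
  if (sg <= 206) return("m-3")
  if (sg <= 230) return("m-3m")
  stop("space group number out of range: ", sg)
}

#' Laue group of a space group number
#'
#' Maps an International Tables space-group number (1-230) to its Laue class
#' and lattice centering, returning the ready-made operator set.
#'
#' @param number Integer space-group number in 1-230.
#' @return A `laue_group` (see [laue_operators()]).
#' @examples
#' laue_for_spacegroup(19)   # P2_1 2_1 2_1 -> mmm
#' @export
laue_for_spacegroup <- function(number) {
  number <- as.integer(number)
  if (is.na(number) || number < 1 || number > 230)
    stop("space group number must be in 1..230")
  laue_operators(.spacegroup_laue(number), .spacegroup_centering[number])
}

# lexicographic score; valid for |index| < 2^19
.hkl_score <- function(hkl) {
  (hkl[, 1] * 2^20 + hkl[, 2]) * 2^20 + hkl[, 3]
}

#' Map Miller indices to a canonical asymmetric-unit representative
#'
#' The canonical representative of a symmetry orbit is the lexicographically
#' greatest image of (h,k,l) under all group operators (h compared first,
#' then k, then l). All symmetry mates, including Friedel pairs, map to the
#' same output.
#'
#' @param hkl Integer matrix (n x 3) of Miller indices, or a length-3 vector.
#' @param laue A `laue_group` from [laue_operators()].
#' @return An n x 3 integer matrix of canonical representatives.
#' @export
map_to_asu <- function(hkl, laue) {
  hkl <- as_hkl_matrix(hkl)
  n <- nrow(hkl)
  if (n == 0) return(hkl)
  best <- hkl %*% t(laue$operators[[1]])
  best_score <- .hkl_score(best)
  for (op in laue$operators[-1]) {
    img <- hkl %*% t(op)
    sc <- .hkl_score(img)
    upd <- sc > best_score
    if (any(upd)) {
      best[upd, ] <- img[upd, , drop = FALSE]
      best_score[upd] <- sc[upd]
    }
  }
  storage.mode(best) <- "integer"
  best
}

# scalar orbit keys used for grouping equivalents
asu_key <- function(hkl, laue) {
  .hkl_score(map_to_asu(hkl, laue))
}

#' Re-index a dataset
#'
#' Applies an index-preserving change of basis to every reflection and
#' transforms the unit cell consistently; intensities and sigmas are left
#' untouched.
#'
#' @param record An `ed_dataset` (see [ed_dataset()]).
#' @param op 3x3 integer matrix with determinant +-1, acting on Miller index
#'   columns.
#' @return The re-indexed `ed_dataset`.
#' @export
reindex <- function(record, op) {
  op <- round(op)
  if (!all(dim(op) == c(3, 3)) || abs(abs(det(op)) - 1) > 1e-9)
    stop("re-indexing operator must be a unimodular 3x3 integer matrix")
  refl <- record$reflections
  hkl <- as.matrix(refl[, c("h", "k", "l")]) %*% t(op)
  refl$h <- as.integer(hkl[, 1])
  refl$k <- as.integer(hkl[, 2])
  refl$l <- as.integer(hkl[, 3])
  record$reflections <- refl
  # metric transforms as G' = M G M^T so that d-spacings are preserved
  G <- cell_metric(record$header$unit_cell)
  Gp <- op %*% G %*% t(op)
  len <- sqrt(diag(Gp))
  ang <- function(i, j) acos(Gp[i, j] / (len[i] * len[j])) * 180 / pi
  record$header$unit_cell <- unit_cell(len[1], len[2], len[3],
                                       ang(2, 3), ang(1, 3), ang(1, 2))
  record
}

.centering_allowed <- function(hkl, centering) {
  h <- hkl[, 1]; k <- hkl[, 2]; l <- hkl[, 3]
  switch(centering,
    P = rep(TRUE, nrow(hkl)),
    A = (k + l) %% 2 == 0,
    B = (h + l) %% 2 == 0,
    C = (h + k) %% 2 == 0,
    I = (h + k + l) %% 2 == 0,
    F = (h %% 2 == k %% 2) & (k %% 2 == l %% 2),
    R = (-h + k + l) %% 3 == 0,
    stop("unknown centering: ", centering))
}

# all indices of the limiting sphere with d in [d_min, d_max], centering-allowed
.enumerate_hkl <- function(cell, d_min, d_max = Inf, centering = "P") {
  hmax <- ceiling(cell[["a"]] / d_min)
  kmax <- ceiling(cell[["b"]] / d_min)
  lmax <- ceiling(cell[["c"]] / d_min)
  grid <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  grid <- grid[rowSums(abs(grid)) > 0, , drop = FALSE]
  d <- d_spacing(grid, cell)
  keep <- d >= d_min & d <= d_max
  grid <- grid[keep, , drop = FALSE]
  grid[.centering_allowed(grid, centering), , drop = FALSE]
}

#' Number of theoretically measurable unique reflections
#'
#' Counts distinct asymmetric-unit representatives with resolution in
#' `[d_min, d_max]`, excluding (0,0,0) and centering-extinct indices. This is
#' the denominator of completeness.
#'
#' @param cell A [unit_cell()].
#' @param laue A `laue_group`.
#' @param d_max,d_min Resolution window bounds in Angstrom, `d_max > d_min`.
#' @return Integer count.
#' @export
count_theoretical_unique <- function(cell, laue, d_max, d_min) {
  if (!(d_max > d_min) || d_min <= 0)
    stop("need d_max > d_min > 0")
  grid <- .enumerate_hkl(cell, d_min, d_max, laue$centering)
  if (nrow(grid) == 0) return(0L)
  length(unique(asu_key(grid, laue)))
}

# predicates for the absence classes screened by screen_absences
.absence_classes <- function() {
  list(
    "h00 odd" = function(h, k, l) list(in_class = k == 0 & l == 0 & h != 0,
                                       violating = h %% 2 != 0),
    "0k0 odd" = function(h, k, l) list(in_class = h == 0 & l == 0 & k != 0,
                                       violating = k %% 2 != 0),
    "00l odd" = function(h, k, l) list(in_class = h == 0 & k == 0 & l != 0,
                                       violating = l %% 2 != 0),
    "I-centering h+k+l odd" = function(h, k, l)
      list(in_class = rep(TRUE, length(h)), violating = (h + k + l) %% 2 != 0),
    "C-centering h+k odd" = function(h, k, l)
      list(in_class = rep(TRUE, length(h)), violating = (h + k) %% 2 != 0)
  )
}

#' Screen reflections for systematic absences
#'
#' Numerical analogue of inspecting the reciprocal lattice for screw-axis and
#' centering extinctions: for each candidate class the mean I/sigma of
#' reflections violating the condition is compared with that of the obeying
#' reflections. A class is reported absent (condition present) when the
#' violating reflections are weak both absolutely and relative to the obeying
#' ones.
#'
#' @param reflections Data frame with columns `h,k,l,intensity,sigma`
#'   (unmerged observations).
#' @param i_sig_max Absolute mean I/sigma below which violators count as
#'   absent (default 2).
#' @param rel_max Violating-to-obeying mean I/sigma ratio bound (default 0.1).
#' @return Data frame with one row per screened class: counts, mean I/sigma
#'   of violating and obeying reflections, and a verdict
#'   (`"absent"`, `"present"`, `"insufficient data"`).
#' @export
screen_absences <- function(reflections, i_sig_max = 2, rel_max = 0.1) {
  h <- reflections$h; k <- reflections$k; l <- reflections$l
  isig <- reflections$intensity / reflections$sigma
  out <- lapply(names(.absence_classes()), function(nm) {
    cls <- .absence_classes()[[nm]](h, k, l)
    v <- cls$in_class & cls$violating
    o <- cls$in_class & !cls$violating
    mv <- if (any(v)) mean(isig[v]) else NA_real_
    mo <- if (any(o)) mean(isig[o]) else NA_real_
    verdict <- if (!any(v) || !any(o)) "insufficient data"
      else if (mv < i_sig_max && mv < rel_max * mo) "absent"
      else "present"
    data.frame(class = nm, n_violating = sum(v), n_obeying = sum(o),
               mean_i_sig_violating = mv, mean_i_sig_obeying = mo,
               verdict = verdict, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
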