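# shared fixtures, memoised so expensive synthetic datasets are built once
# per test run

.fx_env <- new.env(parent = emptyenv())

fx_memo <- function(key, builder) {
  if (is.null(.fx_env[[key]])) .fx_env[[key]] <- builder()
  .fx_env[[key]]
}

fx_triclinic_cell <- function() unit_cell(10, 12, 15, 85, 95, 100)
fx_ortho_cell <- function() unit_cell(8, 11, 14)

fx_truth_p1 <- function() fx_memo("truth_p1", function()
  make_ground_truth(fx_triclinic_cell(), laue_operators("-1"), 1.5, seed = 7))

fx_wedge_dataset <- function() fx_memo("wedge_p1", function()
  make_dataset(fx_truth_p1(),
               wedge_spec(phi_start = 0, phi_end = 60, oscillation = 0.5,
                          error_model = c(a = 1, b = 1e-4),
                          sigma_floor = 0.5, sigma_frac = 0.02),
               seed = 3, dataset_id = "wedge1"))

fx_full_dataset <- function() fx_memo("full_p1", function()
  make_dataset(fx_truth_p1(),
               wedge_spec(phi_start = 0, phi_end = 360, oscillation = 0.5,
                          error_model = c(a = 1, b = 1e-4),
                          sigma_floor = 0.5, sigma_frac = 0.02),
               seed = 4, dataset_id = "full1"))

# a minimal unmerged reflection table around explicit observations
fx_refl <- function(hkl, I, sigma = rep(1, length(I)), frame = NULL) {
  data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3],
             intensity = I, sigma = sigma,
             frame = if (is.null(frame)) seq_along(I) else frame)
}

fx_record <- function(refl, cell = fx_triclinic_cell(), sg = 1L,
                      id = "fix", n_frames = 100L) {
  ed_dataset(list(unit_cell = cell, space_group_number = sg,
                  wavelength = 0.0251, oscillation_per_frame = 0.5,
                  frame_range = c(0L, n_frames)),
             refl, dataset_id = id)
}

# brute-force Rint / Rmeas evaluation over an explicit list of groups
brute_r_factors <- function(group_list) {
  num_i <- num_m <- den <- 0
  for (g in group_list) {
    n <- length(g)
    if (n < 2) next
    m <- mean(g)
    num_i <- num_i + sum(abs(g - m))
    num_m <- num_m + sqrt(n / (n - 1)) * sum(abs(g - m))
    den <- den + sum(g)
  }
  c(r_int = num_i / den, r_meas = num_m / den)
}

# adjusted Rand index between two labellings (oracle from mclust when
# available, else a direct contingency-table evaluation)
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE))
    return(mclust::adjustedRandIndex(a, b))
  tab <- table(a, b)
  comb2 <- function(x) sum(choose(x, 2))
  sij <- comb2(as.vector(tab)); si <- comb2(rowSums(tab)); sj <- comb2(colSums(tab))
  n2 <- choose(sum(tab), 2)
  exp_ <- si * sj / n2
  (sij - exp_) / ((si + sj) / 2 - exp_)
}

# group labels of a cluster_result as a named vector over ids
cluster_labels <- function(cl) {
  lab <- rep(NA_character_, length(cl$ids))
  names(lab) <- cl$ids
  for (nm in names(cl$groups)) lab[cl$groups[[nm]]] <- nm
  lab
}
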