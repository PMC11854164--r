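# Shared fixtures and independent oracles used across the suite.

ref_factors <- function() {
  list(factor_spec("pH", 4, 5, 6),
       factor_spec("enzyme_pct", 1.5, 3, 4.5, "%"),
       factor_spec("time_min", 40, 60, 80, "min"))
}

ref_fixture <- function() load_fixture("table2_bbd")

ref_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- fit_quadratic(ref_fixture()$dataset)
    cache
  }
})

# brute-force quadratic evaluation, independent of model_matrix_quadratic
quad_eval_oracle <- function(b, z) {
  b[1] + b[2] * z[1] + b[3] * z[2] + b[4] * z[3] +
    b[5] * z[1] * z[2] + b[6] * z[1] * z[3] + b[7] * z[2] * z[3] +
    b[8] * z[1]^2 + b[9] * z[2]^2 + b[10] * z[3]^2
}

# single-stage dense grid maximizer (no refinement) for cross-checks
dense_grid_oracle <- function(f, lower, upper, n_axis) {
  axes <- lapply(seq_along(lower),
                 function(j) seq(lower[j], upper[j], length.out = n_axis))
  pts <- as.matrix(do.call(expand.grid, axes))
  vals <- apply(pts, 1L, f)
  list(point = pts[which.max(vals), ], value = max(vals))
}

# build a doe_dataset from an arbitrary actual-unit point matrix
new_lattice_dataset <- function(factors, actual, y, label = "lattice") {
  runs <- data.frame(std = seq_len(nrow(actual)), actual)
  names(runs)[2:4] <- vapply(factors, `[[`, "", "name")
  runs$yield_pct <- y
  yieldsurf:::new_doe_dataset(factors, runs, label)
}

# central finite-difference gradient of a scalar function of a vector
fd_gradient <- function(fun, theta, eps = 1e-6) {
  vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (fun(up) - fun(dn)) / (2 * eps)
  }, numeric(1))
}
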