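#' True synthetic response surface
#'
#' The data-generating process the analysis assumes: a second-order
#' polynomial in coded units plus i.i.d. Gaussian noise.
#'
#' @param coefficients named length-10 vector in design order
#'   (`(Intercept)`, `A`, `B`, `C`, `AB`, `AC`, `BC`, `A2`, `B2`, `C2`).
#' @param noise_sd response noise standard deviation (% yield, >= 0).
#' @param factors list of 3 [factor_spec] objects.
#' @return a `surface_truth` list.
#' @export
surface_truth <- function(coefficients, noise_sd, factors) {
  stopifnot(length(coefficients) == 10L, noise_sd >= 0, length(factors) == 3L)
  names(coefficients) <- c("(Intercept)", "A", "B", "C", "AB", "AC", "BC",
                           "A2", "B2", "C2")
  structure(list(coefficients = coefficients, noise_sd = noise_sd,
                 factors = factors),
            class = "surface_truth")
}

surface_eval <- function(truth, coded) {
  Z <- if (is.null(dim(coded))) matrix(coded, ncol = 3L) else as.matrix(coded)
  drop(model_matrix_quadratic(Z) %*% truth$coefficients)
}

#' Simulate observed yields on a design
#'
#' y = quadratic(truth, coded point) + N(0, noise_sd^2), independently per
#' run — replicated center points therefore get independent noise, which is
#' what makes the pure-error decomposition meaningful.
#'
#' @param truth a [surface_truth()].
#' @param design a `doe_dataset` (its yields, if any, are replaced).
#' @param seed integer seed; same seed, same dataset.
#' @return the design with simulated `yield_pct`.
#' @export
generate_yields <- function(truth, design, seed = 1L) {
  Z <- coded_matrix(design)
  mu <- surface_eval(truth, Z)
  eps <- with_seed(seed, stats::rnorm(length(mu), 0, truth$noise_sd))
  out <- design
  out$runs$yield_pct <- mu + eps
  out$label <- paste0(design$label, "_sim")
  out
}

#' Simulate the 33-point mixed design
#'
#' The 17-run Box-Behnken core plus 16 axial single-factor points: the three
#' univariate screening grids mapped affinely into the coded cube (4 levels
#' on factor 1, 5 on factors 2 and 3, others at center) and two additional
#' center replicates. Mimics augmenting a response-surface design with the
#' screening runs that preceded it.
#'
#' @param truth a [surface_truth()].
#' @param seed integer seed.
#' @param n_center BBD center replicates (default 5).
#' @return a 33-run `doe_dataset` with simulated yields.
#' @export
generate_mixed33 <- function(truth, seed = 1L, n_center = 5L) {
  base <- build_bbd(truth$factors, n_center = n_center, label = "mixed33")
  ax1 <- cbind(c(-1, -1/3, 1/3, 1), 0, 0)
  ax2 <- cbind(0, c(-1, -0.5, 0, 0.5, 1), 0)
  ax3 <- cbind(0, 0, c(-1, -0.5, 0, 0.5, 1))
  extra <- rbind(ax1, ax2, ax3, c(0, 0, 0), c(0, 0, 0))
  actual <- decode(extra, truth$factors)
  add <- data.frame(std = nrow(base$runs) + seq_len(nrow(extra)), actual)
  names(add)[2:4] <- vapply(truth$factors, `[[`, "", "name")
  add$yield_pct <- NA_real_
  base$runs <- rbind(base$runs, add)
  generate_yields(truth, base, seed)
}

#' Load a packaged fixture
#'
#' `"table2_bbd"` is the published 17-run three-factor Box-Behnken dataset
#' (pH, enzyme addition %, ultrasonic time min; crude-polysaccharide yield
#' %), with reference annotations (reported coefficients, ANOVA entries,
#' predicted column, optima) attached read-only. `"single_factor_text"` is
#' the handful of screening-stage yields quoted in the accompanying text.
#'
#' @param name fixture name.
#' @return for `table2_bbd`, a list of class `fixture` with `name`,
#'   `dataset` (a `doe_dataset`) and `annotations`; for
#'   `single_factor_text`, the same with a plain data.frame as `dataset`.
#' @export
load_fixture <- function(name = c("table2_bbd", "single_factor_text")) {
  name <- match.arg(name)
  ext <- function(f) system.file("extdata", f, package = "yieldsurf",
                                 mustWork = TRUE)
  if (name == "table2_bbd") {
    ds <- read_dataset_csv(ext("table2_bbd.csv"), ext("table2_factors.json"),
                           label = "table2_bbd")
    ann <- jsonlite::fromJSON(ext("table2_annotations.json"))
    structure(list(name = name, dataset = ds, annotations = ann),
              class = "fixture")
  } else {
    structure(list(name = name,
                   dataset = utils::read.csv(ext("single_factor_text.csv")),
                   annotations = NULL),
              class = "fixture")
  }
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture>", x$name, "\n")
  if (inherits(x$dataset, "doe_dataset")) print(x$dataset)
  else print(x$dataset)
  invisible(x)
}

#' The reference surface truth behind the packaged dataset
#'
#' Convenience constructor: the least-squares coefficients of the packaged
#' 17-run dataset as a [surface_truth()], with noise defaulting to the
#' pure-error standard deviation of that fit's ANOVA.
#'
#' @param noise_sd Gaussian response noise; default `sqrt(9.52)`, the
#'   replicated-center pure-error mean square of the reference fit.
#' @return a `surface_truth`.
#' @export
reference_truth <- function(noise_sd = sqrt(9.52)) {
  fx <- load_fixture("table2_bbd")
  model <- fit_quadratic(fx$dataset)
  surface_truth(model$coef, noise_sd, fx$dataset$factors)
}
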