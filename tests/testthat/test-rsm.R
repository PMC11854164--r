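test_that("least-squares fit reproduces the reported coded coefficients", {
  m <- ref_model()
  expect_equal(round(m$b0, 3), 27.522)
  expect_equal(round(unname(m$b_lin), 3), c(4.575, 1.950, 1.665))
  # interaction/quadratic values as refit (signs of AB/AC and digits of B2
  # differ from the reported equation, which does not reproduce its own
  # predicted column)
  expect_equal(round(unname(m$b_int), 3), c(-0.730, -1.660, -0.170))
  expect_equal(round(unname(m$b_quad), 3), c(-7.681, -3.551, -3.341))
  # intercept equals the center-replicate mean for a BBD
  center <- ref_fixture()$dataset$runs$yield_pct[13:17]
  expect_equal(m$b0, mean(center), tolerance = 1e-9)
  expect_equal(sum(m$residuals), 0, tolerance = 1e-9)
})

test_that("predictions reproduce the reported column at all 17 runs", {
  m <- ref_model()
  fx <- ref_fixture()
  pred <- predict(m, coded_matrix(fx$dataset))
  expect_equal(round(pred, 3), fx$annotations$predicted_yield$values,
               tolerance = 5e-4)
  # spot values, and polynomial evaluation agrees with a brute-force oracle
  expect_equal(round(predict(m, c(-1, -1, 0)), 3), 9.035)
  expect_equal(round(predict(m, c(-1, 0, -1)), 3), 8.6)
  expect_equal(predict(m, c(0, 0, 0)), m$b0)
  for (z in list(c(0.3, -0.7, 0.2), c(1, 1, 1), c(-0.5, 0, 0.9))) {
    expect_equal(predict(m, z), quad_eval_oracle(unname(m$coef), z),
                 tolerance = 1e-12)
  }
})

test_that("residuals are orthogonal to every design column", {
  m <- ref_model()
  expect_true(all(abs(drop(crossprod(m$X, m$residuals))) < 1e-8))
})

test_that("noise-free quadratic data are recovered exactly", {
  truth <- c(20, 3, -1, 0.5, 0.25, -0.75, 1.2, -4, -2, -1.5)
  d <- build_bbd(ref_factors(), 5L)
  Z <- coded_matrix(d)
  d$runs$yield_pct <- apply(Z, 1L, function(z) quad_eval_oracle(truth, z))
  m <- fit_quadratic(d)
  expect_equal(unname(m$coef), truth, tolerance = 1e-9)
})

test_that("rank-deficient designs fail with the collinear columns named", {
  d <- build_bbd(ref_factors(), 5L)
  d$runs$yield_pct <- rnorm(17)
  d$runs$time_min <- 60          # factor C frozen: C, AC, BC, C2 collinear
  expect_error(fit_quadratic(d), "singular fit.*C")
  d2 <- build_bbd(ref_factors(), 5L)
  d2$runs$yield_pct[1:10] <- NA
  expect_error(fit_quadratic(d2), "at least 10 runs")
})

test_that("ANOVA reproduces the reported table and its bookkeeping", {
  tab <- rsm_anova(ref_model())
  get <- function(term, col) tab[tab$term == term, col]

  expect_equal(round(get("Model", "F"), 2), 3.84)
  expect_equal(round(get("Model", "SS"), 2), 614.36)
  expect_equal(round(get("A", "SS"), 2), 167.45)
  expect_equal(round(get("A", "F"), 2), 9.41)
  expect_equal(round(get("B", "SS"), 2), 30.42)
  expect_equal(round(get("C", "SS"), 2), 22.18)
  expect_equal(round(get("AB", "SS"), 2), 2.13)
  expect_equal(round(get("AC", "SS"), 2), 11.02)
  expect_equal(round(get("BC", "SS"), 4), 0.1156)
  expect_equal(round(get("A2", "SS"), 2), 248.41)
  expect_equal(round(get("B2", "SS"), 2), 53.09)
  expect_equal(round(get("C2", "SS"), 2), 47.00)
  expect_equal(round(get("Pure Error", "SS"), 2), 38.08)
  expect_equal(round(get("Lack of Fit", "F"), 2), 3.03)
  expect_equal(round(get("Model", "p"), 4), 0.0451)
  expect_equal(round(get("A", "p"), 4), 0.0181)
  expect_equal(get("Model", "signif"), "*")

  # additivity and df bookkeeping
  expect_equal(get("Model", "SS") + get("Residual", "SS"),
               get("Cor Total", "SS"), tolerance = 1e-6)
  expect_equal(get("Lack of Fit", "SS") + get("Pure Error", "SS"),
               get("Residual", "SS"), tolerance = 1e-6)
  expect_equal(get("Model", "df"), 9L)
  expect_equal(get("Cor Total", "df"), 16L)
  # orthogonal-linear closed forms: SS(A) = 8 b1^2, SS(AB) = 4 b12^2
  m <- ref_model()
  expect_equal(get("A", "SS"), 8 * m$coef[["A"]]^2, tolerance = 1e-9)
  expect_equal(get("AB", "SS"), 4 * m$coef[["AB"]]^2, tolerance = 1e-9)
})

test_that("quadratic-term partial SS uses the inverse normal-matrix diagonal", {
  # independent oracle: invert the 4x4 intercept/quadratic block of the
  # normal matrix for the 17-run BBD directly
  N <- matrix(c(17, 8, 8, 8,
                8, 8, 4, 4,
                8, 4, 8, 4,
                8, 4, 4, 8), 4, 4, byrow = TRUE)
  c11 <- diag(solve(N))[2]
  expect_equal(c11, 0.2375, tolerance = 1e-12)
  m <- ref_model()
  expect_equal(unname(diag(m$xtx_inv)[c("A2", "B2", "C2")]), rep(c11, 3),
               tolerance = 1e-12)
  tab <- rsm_anova(m)
  expect_equal(tab[tab$term == "B2", "SS"], m$coef[["B2"]]^2 / c11,
               tolerance = 1e-9)
})

test_that("a saturated (zero-noise) fit flags its ANOVA F ratios", {
  truth <- c(10, 1, 2, 3, 0, 0, 0, -1, -1, -1)
  d <- build_bbd(ref_factors(), 5L)
  d$runs$yield_pct <- apply(coded_matrix(d), 1L,
                            function(z) quad_eval_oracle(truth, z))
  m <- fit_quadratic(d)
  tab <- rsm_anova(m)
  expect_equal(tab[tab$term == "Residual", "SS"], 0, tolerance = 1e-18)
  expect_true(all(is.infinite(tab$F[tab$term %in% c("Model", "A", "B2")])))
  expect_true(isTRUE(attr(tab, "saturated")))
})

test_that("lack of fit is unavailable without replicates", {
  d <- build_bbd(ref_factors(), 1L)
  set.seed(7)
  d$runs$yield_pct <- apply(coded_matrix(d), 1L, function(z)
    quad_eval_oracle(c(20, 3, -1, 0.5, 0, 0, 0, -4, -2, -1), z)) + rnorm(13)
  m <- fit_quadratic(d)
  expect_warning(tab <- rsm_anova(m), "lack-of-fit unavailable")
  expect_false(any(tab$term %in% c("Lack of Fit", "Pure Error")))
})

test_that("R-squared is the model-to-total SS ratio", {
  m <- ref_model()
  tab <- rsm_anova(m)
  expect_equal(r_squared(m),
               tab[tab$term == "Model", "SS"] / tab[tab$term == "Cor Total", "SS"],
               tolerance = 1e-12)
  expect_equal(round(r_squared(m), 4), 0.8314)

  # perfect fit -> 1
  d <- build_bbd(ref_factors(), 5L)
  d$runs$yield_pct <- apply(coded_matrix(d), 1L,
                            function(z) quad_eval_oracle(c(10, 1, 2, 3, 0, 0, 0, -1, -1, -1), z))
  expect_equal(r_squared(fit_quadratic(d)), 1, tolerance = 1e-12)

  d$runs$yield_pct <- rep(5, 17)
  expect_error(r_squared(fit_quadratic(d)), "zero variance")
})

test_that("diagnostics satisfy hat-matrix identities and design symmetry", {
  m <- ref_model()
  d <- rsm_diagnostics(m)
  expect_equal(sum(d$leverage), 10, tolerance = 1e-9)   # trace of H = p
  expect_true(all(d$cooks_d >= 0))
  # replicated center runs share identical leverage
  expect_equal(diff(range(d$leverage[13:17])), 0, tolerance = 1e-12)
  # direct hat-matrix oracle
  H <- m$X %*% solve(crossprod(m$X)) %*% t(m$X)
  expect_equal(d$leverage, unname(diag(H)), tolerance = 1e-9)
  # Blom plotting positions
  expect_equal(d$nq_theoretical, qnorm(((1:17) - 0.375) / 17.25))
  expect_equal(d$nq_resid, sort(d$rstudent))
})

test_that("perturbation curves pass through the intercept and track curvature", {
  m <- ref_model()
  pc <- perturbation_curves(m)
  expect_equal(nrow(pc), 3L * 41L)
  at0 <- pc$yield_pct[pc$coded == 0]
  expect_equal(at0, rep(m$b0, 3), tolerance = 1e-12)
  # curve for factor A at +/-1 equals prediction at (+/-1, 0, 0)
  cA <- pc[pc$factor == "A", ]
  expect_equal(cA$yield_pct[cA$coded == 1], predict(m, c(1, 0, 0)))
  expect_equal(cA$yield_pct[cA$coded == -1], predict(m, c(-1, 0, 0)))
  # second difference sign matches the quadratic coefficient sign
  d2 <- diff(cA$yield_pct, differences = 2)
  expect_true(all(sign(d2) == sign(m$coef[["A2"]])))
})

test_that("surface optimization finds the interior stationary maximum", {
  m <- ref_model()
  opt <- optimize_surface(m)
  expect_equal(opt$method, "stationary")
  expect_equal(opt$coded, c(0.268, 0.243, 0.177), tolerance = 5e-3)
  expect_equal(opt$value, 28.52, tolerance = 5e-3)
  # linear-solver oracle on the stationary system
  b <- m$coef
  H <- matrix(c(2 * b["A2"], b["AB"], b["AC"],
                b["AB"], 2 * b["B2"], b["BC"],
                b["AC"], b["BC"], 2 * b["C2"]), 3, 3)
  expect_equal(opt$coded, unname(solve(H, -b[c("A", "B", "C")])),
               tolerance = 1e-9)
  # dense grid oracle agrees within the grid tolerance
  or <- dense_grid_oracle(function(z) predict(m, z), rep(-1, 3), rep(1, 3), 41L)
  expect_gte(opt$value + 1e-9, or$value)
  expect_lt(opt$value - or$value, 1e-2)
})

test_that("boundary optima fall back to deterministic grid refinement", {
  d <- build_bbd(ref_factors(), 5L)
  # pure linear ridge in A: argmax at A = +1
  d$runs$yield_pct <- apply(coded_matrix(d), 1L,
                            function(z) quad_eval_oracle(c(10, 2, 0, 0, 0, 0, 0, 0, 0, 0), z))
  m <- fit_quadratic(d)
  opt <- optimize_surface(m)
  expect_equal(opt$method, "grid")
  expect_equal(opt$flag, "saddle_or_ridge")
  expect_equal(opt$coded[1], 1, tolerance = 1e-3)
  expect_equal(opt$value, 12, tolerance = 1e-3)
})

test_that("ANOVA writers preserve row order and rounding", {
  tab <- rsm_anova(ref_model())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_anova(tab, tsv, "tsv")
  write_anova(tab, json, "json")
  back <- read.delim(tsv)
  expect_equal(back$term, tab$term)
  expect_equal(back$F[1], 3.84)
  expect_equal(back$p[1], 0.0451)
  jb <- jsonlite::fromJSON(json)
  expect_equal(jb$term, tab$term)
  expect_equal(jb$SS[jb$term == "Pure Error"], 38.08)
})
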