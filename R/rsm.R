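#' Fit the full second-order response-surface model
#'
#' Ordinary least squares of observed yield on the 10-column coded design
#' (1, A, B, C, AB, AC, BC, A^2, B^2, C^2). Coefficients are reported in
#' coded units, so they are comparable across factors regardless of units.
#'
#' @param data a `doe_dataset` with at least 10 runs carrying observed yield.
#' @return an object of class `quadratic_model` with components `b0`,
#'   `b_lin`, `b_int`, `b_quad` (named coefficient blocks), `coef` (all 10 in
#'   design order), `fitted`, `residuals`, `n`, and the pieces needed for
#'   ANOVA and diagnostics (`X`, `xtx_inv`, `df_resid`, `y`, `coded`).
#' @export
fit_quadratic <- function(data) {
  y <- observed_yield(data)
  keep <- !is.na(y)
  if (sum(keep) < 10L) {
    stop("need at least 10 runs with observed yield to fit the 10-term model",
         call. = FALSE)
  }
  y <- y[keep]
  Z <- coded_matrix(data)[keep, , drop = FALSE]
  X <- model_matrix_quadratic(Z)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("singular fit: design does not identify column(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  b <- fit$coefficients
  m <- structure(list(
    b0 = unname(b[1L]),
    b_lin = b[2:4], b_int = b[5:7], b_quad = b[8:10],
    coef = b,
    fitted = unname(fit$fitted.values),
    residuals = unname(fit$residuals),
    n = length(y),
    df_resid = length(y) - ncol(X),
    X = X, xtx_inv = chol2inv(qr.R(qx)), y = y, coded = Z,
    factors = data$factors
  ), class = "quadratic_model")
  dimnames(m$xtx_inv) <- list(colnames(X), colnames(X))
  m
}

model_matrix_quadratic <- function(Z) {
  X <- cbind(1, Z[, 1], Z[, 2], Z[, 3],
             Z[, 1] * Z[, 2], Z[, 1] * Z[, 3], Z[, 2] * Z[, 3],
             Z[, 1]^2, Z[, 2]^2, Z[, 3]^2)
  colnames(X) <- c("(Intercept)", "A", "B", "C", "AB", "AC", "BC",
                   "A2", "B2", "C2")
  X
}

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat("<quadratic_model> second-order fit in coded units,", x$n, "runs\n")
  print(round(x$coef, digits))
  cat(sprintf("residual SS %.4f on %d df\n", sum(x$residuals^2), x$df_resid))
  invisible(x)
}

#' Predict yield from a fitted quadratic at coded points
#'
#' @param object a `quadratic_model`.
#' @param coded numeric length-3 vector or n x 3 matrix of coded levels.
#' @param ... unused.
#' @return predicted yield (percent), one value per row.
#' @export
predict.quadratic_model <- function(object, coded, ...) {
  Z <- if (is.null(dim(coded))) matrix(coded, ncol = 3L) else as.matrix(coded)
  drop(model_matrix_quadratic(Z) %*% object$coef)
}

#' ANOVA of the second-order fit with lack-of-fit decomposition
#'
#' Single-degree term sums of squares are partial (Type III): SS(term) =
#' coefficient^2 / its diagonal entry of (X'X)^-1. For this design the linear
#' and interaction columns are orthogonal, so SS(A) = 8 b1^2 and SS(AB) =
#' 4 b12^2; the quadratic columns are not orthogonal to the intercept, and
#' their SS uses the inverse-normal-matrix diagonal. Pure error is the
#' within-group SS over replicated design points; lack of fit is the
#' remainder of the residual SS. Term F-ratios use the residual mean square;
#' the lack-of-fit F uses the pure-error mean square.
#'
#' @param model a `quadratic_model`.
#' @return data.frame of class `rsm_anova` with columns `term`, `SS`, `df`,
#'   `MS`, `F`, `p`, `signif` in the conventional row order (Model, the nine
#'   single-df terms, Residual, Lack of Fit, Pure Error, Cor Total). With a
#'   saturated (zero-residual) fit the F columns are `Inf` and flagged.
#' @export
rsm_anova <- function(model) {
  y <- model$y
  n <- model$n
  sse <- sum(model$residuals^2)
  sst <- sum((y - mean(y))^2)
  ssm <- sst - sse
  df_res <- model$df_resid
  ms_res <- sse / df_res

  terms <- c("A", "B", "C", "AB", "AC", "BC", "A2", "B2", "C2")
  ss_term <- model$coef[terms]^2 / diag(model$xtx_inv)[terms]

  # replicate groups for the pure-error split
  key <- apply(model$coded, 1L, paste, collapse = "\r")
  reps <- split(y, key)
  reps <- reps[lengths(reps) > 1L]
  has_pe <- length(reps) > 0L
  if (has_pe) {
    ss_pe <- sum(vapply(reps, function(g) sum((g - mean(g))^2), numeric(1)))
    df_pe <- sum(lengths(reps) - 1L)
    ss_lof <- sse - ss_pe
    df_lof <- df_res - df_pe
  } else {
    warning("lack-of-fit unavailable: no replicated design points", call. = FALSE)
  }

  row <- function(term, ss, df, denom_ms = ms_res) {
    msq <- ss / df
    f <- if (is.na(denom_ms)) NA_real_ else msq / denom_ms
    p <- if (is.na(f)) NA_real_ else stats::pf(f, df, attr(denom_ms, "df") %||% df_res,
                                               lower.tail = FALSE)
    data.frame(term = term, SS = ss, df = df, MS = msq, F = f, p = p)
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  saturated <- df_res == 0L || sse <= .Machine$double.eps * sst
  denom <- if (df_res > 0L) ms_res else NA_real_

  tab <- rbind(
    row("Model", ssm, 9L, denom),
    do.call(rbind, lapply(terms, function(t) row(t, ss_term[[t]], 1L, denom)))
  )
  res_row <- data.frame(term = "Residual", SS = sse, df = df_res,
                        MS = if (df_res > 0L) ms_res else NA_real_,
                        F = NA_real_, p = NA_real_)
  tab <- rbind(tab, res_row)
  if (has_pe) {
    ms_pe <- ss_pe / df_pe
    f_lof <- if (df_lof > 0L && ms_pe > 0) (ss_lof / df_lof) / ms_pe else NA_real_
    p_lof <- if (is.na(f_lof)) NA_real_ else stats::pf(f_lof, df_lof, df_pe,
                                                       lower.tail = FALSE)
    tab <- rbind(tab,
      data.frame(term = "Lack of Fit", SS = ss_lof, df = df_lof,
                 MS = if (df_lof > 0L) ss_lof / df_lof else NA_real_,
                 F = f_lof, p = p_lof),
      data.frame(term = "Pure Error", SS = ss_pe, df = df_pe, MS = ms_pe,
                 F = NA_real_, p = NA_real_))
  }
  tab <- rbind(tab, data.frame(term = "Cor Total", SS = sst, df = n - 1L,
                               MS = NA_real_, F = NA_real_, p = NA_real_))
  if (saturated) {
    term_rows <- tab$term %in% c("Model", terms)
    tab$F[term_rows] <- Inf
    tab$p[term_rows] <- 0
    attr(tab, "saturated") <- TRUE
  }
  tab$signif <- ifelse(is.na(tab$p), "",
                       ifelse(tab$p < 0.001, "***",
                              ifelse(tab$p < 0.05, "*", "")))
  rownames(tab) <- NULL
  class(tab) <- c("rsm_anova", "data.frame")
  tab
}

#' Coefficient of determination of the fit
#'
#' R^2 = SS(Model) / SS(Cor Total), identical to 1 - SSE/SST for an OLS fit
#' with intercept.
#'
#' @param model a `quadratic_model`.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(model) {
  sst <- sum((model$y - mean(model$y))^2)
  if (sst <= 0) stop("R-squared undefined: observed yields have zero variance",
                     call. = FALSE)
  1 - sum(model$residuals^2) / sst
}

#' Per-run regression diagnostics
#'
#' Leverage is the hat-matrix diagonal; Cook's distance uses the raw residual
#' form D_i = e_i^2 h_i / (p s^2 (1 - h_i)^2) with p = 10 model terms and
#' s^2 the residual mean square; studentized residuals are internally
#' studentized; normal-probability positions use Blom's (i - 3/8)/(n + 1/4).
#'
#' @param model a `quadratic_model` with at least 1 residual df.
#' @return data.frame with `leverage`, `cooks_d`, `rstudent`, and the
#'   normal-probability pair (`nq_resid` = sorted studentized residuals,
#'   `nq_theoretical`). Runs with leverage 1 get `Inf` influence and a warning.
#' @export
rsm_diagnostics <- function(model) {
  if (model$df_resid < 1L) stop("diagnostics need residual df >= 1", call. = FALSE)
  X <- model$X
  h <- rowSums((X %*% model$xtx_inv) * X)
  s2 <- sum(model$residuals^2) / model$df_resid
  p <- ncol(X)
  e <- model$residuals
  if (any(h >= 1 - 1e-12)) {
    warning("run(s) with leverage 1: infinite influence", call. = FALSE)
  }
  d <- e^2 * h / (p * s2 * (1 - h)^2)
  rs <- e / sqrt(s2 * (1 - h))
  n <- model$n
  ord <- order(rs)
  out <- data.frame(run = seq_len(n), leverage = h, cooks_d = d, rstudent = rs)
  out$nq_resid <- sort(rs)
  out$nq_theoretical <- stats::qnorm((seq_len(n) - 0.375) / (n + 0.25))
  out
}

#' Perturbation curves through a reference point
#'
#' For each factor, the fitted yield along a coded grid with the other two
#' factors held at the reference (default the design center).
#'
#' @param model a `quadratic_model`.
#' @param reference coded reference point (default origin).
#' @param n_grid points per curve over `[-1, 1]` (default 41).
#' @return data.frame with `factor`, `coded`, `yield_pct`.
#' @export
perturbation_curves <- function(model, reference = c(0, 0, 0), n_grid = 41L) {
  g <- seq(-1, 1, length.out = n_grid)
  out <- lapply(1:3, function(j) {
    Z <- matrix(reference, nrow = n_grid, ncol = 3L, byrow = TRUE)
    Z[, j] <- g
    data.frame(factor = c("A", "B", "C")[j], coded = g,
               yield_pct = predict(model, Z))
  })
  do.call(rbind, out)
}

#' Maximize the fitted response surface over a coded box
#'
#' Solves the stationary-point system grad Y = 0. If the stationary point is
#' inside the box and the Hessian is negative definite it is the maximizer;
#' otherwise (boundary optimum, saddle, or ridge) the box is searched by
#' deterministic iterative grid refinement down to the stated resolution, so
#' results are bit-reproducible.
#'
#' @param model a `quadratic_model`.
#' @param lower,upper coded box bounds (default the unit cube).
#' @param resolution final coded-unit grid resolution for the fallback search.
#' @return list with `coded` (argmax), `actual` (same point in factor units),
#'   `value` (maximum predicted yield), `stationary_point`, `hessian`,
#'   `method` (`"stationary"` or `"grid"`), and `flag` (`"saddle_or_ridge"`
#'   when the Hessian is not negative definite).
#' @export
optimize_surface <- function(model, lower = c(-1, -1, -1), upper = c(1, 1, 1),
                             resolution = 1e-3) {
  b <- model$coef
  H <- matrix(c(2 * b["A2"], b["AB"], b["AC"],
                b["AB"], 2 * b["B2"], b["BC"],
                b["AC"], b["BC"], 2 * b["C2"]), 3L, 3L)
  g <- b[c("A", "B", "C")]
  flag <- NULL
  sp <- NULL
  if (abs(det(H)) > 1e-12) {
    sp <- drop(solve(H, -g))
  } else {
    flag <- "saddle_or_ridge"
  }
  neg_def <- !is.null(sp) && all(eigen(H, symmetric = TRUE,
                                       only.values = TRUE)$values < 0)
  if (!neg_def && is.null(flag)) flag <- "saddle_or_ridge"
  inside <- !is.null(sp) && all(sp >= lower & sp <= upper)
  if (neg_def && inside) {
    opt <- sp
    method <- "stationary"
  } else {
    opt <- grid_refine_max(function(Z) predict(model, Z), lower, upper,
                           resolution = resolution)
    method <- "grid"
  }
  list(coded = unname(opt),
       actual = unname(decode(opt, model$factors)),
       value = unname(predict(model, opt)),
       stationary_point = if (is.null(sp)) NULL else unname(sp),
       hessian = H, method = method, flag = flag)
}

# Deterministic coarse-to-fine box maximizer. `f` takes an n x k matrix of
# points and returns n values. Each stage lays a 21-per-axis lattice, keeps
# the best node, and shrinks the box around it until the lattice spacing is
# below `resolution` on every axis.
grid_refine_max <- function(f, lower, upper, resolution = 1e-3, n_axis = 21L) {
  lo <- lower; up <- upper
  best <- NULL
  repeat {
    axes <- lapply(seq_along(lo), function(j) seq(lo[j], up[j], length.out = n_axis))
    pts <- as.matrix(do.call(expand.grid, axes))
    vals <- f(pts)
    best <- pts[which.max(vals), ]
    step <- (up - lo) / (n_axis - 1L)
    if (all(step <= resolution)) break
    lo <- pmax(lower, best - step)
    up <- pmin(upper, best + step)
  }
  unname(best)
}

#' Write an ANOVA table to TSV or JSON
#'
#' Rounds as response-surface software conventionally prints: SS and MS to 2
#' decimals, F to 2, p to 4 (configurable), preserving row order.
#'
#' @param tab an `rsm_anova` table.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param digits named list of rounding digits.
#' @export
write_anova <- function(tab, path, format = c("tsv", "json"),
                        digits = list(SS = 2, MS = 2, F = 2, p = 4)) {
  format <- match.arg(format)
  out <- as.data.frame(tab)
  for (col in intersect(names(digits), names(out))) {
    out[[col]] <- round(out[[col]], digits[[col]])
  }
  if (format == "tsv") {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE,
                       na = "")
  } else {
    jsonlite::write_json(out, path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}
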