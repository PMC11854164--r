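#' Specify an experimental factor
#'
#' A factor is described by its low / center / high actual levels, which map
#' to the coded levels -1 / 0 / +1. The center is expected to be the midpoint
#' of low and high; if it is not (to within 1e-9) a warning is issued but the
#' specification is kept, since slightly off-center published designs exist.
#'
#' @param name factor name, e.g. `"pH"`.
#' @param low,center,high actual levels in the factor's units, `low < center < high`.
#' @param unit unit string (may be empty).
#' @return an object of class `factor_spec`.
#' @export
factor_spec <- function(name, low, center, high, unit = "") {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(low), is.numeric(center), is.numeric(high))
  if (!(low < center && center < high)) {
    stop("factor '", name, "': levels must satisfy low < center < high", call. = FALSE)
  }
  if (abs(center - (low + high) / 2) > 1e-9) {
    warning("factor '", name, "': center is not the midpoint of low and high",
            call. = FALSE)
  }
  structure(list(name = name, low = low, center = center, high = high,
                 unit = unit),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("<factor_spec> %s: %g / %g / %g %s\n",
              x$name, x$low, x$center, x$high, x$unit))
  invisible(x)
}

half_range <- function(f) (f$high - f$low) / 2

#' Convert actual factor settings to coded units
#'
#' Coded value = (actual - center) / half-range, so the design levels map to
#' -1 / 0 / +1. `decode()` is the exact inverse.
#'
#' @param actual numeric vector or matrix (columns = factors) of actual settings.
#' @param factors list of [factor_spec] objects, one per column/element.
#' @return numeric of the same shape, in coded units.
#' @export
code <- function(actual, factors) {
  transform_levels(actual, factors, to_coded = TRUE)
}

#' @rdname code
#' @param coded numeric vector or matrix in coded units.
#' @export
decode <- function(coded, factors) {
  transform_levels(coded, factors, to_coded = FALSE)
}

transform_levels <- function(x, factors, to_coded) {
  k <- length(factors)
  hr <- vapply(factors, half_range, numeric(1))
  if (any(hr <= 0)) {
    stop("degenerate factor: zero half-range in ",
         paste(vapply(factors[hr <= 0], `[[`, "", "name"), collapse = ", "),
         call. = FALSE)
  }
  ctr <- vapply(factors, `[[`, numeric(1), "center")
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(m) != k) stop("expected ", k, " columns, got ", ncol(m), call. = FALSE)
  out <- if (to_coded) sweep(sweep(m, 2L, ctr, "-"), 2L, hr, "/")
         else          sweep(sweep(m, 2L, hr, "*"), 2L, ctr, "+")
  if (vec) drop(out) else out
}

#' Build a three-factor Box-Behnken design
#'
#' Returns the 12 edge midpoints of the cube (all four +/-1 combinations of
#' each factor pair, with the third factor at 0, in the pair order (1,2),
#' (1,3), (2,3)) followed by `n_center` replicated center points, in standard
#' order. Each factor sits at +/-1 in exactly 8 runs.
#'
#' @param factors list of exactly 3 [factor_spec] objects.
#' @param n_center number of center replicates (>= 1); 5 is conventional.
#' @param label dataset label.
#' @return a `doe_dataset`: list with `factors`, `runs` (data.frame with
#'   `std`, one actual-unit column per factor, `yield_pct` = `NA`), `label`.
#' @export
build_bbd <- function(factors, n_center = 5L, label = "bbd") {
  if (length(factors) != 3L) {
    stop("unsupported design: Box-Behnken construction here requires exactly 3 factors",
         call. = FALSE)
  }
  stopifnot(n_center >= 1L)
  pm <- as.matrix(expand.grid(c(-1, 1), c(-1, 1)))[, 2:1]  # (-,-),(+,-),(-,+),(+,+)
  edge <- rbind(
    cbind(pm[, 1], pm[, 2], 0),
    cbind(pm[, 1], 0, pm[, 2]),
    cbind(0, pm[, 1], pm[, 2])
  )
  coded <- rbind(edge, matrix(0, nrow = n_center, ncol = 3L))
  actual <- decode(coded, factors)
  runs <- data.frame(std = seq_len(nrow(coded)), actual)
  names(runs)[2:4] <- vapply(factors, `[[`, "", "name")
  runs$yield_pct <- NA_real_
  new_doe_dataset(factors, runs, label)
}

new_doe_dataset <- function(factors, runs, label) {
  structure(list(factors = factors, runs = runs, label = label),
            class = "doe_dataset")
}

#' @export
print.doe_dataset <- function(x, ...) {
  cat(sprintf("<doe_dataset> '%s': %d runs, factors %s\n", x$label,
              nrow(x$runs),
              paste(vapply(x$factors, `[[`, "", "name"), collapse = ", ")))
  print(utils::head(x$runs, 6L))
  if (nrow(x$runs) > 6L) cat("...\n")
  invisible(x)
}

#' Coded design matrix of a dataset
#'
#' @param data a `doe_dataset`.
#' @return n x 3 matrix of coded levels, columns named after the factors.
#' @export
coded_matrix <- function(data) {
  act <- as.matrix(data$runs[, vapply(data$factors, `[[`, "", "name"), drop = FALSE])
  m <- code(act, data$factors)
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  colnames(m) <- vapply(data$factors, `[[`, "", "name")
  m
}

observed_yield <- function(data) data$runs$yield_pct

#' Extraction yield from masses
#'
#' Yield (%) = 100 * dried-extract mass / raw-material mass.
#'
#' @param m1 mass of the dried extract (same unit as `m2`).
#' @param m2 mass of the raw material, > 0.
#' @return yield in percent.
#' @export
yield_percent <- function(m1, m2) {
  if (any(m2 <= 0)) stop("raw-material mass m2 must be positive", call. = FALSE)
  if (any(m1 < 0)) stop("extract mass m1 must be non-negative", call. = FALSE)
  100 * m1 / m2
}

#' Read / write a designed-experiment dataset as CSV + JSON sidecar
#'
#' The CSV holds `std`, one actual-unit column per factor, and `yield_pct`
#' (blank when unobserved); the sidecar is a JSON array of factor specs
#' (`name`, `low`, `center`, `high`, `unit`).
#'
#' @param csv path to the CSV file.
#' @param factors_json path to the factor sidecar; defaults to the CSV path
#'   with `_factors.json` substituted for `.csv`.
#' @param label dataset label (read) .
#' @return [read_dataset_csv()] returns a `doe_dataset`.
#' @export
read_dataset_csv <- function(csv, factors_json = NULL, label = basename(csv)) {
  if (is.null(factors_json)) factors_json <- sub("\\.csv$", "_factors.json", csv)
  fl <- jsonlite::fromJSON(factors_json, simplifyDataFrame = TRUE)
  factors <- lapply(seq_len(nrow(fl)), function(i) {
    factor_spec(fl$name[i], fl$low[i], fl$center[i], fl$high[i], fl$unit[i])
  })
  runs <- utils::read.csv(csv, check.names = FALSE)
  needed <- c("std", vapply(factors, `[[`, "", "name"), "yield_pct")
  missing <- setdiff(needed, names(runs))
  if (length(missing)) {
    stop("malformed dataset CSV '", csv, "': missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  new_doe_dataset(factors, runs[needed], label)
}

#' @rdname read_dataset_csv
#' @param data a `doe_dataset` to write.
#' @export
write_dataset_csv <- function(data, csv, factors_json = NULL) {
  if (is.null(factors_json)) factors_json <- sub("\\.csv$", "_factors.json", csv)
  utils::write.csv(data$runs, csv, row.names = FALSE, quote = FALSE, na = "")
  fl <- do.call(rbind, lapply(data$factors, function(f) {
    data.frame(name = f$name, low = f$low, center = f$center, high = f$high,
               unit = f$unit)
  }))
  jsonlite::write_json(fl, factors_json, dataframe = "rows", auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv = csv, factors = factors_json))
}
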