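#' Model-fit comparison statistics
#'
#' R^2 = 1 - SSE/SST, RMSE = sqrt(mean squared error), AAD in both the
#' absolute convention (mean |obs - pred|, yield units — the default) and
#' the relative-% convention (100/n * sum |obs - pred| / obs).
#'
#' @param predicted,observed equal-length numeric series (length >= 2).
#' @param label model label for reports.
#' @return data.frame of class `fit_metrics` with `model_label`, `r2`,
#'   `rmse`, `aad`, `aad_pct`, `n`.
#' @export
compute_metrics <- function(predicted, observed, label = "model") {
  stopifnot(length(predicted) == length(observed), length(observed) >= 2L)
  e <- observed - predicted
  sst <- sum((observed - mean(observed))^2)
  if (sst <= 0) stop("R-squared undefined: observed series has zero variance",
                     call. = FALSE)
  out <- data.frame(model_label = label,
                    r2 = 1 - sum(e^2) / sst,
                    rmse = sqrt(mean(e^2)),
                    aad = mean(abs(e)),
                    aad_pct = 100 * mean(abs(e) / observed),
                    n = length(e))
  class(out) <- c("fit_metrics", "data.frame")
  out
}

#' Bookkeeping for a single validation experiment
#'
#' Records a model's recommended optimum, its predicted yield, and the yield
#' actually measured there, with the relative error (%) and the squared
#' error of the single point.
#'
#' @param model_label model name.
#' @param optimum actual-unit conditions (length-3 vector).
#' @param predicted,actual predicted and measured yields (%), `actual > 0`.
#' @return data.frame of class `validation_record`.
#' @export
validation_record <- function(model_label, optimum, predicted, actual) {
  stopifnot(actual > 0)
  out <- data.frame(model_label = model_label,
                    cond_1 = optimum[1], cond_2 = optimum[2],
                    cond_3 = optimum[3],
                    predicted_yield = predicted, actual_yield = actual,
                    relative_error_pct = 100 * abs(predicted - actual) / actual,
                    squared_error = (predicted - actual)^2)
  class(out) <- c("validation_record", "data.frame")
  out
}

#' Rank competing yield models
#'
#' Orders models by R^2 (descending), breaking ties by RMSE (ascending), and
#' flags the winner; validation records are carried alongside.
#'
#' @param metrics one or more `fit_metrics` rows (rbind-able).
#' @param validations optional `validation_record` rows.
#' @return list of class `comparison_report` with `ranking` (metrics plus
#'   `rank` and `winner` columns) and `validation`.
#' @export
comparison_report <- function(metrics, validations = NULL) {
  m <- as.data.frame(metrics)
  stopifnot(nrow(m) >= 1L)
  ord <- order(-m$r2, m$rmse)
  m <- m[ord, , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  m$winner <- m$rank == 1L
  rownames(m) <- NULL
  structure(list(ranking = m,
                 validation = if (is.null(validations)) NULL
                              else as.data.frame(validations)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("<comparison_report> winner:", x$ranking$model_label[1L], "\n")
  print(x$ranking)
  if (!is.null(x$validation)) {
    cat("validation experiments:\n")
    print(x$validation)
  }
  invisible(x)
}

#' Write a comparison report as JSON and Markdown
#'
#' @param report a `comparison_report`.
#' @param json_path,md_path output paths (either may be `NULL` to skip).
#' @export
write_comparison <- function(report, json_path = NULL, md_path = NULL) {
  if (!is.null(json_path)) {
    jsonlite::write_json(list(ranking = report$ranking,
                              validation = report$validation),
                         json_path, dataframe = "rows", digits = NA,
                         na = "null", pretty = TRUE)
  }
  if (!is.null(md_path)) {
    md <- c("| Model | R2 | RMSE | AAD | n |",
            "|---|---|---|---|---|",
            sprintf("| %s | %.4f | %.4f | %.4f | %d |",
                    report$ranking$model_label, report$ranking$r2,
                    report$ranking$rmse, report$ranking$aad,
                    report$ranking$n))
    if (!is.null(report$validation)) {
      v <- report$validation
      md <- c(md, "",
              "| Model | Conditions | Predicted | Actual | Rel. error (%) | Squared error |",
              "|---|---|---|---|---|---|",
              sprintf("| %s | %.3f, %.3f, %.3f | %.2f | %.2f | %.2f | %.4f |",
                      v$model_label, v$cond_1, v$cond_2, v$cond_3,
                      v$predicted_yield, v$actual_yield,
                      v$relative_error_pct, v$squared_error))
    }
    writeLines(md, md_path)
  }
  invisible(report)
}
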