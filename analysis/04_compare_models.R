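#!/usr/bin/env Rscript
# Stage 4: compare the RSM fit and the BP surrogate on the 17 runs
# (R-squared, RMSE, AAD) and tabulate the reported validation experiments.

suppressPackageStartupMessages(library(yieldsurf))
dir.create("results", showWarnings = FALSE)

fx <- load_fixture("table2_bbd")
obs <- fx$dataset$runs$yield_pct
X <- as.matrix(fx$dataset$runs[, 2:4])

model <- fit_quadratic(fx$dataset)
net <- read_mlp_json("results/bp_network.json")
metrics <- rbind(
  compute_metrics(predict(model, coded_matrix(fx$dataset)), obs, "RSM"),
  compute_metrics(suppressWarnings(mlp_predict(net, X)), obs, "BP"))

opts <- fx$annotations$reported_optima
validations <- do.call(rbind, lapply(c("RSM", "BP", "GA-BP"), function(nm) {
  r <- opts[[nm]]
  validation_record(nm, c(r$pH, r$enzyme_pct, r$time_min), r$predicted, r$actual)
}))

rep <- comparison_report(metrics, validations)
print(rep)
write_comparison(rep, "results/comparison.json", "results/comparison.md")
cat("wrote results/comparison.{json,md}\n")
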