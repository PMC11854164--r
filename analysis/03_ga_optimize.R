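#!/usr/bin/env Rscript
# Stage 3: maximize predicted yield over the experimental box with the
# real-coded GA, using (a) the trained BP surrogate (the GA-BP pipeline)
# and (b) the fitted quadratic, whose analytic optimum provides a check.

suppressPackageStartupMessages(library(yieldsurf))
dir.create("results", showWarnings = FALSE)

fx <- load_fixture("table2_bbd")
box <- vapply(fx$dataset$factors, function(f) c(low = f$low, high = f$high),
              numeric(2))

# (a) GA over the BP surrogate; restart seeds follow stage 2's selection
net <- read_mlp_json("results/bp_network.json")
fitness_bp <- function(x) suppressWarnings(mlp_predict(net, x))
ga_bp <- run_ga(fitness_bp, ga_config(box, seed = 307L),
                initial = as.matrix(fx$dataset$runs[, 2:4]))
cat(sprintf("GA-BP optimum: pH %.3f, enzyme %.3f%%, time %.3f min -> %.2f%% predicted yield\n",
            ga_bp$best_point[1], ga_bp$best_point[2], ga_bp$best_point[3],
            ga_bp$best_fitness))

# (b) GA over the fitted quadratic, versus the analytic surface optimum
model <- fit_quadratic(fx$dataset)
ga_rsm <- run_ga(function(x) predict(model, code(x, fx$dataset$factors)),
                 ga_config(box, seed = 308L))
opt <- optimize_surface(model)
cat(sprintf("GA on quadratic: %.4f%%; analytic optimum %.4f%% (gap %.2e)\n",
            ga_rsm$best_fitness, opt$value,
            abs(ga_rsm$best_fitness - opt$value)))

write_ga_trace(ga_bp, "results/ga_bp_trace.csv")
write_ga_trace(ga_rsm, "results/ga_rsm_trace.csv")
jsonlite::write_json(list(
  ga_bp = list(point = ga_bp$best_point, yield = ga_bp$best_fitness),
  ga_rsm = list(point = ga_rsm$best_point, yield = ga_rsm$best_fitness),
  rsm_analytic = list(point = opt$actual, yield = opt$value)),
  "results/optima.json", auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/ga_bp_trace.csv, ga_rsm_trace.csv, optima.json\n")
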