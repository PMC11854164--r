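#' Empirical hidden-layer sizing rule
#'
#' The conventional rule for one-hidden-layer perceptrons on small tabular
#' problems: h = round(sqrt(n_inputs + n_outputs)) + a with the additive
#' constant a between 1 and 10. For 3 inputs, 1 output and a = 8 this gives
#' the 10 hidden neurons used throughout.
#'
#' @param n_inputs,n_outputs layer widths (>= 1).
#' @param a additive constant in 1..10.
#' @return integer hidden-layer size.
#' @export
hidden_size <- function(n_inputs, n_outputs, a) {
  stopifnot(n_inputs >= 1L, n_outputs >= 1L)
  if (a < 1 || a > 10) stop("constant a must lie in [1, 10]", call. = FALSE)
  as.integer(round(sqrt(n_inputs + n_outputs)) + a)
}

#' Seeded train / validation / test split
#'
#' Permutes 1..n with the given seed, then assigns round(f * n) indices to
#' validation and test; the training set takes the remainder. For 33 points
#' at 0.70/0.15/0.15 this yields sizes (23, 5, 5).
#'
#' @param n dataset size (or a `doe_dataset`, whose run count is used).
#' @param fractions length-3 (train, validation, test) fractions summing to 1.
#' @param seed integer seed; the split depends on nothing else.
#' @return list of disjoint, exhaustive integer index vectors `train`,
#'   `validation`, `test`.
#' @export
split_dataset <- function(n, fractions = c(0.70, 0.15, 0.15), seed = 1L) {
  if (inherits(n, "doe_dataset")) n <- nrow(n$runs)
  stopifnot(n >= 3L, length(fractions) == 3L,
            abs(sum(fractions) - 1) < 1e-9)
  n_val <- as.integer(round(fractions[2] * n))
  n_test <- as.integer(round(fractions[3] * n))
  n_train <- n - n_val - n_test
  if (min(n_train, n_val, n_test) < 1L) {
    stop("split too small: each subset needs at least one point (n = ", n, ")",
         call. = FALSE)
  }
  perm <- with_seed(seed, sample.int(n))
  list(train = sort(perm[seq_len(n_train)]),
       validation = sort(perm[n_train + seq_len(n_val)]),
       test = sort(perm[n_train + n_val + seq_len(n_test)]))
}

#' Training configuration for the backpropagation network
#'
#' Two deterministic full-batch trainers on the backpropagation gradient are
#' available. `"lm"` (default) is Levenberg-Marquardt: damped Gauss-Newton
#' steps from the per-sample Jacobian, the standard trainer for small
#' feed-forward nets, converging in a handful of epochs. `"gd"` is plain
#' gradient descent with momentum. Either way, early stopping restores the
#' weights of the epoch with the lowest validation MSE.
#'
#' @param algorithm `"lm"` or `"gd"`.
#' @param learning_rate `"gd"` step size on the scaled-MSE gradient (0
#'   deliberately freezes the weights).
#' @param momentum `"gd"` momentum coefficient in `[0, 1)`.
#' @param max_epochs epoch budget.
#' @param patience validation checks without improvement before stopping.
#'   The default 6 suits the fast-converging `"lm"`; first-order `"gd"`
#'   typically needs 50 or more, since its validation error drifts through a
#'   long momentum transient.
#' @param split_fractions (train, validation, test) fractions.
#' @param hidden hidden-layer width.
#' @param goal scaled-MSE target; training stops early when reached (0 = off).
#' @param mu0 initial Levenberg-Marquardt damping.
#' @param seed drives initialization and the split.
#' @return a `train_config` list.
#' @export
train_config <- function(algorithm = c("lm", "gd"),
                         learning_rate = 0.05, momentum = 0.9,
                         max_epochs = 1000L, patience = 6L,
                         split_fractions = c(0.70, 0.15, 0.15),
                         hidden = 10L, goal = 0, mu0 = 1e-3, seed = 1L) {
  algorithm <- match.arg(algorithm)
  stopifnot(learning_rate >= 0, momentum >= 0, momentum < 1,
            max_epochs >= 1L, patience >= 1L, mu0 > 0)
  structure(list(algorithm = algorithm,
                 learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 split_fractions = split_fractions,
                 hidden = as.integer(hidden), goal = goal, mu0 = mu0,
                 seed = as.integer(seed)),
            class = "train_config")
}

# min-max ranges per column, mapping data range onto [-1, 1]
fit_scaler <- function(x) {
  m <- as.matrix(x)
  rng <- rbind(min = apply(m, 2L, min), max = apply(m, 2L, max))
  if (any(rng["max", ] <= rng["min", ])) {
    stop("scaler not invertible: a variable has zero range", call. = FALSE)
  }
  rng
}

scale_to <- function(x, rng) {
  m <- if (is.null(dim(x))) matrix(x, ncol = ncol(rng)) else as.matrix(x)
  sweep(sweep(m, 2L, rng["min", ], "-"), 2L,
        (rng["max", ] - rng["min", ]) / 2, "/") - 1
}

scale_from <- function(s, rng) {
  m <- if (is.null(dim(s))) matrix(s, ncol = ncol(rng)) else as.matrix(s)
  sweep(sweep(m + 1, 2L, (rng["max", ] - rng["min", ]) / 2, "*"), 2L,
        rng["min", ], "+")
}

mlp_init <- function(hidden, seed, n_in = 3L, n_out = 1L) {
  w <- with_seed(seed, stats::runif((n_in + 1L) * hidden + (hidden + 1L) * n_out,
                                    -0.5, 0.5))
  list(W1 = matrix(w[seq_len(hidden * n_in)], hidden, n_in, byrow = TRUE),
       b1 = w[hidden * n_in + seq_len(hidden)],
       W2 = matrix(w[hidden * (n_in + 1L) + seq_len(hidden)], n_out, hidden,
                   byrow = TRUE),
       b2 = w[length(w)])
}

# forward pass on already-scaled inputs; returns list(out, A1) for backprop
mlp_forward_scaled <- function(params, Xs) {
  A1 <- tanh(Xs %*% t(params$W1) + rep(params$b1, each = nrow(Xs)))
  out <- drop(A1 %*% t(params$W2)) + params$b2
  list(out = out, A1 = A1)
}

pack_weights <- function(w) {
  c(as.vector(t(w$W1)), w$b1, as.vector(t(w$W2)), w$b2)
}

unpack_weights <- function(theta, hidden, n_in = 3L) {
  list(W1 = matrix(theta[seq_len(hidden * n_in)], hidden, n_in, byrow = TRUE),
       b1 = theta[hidden * n_in + seq_len(hidden)],
       W2 = matrix(theta[hidden * (n_in + 1L) + seq_len(hidden)], 1L, hidden,
                   byrow = TRUE),
       b2 = theta[length(theta)])
}

# Jacobian of the network output w.r.t. all weights (packed order), one row
# per sample -- the Gauss-Newton building block.
mlp_jacobian <- function(params, Xs) {
  fw <- mlp_forward_scaled(params, Xs)
  n <- nrow(Xs)
  h <- length(params$b1)
  D <- (1 - fw$A1^2) * rep(drop(params$W2), each = n)   # n x h
  JW1 <- do.call(cbind, lapply(seq_len(h), function(j) D[, j] * Xs))
  list(J = cbind(JW1, D, fw$A1, 1), out = fw$out)
}

# analytic gradient of mean squared error on scaled data
mlp_gradient <- function(params, Xs, ts) {
  fw <- mlp_forward_scaled(params, Xs)
  n <- nrow(Xs)
  d_out <- 2 * (fw$out - ts) / n
  dW2 <- matrix(d_out, 1L) %*% fw$A1
  db2 <- sum(d_out)
  dA1 <- outer(d_out, drop(params$W2))
  dZ1 <- dA1 * (1 - fw$A1^2)
  list(W1 = t(dZ1) %*% Xs, b1 = colSums(dZ1), W2 = dW2, b2 = db2,
       mse = mean((fw$out - ts)^2))
}

#' Predict yield with a trained network
#'
#' Scales the raw inputs to `[-1, 1]`, applies the tanh hidden layer and
#' linear output, and inverse-scales to percent yield. Extrapolation beyond
#' the training range is allowed but flagged with a warning once any scaled
#' input falls outside `[-1.5, 1.5]`.
#'
#' @param params an `mlp_params` object from [train_mlp()].
#' @param x length-3 vector or n x 3 matrix of actual-unit conditions.
#' @return predicted yield (percent) per row.
#' @export
mlp_predict <- function(params, x) {
  Xs <- scale_to(x, params$input_scaler)
  if (any(abs(Xs) > 1.5)) {
    warning("input outside 1.5x the scaled training range: extrapolating",
            call. = FALSE)
  }
  out <- mlp_forward_scaled(params, Xs)$out
  drop(scale_from(out, params$output_scaler))
}

#' Train the 3-h-1 backpropagation surrogate
#'
#' Full-batch training on the mean squared error of scaled outputs, by
#' Levenberg-Marquardt (default) or gradient descent with momentum — see
#' [train_config()]. The dataset is split with [split_dataset()]; scalers
#' are fitted on the full dataset before splitting. Training stops on the
#' epoch budget, on the scaled-MSE goal, or when the validation MSE has not
#' improved for `patience` consecutive epochs, whichever comes first; the
#' best-validation-epoch weights are restored. Deterministic given the
#' config seed.
#'
#' @param data a `doe_dataset` with observed yields.
#' @param config a [train_config()].
#' @return list with `params` (class `mlp_params`: weights, biases, scalers,
#'   splits, config) and `history` (class `train_history`: per-epoch train /
#'   validation / test MSE on scaled data, `best_epoch`, `stop_reason`).
#' @export
train_mlp <- function(data, config = train_config()) {
  y <- observed_yield(data)
  keep <- which(!is.na(y))
  X <- as.matrix(data$runs[keep, vapply(data$factors, `[[`, "", "name"),
                           drop = FALSE])
  y <- y[keep]
  n <- length(y)
  in_rng <- fit_scaler(X)
  out_rng <- fit_scaler(matrix(y, ncol = 1L))
  Xs <- scale_to(X, in_rng)
  ys <- drop(scale_to(matrix(y, ncol = 1L), out_rng))
  splits <- split_dataset(n, config$split_fractions, config$seed)

  w <- mlp_init(config$hidden, config$seed)
  v <- lapply(w, function(p) p * 0)   # gd momentum state
  mu <- config$mu0                    # lm damping state
  subset_mse <- function(idx) {
    fw <- mlp_forward_scaled(w, Xs[idx, , drop = FALSE])
    mean((fw$out - ys[idx])^2)
  }
  hist <- matrix(NA_real_, nrow = config$max_epochs + 1L, ncol = 3L,
                 dimnames = list(NULL, c("train", "validation", "test")))
  record <- function(epoch) {
    hist[epoch + 1L, ] <<- c(subset_mse(splits$train),
                             subset_mse(splits$validation),
                             subset_mse(splits$test))
  }
  record(0L)
  best <- list(epoch = 0L, val = hist[1L, "validation"], w = w)
  bad <- 0L
  stop_reason <- "max_epochs"
  last_epoch <- 0L
  Xtr <- Xs[splits$train, , drop = FALSE]
  ytr <- ys[splits$train]

  gd_step <- function() {
    g <- mlp_gradient(w, Xtr, ytr)
    if (!is.finite(g$mse)) {
      stop(sprintf("training diverged at epoch %d (learning rate %g)",
                   last_epoch + 1L, config$learning_rate), call. = FALSE)
    }
    for (nm in names(v)) {
      v[[nm]] <<- config$momentum * v[[nm]] - config$learning_rate * g[[nm]]
      w[[nm]] <<- w[[nm]] + v[[nm]]
    }
    TRUE
  }
  lm_step <- function() {
    jr <- mlp_jacobian(w, Xtr)
    e <- jr$out - ytr
    sse <- sum(e^2)
    theta <- pack_weights(w)
    jtj <- crossprod(jr$J)
    jte <- crossprod(jr$J, e)
    repeat {
      delta <- tryCatch(solve(jtj + mu * diag(nrow(jtj)), jte),
                        error = function(cond) NULL)
      if (!is.null(delta)) {
        cand <- unpack_weights(theta - drop(delta), config$hidden)
        sse_new <- sum((mlp_forward_scaled(cand, Xtr)$out - ytr)^2)
        if (is.finite(sse_new) && sse_new < sse) {
          w <<- cand
          mu <<- max(mu * 0.1, 1e-12)
          return(TRUE)
        }
      }
      mu <<- mu * 10
      if (mu > 1e10) return(FALSE)   # damping exhausted: converged
    }
  }
  step <- if (config$algorithm == "lm") lm_step else gd_step

  for (epoch in seq_len(config$max_epochs)) {
    moved <- step()
    record(epoch)
    last_epoch <- epoch
    val <- hist[epoch + 1L, "validation"]
    if (val < best$val - 1e-15) {
      best <- list(epoch = epoch, val = val, w = w)
      bad <- 0L
    } else {
      bad <- bad + 1L
    }
    if (!moved) {
      stop_reason <- "converged"
      break
    }
    if (config$goal > 0 && hist[epoch + 1L, "train"] <= config$goal) {
      stop_reason <- "goal"
      break
    }
    if (bad >= config$patience) {
      stop_reason <- "patience"
      break
    }
  }
  params <- structure(c(best$w,
                        list(layer_sizes = c(3L, config$hidden, 1L),
                             input_scaler = in_rng, output_scaler = out_rng,
                             splits = splits, config = config,
                             X = X, y = y)),
                      class = "mlp_params")
  history <- structure(list(mse = hist[seq_len(last_epoch + 1L), , drop = FALSE],
                            epoch = 0:last_epoch,
                            best_epoch = best$epoch,
                            stop_reason = stop_reason),
                       class = "train_history")
  list(params = params, history = history)
}

#' @export
print.mlp_params <- function(x, ...) {
  cat(sprintf("<mlp_params> %d-%d-%d tanh/linear network, %d parameters\n",
              x$layer_sizes[1], x$layer_sizes[2], x$layer_sizes[3],
              sum(lengths(list(x$W1, x$b1, x$W2))) + 1L))
  invisible(x)
}

#' @export
print.train_history <- function(x, ...) {
  cat(sprintf("<train_history> %d epochs, best validation MSE %.6f at epoch %d (%s)\n",
              max(x$epoch), x$mse[x$best_epoch + 1L, "validation"],
              x$best_epoch, x$stop_reason))
  invisible(x)
}

#' Prediction-versus-target regression report
#'
#' Pearson R and the least-squares line of predictions on targets, per split
#' subset and pooled — the standard post-training regression panel.
#'
#' @param params a trained `mlp_params` (its stored data and splits are used).
#' @return data.frame with `subset`, `n`, `r`, `slope`, `intercept`. Subsets
#'   with fewer than 2 points or zero-variance predictions get `NA` with a
#'   warning.
#' @export
regression_report <- function(params) {
  pred <- mlp_predict(params, params$X)
  obs <- params$y
  sets <- c(params$splits, list(overall = seq_along(obs)))
  rows <- lapply(names(sets), function(nm) {
    i <- sets[[nm]]
    if (length(i) < 2L) {
      warning("subset '", nm, "' has < 2 points: R undefined", call. = FALSE)
      return(data.frame(subset = nm, n = length(i), r = NA_real_,
                        slope = NA_real_, intercept = NA_real_))
    }
    p <- pred[i]; o <- obs[i]
    if (stats::var(p) == 0 || stats::var(o) == 0) {
      warning("subset '", nm, "' has constant values: R undefined", call. = FALSE)
      return(data.frame(subset = nm, n = length(i), r = NA_real_,
                        slope = NA_real_, intercept = NA_real_))
    }
    sl <- stats::cov(p, o) / stats::var(o)
    data.frame(subset = nm, n = length(i), r = stats::cor(p, o),
               slope = sl, intercept = mean(p) - sl * mean(o))
  })
  do.call(rbind, rows)
}

#' Histogram of prediction errors
#'
#' Equal-width bins of target minus prediction spanning the observed error
#' range, as in the conventional post-training error panel.
#'
#' @param params a trained `mlp_params`.
#' @param n_bins number of bins (default 20).
#' @return list with `breaks` (length `n_bins + 1`) and `counts`
#'   (sum = number of runs).
#' @export
error_histogram <- function(params, n_bins = 20L) {
  stopifnot(n_bins >= 1L)
  err <- params$y - mlp_predict(params, params$X)
  lo <- min(err); hi <- max(err)
  if (hi - lo < 1e-12) {            # degenerate: all errors identical
    lo <- lo - 0.5; hi <- hi + 0.5
  }
  breaks <- seq(lo, hi, length.out = n_bins + 1L)
  counts <- tabulate(pmin(findInterval(err, breaks, rightmost.closed = TRUE),
                          n_bins), nbins = n_bins)
  list(breaks = breaks, counts = counts)
}

#' Serialize / restore a trained network as JSON
#'
#' Stores layer sizes, flattened weights (row-major, hidden layer first),
#' scaler ranges, and the training configuration, so a trained surrogate can
#' be exchanged as plain text.
#'
#' @param params an `mlp_params`.
#' @param path JSON file path.
#' @export
write_mlp_json <- function(params, path) {
  doc <- list(
    layer_sizes = params$layer_sizes,
    hidden_weights = as.vector(t(params$W1)),
    hidden_biases = params$b1,
    output_weights = as.vector(t(params$W2)),
    output_bias = params$b2,
    input_scaler = list(min = unname(params$input_scaler["min", ]),
                        max = unname(params$input_scaler["max", ])),
    output_scaler = list(min = unname(params$output_scaler["min", ]),
                         max = unname(params$output_scaler["max", ])),
    config = unclass(params$config)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_mlp_json
#' @return [read_mlp_json()] returns an `mlp_params` usable with
#'   [mlp_predict()] (without the training data attached).
#' @export
read_mlp_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  h <- doc$layer_sizes[2]
  in_rng <- rbind(min = doc$input_scaler$min, max = doc$input_scaler$max)
  out_rng <- rbind(min = doc$output_scaler$min, max = doc$output_scaler$max)
  structure(list(W1 = matrix(doc$hidden_weights, h, doc$layer_sizes[1],
                             byrow = TRUE),
                 b1 = doc$hidden_biases,
                 W2 = matrix(doc$output_weights, doc$layer_sizes[3], h,
                             byrow = TRUE),
                 b2 = doc$output_bias,
                 layer_sizes = doc$layer_sizes,
                 input_scaler = in_rng, output_scaler = out_rng,
                 config = doc$config),
            class = "mlp_params")
}
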