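#' Training configuration for Levenberg-Marquardt backpropagation
#'
#' @param hidden_size number of tansig hidden units (default 10).
#' @param max_epochs maximum number of accepted LM steps.
#' @param patience consecutive validation-MSE increases tolerated before
#'   early stopping (default 6, the conventional toolbox value).
#' @param seed integer seed for the weight initialization; required.
#' @param lm_damping_init initial LM damping (mu).
#' @param lm_damping_factor multiplier applied to mu on a rejected step and
#'   divided out on an accepted step.
#' @param lm_damping_max training stops once mu exceeds this (the quadratic
#'   model no longer finds a descent direction).
#' @return a `train_config` list.
#' @export
train_config <- function(hidden_size = 10, max_epochs = 1000, patience = 6,
                         seed, lm_damping_init = 1e-3,
                         lm_damping_factor = 10, lm_damping_max = 1e10) {
  if (missing(seed)) stop("an explicit seed is required")
  stopifnot(hidden_size >= 1, patience >= 1, max_epochs >= 1,
            lm_damping_init > 0, lm_damping_factor > 1)
  structure(list(hidden_size = as.integer(hidden_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 seed = as.integer(seed),
                 lm_damping_init = lm_damping_init,
                 lm_damping_factor = lm_damping_factor,
                 lm_damping_max = lm_damping_max),
            class = "train_config")
}

# pack / unpack the 72-ish free parameters of a 4-h-2 network
pack_params <- function(p) {
  c(as.vector(p$w1), p$b1, p$w2_de, p$w2_nde, p$b2_de, p$b2_nde)
}

unpack_params <- function(theta, h) {
  mlp_params(w1 = matrix(theta[seq_len(4 * h)], nrow = h),
             b1 = theta[4 * h + seq_len(h)],
             w2_de = theta[5 * h + seq_len(h)],
             w2_nde = theta[6 * h + seq_len(h)],
             b2_de = theta[7 * h + 1], b2_nde = theta[7 * h + 2])
}

# residuals (pred - target) and Jacobian over the masked (row, output) pairs;
# analytic backprop through tansig: d tansig / d v = 1 - tansig(v)^2
mlp_resid_jac <- function(theta, x, tn, mask, h, want_jac = TRUE) {
  p <- unpack_params(theta, h)
  hh <- tansig(x %*% t(p$w1) + matrix(p$b1, nrow(x), h, byrow = TRUE))
  yn <- cbind(as.vector(hh %*% p$w2_de) + p$b2_de,
              as.vector(hh %*% p$w2_nde) + p$b2_nde)
  r <- (yn - tn)[mask]
  if (!want_jac) return(list(r = r))
  d <- 1 - hh^2
  n <- nrow(x)
  zero <- matrix(0, n, h)
  jac_out <- function(w2) {
    dw <- sweep(d, 2, w2, "*")
    cbind(dw * x[, 1], dw * x[, 2], dw * x[, 3], dw * x[, 4], dw)
  }
  # column order matches pack_params: w1 (column-major), b1, w2_de, w2_nde, b2
  j_de <- cbind(jac_out(p$w2_de), hh, zero, 1, 0)
  j_nde <- cbind(jac_out(p$w2_nde), zero, hh, 0, 1)
  j <- rbind(j_de[mask[, 1], , drop = FALSE], j_nde[mask[, 2], , drop = FALSE])
  # r must line up with j's row order: output 1 rows first, then output 2
  r <- c((yn[, 1] - tn[, 1])[mask[, 1]], (yn[, 2] - tn[, 2])[mask[, 2]])
  list(r = r, j = j)
}

# mean squared error over masked entries, normalized domain
masked_mse <- function(theta, x, tn, mask, h) {
  if (nrow(x) == 0 || !any(mask)) return(NA_real_)
  r <- mlp_resid_jac(theta, x, tn, mask, h, want_jac = FALSE)$r
  mean(r^2)
}

#' Train the network with Levenberg-Marquardt backpropagation
#'
#' Fits all weights and biases jointly on the normalized training rows by
#' damped Gauss-Newton least squares: each epoch computes the analytic
#' Jacobian of the residuals, then solves `(J'J + mu I) step = -J'r`,
#' inflating `mu` until a step reduces the training error and deflating it
#' after every accepted step. Validation-based early stopping returns the
#' parameter snapshot at the epoch of minimum validation MSE, after
#' `patience` consecutive validation increases. Rows with a missing response
#' contribute error terms only for the observed output.
#'
#' @param table a `disinfection_table` with observed responses.
#' @param split a `data_split` from [split_table()].
#' @param scaler a `minmax_scaler`; all fitting happens on its target scale.
#' @param config a `train_config`.
#' @return a `train_report`: `params` (at the best validation epoch),
#'   `best_epoch`, `epochs_run`, `stop_reason`, normalized-domain
#'   `mse_train` / `mse_val` / `mse_test`, pooled-output correlations
#'   `r_train` / `r_val` / `r_test` / `r_all`, and the per-epoch `history`.
#' @export
train_mlp <- function(table, split, scaler, config) {
  stopifnot(inherits(table, "disinfection_table"), inherits(split, "data_split"),
            inherits(config, "train_config"))
  n <- nrow(table)
  idx_all <- sort(c(split$train_idx, split$val_idx, split$test_idx))
  if (!identical(idx_all, seq_len(n))) stop("split does not cover the table")
  h <- config$hidden_size
  x <- normalize_inputs(treatment_matrix(table), scaler)
  tn <- cbind(normalize(table$de_actual, scaler, "de"),
              normalize(table$nde_actual, scaler, "nde"))
  mask <- !is.na(tn)
  tn[!mask] <- 0
  sub <- function(i) list(x = x[i, , drop = FALSE],
                          tn = tn[i, , drop = FALSE],
                          mask = mask[i, , drop = FALSE])
  tr <- sub(split$train_idx); va <- sub(split$val_idx); te <- sub(split$test_idx)
  if (!any(tr$mask)) stop("no observed responses in the training rows")

  theta <- with_seed(config$seed,
                     stats::runif(7 * h + 2, min = -0.7, max = 0.7))
  mu <- config$lm_damping_init
  sse <- sum(mlp_resid_jac(theta, tr$x, tr$tn, tr$mask, h, want_jac = FALSE)$r^2)
  val_mse <- masked_mse(theta, va$x, va$tn, va$mask, h)
  best <- list(theta = theta, val = val_mse, epoch = 0L)
  fails <- 0L
  history <- data.frame(epoch = 0L, mse_train = sse / sum(tr$mask),
                        mse_val = val_mse)
  stop_reason <- "max_epochs"
  epoch <- 0L
  while (epoch < config$max_epochs) {
    rj <- mlp_resid_jac(theta, tr$x, tr$tn, tr$mask, h)
    a <- crossprod(rj$j)
    g <- crossprod(rj$j, rj$r)
    accepted <- FALSE
    while (mu <= config$lm_damping_max) {
      step <- tryCatch(solve(a + mu * diag(nrow(a)), -g),
                       error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta + as.vector(step)
        sse_new <- sum(mlp_resid_jac(cand, tr$x, tr$tn, tr$mask, h,
                                     want_jac = FALSE)$r^2)
        if (is.finite(sse_new) && sse_new < sse) {
          theta <- cand
          sse <- sse_new
          mu <- mu / config$lm_damping_factor
          accepted <- TRUE
          break
        }
      }
      mu <- mu * config$lm_damping_factor
    }
    if (!accepted) {
      stop_reason <- "damping_max"
      break
    }
    epoch <- epoch + 1L
    val_mse <- masked_mse(theta, va$x, va$tn, va$mask, h)
    history <- rbind(history,
                     data.frame(epoch = epoch, mse_train = sse / sum(tr$mask),
                                mse_val = val_mse))
    if (!is.na(val_mse)) {
      if (val_mse < best$val) {
        best <- list(theta = theta, val = val_mse, epoch = epoch)
        fails <- 0L
      } else {
        fails <- fails + 1L
        if (fails >= config$patience) {
          stop_reason <- "early_stop"
          break
        }
      }
    } else {
      best <- list(theta = theta, val = NA_real_, epoch = epoch)
    }
  }
  params <- unpack_params(best$theta, h)
  pooled_r <- function(s) {
    if (nrow(s$x) == 0 || sum(s$mask) < 2) return(NA_real_)
    yn <- mlp_forward(s$x, params)
    stats::cor(yn[s$mask], s$tn[s$mask])
  }
  report <- list(
    params = params, best_epoch = best$epoch, epochs_run = epoch,
    stop_reason = stop_reason, config = config, split = split,
    mse_train = masked_mse(best$theta, tr$x, tr$tn, tr$mask, h),
    mse_val = best$val,
    mse_test = masked_mse(best$theta, te$x, te$tn, te$mask, h),
    r_train = pooled_r(tr), r_val = pooled_r(va), r_test = pooled_r(te),
    r_all = pooled_r(list(x = x, tn = tn, mask = mask)),
    history = history)
  class(report) <- "train_report"
  report
}

#' Trial-and-error search over hidden-layer sizes
#'
#' Trains one network per candidate size and returns the size with the
#' highest validation correlation (ties broken toward the smaller network).
#'
#' @param table,split,scaler as in [train_mlp()].
#' @param sizes integer vector of hidden sizes to try; must be non-empty.
#' @param config a `train_config`; its `hidden_size` is overridden per
#'   candidate.
#' @return list with `best_size`, `best_report` and `reports` (one per size).
#' @export
hidden_size_search <- function(table, split, scaler, sizes, config) {
  if (length(sizes) == 0) stop("sizes must be non-empty")
  reports <- lapply(sizes, function(s) {
    cfg <- config
    cfg$hidden_size <- as.integer(s)
    train_mlp(table, split, scaler, cfg)
  })
  score <- vapply(reports, function(r) {
    if (is.na(r$r_val)) r$r_train else r$r_val
  }, numeric(1))
  # ties toward the smaller size: order by size, pick first maximum
  ord <- order(sizes)
  best <- ord[which.max(score[ord])]
  list(best_size = as.integer(sizes[best]), best_report = reports[[best]],
       sizes = as.integer(sizes), scores = score, reports = reports)
}

#' @export
print.train_report <- function(x, ...) {
  cat(sprintf("4-%d-2 MLP trained by Levenberg-Marquardt (seed %d)\n",
              x$params$hidden_size, x$config$seed))
  cat(sprintf("  best epoch %d of %d run (%s)\n", x$best_epoch, x$epochs_run,
              x$stop_reason))
  cat(sprintf("  MSE (normalized): train %.4g / val %.4g / test %.4g\n",
              x$mse_train, x$mse_val, x$mse_test))
  cat(sprintf("  R: train %.4f / val %.4f / test %.4f / all %.4f\n",
              x$r_train, x$r_val, x$r_test, x$r_all))
  invisible(x)
}
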