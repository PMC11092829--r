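#' Sliding-window specification for temporal fusion
#'
#' @param window Number of consecutive weeks fed to the model (default 3).
#' @param horizon Forecast horizon in weeks ahead of the window (default 1).
#' @param train_fraction Fraction of each group's windows assigned, in
#'   chronological order, to the training portion (default 0.8). The split is
#'   strictly chronological — windows are never shuffled across time.
#' @return An object of class `temporal_window_spec`.
#' @export
temporal_window_spec <- function(window = 3L, horizon = 1L,
                                 train_fraction = 0.8) {
  if (window < 1) stop("'window' must be >= 1", call. = FALSE)
  if (horizon < 1) stop("'horizon' must be >= 1", call. = FALSE)
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("'train_fraction' must lie in (0, 1)", call. = FALSE)
  }
  structure(list(window = as.integer(window), horizon = as.integer(horizon),
                 train_fraction = train_fraction),
            class = "temporal_window_spec")
}

#' Build a sliding-window dataset from a temporal embedding table
#'
#' For every group, emits one window per position: `window` consecutive weeks
#' of features and the target `horizon` weeks after the window's end. A group
#' with `T` usable weeks yields exactly `T - window - horizon + 1` windows.
#' The chronological train/test split is taken per group (first
#' `train_fraction` of windows train, the rest test), so every test target
#' lies strictly after every train target within its group. Per-feature and
#' target normalisation statistics are computed from the train windows only.
#'
#' @param table A temporal [embedding_table()] (with `time_index` and
#'   `group_id`); each group's weeks must be contiguous.
#' @param spec A [temporal_window_spec()].
#' @return An object of class `temporal_windows`.
#' @export
make_windows <- function(table, spec = temporal_window_spec()) {
  stopifnot(inherits(table, "embedding_table"),
            inherits(spec, "temporal_window_spec"))
  df <- as.data.frame(table)
  if (!all(c("time_index", "group_id") %in% names(df))) {
    stop("'table' must carry time_index and group_id columns", call. = FALSE)
  }
  blocks <- modality_blocks(table)
  feat_cols <- unlist(blocks, use.names = FALSE)
  w <- spec$window; h <- spec$horizon
  xs <- vector("list", w)
  ys <- list(); groups <- list(); ttime <- list()
  train_flag <- list()
  for (g in unique(df$group_id)) {
    sub <- df[df$group_id == g, , drop = FALSE]
    sub <- sub[order(sub$time_index), , drop = FALSE]
    ti <- sub$time_index
    gap <- which(diff(ti) != 1L)
    if (length(gap)) {
      stop(sprintf("group '%s' has a gap in time_index after week %d",
                   g, ti[gap[1L]]), call. = FALSE)
    }
    n_weeks <- nrow(sub)
    n_win <- n_weeks - w - h + 1L
    if (n_win <= 0L) {
      warning(sprintf("group '%s' has too few weeks (%d) for window %d + horizon %d; no windows emitted",
                      g, n_weeks, w, h))
      next
    }
    feats <- as.matrix(sub[, feat_cols, drop = FALSE])
    for (k in seq_len(w)) {
      xs[[k]] <- rbind(xs[[k]], feats[(k):(k + n_win - 1L), , drop = FALSE])
    }
    tgt_pos <- (w + h):(w + h + n_win - 1L)
    ys[[g]] <- sub$label[tgt_pos]
    ttime[[g]] <- ti[tgt_pos]
    groups[[g]] <- rep(g, n_win)
    n_tr <- floor(spec$train_fraction * n_win)
    train_flag[[g]] <- c(rep(TRUE, n_tr), rep(FALSE, n_win - n_tr))
  }
  if (length(ys) == 0L) {
    stop("no group produced any window", call. = FALSE)
  }
  y <- unlist(ys, use.names = FALSE)
  is_train <- unlist(train_flag, use.names = FALSE)
  out <- list(x = xs, y = y,
              group = unlist(groups, use.names = FALSE),
              target_time = unlist(ttime, use.names = FALSE),
              block_widths = vapply(blocks, length, integer(1)),
              block_names = names(blocks),
              train_idx = which(is_train), test_idx = which(!is_train),
              spec = spec)
  # normalisation statistics from train windows only
  tr_rows <- do.call(rbind, lapply(xs, function(m) m[out$train_idx, , drop = FALSE]))
  mu <- colMeans(tr_rows)
  sd <- apply(tr_rows, 2L, stats::sd); sd[sd < 1e-12] <- 1
  y_tr <- y[out$train_idx]
  y_sd <- stats::sd(y_tr); if (!is.finite(y_sd) || y_sd < 1e-12) y_sd <- 1
  out$norm <- list(mu = mu, sd = sd, y_mu = mean(y_tr), y_sd = y_sd)
  structure(out, class = "temporal_windows")
}

#' @export
print.temporal_windows <- function(x, ...) {
  cat(sprintf("<temporal_windows> %d windows (window %d, horizon %d) over %d groups\n",
              length(x$y), x$spec$window, x$spec$horizon,
              length(unique(x$group))))
  cat(sprintf("  chronological split: %d train / %d test\n",
              length(x$train_idx), length(x$test_idx)))
  invisible(x)
}

# ---- temporal front end -----------------------------------------------------

init_temporal_params <- function(block_widths, config) {
  c_out <- config$temporal_channels
  p <- list()
  for (m in c("a", "b")) {
    dim_in <- block_widths[[if (m == "a") 1L else 2L]]
    if (config$temporal_block == "conv") {
      # two causal kernel-2 conv blocks: H_t = relu(X_{t-1} W_prev + X_t W_cur + b)
      p[[paste0("tc1", m, "_prev_W")]] <- init_linear(dim_in, c_out)$W
      p[c(paste0("tc1", m, "_cur_W"), paste0("tc1", m, "_b"))] <-
        init_linear(dim_in, c_out)
      p[[paste0("tc2", m, "_prev_W")]] <- init_linear(c_out, c_out)$W
      p[c(paste0("tc2", m, "_cur_W"), paste0("tc2", m, "_b"))] <-
        init_linear(c_out, c_out)
    } else {
      p[c(paste0("tr1", m, "_x_W"), paste0("tr1", m, "_b"))] <-
        init_linear(dim_in, c_out)
      p[[paste0("tr1", m, "_h_W")]] <- init_linear(c_out, c_out)$W
      p[c(paste0("tr2", m, "_x_W"), paste0("tr2", m, "_b"))] <-
        init_linear(c_out, c_out)
      p[[paste0("tr2", m, "_h_W")]] <- init_linear(c_out, c_out)$W
    }
  }
  p
}

# One temporal block over a list of per-week nodes; returns list of nodes.
ad_temporal_block <- function(tape, xs, pn, prefix, type) {
  w <- length(xs)
  out <- vector("list", w)
  if (type == "conv") {
    for (t in seq_len(w)) {
      cur <- ad_add_bias(tape, ad_matmul(tape, xs[[t]], pn[[paste0(prefix, "_cur_W")]]),
                         pn[[paste0(prefix, "_b")]])
      if (t > 1L) {
        cur <- ad_add(tape, cur,
                      ad_matmul(tape, xs[[t - 1L]], pn[[paste0(prefix, "_prev_W")]]))
      }
      out[[t]] <- ad_relu(tape, cur)
    }
  } else {
    h <- NULL
    for (t in seq_len(w)) {
      cur <- ad_add_bias(tape, ad_matmul(tape, xs[[t]], pn[[paste0(prefix, "_x_W")]]),
                         pn[[paste0(prefix, "_b")]])
      if (!is.null(h)) {
        cur <- ad_add(tape, cur, ad_matmul(tape, h, pn[[paste0(prefix, "_h_W")]]))
      }
      h <- ad_tanh(tape, cur)
      out[[t]] <- h
    }
  }
  out
}

# Two stacked temporal blocks; the last time step is the modality feature.
ad_temporal_features <- function(tape, xs, pn, modality, type) {
  pre1 <- paste0(if (type == "conv") "tc1" else "tr1", modality)
  pre2 <- paste0(if (type == "conv") "tc2" else "tr2", modality)
  h1 <- ad_temporal_block(tape, xs, pn, pre1, type)
  h2 <- ad_temporal_block(tape, h1, pn, pre2, type)
  h2[[length(h2)]]
}

#' Fit the temporal disentangled dense fusion model
#'
#' The time-series variant: each modality's window passes through two
#' temporal feature-extraction blocks (causal kernel-2 1-D convolutions by
#' default, a simple recurrent block as an alternative), and the resulting
#' per-modality features enter the same disentangled dense fusion
#' architecture as the classification model, trained with mean-square error
#' as the prediction objective (on normalised targets), the vCLUB MI
#' regulariser, L2 weight decay and early stopping with best-weight restore.
#' Validation for early stopping is the chronologically last
#' `config$val_fraction` of each group's training windows.
#'
#' @param dataset A [make_windows()] dataset (or a temporal
#'   [embedding_table()], which is windowed with `window_spec`).
#' @param config A [ddf_config()]; the task is forced to `"regression"`.
#' @param window_spec Used only when `dataset` is an embedding table.
#' @param lambda Optional override of `config$lambda_mi`.
#' @return An object of class `c("ddf_temporal", "ddf")` with the trained
#'   parameters, the epoch log, the best epoch and held-out test
#'   [regression_metrics()] (on the original target scale).
#' @export
ddf_temporal <- function(dataset, config = ddf_config(task = "regression"),
                         window_spec = temporal_window_spec(),
                         lambda = NULL) {
  if (inherits(dataset, "embedding_table")) {
    dataset <- make_windows(dataset, window_spec)
  }
  stopifnot(inherits(dataset, "temporal_windows"))
  config$task <- "regression"
  if (is.null(lambda)) lambda <- config$lambda_mi

  withr::with_seed(config$seed, {
    norm <- dataset$norm
    xs <- lapply(dataset$x, function(m) {
      sweep(sweep(m, 2L, norm$mu, "-"), 2L, norm$sd, "/")
    })
    y_n <- (dataset$y - norm$y_mu) / norm$y_sd
    wa <- dataset$block_widths[[1L]]
    cols_a <- seq_len(wa)
    cols_b <- (wa + 1L):ncol(xs[[1L]])

    # chronologically last windows of each group's train portion -> validation
    tr <- dataset$train_idx
    val_idx <- unlist(lapply(split(tr, dataset$group[tr]), function(ii) {
      ii <- ii[order(dataset$target_time[ii])]
      k <- max(1L, floor(length(ii) * config$val_fraction))
      utils::tail(ii, k)
    }), use.names = FALSE)
    fit_idx <- setdiff(tr, val_idx)

    sub_xs <- function(idx) lapply(xs, function(m) m[idx, , drop = FALSE])
    c_out <- config$temporal_channels
    params <- c(init_temporal_params(dataset$block_widths, config),
                init_fusion_params(c_out, c_out, 1L, config))
    q <- mi_approximator(2L * config$proj_dim, config$proj_dim,
                         hidden = min(4L * 2L * config$proj_dim, 64L),
                         seed = config$seed)
    st <- adam_init(params); qst <- adam_init(q$params)
    log <- init_epoch_log(config$max_epochs)
    best <- list(val = Inf, epoch = 0L, params = params)
    since_best <- 0L
    q_burnin <- 5L
    xs_fit <- sub_xs(fit_idx); xs_val <- sub_xs(val_idx)
    y_fit <- matrix(y_n[fit_idx], ncol = 1L)
    y_val <- matrix(y_n[val_idx], ncol = 1L)
    for (epoch in seq_len(config$max_epochs)) {
      tape <- ad_tape()
      pn <- ad_wrap_params(tape, params)
      fw <- temporal_forward(tape, pn, xs_fit, cols_a, cols_b, config,
                             dropout = config$dropout)
      if (lambda > 0) {
        sasb_val <- ln_rows(cbind(fw$s_a$value, fw$s_b$value))
        for (k in seq_len(config$q_steps)) {
          qt <- ad_tape()
          qpn <- ad_wrap_params(qt, q$params)
          ql <- ad_neg_loglik_node(qt, qpn, ad_const(qt, sasb_val),
                                   ad_const(qt, ln_rows(fw$s_c$value)))
          ad_backward(qt, ql)
          upd <- adam_step(q$params, ad_collect_grads(qpn), qst,
                           lr = config$q_lr)
          q$params <- upd$params; qst <- upd$state
        }
      }
      loss <- ad_mse_node(tape, fw$pred, y_fit)
      mi_term <- NA_real_
      if (lambda > 0) {
        sasb_node <- ad_layernorm(tape, ad_concat_cols(tape, list(fw$s_a, fw$s_b)))
        sc_node <- ad_layernorm(tape, fw$s_c)
        club <- ad_club_node(tape, q, sasb_node, sc_node)
        mi_term <- club$value[1L]
        if (epoch > q_burnin) {
          ramp <- min(1, (epoch - q_burnin) / 40)
          loss <- ad_add(tape, loss,
                         ad_smul(tape, club, ramp * lambda / ncol(fw$s_c$value)))
        }
      }
      l2 <- ad_l2_node(tape, pn, config$l2_strength)
      if (!is.null(l2)) loss <- ad_add(tape, loss, l2)
      if (!is.finite(loss$value[1L])) {
        stop(sprintf("training diverged (non-finite loss) at epoch %d", epoch),
             call. = FALSE)
      }
      ad_backward(tape, loss)
      upd <- adam_step(params, ad_collect_grads(pn), st,
                       lr = config$learning_rate)
      params <- upd$params; st <- upd$state
      val_pred <- temporal_values(params, xs_val, cols_a, cols_b, config)$pred
      val_loss <- mean((val_pred - y_val)^2)
      log[epoch, ] <- c(epoch, loss$value[1L], val_loss, mi_term)
      if (val_loss < best$val - 1e-12) {
        best <- list(val = val_loss, epoch = epoch, params = params)
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
    log <- log[!is.na(log$epoch), , drop = FALSE]
    params <- best$params
    feats <- temporal_values(params, xs_fit, cols_a, cols_b, config)
    mi_estimate <- residual_mi_estimate(ln_rows(cbind(feats$s_a, feats$s_b)),
                                        ln_rows(feats$s_c), config$seed)
    te <- dataset$test_idx
    pred_te <- temporal_values(params, sub_xs(te), cols_a, cols_b,
                               config)$pred * norm$y_sd + norm$y_mu
    obj <- structure(
      list(params = params, approximator = q, log = log,
           best_epoch = best$epoch, best_val = best$val, lambda = lambda,
           mi_estimate = mi_estimate, model = "disentangled_temporal",
           config = config, task = "regression", dataset_norm = norm,
           block_cols = list(a = cols_a, b = cols_b),
           split = list(fit = fit_idx, val = val_idx, test = te),
           n = length(dataset$y),
           metrics = regression_metrics(pred_te, dataset$y[te]),
           test_predictions = as.vector(pred_te),
           test_targets = dataset$y[te]),
      class = c("ddf_temporal", "ddf"))
    obj
  })
}

temporal_forward <- function(tape, pn, xs, cols_a, cols_b, config,
                             dropout = 0) {
  xa <- lapply(xs, function(m) ad_const(tape, m[, cols_a, drop = FALSE]))
  xb <- lapply(xs, function(m) ad_const(tape, m[, cols_b, drop = FALSE]))
  fa <- ad_temporal_features(tape, xa, pn, "a", config$temporal_block)
  fb <- ad_temporal_features(tape, xb, pn, "b", config$temporal_block)
  fusion_forward(tape, pn, fa, fb, config, dropout)
}

temporal_values <- function(params, xs, cols_a, cols_b, config) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_const(tape, p))
  fw <- temporal_forward(tape, pn, xs, cols_a, cols_b, config)
  list(s_a = fw$s_a$value, s_b = fw$s_b$value, s_c = fw$s_c$value,
       pred = fw$pred$value)
}

#' Predict from a fitted temporal fusion model
#'
#' @param object A fitted [ddf_temporal()] model.
#' @param newdata A [make_windows()] dataset built with the same blocks.
#' @param ... Unused.
#' @return Numeric vector of predictions on the original target scale.
#' @export
predict.ddf_temporal <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "temporal_windows"))
  norm <- object$dataset_norm
  xs <- lapply(newdata$x, function(m) {
    sweep(sweep(m, 2L, norm$mu, "-"), 2L, norm$sd, "/")
  })
  pred <- temporal_values(object$params, xs, object$block_cols$a,
                          object$block_cols$b, object$config)$pred
  as.vector(pred * norm$y_sd + norm$y_mu)
}

#' @export
residuals.ddf_temporal <- function(object, ...) {
  object$test_targets - object$test_predictions
}

#' Repeated training runs with mean and spread of each metric
#'
#' Re-trains the temporal fusion model `n_runs` times under seeds
#' `seed, seed + 1, ...` and reports, per metric, the arithmetic mean and the
#' sample standard deviation (n - 1 denominator) across runs.
#'
#' @param dataset A [make_windows()] dataset.
#' @param config A [ddf_config()].
#' @param n_runs Number of repeated runs (>= 2).
#' @param seeds Optional explicit seed vector overriding the default
#'   sequence (must have length `n_runs`).
#' @return A data frame with one row per metric: `mean`, `sd`, and one
#'   column per run.
#' @export
repeated_evaluation <- function(dataset, config = ddf_config(task = "regression"),
                                n_runs = 3L, seeds = NULL) {
  if (n_runs < 2) stop("'n_runs' must be >= 2", call. = FALSE)
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_runs) - 1L
  stopifnot(length(seeds) == n_runs)
  runs <- lapply(seeds, function(s) {
    cfg <- config; cfg$seed <- as.integer(s)
    m <- ddf_temporal(dataset, cfg)$metrics
    unlist(m[c("mae", "mse", "rmse", "smape", "r2")])
  })
  mat <- do.call(rbind, runs)
  out <- data.frame(metric = colnames(mat),
                    mean = colMeans(mat),
                    sd = apply(mat, 2L, stats::sd))
  run_cols <- as.data.frame(t(mat))
  names(run_cols) <- paste0("run", seq_len(n_runs))
  cbind(out, run_cols)
}
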