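#' Fit a multimodal fusion model to an embedding table
#'
#' The main fitting function of the package. `model = "disentangled"` trains
#' the disentangled dense fusion network: a Kronecker joint interaction,
#' self-attention modality-specific features `Sa`, `Sb`, cross-attention
#' modality-common features `Sc`, a dense skip-connected head, and the
#' combined objective
#' \deqn{L = L_{objective}(g(h_{final})) + \lambda\, \mathrm{MI}(\mathrm{concat}(S_a, S_b), S_c)}
#' where the MI term is the vCLUB upper bound and the variational
#' approximator is updated alternately with the fusion parameters (one
#' maximum-likelihood refresh of the approximator per epoch, features held
#' fixed; then one fusion update with the approximator held fixed).
#' `L_objective` is the class-weighted focal loss for classification and
#' mean-square error for regression.
#'
#' The table is split 70/30 into train and test (stratified by label for
#' classification) under `config$seed`; a further `val_fraction` of the
#' training split is held out for early stopping (halt `patience` epochs
#' after the last validation improvement, restore the best weights).
#'
#' Comparator models are available through the same interface: per-modality
#' logistic regressions and single-hidden-layer networks, an early-fusion
#' concatenation logistic regression, a concatenation MLP, and
#' `"dense_fusion"` — the identical fusion architecture trained without the
#' MI disentanglement term (`lambda_mi = 0`).
#'
#' @param table An [embedding_table()] with at least two modality blocks.
#'   The first block is modality A; all remaining blocks are concatenated
#'   into modality B.
#' @param model One of `"disentangled"`, `"dense_fusion"`, `"concat_mlp"`,
#'   `"nn_a"`, `"nn_b"`, `"logreg_a"`, `"logreg_b"`,
#'   `"early_fusion_logreg"`.
#' @param config A [ddf_config()].
#' @return An object of class `ddf` with the trained parameters, the
#'   per-epoch training log, the held-out test [classification_metrics()] or
#'   [regression_metrics()], and (for the fusion architectures) a post-hoc
#'   vCLUB estimate of the residual MI between the modality-specific and
#'   modality-common features.
#' @examples
#' \donttest{
#' tab <- generate_classification(synthetic_spec(n_samples = 400, seed = 1))
#' fit <- ddf(tab, model = "concat_mlp",
#'            config = ddf_config(proj_dim = 8, head_dim = 16, max_epochs = 30))
#' summary(fit)
#' }
#' @export
ddf <- function(table, model = c("disentangled", "dense_fusion", "concat_mlp",
                                 "nn_a", "nn_b", "logreg_a", "logreg_b",
                                 "early_fusion_logreg"),
                config = ddf_config()) {
  if (!inherits(table, "embedding_table")) {
    stop("'table' must be an embedding_table", call. = FALSE)
  }
  if (is.character(model) && length(model) == 1L &&
      !model %in% c("disentangled", "dense_fusion", "concat_mlp", "nn_a",
                    "nn_b", "logreg_a", "logreg_b", "early_fusion_logreg")) {
    stop(sprintf(paste0("unknown model '%s'; choose one of: disentangled, ",
                        "dense_fusion, concat_mlp, nn_a, nn_b, logreg_a, ",
                        "logreg_b, early_fusion_logreg"), model), call. = FALSE)
  }
  model <- match.arg(model)
  blocks <- modality_blocks(table)
  xa <- block_matrix(table, names(blocks)[1L])
  xb <- do.call(cbind, lapply(names(blocks)[-1L], block_matrix, table = table))
  y <- table$label
  task <- if (is.factor(y) || is.character(y)) "classification" else "regression"
  if (task != config$task) {
    config$task <- task
  }
  if (task == "classification") y <- factor(y)

  withr::with_seed(config$seed, {
    n <- nrow(xa)
    test_idx <- holdout_indices(y, 0.30, task)
    train_idx <- setdiff(seq_len(n), test_idx)
    if (task == "classification" &&
        length(unique(y[train_idx])) < 2L) {
      stop("training labels contain a single class; cannot fit", call. = FALSE)
    }
    val_idx <- train_idx[holdout_indices(y[train_idx], config$val_fraction, task)]
    fit_idx <- setdiff(train_idx, val_idx)

    std <- fit_standardizer(xa[fit_idx, , drop = FALSE],
                            xb[fit_idx, , drop = FALSE])
    xa_s <- apply_standardizer(std, xa, "a")
    xb_s <- apply_standardizer(std, xb, "b")

    cw <- NULL; levels_y <- NULL
    if (task == "classification") {
      levels_y <- levels(y)
      counts <- table(factor(y[fit_idx], levels = levels_y))
      cw <- class_weights(stats::setNames(as.numeric(counts), levels_y))
    }

    fitted <- switch(
      model,
      disentangled = fit_fusion_model(xa_s, xb_s, y, fit_idx, val_idx, config,
                                      cw, lambda = config$lambda_mi),
      dense_fusion = fit_fusion_model(xa_s, xb_s, y, fit_idx, val_idx, config,
                                      cw, lambda = 0),
      concat_mlp = fit_mlp_model(cbind(xa_s, xb_s), y, fit_idx, val_idx,
                                 config, cw),
      nn_a = fit_mlp_model(xa_s, y, fit_idx, val_idx, config, cw),
      nn_b = fit_mlp_model(xb_s, y, fit_idx, val_idx, config, cw),
      logreg_a = fit_logreg_model(xa_s, y, train_idx, cw),
      logreg_b = fit_logreg_model(xb_s, y, train_idx, cw),
      early_fusion_logreg = fit_logreg_model(cbind(xa_s, xb_s), y, train_idx,
                                             cw))

    obj <- structure(
      c(fitted,
        list(model = model, config = config, task = task,
             class_levels = levels_y, class_weight_spec = cw,
             standardizer = std, blocks = blocks,
             split = list(train = train_idx, fit = fit_idx, val = val_idx,
                          test = test_idx),
             n = n)),
      class = c(paste0("ddf_", model), "ddf"))

    probs <- predict_internal(obj, xa_s[test_idx, , drop = FALSE],
                              xb_s[test_idx, , drop = FALSE],
                              standardized = TRUE)
    obj$metrics <- if (task == "classification") {
      classification_metrics(probs, y[test_idx])
    } else {
      regression_metrics(probs, as.numeric(y)[test_idx])
    }
    obj
  })
}

holdout_indices <- function(y, fraction, task) {
  n <- length(y)
  if (task == "classification") {
    idx <- unlist(lapply(split(seq_len(n), y), function(ii) {
      k <- max(1L, round(length(ii) * fraction))
      if (length(ii) == 1L) return(integer(0))
      sample(ii, min(k, length(ii) - 1L))
    }), use.names = FALSE)
    sort(idx)
  } else {
    sort(sample.int(n, max(1L, round(n * fraction))))
  }
}

fit_standardizer <- function(xa, xb) {
  mk <- function(x) {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    sd[sd < 1e-12] <- 1
    list(mu = mu, sd = sd)
  }
  list(a = mk(xa), b = mk(xb))
}

apply_standardizer <- function(std, x, which) {
  s <- std[[which]]
  sweep(sweep(x, 2L, s$mu, "-"), 2L, s$sd, "/")
}

# ---- fusion trainer ---------------------------------------------------------

fit_fusion_model <- function(xa, xb, y, fit_idx, val_idx, config, cw, lambda) {
  task <- config$task
  xa_tr <- xa[fit_idx, , drop = FALSE]; xb_tr <- xb[fit_idx, , drop = FALSE]
  xa_va <- xa[val_idx, , drop = FALSE]; xb_va <- xb[val_idx, , drop = FALSE]
  if (task == "classification") {
    levels_y <- levels(y)
    n_out <- length(levels_y)
    oh_tr <- onehot(y[fit_idx], levels_y)
    alpha_tr <- unname(cw$weights[as.character(y[fit_idx])])
    y_va <- y[val_idx]
  } else {
    n_out <- 1L
    y_tr <- matrix(as.numeric(y)[fit_idx], ncol = 1L)
    y_va <- matrix(as.numeric(y)[val_idx], ncol = 1L)
  }
  params <- init_fusion_params(ncol(xa), ncol(xb), n_out, config)
  q <- mi_approximator(2L * config$proj_dim, config$proj_dim,
                       hidden = min(4L * 2L * config$proj_dim, 64L),
                       seed = config$seed)
  st <- adam_init(params)
  qst <- adam_init(q$params)
  log <- init_epoch_log(config$max_epochs)
  best <- list(val = Inf, epoch = 0L, params = params)
  since_best <- 0L
  q_burnin <- 5L  # approximator-only epochs before the MI penalty engages
  for (epoch in seq_len(config$max_epochs)) {
    tape <- ad_tape()
    pn <- ad_wrap_params(tape, params)
    fw <- fusion_forward(tape, pn, ad_const(tape, xa_tr),
                         ad_const(tape, xb_tr), config,
                         dropout = config$dropout)
    sasb_val <- ln_rows(cbind(fw$s_a$value, fw$s_b$value))
    sc_val <- ln_rows(fw$s_c$value)
    # alternating step 1: refresh the approximator on frozen features
    if (lambda > 0) {
      for (k in seq_len(config$q_steps)) {
        qt <- ad_tape()
        qpn <- ad_wrap_params(qt, q$params)
        ql <- ad_neg_loglik_node(qt, qpn, ad_const(qt, sasb_val),
                                 ad_const(qt, sc_val))
        ad_backward(qt, ql)
        upd <- adam_step(q$params, ad_collect_grads(qpn), qst, lr = config$q_lr)
        q$params <- upd$params; qst <- upd$state
      }
    }
    # alternating step 2: fusion update with the approximator frozen
    objective <- if (task == "classification") {
      ad_focal_loss_node(tape, fw$pred, oh_tr, alpha_tr, config$focal_gamma)
    } else {
      ad_mse_node(tape, fw$pred, y_tr)
    }
    loss <- objective
    mi_term <- NA_real_
    if (lambda > 0) {
      sasb_node <- ad_layernorm(tape, ad_concat_cols(tape, list(fw$s_a, fw$s_b)))
      sc_node <- ad_layernorm(tape, fw$s_c)
      club <- ad_club_node(tape, q, sasb_node, sc_node)
      mi_term <- club$value[1L]
      # per-dimension MI rate keeps lambda's [0,1] range commensurate with
      # the prediction loss across feature widths; the penalty engages only
      # after the approximator burn-in
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

    val_pred <- fusion_values(params, xa_va, xb_va, config)$pred
    val_loss <- if (task == "classification") {
      probs <- softmax_rows(val_pred)
      colnames(probs) <- levels_y
      focal_loss(probs, y_va, gamma = config$focal_gamma, weights = cw)
    } else {
      mean((val_pred - y_va)^2)
    }
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
  # residual MI between the specific and common features at the best epoch,
  # measured with a freshly converged approximator on the training features
  feats <- fusion_values(params, xa_tr, xb_tr, config)
  mi_estimate <- residual_mi_estimate(ln_rows(cbind(feats$s_a, feats$s_b)),
                                      ln_rows(feats$s_c), config$seed)
  list(params = params, approximator = q, log = log,
       best_epoch = best$epoch, best_val = best$val, lambda = lambda,
       mi_estimate = mi_estimate)
}

init_epoch_log <- function(max_epochs) {
  data.frame(epoch = rep(NA_real_, max_epochs), train_loss = NA_real_,
             val_loss = NA_real_, mi_term = NA_real_)
}

fusion_values <- function(params, xa, xb, config) {
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_const(tape, p))
  fw <- fusion_forward(tape, pn, ad_const(tape, xa), ad_const(tape, xb),
                       config)
  list(s_a = fw$s_a$value, s_b = fw$s_b$value, s_c = fw$s_c$value,
       pred = fw$pred$value)
}

onehot <- function(y, levels_y) {
  m <- matrix(0, length(y), length(levels_y))
  m[cbind(seq_along(y), match(as.character(y), levels_y))] <- 1
  m
}

softmax_rows <- function(x) {
  e <- exp(x - row_max(x))
  e / rowSums(e)
}

# ---- single-hidden-layer MLP (per-modality and early-concat baselines) ------

fit_mlp_model <- function(x, y, fit_idx, val_idx, config, cw) {
  task <- config$task
  x_tr <- x[fit_idx, , drop = FALSE]; x_va <- x[val_idx, , drop = FALSE]
  if (task == "classification") {
    levels_y <- levels(y)
    n_out <- length(levels_y)
    oh_tr <- onehot(y[fit_idx], levels_y)
    alpha_tr <- unname(cw$weights[as.character(y[fit_idx])])
    y_va <- y[val_idx]
  } else {
    n_out <- 1L
    y_tr <- matrix(as.numeric(y)[fit_idx], ncol = 1L)
    y_va <- matrix(as.numeric(y)[val_idx], ncol = 1L)
  }
  params <- list()
  params[c("m1_W", "m1_b")] <- init_linear(ncol(x), config$head_dim)
  params[c("m2_W", "m2_b")] <- init_linear(config$head_dim, n_out)
  st <- adam_init(params)
  log <- init_epoch_log(config$max_epochs)
  best <- list(val = Inf, epoch = 0L, params = params)
  since_best <- 0L
  q_burnin <- 5L  # approximator-only epochs before the MI penalty engages
  for (epoch in seq_len(config$max_epochs)) {
    tape <- ad_tape()
    pn <- ad_wrap_params(tape, params)
    h <- ad_dense(tape, ad_const(tape, x_tr), pn, "m1", "relu")
    pred <- ad_dense(tape, ad_dropout(tape, h, config$dropout), pn, "m2",
                     "linear")
    loss <- if (task == "classification") {
      ad_focal_loss_node(tape, pred, oh_tr, alpha_tr, config$focal_gamma)
    } else {
      ad_mse_node(tape, pred, y_tr)
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
    val_pred <- mlp_values(params, x_va)
    val_loss <- if (task == "classification") {
      probs <- softmax_rows(val_pred)
      colnames(probs) <- levels_y
      focal_loss(probs, y_va, gamma = config$focal_gamma, weights = cw)
    } else {
      mean((val_pred - y_va)^2)
    }
    log[epoch, ] <- c(epoch, loss$value[1L], val_loss, NA_real_)
    if (val_loss < best$val - 1e-12) {
      best <- list(val = val_loss, epoch = epoch, params = params)
      since_best <- 0L
    } else {
      since_best <- since_best + 1L
      if (since_best >= config$patience) break
    }
  }
  log <- log[!is.na(log$epoch), , drop = FALSE]
  list(params = best$params, log = log, best_epoch = best$epoch,
       best_val = best$val, lambda = 0, mi_estimate = NA_real_)
}

mlp_values <- function(params, x) {
  h <- pmax(sweep(x %*% params$m1_W, 2L, as.vector(params$m1_b), "+"), 0)
  sweep(h %*% params$m2_W, 2L, as.vector(params$m2_b), "+")
}

# ---- class-weighted multinomial logistic regression -------------------------

fit_logreg_model <- function(x, y, train_idx, cw) {
  df <- as.data.frame(x)
  names(df) <- paste0("f", seq_len(ncol(x)))
  df$.y <- y
  w <- unname(cw$weights[as.character(y[train_idx])])
  fit <- nnet::multinom(.y ~ ., data = df[train_idx, , drop = FALSE],
                        weights = w, trace = FALSE, maxit = 300,
                        MaxNWts = 1e5, decay = 1e-8)
  list(logreg = fit, feature_names = names(df)[seq_len(ncol(x))],
       log = NULL, best_epoch = NA_integer_, lambda = 0,
       mi_estimate = NA_real_)
}

logreg_probs <- function(obj, x) {
  df <- as.data.frame(x)
  names(df) <- obj$feature_names
  p <- stats::predict(obj$logreg, newdata = df, type = "probs")
  if (is.null(dim(p))) {  # binary: vector of P(second level)
    p <- cbind(1 - p, p)
  }
  colnames(p) <- obj$logreg$lev
  p
}

# Internal prediction on standardized or raw matrices.
predict_internal <- function(object, xa, xb, standardized = FALSE) {
  if (!standardized) {
    xa <- apply_standardizer(object$standardizer, xa, "a")
    xb <- apply_standardizer(object$standardizer, xb, "b")
  }
  raw <- switch(
    object$model,
    disentangled = ,
    dense_fusion = fusion_values(object$params, xa, xb, object$config)$pred,
    concat_mlp = mlp_values(object$params, cbind(xa, xb)),
    nn_a = mlp_values(object$params, xa),
    nn_b = mlp_values(object$params, xb),
    logreg_a = return(logreg_probs(object, xa)),
    logreg_b = return(logreg_probs(object, xb)),
    early_fusion_logreg = return(logreg_probs(object, cbind(xa, xb))))
  if (object$task == "classification") {
    p <- softmax_rows(raw)
    colnames(p) <- object$class_levels
    p
  } else {
    as.vector(raw)
  }
}

#' Predict from a fitted fusion model
#'
#' @param object A fitted [ddf()] model.
#' @param newdata An [embedding_table()] with the same blocks as the
#'   training table.
#' @param type `"prob"` for class probabilities, `"class"` for hard labels
#'   (ties broken toward the lowest class index), `"response"` for
#'   regression predictions.
#' @param ... Unused.
#' @return Matrix of probabilities, factor of classes, or numeric vector.
#' @export
predict.ddf <- function(object, newdata,
                        type = c("prob", "class", "response"), ...) {
  type <- match.arg(type)
  if (!inherits(newdata, "embedding_table")) {
    stop("'newdata' must be an embedding_table", call. = FALSE)
  }
  blocks <- modality_blocks(newdata)
  xa <- block_matrix(newdata, names(blocks)[1L])
  xb <- do.call(cbind, lapply(names(blocks)[-1L], block_matrix,
                              table = newdata))
  out <- predict_internal(object, xa, xb)
  if (object$task == "regression") return(as.vector(out))
  if (type == "class") {
    factor(object$class_levels[max.col(out, ties.method = "first")],
           levels = object$class_levels)
  } else {
    out
  }
}

#' @export
print.ddf <- function(x, ...) {
  cat(sprintf("<ddf> %s (%s), %d samples\n", x$model, x$task, x$n))
  if (!is.null(x$log)) {
    cat(sprintf("  epochs run: %d, best epoch: %d\n", nrow(x$log),
                x$best_epoch))
  }
  if (!is.na(x$mi_estimate)) {
    cat(sprintf("  residual vCLUB MI(concat(Sa,Sb); Sc): %.4f nats\n",
                x$mi_estimate))
  }
  cat("  held-out test metrics:\n")
  m <- x$metrics
  keep <- intersect(c("accuracy", "f1_macro", "f1_weighted", "auc_macro",
                      "mae", "rmse", "smape", "r2"), names(m))
  cat(paste0("    ", names(unlist(m[keep])), ": ",
             sprintf("%.4f", unlist(m[keep])), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
summary.ddf <- function(object, ...) {
  print(object)
  print(object$config)
  if (!is.null(object$class_weight_spec)) print(object$class_weight_spec)
  cat(sprintf("  split: %d fit / %d val / %d test\n",
              length(object$split$fit), length(object$split$val),
              length(object$split$test)))
  invisible(object)
}

#' Plot training curves of a fitted fusion model
#'
#' @param x A fitted [ddf()] model with a training log.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.ddf <- function(x, ...) {
  if (is.null(x$log)) {
    stop("this model has no epoch log (closed-form fit)", call. = FALSE)
  }
  graphics::matplot(x$log$epoch, cbind(x$log$train_loss, x$log$val_loss),
                    type = "l", lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::abline(v = x$best_epoch, lty = 3)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

# Post-hoc vCLUB estimate of the residual MI between the specific and common
# features, with a freshly fitted approximator; rows are subsampled (seeded)
# to keep the measurement cheap on large training sets.
residual_mi_estimate <- function(sa_sb, sc, seed, max_rows = 1024L) {
  n <- nrow(sa_sb)
  if (n > max_rows) {
    idx <- sample.int(n, max_rows)
    sa_sb <- sa_sb[idx, , drop = FALSE]
    sc <- sc[idx, , drop = FALSE]
  }
  as.numeric(estimate_mi(sa_sb, sc, steps = 300L, seed = seed))
}

# plain-matrix layer normalisation matching ad_layernorm
ln_rows <- function(x, eps = 1e-5) {
  xc <- x - rowMeans(x)
  xc / sqrt(rowSums(xc^2) / ncol(x) + eps)
}
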