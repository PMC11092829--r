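# Disentangled dense fusion architecture.
#
# Front end: per-modality linear projections into short token sequences,
# self-attention per modality for the modality-specific features Sa, Sb, and
# cross-attention over the Kronecker joint interaction (queries from the
# joint tokens; keys and values are the sums of joint-, A- and B-derived
# projections) for the modality-common features Sc. Head: fully-connected
# deepening of Sa and Sb with a skip concatenation of Sc
# (h_final = concat(h_a, Sc, h_b)) feeding a dense prediction block.

#' Fusion model configuration
#'
#' @param proj_dim Shared width `d` of the token projections and of the
#'   disentangled features `Sa`, `Sb`, `Sc`.
#' @param head_dim Width `d'` of the deepened per-modality representations
#'   `h_a`, `h_b`.
#' @param tokens Number of tokens each modality is projected into before
#'   attention.
#' @param attention_heads Number of attention heads (`proj_dim` must be a
#'   multiple).
#' @param lambda_mi Weight in `[0, 1]` of the mutual-information
#'   (disentanglement) term in the training objective.
#' @param focal_gamma Focusing parameter of the class-weighted focal loss
#'   (classification tasks).
#' @param l2_strength Weight-decay strength applied to weight matrices.
#' @param dropout Dropout rate applied inside the prediction head (and the
#'   baseline MLP hidden layer) during training.
#' @param learning_rate Adam learning rate for the fusion parameters.
#' @param max_epochs Maximum number of training epochs (full-batch).
#' @param patience Early-stopping patience: training halts this many epochs
#'   after the last validation improvement and the best weights are restored.
#' @param val_fraction Fraction of the training split carved out (stratified
#'   for classification) as the early-stopping validation set.
#' @param q_lr,q_steps Learning rate and per-epoch update steps for the
#'   variational MI approximator in the alternating scheme.
#' @param temporal_block Temporal feature-extraction block type for the
#'   time-series variant: causal 1-D convolution (`"conv"`) or a simple
#'   recurrent block (`"rnn"`).
#' @param temporal_channels Channel width of the temporal blocks.
#' @param seed Integer seed governing every random choice in training.
#' @param task `"classification"` or `"regression"`.
#' @return An object of class `ddf_config`.
#' @export
ddf_config <- function(proj_dim = 64L, head_dim = 64L, tokens = 4L,
                       attention_heads = 1L, lambda_mi = 0.5,
                       focal_gamma = 2, l2_strength = 1e-3, dropout = 0.25,
                       learning_rate = 5e-3, max_epochs = 150L,
                       patience = 7L, val_fraction = 0.15,
                       q_lr = 1e-2, q_steps = 2L,
                       temporal_block = c("conv", "rnn"),
                       temporal_channels = 16L,
                       seed = 1L,
                       task = c("classification", "regression")) {
  task <- match.arg(task)
  temporal_block <- match.arg(temporal_block)
  if (lambda_mi < 0 || lambda_mi > 1) {
    stop("'lambda_mi' must lie in [0, 1]", call. = FALSE)
  }
  if (focal_gamma < 0) stop("'focal_gamma' must be >= 0", call. = FALSE)
  if (l2_strength < 0) stop("'l2_strength' must be >= 0", call. = FALSE)
  if (dropout < 0 || dropout >= 1) {
    stop("'dropout' must lie in [0, 1)", call. = FALSE)
  }
  if (patience < 1) stop("'patience' must be >= 1", call. = FALSE)
  if (proj_dim %% attention_heads != 0) {
    stop("'proj_dim' must be a multiple of 'attention_heads'", call. = FALSE)
  }
  structure(list(proj_dim = as.integer(proj_dim), head_dim = as.integer(head_dim),
                 tokens = as.integer(tokens),
                 attention_heads = as.integer(attention_heads),
                 lambda_mi = lambda_mi, focal_gamma = focal_gamma,
                 l2_strength = l2_strength, dropout = dropout,
                 learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), val_fraction = val_fraction,
                 q_lr = q_lr, q_steps = as.integer(q_steps),
                 temporal_block = temporal_block,
                 temporal_channels = as.integer(temporal_channels),
                 seed = as.integer(seed), task = task),
            class = "ddf_config")
}

#' @export
print.ddf_config <- function(x, ...) {
  cat(sprintf(paste0("<ddf_config> task=%s d=%d d'=%d tokens=%d heads=%d ",
                     "lambda_mi=%g gamma=%g l2=%g\n"),
              x$task, x$proj_dim, x$head_dim, x$tokens, x$attention_heads,
              x$lambda_mi, x$focal_gamma, x$l2_strength))
  invisible(x)
}

check_modality_batch <- function(features_a, features_b, labels = NULL) {
  a <- as.matrix(features_a); b <- as.matrix(features_b)
  if (nrow(a) != nrow(b)) stop("modality row counts differ", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("modality features contain non-finite entries", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != nrow(a)) {
    stop("label length does not match feature rows", call. = FALSE)
  }
  list(a = a, b = b)
}

#' Kronecker (outer-product) joint interaction
#'
#' Row `i` of the result is the flattened outer product of the two modality
#' feature vectors: entry `(j, k)` equals `A[i, j] * B[i, k]`, laid out with
#' `k` varying fastest. This approximates the joint distribution of the two
#' modalities by capturing every pairwise cross-modal feature interaction.
#'
#' @param features_a `N x a` matrix.
#' @param features_b `N x b` matrix.
#' @return `N x (a*b)` matrix.
#' @examples
#' kronecker_interaction(matrix(c(1, 2), 1), matrix(c(3, 4), 1))
#' @export
kronecker_interaction <- function(features_a, features_b) {
  ab <- check_modality_batch(features_a, features_b)
  a <- ab$a; b <- ab$b
  a[, rep(seq_len(ncol(a)), each = ncol(b)), drop = FALSE] *
    b[, rep(seq_len(ncol(b)), times = ncol(a)), drop = FALSE]
}

# Tape version of the row-wise outer product.
ad_row_kron <- function(tape, x, y) {
  na <- ncol(x$value); nb <- ncol(y$value)
  ia <- rep(seq_len(na), each = nb)
  ib <- rep(seq_len(nb), times = na)
  ad_node(tape, x$value[, ia, drop = FALSE] * y$value[, ib, drop = FALSE],
          list(x, y), function(g) {
            gx <- matrix(0, nrow(g), na)
            gy <- matrix(0, nrow(g), nb)
            for (j in seq_len(na)) {
              cols <- which(ia == j)
              gx[, j] <- rowSums(g[, cols, drop = FALSE] *
                                   y$value[, ib[cols], drop = FALSE])
            }
            for (k in seq_len(nb)) {
              cols <- which(ib == k)
              gy[, k] <- rowSums(g[, cols, drop = FALSE] *
                                   x$value[, ia[cols], drop = FALSE])
            }
            list(gx, gy)
          })
}

# ---- attention primitives ---------------------------------------------------

# Project x (N x p) into `tokens` tokens of width d; returns list of nodes.
ad_tokenize <- function(tape, x, pn, prefix, tokens, d) {
  z <- ad_dense(tape, x, pn, prefix, "linear")
  lapply(seq_len(tokens), function(i) {
    ad_slice_cols(tape, z, ((i - 1L) * d + 1L):(i * d))
  })
}

# Scaled-dot-product attention over short token lists (multi-head via column
# slicing). q_tok/k_tok/v_tok: lists of N x d nodes of equal length.
# Returns the list of attended tokens.
ad_attention_core <- function(tape, q_tok, k_tok, v_tok, heads) {
  t_q <- length(q_tok); t_k <- length(k_tok)
  d <- ncol(q_tok[[1L]]$value)
  dh <- d %/% heads
  out <- vector("list", t_q)
  for (i in seq_len(t_q)) {
    head_outs <- vector("list", heads)
    for (h in seq_len(heads)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      qh <- ad_slice_cols(tape, q_tok[[i]], cols)
      scores <- vector("list", t_k)
      for (j in seq_len(t_k)) {
        kh <- ad_slice_cols(tape, k_tok[[j]], cols)
        scores[[j]] <- ad_smul(tape, ad_rowsums(tape, ad_mul(tape, qh, kh)),
                               1 / sqrt(dh))
      }
      w <- ad_softmax_rows(tape, ad_concat_cols(tape, scores))
      acc <- NULL
      for (j in seq_len(t_k)) {
        vh <- ad_slice_cols(tape, v_tok[[j]], cols)
        term <- ad_scale_rows(tape, vh, ad_slice_cols(tape, w, j))
        acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
      }
      head_outs[[h]] <- acc
    }
    out[[i]] <- if (heads == 1L) head_outs[[1L]] else {
      ad_concat_cols(tape, head_outs)
    }
  }
  out
}

ad_pool_tokens <- function(tape, toks) {
  acc <- toks[[1L]]
  if (length(toks) > 1L) {
    for (j in 2:length(toks)) acc <- ad_add(tape, acc, toks[[j]])
  }
  ad_smul(tape, acc, 1 / length(toks))
}

# Self-attention branch for one modality: tokens -> Q/K/V -> attention ->
# mean-pooled N x d feature.
ad_specific_branch <- function(tape, toks, pn, prefix, heads) {
  qt <- lapply(toks, function(z) ad_matmul(tape, z, pn[[paste0(prefix, "_q_W")]]))
  kt <- lapply(toks, function(z) ad_matmul(tape, z, pn[[paste0(prefix, "_k_W")]]))
  vt <- lapply(toks, function(z) ad_matmul(tape, z, pn[[paste0(prefix, "_v_W")]]))
  att <- ad_attention_core(tape, qt, kt, vt, heads)
  res <- lapply(seq_along(toks), function(j) ad_add(tape, toks[[j]], att[[j]]))
  ad_pool_tokens(tape, res)
}

# Cross-attention for the common features: queries from the joint tokens;
# keys and values are sums of joint-, A- and B-derived projections.
ad_common_branch <- function(tape, c_toks, a_toks, b_toks, pn, heads) {
  qt <- lapply(c_toks, function(z) ad_matmul(tape, z, pn$cross_q_W))
  sum3 <- function(wc, wa, wb) {
    lapply(seq_along(c_toks), function(j) {
      ad_add(tape, ad_add(tape,
                          ad_matmul(tape, c_toks[[j]], pn[[wc]]),
                          ad_matmul(tape, a_toks[[j]], pn[[wa]])),
             ad_matmul(tape, b_toks[[j]], pn[[wb]]))
    })
  }
  kt <- sum3("key_c_W", "key_a_W", "key_b_W")
  vt <- sum3("val_c_W", "val_a_W", "val_b_W")
  att <- ad_attention_core(tape, qt, kt, vt, heads)
  res <- lapply(seq_along(c_toks), function(j) ad_add(tape, c_toks[[j]], att[[j]]))
  ad_pool_tokens(tape, res)
}

# ---- parameter initialisation ----------------------------------------------

init_fusion_params <- function(dim_a, dim_b, n_out, config) {
  d <- config$proj_dim; t <- config$tokens; dp <- config$head_dim
  p <- list()
  p[c("tok_a_W", "tok_a_b")] <- init_linear(dim_a, t * d)
  p[c("tok_b_W", "tok_b_b")] <- init_linear(dim_b, t * d)
  p[c("tok_c_W", "tok_c_b")] <- init_linear(dim_a * dim_b, t * d)
  for (pre in c("attn_a", "attn_b")) {
    p[[paste0(pre, "_q_W")]] <- init_linear(d, d)$W
    p[[paste0(pre, "_k_W")]] <- init_linear(d, d)$W
    p[[paste0(pre, "_v_W")]] <- init_linear(d, d)$W
  }
  p$cross_q_W <- init_linear(d, d)$W
  for (nm in c("key_c_W", "key_a_W", "key_b_W", "val_c_W", "val_a_W",
               "val_b_W")) {
    p[[nm]] <- init_linear(d, d)$W
  }
  p[c("fa_W", "fa_b")] <- init_linear(d, dp)
  p[c("fb_W", "fb_b")] <- init_linear(d, dp)
  p[c("g1_W", "g1_b")] <- init_linear(2L * dp + d, dp)
  p[c("g2_W", "g2_b")] <- init_linear(dp, n_out)
  p
}

# Full forward pass of the disentangled front end + dense head.
# a_node / b_node: N x dim nodes. Returns nodes for s_a, s_b, s_c, h_final
# and the prediction (logits for classification, N x 1 for regression).
fusion_forward <- function(tape, pn, a_node, b_node, config, dropout = 0) {
  d <- config$proj_dim
  t <- config$tokens
  heads <- config$attention_heads
  joint <- ad_row_kron(tape, a_node, b_node)
  a_toks <- ad_tokenize(tape, a_node, pn, "tok_a", t, d)
  b_toks <- ad_tokenize(tape, b_node, pn, "tok_b", t, d)
  c_toks <- ad_tokenize(tape, joint, pn, "tok_c", t, d)
  if (dropout > 0) {  # token dropout: stochastic features during training
    td <- dropout / 2
    a_toks <- lapply(a_toks, function(z) ad_dropout(tape, z, td))
    b_toks <- lapply(b_toks, function(z) ad_dropout(tape, z, td))
    c_toks <- lapply(c_toks, function(z) ad_dropout(tape, z, td))
  }
  s_a <- ad_specific_branch(tape, a_toks, pn, "attn_a", heads)
  s_b <- ad_specific_branch(tape, b_toks, pn, "attn_b", heads)
  s_c <- ad_common_branch(tape, c_toks, a_toks, b_toks, pn, heads)
  head <- fusion_head_forward(tape, pn, s_a, s_b, s_c, dropout)
  c(list(s_a = s_a, s_b = s_b, s_c = s_c), head)
}

fusion_head_forward <- function(tape, pn, s_a, s_b, s_c, dropout = 0) {
  h_a <- ad_relu(tape, ad_dense(tape, s_a, pn, "fa", "linear"))
  h_b <- ad_relu(tape, ad_dense(tape, s_b, pn, "fb", "linear"))
  if (ncol(h_a$value) == ncol(s_a$value)) {  # residual deepening
    h_a <- ad_add(tape, s_a, h_a)
    h_b <- ad_add(tape, s_b, h_b)
  }
  h_final <- ad_concat_cols(tape, list(h_a, s_c, h_b))
  g <- ad_relu(tape, ad_dense(tape, ad_dropout(tape, h_final, dropout),
                              pn, "g1", "linear"))
  pred <- ad_dense(tape, ad_dropout(tape, g, dropout), pn, "g2", "linear")
  list(h_a = h_a, h_b = h_b, h_final = h_final, pred = pred)
}

# log-softmax with exact closed-form backward.
ad_log_softmax <- function(tape, x) {
  shifted <- x$value - row_max(x$value)
  lse <- log(rowSums(exp(shifted)))
  v <- shifted - lse
  p <- exp(v)
  ad_node(tape, v, list(x), function(g) {
    list(g - p * rowSums(g))
  })
}

# Class-weighted focal loss node from logits. onehot: N x K 0/1 const
# matrix; alpha: N x 1 per-sample class weights.
ad_focal_loss_node <- function(tape, logits, onehot, alpha, gamma) {
  logp <- ad_log_softmax(tape, logits)
  logp_t <- ad_rowsums(tape, ad_mul(tape, logp, ad_const(tape, onehot)))
  neg <- ad_scale_rows(tape, logp_t, ad_const(tape, -alpha))
  if (gamma > 0) {
    p_t <- ad_exp(tape, logp_t)
    mod <- ad_pow_const(tape, ad_add(tape, ad_const(tape, matrix(1, nrow(onehot), 1L)),
                                     ad_smul(tape, p_t, -1)), gamma)
    neg <- ad_mul(tape, neg, mod)
  }
  ad_mean(tape, neg)
}

ad_mse_node <- function(tape, pred, target) {
  ad_mean(tape, ad_square(tape, ad_sub(tape, pred, ad_const(tape, target))))
}

ad_l2_node <- function(tape, pn, strength) {
  if (strength <= 0) return(NULL)
  acc <- NULL
  for (nm in grep("_W$", names(pn), value = TRUE)) {
    term <- ad_sum(tape, ad_square(tape, pn[[nm]]))
    acc <- if (is.null(acc)) term else ad_add(tape, acc, term)
  }
  ad_smul(tape, acc, strength / 2)
}

# ---- exported functional views of the architecture blocks -------------------

#' Modality-specific features via self-attention
#'
#' Projects each modality into a short token sequence, applies scaled
#' dot-product self-attention per modality, and mean-pools the attended
#' tokens into one `proj_dim`-wide feature vector per sample. This controls
#' each modality's expressivity and suppresses noisy feature directions
#' before fusion.
#'
#' @param features_a,features_b Per-modality feature matrices (equal rows).
#' @param config A [ddf_config()].
#' @param params Optional parameter list (as produced by a fitted model);
#'   fresh seeded parameters are drawn from `config$seed` when omitted.
#' @return List with matrices `s_a`, `s_b` and `params`.
#' @export
specific_features <- function(features_a, features_b, config = ddf_config(),
                              params = NULL) {
  ab <- check_modality_batch(features_a, features_b)
  if (is.null(params)) {
    params <- withr::with_seed(config$seed,
      init_fusion_params(ncol(ab$a), ncol(ab$b), 1L, config))
  }
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_const(tape, p))
  a_toks <- ad_tokenize(tape, ad_const(tape, ab$a), pn, "tok_a",
                        config$tokens, config$proj_dim)
  b_toks <- ad_tokenize(tape, ad_const(tape, ab$b), pn, "tok_b",
                        config$tokens, config$proj_dim)
  s_a <- ad_specific_branch(tape, a_toks, pn, "attn_a", config$attention_heads)
  s_b <- ad_specific_branch(tape, b_toks, pn, "attn_b", config$attention_heads)
  list(s_a = s_a$value, s_b = s_b$value, params = params)
}

#' Modality-common features via cross-attention
#'
#' Queries derive from the projected Kronecker joint interaction; keys and
#' values are the element-wise sums of joint-, A- and B-derived projections
#' (`Q_c`, `K_c + K_a + K_b`, `V_c + V_a + V_b`). The attended tokens are
#' mean-pooled to an `N x proj_dim` matrix of modality-common features.
#'
#' @param joint `N x (a*b)` joint-interaction matrix (see
#'   [kronecker_interaction()]).
#' @param s_a,s_b Per-modality feature matrices contributing keys and values.
#' @inheritParams specific_features
#' @return List with matrix `s_c` and `params`.
#' @export
common_features <- function(joint, s_a, s_b, config = ddf_config(),
                            params = NULL) {
  joint <- as.matrix(joint); s_a <- as.matrix(s_a); s_b <- as.matrix(s_b)
  stopifnot(nrow(joint) == nrow(s_a), nrow(joint) == nrow(s_b))
  if (is.null(params)) {
    params <- withr::with_seed(config$seed, {
      p <- init_fusion_params(ncol(s_a), ncol(s_b), 1L, config)
      p[c("tok_c_W", "tok_c_b")] <- init_linear(ncol(joint),
                                                config$tokens * config$proj_dim)
      p
    })
  }
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_const(tape, p))
  c_toks <- ad_tokenize(tape, ad_const(tape, joint), pn, "tok_c",
                        config$tokens, config$proj_dim)
  a_toks <- ad_tokenize(tape, ad_const(tape, s_a), pn, "tok_a",
                        config$tokens, config$proj_dim)
  b_toks <- ad_tokenize(tape, ad_const(tape, s_b), pn, "tok_b",
                        config$tokens, config$proj_dim)
  s_c <- ad_common_branch(tape, c_toks, a_toks, b_toks, pn,
                          config$attention_heads)
  list(s_c = s_c$value, params = params)
}

#' Dense skip-connected fusion head
#'
#' Deepens the modality-specific features through fully-connected layers
#' (`h_a = f_a(S_a)`, `h_b = f_b(S_b)`), concatenates them with the
#' modality-common features into `h_final = concat(h_a, S_c, h_b)`, and
#' applies a dense prediction block. For classification the class scores are
#' normalised to probabilities.
#'
#' @param s_a,s_b,s_c Disentangled feature matrices of equal width
#'   `config$proj_dim`.
#' @param n_out Number of outputs (classes, or 1 for regression).
#' @inheritParams specific_features
#' @return List with `h_a`, `h_b`, `h_final`, `prediction` (probabilities or
#'   real values) and `params`.
#' @export
dense_fusion_head <- function(s_a, s_b, s_c, config = ddf_config(),
                              n_out = 2L, params = NULL) {
  s_a <- as.matrix(s_a); s_b <- as.matrix(s_b); s_c <- as.matrix(s_c)
  stopifnot(nrow(s_a) == nrow(s_b), nrow(s_a) == nrow(s_c),
            ncol(s_a) == ncol(s_c))
  if (is.null(params)) {
    params <- withr::with_seed(config$seed, {
      p <- list()
      p[c("fa_W", "fa_b")] <- init_linear(ncol(s_a), config$head_dim)
      p[c("fb_W", "fb_b")] <- init_linear(ncol(s_b), config$head_dim)
      p[c("g1_W", "g1_b")] <- init_linear(2L * config$head_dim + ncol(s_c),
                                          config$head_dim)
      p[c("g2_W", "g2_b")] <- init_linear(config$head_dim, n_out)
      p
    })
  }
  tape <- ad_tape()
  pn <- lapply(params, function(p) ad_const(tape, p))
  out <- fusion_head_forward(tape, pn, ad_const(tape, s_a),
                             ad_const(tape, s_b), ad_const(tape, s_c))
  pred <- out$pred$value
  if (config$task == "classification") {
    pred <- exp(pred - apply(pred, 1L, max))
    pred <- pred / rowSums(pred)
  }
  list(h_a = out$h_a$value, h_b = out$h_b$value, h_final = out$h_final$value,
       prediction = pred, params = params)
}
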