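#' VAE reconstruction loss (mean squared error)
#'
#' Element-wise mean squared error between an input batch and its
#' reconstruction: \eqn{\frac{1}{n}\sum_i (x_i - \hat x_i)^2} over all
#' entries.
#'
#' @param x,x_hat Numeric arrays/matrices of identical shape.
#' @return Scalar loss.
#' @export
vae_reconstruction_loss <- function(x, x_hat) {
  if (!identical(dim(x), dim(x_hat)) || length(x) != length(x_hat)) {
    stop("'x' and 'x_hat' must have identical shapes", call. = FALSE)
  }
  mean((x - x_hat)^2)
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' \deqn{-\frac{1}{2}\sum_{j=1}^J\left(1 + \log\sigma_j^2 - \mu_j^2
#'   - \sigma_j^2\right)}
#' For matrix inputs (one latent per row) the per-row divergences are
#' averaged.
#'
#' @param mu Mean vector of length `J`, or an `N x J` matrix.
#' @param sigma Standard deviations, strictly positive, same shape as `mu`.
#' @return Scalar KL divergence (nats).
#' @examples
#' vae_kl_divergence(0, 1)       # prior match: 0
#' vae_kl_divergence(1, 1)       # 0.5
#' @export
vae_kl_divergence <- function(mu, sigma) {
  if (any(sigma <= 0)) stop("'sigma' must be strictly positive", call. = FALSE)
  if (length(mu) != length(sigma)) {
    stop("'mu' and 'sigma' must have the same shape", call. = FALSE)
  }
  term <- 1 + log(sigma^2) - mu^2 - sigma^2
  if (is.matrix(mu)) {
    mean(-0.5 * rowSums(term))
  } else {
    -0.5 * sum(term)
  }
}

# ---- convolution primitives (im2col) ---------------------------------------

# Column-gather op: y[, j] = x[, idx[j]] (idx == 0 reads zeros / padding).
ad_gather_cols <- function(tape, x, idx) {
  dmx <- dim(x$value)
  groups <- split(seq_along(idx), idx)
  groups[["0"]] <- NULL
  fwd <- function(xv) {
    y <- matrix(0, dmx[1L], length(idx))
    sel <- idx > 0L
    y[, sel] <- xv[, idx[sel], drop = FALSE]
    y
  }
  ad_node(tape, fwd(x$value), list(x), function(g) {
    dx <- matrix(0, dmx[1L], dmx[2L])
    for (src in names(groups)) {
      cols <- groups[[src]]
      dx[, as.integer(src)] <- rowSums(g[, cols, drop = FALSE])
    }
    list(dx)
  })
}

# Dense layer applied position-wise to an im2col patches matrix:
# patches N x (P*K) -> output N x (P*c_out), sharing W (K x c_out) across
# the P spatial positions.
ad_patch_dense <- function(tape, patches, w_node, b_node, p_count, k_width) {
  n <- nrow(patches$value)
  c_out <- ncol(w_node$value)
  to_rows <- function(m) {  # N x (P*K) -> (N*P) x K
    matrix(aperm(array(m, c(n, k_width, p_count)), c(1L, 3L, 2L)),
           n * p_count, k_width)
  }
  to_cols <- function(m, width) {  # (N*P) x width -> N x (P*width)
    matrix(aperm(array(m, c(n, p_count, width)), c(1L, 3L, 2L)),
           n, p_count * width)
  }
  pr <- to_rows(patches$value)
  out <- sweep(pr %*% w_node$value, 2L, as.vector(b_node$value), "+")
  ad_node(tape, to_cols(out, c_out), list(patches, w_node, b_node),
          function(g) {
            gr <- matrix(aperm(array(g, c(n, c_out, p_count)), c(1L, 3L, 2L)),
                         n * p_count, c_out)
            gp <- gr %*% t(w_node$value)
            list(to_cols(gp, k_width),
                 t(pr) %*% gr,
                 matrix(colSums(gr), 1L))
          })
}

# im2col source-column indices for a square image, position-major layout
# (column (p-1)*C + c for pixel p, channel c), kernel k, stride s, zero pad.
im2col_index <- function(h, w, channels, k, stride, pad) {
  h2 <- (h + 2L * pad - k) %/% stride + 1L
  w2 <- (w + 2L * pad - k) %/% stride + 1L
  idx <- integer(0)
  for (oi in seq_len(h2)) for (oj in seq_len(w2)) {
    for (di in seq_len(k)) for (dj in seq_len(k)) {
      ii <- stride * (oi - 1L) + di - pad
      jj <- stride * (oj - 1L) + dj - pad
      base <- if (ii >= 1L && ii <= h && jj >= 1L && jj <= w) {
        ((ii - 1L) * w + jj - 1L) * channels
      } else NA_integer_
      idx <- c(idx, if (is.na(base)) rep(0L, channels) else base + seq_len(channels))
    }
  }
  list(idx = idx, h_out = h2, w_out = w2, k_width = k * k * channels)
}

ad_conv_layer <- function(tape, x, pn, prefix, im2col) {
  patches <- ad_gather_cols(tape, x, im2col$idx)
  ad_relu(tape, ad_patch_dense(tape, patches, pn[[paste0(prefix, "_W")]],
                               pn[[paste0(prefix, "_b")]],
                               im2col$h_out * im2col$w_out, im2col$k_width))
}

# ---- VAE model --------------------------------------------------------------

init_vae_params <- function(d_in, size, latent_dim, encoder, hidden,
                            conv_channels) {
  p <- list()
  if (encoder == "conv") {
    c1 <- conv_channels[1L]; c2 <- conv_channels[2L]
    i1 <- im2col_index(size, size, 1L, 3L, 2L, 1L)
    i2 <- im2col_index(i1$h_out, i1$w_out, c1, 3L, 2L, 1L)
    p[c("conv1_W", "conv1_b")] <- init_linear(i1$k_width, c1)
    p[c("conv2_W", "conv2_b")] <- init_linear(i2$k_width, c2)
    flat <- i2$h_out * i2$w_out * c2
    p[c("enc_W", "enc_b")] <- init_linear(flat, hidden)
    attr(p, "im2col") <- list(i1, i2)
  } else {
    p[c("e1_W", "e1_b")] <- init_linear(d_in, hidden)
    p[c("e2_W", "e2_b")] <- init_linear(hidden, hidden)
  }
  p[c("mu_W", "mu_b")] <- init_linear(hidden, latent_dim)
  p[c("lv_W", "lv_b")] <- init_linear(hidden, latent_dim)
  p[c("d1_W", "d1_b")] <- init_linear(latent_dim, hidden)
  p[c("d2_W", "d2_b")] <- init_linear(hidden, d_in)
  p
}

vae_encode_tape <- function(tape, pn, x_node, encoder, im2col) {
  h <- if (encoder == "conv") {
    h1 <- ad_conv_layer(tape, x_node, pn, "conv1", im2col[[1L]])
    h2 <- ad_conv_layer(tape, h1, pn, "conv2", im2col[[2L]])
    ad_relu(tape, ad_dense(tape, h2, pn, "enc", "linear"))
  } else {
    ad_dense(tape, ad_dense(tape, x_node, pn, "e1", "relu"), pn, "e2", "relu")
  }
  mu <- ad_dense(tape, h, pn, "mu", "linear")
  lv <- ad_smul(tape, ad_tanh(tape, ad_smul(tape, ad_dense(tape, h, pn, "lv",
                                                           "linear"), 1 / 8)), 8)
  list(mu = mu, lv = lv)
}

vae_decode_tape <- function(tape, pn, z_node) {
  ad_dense(tape, ad_dense(tape, z_node, pn, "d1", "relu"), pn, "d2", "linear")
}

#' Train a variational autoencoder on a batch of small images
#'
#' Encoder to a diagonal Gaussian latent (mean and bounded log-variance),
#' reparameterised sampling, dense decoder, and the standard objective:
#' reconstruction error plus the KL divergence of the posterior from the
#' standard-normal prior (summed over latent dimensions, with the
#' reconstruction term summed over pixels per image and both averaged over
#' the batch — no extra weighting between the two). Training is full-batch
#' Adam and is deterministic under `seed`.
#'
#' The default encoder is a small two-layer convolutional stack (kernel 3,
#' stride 2) suitable for the package's desk-scale images; `encoder = "mlp"`
#' swaps in a dense encoder, and the backbone is pluggable at that level.
#'
#' @param images `N x (size^2)` matrix of flattened grey-scale images (or a
#'   list as returned by [generate_factor_images()]).
#' @param latent_dim Latent dimension `J`.
#' @param encoder `"conv"` (default) or `"mlp"`.
#' @param epochs Training epochs.
#' @param lr Adam learning rate.
#' @param hidden Width of the dense trunk.
#' @param conv_channels Channels of the two conv layers.
#' @param seed Integer seed.
#' @return An object of class `ddf_vae` with the trained parameters and the
#'   per-epoch loss report (`reconstruction`, `kl`, `total`).
#' @export
vae_fit <- function(images, latent_dim = 32L, encoder = c("conv", "mlp"),
                    epochs = 150L, lr = 2e-3, hidden = 64L,
                    conv_channels = c(8L, 16L), seed = 1L) {
  encoder <- match.arg(encoder)
  if (is.list(images) && !is.null(images$images)) images <- images$images
  images <- as.matrix(images)
  d_in <- ncol(images)
  size <- as.integer(round(sqrt(d_in)))
  if (encoder == "conv" && size * size != d_in) {
    stop("conv encoder needs square images (ncol must be a perfect square)",
         call. = FALSE)
  }
  stopifnot(latent_dim >= 1)
  n <- nrow(images)
  withr::with_seed(seed, {
    params <- init_vae_params(d_in, size, latent_dim, encoder, hidden,
                              conv_channels)
    im2col <- attr(params, "im2col")
    st <- adam_init(params)
    log <- data.frame(epoch = rep(NA_real_, epochs), reconstruction = NA_real_,
                      kl = NA_real_, total = NA_real_)
    for (epoch in seq_len(epochs)) {
      eps <- matrix(stats::rnorm(n * latent_dim), n)
      tape <- ad_tape()
      pn <- ad_wrap_params(tape, params)
      x_node <- ad_const(tape, images)
      enc <- vae_encode_tape(tape, pn, x_node, encoder, im2col)
      sig <- ad_exp(tape, ad_smul(tape, enc$lv, 0.5))
      z <- ad_add(tape, enc$mu,
                  ad_mul(tape, sig, ad_const(tape, eps)))
      x_hat <- vae_decode_tape(tape, pn, z)
      # reconstruction summed over pixels per image, averaged over the batch
      recon <- ad_smul(tape, ad_mean(tape, ad_square(tape, ad_sub(tape, x_hat, x_node))),
                       d_in)
      # KL summed over latent dims, averaged over the batch
      kl_elem <- ad_sub(tape,
                        ad_add(tape, ad_square(tape, enc$mu),
                               ad_exp(tape, enc$lv)),
                        ad_add(tape, ad_const(tape, matrix(1, n, latent_dim)),
                               enc$lv))
      kl <- ad_smul(tape, ad_mean(tape, ad_rowsums(tape, kl_elem)), 0.5)
      total <- ad_add(tape, recon, kl)
      if (!is.finite(total$value[1L])) {
        stop(sprintf("VAE training diverged (non-finite loss) at epoch %d",
                     epoch), call. = FALSE)
      }
      ad_backward(tape, total)
      upd <- adam_step(params, ad_collect_grads(pn), st, lr = lr)
      # keep the im2col attribute through updates
      attr(upd$params, "im2col") <- im2col
      params <- upd$params; st <- upd$state
      log[epoch, ] <- c(epoch, recon$value[1L], kl$value[1L], total$value[1L])
    }
    structure(list(params = params, latent_dim = as.integer(latent_dim),
                   encoder = encoder, image_dim = d_in, size = size,
                   hidden = as.integer(hidden), conv_channels = conv_channels,
                   seed = as.integer(seed), log = log),
              class = "ddf_vae")
  })
}

#' @export
print.ddf_vae <- function(x, ...) {
  last <- x$log[nrow(x$log), ]
  cat(sprintf("<ddf_vae> %s encoder, J = %d, %d epochs\n", x$encoder,
              x$latent_dim, nrow(x$log)))
  cat(sprintf("  final loss: reconstruction %.4f + KL %.4f = %.4f\n",
              last$reconstruction, last$kl, last$total))
  invisible(x)
}

#' Extract deterministic embeddings from a trained VAE
#'
#' Returns the posterior mean per image (no sampling), giving a
#' deterministic `J`-wide embedding block ready to enter an
#' [embedding_table()].
#'
#' @param vae A trained [vae_fit()] model.
#' @param images Matrix of flattened images with the same width as the
#'   training images.
#' @return `N x J` matrix with columns `vae__1 ... vae__J`.
#' @export
extract_embeddings <- function(vae, images) {
  stopifnot(inherits(vae, "ddf_vae"))
  if (is.list(images) && !is.null(images$images)) images <- images$images
  images <- as.matrix(images)
  if (ncol(images) != vae$image_dim) {
    stop(sprintf("images have %d pixels but the encoder expects %d",
                 ncol(images), vae$image_dim), call. = FALSE)
  }
  tape <- ad_tape()
  pn <- lapply(vae$params, function(p) ad_const(tape, p))
  enc <- vae_encode_tape(tape, pn, ad_const(tape, images), vae$encoder,
                         attr(vae$params, "im2col"))
  mu <- enc$mu$value
  colnames(mu) <- paste0("vae__", seq_len(ncol(mu)))
  mu
}
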