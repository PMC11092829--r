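#' Specification for the synthetic multimodal generator
#'
#' The generator draws modality-common latents `z_c` and modality-specific
#' latents `z_a`, `z_b` from standard normals, mixes them into two observed
#' embedding blocks through random orthonormal maps, and derives the label
#' from a convex combination of common and specific latent read-outs. The
#' `redundancy` knob moves the label signal between the shared latent
#' (`redundancy = 1`: both modalities carry the full signal, maximal
#' inter-modal redundancy) and the specific latents (`redundancy = 0`: the
#' modalities are complementary and only their combination identifies the
#' label).
#'
#' @param n_samples Number of rows to generate.
#' @param dim_common Dimension of the shared latent `z_c`.
#' @param dim_specific_a,dim_specific_b Dimensions of the modality-specific
#'   latents.
#' @param dim_modality_a,dim_modality_b Observed embedding widths; each must
#'   be at least the total latent dimension feeding it.
#' @param noise_sd Standard deviation of the additive Gaussian observation
#'   noise on the embedding blocks.
#' @param redundancy Fraction in `[0, 1]` of label signal carried by the
#'   common latent.
#' @param n_classes Number of label classes (`>= 2`), or `"regression"` for a
#'   real-valued target.
#' @param class_weights_skew Non-negative imbalance knob: class priors are
#'   drawn from a Dirichlet with concentration `1 / class_weights_skew`
#'   (0 means exactly balanced priors). Large values reproduce the extreme
#'   94/1/2/1/2-style skews seen in clinical grading labels.
#' @param seed Integer seed; the generator is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 1000L, dim_common = 8L,
                           dim_specific_a = 4L, dim_specific_b = 4L,
                           dim_modality_a = 16L, dim_modality_b = 16L,
                           noise_sd = 1, redundancy = 0.5, n_classes = 4L,
                           class_weights_skew = 0, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), dim_common = as.integer(dim_common),
               dim_specific_a = as.integer(dim_specific_a),
               dim_specific_b = as.integer(dim_specific_b),
               dim_modality_a = as.integer(dim_modality_a),
               dim_modality_b = as.integer(dim_modality_b),
               noise_sd = noise_sd, redundancy = redundancy,
               n_classes = n_classes, class_weights_skew = class_weights_skew,
               seed = as.integer(seed))
  validate_synthetic_spec(spec)
  structure(spec, class = "synthetic_spec")
}

validate_synthetic_spec <- function(spec) {
  chk_pos <- function(field) {
    v <- spec[[field]]
    if (!is.numeric(v) || length(v) != 1L || v < 1) {
      stop(sprintf("invalid synthetic_spec: '%s' must be a positive integer",
                   field), call. = FALSE)
    }
  }
  for (f in c("n_samples", "dim_common", "dim_specific_a", "dim_specific_b",
              "dim_modality_a", "dim_modality_b")) chk_pos(f)
  if (spec$noise_sd < 0) {
    stop("invalid synthetic_spec: 'noise_sd' must be >= 0", call. = FALSE)
  }
  if (spec$redundancy < 0 || spec$redundancy > 1) {
    stop("invalid synthetic_spec: 'redundancy' must lie in [0, 1]", call. = FALSE)
  }
  if (spec$class_weights_skew < 0) {
    stop("invalid synthetic_spec: 'class_weights_skew' must be >= 0", call. = FALSE)
  }
  if (spec$dim_modality_a < spec$dim_common + spec$dim_specific_a) {
    stop("invalid synthetic_spec: 'dim_modality_a' must be >= dim_common + dim_specific_a",
         call. = FALSE)
  }
  if (spec$dim_modality_b < spec$dim_common + spec$dim_specific_b) {
    stop("invalid synthetic_spec: 'dim_modality_b' must be >= dim_common + dim_specific_b",
         call. = FALSE)
  }
  if (!identical(spec$n_classes, "regression")) {
    if (!is.numeric(spec$n_classes) || spec$n_classes < 2) {
      stop("invalid synthetic_spec: 'n_classes' must be >= 2 or \"regression\"",
           call. = FALSE)
    }
  }
  invisible(spec)
}

# Random matrix with orthonormal rows mapping latent -> observed; guarantees
# the observed block has full latent rank (no accidental collapse).
orthonormal_mixing <- function(n_latent, n_obs) {
  q <- qr.Q(qr(matrix(stats::rnorm(n_obs * n_latent), n_obs, n_latent)))
  t(q)
}

# Scale applied to the latent label read-out before the softmax; fixed so the
# Bayes accuracy of the default spec sits well away from both chance and 1.
LOGIT_SCALE <- 3

draw_class_priors <- function(k, skew) {
  if (skew <= 0) return(rep(1 / k, k))
  g <- stats::rgamma(k, shape = 1 / skew, rate = 1)
  if (sum(g) == 0) g <- rep(1, k)
  g / sum(g)
}

#' Generate a synthetic classification embedding table
#'
#' @param spec A [synthetic_spec()] with `n_classes >= 2`.
#' @return An [embedding_table()] with blocks `"A"` and `"B"` and a factor
#'   label.
#' @examples
#' tab <- generate_classification(synthetic_spec(n_samples = 50, seed = 3))
#' table(tab$label)
#' @export
generate_classification <- function(spec) {
  validate_synthetic_spec(spec)
  if (identical(spec$n_classes, "regression")) {
    stop("invalid synthetic_spec: 'n_classes' must be >= 2 for classification",
         call. = FALSE)
  }
  k <- as.integer(spec$n_classes)
  n <- spec$n_samples
  withr::with_seed(spec$seed, {
    zc <- matrix(stats::rnorm(n * spec$dim_common), n)
    za <- matrix(stats::rnorm(n * spec$dim_specific_a), n)
    zb <- matrix(stats::rnorm(n * spec$dim_specific_b), n)
    mix_a <- orthonormal_mixing(spec$dim_common + spec$dim_specific_a,
                                spec$dim_modality_a)
    mix_b <- orthonormal_mixing(spec$dim_common + spec$dim_specific_b,
                                spec$dim_modality_b)
    wc <- unit_cols(matrix(stats::rnorm(spec$dim_common * k), ncol = k))
    wa <- unit_cols(matrix(stats::rnorm(spec$dim_specific_a * k), ncol = k))
    wb <- unit_cols(matrix(stats::rnorm(spec$dim_specific_b * k), ncol = k))
    priors <- draw_class_priors(k, spec$class_weights_skew)
    a <- cbind(zc, za) %*% mix_a
    b <- cbind(zc, zb) %*% mix_b
    if (spec$noise_sd > 0) {
      a <- a + matrix(stats::rnorm(length(a), sd = spec$noise_sd), n)
      b <- b + matrix(stats::rnorm(length(b), sd = spec$noise_sd), n)
    }
    r <- spec$redundancy
    logits <- LOGIT_SCALE * (r * zc %*% wc + (1 - r) * (za %*% wa + zb %*% wb))
    logits <- sweep(logits, 2L, log(priors), "+")
    p <- exp(logits - apply(logits, 1L, max))
    p <- p / rowSums(p)
    u <- stats::runif(n)
    lab <- max.col(sweep(t(apply(p, 1L, cumsum)), 1L, u, ">="), "first")
    df <- data.frame(sample_id = sprintf("s%05d", seq_len(n)))
    colnames(a) <- paste0("A__", seq_len(ncol(a)))
    colnames(b) <- paste0("B__", seq_len(ncol(b)))
    df <- cbind(df, as.data.frame(a), as.data.frame(b))
    df$label <- factor(paste0("c", lab), levels = paste0("c", seq_len(k)))
    embedding_table(df, blocks = list(A = colnames(a), B = colnames(b)))
  })
}

unit_cols <- function(m) sweep(m, 2L, sqrt(colSums(m^2)), "/")

#' Generate a synthetic temporal (weekly, grouped) embedding table
#'
#' Per group, the latents evolve as a stationary AR(1) process; the regression
#' target is a softplus read-out of the latents (so it is non-negative, like a
#' weekly case count), and the observed blocks are noisy orthonormal mixes of
#' the latents, exactly as in [generate_classification()].
#'
#' @param spec A [synthetic_spec()]; `n_classes` is ignored (the target is a
#'   non-negative real).
#' @param n_groups Number of groups (e.g. cities).
#' @param n_weeks Number of consecutive weekly time points per group.
#' @param ar_coefficient AR(1) coefficient in `(-1, 1)` for the latent
#'   dynamics.
#' @return A temporal [embedding_table()] with `time_index` and `group_id`.
#' @export
generate_temporal <- function(spec, n_groups, n_weeks, ar_coefficient = 0.8) {
  validate_synthetic_spec(spec)
  if (abs(ar_coefficient) >= 1) {
    stop("'ar_coefficient' must lie strictly inside (-1, 1)", call. = FALSE)
  }
  withr::with_seed(spec$seed, {
    d_lat <- spec$dim_common + spec$dim_specific_a + spec$dim_specific_b
    mix_a <- orthonormal_mixing(spec$dim_common + spec$dim_specific_a,
                                spec$dim_modality_a)
    mix_b <- orthonormal_mixing(spec$dim_common + spec$dim_specific_b,
                                spec$dim_modality_b)
    wc <- unit_cols(matrix(stats::rnorm(spec$dim_common), ncol = 1L))
    wa <- unit_cols(matrix(stats::rnorm(spec$dim_specific_a), ncol = 1L))
    wb <- unit_cols(matrix(stats::rnorm(spec$dim_specific_b), ncol = 1L))
    phi <- ar_coefficient
    innov_sd <- sqrt(1 - phi^2)   # stationary unit-variance latents
    rows <- vector("list", n_groups)
    for (g in seq_len(n_groups)) {
      z <- matrix(0, n_weeks, d_lat)
      z[1L, ] <- stats::rnorm(d_lat)
      if (n_weeks > 1L) {
        eps <- matrix(stats::rnorm((n_weeks - 1L) * d_lat, sd = innov_sd),
                      n_weeks - 1L)
        for (t in 2:n_weeks) z[t, ] <- phi * z[t - 1L, ] + eps[t - 1L, ]
      }
      ic <- seq_len(spec$dim_common)
      ia <- spec$dim_common + seq_len(spec$dim_specific_a)
      ib <- spec$dim_common + spec$dim_specific_a + seq_len(spec$dim_specific_b)
      a <- cbind(z[, ic, drop = FALSE], z[, ia, drop = FALSE]) %*% mix_a
      b <- cbind(z[, ic, drop = FALSE], z[, ib, drop = FALSE]) %*% mix_b
      if (spec$noise_sd > 0) {
        a <- a + matrix(stats::rnorm(length(a), sd = spec$noise_sd), n_weeks)
        b <- b + matrix(stats::rnorm(length(b), sd = spec$noise_sd), n_weeks)
      }
      r <- spec$redundancy
      s <- r * (z[, ic, drop = FALSE] %*% wc) +
        (1 - r) * (z[, ia, drop = FALSE] %*% wa + z[, ib, drop = FALSE] %*% wb)
      y <- log1p(exp(pmin(1 + 2 * s, 30)))  # softplus link: target >= 0
      colnames(a) <- paste0("A__", seq_len(ncol(a)))
      colnames(b) <- paste0("B__", seq_len(ncol(b)))
      df <- data.frame(sample_id = sprintf("g%02d_w%04d", g, seq_len(n_weeks)))
      df <- cbind(df, as.data.frame(a), as.data.frame(b))
      df$label <- as.vector(y)
      df$time_index <- seq_len(n_weeks)
      df$group_id <- sprintf("g%02d", g)
      rows[[g]] <- df
    }
    out <- do.call(rbind, rows)
    embedding_table(out, blocks = list(A = paste0("A__", seq_len(spec$dim_modality_a)),
                                       B = paste0("B__", seq_len(spec$dim_modality_b))))
  })
}

#' Generate synthetic images driven by two latent factors
#'
#' Small grey-scale images built as a linear combination of two fixed
#' orthogonal spatial patterns weighted by standard-normal factors, plus
#' pixel noise. Used to exercise the VAE embedding extractor: a good latent
#' space must linearly recover the two generative factors.
#'
#' @param n Number of images.
#' @param size Image side length in pixels.
#' @param noise_sd Pixel noise standard deviation.
#' @param seed Integer seed.
#' @return List with `images` (an `n x size^2` matrix, rows are flattened
#'   images), `factors` (an `n x 2` matrix of generative factors) and `size`.
#' @export
generate_factor_images <- function(n, size = 16L, noise_sd = 0.05, seed = 1L) {
  withr::with_seed(seed, {
    g <- seq(-1, 1, length.out = size)
    p1 <- outer(rep(1, size), g)          # horizontal gradient
    p2 <- outer(g, rep(1, size))          # vertical gradient
    p1 <- p1 / sqrt(sum(p1^2))
    p2 <- p2 / sqrt(sum(p2^2))
    f <- matrix(stats::rnorm(2 * n), n)
    imgs <- f[, 1L] %o% as.vector(p1) + f[, 2L] %o% as.vector(p2)
    if (noise_sd > 0) {
      imgs <- imgs + matrix(stats::rnorm(length(imgs), sd = noise_sd), n)
    }
    list(images = imgs, factors = f, size = as.integer(size))
  })
}
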