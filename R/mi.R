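#' Variational approximator for the vCLUB mutual-information bound
#'
#' A two-hidden-layer network \eqn{q_\theta(b \mid a)} emitting the mean and
#' log-variance of a diagonal Gaussian over `b` given `a`. It is the
#' variational component of the contrastive log-ratio upper bound (vCLUB)
#' estimator of mutual information: trained by maximum likelihood on paired
#' samples, it turns the intractable MI into a tractable sample bound.
#' Log-variances are clamped smoothly to `[-8, 8]` so the likelihood cannot
#' blow up on degenerate batches.
#'
#' @param input_dim Width of the conditioning variable `a`.
#' @param output_dim Width of the predicted variable `b`.
#' @param hidden Hidden width; defaults to `4 * input_dim` (minimum 4).
#' @param seed Integer seed for parameter initialisation.
#' @return An object of class `mi_approximator`.
#' @export
mi_approximator <- function(input_dim, output_dim,
                            hidden = max(4L * input_dim, 4L), seed = 1L) {
  stopifnot(input_dim >= 1, output_dim >= 1, hidden >= 1)
  params <- withr::with_seed(seed, {
    p <- list()
    p[c("h1_W", "h1_b")] <- init_linear(input_dim, hidden)
    p[c("h2_W", "h2_b")] <- init_linear(hidden, hidden)
    p[c("mu_W", "mu_b")] <- init_linear(hidden, output_dim)
    p[c("lv_W", "lv_b")] <- init_linear(hidden, output_dim)
    p
  })
  structure(list(input_dim = as.integer(input_dim),
                 output_dim = as.integer(output_dim),
                 hidden = as.integer(hidden), seed = as.integer(seed),
                 params = params),
            class = "mi_approximator")
}

#' @export
print.mi_approximator <- function(x, ...) {
  cat(sprintf("<mi_approximator> q(b | a): %d -> %d (hidden %d)\n",
              x$input_dim, x$output_dim, x$hidden))
  invisible(x)
}

# Forward the approximator on the tape; returns list(mu, logvar) nodes.
# `pn` are parameter nodes (tracked leaves to train q, consts to freeze it).
q_forward_tape <- function(tape, pn, a_node) {
  h <- ad_dense(tape, a_node, pn, "h1", "relu")
  h <- ad_dense(tape, h, pn, "h2", "relu")
  mu <- ad_dense(tape, h, pn, "mu", "linear")
  lv <- ad_smul(tape, ad_tanh(tape, ad_smul(tape, ad_dense(tape, h, pn, "lv",
                                                           "linear"), 1 / 8)), 8)
  list(mu = mu, lv = lv)
}

# Plain-matrix forward (single code path: a throwaway tape with const params).
q_forward <- function(q, a) {
  tape <- ad_tape()
  pn <- lapply(q$params, function(p) ad_const(tape, p))
  out <- q_forward_tape(tape, pn, ad_const(tape, a))
  list(mu = out$mu$value, lv = out$lv$value)
}

check_mi_batch <- function(a, b, q = NULL) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) {
    stop(sprintf("paired batch rows differ: %d vs %d", nrow(a), nrow(b)),
         call. = FALSE)
  }
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("batch contains non-finite entries", call. = FALSE)
  }
  if (!is.null(q)) {
    if (ncol(a) != q$input_dim || ncol(b) != q$output_dim) {
      stop(sprintf("approximator dims (%d -> %d) do not match batch (%d -> %d)",
                   q$input_dim, q$output_dim, ncol(a), ncol(b)), call. = FALSE)
    }
  }
  list(a = a, b = b)
}

#' vCLUB upper bound on mutual information
#'
#' Computes the contrastive log-ratio upper bound
#' \deqn{\frac{1}{N^2}\sum_{i=1}^N \sum_{j=1}^N \left[\log q_\theta(b_i \mid a_i)
#'   - \log q_\theta(b_j \mid a_i)\right]}
#' over a paired batch: the positive term scores matched pairs, the negative
#' term averages the log-likelihood of every `b_j` under every `a_i`. The
#' double sum is evaluated exactly (vectorised, chunked over rows to bound
#' memory). With a well-trained approximator this is an upper bound on
#' \eqn{I(a; b)} in nats.
#'
#' @param a,b Paired numeric matrices with equal row counts.
#' @param q An [mi_approximator()] whose dimensions match `a` and `b`.
#' @return A single numeric value (nats).
#' @examples
#' q <- mi_approximator(1, 1, seed = 1)
#' a <- matrix(rnorm(50)); b <- matrix(rnorm(50))
#' club_upper_bound(a, b, q)
#' @export
club_upper_bound <- function(a, b, q) {
  ab <- check_mi_batch(a, b, q)
  a <- ab$a; b <- ab$b
  n <- nrow(a)
  fw <- q_forward(q, a)
  mu <- fw$mu; lv <- fw$lv
  iv <- exp(-lv)
  # positive term: matched pairs
  pos <- -0.5 * rowSums(log(2 * pi) + lv + (b - mu)^2 * iv)
  # negative term: all N^2 pairs, chunked over i
  row_const <- -0.5 * rowSums(log(2 * pi) + lv)
  b2 <- b^2
  total_neg <- 0
  chunk <- 512L
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(s + chunk - 1L, n)
    m <- iv[idx, , drop = FALSE] %*% t(b2) -
      2 * (mu[idx, , drop = FALSE] * iv[idx, , drop = FALSE]) %*% t(b) +
      matrix(rowSums(mu[idx, , drop = FALSE]^2 * iv[idx, , drop = FALSE]),
             length(idx), n)
    total_neg <- total_neg + sum(row_const[idx] * n) - 0.5 * sum(m)
  }
  mean(pos) - total_neg / n^2
}

#' Average conditional log-likelihood under the approximator
#'
#' The estimator-training objective \eqn{\frac{1}{N}\sum_i \log q_\theta(b_i
#' \mid a_i)}; maximised when fitting the approximator.
#'
#' @inheritParams club_upper_bound
#' @return A single numeric value.
#' @export
approximator_log_likelihood <- function(a, b, q) {
  ab <- check_mi_batch(a, b, q)
  a <- ab$a; b <- ab$b
  fw <- q_forward(q, a)
  mean(-0.5 * rowSums(log(2 * pi) + fw$lv + (b - fw$mu)^2 * exp(-fw$lv)))
}

#' Fit the variational approximator by maximum likelihood
#'
#' Full-batch Adam ascent on [approximator_log_likelihood()]. Deterministic
#' given the approximator's initialisation and the data.
#'
#' @inheritParams club_upper_bound
#' @param steps Number of Adam steps.
#' @param lr Learning rate.
#' @return The trained `mi_approximator` with a `log_likelihood` attribute
#'   (final objective value).
#' @export
fit_approximator <- function(q, a, b, steps = 500L, lr = 1e-2) {
  ab <- check_mi_batch(a, b, q)
  a <- ab$a; b <- ab$b
  st <- adam_init(q$params)
  for (it in seq_len(steps)) {
    tape <- ad_tape()
    pn <- ad_wrap_params(tape, q$params)
    loss <- ad_neg_loglik_node(tape, pn, ad_const(tape, a), ad_const(tape, b))
    ad_backward(tape, loss)
    upd <- adam_step(q$params, ad_collect_grads(pn), st, lr = lr)
    q$params <- upd$params
    st <- upd$state
  }
  attr(q, "log_likelihood") <- approximator_log_likelihood(a, b, q)
  q
}

# Negative mean log-likelihood as a tape node (q trainable, data fixed).
ad_neg_loglik_node <- function(tape, pn, a_node, b_node) {
  fw <- q_forward_tape(tape, pn, a_node)
  d <- ad_sub(tape, b_node, fw$mu)
  elem <- ad_add(tape, fw$lv,
                 ad_mul(tape, ad_square(tape, d),
                        ad_exp(tape, ad_smul(tape, fw$lv, -1))))
  ad_smul(tape, ad_mean(tape, ad_rowsums(tape, elem)), 0.5)  # + const dropped
}

# vCLUB term as a tape node with q frozen (params passed as consts); used as
# the disentanglement regulariser so gradients flow into the features only.
# Exact N^2 negative term for N <= exact_max; otherwise one seeded
# derangement (a permutation with no fixed point) per call.
ad_club_node <- function(tape, q, a_node, b_node, exact_max = 512L) {
  pn <- lapply(q$params, function(p) ad_const(tape, p))
  fw <- q_forward_tape(tape, pn, a_node)
  n <- nrow(a_node$value)
  iv <- ad_exp(tape, ad_smul(tape, fw$lv, -1))
  d <- ad_sub(tape, b_node, fw$mu)
  pos_elem <- ad_add(tape, fw$lv, ad_mul(tape, ad_square(tape, d), iv))
  pos <- ad_smul(tape, ad_mean(tape, ad_rowsums(tape, pos_elem)), -0.5)
  if (n <= exact_max) {
    b2 <- ad_square(tape, b_node)
    m <- ad_sub(tape,
                ad_add(tape,
                       ad_matmul(tape, iv, ad_transpose(tape, b2)),
                       ad_matmul(tape,
                                 ad_rowsums(tape, ad_mul(tape, ad_square(tape, fw$mu), iv)),
                                 ad_const(tape, matrix(1, 1L, n)))),
                ad_smul(tape, ad_matmul(tape, ad_mul(tape, fw$mu, iv),
                                        ad_transpose(tape, b_node)), 2))
    lv_row <- ad_matmul(tape, ad_rowsums(tape, fw$lv),
                        ad_const(tape, matrix(1, 1L, n)))
    neg <- ad_smul(tape, ad_mean(tape, ad_add(tape, lv_row, m)), -0.5)
  } else {
    perm <- derangement(n)
    bp <- ad_permute_rows(tape, b_node, perm)
    dneg <- ad_sub(tape, bp, fw$mu)
    neg_elem <- ad_add(tape, fw$lv, ad_mul(tape, ad_square(tape, dneg), iv))
    neg <- ad_smul(tape, ad_mean(tape, ad_rowsums(tape, neg_elem)), -0.5)
  }
  ad_sub(tape, pos, neg)
}

ad_permute_rows <- function(tape, x, perm) {
  inv <- order(perm)
  ad_node(tape, x$value[perm, , drop = FALSE], list(x), function(g) {
    list(g[inv, , drop = FALSE])
  })
}

derangement <- function(n) {
  if (n < 2L) return(seq_len(n))
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Combined mutual-information loss
#'
#' The disentanglement regulariser: the vCLUB bound between the concatenated
#' modality-specific features and the modality-common features, plus the
#' approximator's log-likelihood objective. During model training the two
#' terms are optimised alternately — the likelihood term updates the
#' approximator with the features held fixed, then the vCLUB term penalises
#' the fusion network with the approximator held fixed — so each side sees
#' only its own gradient.
#'
#' @param sa_sb Matrix of concatenated modality-specific features
#'   `cbind(s_a, s_b)`.
#' @param sc Matrix of modality-common features (same row count).
#' @param q An [mi_approximator()] mapping `sa_sb` to `sc`.
#' @return The scalar loss, with attributes `vclub` and `estimator` holding
#'   the two components.
#' @export
mi_loss <- function(sa_sb, sc, q) {
  vclub <- club_upper_bound(sa_sb, sc, q)
  est <- approximator_log_likelihood(sa_sb, sc, q)
  structure(vclub + est, vclub = vclub, estimator = est)
}

#' Closed-form Gaussian mutual information
#'
#' Exact mutual information, in nats, of a bivariate standard Gaussian with
#' correlation `rho`: \eqn{-\tfrac{1}{2}\ln(1-\rho^2)}. Used as an
#' independent oracle when checking the vCLUB estimator.
#'
#' @param rho Correlation in `(-1, 1)`.
#' @return Mutual information in nats.
#' @examples
#' gaussian_mi_oracle(0.9)
#' @export
gaussian_mi_oracle <- function(rho) {
  if (any(abs(rho) >= 1)) {
    stop("'rho' must lie strictly inside (-1, 1)", call. = FALSE)
  }
  -0.5 * log(1 - rho^2)
}

#' Estimate mutual information between two paired samples
#'
#' Convenience wrapper: builds an [mi_approximator()], fits it by maximum
#' likelihood, and returns the vCLUB bound on the same data.
#'
#' @inheritParams club_upper_bound
#' @param steps,lr Passed to [fit_approximator()].
#' @param seed Seed for the approximator initialisation.
#' @return Scalar vCLUB estimate (nats) with the trained approximator
#'   attached as attribute `approximator`.
#' @export
estimate_mi <- function(a, b, steps = 500L, lr = 1e-2, seed = 1L) {
  a <- as.matrix(a); b <- as.matrix(b)
  q <- mi_approximator(ncol(a), ncol(b), seed = seed)
  q <- fit_approximator(q, a, b, steps = steps, lr = lr)
  structure(club_upper_bound(a, b, q), approximator = q)
}
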