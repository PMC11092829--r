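# Internal reverse-mode computational-graph engine on base-R matrices.
#
# Every trained network in the package (the variational MI approximator, the
# fusion architecture, the temporal blocks, the VAE) is expressed as a tape of
# matrix operations built during the forward pass; backward() walks the tape in
# reverse and accumulates gradients into tracked leaves. Values are always
# plain numeric matrices; broadcasting is explicit (dedicated ops), never
# implicit.

ad_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 64L)
  e$n <- 0L
  e
}

ad_push <- function(tape, node) {
  n <- tape$n + 1L
  if (n > length(tape$nodes)) {
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  }
  tape$nodes[[n]] <- node
  tape$n <- n
  node
}

# value: numeric matrix; parents: list of nodes; backfn(grad) -> list of
# parent gradients (NULL entries allowed for untracked parents).
ad_node <- function(tape, value, parents = list(), backfn = NULL,
                    track = NULL) {
  if (is.null(track)) {
    track <- any(vapply(parents, function(p) p$track, logical(1)))
  }
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- if (track) backfn else NULL
  node$track <- track
  ad_push(tape, node)
}

ad_const <- function(tape, v) {
  ad_node(tape, as.matrix(v), track = FALSE)
}

ad_leaf <- function(tape, v) {
  ad_node(tape, as.matrix(v), track = TRUE)
}

ad_backward <- function(tape, loss) {
  stopifnot(length(loss$value) == 1L)
  loss$grad <- matrix(1, 1L, 1L)
  for (i in seq.int(tape$n, 1L)) {
    node <- tape$nodes[[i]]
    if (is.null(node$grad) || is.null(node$backfn)) next
    gs <- node$backfn(node$grad)
    ps <- node$parents
    for (k in seq_along(ps)) {
      p <- ps[[k]]
      if (!p$track || is.null(gs[[k]])) next
      p$grad <- if (is.null(p$grad)) gs[[k]] else p$grad + gs[[k]]
    }
    node$grad <- NULL  # free as we go
  }
  invisible(NULL)
}

ad_matmul <- function(tape, x, y) {
  ad_node(tape, x$value %*% y$value, list(x, y), function(g) {
    list(g %*% t(y$value), t(x$value) %*% g)
  })
}

ad_add <- function(tape, x, y) {
  ad_node(tape, x$value + y$value, list(x, y), function(g) list(g, g))
}

ad_sub <- function(tape, x, y) {
  ad_node(tape, x$value - y$value, list(x, y), function(g) list(g, -g))
}

# x: N x k, b: 1 x k row vector broadcast over rows
ad_add_bias <- function(tape, x, b) {
  n <- nrow(x$value)
  ad_node(tape, x$value + rep(as.vector(b$value), each = n), list(x, b),
          function(g) list(g, matrix(colSums(g), 1L)))
}

ad_mul <- function(tape, x, y) {
  ad_node(tape, x$value * y$value, list(x, y), function(g) {
    list(g * y$value, g * x$value)
  })
}

# x: N x k scaled row-wise by s: N x 1
ad_scale_rows <- function(tape, x, s) {
  sv <- as.vector(s$value)
  ad_node(tape, x$value * sv, list(x, s), function(g) {
    list(g * sv, matrix(rowSums(g * x$value), ncol = 1L))
  })
}

ad_smul <- function(tape, x, a) {
  ad_node(tape, x$value * a, list(x), function(g) list(g * a))
}

ad_relu <- function(tape, x) {
  v <- x$value
  v[v < 0] <- 0
  ad_node(tape, v, list(x), function(g) list(g * (x$value > 0)))
}

ad_tanh <- function(tape, x) {
  v <- tanh(x$value)
  ad_node(tape, v, list(x), function(g) list(g * (1 - v^2)))
}

ad_sigmoid <- function(tape, x) {
  v <- 1 / (1 + exp(-x$value))
  ad_node(tape, v, list(x), function(g) list(g * v * (1 - v)))
}

ad_softplus <- function(tape, x) {
  xv <- x$value
  v <- ifelse(xv > 30, xv, log1p(exp(pmin(xv, 30))))
  ad_node(tape, v, list(x), function(g) list(g / (1 + exp(-xv))))
}

ad_exp <- function(tape, x) {
  v <- exp(x$value)
  ad_node(tape, v, list(x), function(g) list(g * v))
}

ad_log <- function(tape, x) {
  ad_node(tape, log(x$value), list(x), function(g) list(g / x$value))
}

ad_square <- function(tape, x) {
  ad_node(tape, x$value^2, list(x), function(g) list(2 * g * x$value))
}

ad_pow_const <- function(tape, x, p) {
  ad_node(tape, x$value^p, list(x), function(g) {
    list(g * p * x$value^(p - 1))
  })
}

ad_sum <- function(tape, x) {
  dm <- dim(x$value)
  ad_node(tape, matrix(sum(x$value), 1L, 1L), list(x), function(g) {
    list(matrix(g[1L], dm[1L], dm[2L]))
  })
}

ad_mean <- function(tape, x) {
  dm <- dim(x$value)
  n <- length(x$value)
  ad_node(tape, matrix(mean(x$value), 1L, 1L), list(x), function(g) {
    list(matrix(g[1L] / n, dm[1L], dm[2L]))
  })
}

ad_rowsums <- function(tape, x) {
  k <- ncol(x$value)
  ad_node(tape, matrix(rowSums(x$value), ncol = 1L), list(x), function(g) {
    list(matrix(g, nrow(g), k))
  })
}

ad_concat_cols <- function(tape, xs) {
  widths <- vapply(xs, function(x) ncol(x$value), integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  ad_node(tape, do.call(cbind, lapply(xs, function(x) x$value)), xs,
          function(g) {
            lapply(seq_along(xs), function(k) g[, starts[k]:ends[k], drop = FALSE])
          })
}

ad_slice_cols <- function(tape, x, idx) {
  dm <- dim(x$value)
  ad_node(tape, x$value[, idx, drop = FALSE], list(x), function(g) {
    out <- matrix(0, dm[1L], dm[2L])
    out[, idx] <- g
    list(out)
  })
}

ad_softmax_rows <- function(tape, x) {
  v <- x$value - row_max(x$value)
  v <- exp(v)
  v <- v / rowSums(v)
  ad_node(tape, v, list(x), function(g) {
    list(v * (g - rowSums(g * v)))
  })
}

ad_diag <- function(tape, x) {
  n <- nrow(x$value)
  ad_node(tape, matrix(diag(x$value), ncol = 1L), list(x), function(g) {
    out <- matrix(0, n, n)
    diag(out) <- g
    list(out)
  })
}

ad_transpose <- function(tape, x) {
  ad_node(tape, t(x$value), list(x), function(g) list(t(g)))
}

# Gather columns of the flattened value by `idx`; idx == 0 reads a zero
# (used for padding). Backward scatter-adds duplicated reads.
ad_reindex <- function(tape, x, idx, out_nrow, out_ncol) {
  dm <- dim(x$value)
  sel <- idx > 0L
  fwd <- function(xv) {
    yv <- numeric(length(idx))
    yv[sel] <- xv[idx[sel]]
    matrix(yv, out_nrow, out_ncol)
  }
  ad_node(tape, fwd(as.vector(x$value)), list(x), function(g) {
    gv <- as.vector(g)
    dx <- numeric(dm[1L] * dm[2L])
    acc <- rowsum(gv[sel], group = idx[sel])
    dx[as.integer(rownames(acc))] <- acc[, 1L]
    list(matrix(dx, dm[1L], dm[2L]))
  })
}

# ---- Adam optimizer on a flat named list of matrices -----------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-2,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# Xavier/Glorot initialisation for a dense layer.
init_linear <- function(n_in, n_out) {
  s <- sqrt(2 / (n_in + n_out))
  list(W = matrix(stats::rnorm(n_in * n_out, sd = s), n_in, n_out),
       b = matrix(0, 1L, n_out))
}

# Forward a dense layer on the tape; params named <prefix>_W / <prefix>_b.
ad_dense <- function(tape, x, pn, prefix, act = c("linear", "relu", "tanh")) {
  act <- match.arg(act)
  h <- ad_add_bias(tape, ad_matmul(tape, x, pn[[paste0(prefix, "_W")]]),
                   pn[[paste0(prefix, "_b")]])
  switch(act, linear = h, relu = ad_relu(tape, h), tanh = ad_tanh(tape, h))
}

# Wrap a flat parameter list as tracked leaves on a fresh tape.
ad_wrap_params <- function(tape, params) {
  lapply(params, function(p) ad_leaf(tape, p))
}

ad_collect_grads <- function(pnodes) {
  lapply(pnodes, function(n) n$grad)
}

# per-row layer normalisation (no affine parameters)
ad_layernorm <- function(tape, x, eps = 1e-5) {
  xv <- x$value
  d <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowSums(xc^2) / d
  inv <- 1 / sqrt(v + eps)
  y <- xc * inv
  ad_node(tape, y, list(x), function(g) {
    gm <- rowMeans(g)
    gym <- rowMeans(g * y)
    list((g - gm - y * gym) * inv)
  })
}

# inverted dropout; mask drawn from the ambient RNG stream at call time
ad_dropout <- function(tape, x, rate) {
  if (rate <= 0) return(x)
  keep <- (matrix(stats::runif(length(x$value)), nrow(x$value)) >= rate) /
    (1 - rate)
  ad_node(tape, x$value * keep, list(x), function(g) list(g * keep))
}

row_max <- function(x) {
  x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]
}
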