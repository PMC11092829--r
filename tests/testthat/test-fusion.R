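test_that("the joint interaction is the row-wise outer product", {
  expect_equal(as.vector(kronecker_interaction(matrix(c(1, 2), 1),
                                               matrix(c(3, 4), 1))),
               c(3, 4, 6, 8))
  a <- matrix(0, 3, 4); b <- matrix(rnorm(6), 3)
  expect_true(all(kronecker_interaction(a, b) == 0))
  set.seed(12)
  a <- matrix(rnorm(20), 5); b <- matrix(rnorm(15), 5)
  k <- kronecker_interaction(a, b)
  expect_equal(sqrt(rowSums(k^2)),
               sqrt(rowSums(a^2)) * sqrt(rowSums(b^2)), tolerance = 1e-12)
})

test_that("self-attention over a single token is its value projection", {
  ns <- asNamespace("ddfusion")
  set.seed(5)
  tape <- ns$ad_tape()
  z <- ns$ad_const(tape, matrix(rnorm(12), 4))
  w <- matrix(rnorm(9), 3, 3)
  v <- ns$ad_matmul(tape, z, ns$ad_const(tape, w))
  out <- ns$ad_attention_core(tape, list(v), list(v), list(v), heads = 1L)
  expect_equal(out[[1L]]$value, z$value %*% w, tolerance = 1e-12)
})

test_that("attention weights normalise to one per query", {
  ns <- asNamespace("ddfusion")
  set.seed(6)
  tape <- ns$ad_tape()
  s <- ns$ad_softmax_rows(tape, ns$ad_const(tape, matrix(rnorm(40), 10)))
  expect_equal(rowSums(s$value), rep(1, 10), tolerance = 1e-6)
})

test_that("specific features mix nothing across samples", {
  set.seed(7)
  a <- matrix(rnorm(60), 10); b <- matrix(rnorm(80), 10)
  cfg <- quick_config()
  base <- specific_features(a, b, cfg)
  perm <- sample(10)
  permuted <- specific_features(a[perm, ], b[perm, ], cfg,
                                params = base$params)
  expect_equal(permuted$s_a, base$s_a[perm, ], tolerance = 1e-10)
  expect_equal(permuted$s_b, base$s_b[perm, ], tolerance = 1e-10)
})

test_that("common features have width d and reduce to joint self-attention", {
  set.seed(8)
  cfg <- quick_config()
  n <- 12
  joint <- matrix(rnorm(n * 10), n)
  s_a <- matrix(rnorm(n * 6), n); s_b <- matrix(rnorm(n * 4), n)
  out <- common_features(joint, s_a, s_b, cfg)
  expect_equal(dim(out$s_c), c(n, cfg$proj_dim))
  # zero the A- and B-derived key/value projections: Sc must ignore A and B
  p0 <- out$params
  for (nm in c("key_a_W", "key_b_W", "val_a_W", "val_b_W")) p0[[nm]] <- p0[[nm]] * 0
  z1 <- common_features(joint, s_a, s_b, cfg, params = p0)$s_c
  z2 <- common_features(joint, matrix(rnorm(n * 6), n),
                        matrix(rnorm(n * 4), n), cfg, params = p0)$s_c
  expect_equal(z1, z2, tolerance = 1e-12)
})

test_that("common features are symmetric under modality relabeling", {
  set.seed(9)
  cfg <- quick_config()
  n <- 9
  joint <- matrix(rnorm(n * 8), n)
  s_a <- matrix(rnorm(n * 5), n); s_b <- matrix(rnorm(n * 5), n)
  base <- common_features(joint, s_a, s_b, cfg)
  swapped_params <- base$params
  swap <- function(p, x, y) { tmp <- p[[x]]; p[[x]] <- p[[y]]; p[[y]] <- tmp; p }
  for (pair in list(c("key_a_W", "key_b_W"), c("val_a_W", "val_b_W"),
                    c("tok_a_W", "tok_b_W"), c("tok_a_b", "tok_b_b"))) {
    swapped_params <- swap(swapped_params, pair[1], pair[2])
  }
  swapped <- common_features(joint, s_b, s_a, cfg, params = swapped_params)
  expect_equal(swapped$s_c, base$s_c, tolerance = 1e-10)
})

test_that("the dense head concatenates to the declared width and normalises", {
  set.seed(10)
  cfg <- quick_config()
  n <- 7
  s <- function() matrix(rnorm(n * cfg$proj_dim), n)
  out <- dense_fusion_head(s(), s(), s(), cfg, n_out = 4)
  expect_equal(ncol(out$h_final), 2 * cfg$head_dim + cfg$proj_dim)
  expect_equal(rowSums(out$prediction), rep(1, n), tolerance = 1e-6)
})

test_that("zeroing the common features shifts trained predictions", {
  ns <- asNamespace("ddfusion")
  tab <- generate_classification(synthetic_spec(
    n_samples = 400, redundancy = 1, dim_common = 4, dim_specific_a = 2,
    dim_specific_b = 2, dim_modality_a = 8, dim_modality_b = 8, seed = 13))
  fit <- ddf(tab, "dense_fusion", quick_config(seed = 1))
  xa <- ns$apply_standardizer(fit$standardizer, block_matrix(tab, "A"), "a")
  xb <- ns$apply_standardizer(fit$standardizer, block_matrix(tab, "B"), "b")
  feats <- ns$fusion_values(fit$params, xa, xb, fit$config)
  head_with <- function(sc) {
    tape <- ns$ad_tape()
    pn <- lapply(fit$params, function(p) ns$ad_const(tape, p))
    out <- ns$fusion_head_forward(tape, pn, ns$ad_const(tape, feats$s_a),
                                  ns$ad_const(tape, feats$s_b),
                                  ns$ad_const(tape, sc))
    ns$softmax_rows(out$pred$value)
  }
  shift <- mean(abs(head_with(feats$s_c) - head_with(feats$s_c * 0)))
  expect_gt(shift, 0)
})

test_that("training is deterministic, logged, and early-stopping-consistent", {
  tab <- small_table(n = 400, seed = 2)
  cfg <- quick_config(seed = 3)
  f1 <- ddf(tab, "disentangled", cfg)
  f2 <- ddf(tab, "disentangled", cfg)
  expect_identical(f1$log, f2$log)
  expect_identical(f1$metrics$f1_macro, f2$metrics$f1_macro)
  expect_lte(nrow(f1$log), cfg$max_epochs)
  expect_equal(f1$best_epoch, f1$log$epoch[which.min(f1$log$val_loss)])
  # lambda = 0 removes the MI term from the loss entirely
  f0 <- ddf(tab, "dense_fusion", cfg)
  expect_true(all(is.na(f0$log$mi_term)))
  expect_false(any(is.na(f1$log$mi_term)))
})

test_that("the approximator trains only when the MI term is active", {
  tab <- small_table(n = 300, seed = 4)
  cfg <- quick_config(seed = 5, max_epochs = 8L)
  init_q <- mi_approximator(2L * cfg$proj_dim, cfg$proj_dim,
                            hidden = min(8L * cfg$proj_dim, 64L),
                            seed = cfg$seed)
  f_dense <- ddf(tab, "dense_fusion", cfg)
  f_dis <- ddf(tab, "disentangled", cfg)
  expect_identical(f_dense$approximator$params, init_q$params)
  expect_false(identical(f_dis$approximator$params, init_q$params))
})

test_that("single-class training labels are rejected", {
  tab <- small_table(n = 60, seed = 6)
  df <- as.data.frame(tab)
  df$label <- factor(rep("c1", nrow(df)), levels = "c1")
  one <- embedding_table(df, modality_blocks(tab))
  expect_error(ddf(one, "concat_mlp", quick_config()), "single class")
})

test_that("unknown baselines fail listing the choices", {
  tab <- small_table(n = 60, seed = 6)
  expect_error(ddf(tab, "boosted_trees", quick_config()), "concat_mlp")
})

test_that("per-modality logistic regression ignores the other block", {
  tab <- small_table(n = 300, seed = 7)
  fit <- ddf(tab, "logreg_a", quick_config(seed = 1))
  df <- as.data.frame(tab)
  cols_b <- modality_blocks(tab)$B
  df[cols_b] <- df[rev(cols_b)]  # scramble modality B
  scrambled <- embedding_table(df, modality_blocks(tab))
  expect_equal(predict(fit, scrambled), predict(fit, tab), tolerance = 1e-12)
})

test_that("early-fusion logistic regression separates separable data", {
  set.seed(20)
  n <- 120
  df <- data.frame(sample_id = paste0("s", 1:n))
  for (i in 1:3) df[[paste0("A__", i)]] <- rnorm(n)
  for (i in 1:2) df[[paste0("B__", i)]] <- rnorm(n)
  df$label <- factor(ifelse(df$A__1 + df$B__1 > 0, "pos", "neg"))
  tab <- embedding_table(df, list(A = paste0("A__", 1:3),
                                  B = paste0("B__", 1:2)))
  fit <- ddf(tab, "early_fusion_logreg", quick_config(seed = 2))
  pred <- predict(fit, tab, type = "class")
  expect_equal(mean(pred[fit$split$train] == tab$label[fit$split$train]), 1.0)
})

test_that("complementary modalities make fusion beat single-modality nets", {
  wins <- sapply(1:3, function(s) {
    tab <- generate_classification(synthetic_spec(
      n_samples = 1500, redundancy = 0, noise_sd = 0.5, dim_common = 4,
      dim_specific_a = 2, dim_specific_b = 2, dim_modality_a = 8,
      dim_modality_b = 8, seed = 60 + s))
    cfg <- quick_config(seed = s, max_epochs = 60L, patience = 15L)
    f1 <- function(m) ddf(tab, m, cfg)$metrics$f1_macro
    f1("concat_mlp") > max(f1("nn_a"), f1("nn_b"))
  })
  expect_true(all(wins))
})

test_that("predictions are probabilities over the declared classes", {
  tab <- small_table(n = 300, seed = 8)
  fit <- ddf(tab, "concat_mlp", quick_config(seed = 1))
  p <- predict(fit, tab)
  expect_equal(colnames(p), levels(tab$label))
  expect_equal(unname(rowSums(p)), rep(1, nrow(tab)), tolerance = 1e-6)
  cl <- predict(fit, tab, type = "class")
  expect_s3_class(cl, "factor")
  expect_equal(levels(cl), levels(tab$label))
})
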