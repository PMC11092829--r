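test_that("generation is a pure function of the spec", {
  s <- synthetic_spec(n_samples = 100, seed = 7)
  t1 <- generate_classification(s)
  t2 <- generate_classification(s)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- generate_temporal(synthetic_spec(seed = 7), 3, 30, 0.5)
  t4 <- generate_temporal(synthetic_spec(seed = 7), 3, 30, 0.5)
  expect_identical(as.data.frame(t3), as.data.frame(t4))
})

test_that("invalid specs fail naming the violated field", {
  expect_error(synthetic_spec(redundancy = 1.2), "redundancy")
  expect_error(synthetic_spec(noise_sd = -1), "noise_sd")
  expect_error(synthetic_spec(dim_modality_a = 5, dim_common = 8),
               "dim_modality_a")
  expect_error(synthetic_spec(n_classes = 1), "n_classes")
  expect_error(generate_temporal(synthetic_spec(), 2, 20, 1.0),
               "ar_coefficient")
})

probe_accuracy <- function(x, y, train, test) {
  df <- data.frame(x)
  df$.y <- y
  fit <- nnet::multinom(.y ~ ., df[train, ], trace = FALSE, MaxNWts = 1e5)
  mean(stats::predict(fit, df[test, ]) == y[test])
}

test_that("full redundancy makes one modality as informative as both", {
  tab <- generate_classification(synthetic_spec(
    n_samples = 1500, redundancy = 1, noise_sd = 0, seed = 5))
  a <- block_matrix(tab, "A"); b <- block_matrix(tab, "B")
  tr <- 1:1000; te <- 1001:1500
  acc_a <- probe_accuracy(a, tab$label, tr, te)
  acc_ab <- probe_accuracy(cbind(a, b), tab$label, tr, te)
  expect_lt(abs(acc_a - acc_ab), 0.05)
})

test_that("zero redundancy makes the modalities complementary", {
  tab <- generate_classification(synthetic_spec(
    n_samples = 2000, redundancy = 0, noise_sd = 0, seed = 9))
  a <- block_matrix(tab, "A"); b <- block_matrix(tab, "B")
  tr <- seq_len(2000)
  acc_a <- probe_accuracy(a, tab$label, tr, tr)
  acc_b <- probe_accuracy(b, tab$label, tr, tr)
  acc_ab <- probe_accuracy(cbind(a, b), tab$label, tr, tr)
  expect_gt(acc_ab, acc_a)
  expect_gt(acc_ab, acc_b)
})

test_that("class imbalance knob skews the label distribution", {
  bal <- generate_classification(synthetic_spec(n_samples = 3000, seed = 3,
                                                class_weights_skew = 0))
  skw <- generate_classification(synthetic_spec(n_samples = 3000, seed = 3,
                                                class_weights_skew = 10))
  expect_gt(max(prop.table(table(skw$label))),
            max(prop.table(table(bal$label))) + 0.1)
})

test_that("temporal tables have the declared shape and non-negative targets", {
  tab <- generate_temporal(synthetic_spec(seed = 2), 10, 260, 0.8)
  expect_equal(nrow(tab), 2600)
  expect_true(all(tab$label >= 0))
  expect_false(anyDuplicated(paste(tab$group_id, tab$time_index)) > 0)
})

test_that("ar_coefficient = 0 gives white-noise weekly targets", {
  tab <- generate_temporal(synthetic_spec(seed = 4, noise_sd = 0), 5, 260, 0)
  rho <- vapply(split(tab$label, tab$group_id), function(y) {
    stats::cor(y[-1], y[-length(y)])
  }, numeric(1))
  expect_true(all(abs(rho) < 3 / sqrt(260)))
})

test_that("CSV round trip preserves the table", {
  tab <- small_table(n = 5, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding_table(tab, path)
  back <- read_embedding_table(path)
  expect_equal(modality_blocks(back), modality_blocks(tab))
  for (bn in names(modality_blocks(tab))) {
    expect_equal(block_matrix(back, bn), block_matrix(tab, bn),
                 tolerance = 1e-12)
  }
  expect_equal(as.character(back$label), as.character(tab$label))
})

test_that("CSV column layout follows the block-prefix dialect", {
  df <- data.frame(sample_id = paste0("s", 1:4))
  for (i in 1:8) df[[paste0("img__", i)]] <- rnorm(4)
  for (i in 1:3) df[[paste0("meta__", i)]] <- rnorm(4)
  df$label <- factor(c("x", "y", "x", "y"))
  tab <- embedding_table(df, blocks = list(img = paste0("img__", 1:8),
                                           meta = paste0("meta__", 1:3)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_embedding_table(tab, path)
  header <- strsplit(readLines(path, n = 1L), ",")[[1L]]
  expect_length(header, 1 + 11 + 1)
  expect_equal(header[1], "sample_id")
  expect_equal(header[13], "label")
})

test_that("malformed CSVs fail with located diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,A__1,B__1", "s1,0.5,0.2"), path)
  expect_error(read_embedding_table(path), "label")
  writeLines(c("sample_id,A__1,B__1,label", "s1,oops,0.2,x", "s2,1,0.3,y"),
             path)
  expect_error(read_embedding_table(path), "A__1")
})

test_that("inter-modal redundancy raises estimated cross-modal MI", {
  mis <- sapply(1:3, function(s) {
    sapply(c(0, 0.5, 1), function(r) {
      tab <- generate_classification(synthetic_spec(
        n_samples = 5000, redundancy = r, seed = 50 + s,
        dim_common = 4, dim_specific_a = 2, dim_specific_b = 2,
        dim_modality_a = 8, dim_modality_b = 8))
      oh <- ddfusion:::onehot(tab$label, levels(tab$label))
      proj <- function(x) stats::lm.fit(cbind(1, x), oh)$fitted.values
      pa <- proj(block_matrix(tab, "A"))
      pb <- proj(block_matrix(tab, "B"))
      as.numeric(estimate_mi(pa, pb, steps = 300, seed = s))
    })
  })
  # columns: seeds; rows: redundancy 0, 0.5, 1 (small estimator slack)
  for (s in 1:3) {
    expect_gt(mis[2, s], mis[1, s] - 0.02)
    expect_gt(mis[3, s], mis[2, s] - 0.02)
  }
  expect_gt(mean(mis[3, ]), mean(mis[1, ]))
})
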