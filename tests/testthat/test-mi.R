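# zero out an approximator's parameters so it emits mu = 0, logvar = 0
zeroed_q <- function(input_dim = 1, output_dim = 1) {
  q <- mi_approximator(input_dim, output_dim, seed = 1)
  q$params <- lapply(q$params, function(p) p * 0)
  q
}

test_that("degenerate batches give a zero bound", {
  q <- mi_approximator(1, 1, seed = 1)
  expect_equal(club_upper_bound(matrix(0.3), matrix(-1.2), q), 0)
  a <- matrix(rnorm(100))
  b <- matrix(1, 100, 1)
  expect_equal(club_upper_bound(a, b, q), 0, tolerance = 1e-12)
})

test_that("average log-likelihood matches the Gaussian closed form", {
  q <- zeroed_q()
  a <- matrix(rnorm(10))
  b <- matrix(0, 10, 1)
  expect_equal(approximator_log_likelihood(a, b, q), -0.5 * log(2 * pi),
               tolerance = 1e-12)
  # duplicating rows leaves the mean unchanged
  q2 <- mi_approximator(2, 2, seed = 3)
  a <- matrix(rnorm(12), 6); b <- matrix(rnorm(12), 6)
  expect_equal(approximator_log_likelihood(rbind(a, a), rbind(b, b), q2),
               approximator_log_likelihood(a, b, q2), tolerance = 1e-12)
})

test_that("likelihood of a perfect prediction rises as variance shrinks", {
  lls <- sapply(c(0, -1, -2, -4), function(lv) {
    q <- zeroed_q()
    q$params$lv_b <- matrix(8 * atanh(lv / 8), 1)  # bounded head inversion
    approximator_log_likelihood(matrix(rnorm(5)), matrix(0, 5, 1), q)
  })
  expect_true(all(diff(lls) > 0))
})

test_that("vectorised bound equals the literal double loop", {
  for (ns in list(c(3, 1, 1), c(16, 2, 3), c(64, 4, 2))) {
    set.seed(sum(ns))
    q <- mi_approximator(ns[2], ns[3], seed = 1)
    a <- matrix(rnorm(ns[1] * ns[2]), ns[1])
    b <- matrix(rnorm(ns[1] * ns[3]), ns[1])
    expect_equal(club_upper_bound(a, b, q), club_reference(a, b, q),
                 tolerance = 1e-10)
  }
})

test_that("independent variables estimate to zero MI", {
  ests <- sapply(1:5, function(s) {
    set.seed(200 + s)
    as.numeric(estimate_mi(matrix(rnorm(2000)), matrix(rnorm(2000)),
                           steps = 400, seed = s))
  })
  expect_lt(abs(mean(ests)), 0.05)
})

test_that("the Gaussian oracle matches its closed form", {
  expect_equal(gaussian_mi_oracle(0), 0)
  expect_equal(gaussian_mi_oracle(0.9), -0.5 * log(0.19), tolerance = 1e-12)
  expect_equal(gaussian_mi_oracle(0.9), 0.8304, tolerance = 1e-4)
  expect_equal(gaussian_mi_oracle(0.7), gaussian_mi_oracle(-0.7))
  expect_error(gaussian_mi_oracle(1), "rho")
})

test_that("mi_loss decomposes into its vCLUB and estimator terms", {
  set.seed(8)
  sa_sb <- matrix(rnorm(40), 20)
  sc <- matrix(1, 20, 1)  # constant across rows -> vCLUB term 0
  q <- mi_approximator(2, 1, seed = 2)
  l <- mi_loss(sa_sb, sc, q)
  expect_equal(attr(l, "vclub"), 0, tolerance = 1e-12)
  expect_equal(as.numeric(l), attr(l, "vclub") + attr(l, "estimator"))
})

test_that("the alternating contract blocks gradients across the two sides", {
  ns <- asNamespace("ddfusion")
  set.seed(4)
  a <- matrix(rnorm(30), 15); b <- matrix(rnorm(30), 15)
  q <- mi_approximator(2, 2, seed = 1)
  # vCLUB term: features tracked, q frozen as constants
  tape <- ns$ad_tape()
  an <- ns$ad_leaf(tape, a); bn <- ns$ad_leaf(tape, b)
  club <- ns$ad_club_node(tape, q, an, bn)
  ns$ad_backward(tape, club)
  expect_false(is.null(an$grad))
  expect_false(is.null(bn$grad))
  # estimator term: q tracked, features frozen as constants
  tape2 <- ns$ad_tape()
  qpn <- ns$ad_wrap_params(tape2, q$params)
  ac <- ns$ad_const(tape2, a); bc <- ns$ad_const(tape2, b)
  ll <- ns$ad_neg_loglik_node(tape2, qpn, ac, bc)
  ns$ad_backward(tape2, ll)
  expect_false(is.null(qpn$mu_W$grad))
  expect_null(ac$grad)
  expect_null(bc$grad)
})

test_that("minimising the MI loss shrinks the bound on copied features", {
  ns <- asNamespace("ddfusion")
  for (s in 1:3) {
    set.seed(300 + s)
    n <- 128
    sa <- matrix(rnorm(n * 3), n)
    sc0 <- cbind(sa[, 1], rnorm(n) * 0.1)  # Sc starts as a copy of Sa coord 1
    q <- mi_approximator(3, 2, seed = s)
    q <- fit_approximator(q, sa, sc0, steps = 200)
    club0 <- club_upper_bound(sa, sc0, q)
    sc <- sc0
    st <- ns$adam_init(list(sc_W = sc))
    qst <- ns$adam_init(q$params)
    for (it in 1:200) {
      qt <- ns$ad_tape()
      qpn <- ns$ad_wrap_params(qt, q$params)
      ql <- ns$ad_neg_loglik_node(qt, qpn, ns$ad_const(qt, sa),
                                  ns$ad_const(qt, sc))
      ns$ad_backward(qt, ql)
      upd <- ns$adam_step(q$params, ns$ad_collect_grads(qpn), qst, lr = 1e-2)
      q$params <- upd$params; qst <- upd$state
      tape <- ns$ad_tape()
      scn <- ns$ad_leaf(tape, sc)
      club <- ns$ad_club_node(tape, q, ns$ad_const(tape, sa), scn)
      ns$ad_backward(tape, club)
      upd2 <- ns$adam_step(list(sc_W = sc), list(sc_W = scn$grad), st,
                           lr = 2e-2)
      sc <- upd2$params$sc_W; st <- upd2$state
    }
    q <- fit_approximator(q, sa, sc, steps = 200)
    expect_lt(club_upper_bound(sa, sc, q), 0.5 * club0)
  }
})

test_that("the bound stays finite for large-magnitude inputs", {
  q <- mi_approximator(2, 2, seed = 6)
  a <- matrix(runif(40, -1e3, 1e3), 20)
  b <- matrix(runif(40, -1e3, 1e3), 20)
  expect_true(is.finite(club_upper_bound(a, b, q)))
  expect_true(is.finite(approximator_log_likelihood(a, b, q)))
})

test_that("dimension mismatches raise shape errors", {
  q <- mi_approximator(2, 2, seed = 1)
  expect_error(club_upper_bound(matrix(rnorm(10), 5), matrix(rnorm(8), 4), q),
               "rows")
  expect_error(club_upper_bound(matrix(rnorm(15), 5), matrix(rnorm(10), 5), q),
               "dims")
})
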