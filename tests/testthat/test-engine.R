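random_instance <- function(Tlen, n, mask_prob = 0) {
  node <- matrix(stats::rnorm(Tlen * n), Tlen, n)
  trans <- matrix(stats::rnorm((n + 1L) * n), n + 1L, n)
  if (mask_prob > 0) {
    forbid <- matrix(stats::runif((n + 1L) * n) < mask_prob, n + 1L, n)
    # keep the lattice feasible: self-transitions stay open and the
    # start state keeps at least one successor
    forbid[cbind(seq_len(n), seq_len(n))] <- FALSE
    if (all(forbid[n + 1L, ])) forbid[n + 1L, 1L] <- FALSE
    trans[forbid] <- -Inf
  }
  list(node = node, trans = trans)
}

test_that("single-position uniform lattice normalizes to the state count", {
  node <- matrix(0, 1L, 2L)
  trans <- matrix(0, 3L, 2L)
  lat <- forward_backward(node, trans)
  expect_equal(exp(lat$log_z), 2)
  expect_equal(lat$node_marginals[1L, ], c(0.5, 0.5))
})

test_that("forward-backward matches exhaustive enumeration", {
  set.seed(41)
  for (i in 1:40) {
    Tlen <- sample(1:4, 1L); n <- sample(1:4, 1L)
    inst <- random_instance(Tlen, n, mask_prob = if (i %% 2) 0 else 0.3)
    lat <- forward_backward(inst$node, inst$trans)
    oracle <- enum_lattice(inst$node, inst$trans)
    expect_equal(lat$log_z, oracle$log_z, tolerance = 1e-10)
    expect_equal(lat$node_marginals, oracle$node_marginals,
                 tolerance = 1e-8)
    # position marginals sum to one
    expect_equal(rowSums(lat$node_marginals), rep(1, Tlen),
                 tolerance = 1e-8)
    # alpha- and beta-side partition functions agree
    lz_beta <- picrf:::log_sum_exp(inst$trans[n + 1L, ] +
                                     inst$node[1L, ] + lat$log_beta[1L, ])
    expect_equal(lz_beta, lat$log_z, tolerance = 1e-8)
  }
})

test_that("transition marginals are consistent with node marginals", {
  set.seed(42)
  inst <- random_instance(3L, 3L)
  lat <- forward_backward(inst$node, inst$trans)
  for (t in 2:3) {
    summed <- colSums(lat$trans_marginals[t - 1L, , ])
    expect_equal(summed, lat$node_marginals[t, ], tolerance = 1e-8)
  }
})

test_that("mask-violating paths carry exactly zero probability", {
  set.seed(43)
  inst <- random_instance(3L, 3L, mask_prob = 0.4)
  oracle <- enum_lattice(inst$node, inst$trans)
  lat <- forward_backward(inst$node, inst$trans)
  feasible <- is.finite(oracle$scores)
  m <- max(oracle$scores[feasible])
  lz <- m + log(sum(exp(oracle$scores[feasible] - m)))
  expect_equal(lat$log_z, lz, tolerance = 1e-10)
})

test_that("viterbi attains the exhaustive maximum and respects the mask", {
  set.seed(44)
  for (i in 1:100) {
    Tlen <- sample(1:4, 1L); n <- sample(2:4, 1L)
    inst <- random_instance(Tlen, n, mask_prob = if (i %% 2) 0 else 0.3)
    path <- viterbi(inst$node, inst$trans)
    oracle <- enum_lattice(inst$node, inst$trans)
    expect_equal(path_score(path, inst$node, inst$trans),
                 oracle$max_score, tolerance = 1e-10)
    # no masked transition on the decoded path
    expect_true(is.finite(path_score(path, inst$node, inst$trans)))
  }
})

test_that("viterbi breaks exact ties toward the lower state index", {
  node <- matrix(0, 3L, 2L)
  trans <- matrix(0, 3L, 2L)
  expect_equal(viterbi(node, trans), c(1L, 1L, 1L))
})

test_that("log-likelihood penalty follows the l2 definition", {
  setup <- toy_model_setup()
  idx <- setup$index
  K <- idx$n_params
  # zero weights: no penalty, no penalty gradient
  r0_pen <- crf_loglik(rep(0, K), setup$corpus, idx, sigma = 1)
  r0_free <- crf_loglik(rep(0, K), setup$corpus, idx, sigma = Inf)
  expect_equal(r0_pen$value, r0_free$value)
  expect_equal(r0_pen$gradient, r0_free$gradient)
  # unit weights at sigma = 1: penalty is exactly K / 2
  w1 <- rep(1, K)
  r1_pen <- crf_loglik(w1, setup$corpus, idx, sigma = 1)
  r1_free <- crf_loglik(w1, setup$corpus, idx, sigma = Inf)
  expect_equal(r1_free$value - r1_pen$value, K / 2)
})

test_that("analytic gradient matches central finite differences", {
  for (share in c(TRUE, FALSE)) {
    setup <- toy_model_setup(share = share)
    idx <- setup$index
    set.seed(45)
    for (theta in list(rep(0, idx$n_params),
                       stats::rnorm(idx$n_params, sd = 0.5))) {
      res <- crf_loglik(theta, setup$corpus, idx, sigma = 2)
      h <- 1e-5
      pick <- sample.int(idx$n_params, min(25L, idx$n_params))
      for (k in pick) {
        ep <- em <- theta
        ep[k] <- ep[k] + h; em[k] <- em[k] - h
        fd <- (crf_loglik(ep, setup$corpus, idx, sigma = 2)$value -
               crf_loglik(em, setup$corpus, idx, sigma = 2)$value) / (2 * h)
        expect_lt(abs(res$gradient[k] - fd) / max(1, abs(fd)), 1e-4)
      }
    }
  }
})

test_that("likelihood of the compiled core agrees with the R lattice", {
  setup <- toy_model_setup()
  idx <- setup$index
  set.seed(46)
  w <- stats::rnorm(idx$n_params, sd = 0.5)
  tw <- picrf:::transition_scores(idx, w)
  enc <- picrf:::encode_corpus(setup$corpus, idx)
  ll_r <- 0
  for (i in seq_along(setup$corpus)) {
    node <- picrf:::node_scores(enc$obs[[i]], idx, w)
    lat <- forward_backward(node, tw)
    ll_r <- ll_r + path_score(enc$gold[[i]], node, tw) - lat$log_z
  }
  expect_equal(crf_loglik(w, setup$corpus, idx, sigma = Inf)$value, ll_r,
               tolerance = 1e-10)
})

test_that("training solves a separable problem and behaves monotonically", {
  corp <- toy_separable_corpus()
  sch <- schAB_iob()
  space <- picrf:::space_from_scheme(sch)
  idx <- build_feature_index(corp, feature_setting(1L), space, TRUE)
  fit <- crf_train(corp, idx, sigma = 10, max_iter = 200L)
  # perfect recovery of the training labels
  tw <- picrf:::transition_scores(idx, fit$weights)
  enc <- picrf:::encode_corpus(corp, idx)
  for (i in seq_along(corp)) {
    node <- picrf:::node_scores(enc$obs[[i]], idx, fit$weights)
    expect_equal(viterbi(node, tw), enc$gold[[i]])
  }
  # ascent: converged objective is at least the objective at zero
  expect_gte(fit$value, fit$evaluations[1L])
  # the per-iteration log is non-decreasing
  expect_true(all(diff(fit$objective_log) >= 0))
  # stronger regularization shrinks the weights
  fit_small <- crf_train(corp, idx, sigma = 0.3, max_iter = 200L)
  expect_lte(sqrt(sum(fit_small$weights^2)),
             sqrt(sum(fit$weights^2)))
})

test_that("training is deterministic", {
  corp <- toy_separable_corpus(2L)
  sch <- schAB_iob()
  idx <- build_feature_index(corp, feature_setting(1L),
                             picrf:::space_from_scheme(sch), TRUE)
  f1 <- crf_train(corp, idx, sigma = 5, max_iter = 50L)
  f2 <- crf_train(corp, idx, sigma = 5, max_iter = 50L)
  expect_identical(f1$evaluations, f2$evaluations)
  expect_identical(f1$weights, f2$weights)
})

test_that("state counts follow the states-plus-start convention", {
  s3 <- sch3()
  first <- picrf:::space_from_scheme(s3)
  induced <- picrf:::space_from_induced(build_induced_scheme(s3))
  second <- expand_second_order(first)
  expect_equal(state_count(first), 8L)
  expect_equal(state_count(induced), 11L)
  expect_equal(state_count(second), 64L)
  expect_equal(state_count(picrf:::space_from_scheme(label_scheme(character()))), 2L)
  # complexity ordering
  expect_lt(state_count(first), state_count(induced))
  expect_lt(state_count(induced), state_count(second))
})

test_that("second-order expansion projects to well-formed label sequences", {
  sch <- schAB_iob()
  corp <- toy_separable_corpus()
  m <- crf_fit(corp, variant = "second", sigma = 10, max_iter = 100L)
  pred <- predict(m, corp)
  for (i in seq_along(pred)) {
    expect_length(pred[[i]]$labels, length(corp[[i]]$tokens))
    expect_true(picrf:::is_iob2_consistent(pred[[i]]$labels, sch))
  }
})

test_that("a second-order chain with weights ignoring y[t-2] reproduces first-order marginals", {
  sch <- schAB()
  sp1 <- picrf:::space_from_scheme(sch)
  sp2 <- expand_second_order(sp1)
  n1 <- length(sp1$symbols); n2 <- length(sp2$symbols)
  set.seed(47)
  Tlen <- 4L
  node1 <- matrix(stats::rnorm(Tlen * n1), Tlen, n1)
  trans1 <- matrix(stats::rnorm((n1 + 1L) * n1), n1 + 1L, n1)
  # tie pair-state scores to their second / current components
  node2 <- node1[, sp2$pair_cur, drop = FALSE]
  trans2 <- matrix(-Inf, n2 + 1L, n2)
  for (j in seq_len(n2)) {
    for (i in seq_len(n2)) {
      if (sp2$mask[i, j])
        trans2[i, j] <- trans1[sp2$pair_cur[i], sp2$pair_cur[j]]
    }
    if (sp2$mask[n2 + 1L, j])
      trans2[n2 + 1L, j] <- trans1[n1 + 1L, sp2$pair_cur[j]]
  }
  lat1 <- forward_backward(node1, trans1)
  lat2 <- forward_backward(node2, trans2)
  expect_equal(lat2$log_z, lat1$log_z, tolerance = 1e-6)
  proj <- sapply(seq_len(n1), function(b)
    rowSums(lat2$node_marginals[, sp2$pair_cur == b, drop = FALSE]))
  expect_equal(proj, lat1$node_marginals, tolerance = 1e-6)
})
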