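test_that("windowed token features read the stated offsets", {
  obs <- extract_observations(c("She", "was", "sedated"),
                              feature_setting(1L))
  expect_setequal(obs[[2]],
    c("w[-1]=She", "w[0]=was", "w[1]=sedated",
      "nw[-1]=she", "nw[0]=was", "nw[1]=sedated"))
  # boundary symbols outside the sentence
  expect_true("w[-1]=<S>" %in% obs[[1]])
  expect_true("w[1]=</S>" %in% obs[[3]])
})

test_that("capitalization, affix and n-gram features follow their definitions", {
  expect_equal(picrf:::cap_shape(c("BUN", "Seoul", "b6", "was", "mg/dL")),
               c("ALLCAPS", "INITCAP", "HASDIGIT", "LOWER", "MIXED"))

  obs <- extract_observations("doctor",
    list(feature_template("affix", len_min = 2L, len_max = 3L)))
  expect_setequal(obs[[1]],
    c("pre=do", "pre=doc", "suf=or", "suf=tor"))

  ng <- extract_observations("do", list(feature_template("ngram", n = 2L)))
  expect_setequal(ng[[1]], c("ng2=^d", "ng2=do", "ng2=o$"))

  # norm-token lowercases and masks digits
  expect_equal(picrf:::norm_token("DDI-9/26"), "ddi-0/00")
})

test_that("feature extraction is pure and label-independent", {
  tpl <- feature_setting(2L)
  a <- extract_observations(c("fever", "and", "WBC"), tpl)
  b <- extract_observations(
    labeled_sequence(c("fever", "and", "WBC"),
                     c("B-problem", "O", "B-test")), tpl)
  expect_identical(a, b)
})

test_that("outside sharing allocates one slot where unshared allocates three", {
  # the same token under all three outside symbols
  sch <- schAB()
  isch <- build_induced_scheme(sch)
  space <- picrf:::space_from_induced(isch)
  tpl <- list(feature_template("token"))
  corp <- list(
    labeled_sequence("doctor", "O[O]+"),
    labeled_sequence(c("a1", "doctor"), c("A", "A[O]+")),
    labeled_sequence(c("b1", "doctor"), c("B", "B[O]+")))
  shared <- build_feature_index(corp, tpl, space, share_outside = TRUE)
  unshared <- build_feature_index(corp, tpl, space, share_outside = FALSE)
  slot_count <- function(idx, sym) {
    sid <- match(sym, idx$vocab)
    sum(idx$obs_slot[, sid] > 0L)
  }
  expect_equal(slot_count(shared, "w[0]=doctor"), 1L)
  expect_equal(slot_count(unshared, "w[0]=doctor"), 3L)
  # an observation seen only under an entity state: one slot either way
  expect_equal(slot_count(shared, "w[0]=a1"), 1L)
  expect_equal(slot_count(unshared, "w[0]=a1"), 1L)
})

test_that("with sharing on, outside states score identically everywhere", {
  setup <- toy_model_setup(share = TRUE)
  idx <- setup$index
  set.seed(31)
  w <- stats::rnorm(idx$n_params)
  outside <- setup$ischeme$outside_symbols
  for (s in setup$corpus) {
    obs <- extract_observations(s, idx$templates)
    for (t in seq_along(obs)) {
      scores <- vapply(outside, function(st)
        score_observations(idx, w, obs[[t]], st), 0)
      expect_equal(max(scores) - min(scores), 0)
    }
  }
})

test_that("score_observations equals the brute-force indicator sum", {
  setup <- toy_model_setup(share = TRUE)
  idx <- setup$index
  set.seed(32)
  w <- stats::rnorm(idx$n_params)
  s <- setup$corpus[[1]]
  obs <- extract_observations(s, idx$templates)
  for (st in idx$space$symbols) {
    tg <- idx$target_of_state[match(st, idx$space$symbols)]
    for (t in seq_along(obs)) {
      # brute force: sum over all (target, symbol) slots whose indicator fires
      total <- 0
      for (sym in obs[[t]]) {
        sid <- match(sym, idx$vocab)
        if (is.na(sid)) next
        k <- idx$obs_slot[tg, sid]
        if (k > 0L) total <- total + w[k]
      }
      expect_equal(score_observations(idx, w, obs[[t]], st), total)
    }
  }
  # all-zero weights score zero for every state
  expect_equal(score_observations(idx, rep(0, idx$n_params),
                                  obs[[1]], "A"), 0)
})

test_that("pi and plain first-order indices have equal observation counts", {
  set.seed(33)
  corpus <- synth_corpus(synth_config(sentences = 30L), seed = 5L)
  sch <- sch3()
  tpl <- feature_setting(1L)
  plain <- build_feature_index(corpus, tpl,
                               picrf:::space_from_scheme(sch), TRUE)
  isch <- build_induced_scheme(sch)
  icorp <- lapply(corpus, function(s) {
    s$labels <- induce_labels(s$labels, sch)
    s
  })
  induced <- build_feature_index(icorp, tpl,
                                 picrf:::space_from_induced(isch), TRUE)
  expect_equal(induced$n_obs, plain$n_obs)
})
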