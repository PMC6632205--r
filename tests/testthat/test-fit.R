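test_that("pi model state set is entities plus induced outside symbols", {
  corp <- synth_corpus(synth_config(sentences = 20L), seed = 3L)
  m <- crf_fit(corp, variant = "pi", sigma = 10, max_iter = 50L)
  isch <- build_induced_scheme(m$scheme)
  expect_identical(m$space$symbols, isch$all_symbols)
  expect_equal(state_count(m$space),
               state_count(picrf:::space_from_scheme(m$scheme)) +
                 length(m$scheme$classes))
})

test_that("pi and first-order models have equal observation parameter counts", {
  corp <- synth_corpus(synth_config(sentences = 25L), seed = 4L)
  mp <- crf_fit(corp, variant = "pi", sigma = 10, max_iter = 5L)
  mf <- crf_fit(corp, variant = "first", sigma = 10, max_iter = 5L)
  expect_equal(mp$index$n_obs, mf$index$n_obs)
})

test_that("unshared induced binding allocates strictly more observation slots", {
  corp <- synth_corpus(synth_config(sentences = 25L), seed = 4L)
  mi <- crf_fit(corp, variant = "first_induced", sigma = 10, max_iter = 5L)
  mf <- crf_fit(corp, variant = "first", sigma = 10, max_iter = 5L)
  expect_gt(mi$index$n_obs, mf$index$n_obs)
})

test_that("the pi model reproduces the worked-example mini-corpus", {
  corp <- table3_corpus()
  m <- crf_fit(corp, variant = "pi", scheme = sch3(), sigma = 100,
               max_iter = 300L)
  pred <- predict(m, corp)
  for (i in seq_along(corp))
    expect_identical(pred[[i]]$labels, corp[[i]]$labels)
})

test_that("predictions live in the original label space and are deterministic", {
  cfg <- synth_config(sentences = 25L)
  corp <- synth_corpus(cfg, seed = 6L)
  test <- synth_corpus(cfg, sentences = 10L, seed = 7L)
  for (v in c("first", "pi", "first_induced")) {
    m <- crf_fit(corp, variant = v, sigma = 10, max_iter = 60L)
    p1 <- predict(m, test)
    expect_false(any(grepl("\\[O\\]\\+", unlist(lapply(p1, `[[`, "labels")))))
    for (i in seq_along(test)) {
      expect_length(p1[[i]]$labels, length(test[[i]]$tokens))
      expect_true(picrf:::is_iob2_consistent(p1[[i]]$labels, m$scheme))
    }
    expect_identical(predict(m, test), p1)
  }
})

test_that("the pi model recovers precursor-dependent classes that defeat the first-order model", {
  # fully ambiguous entity surfaces with a deterministic class cycle:
  # only the precursor identifies the class
  cfg <- synth_config(sentences = 120L, ambiguity_rate = 1,
                      type_transition = matrix(c(0, 1, 0,
                                                 0, 0, 1,
                                                 1, 0, 0), 3L, 3L,
                                               byrow = TRUE),
                      initial = c(1, 0, 0))
  train <- synth_corpus(cfg, seed = 8L)
  test <- synth_corpus(cfg, sentences = 60L, seed = 9L)
  mp <- crf_fit(train, variant = "pi", sigma = 10, max_iter = 150L)
  mf <- crf_fit(train, variant = "first", sigma = 10, max_iter = 150L)
  f1_pi <- ner_score(test, predict(mp, test))["micro", "f1"]
  f1_first <- ner_score(test, predict(mf, test))["micro", "f1"]
  expect_gt(f1_pi, f1_first + 5)
})

test_that("pi-CRF beats the first-order model on default synthetic corpora", {
  res <- compare_variants(seeds = 1:3,
                          config = synth_config(sentences = 120L),
                          variants = c("pi", "first"),
                          max_iter = 150L, test_sentences = 80L)
  med <- tapply(res$f1, res$variant, stats::median)
  expect_gt(med[["pi"]], med[["first"]])
})

test_that("model archives round-trip", {
  corp <- synth_corpus(synth_config(sentences = 15L), seed = 10L)
  m <- crf_fit(corp, variant = "pi", sigma = 10, max_iter = 30L)
  path <- tempfile(fileext = ".rds")
  write_crf_model(m, path)
  m2 <- read_crf_model(path)
  expect_identical(m2$weights, m$weights)
  expect_identical(predict(m2, corp), predict(m, corp))
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(read_crf_model(other), "archive")
})

test_that("summary and coef expose the fitted structure", {
  corp <- synth_corpus(synth_config(sentences = 15L), seed = 11L)
  m <- crf_fit(corp, variant = "pi", sigma = 10, max_iter = 30L)
  s <- summary(m)
  expect_equal(s$state_count, 11L)
  expect_equal(s$n_params, m$index$n_params)
  cf <- coef(m)
  expect_length(cf, m$index$n_params)
  expect_true(any(grepl(" -> ", names(cf))))
  expect_true(any(grepl(" \\| ", names(cf))))
  expect_equal(as.numeric(logLik(m)), m$fit$value)
})
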