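# Shared fixtures and independent oracles for the test suite.

sch3 <- function() label_scheme(c("problem", "test", "treatment"))
schAB <- function() label_scheme(c("A", "B"), tagging = "bare")
schAB_iob <- function() label_scheme(c("A", "B"))

# the four printed worked-example sentences (inline bracket annotation)
table3_sentences <- function() c(
  single = "The patient is a 28-year-old woman who is [HIV positive]_problem_ for 2 years .",
  d0 = "With [intravenous hydration]_treatment_ [the BUN]_test_ and ...",
  d1 = "... because of [pancytopenia]_problem_ and [vomiting]_problem_ on [DDI]_treatment_",
  d8 = "She was brought in for [an esophagogastroduodenoscopy]_test_ on 9/26 but she basically was not sufficiently [sedated]_treatment_ and readmitted at this time for [a GI work-up]_test_ .")

table3_corpus <- function() {
  lapply(unname(table3_sentences()), parse_bracketed, scheme = sch3())
}

# random IOB2-consistent label sequence (independent of package code)
rand_iob2_labels <- function(len, classes, p_entity = 0.4, p_cont = 0.5) {
  labs <- character(len)
  prev_cls <- NA_character_
  for (t in seq_len(len)) {
    if (!is.na(prev_cls) && stats::runif(1) < p_cont) {
      labs[t] <- paste0("I-", prev_cls)
    } else if (stats::runif(1) < p_entity) {
      prev_cls <- sample(classes, 1L)
      labs[t] <- paste0("B-", prev_cls)
    } else {
      labs[t] <- "O"
      prev_cls <- NA_character_
    }
  }
  labs
}

# brute-force span scanner: an independent reading of the IOB2 definition
span_scan_oracle <- function(labels) {
  out <- list()
  t <- 1L
  while (t <= length(labels)) {
    if (startsWith(labels[t], "B-")) {
      cls <- substring(labels[t], 3L)
      e <- t
      while (e < length(labels) &&
             identical(labels[e + 1L], paste0("I-", cls))) e <- e + 1L
      out[[length(out) + 1L]] <- data.frame(class = cls, start = t - 1L,
                                            end = e)
      t <- e + 1L
    } else t <- t + 1L
  }
  if (!length(out))
    return(data.frame(class = character(), start = integer(),
                      end = integer()))
  do.call(rbind, out)
}

# exhaustive-path lattice oracle: enumerate all N^T paths
enum_lattice <- function(node, trans) {
  Tlen <- nrow(node); n <- ncol(node)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), Tlen)))
  scores <- apply(paths, 1L, function(p) {
    s <- trans[n + 1L, p[1L]] + node[1L, p[1L]]
    if (Tlen > 1L)
      for (t in 2:Tlen) s <- s + trans[p[t - 1L], p[t]] + node[t, p[t]]
    s
  })
  m <- max(scores)
  log_z <- m + log(sum(exp(scores - m)))
  probs <- exp(scores - log_z)
  node_marg <- matrix(0, Tlen, n)
  for (t in seq_len(Tlen))
    for (j in seq_len(n))
      node_marg[t, j] <- sum(probs[paths[, t] == j])
  list(log_z = log_z, node_marginals = node_marg, scores = scores,
       paths = paths, max_score = m)
}

# score of one concrete path under (node, trans)
path_score <- function(path, node, trans) {
  n <- ncol(node)
  s <- trans[n + 1L, path[1L]] + node[1L, path[1L]]
  if (length(path) > 1L)
    for (t in 2:length(path))
      s <- s + trans[path[t - 1L], path[t]] + node[t, path[t]]
  s
}

# small separable toy corpus: each label has a dedicated surface token
toy_separable_corpus <- function(n_rep = 3L) {
  sch <- schAB_iob()
  sents <- list(
    list(tokens = c("aa", "xx", "bb"), labels = c("B-A", "O", "B-B")),
    list(tokens = c("bb", "yy", "aa", "aa2"),
         labels = c("B-B", "O", "B-A", "I-A")),
    list(tokens = c("xx", "yy"), labels = c("O", "O")))
  corp <- rep(sents, n_rep)
  lapply(corp, function(s) labeled_sequence(s$tokens, s$labels))
}

# tiny corpus + index for gradient and likelihood tests
toy_model_setup <- function(share = TRUE, seed = 42L) {
  set.seed(seed)
  sch <- schAB()
  isch <- build_induced_scheme(sch)
  corp <- list(
    labeled_sequence(c("a1", "w", "b1"), c("A", "O", "B")),
    labeled_sequence(c("w", "w"), c("O", "O")),
    labeled_sequence(c("b1", "a1"), c("B", "A")),
    labeled_sequence(c("a1", "w", "w", "a2"), c("A", "O", "O", "A")),
    labeled_sequence(c("w", "b1", "w"), c("O", "B", "O")))
  icorp <- lapply(corp, function(s) {
    s$labels <- induce_labels(s$labels, sch)
    s
  })
  space <- picrf:::space_from_induced(isch)
  idx <- build_feature_index(icorp, feature_setting(1L), space,
                             share_outside = share)
  list(scheme = sch, ischeme = isch, corpus = icorp, index = idx)
}
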