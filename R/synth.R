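#' Configuration of the synthetic clinical-corpus generator
#'
#' The generator emulates the structural statistics of clinical NER
#' corpora: sentences contain several entities separated by runs of
#' non-entity tokens, the class of an entity depends on the class of its
#' precursor, and a controllable fraction of entity tokens is drawn from
#' an ambiguous vocabulary shared between classes — for those entities
#' only the precursor disambiguates the class.
#'
#' Defaults: three clinical classes; a truncated Poisson
#' (`lambda = 2.5`, support 1..8) number of entities per sentence, giving
#' a precursor ratio near 0.63; geometric gaps with `gap_p = 0.18`
#' (median 3, mean 4.6 non-entity tokens between consecutive entities);
#' entity lengths 1-3 tokens; a strongly skewed class-transition table;
#' and 60% ambiguous entity tokens.
#'
#' @param classes entity class names.
#' @param sentences number of sentences to generate.
#' @param lambda mean of the (un-truncated) Poisson entity count;
#'   truncated to 1..`max_entities`.
#' @param max_entities truncation point of the entity count.
#' @param entity_len_probs probabilities of entity lengths 1, 2, 3.
#' @param gap_p geometric parameter of the inter-entity gap (support 0,
#'   1, 2, ...; mean `(1 - gap_p) / gap_p`).
#' @param context_p geometric parameter of the leading/trailing
#'   non-entity runs of a sentence.
#' @param type_transition row-stochastic matrix `P(next class |
#'   precursor class)`; default: 0.7 on a cyclic successor, 0.15
#'   elsewhere.
#' @param initial initial class distribution (first entity of a
#'   sentence); default uniform.
#' @param vocab_class,vocab_background,vocab_ambiguous vocabulary sizes
#'   (per class / background / shared-ambiguous).  Background tokens are
#'   drawn with Zipf-like (1/rank) frequencies, as in natural text, so
#'   many background types are rare.
#' @param ambiguity_rate fraction of entity tokens drawn from the
#'   ambiguous list.
#' @param leak_rate fraction of non-entity tokens drawn from the
#'   ambiguous vocabulary instead of the background list, mimicking the
#'   generic usage of polysemous clinical words outside entity spans;
#'   0 by default, so entity and non-entity vocabularies are disjoint
#'   and class membership is the only ambiguity.
#' @param seed RNG seed; the same seed yields a byte-identical corpus.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(classes = c("problem", "test", "treatment"),
                         sentences = 200L, lambda = 2.5,
                         max_entities = 8L,
                         entity_len_probs = c(0.5, 0.3, 0.2),
                         gap_p = 0.18, context_p = 0.35,
                         type_transition = NULL, initial = NULL,
                         vocab_class = 40L, vocab_background = 800L,
                         vocab_ambiguous = 20L, ambiguity_rate = 0.6,
                         leak_rate = 0, seed = 1L) {
  k <- length(classes)
  stopifnot(k >= 1L, sentences >= 1L, lambda > 0, max_entities >= 1L,
            gap_p > 0, gap_p < 1, context_p > 0, context_p <= 1,
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            leak_rate >= 0, leak_rate <= 1)
  entity_len_probs <- entity_len_probs / sum(entity_len_probs)
  if (is.null(type_transition)) {
    # skewed cyclic-successor table: 0.7 on the successor class,
    # the remaining 0.3 spread evenly (k = 1: degenerate identity)
    type_transition <- matrix(if (k > 1) 0.3 / (k - 1) else 1, k, k)
    if (k > 1)
      for (i in seq_len(k)) type_transition[i, (i %% k) + 1L] <- 0.7
    dimnames(type_transition) <- list(classes, classes)
  }
  type_transition <- as.matrix(type_transition)
  if (!all(dim(type_transition) == k) ||
      any(abs(rowSums(type_transition) - 1) > 1e-8))
    stop("type_transition must be a row-stochastic k x k matrix")
  dimnames(type_transition) <- list(classes, classes)
  if (is.null(initial)) initial <- rep(1 / k, k)
  initial <- initial / sum(initial)
  if (ambiguity_rate > 0 && vocab_ambiguous < 1L)
    stop("ambiguous vocabulary must be non-empty when ambiguity_rate > 0")
  structure(list(classes = classes, sentences = as.integer(sentences),
                 lambda = lambda, max_entities = as.integer(max_entities),
                 entity_len_probs = entity_len_probs, gap_p = gap_p,
                 context_p = context_p, type_transition = type_transition,
                 initial = initial, vocab_class = as.integer(vocab_class),
                 vocab_background = as.integer(vocab_background),
                 vocab_ambiguous = as.integer(vocab_ambiguous),
                 ambiguity_rate = ambiguity_rate, leak_rate = leak_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_vocab <- function(config) {
  cls <- lapply(seq_along(config$classes), function(i)
    sprintf("%s_w%03d", substr(config$classes[i], 1L, 4L),
            seq_len(config$vocab_class)))
  names(cls) <- config$classes
  list(class = cls,
       background = sprintf("ctx%04d", seq_len(config$vocab_background)),
       ambiguous = sprintf("amb%03d", seq_len(config$vocab_ambiguous)))
}

rgeom_plus <- function(n, p) stats::rgeom(n, p)

#' Generate a synthetic IOB2 clinical corpus
#'
#' Per sentence: the entity count is drawn from the truncated Poisson;
#' the first class from the initial distribution and each subsequent
#' class from the transition table conditioned on its precursor; gaps
#' between entities (and leading/trailing context) are geometric runs of
#' background tokens; entity tokens are drawn from the ambiguous
#' vocabulary with probability `ambiguity_rate`, otherwise from the
#' class vocabulary.  IOB2 labels are emitted.  Deterministic given the
#' config's seed.
#'
#' @param config a [synth_config()].
#' @param sentences optional override of `config$sentences`.
#' @param seed optional override of `config$seed`.
#' @return a list of [labeled_sequence()] objects.
#' @export
synth_corpus <- function(config = synth_config(), sentences = NULL,
                         seed = NULL) {
  stopifnot(inherits(config, "synth_config"))
  n_sent <- sentences %||% config$sentences
  seed <- seed %||% config$seed
  vocab <- synth_vocab(config)
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                    envir = globalenv()))
  set.seed(seed)
  k <- length(config$classes)
  out <- vector("list", n_sent)
  for (si in seq_len(n_sent)) {
    n_ent <- 0L
    while (n_ent < 1L || n_ent > config$max_entities)
      n_ent <- stats::rpois(1L, config$lambda)
    cls_idx <- integer(n_ent)
    cls_idx[1L] <- sample.int(k, 1L, prob = config$initial)
    if (n_ent > 1L)
      for (e in 2:n_ent)
        cls_idx[e] <- sample.int(k, 1L,
                                 prob = config$type_transition[cls_idx[e - 1L], ])
    tokens <- character(); labels <- character()
    zipf_w <- 1 / seq_len(config$vocab_background)
    emit_bg <- function(n) {
      if (n > 0L) {
        leak <- stats::runif(n) < config$leak_rate
        tk <- character(n)
        if (any(!leak))
          tk[!leak] <- sample(vocab$background, sum(!leak),
                              replace = TRUE, prob = zipf_w)
        if (any(leak))
          tk[leak] <- sample(vocab$ambiguous, sum(leak), replace = TRUE)
        tokens <<- c(tokens, tk)
        labels <<- c(labels, rep("O", n))
      }
    }
    emit_bg(rgeom_plus(1L, config$context_p))
    for (e in seq_len(n_ent)) {
      if (e > 1L) emit_bg(rgeom_plus(1L, config$gap_p))
      len <- sample.int(3L, 1L, prob = config$entity_len_probs)
      cl <- config$classes[cls_idx[e]]
      amb <- stats::runif(len) < config$ambiguity_rate
      surf <- character(len)
      if (any(amb))
        surf[amb] <- sample(vocab$ambiguous, sum(amb), replace = TRUE)
      if (any(!amb))
        surf[!amb] <- sample(vocab$class[[cl]], sum(!amb), replace = TRUE)
      tokens <- c(tokens, surf)
      labels <- c(labels, c(paste0("B-", cl),
                            rep(paste0("I-", cl), len - 1L)))
    }
    emit_bg(rgeom_plus(1L, config$context_p))
    out[[si]] <- labeled_sequence(tokens, labels)
  }
  out
}

#' Check a corpus against its generator configuration
#'
#' Compares the empirical distance profile and class-transition
#' frequencies of a corpus with the distributions its [synth_config()]
#' prescribes: median gap within 1 of the geometric median, mean gap
#' within 15%, precursor ratio within `ratio_range`, and L1 distance of
#' the empirical transition table from the configured one below
#' `transition_l1` (per row, averaged).
#'
#' @param corpus a corpus, typically from [synth_corpus()].
#' @param config the generating [synth_config()].
#' @param ratio_range acceptable precursor-ratio interval.
#' @param transition_l1 maximal mean per-row L1 deviation.
#' @return a list with the empirical `profile`, the individual check
#'   results and an overall `ok` flag.
#' @export
profile_check <- function(corpus, config, ratio_range = c(0.6, 0.9),
                          transition_l1 = 0.1) {
  prof <- distance_profile(corpus)
  p <- config$gap_p
  med_theory <- stats::qgeom(0.5, p)
  mean_theory <- (1 - p) / p
  checks <- list(
    median_gap = is.finite(prof$median_gap) &&
      abs(prof$median_gap - med_theory) <= 1,
    mean_gap = is.finite(prof$mean_gap) &&
      abs(prof$mean_gap - mean_theory) <= 0.15 * mean_theory,
    precursor_ratio = !is.na(prof$precursor_ratio) &&
      prof$precursor_ratio >= ratio_range[1L] &&
      prof$precursor_ratio <= ratio_range[2L],
    transition = TRUE)
  if (!is.null(prof$transition)) {
    common <- intersect(rownames(prof$transition), config$classes)
    dev <- vapply(common, function(cl) {
      emp <- rep(0, length(config$classes))
      names(emp) <- config$classes
      emp[colnames(prof$transition)] <- prof$transition[cl, ]
      sum(abs(emp - config$type_transition[cl, ]))
    }, 0)
    checks$transition <- mean(dev) <= transition_l1
    checks$transition_l1 <- mean(dev)
  }
  c(list(profile = prof), checks,
    list(ok = isTRUE(checks$median_gap) && isTRUE(checks$mean_gap) &&
           isTRUE(checks$precursor_ratio) && isTRUE(checks$transition)))
}
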