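#' Entity-level precision, recall and F1
#'
#' Exact-match scoring: a predicted entity counts as correct only when
#' its class, start and end all equal a gold entity's.  Scores are on
#' the 0-100 scale; micro scores pool the per-class counts.  With
#' `distanced_only = TRUE` the evaluation is restricted to sentences
#' whose gold annotation contains two or more entities (both gold and
#' predictions of other sentences are dropped).
#'
#' @param gold list of gold [labeled_sequence()] objects.
#' @param pred list of predicted sequences, aligned with `gold`.
#' @param distanced_only restrict to multi-entity sentences?
#' @return an object of class `ner_eval`: a data frame with one row per
#'   class plus a `"micro"` row, columns `gold`, `expected` (number
#'   predicted), `correct`, `precision`, `recall`, `f1`; the subset tag
#'   is attached as attribute `subset`.
#' @export
ner_score <- function(gold, pred, distanced_only = FALSE) {
  if (length(gold) != length(pred))
    stop("gold and predicted corpora differ in sentence count")
  glens <- vapply(gold, function(s) length(s$tokens), 0L)
  plens <- vapply(pred, function(s) length(s$tokens), 0L)
  if (!all(glens == plens))
    stop("gold and predicted sentence lengths differ")
  gspans <- lapply(gold, labels_to_spans)
  if (distanced_only) {
    keep <- vapply(gspans, nrow, 0L) >= 2L
    gold <- gold[keep]; pred <- pred[keep]; gspans <- gspans[keep]
  }
  pspans <- lapply(pred, labels_to_spans)
  classes <- sort(unique(c(unlist(lapply(gspans, `[[`, "class")),
                           unlist(lapply(pspans, `[[`, "class")))))
  count <- matrix(0L, length(classes) + 1L, 3L,
                  dimnames = list(c(classes, "micro"),
                                  c("gold", "expected", "correct")))
  for (i in seq_along(gold)) {
    g <- gspans[[i]]; p <- pspans[[i]]
    gk <- paste(g$class, g$start, g$end)
    pk <- paste(p$class, p$start, p$end)
    hit <- pk %in% gk
    for (cl in classes) {
      count[cl, "gold"] <- count[cl, "gold"] + sum(g$class == cl)
      count[cl, "expected"] <- count[cl, "expected"] + sum(p$class == cl)
      count[cl, "correct"] <- count[cl, "correct"] +
        sum(hit & p$class == cl)
    }
  }
  count["micro", ] <- colSums(count[seq_along(classes), , drop = FALSE])
  prf <- function(g, e, c) {
    p <- if (e > 0) 100 * c / e else 0
    r <- if (g > 0) 100 * c / g else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  scores <- t(apply(count, 1L, function(x) prf(x[1L], x[2L], x[3L])))
  out <- data.frame(count, precision = scores[, 1L],
                    recall = scores[, 2L], f1 = scores[, 3L])
  attr(out, "subset") <- if (distanced_only) "distanced" else "whole"
  class(out) <- c("ner_eval", "data.frame")
  out
}

#' @export
print.ner_eval <- function(x, digits = 2L, ...) {
  cat(sprintf("Entity-level evaluation (%s instances)\n",
              attr(x, "subset")))
  y <- as.data.frame(x)
  y$precision <- round(y$precision, digits)
  y$recall <- round(y$recall, digits)
  y$f1 <- round(y$f1, digits)
  print(y, ...)
  invisible(x)
}

#' Inter-entity gap distances within a sentence
#'
#' For every pair of consecutive gold entity spans, the gap is the
#' number of tokens strictly between them (all labeled `"O"`, since
#' spans cannot overlap).  The first entity of a sentence has no
#' precursor and is recorded as a `"single"` row with `NA` gap.
#'
#' @param x a [labeled_sequence()] or a character label vector.
#' @param scheme optional [label_scheme()] passed to
#'   [labels_to_spans()].
#' @return a data frame with columns `precursor` (class name or
#'   `"single"`), `class` and `gap` (`NA` for the precursor-less first
#'   entity).
#' @export
gap_distances <- function(x, scheme = NULL) {
  spans <- labels_to_spans(x, scheme)
  n <- nrow(spans)
  if (!n)
    return(data.frame(precursor = character(), class = character(),
                      gap = integer(), stringsAsFactors = FALSE))
  data.frame(
    precursor = c("single", spans$class[-n]),
    class = spans$class,
    gap = c(NA_integer_, spans$start[-1L] - spans$end[-n]),
    stringsAsFactors = FALSE)
}

#' Corpus-level inter-entity distance profile
#'
#' Aggregates [gap_distances()] over a corpus: the histogram of gaps
#' between consecutive entities, the number of precursor-less
#' (`"single"`) entities, median and mean gap, the precursor ratio
#' (entities having a precursor / total entities) and the empirical
#' class-transition table `P(class | precursor class)`.
#'
#' @param corpus list of [labeled_sequence()] objects.
#' @return an object of class `distance_profile`.
#' @export
distance_profile <- function(corpus) {
  gd <- do.call(rbind, lapply(corpus, gap_distances))
  if (is.null(gd)) gd <- gap_distances(character())
  gaps <- gd$gap[!is.na(gd$gap)]
  n_total <- nrow(gd)
  n_single <- sum(gd$precursor == "single")
  trans <- NULL
  linked <- gd[gd$precursor != "single", , drop = FALSE]
  if (nrow(linked))
    trans <- prop.table(table(precursor = linked$precursor,
                              class = linked$class), margin = 1L)
  structure(list(
    gap_counts = if (length(gaps)) table(gap = gaps) else table(integer()),
    n_single = n_single,
    n_entities = n_total,
    median_gap = if (length(gaps)) stats::median(gaps) else NA_real_,
    mean_gap = if (length(gaps)) mean(gaps) else NA_real_,
    precursor_ratio = if (n_total) (n_total - n_single) / n_total else NA_real_,
    transition = trans),
    class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("Inter-entity distance profile\n")
  cat(sprintf("  entities: %d (%d without precursor); precursor ratio %.3f\n",
              x$n_entities, x$n_single, x$precursor_ratio))
  cat(sprintf("  gap: median %s, mean %s\n",
              format(x$median_gap), format(round(x$mean_gap, 2))))
  if (length(x$gap_counts)) {
    cat("  gap histogram:\n")
    print(x$gap_counts)
  }
  invisible(x)
}

#' Cumulative recall by precursor distance
#'
#' Starting from the entities without a precursor (distance -1), the
#' recall is recomputed as entities are added in order of their gap from
#' the immediately preceding entity: the point at distance `d` is the
#' recall over the union of precursor-less entities and entities whose
#' gap is at most `d`.  The final point equals whole-corpus recall.
#'
#' @param gold,pred aligned corpora as in [ner_score()].
#' @return a data frame with columns `distance` (-1, 0, 1, ..., max
#'   gap), `n` (entities included) and `recall` (0-1 scale).
#' @export
recall_by_distance <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("gold and predicted corpora differ in sentence count")
  rows <- lapply(seq_along(gold), function(i) {
    g <- labels_to_spans(gold[[i]])
    if (!nrow(g)) return(NULL)
    p <- labels_to_spans(pred[[i]])
    pk <- paste(p$class, p$start, p$end)
    gd <- gap_distances(gold[[i]])
    data.frame(gap = ifelse(is.na(gd$gap), -1L, gd$gap),
               correct = paste(g$class, g$start, g$end) %in% pk)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab))
    return(data.frame(distance = integer(), n = integer(),
                      recall = numeric()))
  dmax <- max(tab$gap)
  dists <- seq.int(-1L, dmax)
  n <- vapply(dists, function(d) sum(tab$gap <= d), 0L)
  rec <- vapply(dists, function(d) {
    sub <- tab[tab$gap <= d, , drop = FALSE]
    if (nrow(sub)) mean(sub$correct) else NA_real_
  }, 0)
  data.frame(distance = dists, n = n, recall = rec)
}
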