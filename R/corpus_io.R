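#' Construct a labeled token sequence
#'
#' The basic unit of a corpus: one sentence's tokens, their labels, and
#' optional auxiliary columns (POS tags, chunk tags, ...).
#'
#' @param tokens character vector of token surfaces; non-empty strings
#'   without whitespace.
#' @param labels character vector of label symbols, same length as
#'   `tokens`.
#' @param extras `NULL`, or a character matrix with one row per token
#'   holding auxiliary columns.
#' @return an object of class `labeled_sequence`.
#' @export
labeled_sequence <- function(tokens, labels, extras = NULL) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) != length(labels))
    stop("tokens and labels must have the same length")
  if (any(!nzchar(tokens)) || any(grepl("\\s", tokens)))
    stop("tokens must be non-empty and contain no whitespace")
  if (!is.null(extras)) {
    extras <- as.matrix(extras)
    storage.mode(extras) <- "character"
    if (nrow(extras) != length(tokens))
      stop("extras must have one row per token")
  }
  structure(list(tokens = tokens, labels = labels, extras = extras),
            class = "labeled_sequence")
}

#' @export
print.labeled_sequence <- function(x, ...) {
  cat(sprintf("<labeled_sequence: %d tokens>\n", length(x$tokens)))
  print(data.frame(token = x$tokens, label = x$labels,
                   stringsAsFactors = FALSE), ...)
  invisible(x)
}

#' @export
length.labeled_sequence <- function(x) length(x$tokens)

#' Read a CoNLL-style token-per-line corpus
#'
#' One token per line, columns separated by runs of spaces or tabs, the
#' last column being the label and intermediate columns auxiliary
#' (POS/chunk) information.  Sentences are separated by blank lines;
#' `-DOCSTART-` lines are skipped.  Label sequences are validated against
#' `scheme` and, for IOB2 schemes, repaired (`I-X` without a legal
#' predecessor becomes `B-X`) with a warning.
#'
#' @param x a file path, or a character vector of lines, or a single
#'   string containing newlines.
#' @param scheme a [label_scheme()].
#' @param repair repair IOB2 violations instead of failing?
#' @return a list of [labeled_sequence()] objects.
#' @seealso [write_conll()]
#' @export
read_conll <- function(x, scheme, repair = TRUE) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, encoding = "UTF-8", warn = FALSE)
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE), use.names = FALSE)
  }
  doc <- grepl("^-DOCSTART-", lines)
  lines[doc] <- ""
  blank <- grepl("^[ \t]*$", lines)
  grp <- cumsum(blank)
  out <- list()
  for (g in split(which(!blank), grp[!blank])) {
    fields <- strsplit(trimws(lines[g]), "[ \t]+")
    ncols <- lengths(fields)
    if (any(ncols < 2L))
      stop(sprintf("line %d: expected at least 2 columns, found %d",
                   g[which(ncols < 2L)[1L]], min(ncols)))
    tokens <- vapply(fields, `[[`, "", 1L)
    labels <- vapply(fields, function(f) f[[length(f)]], "")
    validate_labels(labels, scheme)
    if (scheme$tagging == "iob2") {
      if (repair) labels <- repair_iob2(labels, scheme)
      else if (!is_iob2_consistent(labels, scheme))
        stop("IOB2-inconsistent label sequence (set repair = TRUE to fix)")
    }
    extras <- NULL
    if (max(ncols) > 2L) {
      k <- max(ncols) - 2L
      extras <- t(vapply(fields, function(f) {
        e <- f[-c(1L, length(f))]
        c(e, rep("", k - length(e)))
      }, character(k)))
    }
    out[[length(out) + 1L]] <- labeled_sequence(tokens, labels, extras)
  }
  out
}

#' Write a corpus in CoNLL token-per-line format
#'
#' @param corpus a list of [labeled_sequence()] objects.
#' @param path output file path, or `NULL` to return the text.
#' @return the corpus text, invisibly when written to a file.
#' @export
write_conll <- function(corpus, path = NULL) {
  chunks <- vapply(corpus, function(s) {
    cols <- if (is.null(s$extras)) cbind(s$tokens, s$labels)
            else cbind(s$tokens, s$extras, s$labels)
    paste(apply(cols, 1L, paste, collapse = "\t"), collapse = "\n")
  }, "")
  txt <- paste0(paste(chunks, collapse = "\n\n"), "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path, sep = "")
  invisible(txt)
}

#' Parse a bracket-annotated example sentence
#'
#' Parses the inline annotation mini-format in which an entity is written
#' `[span words]_class_`, e.g.
#' `"With [intravenous hydration]_treatment_ [the BUN]_test_ and"`.
#' Tokenization is whitespace splitting; tokens inside brackets receive
#' `B-`/`I-` labels of the class, all others `"O"`.
#'
#' @param text a single annotated sentence.
#' @param scheme a [label_scheme()]; annotation classes must belong to it.
#' @return a [labeled_sequence()].
#' @export
parse_bracketed <- function(text, scheme) {
  stopifnot(length(text) == 1L)
  pat <- "\\[([^][]*)\\]_([^_[:space:]]+)_"
  m <- gregexpr(pat, text)[[1L]]
  tokens <- character()
  labels <- character()
  push_outside <- function(s) {
    if (grepl("[][]", s)) stop("unbalanced or nested brackets in: ", text)
    tk <- strsplit(trimws(s), "[ \t]+")[[1L]]
    tk <- tk[nzchar(tk)]
    tokens <<- c(tokens, tk)
    labels <<- c(labels, rep("O", length(tk)))
  }
  pos <- 1L
  if (m[1L] != -1L) {
    len <- attr(m, "match.length")
    for (i in seq_along(m)) {
      push_outside(substr(text, pos, m[i] - 1L))
      piece <- substr(text, m[i], m[i] + len[i] - 1L)
      span <- sub(pat, "\\1", piece)
      cls <- sub(pat, "\\2", piece)
      if (!cls %in% scheme$classes)
        stop("unknown entity class in annotation: ", cls)
      tk <- strsplit(trimws(span), "[ \t]+")[[1L]]
      tk <- tk[nzchar(tk)]
      if (!length(tk)) stop("empty annotation span in: ", text)
      tokens <- c(tokens, tk)
      labels <- c(labels,
                  if (scheme$tagging == "iob2")
                    c(paste0("B-", cls), rep(paste0("I-", cls),
                                             length(tk) - 1L))
                  else rep(cls, length(tk)))
      pos <- m[i] + len[i]
    }
  }
  push_outside(substr(text, pos, nchar(text)))
  labeled_sequence(tokens, labels)
}

#' Extract entity spans from a label sequence
#'
#' Maximal `B-c (I-c)*` runs (IOB2) or maximal runs of the same class
#' symbol (bare tagging) become one span.  Coordinates are 0-based,
#' half-open.
#'
#' @param x a [labeled_sequence()] or a character vector of labels.
#' @param scheme optional [label_scheme()]; inferred (IOB2 if any label
#'   starts with `B-`/`I-`) when absent.
#' @return a data frame with columns `class`, `start`, `end`, ordered by
#'   `start`.
#' @export
labels_to_spans <- function(x, scheme = NULL) {
  labels <- if (inherits(x, "labeled_sequence")) x$labels else as.character(x)
  iob2 <- if (!is.null(scheme)) scheme$tagging == "iob2"
          else any(grepl("^[BI]-", labels))
  cls <- character(); start <- integer(); end <- integer()
  if (iob2) {
    open <- NA_character_; s0 <- NA_integer_
    close_span <- function(t) {
      if (!is.na(open)) {
        cls <<- c(cls, open); start <<- c(start, s0); end <<- c(end, t)
      }
    }
    for (t in seq_along(labels)) {
      lab <- labels[t]
      if (startsWith(lab, "B-")) {
        close_span(t - 1L); open <- substring(lab, 3L); s0 <- t - 1L
      } else if (startsWith(lab, "I-")) {
        if (is.na(open) || substring(lab, 3L) != open)
          stop("IOB2-inconsistent labels at position ", t)
      } else {
        close_span(t - 1L); open <- NA_character_
      }
    }
    close_span(length(labels))
  } else {
    rle_ <- rle(labels)
    ends <- cumsum(rle_$lengths)
    starts <- ends - rle_$lengths
    keep <- rle_$values != "O"
    cls <- rle_$values[keep]; start <- starts[keep]; end <- ends[keep]
  }
  data.frame(class = cls, start = start, end = end,
             stringsAsFactors = FALSE)
}

#' Rebuild a label sequence from entity spans
#'
#' Inverse of [labels_to_spans()]: spans become `B-c (I-c)*` runs (or bare
#' class runs) over an all-`"O"` background.
#'
#' @param spans a data frame with columns `class`, `start`, `end`
#'   (0-based, half-open, non-overlapping).
#' @param len sentence length in tokens.
#' @param tagging `"iob2"` or `"bare"`.
#' @return a character vector of `len` labels.
#' @export
spans_to_labels <- function(spans, len, tagging = c("iob2", "bare")) {
  tagging <- match.arg(tagging)
  labels <- rep("O", len)
  if (nrow(spans)) {
    if (any(spans$start < 0L) || any(spans$end > len) ||
        any(spans$start >= spans$end))
      stop("invalid span coordinates")
    for (i in seq_len(nrow(spans))) {
      idx <- (spans$start[i] + 1L):spans$end[i]
      labels[idx] <- if (tagging == "iob2")
        c(paste0("B-", spans$class[i]),
          rep(paste0("I-", spans$class[i]), length(idx) - 1L))
      else spans$class[i]
    }
  }
  labels
}
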