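#' Create a feature template
#'
#' A template describes one family of observation symbols extracted at
#' every token position.  `window` is the total window size `w`: a value
#' of 3 reads offsets -1..+1, 5 reads -2..+2, and `NULL` reads the
#' current token only.  Out-of-sentence offsets yield the boundary
#' symbols `"<S>"` / `"</S>"`.
#'
#' Kinds:
#' \describe{
#'   \item{token}{the raw token surface.}
#'   \item{norm_token}{lowercased surface with digits mapped to `"0"`.}
#'   \item{ngram}{character n-grams of the current token, boundary-padded
#'     with `^`/`$` (`n` in `params$n`).}
#'   \item{affix}{character prefixes and suffixes of the current token,
#'     lengths `params$len_min .. params$len_max`.}
#'   \item{capitalization}{word-shape class: `ALLCAPS`, `INITCAP`,
#'     `HASDIGIT`, `LOWER` or `MIXED`.}
#'   \item{pos_chunk}{auxiliary corpus columns (POS/chunk tags) from the
#'     sequence's `extras`; `params$cols` selects columns (default all).}
#'   \item{gazetteer}{case-insensitive membership of the token in a
#'     lexicon (`params$name`, `params$terms`).}
#' }
#'
#' @param kind one of the kinds above.
#' @param window total window size (odd integer) or `NULL`.
#' @param ... kind-specific parameters (see above).
#' @return an object of class `feature_template`.
#' @export
feature_template <- function(kind = c("token", "norm_token", "ngram",
                                      "affix", "capitalization",
                                      "pos_chunk", "gazetteer"),
                             window = NULL, ...) {
  kind <- match.arg(kind)
  params <- list(...)
  if (!is.null(window)) {
    stopifnot(window >= 1L, window %% 2L == 1L)
  }
  if (kind == "ngram" && is.null(params$n)) params$n <- 2L
  if (kind == "affix") {
    if (is.null(params$len_min)) params$len_min <- 2L
    if (is.null(params$len_max)) params$len_max <- 3L
    stopifnot(params$len_min >= 1L, params$len_max >= params$len_min)
  }
  if (kind == "gazetteer") {
    stopifnot(!is.null(params$name), !is.null(params$terms))
    params$terms <- tolower(as.character(params$terms))
  }
  structure(list(kind = kind, window = window, params = params),
            class = "feature_template")
}

#' Standard feature settings
#'
#' Three bundled template sets of increasing richness:
#' \describe{
#'   \item{1 (context)}{token and normalized token, window 3.}
#'   \item{2 (morphology)}{setting 1 plus character affixes of length
#'     2-3 and capitalization patterns (window 3).}
#'   \item{3 (rich)}{token and normalized token at window 5, character
#'     2-grams, affixes of length 2-7, capitalization (window 3), plus
#'     POS/chunk columns (window 1) when `use_extras = TRUE` and any
#'     supplied gazetteers.}
#' }
#'
#' @param set 1, 2 or 3.
#' @param use_extras include `pos_chunk` templates (requires corpora with
#'   auxiliary columns)?
#' @param gazetteers optional named list of character vectors; each
#'   becomes one gazetteer template.
#' @return a list of [feature_template()] objects.
#' @export
feature_setting <- function(set = 1L, use_extras = FALSE,
                            gazetteers = NULL) {
  stopifnot(set %in% 1:3)
  tpl <- list(feature_template("token", window = if (set == 3L) 5L else 3L),
              feature_template("norm_token",
                               window = if (set == 3L) 5L else 3L))
  if (set >= 2L) {
    lmax <- if (set == 3L) 7L else 3L
    tpl <- c(tpl, list(feature_template("affix", len_min = 2L,
                                        len_max = lmax),
                       feature_template("capitalization", window = 3L)))
  }
  if (set == 3L) {
    tpl <- c(tpl, list(feature_template("ngram", n = 2L)))
    if (use_extras)
      tpl <- c(tpl, list(feature_template("pos_chunk", window = 1L)))
  }
  for (nm in names(gazetteers))
    tpl <- c(tpl, list(feature_template("gazetteer", name = nm,
                                        terms = gazetteers[[nm]])))
  tpl
}

cap_shape <- function(tok) {
  alpha <- grepl("^[[:alpha:]]+$", tok)
  ifelse(alpha & tok == toupper(tok), "ALLCAPS",
  ifelse(alpha & grepl("^[[:upper:]][[:lower:]]*$", tok), "INITCAP",
  ifelse(grepl("[[:digit:]]", tok), "HASDIGIT",
  ifelse(alpha & tok == tolower(tok), "LOWER", "MIXED"))))
}

norm_token <- function(tok) gsub("[0-9]", "0", tolower(tok))

offsets_of <- function(window) {
  if (is.null(window)) 0L else (-(window %/% 2L)):(window %/% 2L)
}

#' Extract observation symbols for every token position
#'
#' Applies a list of feature templates to a sentence and returns, for
#' each position, the set of observation symbols firing there.  Symbols
#' are strings such as `"w[-1]=She"`; they depend only on the tokens (and
#' auxiliary columns), never on labels, so extraction is identical at
#' train and test time.
#'
#' @param x a [labeled_sequence()] or a character vector of tokens.
#' @param templates a list of [feature_template()] objects (e.g. from
#'   [feature_setting()]).
#' @return a list (one element per position) of character vectors.
#' @export
extract_observations <- function(x, templates) {
  tokens <- if (inherits(x, "labeled_sequence")) x$tokens else as.character(x)
  extras <- if (inherits(x, "labeled_sequence")) x$extras else NULL
  n <- length(tokens)
  out <- vector("list", n)
  if (!n) return(out)
  per_tpl <- lapply(templates, function(tp) {
    switch(tp$kind,
      token = windowed(tokens, tp, "w", identity),
      norm_token = windowed(tokens, tp, "nw", norm_token),
      capitalization = windowed(tokens, tp, "cap", cap_shape),
      pos_chunk = {
        if (is.null(extras))
          stop("pos_chunk template requires auxiliary columns (extras)")
        cols <- tp$params$cols %||% seq_len(ncol(extras))
        res <- vector("list", n)
        for (ci in cols) {
          v <- windowed(extras[, ci], tp, paste0("x", ci), identity)
          res <- Map(c, res, v)
        }
        res
      },
      ngram = {
        nn <- tp$params$n
        lapply(seq_len(n), function(t) {
          s <- paste0("^", tokens[t], "$")
          k <- nchar(s)
          if (k < nn) return(character())
          unique(paste0("ng", nn, "=",
                        substring(s, 1:(k - nn + 1L), nn:k)))
        })
      },
      affix = {
        lmin <- tp$params$len_min; lmax <- tp$params$len_max
        lapply(seq_len(n), function(t) {
          tok <- tokens[t]; k <- nchar(tok)
          lens <- lmin:lmax
          lens <- lens[lens <= k]
          if (!length(lens)) return(character())
          c(paste0("pre=", substring(tok, 1L, lens)),
            paste0("suf=", substring(tok, k - lens + 1L, k)))
        })
      },
      gazetteer = {
        hit <- tolower(tokens) %in% tp$params$terms
        lapply(seq_len(n), function(t)
          if (hit[t]) paste0("lex=", tp$params$name) else character())
      })
  })
  for (t in seq_len(n))
    out[[t]] <- unlist(lapply(per_tpl, `[[`, t), use.names = FALSE)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# window a per-position string feature into observation symbols
windowed <- function(values, tp, tag, f) {
  n <- length(values)
  offs <- offsets_of(tp$window)
  vals <- f(values)
  lapply(seq_len(n), function(t) {
    v <- vapply(offs, function(o) {
      p <- t + o
      if (p < 1L) "<S>" else if (p > n) "</S>" else vals[p]
    }, "")
    paste0(tag, "[", offs, "]=", v)
  })
}

#' Build the feature index binding observations and transitions to
#' parameter slots
#'
#' Allocates one dense parameter vector slot for every transition
#' permitted by the state-space mask (including transitions from the
#' start state) and for every (binding target, observation symbol) pair
#' observed in the training corpus.  With `share_outside = TRUE` all
#' outside states form a single binding target, so an observation symbol
#' co-occurring with any outside state yields one shared parameter —
#' the many-to-one observation feature of the precursor-induced model.
#' With sharing off, every (state, symbol) co-occurrence gets its own
#' slot.  Entity states always bind one-to-one.
#'
#' @param corpus list of [labeled_sequence()] whose labels belong to
#'   `space$symbols`.
#' @param templates list of [feature_template()] objects.
#' @param space a [state_space()].
#' @param share_outside share observation parameters across all outside
#'   states?
#' @return an object of class `feature_index` (frozen): vocabulary,
#'   observation slot matrix, state-to-target binding, transition slot
#'   matrix and parameter counts.
#' @export
build_feature_index <- function(corpus, templates, space,
                                share_outside = TRUE) {
  n <- length(space$symbols)
  outside <- is_outside_symbol(space$symbols) | space$symbols == "O"
  if (share_outside && any(outside)) {
    target_of_state <- integer(n)
    target_of_state[!outside] <- seq_len(sum(!outside))
    target_of_state[outside] <- sum(!outside) + 1L
    targets <- c(space$symbols[!outside], "<OUTSIDE>")
  } else {
    target_of_state <- seq_len(n)
    targets <- space$symbols
  }
  # transition slots for every mask-permitted bigram (start row last)
  trans_slot <- matrix(0L, n + 1L, n,
                       dimnames = dimnames(space$mask))
  k <- 0L
  for (i in seq_len(n + 1L)) for (j in seq_len(n)) {
    if (space$mask[i, j]) { k <- k + 1L; trans_slot[i, j] <- k }
  }
  n_trans <- k
  obs <- lapply(corpus, extract_observations, templates = templates)
  vocab <- unique(unlist(obs, use.names = FALSE))
  n_targets <- length(targets)
  key_chunks <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    st <- match(corpus[[i]]$labels, space$symbols)
    if (anyNA(st))
      stop("corpus labels outside the state space in sentence ", i)
    tg <- target_of_state[st]
    ids <- lapply(obs[[i]], function(s) match(s, vocab))
    key_chunks[[i]] <- unlist(Map(function(s, g) (s - 1L) * n_targets + g,
                                  ids, tg), use.names = FALSE)
  }
  keys <- sort(unique(unlist(key_chunks, use.names = FALSE)))
  obs_slot <- matrix(0L, n_targets, length(vocab),
                     dimnames = list(targets, NULL))
  obs_slot[keys] <- n_trans + seq_along(keys)
  structure(list(vocab = vocab, obs_slot = obs_slot,
                 target_of_state = target_of_state, targets = targets,
                 trans_slot = trans_slot, n_trans = n_trans,
                 n_obs = length(keys),
                 n_params = n_trans + length(keys),
                 templates = templates, space = space,
                 share_outside = share_outside, frozen = TRUE),
            class = "feature_index")
}

#' @export
print.feature_index <- function(x, ...) {
  cat(sprintf("<feature_index: %d parameters (%d transition + %d observation), %d symbols>\n",
              x$n_params, x$n_trans, x$n_obs, length(x$vocab)))
  invisible(x)
}

#' Observation score of a state at one position
#'
#' Sums the weights of the parameter slots bound to
#' `(binding_target(state), symbol)` for the observation symbols present;
#' symbols unseen at indexing time contribute zero.
#'
#' @param index a frozen [build_feature_index()] result.
#' @param weights numeric weight vector of length `index$n_params`.
#' @param symbols character vector of observation symbols at a position.
#' @param state a state symbol of the index's state space.
#' @return a numeric score.
#' @export
score_observations <- function(index, weights, symbols, state) {
  st <- match(state, index$space$symbols)
  if (is.na(st)) stop("unknown state: ", state)
  ids <- match(symbols, index$vocab)
  ids <- ids[!is.na(ids)]
  if (!length(ids)) return(0)
  slots <- index$obs_slot[index$target_of_state[st], ids]
  sum(weights[slots[slots > 0L]])
}

# map a corpus to per-position vocabulary ids (NA-dropped), reusing the
# index's templates; used by training and prediction
corpus_symbol_ids <- function(corpus, index) {
  lapply(corpus, function(s) {
    obs <- extract_observations(s, index$templates)
    lapply(obs, function(sy) {
      ids <- match(sy, index$vocab)
      as.integer(ids[!is.na(ids)])
    })
  })
}
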