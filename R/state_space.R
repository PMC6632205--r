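#' Construct a chain-model state space
#'
#' Bundles the emitting state symbols, the distinguished start state and
#' the structural transition mask used by the forward-backward and
#' Viterbi recursions.
#'
#' @param symbols ordered character vector of emitting state symbols.
#' @param start start symbol (non-emitting).
#' @param mask logical matrix `(N + 1) x N`; rows are the emitting
#'   symbols followed by the start symbol, columns the emitting symbols.
#'   `NULL` means all transitions allowed.
#' @param order `"first"` or `"second_expanded"`.
#' @return an object of class `state_space`.
#' @export
state_space <- function(symbols, start = "<START>", mask = NULL,
                        order = c("first", "second_expanded")) {
  order <- match.arg(order)
  n <- length(symbols)
  stopifnot(n >= 1L, !start %in% symbols)
  if (is.null(mask)) {
    mask <- matrix(TRUE, n + 1L, n,
                   dimnames = list(c(symbols, start), symbols))
  }
  stopifnot(nrow(mask) == n + 1L, ncol(mask) == n)
  dimnames(mask) <- list(c(symbols, start), symbols)
  if (!any(mask[n + 1L, ])) stop("start state has no allowed successor")
  structure(list(symbols = symbols, start = start, mask = mask,
                 order = order),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat(sprintf("<state_space: %s order, %d emitting states (+ start)>\n",
              if (x$order == "first") "first" else "second (pair-expanded)",
              length(x$symbols)))
  invisible(x)
}

# first-order space over the original labels (IOB2 mask applied)
space_from_scheme <- function(scheme) {
  state_space(scheme$labels, scheme$start, scheme_mask(scheme), "first")
}

# first-order space over the induced labels; structural = TRUE applies
# the precursor transition_mask (pi-CRF), FALSE the conventional mask of
# a vanilla CRF over opaque induced symbols (the sharing ablation)
space_from_induced <- function(ischeme, structural = TRUE) {
  state_space(ischeme$all_symbols, ischeme$start,
              if (structural) transition_mask(ischeme)
              else conventional_induced_mask(ischeme),
              "first")
}

#' Expand a first-order state space to second order
#'
#' Builds the pair-state space whose states are `(y[t-1], y[t])` pairs of
#' first-order symbols (the first component may be the start symbol).
#' Only pairs permitted by the first-order mask are materialized; the
#' pair mask allows `(a, b) -> (b', c)` exactly when `b == b'` and
#' `b -> c` is permitted at first order.  Observation scores are bound to
#' the second pair component, so decoding projects pairs back to single
#' labels.
#'
#' @param space a first-order [state_space()].
#' @return a `state_space` with `order = "second_expanded"`; the base
#'   space, the pair components (`pair_prev`, `pair_cur`, indices into
#'   `c(base$symbols, base$start)` and `base$symbols`) are attached.
#' @export
expand_second_order <- function(space) {
  stopifnot(inherits(space, "state_space"), space$order == "first")
  n <- length(space$symbols)
  comp_a <- c(space$symbols, space$start)   # n + 1 options (start last)
  pairs <- which(space$mask, arr.ind = TRUE)   # feasible (a, b)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  a <- pairs[, 1L]; b <- pairs[, 2L]
  psyms <- paste0(comp_a[a], "|", space$symbols[b])
  np <- length(psyms)
  mask <- matrix(FALSE, np + 1L, np)
  # (a,b) -> (b', c): b == b' and b -> c allowed
  for (j in seq_len(np)) {
    mask[seq_len(np), j] <- b == a[j] & space$mask[b, space$symbols[b[j]]]
  }
  # start -> (start, c) when start -> c allowed
  mask[np + 1L, ] <- a == n + 1L
  out <- state_space(psyms, space$start, mask, "second_expanded")
  out$base <- space
  out$pair_prev <- a
  out$pair_cur <- b
  out
}

#' Number of states of a chain model
#'
#' Uses the convention of counting the emitting symbols plus the single
#' distinguished start state for first-order models, and the square of
#' that number for the pair-expanded second-order model.
#'
#' @param space a [state_space()].
#' @return an integer state count.
#' @examples
#' sch <- label_scheme(c("problem", "test", "treatment"))
#' state_count(space_from_scheme(sch))                         # 8
#' state_count(space_from_induced(build_induced_scheme(sch)))  # 11
#' @export
state_count <- function(space) {
  stopifnot(inherits(space, "state_space"))
  if (space$order == "first") length(space$symbols) + 1L
  else (length(space$base$symbols) + 1L)^2L
}
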