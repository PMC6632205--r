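log_sum_exp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# (N+1) x N matrix of transition log-potentials from an index + weights;
# forbidden transitions are -Inf
transition_scores <- function(index, weights) {
  tw <- matrix(-Inf, nrow(index$trans_slot), ncol(index$trans_slot),
               dimnames = dimnames(index$trans_slot))
  pos <- index$trans_slot > 0L
  tw[pos] <- weights[index$trans_slot[pos]]
  tw
}

# T x N node score matrix for one sentence's symbol ids
node_scores <- function(sym_ids, index, weights) {
  n <- length(index$space$symbols)
  Tlen <- length(sym_ids)
  g <- length(index$targets)
  ts <- matrix(0, Tlen, g)
  for (t in seq_len(Tlen)) {
    ids <- sym_ids[[t]]
    if (length(ids)) {
      slots <- index$obs_slot[, ids, drop = FALSE]
      ts[t, ] <- rowSums(matrix(ifelse(slots > 0L, weights[pmax(slots, 1L)], 0),
                                g, length(ids)))
    }
  }
  ts[, index$target_of_state, drop = FALSE]
}

#' Forward-backward inference on a chain lattice
#'
#' Exact log-domain sum-product over mask-permitted transitions.  Node
#' scores hold the observation log-potentials; `trans` holds transition
#' log-potentials with `-Inf` marking forbidden transitions (its last row
#' is the transition from the start state).
#'
#' @param node numeric `T x N` matrix of per-position, per-state
#'   observation scores.
#' @param trans numeric `(N + 1) x N` transition score matrix (start row
#'   last).
#' @return a `crf_lattice` list: `log_alpha`, `log_beta` (`T x N`),
#'   `log_z`, `node_marginals` (`T x N`, rows sum to 1),
#'   `trans_marginals` (array `(T - 1) x N x N`, previous state by
#'   current state) and `start_marginals`.
#' @export
forward_backward <- function(node, trans) {
  Tlen <- nrow(node); n <- ncol(node)
  stopifnot(nrow(trans) == n + 1L, ncol(trans) == n, Tlen >= 1L)
  la <- matrix(-Inf, Tlen, n)
  lb <- matrix(-Inf, Tlen, n)
  la[1L, ] <- trans[n + 1L, ] + node[1L, ]
  if (Tlen > 1L) {
    for (t in 2:Tlen) {
      prev <- la[t - 1L, ] + trans[seq_len(n), , drop = FALSE]
      la[t, ] <- apply(prev, 2L, log_sum_exp) + node[t, ]
    }
  }
  log_z <- log_sum_exp(la[Tlen, ])
  if (!is.finite(log_z)) stop("infeasible lattice: all paths masked")
  lb[Tlen, ] <- 0
  if (Tlen > 1L) {
    for (t in (Tlen - 1L):1L) {
      nxt <- sweep(trans[seq_len(n), , drop = FALSE], 2L,
                   node[t + 1L, ] + lb[t + 1L, ], `+`)
      lb[t, ] <- apply(nxt, 1L, log_sum_exp)
    }
  }
  node_marg <- exp(la + lb - log_z)
  tm <- NULL
  if (Tlen > 1L) {
    tm <- array(0, dim = c(Tlen - 1L, n, n))
    for (t in 2:Tlen) {
      m <- exp(outer(la[t - 1L, ], node[t, ] + lb[t, ], `+`) +
                 trans[seq_len(n), , drop = FALSE] - log_z)
      m[!is.finite(m)] <- 0
      tm[t - 1L, , ] <- m
    }
  }
  structure(list(log_alpha = la, log_beta = lb, log_z = log_z,
                 node_marginals = node_marg, trans_marginals = tm,
                 start_marginals = node_marg[1L, ]),
            class = "crf_lattice")
}

#' Viterbi decoding on a chain lattice
#'
#' Max-scoring mask-permitted path; ties are broken toward the lower
#' state index at every backpointer.
#'
#' @inheritParams forward_backward
#' @return an integer vector of state indices (length `T`).
#' @export
viterbi <- function(node, trans) {
  Tlen <- nrow(node); n <- ncol(node)
  stopifnot(nrow(trans) == n + 1L, ncol(trans) == n)
  delta <- matrix(-Inf, Tlen, n)
  bp <- matrix(0L, Tlen, n)
  delta[1L, ] <- trans[n + 1L, ] + node[1L, ]
  if (Tlen > 1L) {
    tr <- trans[seq_len(n), , drop = FALSE]
    for (t in 2:Tlen) {
      sc <- delta[t - 1L, ] + tr
      best <- apply(sc, 2L, which.max)   # first max = lowest index
      delta[t, ] <- sc[cbind(best, seq_len(n))] + node[t, ]
      bp[t, ] <- best
    }
  }
  if (!is.finite(max(delta[Tlen, ]))) stop("infeasible lattice: all paths masked")
  path <- integer(Tlen)
  path[Tlen] <- which.max(delta[Tlen, ])
  if (Tlen > 1L)
    for (t in (Tlen - 1L):1L) path[t] <- bp[t + 1L, path[t + 1L]]
  path
}

# encode a corpus for the compiled core: per-sentence symbol ids and
# gold state ids
encode_corpus <- function(corpus, index) {
  syms <- index$space$symbols
  gold <- lapply(seq_along(corpus), function(i) {
    st <- match(corpus[[i]]$labels, syms)
    if (anyNA(st)) stop("labels outside the state space in sentence ", i)
    st
  })
  list(obs = corpus_symbol_ids(corpus, index), gold = gold)
}

#' Penalized log-likelihood and gradient of a chain CRF
#'
#' Computes the l2-penalized conditional log-likelihood
#' `sum_i [score(y_i) - log Z(x_i)] - sum_k theta_k^2 / (2 sigma^2)`
#' and its exact gradient (empirical feature counts minus expected
#' counts minus `theta / sigma^2`) over a corpus.
#'
#' @param weights numeric parameter vector.
#' @param corpus list of [labeled_sequence()] with labels in the index's
#'   state space (pass induced labels for induced models).
#' @param index a [build_feature_index()] result.
#' @param sigma l2 regularization scale (`Inf` = no penalty).
#' @param encoded optional pre-encoded corpus from an earlier call
#'   (internal use; avoids re-extracting features).
#' @return a list with `value` (penalized log-likelihood) and `gradient`.
#' @export
crf_loglik <- function(weights, corpus, index, sigma = 10,
                       encoded = NULL) {
  stopifnot(length(weights) == index$n_params, sigma > 0)
  if (is.null(encoded)) encoded <- encode_corpus(corpus, index)
  res <- cpp_corpus_nll_grad(encoded$obs, encoded$gold, index$obs_slot,
                             index$target_of_state, index$trans_slot,
                             as.numeric(weights),
                             if (is.finite(sigma)) 1 / sigma^2 else 0)
  list(value = -res$nll, gradient = -res$grad)
}

#' Train a chain CRF by L-BFGS
#'
#' Maximizes the l2-penalized conditional log-likelihood from `theta = 0`
#' using `stats::optim(method = "L-BFGS-B")`.  Stops when the relative
#' objective change falls below `tol` or after `max_iter` iterations.
#' Training is deterministic given identical inputs.
#'
#' @param corpus training corpus (labels in the index's state space).
#' @param index a [build_feature_index()] result.
#' @param sigma l2 regularization scale.
#' @param max_iter iteration cap.
#' @param tol relative objective-change stopping threshold.
#' @param lbfgs_memory number of L-BFGS correction pairs.
#' @param verbose print per-iteration objectives?
#' @return a list: `weights`, `value` (final penalized log-likelihood),
#'   `objective_log` (best objective after each evaluation,
#'   non-decreasing), `evaluations` (raw objective per function
#'   evaluation), `iterations`, `converged`.
#' @export
crf_train <- function(corpus, index, sigma = 10, max_iter = 500L,
                      tol = 1e-6, lbfgs_memory = 10L, verbose = FALSE) {
  stopifnot(length(corpus) >= 1L, tol > 0, tol < 1, max_iter >= 1L)
  encoded <- encode_corpus(corpus, index)
  evals <- numeric(0)
  last <- NULL
  objective <- function(w) {
    if (is.null(last) || !identical(w, last$w)) {
      res <- crf_loglik(w, corpus = NULL, index = index, sigma = sigma,
                        encoded = encoded)
      if (!is.finite(res$value))
        stop("non-finite objective during training")
      last <<- list(w = w, res = res)
      evals[length(evals) + 1L] <<- res$value
      if (verbose)
        message(sprintf("eval %d: penalized LL = %.6f",
                        length(evals), res$value))
    }
    last$res
  }
  fit <- stats::optim(
    par = rep(0, index$n_params),
    fn = function(w) -objective(w)$value,
    gr = function(w) -objective(w)$gradient,
    method = "L-BFGS-B",
    control = list(maxit = max_iter, lmm = lbfgs_memory,
                   factr = tol / .Machine$double.eps))
  list(weights = fit$par, value = -fit$value,
       objective_log = cummax(evals), evaluations = evals,
       iterations = fit$counts[["function"]],
       converged = fit$convergence == 0L)
}
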