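#' Fit a chain CRF for named entity recognition
#'
#' The single fitting entry point for all model variants:
#' \describe{
#'   \item{`"first"`}{conventional first-order linear-chain CRF over the
#'     IOB2 labels.}
#'   \item{`"pi"`}{precursor-induced CRF: the training labels are passed
#'     through [induce_labels()], the state space is expanded with
#'     precursor-carrying outside symbols constrained by
#'     [transition_mask()], and observation symbols are shared across all
#'     outside states ([build_feature_index()] with
#'     `share_outside = TRUE`).  Decoding runs in the induced space —
#'     nothing is induced at test time; the state space itself carries
#'     the precursor memory — and predictions are collapsed back to the
#'     original labels.}
#'   \item{`"first_induced"`}{ablation: a conventional first-order CRF
#'     trained on the induced labels as opaque symbols — per-state
#'     one-to-one observation binding (no sharing) and no structural
#'     precursor mask (only tagging-scheme validity), so decoded
#'     precursor chains may break.}
#'   \item{`"second"`}{second-order CRF via pair-state expansion
#'     ([expand_second_order()]); observations bind to the second pair
#'     component.}
#' }
#'
#' Training maximizes the l2-penalized conditional log-likelihood by
#' L-BFGS (see [crf_train()]).
#'
#' @param corpus a list of [labeled_sequence()] with IOB2-consistent
#'   labels (e.g. from [read_conll()] or [synth_corpus()]).
#' @param variant model variant, see above.
#' @param templates list of [feature_template()] objects; default
#'   [feature_setting()] 1.
#' @param scheme a [label_scheme()]; inferred from the corpus labels
#'   (classes sorted alphabetically) when `NULL`.
#' @param sigma l2 regularization scale of the
#'   `-sum theta^2 / (2 sigma^2)` penalty.
#' @param max_iter,tol,lbfgs_memory L-BFGS controls, see [crf_train()].
#' @param verbose print training progress?
#' @return an object of class `crf_model`.
#' @examples
#' sch <- label_scheme(c("problem", "test"))
#' corp <- list(
#'   labeled_sequence(c("fever", "and", "wbc"), c("B-problem", "O", "B-test")),
#'   labeled_sequence(c("wbc", "after", "fever"), c("B-test", "O", "B-problem")))
#' m <- crf_fit(corp, variant = "pi", sigma = 100)
#' predict(m, corp)
#' @export
crf_fit <- function(corpus,
                    variant = c("first", "pi", "first_induced", "second"),
                    templates = feature_setting(1L), scheme = NULL,
                    sigma = 10, max_iter = 500L, tol = 1e-6,
                    lbfgs_memory = 10L, verbose = FALSE) {
  variant <- match.arg(variant)
  stopifnot(length(corpus) >= 1L)
  if (is.null(scheme)) scheme <- infer_scheme(corpus)
  for (i in seq_along(corpus)) {
    validate_labels(corpus[[i]]$labels, scheme)
    if (!is_iob2_consistent(corpus[[i]]$labels, scheme))
      stop("IOB2-inconsistent labels in sentence ", i,
           " (repair with read_conll / repair_iob2 first)")
  }
  ischeme <- NULL
  if (variant %in% c("pi", "first_induced")) {
    ischeme <- build_induced_scheme(scheme)
    space <- space_from_induced(ischeme, structural = (variant == "pi"))
    train_corpus <- lapply(corpus, function(s) {
      s$labels <- induce_labels(s$labels, scheme)
      s
    })
  } else if (variant == "second") {
    space <- expand_second_order(space_from_scheme(scheme))
    train_corpus <- lapply(corpus, function(s) {
      s$labels <- pair_labels(s$labels, space)
      s
    })
  } else {
    space <- space_from_scheme(scheme)
    train_corpus <- corpus
  }
  index <- if (variant == "second")
    build_second_order_index(train_corpus, templates, space)
  else build_feature_index(train_corpus, templates, space,
                           share_outside = (variant == "pi"))
  fit <- crf_train(train_corpus, index, sigma = sigma,
                   max_iter = max_iter, tol = tol,
                   lbfgs_memory = lbfgs_memory, verbose = verbose)
  structure(list(variant = variant, scheme = scheme, ischeme = ischeme,
                 space = space, templates = templates, index = index,
                 weights = fit$weights, sigma = sigma,
                 fit = fit, n_train = length(corpus),
                 call = match.call()),
            class = "crf_model")
}

infer_scheme <- function(corpus) {
  labs <- unique(unlist(lapply(corpus, `[[`, "labels"), use.names = FALSE))
  ent <- labs[labs != "O"]
  if (all(grepl("^[BI]-", ent))) {
    label_scheme(sort(unique(sub("^[BI]-", "", ent))), tagging = "iob2")
  } else {
    label_scheme(sort(ent), tagging = "bare")
  }
}

# map an original label sequence to pair-state symbols of a
# second-order space
pair_labels <- function(labels, space2) {
  base <- space2$base
  prev <- c(base$start, labels[-length(labels)])
  paste0(prev, "|", labels)
}

# second-order index: observation binding by the second pair component
build_second_order_index <- function(corpus, templates, space2) {
  idx <- build_feature_index(corpus, templates, space2,
                             share_outside = FALSE)
  base <- space2$base
  # rebind: target = second pair component (shared across pairs)
  nb <- length(base$symbols)
  target_of_state <- space2$pair_cur
  targets <- base$symbols
  # reallocate observation slots under the coarser binding
  n_targets <- length(targets)
  vocab <- idx$vocab
  key_chunks <- vector("list", length(corpus))
  for (i in seq_along(corpus)) {
    st <- match(corpus[[i]]$labels, space2$symbols)
    tg <- target_of_state[st]
    obs <- extract_observations(corpus[[i]], templates)
    ids <- lapply(obs, function(s) match(s, vocab))
    key_chunks[[i]] <- unlist(Map(function(s, g) (s - 1L) * n_targets + g,
                                  ids, tg), use.names = FALSE)
  }
  keys <- sort(unique(unlist(key_chunks, use.names = FALSE)))
  obs_slot <- matrix(0L, n_targets, length(vocab),
                     dimnames = list(targets, NULL))
  obs_slot[keys] <- idx$n_trans + seq_along(keys)
  idx$obs_slot <- obs_slot
  idx$target_of_state <- target_of_state
  idx$targets <- targets
  idx$n_obs <- length(keys)
  idx$n_params <- idx$n_trans + length(keys)
  idx
}

#' Predict labels for new sentences
#'
#' Viterbi-decodes each sentence in the model's own state space, then
#' maps the decoded states back to the original label space: induced
#' outside symbols are collapsed to `"O"` and second-order pair states
#' are projected to their current component.  The transition mask
#' guarantees IOB2-valid output.
#'
#' @param object a fitted [crf_fit()] model.
#' @param newdata a list of [labeled_sequence()] objects or of character
#'   token vectors.
#' @param ... unused.
#' @return a list of [labeled_sequence()] with predicted labels in the
#'   original label space.
#' @export
predict.crf_model <- function(object, newdata, ...) {
  tw <- transition_scores(object$index, object$weights)
  sym_ids <- corpus_symbol_ids(lapply(newdata, as_sequence), object$index)
  lapply(seq_along(newdata), function(i) {
    s <- as_sequence(newdata[[i]])
    if (!length(s$tokens))
      return(labeled_sequence(character(), character()))
    node <- node_scores(sym_ids[[i]], object$index, object$weights)
    path <- viterbi(node, tw)
    labs <- object$space$symbols[path]
    labs <- switch(object$variant,
      first = labs,
      pi = ,
      first_induced = collapse_labels(labs, object$ischeme),
      second = object$space$base$symbols[object$space$pair_cur[path]])
    labeled_sequence(s$tokens, labs, s$extras)
  })
}

as_sequence <- function(x) {
  if (inherits(x, "labeled_sequence")) x
  else labeled_sequence(x, rep("O", length(x)))
}

#' @export
print.crf_model <- function(x, ...) {
  cat(sprintf("<crf_model: %s>\n", variant_name(x$variant)))
  cat(sprintf("  states: %d (+ start), parameters: %d (%d transition, %d observation)\n",
              length(x$space$symbols), x$index$n_params,
              x$index$n_trans, x$index$n_obs))
  cat(sprintf("  sigma = %g, trained on %d sentences, penalized LL = %.3f\n",
              x$sigma, x$n_train, x$fit$value))
  invisible(x)
}

variant_name <- function(v) {
  c(first = "first-order CRF",
    pi = "precursor-induced CRF",
    first_induced = "first-order CRF with induced labels (unshared)",
    second = "second-order CRF")[[v]]
}

#' @export
summary.crf_model <- function(object, ...) {
  out <- list(variant = object$variant,
              variant_name = variant_name(object$variant),
              classes = object$scheme$classes,
              state_count = state_count(object$space),
              n_params = object$index$n_params,
              n_trans = object$index$n_trans,
              n_obs = object$index$n_obs,
              vocab_size = length(object$index$vocab),
              sigma = object$sigma,
              n_train = object$n_train,
              loglik = object$fit$value,
              iterations = object$fit$iterations,
              converged = object$fit$converged)
  class(out) <- "summary.crf_model"
  out
}

#' @export
print.summary.crf_model <- function(x, ...) {
  cat(sprintf("%s\n", x$variant_name))
  cat(sprintf("  entity classes : %s\n", paste(x$classes, collapse = ", ")))
  cat(sprintf("  states         : %d (start included)\n", x$state_count))
  cat(sprintf("  parameters     : %d (%d transition + %d observation; %d symbols)\n",
              x$n_params, x$n_trans, x$n_obs, x$vocab_size))
  cat(sprintf("  sigma          : %g\n", x$sigma))
  cat(sprintf("  training       : %d sentences, %d evaluations, %s\n",
              x$n_train, x$iterations,
              if (x$converged) "converged" else "iteration cap reached"))
  cat(sprintf("  penalized LL   : %.4f\n", x$loglik))
  invisible(x)
}

#' @export
coef.crf_model <- function(object, ...) {
  w <- object$weights
  nms <- character(length(w))
  ts <- object$index$trans_slot
  pos <- which(ts > 0L, arr.ind = TRUE)
  nms[ts[pos]] <- paste0(rownames(ts)[pos[, 1L]], " -> ",
                         colnames(ts)[pos[, 2L]])
  os <- object$index$obs_slot
  opos <- which(os > 0L, arr.ind = TRUE)
  nms[os[opos]] <- paste0(object$index$targets[opos[, 1L]], " | ",
                          object$index$vocab[opos[, 2L]])
  stats::setNames(w, nms)
}

#' @export
logLik.crf_model <- function(object, ...) {
  structure(object$fit$value, df = object$index$n_params,
            class = "logLik")
}

#' @export
plot.crf_model <- function(x, ...) {
  obj <- x$fit$objective_log
  plot(seq_along(obj), obj, type = "l", xlab = "evaluation",
       ylab = "best penalized log-likelihood",
       main = variant_name(x$variant), ...)
  invisible(x)
}

#' Write a fitted model to a self-describing archive
#'
#' The archive is a versioned serialization of the full model object
#' (schemes, templates, feature vocabulary, weights, sigma and
#' transition mask), round-trippable via [read_crf_model()].
#'
#' @param model a [crf_fit()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_crf_model <- function(model, path) {
  stopifnot(inherits(model, "crf_model"))
  saveRDS(list(format = "picrf-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' Read a model archive written by [write_crf_model()]
#'
#' @param path archive path.
#' @return the `crf_model` object.
#' @export
read_crf_model <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "picrf-model"))
    stop("not a picrf model archive: ", path)
  if (!identical(x$version, 1L))
    stop("unsupported model archive version: ", x$version)
  x$model
}
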