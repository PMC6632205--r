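#' Build the precursor-induced label scheme
#'
#' Label induction replaces the single outside label `"O"` with a family
#' of precursor-carrying outside symbols: `"c[O]+"` for every entity
#' class `c` (an outside run preceded, somewhere in the sentence, most
#' recently by an entity of class `c`) plus `"O[O]+"` (no entity has
#' occurred yet).  Entity label symbols are unchanged.  The precursor is
#' tracked at the granularity of the entity class, not of the refined
#' `B-`/`I-` label, so under IOB2 the state set grows by the number of
#' classes only.
#'
#' @param scheme a [label_scheme()].
#' @return an object of class `induced_scheme` with elements `base`,
#'   `entity_symbols`, `outside_symbols` (no-precursor symbol first),
#'   `all_symbols` (entities then outsides) and `start`.
#' @examples
#' build_induced_scheme(label_scheme(c("A", "B"), tagging = "bare"))$outside_symbols
#' @export
build_induced_scheme <- function(scheme) {
  stopifnot(inherits(scheme, "label_scheme"))
  entity <- setdiff(scheme$labels, "O")
  outside <- c("O[O]+", if (length(scheme$classes))
    paste0(scheme$classes, "[O]+"))
  structure(list(base = scheme,
                 entity_symbols = entity,
                 outside_symbols = outside,
                 all_symbols = c(entity, outside),
                 start = scheme$start),
            class = "induced_scheme")
}

#' @export
print.induced_scheme <- function(x, ...) {
  cat(sprintf("<induced_scheme: %d entity + %d outside symbols>\n",
              length(x$entity_symbols), length(x$outside_symbols)))
  cat("  outside:", paste(x$outside_symbols, collapse = " "), "\n")
  invisible(x)
}

is_outside_symbol <- function(symbols) grepl("\\[O\\]\\+$", symbols)

#' Induce precursor information into a label sequence
#'
#' Left-to-right single pass: entity labels pass through unchanged and
#' update the running precursor to their class; each `"O"` becomes
#' `"c[O]+"` where `c` is the class of the most recent preceding entity
#' token, or `"O[O]+"` when no entity has been seen yet.  The precursor
#' persists to the end of the sentence.
#'
#' @param labels character vector of labels valid under `scheme`.
#' @param scheme a [label_scheme()].
#' @return the induced label vector.
#' @examples
#' sch <- label_scheme(c("A", "B"), tagging = "bare")
#' induce_labels(c("A", "O", "O", "B"), sch)
#' @export
induce_labels <- function(labels, scheme) {
  validate_labels(labels, scheme)
  n <- length(labels)
  if (!n) return(labels)
  cls <- label_class(labels, scheme)
  # precursor at t = class of most recent entity token strictly before t
  prec <- rep(NA_character_, n)
  last <- NA_character_
  for (t in seq_len(n)) {
    prec[t] <- last
    if (!is.na(cls[t])) last <- cls[t]
  }
  out <- labels
  o <- labels == "O"
  out[o] <- ifelse(is.na(prec[o]), "O[O]+", paste0(prec[o], "[O]+"))
  out
}

#' Collapse induced labels back to the original label space
#'
#' Every `"*[O]+"` symbol becomes `"O"`; entity symbols are unchanged.
#' The definitional inverse of [induce_labels()].
#'
#' @param labels character vector of induced labels.
#' @param ischeme optional [build_induced_scheme()] result; when supplied,
#'   symbols outside the induced scheme raise an error.
#' @return the collapsed label vector.
#' @export
collapse_labels <- function(labels, ischeme = NULL) {
  if (!is.null(ischeme)) {
    bad <- setdiff(unique(labels), ischeme$all_symbols)
    if (length(bad))
      stop("unknown induced symbol(s): ", paste(bad, collapse = ", "))
  }
  ifelse(is_outside_symbol(labels), "O", labels)
}

#' Structural transition mask of the induced state space
#'
#' Induction makes the admissible label bigrams a structural property of
#' the scheme: `"c[O]+"` can only follow an entity token of class `c` or
#' `"c[O]+"` itself; `"O[O]+"` can only follow the start state or
#' `"O[O]+"`; entity symbols obey IOB2 (`I-c` only after `B-c`/`I-c`;
#' `B-c` anywhere).  All structurally consistent transitions are allowed
#' even if unseen in training.
#'
#' @param ischeme an [build_induced_scheme()] result.
#' @return a logical matrix; rows are the emitting symbols followed by the
#'   start symbol, columns the emitting symbols; `TRUE` = allowed.
#' @export
transition_mask <- function(ischeme) {
  stopifnot(inherits(ischeme, "induced_scheme"))
  base <- ischeme$base
  syms <- ischeme$all_symbols
  n <- length(syms)
  rows <- c(syms, ischeme$start)
  mask <- matrix(FALSE, n + 1L, n, dimnames = list(rows, syms))
  sym_cls <- label_class(syms, base)        # NA for outside symbols
  out_prec <- rep(NA_character_, n)         # precursor class of c[O]+
  is_out <- is_outside_symbol(syms)
  out_prec[is_out] <- sub("\\[O\\]\\+$", "", syms[is_out])
  out_prec[syms == "O[O]+"] <- NA_character_
  for (j in seq_len(n)) {
    cur <- syms[j]
    if (is_out[j]) {
      if (cur == "O[O]+") {
        mask[ischeme$start, j] <- TRUE
        mask["O[O]+", j] <- TRUE
      } else {
        cc <- out_prec[j]
        # from an entity token of class cc, or from itself
        from <- !is_out & sym_cls == cc
        mask[seq_len(n), j] <- (from & !is.na(from)) | syms == cur
      }
    } else if (base$tagging == "iob2" && startsWith(cur, "I-")) {
      cc <- substring(cur, 3L)
      mask[c(paste0("B-", cc), paste0("I-", cc)), j] <- TRUE
    } else {
      # B-c (or bare class symbol): reachable from any state including start
      mask[, j] <- TRUE
    }
  }
  mask
}

# conventional mask over the induced symbols: tagging-scheme validity
# only (I-c after B-c/I-c), every outside variant freely reachable.
# This is the state space of a vanilla CRF that treats induced labels as
# opaque symbols -- decoded precursor chains may break.
conventional_induced_mask <- function(ischeme) {
  base <- ischeme$base
  syms <- ischeme$all_symbols
  n <- length(syms)
  mask <- matrix(TRUE, n + 1L, n,
                 dimnames = list(c(syms, ischeme$start), syms))
  if (base$tagging == "iob2") {
    for (j in seq_len(n)) {
      if (startsWith(syms[j], "I-") && !is_outside_symbol(syms[j])) {
        cc <- substring(syms[j], 3L)
        mask[, j] <- FALSE
        mask[c(paste0("B-", cc), paste0("I-", cc)), j] <- TRUE
      }
    }
  }
  mask
}

# transition mask for a plain (non-induced) scheme: IOB2 consistency only
scheme_mask <- function(scheme) {
  syms <- scheme$labels
  n <- length(syms)
  mask <- matrix(TRUE, n + 1L, n,
                 dimnames = list(c(syms, scheme$start), syms))
  if (scheme$tagging == "iob2") {
    for (j in seq_len(n)) {
      if (startsWith(syms[j], "I-")) {
        cc <- substring(syms[j], 3L)
        mask[, j] <- FALSE
        mask[c(paste0("B-", cc), paste0("I-", cc)), j] <- TRUE
      }
    }
  }
  mask
}
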