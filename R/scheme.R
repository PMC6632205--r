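#' Define a label scheme for named entity recognition
#'
#' A label scheme fixes the entity classes and the tagging convention used
#' throughout a corpus.  Under IOB2 every entity starts with a `B-class`
#' label and continues with `I-class`; non-entity tokens carry the single
#' outside label `"O"`.  Under bare tagging each class has one symbol and
#' runs of the same symbol form one entity.
#'
#' Label symbols are ordered deterministically: classes in declaration
#' order, `B-` before `I-` within a class, and `"O"` last.  The scheme also
#' carries a distinguished non-emitting start symbol used by the chain
#' models for the transition into the first token.
#'
#' @param classes character vector of entity class names (e.g.
#'   `c("problem", "test", "treatment")`).  May be empty.
#' @param tagging `"iob2"` (default) or `"bare"`.
#' @param start start-state symbol; must not collide with any label.
#' @return an object of class `label_scheme` with elements `classes`,
#'   `tagging`, `labels` (all emitting label symbols, `"O"` last) and
#'   `start`.
#' @examples
#' sch <- label_scheme(c("problem", "test", "treatment"))
#' sch$labels
#' @export
label_scheme <- function(classes = character(), tagging = c("iob2", "bare"),
                         start = "<START>") {
  tagging <- match.arg(tagging)
  classes <- as.character(classes)
  if (anyDuplicated(classes)) stop("duplicate entity class names")
  if ("O" %in% classes) stop("\"O\" is reserved for the outside label")
  if (any(grepl("\\s", classes)) || any(!nzchar(classes)))
    stop("class names must be non-empty and contain no whitespace")
  labels <- switch(tagging,
    iob2 = c(as.vector(rbind(paste0("B-", classes), paste0("I-", classes)))[
      seq_len(2 * length(classes))], "O"),
    bare = c(classes, "O"))
  if (start %in% labels) stop("start symbol collides with a label symbol")
  structure(list(classes = classes, tagging = tagging,
                 labels = labels, start = start),
            class = "label_scheme")
}

#' @export
print.label_scheme <- function(x, ...) {
  cat(sprintf("<label_scheme: %s, %d class%s>\n", x$tagging,
              length(x$classes), if (length(x$classes) == 1) "" else "es"))
  cat("  labels:", paste(x$labels, collapse = " "), "\n")
  invisible(x)
}

# class of an entity label symbol; NA for "O"
label_class <- function(labels, scheme) {
  if (scheme$tagging == "iob2") {
    cls <- sub("^[BI]-", "", labels)
    cls[!grepl("^[BI]-", labels)] <- NA_character_
  } else {
    cls <- ifelse(labels %in% scheme$classes, labels, NA_character_)
  }
  cls
}

validate_labels <- function(labels, scheme) {
  bad <- setdiff(unique(labels), scheme$labels)
  if (length(bad))
    stop("unknown label symbol(s): ", paste(bad, collapse = ", "))
  invisible(TRUE)
}

#' Repair an IOB2 label sequence
#'
#' Rewrites every `I-X` that lacks a legal predecessor (start of sentence,
#' or preceded by `O` or a label of a different class) to `B-X`.  Labels
#' are never dropped.
#'
#' @param labels character vector of IOB2 labels.
#' @param scheme a [label_scheme()].
#' @param warn emit a warning when a repair is made?
#' @return the repaired label vector.
#' @export
repair_iob2 <- function(labels, scheme, warn = TRUE) {
  validate_labels(labels, scheme)
  if (scheme$tagging != "iob2" || !length(labels)) return(labels)
  out <- labels
  prev <- "O"
  n_fix <- 0L
  for (t in seq_along(out)) {
    lab <- out[t]
    if (startsWith(lab, "I-")) {
      cls <- substring(lab, 3L)
      ok <- prev %in% c(paste0("B-", cls), paste0("I-", cls))
      if (!ok) {
        out[t] <- paste0("B-", cls)
        n_fix <- n_fix + 1L
      }
    }
    prev <- out[t]
  }
  if (n_fix && warn)
    warning(sprintf("repaired %d IOB2 violation(s) (I-X without predecessor -> B-X)",
                    n_fix))
  out
}

is_iob2_consistent <- function(labels, scheme) {
  identical(labels, suppressWarnings(repair_iob2(labels, scheme, warn = FALSE)))
}
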