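# Target sets: plain-text symbol lists, case-folded set semantics, and the
# drug x disease intersection (the Venn step).

#' Construct a target set
#'
#' @param symbols Character vector of gene symbols; trimmed, upper-cased,
#'   deduplicated.
#' @param label Free-text provenance label.
#' @return An object of class `target_set`: a list with `label`, sorted
#'   `symbols`, and the raw/unique counts seen at construction.
#' @export
target_set <- function(symbols, label = "targets") {
  symbols <- trimws(as.character(symbols))
  symbols <- symbols[nzchar(symbols)]
  raw <- length(symbols)
  symbols <- sort_c(unique(toupper(symbols)))
  structure(list(label = label, symbols = symbols,
                 n_raw = raw, n_unique = length(symbols)),
            class = "target_set")
}

#' @export
print.target_set <- function(x, ...) {
  cat(sprintf("<target_set '%s': %d symbols (%d raw)>\n",
              x$label, x$n_unique, x$n_raw))
  invisible(x)
}

#' @export
length.target_set <- function(x) length(x$symbols)

#' Load a target list from a plain-text file
#'
#' One gene symbol per line; blank lines ignored; symbols are compared
#' case-insensitively and stored upper-case so mixed-case exports from
#' different databases collide as they should. No alias or ortholog
#' resolution is attempted.
#'
#' @param path Path to the symbol list.
#' @param label Provenance label for the set.
#' @return A [target_set()].
#' @export
read_target_list <- function(path, label = basename(path)) {
  if (!file.exists(path)) {
    stop_format(sprintf("target list does not exist: '%s'", path))
  }
  lines <- readLines(path, warn = FALSE)
  ts <- target_set(lines, label = label)
  if (ts$n_unique == 0L) {
    warning(sprintf("target list '%s' is empty", path), call. = FALSE)
  }
  message(sprintf("loaded '%s': %d raw lines, %d unique symbols",
                  label, ts$n_raw, ts$n_unique))
  ts
}

#' Intersect drug and disease target sets
#'
#' The exact set intersection of predicted drug targets with disease
#' targets: the candidate targets through which the drug can act on the
#' disease. Output order is deterministic (sorted).
#'
#' @param drug,disease Two [target_set()] objects.
#' @return A [target_set()] labelled with both parents.
#' @export
intersect_targets <- function(drug, disease) {
  stopifnot(inherits(drug, "target_set"), inherits(disease, "target_set"))
  target_set(intersect(drug$symbols, disease$symbols),
             label = paste(drug$label, "&", disease$label))
}
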