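# Internal helpers: condition classes, delimited IO, seeded RNG streams.

stop_qenp <- function(msg, class, call. = FALSE) {
  stop(structure(
    class = c(class, "qenp_error", "error", "condition"),
    list(message = msg, call = if (isTRUE(call.)) sys.call(-1))
  ))
}

#' @noRd
stop_validation <- function(msg) stop_qenp(msg, "qenp_validation_error")

#' @noRd
stop_format <- function(msg) stop_qenp(msg, "qenp_format_error")

#' @noRd
stop_range <- function(msg) stop_qenp(msg, "qenp_range_error")

# Read a delimited table with an auto/tab/comma dialect switch.
# Returns a data.frame of character columns; callers coerce and validate.
read_delim_table <- function(path, dialect = c("auto", "tab", "comma")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop_format(sprintf("input file does not exist: '%s'", path))
  }
  sep <- switch(dialect, tab = "\t", comma = ",", auto = {
    first <- readLines(path, n = 1L, warn = FALSE)
    if (length(first) && !grepl("\t", first) && grepl(",", first)) "," else "\t"
  })
  utils::read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE,
                    blank.lines.skip = TRUE, comment.char = "")
}

require_columns <- function(df, cols, path) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_format(sprintf("'%s' is missing required column(s): %s",
                        path, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

as_real <- function(x, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is.na(x) & nzchar(trimws(x))
  if (any(bad)) {
    stop_format(sprintf("non-numeric value in column '%s': '%s'",
                        what, x[which(bad)[1L]]))
  }
  out
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# Locale-independent (C byte order) sorting so tie-breaks and output order
# never depend on LC_COLLATE.
sort_c <- function(x) sort(x, method = "radix")
order_c <- function(...) order(..., method = "radix")

# One pseudo-random stream per (seed, stream-name) pair, so adding a
# generator never perturbs existing fixtures. The polynomial string hash is
# kept below 2^31 - 1 at every step.
stream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- 0
  for (code in utf8ToInt(name)) h <- (h * 31 + code) %% 2147483629
  as.integer((h + (seed %% 2147483629)) %% 2147483629)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(seed, name))
  force(expr)
}
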