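#' Read a GC-MS compound composition table
#'
#' Reads a delimited table of GC-MS peaks with identities, retention times
#' and relative contents (percent of total ion current). The relative
#' content column is the `Ri` factor of the quantity-effect weight chain.
#'
#' @param path Path to a TSV/CSV file with header columns `compound_id`,
#'   `name`, `cas`, `retention_time_min`, `pct_total`. An optional
#'   `retention_index` column is carried through if present.
#' @param dialect Delimiter: `"auto"` (default; tab unless the header has
#'   commas and no tabs), `"tab"` or `"comma"`.
#' @return A `data.frame` with columns `compound_id`, `name`, `cas`,
#'   `retention_time_min`, `retention_index` (NA where not supplied) and
#'   `pct_total`, one row per input row in file order.
#' @details Validation: `compound_id` must be unique and non-empty,
#'   retention times strictly positive, contents non-negative, and the
#'   content column must not sum above 100 (tolerance 1e-6). CAS may be
#'   blank. Contents are *not* renormalised to sum to 100: downstream
#'   weight arithmetic is scale-invariant, so the table is taken as
#'   printed.
#' @export
read_compound_table <- function(path, dialect = c("auto", "tab", "comma")) {
  df <- read_delim_table(path, dialect)
  cols <- c("compound_id", "name", "cas", "retention_time_min", "pct_total")
  require_columns(df, cols, path)
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    name = trimws(df$name),
    cas = trimws(df$cas),
    retention_time_min = as_real(df$retention_time_min, "retention_time_min"),
    retention_index = if ("retention_index" %in% names(df)) {
      as_real(df$retention_index, "retention_index")
    } else rep(NA_real_, nrow(df)),
    pct_total = as_real(df$pct_total, "pct_total"),
    stringsAsFactors = FALSE
  )
  validate_compound_table(out)
  out
}

validate_compound_table <- function(df) {
  if (!nrow(df)) return(invisible(df))
  if (anyNA(df$retention_time_min) || any(df$retention_time_min <= 0)) {
    stop_validation("retention_time_min must be strictly positive for every compound")
  }
  if (anyNA(df$pct_total) || any(df$pct_total < 0)) {
    stop_validation("pct_total must be a non-negative real for every compound")
  }
  if (sum(df$pct_total) > 100 + 1e-6) {
    stop_validation(sprintf(
      "pct_total sums to %.6f, above the 100%% budget", sum(df$pct_total)))
  }
  dup <- df$compound_id[duplicated(df$compound_id)]
  if (length(dup)) {
    stop_validation(sprintf("duplicate compound_id: %s",
                            paste(unique(dup), collapse = ", ")))
  }
  if (any(!nzchar(df$compound_id))) stop_validation("empty compound_id")
  invisible(df)
}

#' Read an n-alkane retention-time ladder
#'
#' @param path TSV with header `carbon_number`, `retention_time_min`.
#' @return A `data.frame` with integer `carbon_number` and numeric
#'   `retention_time_min`, both strictly increasing.
#' @details Carbon numbers must lie in the C8-C40 range conventionally run
#'   alongside essential-oil GC-MS programmes.
#' @export
read_alkane_ladder <- function(path) {
  df <- read_delim_table(path, "tab")
  require_columns(df, c("carbon_number", "retention_time_min"), path)
  out <- data.frame(
    carbon_number = as.integer(as_real(df$carbon_number, "carbon_number")),
    retention_time_min = as_real(df$retention_time_min, "retention_time_min"),
    stringsAsFactors = FALSE
  )
  validate_alkane_ladder(out)
  out
}

validate_alkane_ladder <- function(ladder) {
  if (nrow(ladder) < 2L) stop_validation("alkane ladder needs at least 2 entries")
  if (any(ladder$carbon_number < 8L) || any(ladder$carbon_number > 40L)) {
    stop_validation("alkane carbon numbers must lie within C8-C40")
  }
  if (any(diff(ladder$carbon_number) <= 0)) {
    stop_validation("alkane carbon numbers must be strictly increasing")
  }
  if (any(diff(ladder$retention_time_min) <= 0)) {
    stop_validation("alkane retention times must be strictly increasing")
  }
  invisible(ladder)
}

#' Kovats retention index of one analyte
#'
#' Linear interpolation of the analyte's retention time between the
#' bracketing n-alkanes: `RI = 100 n + 100 (t_x - t_n) / (t_{n+1} - t_n)`
#' for an analyte eluting between alkanes Cn and Cn+1. When the ladder
#' skips carbons the multiplier generalises to `100 (n' - n)` where n' is
#' the next ladder carbon; for consecutive alkanes this is the textbook
#' formula unchanged.
#'
#' @param rt_x Analyte retention time in minutes.
#' @param ladder Alkane ladder `data.frame` (see [read_alkane_ladder()]).
#' @return The dimensionless retention index. An analyte coinciding with an
#'   alkane returns exactly `100 * carbon_number`.
#' @details No extrapolation: a retention time outside the ladder span is an
#'   error, not a clamp.
#' @export
compute_retention_index <- function(rt_x, ladder) {
  validate_alkane_ladder(ladder)
  stopifnot(is.numeric(rt_x), length(rt_x) == 1L)
  rts <- ladder$retention_time_min
  carbons <- ladder$carbon_number
  if (rt_x < rts[1L] || rt_x > rts[length(rts)]) {
    stop_range(sprintf(
      "retention time %.4f min outside ladder span [%.4f, %.4f]",
      rt_x, rts[1L], rts[length(rts)]))
  }
  hit <- which(rts == rt_x)
  if (length(hit)) return(100 * carbons[hit[1L]])
  n <- findInterval(rt_x, rts)  # rts[n] < rt_x < rts[n + 1]
  frac <- (rt_x - rts[n]) / (rts[n + 1L] - rts[n])
  100 * carbons[n] + 100 * (carbons[n + 1L] - carbons[n]) * frac
}

#' Annotate a compound table with retention indices
#'
#' @param compounds Compound table from [read_compound_table()].
#' @param ladder Alkane ladder from [read_alkane_ladder()].
#' @return The compound table with `retention_index` filled in, row order
#'   preserved.
#' @export
annotate_retention_indices <- function(compounds, ladder) {
  validate_compound_table(compounds)
  if (!nrow(compounds)) return(compounds)
  ri <- vapply(seq_len(nrow(compounds)), function(i) {
    tryCatch(
      compute_retention_index(compounds$retention_time_min[i], ladder),
      qenp_range_error = function(e) {
        stop_range(sprintf("compound '%s': %s",
                           compounds$compound_id[i], conditionMessage(e)))
      })
  }, numeric(1))
  compounds$retention_index <- ri
  compounds
}
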