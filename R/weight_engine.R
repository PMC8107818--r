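# Quantity-effect weight chain: Ci = Ri * Oi per compound, Ti = sum of Ci
# over compounds hitting target i, P = sum of Ti over a pathway's scored
# members, and weight-based re-ranking of enrichment rows. All sums are
# linear in Ri, so every ranking downstream is invariant to the content
# scale (percent vs fraction).

#' Normalise an oral-bioavailability value to a probability
#'
#' OB sources report either fractions (0-1) or percentages (0-100); this
#' maps both onto \[0, 1\].
#'
#' @param raw_ob Non-negative numeric vector of raw OB values.
#' @param scale_hint `"fraction"` (pass through, must be <= 1), `"percent"`
#'   (divide by 100), or `"auto"` (divide by 100 only when the value
#'   exceeds 1).
#' @return Numeric vector of probabilities in \[0, 1\].
#' @export
normalize_ob <- function(raw_ob, scale_hint = c("auto", "fraction", "percent")) {
  scale_hint <- match.arg(scale_hint)
  if (anyNA(raw_ob) || any(raw_ob < 0)) {
    stop_validation("oral bioavailability must be non-negative and non-missing")
  }
  out <- switch(scale_hint,
    fraction = {
      if (any(raw_ob > 1)) {
        stop_validation("OB > 1 is not a fraction; use scale_hint = 'percent' or 'auto'")
      }
      raw_ob
    },
    percent = raw_ob / 100,
    auto = ifelse(raw_ob > 1, raw_ob / 100, raw_ob)
  )
  if (any(out > 1)) stop_validation("OB above 100% after normalisation")
  out
}

#' Read an oral-bioavailability table
#'
#' @param path TSV with header `compound_id`, `ob`.
#' @param scale_hint Passed to [normalize_ob()].
#' @return `data.frame` with `compound_id` and normalised `ob` in \[0, 1\].
#' @export
read_ob_table <- function(path, scale_hint = c("auto", "fraction", "percent")) {
  df <- read_delim_table(path, "tab")
  require_columns(df, c("compound_id", "ob"), path)
  out <- data.frame(
    compound_id = trimws(df$compound_id),
    ob = normalize_ob(as_real(df$ob, "ob"), match.arg(scale_hint)),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$compound_id)) {
    stop_validation("duplicate compound_id in OB table")
  }
  out
}

#' Component weight coefficients Ci = Ri * Oi
#'
#' The per-component weight is the product of relative content (`pct_total`,
#' the paper-style percent of total) and oral bioavailability, a proxy for
#' the amount of the component reaching systemic circulation.
#'
#' @param compounds Compound table (see [read_compound_table()]).
#' @param ob_table `data.frame` with `compound_id`, `ob` in \[0, 1\].
#' @param missing_ob_policy What to do with compounds lacking an OB record:
#'   `"error"` (default), `"drop"`, or `"default"` (substitute
#'   `default_ob`).
#' @param default_ob OB substituted under `missing_ob_policy = "default"`.
#' @return `data.frame` with columns `compound_id`, `ri`, `ob`, `ci`,
#'   sorted by descending `ci`, ties broken by `compound_id`.
#' @export
compute_component_weights <- function(compounds, ob_table,
                                      missing_ob_policy = c("error", "drop", "default"),
                                      default_ob = NULL) {
  missing_ob_policy <- match.arg(missing_ob_policy)
  validate_compound_table(compounds)
  if (anyDuplicated(ob_table$compound_id)) {
    stop_validation("duplicate compound_id in OB table")
  }
  if (anyNA(ob_table$ob) || any(ob_table$ob < 0) || any(ob_table$ob > 1)) {
    stop_validation("OB values must lie in [0, 1]; run normalize_ob() first")
  }
  idx <- match(compounds$compound_id, ob_table$compound_id)
  ob <- ob_table$ob[idx]
  missing <- is.na(idx)
  if (any(missing)) {
    if (missing_ob_policy == "error") {
      stop_validation(sprintf(
        "no OB record for compound(s): %s",
        paste(compounds$compound_id[missing], collapse = ", ")))
    }
    if (missing_ob_policy == "default") {
      if (is.null(default_ob) || default_ob < 0 || default_ob > 1) {
        stop_validation("missing_ob_policy = 'default' needs default_ob in [0, 1]")
      }
      ob[missing] <- default_ob
    }
  }
  keep <- if (missing_ob_policy == "drop") !missing else rep(TRUE, nrow(compounds))
  out <- data.frame(
    compound_id = compounds$compound_id[keep],
    ri = compounds$pct_total[keep],
    ob = ob[keep],
    ci = compounds$pct_total[keep] * ob[keep],
    stringsAsFactors = FALSE
  )
  out[order_c(-out$ci, out$compound_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Target weight coefficients Ti
#'
#' `Ti` for a protein target is the sum of `Ci` over the distinct compounds
#' mapped to it ("cumulative target" weight); a repeated compound-target
#' edge counts once.
#'
#' @param weights Component weights from [compute_component_weights()].
#' @param mapping `data.frame` with `compound_id`, `target_symbol` edges.
#' @param strict Error on mapping rows whose `compound_id` has no weight
#'   (`TRUE`, default) or drop them silently.
#' @return `data.frame` with `target_symbol` (upper-cased) and `ti`, one
#'   row per distinct target with at least one weighted compound, sorted by
#'   descending `ti` then symbol.
#' @export
aggregate_target_weights <- function(weights, mapping, strict = TRUE) {
  mapping <- normalize_target_map(mapping)
  unknown <- setdiff(unique(mapping$compound_id), weights$compound_id)
  if (length(unknown)) {
    if (strict) {
      stop_validation(sprintf("mapping references unknown compound_id(s): %s",
                              paste(unknown, collapse = ", ")))
    }
    mapping <- mapping[!(mapping$compound_id %in% unknown), , drop = FALSE]
  }
  if (!nrow(mapping)) {
    return(data.frame(target_symbol = character(), ti = numeric(),
                      stringsAsFactors = FALSE))
  }
  ci <- weights$ci[match(mapping$compound_id, weights$compound_id)]
  agg <- tapply(ci, mapping$target_symbol, sum)
  out <- data.frame(target_symbol = names(agg), ti = as.numeric(agg),
                    stringsAsFactors = FALSE)
  out[order_c(-out$ti, out$target_symbol), , drop = FALSE] |>
    `rownames<-`(NULL)
}

# Upper-case symbols, trim, drop duplicate edges; endpoints must be non-empty.
normalize_target_map <- function(mapping) {
  require_columns(mapping, c("compound_id", "target_symbol"), "compound-target map")
  out <- data.frame(
    compound_id = trimws(mapping$compound_id),
    target_symbol = toupper(trimws(mapping$target_symbol)),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$compound_id)) || any(!nzchar(out$target_symbol))) {
    stop_validation("compound-target map has empty endpoints")
  }
  unique(out)
}

#' Pathway weight P for one member set
#'
#' `P` is the sum of `Ti` over the pathway's member targets that carry a
#' score; members without a target weight contribute zero.
#'
#' @param target_weights `data.frame` from [aggregate_target_weights()].
#' @param members Character vector of member gene symbols.
#' @return A single non-negative number.
#' @export
aggregate_pathway_weight <- function(target_weights, members) {
  members <- toupper(trimws(members))
  sum(target_weights$ti[target_weights$target_symbol %in% members])
}

#' Re-rank enrichment rows by pathway weight
#'
#' Sorts enrichment rows by descending pathway weight, breaking ties by
#' ascending p-value and then `set_id`, and assigns `rank_after`. Both the
#' p-value rank (`rank_before`) and the weight rank are retained, so runs
#' are fully reproducible.
#'
#' @param rows `data.frame` with at least `set_id`, `p_value`, `p_weight`,
#'   `rank_before`.
#' @return The rows sorted into weight order with `rank_after` = 1..m.
#' @export
rerank_by_weight <- function(rows) {
  require_columns(rows, c("set_id", "p_value", "p_weight", "rank_before"),
                  "enrichment rows")
  ord <- order_c(-rows$p_weight, rows$p_value, rows$set_id)
  out <- rows[ord, , drop = FALSE]
  out$rank_after <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Before/after rank-shift table
#'
#' @param rows Re-ranked enrichment rows (see [rerank_by_weight()]).
#' @return `data.frame` with `set_id`, `rank_before`, `rank_after` and
#'   `delta = rank_before - rank_after` (positive = promoted by the weight),
#'   sorted by descending `delta`.
#' @export
rank_shift_report <- function(rows) {
  require_columns(rows, c("set_id", "rank_before", "rank_after"),
                  "re-ranked rows")
  out <- data.frame(
    set_id = rows$set_id,
    rank_before = rows$rank_before,
    rank_after = rows$rank_after,
    delta = rows$rank_before - rows$rank_after,
    stringsAsFactors = FALSE
  )
  out[order_c(-out$delta, out$set_id), , drop = FALSE] |>
    `rownames<-`(NULL)
}
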