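# Self-contained over-representation analysis: GMT collections, the
# hypergeometric upper tail, Benjamini-Hochberg adjustment, and the
# weight-based re-ranking that is the point of the quantity-effect method.

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: `set_id<TAB>description<TAB>member...`, one
#' set per line, at least one member per set. Members are upper-cased and
#' deduplicated; line order is preserved.
#'
#' @param path Path to the GMT file.
#' @param namespace Label for the collection (`"pathway"`, `"BP"`, `"CC"`,
#'   `"MF"`, ...). GO namespaces are loaded as separate collections and
#'   ranked independently.
#' @return An object of class `gene_set_collection`: a named list of sets,
#'   each a list with `set_id`, `description`, `members`.
#' @export
read_gmt <- function(path, namespace = "pathway") {
  if (!file.exists(path)) stop_format(sprintf("GMT file does not exist: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_format(sprintf("GMT file '%s' contains no sets", path))
  sets <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop_format(sprintf("GMT line %d: expected >= 3 tab-separated fields, got %d",
                          i, length(fields)))
    }
    members <- unique(toupper(trimws(fields[-(1:2)])))
    members <- members[nzchar(members)]
    if (!length(members)) {
      stop_format(sprintf("GMT line %d: set '%s' has no members", i, fields[1]))
    }
    ids[i] <- trimws(fields[1])
    sets[[i]] <- list(set_id = ids[i], description = trimws(fields[2]),
                      members = members)
  }
  if (anyDuplicated(ids)) {
    stop_format(sprintf("duplicate set_id in GMT: %s",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  names(sets) <- ids
  structure(sets, class = "gene_set_collection", namespace = namespace)
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection [%s]: %d sets>\n",
              attr(x, "namespace"), length(x)))
  invisible(x)
}

collection_universe <- function(collection) {
  sort_c(unique(unlist(lapply(collection, `[[`, "members"), use.names = FALSE)))
}

#' Upper-tail hypergeometric p-value for over-representation
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` genes (the
#' hit list) from a universe of `N` of which `K` belong to the set, the
#' probability of an overlap at least as large as the one observed.
#' Delegates to the log-space-stable `stats::phyper` upper tail.
#'
#' @param k Observed overlap. @param n Hit-list size. @param K Set size in
#'   the universe. @param N Universe size.
#' @return The p-value in (0, 1].
#' @export
hypergeometric_p <- function(k, n, K, N) {
  ok <- k >= 0 & n >= 0 & K >= 0 & n <= N & K <= N & k <= pmin(n, K)
  if (anyNA(ok) || !all(ok)) {
    stop_validation("inconsistent counts: need 0 <= k <= min(n, K) and n, K <= N")
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p_values Numeric vector of raw p-values in (0, 1].
#' @return Adjusted values, clipped at 1, in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric())
  if (anyNA(p_values) || any(p_values <= 0) || any(p_values > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  m <- length(p_values)
  o <- order(p_values, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p_values[o]))[ro]
}

#' Over-representation analysis of a hit list
#'
#' Tests each gene set for enrichment of the hit list against the universe
#' with the upper-tail hypergeometric test, BH-adjusts across the tested
#' sets, and ranks by ascending p-value (`rank_before`, ties broken by
#' `set_id`). Sets with zero overlap are excluded: they carry no pathway
#' weight and only enriched terms are reported.
#'
#' @param hits [target_set()] of query genes (e.g. drug-on-disease targets).
#' @param collection [read_gmt()] collection.
#' @param universe Optional [target_set()] background; defaults to every
#'   symbol annotated in the collection. Hits outside the universe are
#'   dropped with a message.
#' @param min_size,max_size In-universe set-size gates (defaults 5, 500).
#' @param rank_on Rank `rank_before` on raw (`"p_value"`, default) or
#'   BH-adjusted (`"p_adjusted"`) values.
#' @return `data.frame` with `set_id`, `description`, `k`, `n`, `K`, `N`,
#'   `p_value`, `p_adjusted`, `rank_before`, sorted by `rank_before`.
#' @export
run_ora <- function(hits, collection, universe = NULL,
                    min_size = 5L, max_size = 500L,
                    rank_on = c("p_value", "p_adjusted")) {
  rank_on <- match.arg(rank_on)
  stopifnot(inherits(hits, "target_set"), inherits(collection, "gene_set_collection"))
  bg <- if (is.null(universe)) collection_universe(collection) else {
    stopifnot(inherits(universe, "target_set"))
    universe$symbols
  }
  if (!length(bg)) stop_validation("empty universe")
  N <- length(bg)
  hit_syms <- intersect(hits$symbols, bg)
  dropped <- length(hits$symbols) - length(hit_syms)
  if (dropped > 0) {
    message(sprintf("%d hit symbol(s) outside the universe dropped", dropped))
  }
  n <- length(hit_syms)
  rows <- lapply(collection, function(s) {
    members <- intersect(s$members, bg)
    K <- length(members)
    if (K < min_size || K > max_size) return(NULL)
    k <- length(intersect(hit_syms, members))
    if (k == 0L) return(NULL)
    data.frame(set_id = s$set_id, description = s$description,
               k = k, n = n, K = K, N = N,
               p_value = hypergeometric_p(k, n, K, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || !nrow(out)) {
    return(data.frame(set_id = character(), description = character(),
                      k = integer(), n = integer(), K = integer(), N = integer(),
                      p_value = numeric(), p_adjusted = numeric(),
                      rank_before = integer(), stringsAsFactors = FALSE))
  }
  out$p_adjusted <- bh_adjust(out$p_value)
  key <- if (rank_on == "p_value") out$p_value else out$p_adjusted
  out <- out[order_c(key, out$set_id), , drop = FALSE]
  out$rank_before <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Enrich and re-rank by the quantity-effect pathway weight
#'
#' Runs [run_ora()], attaches to each enriched set its pathway weight `P`
#' (the sum of target weights `Ti` over the set's members that are also
#' hits, or over all annotated members with `members_scope = "annotated"`),
#' re-ranks by descending weight, and reports the rank shift.
#'
#' @inheritParams run_ora
#' @param target_weights `data.frame` from [aggregate_target_weights()].
#' @param top_m Number of top rows (in weight order) returned; default 30.
#' @param members_scope Sum `Ti` over `"hits"` (members that are hits;
#'   default, "target scores participating in the pathway") or all
#'   `"annotated"` members.
#' @return `data.frame` of the top `top_m` rows with `p_weight`,
#'   `rank_before`, `rank_after` and `delta` columns.
#' @export
enrich_and_rerank <- function(hits, target_weights, collection,
                              universe = NULL, min_size = 5L, max_size = 500L,
                              top_m = 30L,
                              members_scope = c("hits", "annotated"),
                              rank_on = c("p_value", "p_adjusted")) {
  members_scope <- match.arg(members_scope)
  ora <- run_ora(hits, collection, universe, min_size, max_size,
                 rank_on = match.arg(rank_on))
  if (!nrow(ora)) {
    ora$p_weight <- numeric()
    ora$rank_after <- integer()
    ora$delta <- integer()
    return(ora)
  }
  hit_syms <- toupper(hits$symbols)
  ora$p_weight <- vapply(ora$set_id, function(id) {
    members <- collection[[id]]$members
    if (members_scope == "hits") members <- intersect(members, hit_syms)
    aggregate_pathway_weight(target_weights, members)
  }, numeric(1))
  out <- rerank_by_weight(ora)
  out$delta <- out$rank_before - out$rank_after
  utils::head(out, top_m)
}
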