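# Seeded generators for every pipeline input: compound tables with a
# Table-2-like skewed composition, OB tables, compound-target maps,
# disease lists, gene-set collections with one planted pathway, and scored
# PPI edge lists. Each generator draws from its own RNG stream derived
# from (seed, generator name), so adding a generator never perturbs the
# fixtures another one emits. Fixture symbols live in a reserved namespace
# (T0001..., D0001...) to avoid colliding with real gene symbols.

#' Specification of a synthetic fixture world
#'
#' @param seed Integer master seed; the same spec (including seed) yields
#'   byte-identical fixtures.
#' @param n_compounds Number of GC-MS components (default 19, the size of
#'   a typical essential-oil profile).
#' @param n_targets Size of the predicted-target namespace (T0001...).
#' @param n_disease_targets Size of the disease target list.
#' @param overlap_fraction Fraction of the disease list drawn from targets
#'   actually mapped to compounds (drives the Venn intersection size).
#' @param n_sets Number of gene sets in the collection (set 1 is planted).
#' @param set_size_range Integer range of set sizes.
#' @param content_concentration Dirichlet concentration of the relative
#'   contents: small values give a few dominant components and a long tail
#'   (0.3 mimics a composition where the top component holds ~20%);
#'   `Inf` gives exactly equal contents.
#' @param ob_range Range the OB values are drawn from / mapped into.
#' @param planted_set_fraction Fraction of the planted pathway's members
#'   drawn from targets of the top-content x top-OB compounds.
#' @param ob_correlated If `TRUE`, OB increases with relative content (the
#'   planted "quantity-effect" signal); if `FALSE`, OB is uniform on
#'   `ob_range` independent of content.
#' @param mean_targets_per_compound Mean out-degree of the bipartite map.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_compounds = 19L, n_targets = 150L,
                         n_disease_targets = 120L, overlap_fraction = 0.7,
                         n_sets = 20L, set_size_range = c(10L, 30L),
                         content_concentration = 0.3, ob_range = c(0.2, 0.9),
                         planted_set_fraction = 0.9, ob_correlated = TRUE,
                         mean_targets_per_compound = 12) {
  stopifnot(n_compounds >= 1, n_targets >= 1,
            overlap_fraction >= 0, overlap_fraction <= 1,
            planted_set_fraction >= 0, planted_set_fraction <= 1,
            length(set_size_range) == 2L, set_size_range[1] <= set_size_range[2],
            length(ob_range) == 2L, ob_range[1] >= 0, ob_range[2] <= 1,
            ob_range[1] <= ob_range[2],
            content_concentration > 0)
  structure(as.list(environment()), class = "fixture_spec")
}

#' Generate a synthetic compound table
#'
#' Relative contents are a symmetric Dirichlet draw (gamma normalisation)
#' scaled to sum to exactly 100; retention times are strictly increasing
#' over a 4-18 min window, the span of a typical essential-oil GC run.
#'
#' @param spec A [fixture_spec()].
#' @return A compound table `data.frame` (see [read_compound_table()]).
#' @export
gen_compound_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- spec$n_compounds
  with_stream(spec$seed, "compound_table", {
    shares <- if (is.infinite(spec$content_concentration)) rep(1, n) else
      stats::rgamma(n, shape = spec$content_concentration)
    if (sum(shares) == 0) shares <- rep(1, n)
    pct <- shares / sum(shares) * 100
    rt <- sort(stats::runif(n, 4, 18))
    data.frame(
      compound_id = sprintf("cmp%02d", seq_len(n)),
      name = sprintf("Synthetic compound %02d", seq_len(n)),
      cas = "",
      retention_time_min = rt,
      retention_index = NA_real_,
      pct_total = pct,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a synthetic OB table
#'
#' @param spec A [fixture_spec()].
#' @param compounds Compound table the OBs are for (defaults to
#'   `gen_compound_table(spec)`).
#' @return `data.frame` with `compound_id`, `ob`.
#' @details With `ob_correlated = TRUE` the OB of a compound rises with its
#'   content rank (plus a little noise), planting the quantity-effect
#'   signal; otherwise OB is uniform on `ob_range`.
#' @export
gen_ob_table <- function(spec, compounds = gen_compound_table(spec)) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- nrow(compounds)
  lo <- spec$ob_range[1]; hi <- spec$ob_range[2]
  with_stream(spec$seed, "ob_table", {
    ob <- if (spec$ob_correlated) {
      frac <- (rank(compounds$pct_total, ties.method = "first") - 0.5) / n
      pmin(hi, pmax(lo, lo + (hi - lo) * frac + stats::runif(n, -0.05, 0.05)))
    } else {
      stats::runif(n, lo, hi)
    }
    data.frame(compound_id = compounds$compound_id, ob = ob,
               stringsAsFactors = FALSE)
  })
}

#' Generate the target universe: mapping, disease list, gene sets
#'
#' Builds a bipartite compound-target map (Poisson out-degrees, minimum 1),
#' a disease target list overlapping the mapped targets by
#' `overlap_fraction` (the remainder from a disease-only `D####`
#' namespace), and a gene-set collection whose first set (`SET_PLANTED`)
#' draws `planted_set_fraction` of its members from targets of the
#' top-quartile compounds by `ci = pct * ob`; every other set is drawn
#' uniformly from the mapped-target pool, so in a world without a content
#' signal the planted set is statistically exchangeable with the rest.
#'
#' @param spec A [fixture_spec()].
#' @param compounds,ob_table Optional pre-generated inputs (regenerated
#'   from `spec` when omitted, so calls compose deterministically).
#' @return A list with `mapping` (edge `data.frame`), `disease`
#'   ([target_set()]), `collection` ([read_gmt()]-style collection),
#'   `universe` ([target_set()] of all symbols the collection annotates),
#'   plus the `compounds` and `ob_table` used.
#' @export
gen_target_universe <- function(spec, compounds = gen_compound_table(spec),
                                ob_table = gen_ob_table(spec, compounds)) {
  stopifnot(inherits(spec, "fixture_spec"))
  n <- nrow(compounds)
  pool <- sprintf("T%04d", seq_len(spec$n_targets))

  mapping <- with_stream(spec$seed, "mapping", {
    deg <- pmax(1L, stats::rpois(n, spec$mean_targets_per_compound))
    deg <- pmin(deg, spec$n_targets)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(compound_id = compounds$compound_id[i],
                 target_symbol = sample(pool, deg[i]),
                 stringsAsFactors = FALSE)
    }))
  })
  mapped <- sort_c(unique(mapping$target_symbol))

  disease <- with_stream(spec$seed, "disease", {
    n_overlap <- round(spec$overlap_fraction * spec$n_disease_targets)
    if (n_overlap > length(mapped)) {
      stop_validation(sprintf(
        "overlap_fraction %.2f demands %d shared targets but only %d are mapped",
        spec$overlap_fraction, n_overlap, length(mapped)))
    }
    shared <- sample(mapped, n_overlap)
    extra <- sprintf("D%04d", seq_len(spec$n_disease_targets - n_overlap))
    target_set(c(shared, extra), label = "synthetic disease targets")
  })

  # Rank by relative content (ties by id), not realized ci: under a flat
  # composition the planted pool must stay independent of the OB draw, or
  # the "no signal" world would still carry a signal.
  top_ids <- compounds$compound_id[order_c(-compounds$pct_total,
                                         compounds$compound_id)]
  top_ids <- top_ids[seq_len(max(1L, ceiling(n / 4)))]
  top_pool <- sort_c(unique(mapping$target_symbol[mapping$compound_id %in% top_ids]))

  collection <- with_stream(spec$seed, "collection", {
    sizes <- sample(seq(spec$set_size_range[1], spec$set_size_range[2]),
                    spec$n_sets, replace = TRUE)
    sizes <- pmin(sizes, length(mapped))
    sets <- vector("list", spec$n_sets)
    n_planted <- min(round(spec$planted_set_fraction * sizes[1]),
                     length(top_pool))
    planted <- sample(top_pool, n_planted)
    rest <- sample(setdiff(mapped, planted),
                   min(sizes[1] - n_planted, length(mapped) - n_planted))
    sets[[1]] <- list(set_id = "SET_PLANTED",
                      description = "planted quantity-effect pathway",
                      members = sort_c(unique(c(planted, rest))))
    for (j in seq_len(spec$n_sets)[-1]) {
      sets[[j]] <- list(set_id = sprintf("SET%02d", j),
                        description = sprintf("synthetic set %02d", j),
                        members = sort_c(sample(mapped, sizes[j])))
    }
    names(sets) <- vapply(sets, `[[`, "", "set_id")
    structure(sets, class = "gene_set_collection", namespace = "pathway")
  })

  list(mapping = mapping, disease = disease, collection = collection,
       universe = target_set(collection_universe(collection),
                             label = "synthetic universe"),
       compounds = compounds, ob_table = ob_table)
}

#' Generate a scored synthetic PPI network
#'
#' Erdos-Renyi edges over the target set: each unordered pair enters
#' independently with probability `density`, with a Uniform(0, 1)
#' confidence score.
#'
#' @param targets A [target_set()] or character vector of node symbols.
#' @param density Edge-inclusion probability in \[0, 1\].
#' @param seed Integer seed (its own `"ppi"` stream).
#' @return Undirected `igraph` with a `score` edge attribute; nodes with no
#'   edges are kept.
#' @export
gen_ppi_edges <- function(targets, density, seed = 1L) {
  syms <- if (inherits(targets, "target_set")) targets$symbols else
    sort_c(unique(toupper(targets)))
  stopifnot(density >= 0, density <= 1)
  with_stream(seed, "ppi", {
    g <- igraph::make_empty_graph(length(syms), directed = FALSE)
    igraph::V(g)$name <- syms
    if (length(syms) >= 2L && density > 0) {
      pairs <- utils::combn(syms, 2L)
      keep <- stats::runif(ncol(pairs)) < density
      if (density == 1) keep[] <- TRUE
      if (any(keep)) {
        g <- igraph::add_edges(g, as.vector(pairs[, keep, drop = FALSE]))
        igraph::E(g)$score <- stats::runif(sum(keep))
      }
    }
    g
  })
}

#' Write a complete demo workspace of fixtures
#'
#' Emits every file the pipeline consumes, in the dialects the readers
#' expect: `compounds.tsv`, `alkane_ladder.tsv`, `ob.tsv`,
#' `compound_targets.tsv`, `disease_targets.txt`, `gene_sets.gmt`,
#' `ppi_edges.tsv`. Same spec, same bytes.
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory (created if needed).
#' @param ppi_density Density of the synthetic PPI graph (default 0.3).
#' @return Invisibly, a named character vector of the paths written.
#' @export
write_fixture_workspace <- function(spec, dir, ppi_density = 0.3) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  world <- gen_target_universe(spec)
  fmt <- function(x) sprintf("%.6f", x)
  paths <- c(
    compounds = file.path(dir, "compounds.tsv"),
    ladder = file.path(dir, "alkane_ladder.tsv"),
    ob = file.path(dir, "ob.tsv"),
    mapping = file.path(dir, "compound_targets.tsv"),
    disease = file.path(dir, "disease_targets.txt"),
    gmt = file.path(dir, "gene_sets.gmt"),
    ppi = file.path(dir, "ppi_edges.tsv")
  )
  cmp <- world$compounds
  write_tsv(data.frame(compound_id = cmp$compound_id, name = cmp$name,
                       cas = cmp$cas,
                       retention_time_min = fmt(cmp$retention_time_min),
                       pct_total = fmt(cmp$pct_total)),
            paths[["compounds"]])
  # ladder spanning the generated RT window (C8-C22, 1 carbon per minute)
  carbons <- 8:22
  write_tsv(data.frame(carbon_number = carbons,
                       retention_time_min = fmt(seq(3.5, by = 1.05,
                                                    length.out = length(carbons)))),
            paths[["ladder"]])
  write_tsv(data.frame(compound_id = world$ob_table$compound_id,
                       ob = fmt(world$ob_table$ob)),
            paths[["ob"]])
  write_tsv(world$mapping, paths[["mapping"]])
  writeLines(world$disease$symbols, paths[["disease"]])
  writeLines(vapply(world$collection, function(s) {
    paste(c(s$set_id, s$description, s$members), collapse = "\t")
  }, ""), paths[["gmt"]])
  ppi <- gen_ppi_edges(world$universe, ppi_density, seed = spec$seed)
  el <- igraph::as_edgelist(ppi)
  write_tsv(data.frame(node_a = el[, 1], node_b = el[, 2],
                       score = fmt(igraph::E(ppi)$score)),
            paths[["ppi"]])
  invisible(paths)
}
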