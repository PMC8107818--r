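# GMT parsing, the hypergeometric ORA, BH, and weight-aware re-ranking.

test_that("GMT parsing deduplicates members and reports bad lines", {
  gmt <- read_gmt(write_lines_tmp("S1\tdesc\tA\tB\ta", ".gmt"))
  expect_equal(gmt[["S1"]]$members, c("A", "B"))

  expect_error(read_gmt(write_lines_tmp(character(), ".gmt")),
               class = "qenp_format_error")
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S2\tdesc-only"), ".gmt")),
               regexp = "line 2", class = "qenp_format_error")
  expect_error(read_gmt(write_lines_tmp(c("S1\td\tA", "S1\td\tB"), ".gmt")),
               class = "qenp_format_error")

  three <- read_gmt(write_lines_tmp(
    c("S1\tfirst\tA\tB", "S2\tsecond\tB\tC\tD", "S3\tthird\tE"), ".gmt"),
    namespace = "BP")
  expect_equal(length(three), 3L)
  expect_equal(three[["S2"]]$members, c("B", "C", "D"))
  expect_equal(attr(three, "namespace"), "BP")
})

test_that("hypergeometric upper tail matches combinatorial enumeration", {
  expect_equal(hypergeometric_p(0, 5, 4, 10), 1.0)
  expect_equal(hypergeometric_p(5, 5, 10, 10), 1.0)  # set equals universe
  expect_equal(hypergeometric_p(3, 5, 4, 10), 66 / 252)
  expect_equal(hypergeometric_p(3, 5, 4, 10), oracle_hypergeom(3, 5, 4, 10))
  expect_error(hypergeometric_p(5, 4, 4, 10), class = "qenp_validation_error")
  expect_error(hypergeometric_p(1, 4, 11, 10), class = "qenp_validation_error")
})

test_that("BH adjustment equals the hand step-up rule", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.4, 7)), rep(0.4, 7))
  expect_error(bh_adjust(c(0.5, 0)), class = "qenp_validation_error")
  expect_error(bh_adjust(c(0.5, 1.2)), class = "qenp_validation_error")

  set.seed(8)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p))
    expect_equal(adj, stats::p.adjust(p, "BH"))
    expect_true(all(adj >= p - 1e-15))
    # monotone when input sorted ascending
    expect_true(all(diff(bh_adjust(sort(p))) >= -1e-15))
  }
})

mk_collection <- function(sets, namespace = "pathway") {
  out <- lapply(names(sets), function(id) {
    list(set_id = id, description = id, members = sets[[id]])
  })
  names(out) <- names(sets)
  structure(out, class = "gene_set_collection", namespace = namespace)
}

test_that("ORA tests gated sets, excludes k = 0, and ranks by p", {
  uni_syms <- sprintf("G%02d", 1:15)
  coll <- mk_collection(list(
    S1 = uni_syms[1:6], S2 = uni_syms[4:11], S3 = uni_syms[10:15],
    TINY = uni_syms[1:2]))                      # gated out by min_size
  hits <- target_set(uni_syms[1:5], "hits")
  res <- suppressMessages(run_ora(hits, coll, min_size = 5, max_size = 10))
  expect_false("TINY" %in% res$set_id)
  expect_false("S3" %in% res$set_id)            # zero overlap excluded
  expect_equal(res$rank_before, seq_len(nrow(res)))
  expect_equal(res$set_id[1], "S1")             # maximal overlap dominates
  # every p equals the enumeration oracle at this universe size (N = 15)
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 oracle_hypergeom(res$k[i], res$n[i], res$K[i], res$N[i]),
                 tolerance = 1e-12)
  }
  expect_true(all(res$p_adjusted >= res$p_value))

  expect_equal(nrow(suppressMessages(
    run_ora(target_set(character(), "none"), coll))), 0L)
  expect_error(run_ora(hits, coll, universe = target_set(character())),
               class = "qenp_validation_error")
})

test_that("hits outside the universe are dropped before testing", {
  coll <- mk_collection(list(S1 = c("A", "B", "C", "D", "E")))
  hits <- target_set(c("A", "B", "ZZZ"), "hits")
  expect_message(res <- run_ora(hits, coll, min_size = 2), regexp = "outside")
  expect_equal(res$n[1], 2L)
})

test_that("enrich_and_rerank promotes the weighted pathway on a planted toy", {
  uni <- sprintf("G%02d", 1:20)
  coll <- mk_collection(list(
    HEAVY = uni[1:6],    # members of the high-ci compounds
    LIGHT = uni[7:12],
    MIXED = uni[c(1, 7:11)]))
  hits <- target_set(uni[c(1:4, 7:12)], "hits")
  tw <- data.frame(target_symbol = uni[1:12],
                   ti = c(rep(10, 6), rep(0.1, 6)))
  res <- suppressMessages(enrich_and_rerank(hits, tw, coll, min_size = 2))
  # manual weight sums over hit-and-member targets:
  #   HEAVY: G01..G04 hits -> 40; LIGHT: 6 * 0.1 = 0.6; MIXED: 10 + 0.5
  expect_equal(res$p_weight[res$set_id == "HEAVY"], 40)
  expect_equal(res$p_weight[res$set_id == "LIGHT"], 0.6)
  expect_equal(res$p_weight[res$set_id == "MIXED"], 10.5)
  heavy <- res[res$set_id == "HEAVY", ]
  expect_lte(heavy$rank_after, heavy$rank_before)
  expect_equal(heavy$rank_after, 1L)
  # LIGHT has the most hit members but nearly no weight: demoted to last
  expect_equal(res$set_id[res$rank_after == 3], "LIGHT")

  top1 <- suppressMessages(enrich_and_rerank(hits, tw, coll, min_size = 2,
                                             top_m = 1))
  expect_equal(nrow(top1), 1L)
  expect_equal(top1$set_id, "HEAVY")
})

test_that("equal target weights degrade to ranking by scored-member count", {
  uni <- sprintf("G%02d", 1:18)
  coll <- mk_collection(list(A = uni[1:8], B = uni[3:8], C = uni[9:14]))
  hits <- target_set(uni[1:10], "hits")
  tw <- data.frame(target_symbol = uni, ti = 2)
  res <- suppressMessages(enrich_and_rerank(hits, tw, coll, min_size = 2))
  expect_equal(res$p_weight, 2 * res$k)
  ord <- order(-res$k, res$p_value, res$set_id)
  expect_equal(res$set_id, res$set_id[ord])
  # re-ranking permutes, never changes, the reported set
  expect_setequal(res$rank_before, seq_len(nrow(res)))
  expect_setequal(res$rank_after, seq_len(nrow(res)))
})

test_that("ORA p-values match enumeration on random small instances", {
  set.seed(14)
  for (rep in 1:40) {
    N <- sample(5:15, 1)
    K <- sample(1:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeometric_p(k, n, K, N), oracle_hypergeom(k, n, K, N),
                 tolerance = 1e-12)
  }
})
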