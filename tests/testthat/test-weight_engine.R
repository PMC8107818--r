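# The quantity-effect chain: Ci = Ri * Oi, Ti, P, re-ranking.

mk_compounds <- function(ids, pct, rt = seq_along(ids)) {
  data.frame(compound_id = ids, name = ids, cas = "",
             retention_time_min = rt, retention_index = NA_real_,
             pct_total = pct, stringsAsFactors = FALSE)
}

test_that("normalize_ob handles fraction, percent and auto scales", {
  expect_equal(normalize_ob(0.35, "fraction"), 0.35)
  expect_equal(normalize_ob(35, "percent"), 0.35)
  expect_equal(normalize_ob(1.0, "auto"), 1.0)
  expect_equal(normalize_ob(35, "auto"), 0.35)
  expect_equal(normalize_ob(c(0.2, 80), "auto"), c(0.2, 0.8))
  expect_error(normalize_ob(-0.1), class = "qenp_validation_error")
  expect_error(normalize_ob(1.2, "fraction"), class = "qenp_validation_error")
})

test_that("component weights are Ri * Oi, sorted, with missing-OB policies", {
  cmp <- mk_compounds(c("a", "b", "c"), c(10, 30, 5))
  ob <- data.frame(compound_id = c("a", "b", "c"), ob = c(0.3, 0, 1))
  cw <- compute_component_weights(cmp, ob)
  expect_equal(cw$compound_id, c("c", "a", "b"))  # 5, 3, 0
  expect_equal(cw$ci, c(5, 3, 0))
  expect_equal(cw$ci, cw$ri * cw$ob)

  # ties broken by compound_id
  tied <- compute_component_weights(
    mk_compounds(c("z", "y"), c(10, 10)),
    data.frame(compound_id = c("z", "y"), ob = c(0.5, 0.5)))
  expect_equal(tied$compound_id, c("y", "z"))

  partial <- ob[1:2, ]
  expect_error(compute_component_weights(cmp, partial), regexp = "c",
               class = "qenp_validation_error")
  dropped <- compute_component_weights(cmp, partial, missing_ob_policy = "drop")
  expect_setequal(dropped$compound_id, c("a", "b"))
  dflt <- compute_component_weights(cmp, partial, missing_ob_policy = "default",
                                    default_ob = 0.5)
  expect_equal(dflt$ci[dflt$compound_id == "c"], 2.5)
  expect_error(compute_component_weights(cmp, partial,
                                         missing_ob_policy = "default"),
               class = "qenp_validation_error")
})

test_that("identity OB makes ci equal the relative content", {
  tbl <- read_compound_table(table2_path())
  cw <- compute_component_weights(
    tbl, data.frame(compound_id = tbl$compound_id, ob = 1))
  expect_equal(cw$ci, cw$ri)
  expect_equal(max(cw$ci), 21.999)
})

test_that("target weights sum ci per mapped target, edges deduplicated", {
  w <- data.frame(compound_id = c("a", "b"), ri = c(4, 7), ob = c(0.5, 0.5),
                  ci = c(2.0, 3.5))
  map <- data.frame(compound_id = c("a", "b", "b", "a"),
                    target_symbol = c("t1", "t1", "t1", "t2"))
  tw <- aggregate_target_weights(w, map)
  expect_equal(tw$ti[tw$target_symbol == "T1"], 5.5)  # duplicate edge once
  expect_equal(tw$ti[tw$target_symbol == "T2"], 2.0)

  single <- aggregate_target_weights(
    data.frame(compound_id = "a", ci = 5.5),
    data.frame(compound_id = "a", target_symbol = "T1"))
  expect_equal(single$ti, 5.5)

  expect_error(aggregate_target_weights(
    w, data.frame(compound_id = "ghost", target_symbol = "T9")),
    regexp = "ghost", class = "qenp_validation_error")
  lax <- aggregate_target_weights(
    w, data.frame(compound_id = c("a", "ghost"), target_symbol = c("T1", "T9")),
    strict = FALSE)
  expect_false("T9" %in% lax$target_symbol)  # unmapped target absent
})

test_that("pathway weight sums scored members only", {
  tw <- data.frame(target_symbol = c("A", "B"), ti = c(1.0, 2.0))
  expect_equal(aggregate_pathway_weight(tw, character()), 0)
  expect_equal(aggregate_pathway_weight(tw, "A"), 1.0)
  expect_equal(aggregate_pathway_weight(data.frame(target_symbol = "X", ti = 4.2),
                                        c("X", "Y")), 4.2)
  expect_equal(aggregate_pathway_weight(tw, c("A", "B", "C")), 3.0)
})

test_that("re-ranking sorts by weight with deterministic tie-breaks", {
  rows <- data.frame(set_id = c("A", "B", "C"), p_value = c(0.01, 0.02, 0.03),
                     p_weight = c(1, 9, 5), rank_before = 1:3)
  out <- rerank_by_weight(rows)
  expect_equal(out$set_id, c("B", "C", "A"))
  expect_equal(out$rank_after, 1:3)

  ties <- data.frame(set_id = c("A", "B", "C"), p_value = c(0.01, 0.02, 0.03),
                     p_weight = c(7, 7, 7), rank_before = 1:3)
  out2 <- rerank_by_weight(ties)
  expect_equal(out2$rank_after, out2$rank_before)  # falls through to p-value
})

test_that("re-ranking matches a naive sort oracle on 50 synthetic rows", {
  set.seed(42)
  rows <- data.frame(
    set_id = sprintf("S%02d", 1:50),
    p_value = round(runif(50), 2),              # deliberate ties
    p_weight = sample(round(runif(20, 0, 5), 1), 50, replace = TRUE),
    rank_before = 1:50, stringsAsFactors = FALSE)
  out <- rerank_by_weight(rows)
  expect_equal(out$set_id, rows$set_id[oracle_rerank_order(rows)])
})

test_that("rank-shift deltas behave like a permutation statistic", {
  one <- data.frame(set_id = "A", rank_before = 1L, rank_after = 1L)
  expect_equal(rank_shift_report(one)$delta, 0L)

  moved <- data.frame(set_id = "TH17", rank_before = 11L, rank_after = 3L)
  expect_equal(rank_shift_report(moved)$delta, 8L)

  set.seed(5)
  rows <- data.frame(set_id = sprintf("S%d", 1:12), rank_before = 1:12,
                     rank_after = sample(12))
  rep <- rank_shift_report(rows)
  expect_equal(sum(rep$delta), 0L)
  expect_true(all(diff(rep$delta) <= 0))  # sorted by descending delta
})

test_that("the chain is scale-invariant, monotone and conserving", {
  set.seed(9)
  cmp <- mk_compounds(sprintf("c%02d", 1:10), runif(10, 0, 10))
  ob <- data.frame(compound_id = cmp$compound_id, ob = runif(10))
  map <- data.frame(
    compound_id = rep(cmp$compound_id, each = 3),
    target_symbol = sample(sprintf("T%02d", 1:12), 30, replace = TRUE))
  map <- unique(map)

  cw <- compute_component_weights(cmp, ob)
  tw <- aggregate_target_weights(cw, map)

  # scale invariance: Ri -> c * Ri scales every weight by c, ranks unchanged
  # (c < 1 so the scaled table still respects the 100% content budget)
  cmp2 <- cmp; cmp2$pct_total <- cmp2$pct_total * 0.25
  cw2 <- compute_component_weights(cmp2, ob)
  tw2 <- aggregate_target_weights(cw2, map)
  expect_equal(cw2$ci, 0.25 * cw$ci)
  expect_equal(cw2$compound_id, cw$compound_id)
  expect_equal(tw2$ti, 0.25 * tw$ti)
  expect_equal(tw2$target_symbol, tw$target_symbol)
  members <- sprintf("T%02d", 1:5)
  expect_equal(aggregate_pathway_weight(tw2, members),
               0.25 * aggregate_pathway_weight(tw, members))

  # monotonicity: raising one ob never decreases any ti
  ob3 <- ob; ob3$ob[4] <- min(1, ob3$ob[4] + 0.3)
  tw3 <- aggregate_target_weights(compute_component_weights(cmp, ob3), map)
  joined <- merge(tw, tw3, by = "target_symbol")
  expect_true(all(joined$ti.y >= joined$ti.x - 1e-12))

  # conservation: sum of ti = sum of ci * out-degree
  outdeg <- table(map$compound_id)
  expect_equal(sum(tw$ti),
               sum(cw$ci * as.integer(outdeg[cw$compound_id])))
})
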