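# Shared fixture pipeline: run the full quantity-effect chain on one
# synthetic world and return the re-ranked enrichment table.
run_fixture_world <- function(spec, top_m = 100L) {
  w <- gen_target_universe(spec)
  hits <- intersect_targets(target_set(w$mapping$target_symbol, "drug"),
                            w$disease)
  cw <- compute_component_weights(w$compounds, w$ob_table)
  tw <- aggregate_target_weights(cw, w$mapping)
  suppressMessages(enrich_and_rerank(hits, tw, w$collection, top_m = top_m))
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

table2_path <- function() {
  system.file("extdata", "lavender_gcms_table2.tsv", package = "qenp")
}
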