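# Disease activity index (DAI) for murine colitis: three 0-4 rubric scores
# (body-weight loss, stool consistency, fecal blood) averaged into a 0-4
# composite.

.fecal_levels <- c("normal", "between_normal_semithin", "semithin",
                   "between_semithin_sparse", "sparse")
.blood_levels <- c("negative", "between_neg_occult", "occult",
                   "between_occult_gross", "gross")

#' Score body-weight loss
#'
#' Step rubric over percent weight decline: 0 -> 0; (0, 5] -> 1;
#' (5, 10] -> 2; (10, 15) -> 3; >= 15 -> 4. The top band is printed as
#' ">= 15", so 15 itself scores 4; interior band boundaries are taken
#' left-open right-closed by convention.
#'
#' @param pct Non-negative percent weight decline (vectorised).
#' @return Integer scores in 0..4.
#' @export
score_weight_loss <- function(pct) {
  if (anyNA(pct) || any(pct < 0)) {
    stop_validation("weight-loss percent must be non-negative")
  }
  as.integer(ifelse(pct >= 15, 4L,
              ifelse(pct > 10, 3L,
               ifelse(pct > 5, 2L,
                ifelse(pct > 0, 1L, 0L)))))
}

#' Score stool consistency
#'
#' Positional rubric: `normal` 0, `between_normal_semithin` 1, `semithin`
#' 2, `between_semithin_sparse` 3, `sparse` 4 (the "between the two" rubric
#' rows score 1 and 3).
#'
#' @param state Character vector of stool-state categories.
#' @return Integer scores in 0..4.
#' @export
score_fecal_state <- function(state) {
  idx <- match(state, .fecal_levels)
  if (anyNA(idx)) {
    stop_validation(sprintf("unknown fecal state '%s'; expected one of: %s",
                            state[which(is.na(idx))[1]],
                            paste(.fecal_levels, collapse = ", ")))
  }
  as.integer(idx - 1L)
}

#' Score fecal blood
#'
#' Positional rubric: `negative` 0, `between_neg_occult` 1, `occult` 2,
#' `between_occult_gross` 3, `gross` (naked-eye bloody stool) 4.
#'
#' @param state Character vector of blood-state categories.
#' @return Integer scores in 0..4.
#' @export
score_blood_state <- function(state) {
  idx <- match(state, .blood_levels)
  if (anyNA(idx)) {
    stop_validation(sprintf("unknown blood state '%s'; expected one of: %s",
                            state[which(is.na(idx))[1]],
                            paste(.blood_levels, collapse = ", ")))
  }
  as.integer(idx - 1L)
}

#' Composite disease activity index
#'
#' `DAI = (weight-loss score + stool score + blood score) / 3`, reported to
#' one decimal; always in \[0, 4\].
#'
#' @param weight_score,fecal_score,blood_score Integer component scores in
#'   0..4 (vectorised).
#' @return Numeric DAI values rounded to one decimal.
#' @export
score_dai <- function(weight_score, fecal_score, blood_score) {
  for (s in list(weight_score, fecal_score, blood_score)) {
    if (anyNA(s) || any(s < 0 | s > 4 | s != as.integer(s))) {
      stop_validation("component scores must be integers in 0..4")
    }
  }
  round((weight_score + fecal_score + blood_score) / 3, 1)
}

#' Score a table of animal-day observations
#'
#' @param path TSV with header `animal_id`, `day`, `weight_loss_pct`,
#'   `fecal_state`, `blood_state`.
#' @return The table with `weight_score`, `fecal_score`, `blood_score` and
#'   `dai` columns appended.
#' @export
score_dai_table <- function(path) {
  df <- read_delim_table(path, "tab")
  require_columns(df, c("animal_id", "day", "weight_loss_pct",
                        "fecal_state", "blood_state"), path)
  out <- data.frame(
    animal_id = df$animal_id,
    day = as.integer(as_real(df$day, "day")),
    weight_loss_pct = as_real(df$weight_loss_pct, "weight_loss_pct"),
    fecal_state = trimws(df$fecal_state),
    blood_state = trimws(df$blood_state),
    stringsAsFactors = FALSE
  )
  out$weight_score <- score_weight_loss(out$weight_loss_pct)
  out$fecal_score <- score_fecal_state(out$fecal_state)
  out$blood_score <- score_blood_state(out$blood_state)
  out$dai <- score_dai(out$weight_score, out$fecal_score, out$blood_score)
  out
}
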