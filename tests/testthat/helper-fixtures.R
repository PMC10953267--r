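# Programmatic fixtures: tiny panel CSVs and hand-built panel datasets.

# two-scale toy design: "mood" (3 items, 1-5, one reverse-keyed) and
# "worry" (2 items, 1-5)
toy_scales <- function() {
  list(
    mood = scale_definition("mood", "mental_health", paste0("mood_i", 1:3),
                            c(1, 5), reverse_keyed = "mood_i3"),
    worry = scale_definition("worry", "mental_health", paste0("worry_i", 1:2),
                             c(1, 5))
  )
}

# wide CSV for the toy design; `rows` is a data frame with participant_id
# plus the ten item columns (and optional covariates)
write_toy_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  utils::write.csv(rows, path, row.names = FALSE)
  path
}

toy_rows <- function(n = 3) {
  cols <- as.vector(outer(c(paste0("mood_i", 1:3), paste0("worry_i", 1:2)),
                          c("_t1", "_t2"), paste0))
  df <- data.frame(participant_id = seq_len(n))
  for (cl in cols) df[[cl]] <- rep_len(c(2, 3, 4), n)
  df
}

# panel dataset built directly (no file I/O) with given per-wave score
# vectors for a single 2-item scale; items are set so that their mean
# reproduces the scores exactly
pd_from_scores <- function(s_t1, s_t2) {
  defs <- list(s = scale_definition("s", "mental_health", c("s_i1", "s_i2"),
                                    c(0, 10)))
  df <- data.frame(participant_id = seq_along(s_t1),
                   s_i1_t1 = s_t1, s_i2_t1 = s_t1,
                   s_i1_t2 = s_t2, s_i2_t2 = s_t2)
  pd <- panelnet:::new_panel_dataset(df, defs, c("_t1", "_t2"), character())
  score_scales(pd)
}

# residual-matrix-shaped score matrix from a default-spec simulation,
# scored and residualized the way the pipeline does it
simulated_residuals <- function(spec) {
  pd <- score_scales(simulate_panel(spec))
  cols <- as.vector(outer(spec$nodes, c("_t1", "_t2"), paste0))
  residualize(pd$data[cols],
              pd$data[c("gender", "age", "education", "income")])
}
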