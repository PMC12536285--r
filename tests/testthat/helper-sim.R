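# deterministic, noise-free parameters used to check exact identities
exact_params <- function(...) {
  sim_params(participant_sd = 0, residual_cv = 0, late_prob = 0,
             error_hazard = c(post = 0, sub = 0, comp = 0, super = 0), ...)
}

# a tiny hand-built study-1 trial log: one participant, `n_lists` lists of
# two steps each, with explicit correctness/lateness/latency per list
toy_log <- function(correct, late, latency = NULL,
                    presentation_index = NULL) {
  n <- length(correct)
  if (is.null(latency)) latency <- rep(500, n)
  if (is.null(presentation_index)) presentation_index <- rep(1L, n)
  rows <- lapply(seq_len(n), function(i) {
    data.frame(
      participant_id = 1L, study = 1L, list_id = i,
      list_type = c("none", "one", "two")[(i - 1L) %% 3L + 1L],
      presentation_index = presentation_index[i],
      step_index = 1:2, augend = c(5L, 9L), addend1 = c(4L, 3L),
      addend2 = NA_integer_, chosen_plan = NA_character_,
      step_type = c("sub", "super"), dual_type = NA_character_,
      latency_ms = latency[i], entry_ms = c(NA, 700),
      list_correct = correct[i], late_entry = late[i],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  class(out) <- c("trial_log", "data.frame")
  out
}
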