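#' Simulation parameters for the serial-addition generative model
#'
#' Bundles the parameters of the generative model of a participant adding
#' digit lists. Latencies are additive in a type-specific intercept, a
#' problem-size slope and a participant random intercept, with multiplicative
#' lognormal noise; miscalculation is a per-addition hazard, observed only at
#' the list level; result entry can exceed the 2-second limit (a late entry);
#' and in the paired-addend task the facilitative evaluation order is chosen
#' with probability `strategy_prob`.
#'
#' The default type intercepts are the observed mean latencies of the four
#' addition types (post/sub/comp/super = 638/935/823/1298 ms), so with the
#' default zero slope the simulated marginal type means reproduce them; a
#' nonzero slope redistributes the same means into intercept plus size term.
#'
#' @param base_latency Named numeric, mean latency (ms) per addition type.
#' @param addend_slope ms per unit addend (study 1) or per unit addend sum
#'   (study 2).
#' @param participant_sd SD (ms) of the participant random intercept.
#' @param residual_cv Coefficient of variation of the multiplicative
#'   lognormal latency noise (0 disables noise).
#' @param error_hazard Named numeric, per-addition miscalculation
#'   probability by addition type.
#' @param late_prob Probability that a result entry exceeds the 2 s limit.
#' @param strategy_prob Probability of evaluating the top-ranked (possibly
#'   non-linear) plan in the paired-addend task.
#' @param search_cost ms added when a non-linear plan is executed.
#' @param entry_mean Mean result-entry time (ms).
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(base_latency = c(post = 638, sub = 935, comp = 823,
                                        super = 1298),
                       addend_slope = 0,
                       participant_sd = 120,
                       residual_cv = 0.25,
                       error_hazard = c(post = 0.005, sub = 0.045,
                                        comp = 0.010, super = 0.075),
                       late_prob = 0.03,
                       strategy_prob = 0.9,
                       search_cost = 50,
                       entry_mean = 800) {
  stopifnot(
    all(addition_types() %in% names(base_latency)),
    all(base_latency > 0),
    all(addition_types() %in% names(error_hazard)),
    all(error_hazard >= 0), all(error_hazard < 1),
    late_prob >= 0, late_prob <= 1,
    strategy_prob >= 0, strategy_prob <= 1,
    residual_cv >= 0, participant_sd >= 0, entry_mean > 0
  )
  structure(
    list(base_latency = base_latency[addition_types()],
         addend_slope = addend_slope,
         participant_sd = participant_sd,
         residual_cv = residual_cv,
         error_hazard = error_hazard[addition_types()],
         late_prob = late_prob,
         strategy_prob = strategy_prob,
         search_cost = search_cost,
         entry_mean = entry_mean),
    class = "sim_params"
  )
}

#' Parameters and stimuli for null simulations
#'
#' For calibration studies the list types must be exchangeable: all type
#' intercepts and hazards equal, no size slope, and identical length
#' distributions and sum windows across list types so that no latency or
#' accuracy difference is induced by construction.
#'
#' @return `null_sim_params()`: a [sim_params()] object with no type effects.
#'   `null_set_specs()`: a named list of [list_spec()] objects with uniform
#'   length weights and a common sum window.
#' @param study 1 or 2.
#' @export
null_sim_params <- function() {
  sim_params(
    base_latency = c(post = 800, sub = 800, comp = 800, super = 800),
    addend_slope = 0,
    error_hazard = c(post = 0.08, sub = 0.08, comp = 0.08, super = 0.08)
  )
}

#' @rdname null_sim_params
#' @export
null_set_specs <- function(study = 1) {
  study <- as.integer(study)
  types <- if (study == 1L) c("none", "one", "two") else c("no", "some", "many")
  lengths <- if (study == 1L) 4:6 else c(8L, 10L, 12L)
  window <- if (study == 1L) c(20, 30) else c(44, 56)
  specs <- lapply(types, function(tt) {
    list_spec(study, tt, lengths = lengths,
              length_weights = rep(1 / length(lengths), length(lengths)),
              sum_window = window)
  })
  names(specs) <- types
  specs
}

# lognormal noise factor with unit mean and coefficient of variation cv
.noise_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw latencies for addition steps
#'
#' The latency of a step is `(base[type] + slope * size + participant
#' effect)` times a unit-mean lognormal noise factor, floored at 1 ms.
#'
#' @param step_type Character/factor vector of addition types.
#' @param size Numeric problem-size covariate (addend, or addend sum).
#' @param participant_effect Participant random intercept (ms).
#' @param params A [sim_params()].
#' @return Numeric vector of latencies in ms.
#' @export
step_latency <- function(step_type, size = 0, participant_effect = 0,
                         params = sim_params()) {
  step_type <- as.character(step_type)
  n <- max(length(step_type), length(size))
  step_type <- rep_len(step_type, n)
  size <- rep_len(size, n)
  mu <- unname(params$base_latency[step_type]) +
    params$addend_slope * size + participant_effect
  pmax(mu * .noise_factor(n, params$residual_cv), 1)
}

#' Choose an evaluation plan for a paired addition
#'
#' With probability `strategy_prob` the top-ranked plan from
#' [optimal_sequences()] is executed (modelling strategic addend-order
#' choice); otherwise the displayed linear order is followed.
#'
#' @param augend,a1,a2 The paired addition (scalars).
#' @param params A [sim_params()].
#' @return One row of the plan table from [optimal_sequences()].
#' @export
choose_plan <- function(augend, a1, a2, params = sim_params()) {
  plans <- optimal_sequences(augend, a1, a2)
  if (stats::runif(1) < params$strategy_prob) {
    plans[1, , drop = FALSE]
  } else {
    plans[plans$plan == "linear", , drop = FALSE]
  }
}

# simulate the result-entry event; returns list(entry_ms, late)
.entry_event <- function(params) {
  late <- stats::runif(1) < params$late_prob
  if (late) {
    list(entry_ms = 2000 + stats::rexp(1, 1 / 300), late = TRUE)
  } else {
    e <- params$entry_mean * .noise_factor(1, params$residual_cv)
    list(entry_ms = min(e, 1999), late = FALSE)
  }
}

# one presentation of one list; returns a data.frame of step rows
.present_list <- function(sl, list_id, presentation_index, participant_id,
                          study, params, p_effect) {
  el <- sl$elements
  if (study == 1L) {
    k <- length(el) - 1L
    totals <- cumsum(el)
    augend <- totals[seq_len(k)]
    addend1 <- el[-1]
    type <- as.character(classify_single(augend, addend1))
    latency <- step_latency(type, addend1, p_effect, params)
    err_p <- unname(params$error_hazard[type])
    addend2 <- rep(NA_integer_, k)
    plan <- rep(NA_character_, k)
    dual <- rep(NA_character_, k)
  } else {
    k <- length(el) %/% 2L
    a1 <- el[2 * seq_len(k) - 1L]
    a2 <- el[2 * seq_len(k)]
    augend <- c(0L, cumsum(a1 + a2))[seq_len(k)]
    cls <- classify_dual(augend, a1, a2)
    type <- as.character(cls$category)
    dual <- paste0(cls$type_index,
                   ifelse(cls$subtype == "none", "", cls$subtype))
    plan <- character(k)
    latency <- numeric(k)
    err_p <- numeric(k)
    noise <- .noise_factor(k, params$residual_cv)
    for (j in seq_len(k)) {
      pl <- choose_plan(augend[j], a1[j], a2[j], params)
      plan[j] <- pl$plan
      mu <- unname(params$base_latency[pl$step1_type]) +
        unname(params$base_latency[pl$step2_type]) +
        params$addend_slope * (a1[j] + a2[j]) +
        if (pl$plan == "linear") 0 else params$search_cost
      latency[j] <- max((mu + p_effect) * noise[j], 1)
      err_p[j] <- 1 - (1 - unname(params$error_hazard[pl$step1_type])) *
        (1 - unname(params$error_hazard[pl$step2_type]))
    }
    addend1 <- a1
    addend2 <- a2
  }
  miscalc <- any(stats::runif(k) < err_p)
  entry <- .entry_event(params)
  entry_ms <- c(rep(NA_real_, k - 1L), entry$entry_ms)
  data.frame(
    participant_id = participant_id, study = study, list_id = list_id,
    list_type = sl$list_type, presentation_index = presentation_index,
    step_index = seq_len(k), augend = augend, addend1 = addend1,
    addend2 = addend2, chosen_plan = plan, step_type = type,
    dual_type = dual, latency_ms = latency, entry_ms = entry_ms,
    list_correct = !miscalc, late_entry = entry$late,
    stringsAsFactors = FALSE
  )
}

#' Simulate one participant's session
#'
#' Presents every list of the stimulus set in random order; lists answered
#' incorrectly (miscalculated or entered late) are re-presented at the end of
#' the sequence with an incremented presentation index, until every list has
#' a correct, on-time presentation (as in the experimental procedure, where
#' a session ends once 30 lists have been correctly added).
#'
#' @param stimulus_set A [generate_set()] result.
#' @param params A [sim_params()].
#' @param participant_id Integer id recorded in the log.
#' @param p_effect Participant random intercept (ms); drawn from
#'   `Normal(0, participant_sd^2)` when `NULL`.
#' @return A `trial_log` data frame, one row per addition step.
#' @export
simulate_participant <- function(stimulus_set, params = sim_params(),
                                 participant_id = 1L, p_effect = NULL) {
  study <- attr(stimulus_set, "study")
  if (is.null(p_effect)) {
    p_effect <- stats::rnorm(1, 0, params$participant_sd)
  }
  queue <- sample(seq_along(stimulus_set))
  pres_index <- rep(1L, length(stimulus_set))
  out <- list()
  rounds <- 0L
  while (length(queue) > 0) {
    rounds <- rounds + 1L
    if (rounds > 100L) stop("re-presentation did not terminate", call. = FALSE)
    requeue <- integer(0)
    for (li in queue) {
      rows <- .present_list(stimulus_set[[li]], li, pres_index[li],
                            participant_id, study, params, p_effect)
      out[[length(out) + 1L]] <- rows
      if (!rows$list_correct[1] || rows$late_entry[1]) {
        requeue <- c(requeue, li)
        pres_index[li] <- pres_index[li] + 1L
      }
    }
    queue <- requeue
  }
  log <- do.call(rbind, out)
  class(log) <- c("trial_log", "data.frame")
  log
}

#' Simulate a full experiment
#'
#' Every participant receives a unique randomly generated stimulus set and a
#' participant-level random intercept; all randomness flows from `seed`
#' through deterministic per-participant sub-streams.
#'
#' @param n_participants Number of participants (default 21, the reported
#'   sample size).
#' @param study 1 or 2.
#' @param params A [sim_params()].
#' @param seed Optional integer seed.
#' @param set_specs Optional named list of [list_spec()]s passed to
#'   [generate_set()] (e.g. [null_set_specs()]).
#' @return A `trial_log` data frame with attributes `study`, `seed` and
#'   `params`.
#' @export
simulate_experiment <- function(n_participants = 21L, study = 1L,
                                params = sim_params(), seed = NULL,
                                set_specs = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  # participant effects come from the experiment-level stream; stimulus
  # sets and trial noise from deterministic per-participant sub-streams
  p_effects <- stats::rnorm(n_participants, 0, params$participant_sd)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_participants)
  logs <- vector("list", n_participants)
  for (p in seq_len(n_participants)) {
    set.seed(sub_seeds[p])
    stim <- generate_set(study, specs = set_specs)
    logs[[p]] <- simulate_participant(stim, params, participant_id = p,
                                      p_effect = p_effects[p])
  }
  log <- do.call(rbind, logs)
  class(log) <- c("trial_log", "data.frame")
  attr(log, "study") <- as.integer(study)
  attr(log, "seed") <- seed
  attr(log, "params") <- params
  log
}

#' @method print trial_log
#' @export
print.trial_log <- function(x, ...) {
  cat(sprintf(
    "<trial_log: %d addition steps, %d participants, %d list presentations>\n",
    nrow(x), length(unique(x$participant_id)),
    nrow(unique(x[, c("participant_id", "list_id", "presentation_index")]))
  ))
  cat(sprintf("  study %s | list types: %s\n",
              paste(unique(x$study), collapse = "/"),
              paste(unique(x$list_type), collapse = ", ")))
  invisible(x)
}
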