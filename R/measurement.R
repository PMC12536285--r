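#' Measurement configuration
#'
#' Controls the conservative accuracy/latency conventions: accuracy uses only
#' a list's first presentation; latency uses only correctly added,
#' on-time lists; latencies exceeding the overall mean by more than
#' `outlier_k` standard deviations are screened out (one-sided by default,
#' computed once on the full vector); the result-entry interval is excluded
#' from list latencies unless `include_entry`.
#'
#' @param outlier_k Standard-deviation multiplier (default 3).
#' @param outlier_side `"upper"` (default) or `"both"`.
#' @param latency_scope `"correct"` (default) restricts latency measures to
#'   correct, on-time presentations; `"all"` uses everything.
#' @param accuracy_scope `"first"` (default) restricts accuracy to first
#'   presentations; `"all"` uses everything.
#' @param include_entry Add the result-entry interval to list latencies.
#' @return An object of class `measurement_config`.
#' @export
measurement_config <- function(outlier_k = 3,
                               outlier_side = c("upper", "both"),
                               latency_scope = c("correct", "all"),
                               accuracy_scope = c("first", "all"),
                               include_entry = FALSE) {
  stopifnot(outlier_k > 0)
  structure(
    list(outlier_k = outlier_k,
         outlier_side = match.arg(outlier_side),
         latency_scope = match.arg(latency_scope),
         accuracy_scope = match.arg(accuracy_scope),
         include_entry = isTRUE(include_entry)),
    class = "measurement_config"
  )
}

#' Screen latency outliers
#'
#' Flags values exceeding the overall mean by more than `k` standard
#' deviations. Mean and SD are computed once on the full vector, not
#' iteratively; screening is one-sided (upper) by default.
#'
#' @param x Numeric vector (at least 2 values).
#' @param config A [measurement_config()].
#' @return Logical inclusion mask (`TRUE` = keep).
#' @examples
#' screen_outliers(c(rep(1, 19), 20))  # the 20 is excluded
#' @export
screen_outliers <- function(x, config = measurement_config()) {
  if (length(x) < 2) stop("need at least 2 values", call. = FALSE)
  m <- mean(x)
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(TRUE, length(x)))
  keep <- x <= m + config$outlier_k * s
  if (config$outlier_side == "both") {
    keep <- keep & x >= m - config$outlier_k * s
  }
  keep
}

.list_type_levels <- function(study) {
  if (study == 1L) c("none", "one", "two") else c("no", "some", "many")
}

# collapse a step-level log to one row per list presentation
.list_presentations <- function(log, include_entry = FALSE) {
  key <- interaction(log$participant_id, log$list_id, log$presentation_index,
                     drop = TRUE)
  idx <- split(seq_len(nrow(log)), key)
  rows <- lapply(idx, function(i) {
    sub <- log[i, , drop = FALSE]
    sub <- sub[order(sub$step_index), , drop = FALSE]
    k <- nrow(sub)
    study <- sub$study[1]
    n_elements <- if (study == 1L) k + 1L else 2L * k
    final_total <- if (study == 1L) {
      sub$augend[k] + sub$addend1[k]
    } else {
      sub$augend[k] + sub$addend1[k] + sub$addend2[k]
    }
    lat <- sum(sub$latency_ms)
    entry <- sub$entry_ms[k]
    if (include_entry && is.finite(entry)) lat <- lat + entry
    data.frame(
      participant_id = sub$participant_id[1], study = study,
      list_id = sub$list_id[1], list_type = sub$list_type[1],
      presentation_index = sub$presentation_index[1],
      n_elements = n_elements, list_sum = final_total,
      latency_ms = lat, entry_ms = entry,
      list_correct = sub$list_correct[1], late_entry = sub$late_entry[1],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' List-presentation view of a trial log
#'
#' One row per list presentation, with derived element count, list sum and
#' summed addition latency; the result-entry interval is kept in a separate
#' column so either latency convention can be computed.
#'
#' @param log A `trial_log`.
#' @param include_entry Add the entry interval to `latency_ms`.
#' @return A data frame, one row per presentation.
#' @export
list_presentations <- function(log, include_entry = FALSE) {
  .list_presentations(log, include_entry)
}

#' First-presentation accuracy by list type
#'
#' The proportion of genuine errors (miscalculations) on a list's first
#' presentation, with late entries removed from both numerator and
#' denominator.
#'
#' @param log A `trial_log`.
#' @param config A [measurement_config()].
#' @return Data frame with one row per list type: `n` (presentations in the
#'   denominator), `n_late` (excluded late entries), `n_errors` and
#'   `error_rate` (proportion; `NA` for empty cells).
#' @export
first_presentation_accuracy <- function(log, config = measurement_config()) {
  lists <- .list_presentations(log)
  if (config$accuracy_scope == "first") {
    lists <- lists[lists$presentation_index == 1L, , drop = FALSE]
  }
  study <- lists$study[1]
  levs <- .list_type_levels(study)
  out <- lapply(levs, function(tt) {
    sub <- lists[lists$list_type == tt, , drop = FALSE]
    n_late <- sum(sub$late_entry)
    sub <- sub[!sub$late_entry, , drop = FALSE]
    n <- nrow(sub)
    n_err <- sum(!sub$list_correct)
    data.frame(list_type = tt, n = n, n_late = n_late, n_errors = n_err,
               error_rate = if (n > 0) n_err / n else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

.se <- function(x) stats::sd(x) / sqrt(length(x))

#' Per-type latency and problem-size summary of individual additions
#'
#' Restricts the log to correct, on-time list presentations, screens
#' latency outliers against the overall mean, and summarises latency and
#' problem-size indicators per addition type (or, for the paired-addend
#' task, per fine-grained dual type).
#'
#' @param log A `trial_log`.
#' @param config A [measurement_config()].
#' @param by `"category"` (four-way types) or `"dual"` (nine-way types with
#'   subtypes; paired-addend logs only).
#' @param min_n Warn when a type has fewer observations than this.
#' @return Data frame with per-type `N`, `mean_augend`, `mean_addend`,
#'   `mean_sum`, `latency_ms` and `se`; attributes `n_outliers` and
#'   `outlier_pct` record the screening.
#' @export
addition_latency_table <- function(log, config = measurement_config(),
                                   by = c("category", "dual"), min_n = 10L) {
  by <- match.arg(by)
  if (config$latency_scope == "correct") {
    log <- log[log$list_correct & !log$late_entry, , drop = FALSE]
  }
  n_before <- nrow(log)
  keep <- screen_outliers(log$latency_ms, config)
  log <- log[keep, , drop = FALSE]
  n_out <- n_before - nrow(log)
  study <- log$study[1]
  addend <- if (study == 1L) log$addend1 else log$addend1 + log$addend2
  total <- log$augend + addend
  group <- if (by == "category") {
    factor(log$step_type, levels = addition_types())
  } else {
    if (study != 2L) stop("by = 'dual' requires a paired-addend log",
                          call. = FALSE)
    factor(log$dual_type,
           levels = c("1", "2", "3", "4", "5", "6a", "6b", "6c", "6d", "6e",
                      "7", "8", "9"))
  }
  rows <- lapply(levels(group), function(g) {
    i <- which(group == g)
    data.frame(
      type = g,
      notation = if (by == "category") type_notation(g) else
        dual_type_notation(substr(g, 1, 1)),
      N = length(i),
      mean_augend = if (length(i)) mean(log$augend[i]) else NA_real_,
      mean_addend = if (length(i)) mean(addend[i]) else NA_real_,
      mean_sum = if (length(i)) mean(total[i]) else NA_real_,
      latency_ms = if (length(i)) mean(log$latency_ms[i]) else NA_real_,
      se = if (length(i) > 1) .se(log$latency_ms[i]) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  low <- out$N > 0 & out$N < min_n
  if (any(low)) {
    warning("types with fewer than ", min_n, " observations: ",
            paste(out$type[low], collapse = ", "), call. = FALSE)
  }
  attr(out, "n_outliers") <- n_out
  attr(out, "outlier_pct") <- 100 * n_out / n_before
  out
}

#' Per-list-type latency and size summary of whole lists
#'
#' Restricts to correct, on-time presentations, screens list-level latency
#' outliers, and reports mean element counts, list sums and latencies (in
#' seconds) per list type.
#'
#' @param log A `trial_log`.
#' @param config A [measurement_config()]; `include_entry` controls whether
#'   the result-entry interval counts towards list latency.
#' @return Data frame with per-type `N`, `mean_elements`, `mean_sum`,
#'   `latency_s` and `se`; attributes `n_outliers` and `outlier_pct`.
#' @export
list_latency_table <- function(log, config = measurement_config()) {
  lists <- .list_presentations(log, include_entry = config$include_entry)
  if (config$latency_scope == "correct") {
    lists <- lists[lists$list_correct & !lists$late_entry, , drop = FALSE]
  }
  n_before <- nrow(lists)
  keep <- screen_outliers(lists$latency_ms, config)
  lists <- lists[keep, , drop = FALSE]
  levs <- .list_type_levels(lists$study[1])
  rows <- lapply(levs, function(tt) {
    sub <- lists[lists$list_type == tt, , drop = FALSE]
    data.frame(
      list_type = tt, N = nrow(sub),
      mean_elements = if (nrow(sub)) mean(sub$n_elements) else NA_real_,
      mean_sum = if (nrow(sub)) mean(sub$list_sum) else NA_real_,
      latency_s = if (nrow(sub)) mean(sub$latency_ms) / 1000 else NA_real_,
      se = if (nrow(sub) > 1) .se(sub$latency_ms) / 1000 else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  attr(out, "n_outliers") <- n_before - sum(keep)
  attr(out, "outlier_pct") <- 100 * (n_before - sum(keep)) / n_before
  out
}
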