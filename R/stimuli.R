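#' Count complement steps in a single-addend list
#'
#' Walks a digit list as a participant would in the single-addend task: the
#' first element is the initial augend, every later element is an addend on
#' the running total. Returns how many of those steps are complements (sum
#' exactly reaching the next decade).
#'
#' @param elements Integer vector of digits 1-9, length at least 2.
#' @return Integer count of complement steps.
#' @examples
#' count_complements(c(2, 9, 4, 2, 6, 4))  # 0
#' count_complements(c(2, 1, 4, 3, 8))     # 1
#' count_complements(c(6, 4, 2, 7, 1))     # 2
#' @export
count_complements <- function(elements) {
  elements <- .check_addend(elements, "elements")
  if (length(elements) < 2) {
    stop("a list needs at least two elements (augend plus one addend)",
         call. = FALSE)
  }
  totals <- cumsum(elements)
  augends <- totals[-length(totals)]
  types <- classify_single(augends, elements[-1])
  sum(types == "comp")
}

#' Count facilitative opportunities in a paired-addend list
#'
#' Walks a digit list as presented in the paired-addend task: elements are
#' consumed two at a time, starting from an initial augend of zero. For each
#' paired step `(Au, a1, a2)` it counts overt complements (each addend with
#' `u + a == 10`, `u > 0`, counted separately), pairs (`a1 + a2 == 10`) and
#' covert complements (steps of dual types 2, 5 or 8, whose totals reach a
#' decade only via the associative order).
#'
#' @param elements Integer vector of digits 1-9 with even length.
#' @return Named integer vector with entries `complements`, `pairs`,
#'   `covert`.
#' @examples
#' count_opportunities(c(4, 5, 3, 4, 9, 6, 4, 3))  # no overt opportunities
#' count_opportunities(c(6, 1, 4, 3, 8, 2, 9, 4))  # one complement, one pair
#' @export
count_opportunities <- function(elements) {
  elements <- .check_addend(elements, "elements")
  if (length(elements) %% 2 != 0) {
    stop("paired-addend lists must have an even number of elements",
         call. = FALSE)
  }
  n_steps <- length(elements) / 2
  a1 <- elements[2 * seq_len(n_steps) - 1]
  a2 <- elements[2 * seq_len(n_steps)]
  augends <- c(0L, cumsum(a1 + a2))[seq_len(n_steps)]
  u <- augends %% 10L
  comp <- sum((u > 0L & u + a1 == 10L)) + sum((u > 0L & u + a2 == 10L))
  pair <- sum(a1 + a2 == 10L)
  covert <- sum(classify_dual(augends, a1, a2)$type_index %in% c(2L, 5L, 8L))
  c(complements = as.integer(comp), pairs = as.integer(pair),
    covert = as.integer(covert))
}

# length distributions per list type, calibrated so that expected element
# counts match the reported set composition (4.92/5.06/5.23 for study 1,
# 9.79/10.03/10.26 for study 2)
.length_weights <- list(
  "1" = list(
    none = c("4" = 0.40, "5" = 0.28, "6" = 0.32),
    one  = c("4" = 0.32, "5" = 0.30, "6" = 0.38),
    # two complements and a sum above 20 are impossible in a 4-element list
    # (the only two-complement pattern there runs 10 -> 20), so lengths 5-6
    two  = c("5" = 0.77, "6" = 0.23)
  ),
  "2" = list(
    no   = c("8" = 0.450, "10" = 0.205, "12" = 0.345),
    some = c("8" = 0.370, "10" = 0.245, "12" = 0.385),
    many = c("8" = 0.330, "10" = 0.210, "12" = 0.460)
  )
)

.sum_windows <- list(
  "1" = list(none = c(20, 29), one = c(20, 30), two = c(21, 30)),
  "2" = list(no = c(44, 55), some = c(44, 56), many = c(45, 56))
)

#' List-type specification for stimulus generation
#'
#' Bundles the constraints a stimulus list of a given type must satisfy:
#' admissible lengths (with sampling weights), the total-sum window, the
#' adjacency rule and the facilitation-count contract. Study-1 list types
#' fix the number of complement steps (`none`/`one`/`two`); study-2 list
#' types constrain overt complements and pairs (`no`: zero of either;
#' `some`: exactly one of each; `many`: three or more in total).
#'
#' @param study 1 or 2.
#' @param list_type For study 1 one of `"none"`, `"one"`, `"two"`; for
#'   study 2 one of `"no"`, `"some"`, `"many"`.
#' @param lengths Optional integer vector of admissible lengths (defaults to
#'   4-6 for study 1, `c(8, 10, 12)` for study 2).
#' @param length_weights Optional sampling weights over `lengths`.
#' @param sum_window Optional numeric length-2 vector of admissible list
#'   sums.
#' @param max_attempts Rejection-sampling budget before generation fails.
#' @return An object of class `list_spec`.
#' @export
list_spec <- function(study, list_type, lengths = NULL, length_weights = NULL,
                      sum_window = NULL, max_attempts = 50000L) {
  study <- match.arg(as.character(study), c("1", "2"))
  valid_types <- if (study == "1") c("none", "one", "two") else
    c("no", "some", "many")
  list_type <- match.arg(list_type, valid_types)
  if (is.null(length_weights)) {
    length_weights <- .length_weights[[study]][[list_type]]
  }
  if (is.null(lengths)) lengths <- as.integer(names(length_weights))
  if (length(length_weights) != length(lengths)) {
    stop("length_weights must match lengths", call. = FALSE)
  }
  if (is.null(sum_window)) sum_window <- .sum_windows[[study]][[list_type]]
  if (as.integer(study) == 2L && any(lengths %% 2 != 0)) {
    stop("study-2 lists must have even lengths", call. = FALSE)
  }
  structure(
    list(study = as.integer(study), list_type = list_type,
         lengths = as.integer(lengths),
         length_weights = as.numeric(length_weights) / sum(length_weights),
         sum_window = as.numeric(sum_window),
         max_attempts = as.integer(max_attempts)),
    class = "list_spec"
  )
}

# does `elements` satisfy the facilitation-count contract of `spec`?
# (fast arithmetic path for the sampler's inner loop; the public counters in
# count_complements()/count_opportunities() are the independent validator
# route and agree with these by construction tests)
.counts_ok <- function(elements, spec) {
  if (spec$study == 1L) {
    u <- cumsum(elements)[-length(elements)] %% 10L
    k <- sum(u != 0L & u + elements[-1] == 10L)
    switch(spec$list_type, none = k == 0L, one = k == 1L, two = k == 2L)
  } else {
    ns <- length(elements) %/% 2L
    a1 <- elements[2L * seq_len(ns) - 1L]
    a2 <- elements[2L * seq_len(ns)]
    u <- c(0L, cumsum(a1 + a2))[seq_len(ns)] %% 10L
    comp <- sum(u > 0L & u + a1 == 10L) + sum(u > 0L & u + a2 == 10L)
    pair <- sum(a1 + a2 == 10L)
    switch(spec$list_type,
           no = comp == 0L && pair == 0L,
           some = comp == 1L && pair == 1L,
           many = comp + pair >= 3L)
  }
}

# one candidate digit sequence of given length under the adjacency rule
.random_digits <- function(len) {
  out <- integer(len)
  out[1] <- sample.int(9L, 1L)
  for (i in 2:len) {
    d <- sample.int(8L, 1L)
    out[i] <- if (d >= out[i - 1]) d + 1L else d
  }
  out
}

#' Generate one stimulus list satisfying a specification
#'
#' Draws the list length from the specification's weights, then
#' rejection-samples uniform digit sequences of that length under the
#' adjacency rule until the sum window and the facilitation-count contract
#' are satisfied; conditional on length the distribution is uniform over
#' valid lists.
#'
#' @param spec A [list_spec()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return An object of class `stimulus_list`: a list with fields `study`,
#'   `list_type`, `elements`, `length`, `list_sum` and `counts` (the derived
#'   facilitation counts).
#' @export
generate_list <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "list_spec"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  # the length is drawn once, then digits are rejection-sampled at that
  # length: conditioning on the facilitation counts must not distort the
  # calibrated length distribution
  len <- if (length(spec$lengths) == 1L) spec$lengths else
    sample(spec$lengths, 1L, prob = spec$length_weights)
  for (attempt in seq_len(spec$max_attempts)) {
    el <- .random_digits(len)
    s <- sum(el)
    if (s < spec$sum_window[1] || s > spec$sum_window[2]) next
    if (!.counts_ok(el, spec)) next
    counts <- if (spec$study == 1L) {
      c(complements = count_complements(el))
    } else {
      count_opportunities(el)
    }
    return(structure(
      list(study = spec$study, list_type = spec$list_type, elements = el,
           length = len, list_sum = s, counts = counts),
      class = "stimulus_list"
    ))
  }
  stop("could not generate a '", spec$list_type, "' list within ",
       spec$max_attempts, " attempts; the specification may be too tight",
       call. = FALSE)
}

#' @method print stimulus_list
#' @export
print.stimulus_list <- function(x, ...) {
  cat(sprintf("<stimulus_list study %d, type '%s'>\n", x$study, x$list_type))
  cat("  elements:", paste(x$elements, collapse = ", "), "\n")
  cat("  sum:", x$list_sum, " counts:",
      paste(names(x$counts), x$counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Generate a participant's full stimulus set
#'
#' A set is 30 lists, 10 per list type, mirroring the experimental sessions
#' in which every participant received a unique randomly generated set.
#'
#' @param study 1 or 2.
#' @param seed Optional integer seed for reproducibility.
#' @param n_per_type Lists per type (default 10).
#' @param specs Optional named list of [list_spec()] objects overriding the
#'   per-type defaults (used e.g. for null simulations in which list types
#'   must be exchangeable).
#' @return An object of class `stimulus_set`: list of `stimulus_list`
#'   objects with attributes `study` and `seed`.
#' @export
generate_set <- function(study, seed = NULL, n_per_type = 10L, specs = NULL) {
  study <- as.integer(study)
  if (!is.null(seed)) set.seed(as.integer(seed))
  types <- if (study == 1L) c("none", "one", "two") else c("no", "some", "many")
  if (is.null(specs)) {
    specs <- lapply(types, function(tt) list_spec(study, tt))
    names(specs) <- types
  }
  lists <- list()
  for (tt in types) {
    for (i in seq_len(n_per_type)) {
      lists[[length(lists) + 1L]] <- generate_list(specs[[tt]])
    }
  }
  structure(lists, class = "stimulus_set", study = study, seed = seed)
}

#' Validate a digit list against a specification
#'
#' Checks each constraint separately and reports a pass/fail table, usable
#' both as a guard on external stimuli and as the oracle for the generator.
#'
#' @param elements Integer vector of digits, or a `stimulus_list`.
#' @param spec A [list_spec()].
#' @return A data frame with columns `constraint` and `ok`, plus attribute
#'   `valid` (all constraints satisfied).
#' @export
validate_list <- function(elements, spec) {
  stopifnot(inherits(spec, "list_spec"))
  if (inherits(elements, "stimulus_list")) elements <- elements$elements
  checks <- list(
    digits_1_9 = all(elements %in% 1:9),
    length_admissible = length(elements) %in% spec$lengths,
    no_adjacent_repeats = all(diff(elements) != 0),
    sum_in_window = sum(elements) >= spec$sum_window[1] &&
      sum(elements) <= spec$sum_window[2]
  )
  checks$facilitation_counts <- checks$digits_1_9 &&
    length(elements) >= 2 &&
    (spec$study == 1L || length(elements) %% 2 == 0) &&
    .counts_ok(as.integer(elements), spec)
  out <- data.frame(constraint = names(checks),
                    ok = unlist(checks, use.names = FALSE),
                    stringsAsFactors = FALSE)
  attr(out, "valid") <- all(out$ok)
  out
}

#' Round-trip a list specification through JSON
#'
#' @param spec A [list_spec()].
#' @param path JSON path.
#' @return `write_spec_json()` returns `path` invisibly;
#'   `read_spec_json()` returns a [list_spec()].
#' @export
write_spec_json <- function(spec, path) {
  stopifnot(inherits(spec, "list_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_spec_json
#' @export
read_spec_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list_spec(raw$study, raw$list_type, lengths = raw$lengths,
            length_weights = raw$length_weights,
            sum_window = raw$sum_window,
            max_attempts = raw$max_attempts)
}

#' Serialize stimulus sets to a data frame / CSV
#'
#' @param x A `stimulus_set`.
#' @param ... Unused.
#' @return One row per list: `study`, `list_type`, `list_id`, `elements`
#'   (comma-joined digits), `length`, `list_sum` and the derived counts.
#' @method as.data.frame stimulus_set
#' @export
as.data.frame.stimulus_set <- function(x, ...) {
  rows <- lapply(seq_along(x), function(i) {
    sl <- x[[i]]
    counts <- as.list(sl$counts)
    names(counts) <- paste0("n_", names(counts))
    cbind(
      data.frame(study = sl$study, list_type = sl$list_type, list_id = i,
                 elements = paste(sl$elements, collapse = ","),
                 length = sl$length, list_sum = sl$list_sum,
                 stringsAsFactors = FALSE),
      as.data.frame(counts)
    )
  })
  do.call(rbind, rows)
}

#' Write / read stimulus lists as CSV
#'
#' Files carry a `#`-prefixed provenance header recording the seed.
#'
#' @param x A `stimulus_set`.
#' @param path Output path.
#' @param seed Seed recorded in the provenance header.
#' @return `write_stimulus_csv()` returns `path` invisibly;
#'   `read_stimulus_csv()` returns the data frame form.
#' @export
write_stimulus_csv <- function(x, path, seed = attr(x, "seed")) {
  df <- as.data.frame(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# decadd stimulus set | study=%d | seed=%s",
                     attr(x, "study"),
                     if (is.null(seed)) "NA" else as.character(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stimulus_csv
#' @export
read_stimulus_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
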