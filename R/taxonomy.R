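#' Addition-type levels
#'
#' The four qualitative types of a single serial addition `Au + a`, defined by
#' the relation of the augend and the sum to the decade boundary:
#' post-complement (round augend), subcomplement (sum stays below the next
#' decade), complement (sum exactly reaches it) and supercomplement (sum
#' crosses it, requiring a carry).
#'
#' @return Character vector of the four type labels, in the conventional
#'   display order `post`, `sub`, `comp`, `super`.
#' @export
addition_types <- function() c("post", "sub", "comp", "super")

# empirical latency ordering of the four types (fastest first), used to rank
# evaluation plans: post < comp < sub < super
.type_difficulty <- c(post = 1, comp = 2, sub = 3, super = 4)

.single_notation <- c(post = "[-]", sub = "[<]", comp = "[=]", super = "[>]")

.dual_notation <- c(
  "1" = "[-<]", "2" = "[-=]", "3" = "[->]",
  "4" = "[<<]", "5" = "[<=]", "6" = "[=-]",
  "7" = "[<>]", "8" = "[>=]", "9" = "[>>]"
)

.dual_names <- c(
  "1" = "decade-subcomplement", "2" = "decade-complement",
  "3" = "decade-supercomplement", "4" = "subcomplement",
  "5" = "covert complement", "6" = "overt complement and pair",
  "7" = "supercomplement", "8" = "covert complement 2",
  "9" = "supercomplement 2"
)

#' Bracket notation for addition types
#'
#' @param type For `type_notation()`, a character vector of single-addition
#'   type labels (see [addition_types()]).
#' @param type_index For `dual_type_notation()`, an integer vector of dual
#'   addition type indices (1-9).
#' @return Character vector of bracket-notation strings (e.g. `"[=]"`,
#'   `"[-=]"`).
#' @export
type_notation <- function(type) {
  unname(.single_notation[as.character(type)])
}

#' @rdname type_notation
#' @export
dual_type_notation <- function(type_index) {
  unname(.dual_notation[as.character(type_index)])
}

.check_addend <- function(a, what = "addend") {
  if (length(a) == 0 || anyNA(a) || any(a != as.integer(a)) ||
      any(a < 1) || any(a > 9)) {
    stop(what, " must be an integer in 1..9 (malformed stimulus)",
         call. = FALSE)
  }
  as.integer(a)
}

.check_augend <- function(au) {
  if (length(au) == 0 || anyNA(au) || any(au != as.integer(au)) || any(au < 0)) {
    stop("augend must be a non-negative integer", call. = FALSE)
  }
  as.integer(au)
}

#' Classify a single serial addition
#'
#' Classifies the addition of a single-digit addend `a` (1-9) to a running
#' total (augend) `Au` by its relation to the decade boundary. Only the
#' augend's unit digit `u = Au mod 10` matters: a round augend (`u == 0`)
#' yields a post-complement; otherwise the unit sum `u + a` decides between
#' subcomplement (`< 10`), complement (`== 10`) and supercomplement (`> 10`).
#'
#' @param augend Non-negative integer vector: the running total.
#' @param addend Integer vector in 1..9: the displayed addend.
#' @return A factor with levels [addition_types()], one per input.
#' @examples
#' classify_single(10, 5)                 # post
#' classify_single(15, c(4, 5, 6))        # sub, comp, super
#' @export
classify_single <- function(augend, addend) {
  augend <- .check_augend(augend)
  addend <- .check_addend(addend)
  n <- max(length(augend), length(addend))
  augend <- rep_len(augend, n)
  addend <- rep_len(addend, n)
  u <- augend %% 10L
  s <- u + addend
  out <- ifelse(u == 0L, "post",
         ifelse(s < 10L, "sub",
         ifelse(s == 10L, "comp", "super")))
  factor(out, levels = addition_types())
}

# Generalised step classification used when scoring evaluation plans. The
# addend may exceed 9 (an associative plan adds the pair total a1 + a2 in one
# step). A round addend (10) is a pure decade increment and is typed like a
# post-complement; a round augend likewise; otherwise the unit sum decides,
# with sums landing on a decade typed as complements.
.classify_step <- function(augend, addend) {
  u <- augend %% 10L
  if (u == 0L || addend %% 10L == 0L) return("post")
  s <- u + addend
  if (s %% 10L == 0L) return("comp")
  if (s < 10L) return("sub")
  "super"
}

#' Classify a paired serial addition
#'
#' Classifies the addition of two simultaneously displayed single-digit
#' addends `a1` and `a2` to a running total `Au` into one of nine types
#' (type 6 carrying subtypes a-e), following the decision cascade over the
#' task features `u + a1`, `u + a2`, `a1 + a2` and `u + a1 + a2`:
#' round augends give types 1-3 (by the pair sum against 10); otherwise any
#' partial sum equal to 10 gives type 6 (subtype by which sums hit 10, with
#' complement-pairs 6d/6e taking precedence over 6a/6b over the pure pair
#' 6c); otherwise the total decides between 4 (`< 10`), 5 (`== 10`),
#' 7 (`11..19`), 8 (`== 20`) and 9 (`> 20`).
#'
#' @param augend Non-negative integer vector: the running total.
#' @param a1,a2 Integer vectors in 1..9: the two displayed addends.
#' @return A data frame with one row per input and columns `type_index`
#'   (integer 1-9), `subtype` (`"none"` or `"a"`-`"e"`, non-none only for
#'   type 6), `label` (the type's name), `notation` (two-symbol bracket
#'   string) and `category` (the four-way grouping, a factor as returned by
#'   [classify_single()]).
#' @examples
#' classify_dual(15, 4, 5)   # type 6, subtype b (indirect complement)
#' classify_dual(18, 5, 7)   # type 8 (covert complement 2)
#' @export
classify_dual <- function(augend, a1, a2) {
  augend <- .check_augend(augend)
  a1 <- .check_addend(a1, "a1")
  a2 <- .check_addend(a2, "a2")
  n <- max(length(augend), length(a1), length(a2))
  augend <- rep_len(augend, n)
  a1 <- rep_len(a1, n)
  a2 <- rep_len(a2, n)
  u <- augend %% 10L
  s1 <- u + a1
  s2 <- u + a2
  sp <- a1 + a2
  tot <- u + a1 + a2

  type <- integer(n)
  subtype <- rep("none", n)

  round_au <- u == 0L
  type[round_au & sp < 10L] <- 1L
  type[round_au & sp == 10L] <- 2L
  type[round_au & sp > 10L] <- 3L

  six <- !round_au & (s1 == 10L | s2 == 10L | sp == 10L)
  type[six] <- 6L
  # precedence: complement-pairs (d/e) first, then direct/indirect
  # complements (a/b), then the pure pair (c); a genuine pair needs two
  # distinct addends, so equal addends (never generated, but classifiable)
  # fall back to the direct complement and 6d/6e cannot arise
  subtype[six & s1 == 10L & sp == 10L & a1 != a2] <- "d"
  subtype[six & s2 == 10L & sp == 10L & a1 != a2] <- "e"
  subtype[six & s1 == 10L & subtype == "none"] <- "a"
  subtype[six & s2 == 10L & subtype == "none"] <- "b"
  subtype[six & sp == 10L & subtype == "none"] <- "c"

  rest <- !round_au & !six
  type[rest & tot < 10L] <- 4L
  type[rest & tot == 10L] <- 5L
  type[rest & tot > 10L & tot < 20L] <- 7L
  type[rest & tot == 20L] <- 8L
  type[rest & tot > 20L] <- 9L

  data.frame(
    type_index = type,
    subtype = subtype,
    label = unname(.dual_names[as.character(type)]),
    notation = dual_type_notation(type),
    category = category_of(type),
    stringsAsFactors = FALSE
  )
}

#' Map dual addition types to the four single-addition categories
#'
#' Groups the nine paired-addend types back into the four basic categories:
#' round-augend types 1-3 are post-complements, types 4-5 subcomplements,
#' type 6 (overt complements and pairs) complements, and types 7-9
#' supercomplements.
#'
#' @param type_index Integer vector of dual type indices (1-9).
#' @return A factor with levels [addition_types()].
#' @export
category_of <- function(type_index) {
  if (anyNA(type_index) || any(!type_index %in% 1:9)) {
    stop("type_index must be in 1..9", call. = FALSE)
  }
  map <- c("post", "post", "post", "sub", "sub", "comp",
           "super", "super", "super")
  factor(map[as.integer(type_index)], levels = addition_types())
}

#' Enumerate and rank evaluation plans for a paired addition
#'
#' A paired addition `Au + a1 + a2` can be evaluated three ways: the linear
#' sequence (`+a1` then `+a2`), the commuted sequence (`+a2` then `+a1`) and
#' the associative sequence (form `a1 + a2`, then add it in one step). Each
#' plan induces a pair of single-addition step types; plans are ranked by the
#' number of facilitative steps (post-complements and complements) they
#' induce, then by total step difficulty under the empirical latency ordering
#' post < comp < sub < super, with ties broken deterministically (linear
#' before commuted before associative).
#'
#' In the associative plan the first step is the pair formation (`a1` as
#' augend, `a2` as addend; a pair summing to 10 is a complement) and the
#' second the addition of the pair total to the running augend, where adding
#' a round total is a pure decade increment, typed like a post-complement.
#'
#' @param augend Non-negative integer scalar.
#' @param a1,a2 Integer scalars in 1..9.
#' @return A data frame ordered best plan first, with columns `plan`
#'   (`"linear"`, `"commuted"`, `"associative"`), `step1_type`, `step2_type`,
#'   `step1_addend`, `step2_addend`, `facilitative` (count of post/comp
#'   steps) and `difficulty` (summed difficulty ranks).
#' @examples
#' optimal_sequences(15, 4, 5)  # commuted plan first: complement then post
#' @export
optimal_sequences <- function(augend, a1, a2) {
  augend <- .check_augend(augend)[1]
  a1 <- .check_addend(a1, "a1")[1]
  a2 <- .check_addend(a2, "a2")[1]

  plans <- data.frame(
    plan = c("linear", "commuted", "associative"),
    step1_type = c(
      .classify_step(augend, a1),
      .classify_step(augend, a2),
      .classify_step(a1, a2)
    ),
    step2_type = c(
      .classify_step(augend + a1, a2),
      .classify_step(augend + a2, a1),
      .classify_step(augend, a1 + a2)
    ),
    step1_addend = c(a1, a2, a2),
    step2_addend = c(a2, a1, a1 + a2),
    stringsAsFactors = FALSE
  )
  fac <- (plans$step1_type %in% c("post", "comp")) +
         (plans$step2_type %in% c("post", "comp"))
  diff <- .type_difficulty[plans$step1_type] + .type_difficulty[plans$step2_type]
  plans$facilitative <- as.integer(fac)
  plans$difficulty <- unname(diff)
  ord <- order(-plans$facilitative, plans$difficulty, seq_len(3))
  out <- plans[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
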