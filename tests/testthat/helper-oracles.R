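# Independent brute-force oracles for the addition-type taxonomy: direct
# evaluation of the classification tables' feature columns, written as
# per-row predicates rather than a decision cascade, so they exercise a
# different code path than the package's classifiers.

oracle_single <- function(augend, addend) {
  u <- augend %% 10
  if (u == 0) return("post")
  s <- u + addend
  if (s < 10) return("sub")
  if (s == 10) return("comp")
  "super"
}

# every feature row of the dual-addend classification table as a predicate
# over (u == 0, u+a1, u+a2, a1+a2, u+a1+a2); returns e.g. "3", "6b"
oracle_dual <- function(augend, a1, a2) {
  u <- augend %% 10
  s1 <- u + a1
  s2 <- u + a2
  sp <- a1 + a2
  tot <- u + a1 + a2
  rows <- c(
    "1"  = (u == 0 && sp < 10 && tot < 10),
    "2"  = (u == 0 && sp == 10 && tot == 10),
    "3"  = (u == 0 && sp > 10 && tot > 10),
    "4"  = (u > 0 && s1 < 10 && s2 < 10 && sp < 10 && tot < 10),
    "5"  = (u > 0 && s1 < 10 && s2 < 10 && sp < 10 && tot == 10),
    "6a" = (u > 0 && s1 == 10 && s2 != 10 && sp != 10 && tot > 10),
    "6b" = (u > 0 && s1 != 10 && s2 == 10 && sp != 10 && tot > 10),
    "6c" = (u > 0 && s1 != 10 && s2 != 10 && sp == 10 && tot > 10),
    "6d" = (u > 0 && s1 == 10 && s2 != 10 && sp == 10 && tot > 10),
    "6e" = (u > 0 && s1 != 10 && s2 == 10 && sp == 10 && tot > 10),
    "7"  = (u > 0 && s1 != 10 && s2 != 10 && sp != 10 && tot > 10 && tot < 20),
    "8"  = (u > 0 && s1 > 10 && s2 > 10 && sp > 10 && tot == 20),
    "9"  = (u > 0 && s1 > 10 && s2 > 10 && sp > 10 && tot > 20)
  )
  hits <- names(rows)[rows]
  if (length(hits) != 1) {
    stop(sprintf("oracle rows not mutually exclusive/exhaustive at (%d,%d,%d): %s",
                 augend, a1, a2, paste(hits, collapse = ",")))
  }
  hits
}

# all (u, a1, a2) triples with distinct addends
all_dual_triples <- function() {
  g <- expand.grid(u = 0:9, a1 = 1:9, a2 = 1:9)
  g[g$a1 != g$a2, , drop = FALSE]
}

dual_code <- function(cls) {
  paste0(cls$type_index, ifelse(cls$subtype == "none", "", cls$subtype))
}
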