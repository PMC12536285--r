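test_that("outlier screening applies mean + k*sd once, upper side only", {
  # borderline case: the extreme value stays inside 3 sd of the full vector
  x <- c(rep(1, 9), 10)
  expect_true(all(screen_outliers(x)))
  # a more extreme value is excluded
  y <- c(rep(1, 19), 20)
  keep <- screen_outliers(y)
  expect_equal(which(!keep), 20L)
  expect_equal(mean(y) + 3 * sd(y), 14.695, tolerance = 1e-3)
  # constant vectors have sd 0 and nothing is excluded
  expect_true(all(screen_outliers(rep(5, 10))))
  # the screen is not applied to the lower tail by default
  z <- c(rep(100, 19), 1)
  expect_true(all(screen_outliers(z)))
  cfg <- measurement_config(outlier_side = "both")
  expect_false(all(screen_outliers(z, cfg)))
  expect_error(screen_outliers(1), "at least 2")
})

test_that("accuracy counts genuine errors on first presentations, excluding late entries", {
  # 10 first presentations: 2 genuine errors, 1 late -> 2/9
  log <- toy_log(correct = c(rep(TRUE, 7), FALSE, FALSE, FALSE),
                 late = c(rep(FALSE, 9), TRUE))
  acc <- first_presentation_accuracy(log)
  expect_equal(sum(acc$n), 9L)
  expect_equal(sum(acc$n_late), 1L)
  expect_equal(sum(acc$n_errors), 2L)
  expect_equal(sum(acc$n_errors) / sum(acc$n), 2 / 9)
})

test_that("re-presentations never enter the accuracy measure", {
  log <- rbind(
    toy_log(correct = rep(TRUE, 6), late = rep(FALSE, 6)),
    toy_log(correct = rep(FALSE, 6), late = rep(FALSE, 6),
            presentation_index = rep(2L, 6))
  )
  class(log) <- c("trial_log", "data.frame")
  acc <- first_presentation_accuracy(log)
  expect_equal(sum(acc$n_errors), 0L)
  expect_equal(sum(acc$n), 6L)
})

test_that("an all-correct log yields zero error rates everywhere", {
  log <- toy_log(correct = rep(TRUE, 9), late = rep(FALSE, 9))
  acc <- first_presentation_accuracy(log)
  expect_true(all(acc$error_rate == 0))
})

test_that("incorrect and late lists never enter the latency measures", {
  # incorrect/late lists carry absurd latencies; tables must ignore them
  log <- toy_log(correct = c(rep(TRUE, 6), FALSE, TRUE, FALSE),
                 late = c(rep(FALSE, 7), TRUE, FALSE),
                 latency = c(rep(500, 6), 1e6, 1e6, 1e6))
  tab <- addition_latency_table(log, min_n = 1)
  expect_true(all(tab$latency_ms[tab$N > 0] == 500))
  lt <- list_latency_table(log)
  expect_true(all(lt$latency_s[lt$N > 0] == 1))  # two 500 ms steps
})

test_that("noise-free logs reproduce the generating means exactly", {
  set.seed(8)
  log <- simulate_experiment(3, 1, exact_params(), seed = 8)
  tab <- addition_latency_table(log)
  expect_equal(tab$latency_ms[match(addition_types(), tab$type)],
               c(638, 935, 823, 1298))
  # list latency equals the sum of its noise-free step means
  lt <- list_latency_table(log)
  lp <- list_presentations(log)
  base <- c(post = 638, sub = 935, comp = 823, super = 1298)
  manual <- sum(base[log$step_type]) / 1000
  expect_equal(sum(lt$latency_s * lt$N), manual, tolerance = 1e-10)
  expect_equal(attr(lt, "n_outliers"), 0L)
})

test_that("problem-size indicators follow the type structure", {
  set.seed(12)
  log <- simulate_experiment(6, 1, seed = 12)
  tab <- addition_latency_table(log)
  tab <- tab[match(addition_types(), tab$type), ]
  # subcomplements have the smallest mean addend (their sums stay below 10)
  expect_equal(which.min(tab$mean_addend), which(tab$type == "sub"))
  # supercomplements have the largest mean addend
  expect_equal(which.max(tab$mean_addend), which(tab$type == "super"))
  # default gradient: post < comp < sub < super
  lat <- tab$latency_ms
  names(lat) <- tab$type
  expect_true(lat["post"] < lat["comp"] &&
                lat["comp"] < lat["sub"] &&
                lat["sub"] < lat["super"])
})

test_that("list latency decreases as complements increase under the default gradient", {
  set.seed(13)
  log <- simulate_experiment(8, 1, seed = 13)
  lt <- list_latency_table(log)
  lat <- lt$latency_s
  names(lat) <- lt$list_type
  expect_true(lat["two"] < lat["one"] && lat["one"] < lat["none"])
})

test_that("outlier screening removes only a small share of default data", {
  set.seed(14)
  log <- simulate_experiment(8, 1, seed = 14)
  tab <- addition_latency_table(log)
  expect_lt(attr(tab, "outlier_pct"), 5)
  lt <- list_latency_table(log)
  expect_lt(attr(lt, "outlier_pct"), 5)
})

test_that("the entry interval is reported separately and added only on request", {
  log <- toy_log(correct = rep(TRUE, 6), late = rep(FALSE, 6))
  ex <- list_presentations(log)
  inc <- list_presentations(log, include_entry = TRUE)
  expect_equal(inc$latency_ms - ex$latency_ms, rep(700, 6))
})
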