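test_that("noise-free step latencies equal the closed-form means", {
  p <- exact_params(addend_slope = 20)
  expect_equal(step_latency("post", 0, 0, p), 638)
  expect_equal(step_latency("post", 3, 10, p), 638 + 60 + 10)
  expect_equal(step_latency(c("post", "comp", "sub", "super"), 0, 0, p),
               c(638, 823, 935, 1298))
  # noise-free means preserve the empirical ordering at equal size
  m <- step_latency(addition_types(), 5, 0, exact_params())
  expect_equal(order(m), order(c(638, 935, 823, 1298)))
})

test_that("noisy latencies are unbiased for the closed-form mean", {
  set.seed(2024)
  p <- sim_params()
  draws <- step_latency(rep("sub", 10000), 0, 0, p)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - 935), 3 * se)
  expect_true(all(draws > 0))
})

test_that("plan choice follows the strategy probability", {
  set.seed(7)
  p0 <- sim_params(strategy_prob = 0)
  expect_true(all(replicate(30, choose_plan(15, 4, 5, p0)$plan) == "linear"))
  p1 <- sim_params(strategy_prob = 1)
  pl <- choose_plan(15, 4, 5, p1)  # indirect complement
  expect_equal(pl$plan, "commuted")
  expect_equal(c(pl$step1_type, pl$step2_type), c("comp", "post"))
  # the commuted fraction estimates strategy_prob
  pp <- sim_params(strategy_prob = 0.3)
  frac <- mean(replicate(2000, choose_plan(15, 4, 5, pp)$plan) == "commuted")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
})

test_that("an error-free participant adds all 30 lists on first presentation", {
  set.seed(11)
  stim <- generate_set(1)
  log <- simulate_participant(stim, exact_params())
  expect_equal(max(log$presentation_index), 1L)
  expect_true(all(log$list_correct))
  expect_false(any(log$late_entry))
  expect_equal(length(unique(log$list_id)), 30L)
})

test_that("first-presentation error rates match the per-addition hazard closed form", {
  set.seed(21)
  h <- 0.1
  p <- sim_params(participant_sd = 0,
                  error_hazard = c(post = h, sub = h, comp = h, super = h),
                  late_prob = 0)
  obs <- 0L
  expected <- 0
  n_lists <- 0L
  for (r in 1:3) {
    stim <- generate_set(1, n_per_type = 30L)
    log <- simulate_participant(stim, p)
    first <- log[log$presentation_index == 1 & log$step_index == 1, ]
    steps <- sapply(stim, function(x) length(x$elements) - 1L)
    expected <- expected + sum(1 - (1 - h)^steps)
    obs <- obs + sum(!first$list_correct)
    n_lists <- n_lists + length(stim)
  }
  se <- sqrt(expected * (1 - expected / n_lists))
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("erroneous lists are re-presented after the whole first round", {
  set.seed(4)
  h <- 0.5
  p <- sim_params(error_hazard = c(post = h, sub = h, comp = h, super = h))
  log <- simulate_participant(generate_set(1), p)
  expect_gt(max(log$presentation_index), 1L)
  # presentation order is monotone in presentation index
  last_first <- max(which(log$presentation_index == 1))
  first_second <- min(which(log$presentation_index == 2))
  expect_gt(first_second, last_first)
  # a re-presented list appeared (incorrect or late) one index earlier
  redone <- unique(log$list_id[log$presentation_index == 2])
  for (li in redone) {
    prev <- log[log$list_id == li & log$presentation_index == 1, ]
    expect_true(!prev$list_correct[1] || prev$late_entry[1])
  }
  # every list ends in a correct, on-time presentation
  final <- log[log$step_index == 1, ]
  final <- do.call(rbind, lapply(split(final, final$list_id),
                                 function(d) d[which.max(d$presentation_index), ]))
  expect_true(all(final$list_correct & !final$late_entry))
})

test_that("an experiment has one unique set and effect per participant", {
  log <- simulate_experiment(5, 1, seed = 99)
  expect_equal(sort(unique(log$participant_id)), 1:5)
  expect_identical(log, simulate_experiment(5, 1, seed = 99))
  # default sample size matches the study's
  expect_equal(eval(formals(simulate_experiment)$n_participants), 21L)
  # stimulus sets differ between participants
  el1 <- log$addend1[log$participant_id == 1]
  el2 <- log$addend1[log$participant_id == 2]
  expect_false(identical(el1, el2))
})

test_that("participant variance collapses when the random-intercept SD is zero", {
  p_means <- function(sd) {
    log <- simulate_experiment(8, 1, sim_params(participant_sd = sd), seed = 17)
    tapply(log$latency_ms, log$participant_id, mean)
  }
  spread0 <- sd(p_means(0))
  spread300 <- sd(p_means(300))
  expect_lt(spread0, spread300)
  # with no participant effect, between-participant spread is sampling noise
  expect_lt(spread0, 60)
})

test_that("paired-addend logs record plans, dual types and both addends", {
  log <- simulate_experiment(2, 2, seed = 3)
  expect_true(all(log$chosen_plan %in% c("linear", "commuted", "associative")))
  expect_true(all(!is.na(log$addend2)))
  expect_true(all(log$dual_type %in%
                    c("1", "2", "3", "4", "5", "6a", "6b", "6c", "6d", "6e",
                      "7", "8", "9")))
  # recorded category agrees with reclassifying the recorded operands
  re <- classify_dual(log$augend, log$addend1, log$addend2)
  expect_equal(log$step_type, as.character(re$category))
})
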