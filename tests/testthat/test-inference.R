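# small synthetic modelling frames built directly, independent of the simulator
make_latency_data <- function(n_participants = 10, n_per = 40,
                              means = c(post = 800, sub = 800, comp = 800,
                                        super = 800),
                              participant_sd = 100, resid_sd = 150) {
  p_eff <- rnorm(n_participants, 0, participant_sd)
  rows <- lapply(seq_len(n_participants), function(p) {
    type <- sample(names(means), n_per, replace = TRUE)
    data.frame(
      latency_ms = means[type] + p_eff[p] + rnorm(n_per, 0, resid_sd),
      step_type = factor(type, levels = addition_types()),
      addend = sample(1:9, n_per, replace = TRUE),
      participant_id = p,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

test_that("latency contrasts are centred on zero under equal type means", {
  set.seed(101)
  d <- make_latency_data()
  fit <- fit_latency_model(d, "step_type")
  expect_true(all(abs(fit$contrasts$estimate) < 4 * fit$contrasts$se))
  # Tukey adjustment can only make p-values larger
  expect_true(all(fit$contrasts$p_adj >= fit$contrasts$p_unadj - 1e-12))
  expect_true(all(fit$contrasts$eta_p2 >= 0 & fit$contrasts$eta_p2 <= 1))
})

test_that("the latency model recovers a generated type gradient", {
  set.seed(102)
  d <- make_latency_data(means = c(post = 638, sub = 935, comp = 823,
                                   super = 1298))
  fit <- fit_latency_model(d, "step_type")
  ctr <- fit$contrasts
  ps <- ctr[ctr$pair == "post - super", ]
  expect_lt(abs(ps$estimate - (638 - 1298)), 3 * ps$se)
  expect_lt(ps$p_adj, 0.001)
  # the participant intercept SD is estimated near its generating value
  expect_gt(fit$ranef_sd, 30)
  expect_lt(fit$ranef_sd, 250)
})

test_that("degenerate grouping is reported, not hidden", {
  set.seed(103)
  d <- make_latency_data(n_participants = 1, n_per = 120, participant_sd = 0)
  expect_warning(fit <- fit_latency_model(d, "step_type"), "degenerate|singular")
  expect_lt(fit$ranef_sd, 1e-6)
})

test_that("the accuracy model detects a strong complement advantage", {
  set.seed(104)
  p_err <- c(none = 0.45, one = 0.30, two = 0.05)
  d <- expand.grid(participant_id = 1:12, rep = 1:10,
                   list_type = names(p_err))
  d$list_type <- factor(d$list_type, levels = names(p_err))
  d$error <- rbinom(nrow(d), 1, p_err[as.character(d$list_type)])
  fit <- fit_accuracy_model(d)
  ctr <- fit$contrasts
  two_vs_none <- ctr[ctr$pair == "none - two", ]
  expect_gt(two_vs_none$OR, 1)
  expect_lt(two_vs_none$p_adj, 0.001)
  expect_true(all(ctr$p_adj >= ctr$p_unadj - 1e-12))
})

test_that("a zero-variance outcome raises a structured degenerate-fit error", {
  d <- data.frame(error = 0L, list_type = rep(c("none", "one", "two"), 20),
                  participant_id = rep(1:10, 6))
  expect_error(fit_accuracy_model(d), "no variance",
               class = "decadd_degenerate_fit")
})

test_that("nested comparisons behave like likelihood-ratio tests", {
  set.seed(105)
  d <- make_latency_data(means = c(post = 638, sub = 935, comp = 823,
                                   super = 1298))
  cmp <- compare_models(d, "addend", "step_type")
  expect_gte(cmp$chi_square, 0)
  expect_equal(cmp$df, 3L)
  expect_gte(as.numeric(logLik(cmp$full)), as.numeric(logLik(cmp$base)))
  expect_gt(cmp$pseudo_r2, 0)
  # comparing a model with itself is the degenerate 0-on-0-df case
  self <- compare_models(d, "addend", character(0))
  expect_equal(self$chi_square, 0)
  expect_equal(self$df, 0L)
  # non-nested requests are refused
  expect_error(compare_models(d, "step_type", "step_type"), "nested")
})

test_that("null factors produce chi-squares near their degrees of freedom", {
  set.seed(106)
  chis <- replicate(20, {
    d <- make_latency_data(n_participants = 8, n_per = 30)
    compare_models(d, character(0), "step_type")$chi_square
  })
  # mean of chi-square(3) draws is 3; allow generous Monte-Carlo slack
  expect_lt(abs(mean(chis) - 3), 2.5)
})

test_that("the full study analysis produces the report structure end-to-end", {
  log <- simulate_experiment(5, 1, seed = 107)
  rep <- run_study_analysis(log)
  expect_s3_class(rep, "decadd_report")
  expect_named(rep$accuracy_table,
               c("list_type", "n", "n_late", "n_errors", "error_rate"))
  expect_equal(nrow(rep$addition_table), 4L)
  expect_equal(nrow(rep$list_model$contrasts), 3L)
  expect_equal(nrow(rep$addition_model$contrasts), 6L)
  expect_equal(rep$comparison_type$df, 3L)
  expect_equal(rep$comparison_size$df, 1L)
  # addition type explains more incremental variance than addend size
  expect_gt(rep$comparison_type$pseudo_r2, rep$comparison_size$pseudo_r2)
  path <- withr::local_tempfile(fileext = ".json")
  report_json(rep, path)
  js <- jsonlite::read_json(path)
  expect_true(all(c("accuracy_table", "comparison_type", "addition_table")
                  %in% names(js)))
  expect_output(print(rep), "Serial-addition analysis")
})

test_that("the paired-addend analysis adds the fine-grained type table", {
  log <- simulate_experiment(4, 2, seed = 108)
  rep <- suppressWarnings(run_study_analysis(log))
  expect_false(is.null(rep$dual_table))
  expect_equal(nrow(rep$dual_table), 13L)
  expect_true(all(c("6a", "6b", "6c") %in% rep$dual_table$type))
})
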