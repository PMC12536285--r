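#' @importFrom stats as.formula anova
NULL

# capture (but do not swallow) fitting warnings so convergence issues are
# reported with the fit instead of failing silently
.fit_with_diagnostics <- function(expr) {
  notes <- character(0)
  fit <- withCallingHandlers(
    expr,
    warning = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      notes <<- c(notes, conditionMessage(m))
      invokeRestart("muffleMessage")
    }
  )
  list(fit = fit, notes = notes)
}

.degenerate_error <- function(msg) {
  stop(structure(
    class = c("decadd_degenerate_fit", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

#' Accuracy model: binomial mixed-effects regression with Tukey contrasts
#'
#' Fits a logistic mixed model of genuine errors on list type with a
#' participant random intercept, and derives all pairwise contrasts between
#' the marginal means with Tukey adjustment. Estimates are reported on the
#' log-odds scale together with odds ratios.
#'
#' @param data Either a `trial_log` (collapsed internally to non-late first
#'   presentations) or a data frame with columns `error` (0/1), `list_type`
#'   and `participant_id`.
#' @param config A [measurement_config()] (used when `data` is a log).
#' @return An object of class `decadd_fit` with elements `model`, `family`,
#'   `emmeans`, `contrasts` (pair, estimate `b`, `OR`, SE, adjusted and
#'   unadjusted p) and `diagnostics` (convergence notes).
#' @export
fit_accuracy_model <- function(data, config = measurement_config()) {
  if (inherits(data, "trial_log")) {
    lists <- .list_presentations(data)
    if (config$accuracy_scope == "first") {
      lists <- lists[lists$presentation_index == 1L, , drop = FALSE]
    }
    lists <- lists[!lists$late_entry, , drop = FALSE]
    data <- data.frame(
      error = as.integer(!lists$list_correct),
      list_type = factor(lists$list_type,
                         levels = .list_type_levels(lists$study[1])),
      participant_id = factor(lists$participant_id)
    )
  }
  stopifnot(all(c("error", "list_type", "participant_id") %in% names(data)))
  if (!is.factor(data$list_type)) data$list_type <- factor(data$list_type)
  if (length(unique(data$error)) < 2) {
    .degenerate_error(
      "outcome has no variance (all presentations correct or all erroneous); the accuracy model is unidentifiable"
    )
  }
  fd <- .fit_with_diagnostics(
    lme4::glmer(error ~ list_type + (1 | participant_id),
                data = data, family = stats::binomial())
  )
  emm <- emmeans::emmeans(fd$fit, ~list_type)
  adj <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "tukey", infer = TRUE))
  raw <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "none"))
  contrasts <- data.frame(
    pair = as.character(adj$contrast),
    b = adj$estimate,
    OR = exp(adj$estimate),
    se = adj$SE,
    z = adj$z.ratio,
    p_adj = adj$p.value,
    p_unadj = raw$p.value,
    adjust = "tukey",
    stringsAsFactors = FALSE
  )
  structure(
    list(model = fd$fit, family = "binomial-logit",
         formula = "error ~ list_type + (1 | participant_id)",
         emmeans = as.data.frame(summary(emm)),
         contrasts = contrasts, diagnostics = fd$notes),
    class = "decadd_fit"
  )
}

#' Latency model: linear mixed-effects regression with Tukey contrasts
#'
#' Fits a linear mixed model of latency on a factor (plus optional
#' problem-size covariates) with a participant random intercept, and derives
#' Tukey-adjusted pairwise contrasts between the factor's marginal means.
#' Each contrast carries a partial eta-squared computed from its
#' t-statistic and Satterthwaite denominator degrees of freedom as
#' `t^2 / (t^2 + df)`.
#'
#' @param data Data frame with the response, the factor, optional covariates
#'   and `participant_id`.
#' @param factor_name Name of the factor column to contrast.
#' @param covariates Character vector of covariate column names.
#' @param response Name of the response column.
#' @param df_method `"satterthwaite"` (default) or `"asymptotic"` degrees of
#'   freedom for the contrasts.
#' @return A `decadd_fit` with elements `model`, `emmeans`, `contrasts`
#'   (estimate in the response's units, SE, df, t, adjusted and unadjusted
#'   p, `eta_p2`), `ranef_sd` (participant intercept SD) and `diagnostics`.
#' @export
fit_latency_model <- function(data, factor_name, covariates = character(0),
                              response = "latency_ms",
                              df_method = c("satterthwaite", "asymptotic")) {
  df_method <- match.arg(df_method)
  stopifnot(all(c(response, factor_name, "participant_id") %in% names(data)))
  if (!is.factor(data[[factor_name]])) {
    data[[factor_name]] <- factor(data[[factor_name]])
  }
  data[[factor_name]] <- droplevels(data[[factor_name]])
  data$participant_id <- factor(data$participant_id)
  rhs <- paste(c(factor_name, covariates, "(1 | participant_id)"),
               collapse = " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  # degenerate single-participant data must fit (variance ~ 0) with a
  # warning rather than fail outright
  ctrl <- lme4::lmerControl(check.nlev.gtr.1 = "warning")
  fd <- .fit_with_diagnostics(lmerTest::lmer(form, data = data,
                                             control = ctrl))
  vc <- as.data.frame(lme4::VarCorr(fd$fit))
  ranef_sd <- vc$sdcor[vc$grp == "participant_id"][1]
  if (nlevels(data$participant_id) < 2 || isTRUE(lme4::isSingular(fd$fit))) {
    warning("participant random-intercept variance is (near) zero; ",
            "grouping may be degenerate", call. = FALSE)
  }
  emm <- emmeans::emmeans(fd$fit, stats::as.formula(paste("~", factor_name)),
                          lmer.df = df_method,
                          lmerTest.limit = 1e6, pbkrtest.limit = 0)
  adj <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "tukey", infer = TRUE))
  raw <- as.data.frame(summary(emmeans::contrast(emm, "pairwise"),
                               adjust = "none"))
  tt <- if (!is.null(adj$t.ratio)) adj$t.ratio else adj$z.ratio
  dfree <- adj$df
  # under asymptotic (z) inference use the residual df for the effect-size
  # conversion so eta_p^2 does not degenerate to zero
  if (is.null(dfree) || all(!is.finite(dfree))) {
    dfree <- rep(stats::df.residual(fd$fit), length(tt))
  }
  contrasts <- data.frame(
    pair = as.character(adj$contrast),
    estimate = adj$estimate,
    se = adj$SE,
    df = dfree,
    t = tt,
    p_adj = adj$p.value,
    p_unadj = raw$p.value,
    eta_p2 = tt^2 / (tt^2 + dfree),
    adjust = "tukey",
    stringsAsFactors = FALSE
  )
  structure(
    list(model = fd$fit, family = "gaussian-identity",
         formula = deparse(form),
         emmeans = as.data.frame(summary(emm, infer = TRUE)),
         contrasts = contrasts, ranef_sd = ranef_sd,
         diagnostics = fd$notes),
    class = "decadd_fit"
  )
}

#' @method print decadd_fit
#' @export
print.decadd_fit <- function(x, ...) {
  cat(sprintf("<decadd_fit: %s>\n  %s\n", x$family, x$formula))
  print(x$contrasts, digits = 4)
  if (length(x$diagnostics)) {
    cat("  diagnostics:", paste(x$diagnostics, collapse = "; "), "\n")
  }
  invisible(x)
}

# Nakagawa-style marginal R^2: fixed-effect variance over total
# (fixed + random + residual) variance
.marginal_r2 <- function(fit) {
  fe <- as.vector(stats::model.matrix(fit) %*% lme4::fixef(fit))
  var_f <- stats::var(fe)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_r <- sum(vc$vcov[vc$grp != "Residual"])
  var_e <- stats::sigma(fit)^2
  var_f / (var_f + var_r + var_e)
}

#' Nested model comparison (likelihood-ratio test and incremental pseudo-R2)
#'
#' Fits two nested linear mixed models by maximum likelihood — a baseline
#' with `base_factors` and a full model adding `added_factor` — and reports
#' the likelihood-ratio chi-square, its degrees of freedom (the difference
#' in fixed-effect parameter counts), the p-value, and the incremental
#' pseudo-R2 of the added factor. Two pseudo-R2 variants are reported: the
#' default is the gain in marginal R2 (fixed-effect variance over total
#' variance); the alternative is the likelihood-based
#' `1 - exp(-chi^2 / n)`.
#'
#' @param data Data frame with the response, factors and `participant_id`.
#' @param base_factors Character vector of baseline fixed-effect terms (may
#'   be empty for an intercept-only baseline).
#' @param added_factor Character vector of terms added in the full model
#'   (empty compares the baseline with itself: chi-square 0 on 0 df).
#' @param response Response column name.
#' @return An object of class `decadd_comparison`: `chi_square`, `df`, `p`,
#'   `pseudo_r2` (marginal-R2 gain), `pseudo_r2_lik`, plus both fits.
#' @export
compare_models <- function(data, base_factors, added_factor,
                           response = "latency_ms") {
  stopifnot(response %in% names(data), "participant_id" %in% names(data))
  if (any(added_factor %in% base_factors)) {
    stop("added_factor already appears in the baseline; ",
         "models must be strictly nested", call. = FALSE)
  }
  data$participant_id <- factor(data$participant_id)
  mk <- function(terms) {
    rhs <- paste(c(if (length(terms)) terms else "1", "(1 | participant_id)"),
                 collapse = " + ")
    stats::as.formula(paste(response, "~", rhs))
  }
  base_fit <- .fit_with_diagnostics(
    lme4::lmer(mk(base_factors), data = data, REML = FALSE)
  )$fit
  if (length(added_factor) == 0) {
    out <- list(chi_square = 0, df = 0L, p = NA_real_,
                pseudo_r2 = 0, pseudo_r2_lik = 0,
                base = base_fit, full = base_fit)
    return(structure(out, class = "decadd_comparison"))
  }
  full_fit <- .fit_with_diagnostics(
    lme4::lmer(mk(c(base_factors, added_factor)), data = data, REML = FALSE)
  )$fit
  lrt <- suppressMessages(anova(base_fit, full_fit))
  chi <- lrt$Chisq[2]
  dfd <- lrt$Df[2]
  n <- stats::nobs(full_fit)
  structure(
    list(chi_square = chi, df = as.integer(dfd), p = lrt$`Pr(>Chisq)`[2],
         pseudo_r2 = .marginal_r2(full_fit) - .marginal_r2(base_fit),
         pseudo_r2_lik = 1 - exp(-chi / n),
         base = base_fit, full = full_fit),
    class = "decadd_comparison"
  )
}

#' @method print decadd_comparison
#' @export
print.decadd_comparison <- function(x, ...) {
  cat(sprintf("chi-square(%d) = %.2f, p = %.3g; incremental pseudo-R2 = %.3f (likelihood variant %.3f)\n",
              x$df, x$chi_square,
              if (is.na(x$p)) NA else x$p, x$pseudo_r2, x$pseudo_r2_lik))
  invisible(x)
}

# addition-level modelling frame: correct, on-time, outlier-screened steps
.addition_data <- function(log, config = measurement_config()) {
  if (config$latency_scope == "correct") {
    log <- log[log$list_correct & !log$late_entry, , drop = FALSE]
  }
  log <- log[screen_outliers(log$latency_ms, config), , drop = FALSE]
  study <- log$study[1]
  data.frame(
    latency_ms = log$latency_ms,
    step_type = factor(log$step_type, levels = addition_types()),
    dual_type = log$dual_type,
    addend = if (study == 1L) log$addend1 else log$addend1 + log$addend2,
    total = log$augend +
      (if (study == 1L) log$addend1 else log$addend1 + log$addend2),
    participant_id = factor(log$participant_id),
    stringsAsFactors = FALSE
  )
}

# list-level modelling frame: correct, on-time, outlier-screened lists
.list_data <- function(log, config = measurement_config()) {
  lists <- .list_presentations(log, include_entry = config$include_entry)
  if (config$latency_scope == "correct") {
    lists <- lists[lists$list_correct & !lists$late_entry, , drop = FALSE]
  }
  lists <- lists[screen_outliers(lists$latency_ms, config), , drop = FALSE]
  lists$latency_s <- lists$latency_ms / 1000
  lists$list_type <- factor(lists$list_type,
                            levels = .list_type_levels(lists$study[1]))
  lists$participant_id <- factor(lists$participant_id)
  lists
}

#' Full study analysis: tables, contrasts and model comparisons
#'
#' Orchestrates measurement and inference into the study's report shape:
#' first-presentation accuracy by list type with binomial-model contrasts;
#' list latency by list type with linear-model contrasts; individual-addition
#' latency by addition type with contrasts; and the nested model comparisons
#' pitting addition type against problem size (operationalized as addend
#' size). For the paired-addend study the fine-grained nine-type latency
#' table is added.
#'
#' @param log A `trial_log`.
#' @param study 1 or 2 (defaults to the log's `study` attribute/column).
#' @param config A [measurement_config()].
#' @return An object of class `decadd_report`.
#' @export
run_study_analysis <- function(log, study = NULL,
                               config = measurement_config()) {
  if (is.null(study)) study <- log$study[1]
  study <- as.integer(study)
  report <- list(study = study)

  report$accuracy_table <- first_presentation_accuracy(log, config)
  report$accuracy_model <- tryCatch(
    fit_accuracy_model(log, config),
    decadd_degenerate_fit = function(e) {
      list(error = conditionMessage(e))
    }
  )

  ldat <- .list_data(log, config)
  report$list_table <- list_latency_table(log, config)
  report$list_model <- fit_latency_model(ldat, "list_type",
                                         response = "latency_s")

  adat <- .addition_data(log, config)
  report$addition_table <- addition_latency_table(log, config)
  report$addition_model <- fit_latency_model(adat, "step_type")

  report$comparison_type <- compare_models(adat, "addend", "step_type")
  report$comparison_size <- compare_models(adat, "step_type", "addend")

  if (study == 2L) {
    report$dual_table <- addition_latency_table(log, config, by = "dual")
  }
  structure(report, class = "decadd_report")
}

#' @method print decadd_report
#' @export
print.decadd_report <- function(x, ...) {
  cat(sprintf("== Serial-addition analysis, study %d ==\n\n", x$study))
  cat("First-presentation accuracy by list type:\n")
  print(x$accuracy_table, digits = 3)
  cat("\nList latency by list type:\n")
  print(x$list_table, digits = 4)
  if (!is.null(x$list_model$contrasts)) {
    cat("\nList-latency contrasts (Tukey-adjusted):\n")
    print(x$list_model$contrasts, digits = 3)
  }
  cat("\nIndividual-addition latency by addition type:\n")
  print(x$addition_table, digits = 4)
  cat("\nAddition type vs problem size (nested model comparisons):\n")
  cat("  adding addition type: ")
  print(x$comparison_type)
  cat("  adding addend size:   ")
  print(x$comparison_size)
  if (!is.null(x$dual_table)) {
    cat("\nFine-grained dual addition types:\n")
    print(x$dual_table, digits = 4)
  }
  invisible(x)
}

#' @method summary decadd_report
#' @export
summary.decadd_report <- function(object, ...) print(object, ...)

#' Serialize a report to JSON
#'
#' Writes the report's tables, contrasts and comparison statistics as a
#' machine-readable JSON document.
#'
#' @param report A `decadd_report`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string) invisibly.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(
    study = report$study,
    accuracy_table = report$accuracy_table,
    accuracy_contrasts = if (!is.null(report$accuracy_model$contrasts)) {
      report$accuracy_model$contrasts
    } else {
      report$accuracy_model$error
    },
    list_table = report$list_table,
    list_contrasts = report$list_model$contrasts,
    addition_table = report$addition_table,
    addition_contrasts = report$addition_model$contrasts,
    comparison_type = report$comparison_type[
      c("chi_square", "df", "p", "pseudo_r2", "pseudo_r2_lik")],
    comparison_size = report$comparison_size[
      c("chi_square", "df", "p", "pseudo_r2", "pseudo_r2_lik")],
    dual_table = report$dual_table
  )
  json <- jsonlite::toJSON(payload, dataframe = "rows", auto_unbox = TRUE,
                           digits = NA, na = "null", pretty = TRUE)
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
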