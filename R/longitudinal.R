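# Time-course and ancillary models: the productivity-richness relationship
# at the start, its trajectory over weeks (mixed model), the extinction GLM,
# and the isolate-yield trend with source-community diversity.

.eep_trend_fit <- function(label, fit, coefficients, anova_table = NULL) {
  structure(list(label = label, fit = fit, coefficients = coefficients,
                 anova = anova_table, aic = stats::AIC(fit),
                 loglik = as.numeric(stats::logLik(fit))),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat("Trend fit:", x$label, "\n")
  print(x$coefficients, digits = 3, row.names = FALSE)
  cat("AIC =", format(x$aic, digits = 6),
      " logLik =", format(x$loglik, digits = 6), "\n")
  invisible(x)
}

.eep_lm_coef_table <- function(fit) {
  cf <- summary(fit)$coefficients
  data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
             statistic = cf[, 3], df = fit$df.residual, p_value = cf[, 4],
             row.names = NULL)
}

#' Productivity-richness relationship in the first growth period
#'
#' Linear model of week-0 yield (all microcosms, monocultures included) on
#' environment interacting with log richness — the classical
#' diversity-productivity regression — with the environment x richness
#' interaction F test.
#'
#' @param yields Yield table.
#' @param design Design table.
#' @param week Week analysed (default 0, the first period after the
#'   environmental split).
#' @return A `trend_fit`; its `anova` element holds the interaction F test.
#' @export
fit_initial_richness_model <- function(yields, design, week = 0) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  dat <- yields[yields$week == week, , drop = FALSE]
  if (nrow(dat) == 0L) stop("no observations at week ", week)
  dat$environment <- normalize_environment(dat$environment)
  missing_env <- setdiff(environments(), as.character(unique(dat$environment)))
  if (length(missing_env) > 0L) {
    stop("missing environment level(s): ", paste(missing_env, collapse = ", "))
  }
  dat$logS <- log(rich[dat$composition_id])
  if (stats::var(dat$logS) == 0) {
    stop("richness is constant; no diversity-productivity slope to fit")
  }
  fit <- stats::lm(yield ~ environment * logS, data = dat)
  an <- stats::anova(fit)
  .eep_trend_fit("yield ~ environment * log(richness), week 0", fit,
                 .eep_lm_coef_table(fit),
                 data.frame(term = rownames(an), df = an$Df,
                            f = an$`F value`, p_value = an$`Pr(>F)`,
                            row.names = NULL))
}

#' Mixed model of the yield trajectory over weeks
#'
#' Community-and-monoculture yields across all observed weeks, with fixed
#' effects time x log richness x environment (all two- and three-way
#' interactions), a per-microcosm random intercept, maximum-likelihood
#' fitting, backward AIC simplification of the fixed effects, and a final
#' REML refit for reporting.
#'
#' @param yields Yield table with two or more weeks.
#' @param design Design table.
#' @return A `trend_fit` whose `fit` is the REML refit; the element
#'   `retained` lists the fixed-effect terms surviving simplification.
#' @export
fit_time_mixed_model <- function(yields, design) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  dat <- yields
  dat$environment <- normalize_environment(dat$environment)
  dat$logS <- log(rich[dat$composition_id])
  dat$week <- as.numeric(dat$week)
  if (length(unique(dat$week)) < 2L) {
    stop("need observations at two or more weeks")
  }
  fitter <- function(f, d) {
    nlme::lme(f, random = ~ 1 | microcosm_id, data = d, method = "ML",
              control = nlme::lmeControl(returnObject = TRUE))
  }
  step <- .eep_step_backward(yield ~ week * logS * environment, dat, fitter)
  reml <- nlme::lme(step$formula, random = ~ 1 | microcosm_id, data = dat,
                    method = "REML",
                    control = nlme::lmeControl(returnObject = TRUE))
  tt <- summary(reml)$tTable
  out <- .eep_trend_fit(
    "yield ~ week * log(richness) * environment, random ~1|microcosm (REML)",
    reml,
    data.frame(term = rownames(tt), estimate = tt[, "Value"],
               se = tt[, "Std.Error"], statistic = tt[, "t-value"],
               df = tt[, "DF"], p_value = tt[, "p-value"], row.names = NULL))
  out$retained <- step$retained
  out$dropped <- step$dropped
  out
}

#' Binomial GLM of extinction on richness and environment
#'
#' Models the per-species extinction indicator on log richness and
#' environment with binomial errors, reporting per-term z statistics.
#' Complete separation is flagged with a warning.
#'
#' @param survival Survival table.
#' @param microcosms Microcosm roster from [expand_microcosms()] (supplies
#'   richness and environment).
#' @return A `trend_fit`; helper [predicted_extinction()] evaluates the
#'   fitted extinction probability at chosen richness and environment.
#' @export
extinction_glm <- function(survival, microcosms) {
  m <- match(survival$microcosm_id, microcosms$microcosm_id)
  dat <- data.frame(
    extinct = 1L - survival$survived,
    logS = log(microcosms$richness[m]),
    environment = normalize_environment(microcosms$environment[m]))
  if (length(unique(dat$extinct)) < 2L) {
    stop("cannot fit extinction model: only one outcome class present")
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(extinct ~ logS + environment, family = stats::binomial(),
               data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1",
                conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) warning("possible separation in extinction model")
  cf <- summary(fit)$coefficients
  out <- .eep_trend_fit(
    "extinct ~ log(richness) + environment (binomial)", fit,
    data.frame(term = rownames(cf), estimate = cf[, 1], se = cf[, 2],
               statistic = cf[, 3], df = fit$df.residual, p_value = cf[, 4],
               row.names = NULL))
  out$separation <- separation
  out
}

#' Fitted extinction probability at a richness and environment
#'
#' @param trend A `trend_fit` from [extinction_glm()].
#' @param richness Community richness.
#' @param environment Environment label.
#' @return Fitted extinction probability.
#' @export
predicted_extinction <- function(trend, richness = 12, environment = "beech") {
  nd <- data.frame(logS = log(richness),
                   environment = normalize_environment(environment))
  unname(stats::predict(trend$fit, newdata = nd, type = "response"))
}

#' Trend of isolate yields with source-community diversity
#'
#' Linear model of the isolate yield relative to its matched ancestral
#' isolate on log source richness and environment; the richness slope t test
#' is the headline statistic. Rows with a non-positive ancestral yield are
#' excluded with a message.
#'
#' @param isolates Isolate table.
#' @return A `trend_fit`; element `richness_slope` is the log-richness row
#'   of the coefficient table.
#' @export
isolate_yield_trend <- function(isolates) {
  bad <- isolates$ancestral_yield <= 0
  if (any(bad)) {
    message("excluding ", sum(bad), " isolate row(s) with non-positive ",
            "ancestral yield")
    isolates <- isolates[!bad, , drop = FALSE]
  }
  if (length(unique(isolates$source_richness)) < 2L) {
    stop("need isolates from more than one richness level")
  }
  dat <- data.frame(
    rel_yield = isolates$yield / isolates$ancestral_yield,
    logS = log(isolates$source_richness),
    environment = normalize_environment(isolates$environment))
  fit <- stats::lm(rel_yield ~ logS + environment, data = dat)
  out <- .eep_trend_fit("relative isolate yield ~ log(source richness) + environment",
                        fit, .eep_lm_coef_table(fit))
  out$richness_slope <- out$coefficients[out$coefficients$term == "logS", ]
  out
}
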