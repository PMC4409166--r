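# Counterfactual regression framework. A baseline linear model of community
# yield on the additive sum of monoculture yields (slopes and intercepts
# varying with environment and log richness) is fitted at week 0 and its
# frozen coefficients are applied to counterfactual additive sums to predict
# week-5 yields under hypothesised mechanisms: extinction only, additive
# evolution of species yields, or both. Refitting the coefficients at week 5
# (by richness, then by composition) quantifies evolution of species
# interactions. Adjusted R-squared of the observed-versus-predicted change
# regressions yields the variance-decomposition ledger.

# ---- additive sums ---------------------------------------------------------

.eep_mono_lookup <- function(yields, design, week) {
  mono <- monoculture_yields(yields, design, week = week)
  stats::setNames(mono$yield, paste(mono$species_id, mono$environment,
                                    mono$replicate, sep = "|"))
}

.eep_survival_mask <- function(survival) {
  stats::setNames(survival$survived,
                  paste(survival$microcosm_id, survival$species_id, sep = "|"))
}

# additive sum for each community microcosm row of `comm`
# source "mono": sum of monoculture yields measured at `a_week` in the same
#   environment and replicate; source "isolate": sum of community-isolate
#   yields (survivors only, which makes the survival mask implicit)
.eep_addsums <- function(comm, design, yields = NULL, a_week = 0,
                         source = c("mono", "isolate"),
                         survival = NULL, apply_survival = FALSE,
                         isolates = NULL) {
  source <- match.arg(source)
  members <- composition_members(design)
  lookup <- if (source == "mono") .eep_mono_lookup(yields, design, a_week)
  mask <- if (!is.null(survival)) .eep_survival_mask(survival)
  vapply(seq_len(nrow(comm)), function(i) {
    mem <- members[[comm$composition_id[i]]]
    if (source == "mono") {
      a <- lookup[paste(mem, comm$environment[i], comm$replicate[i],
                        sep = "|")]
      if (anyNA(a)) {
        stop("no monoculture yield at week ", a_week, " for species: ",
             paste(mem[is.na(a)], collapse = ", "))
      }
      eps <- rep(1, length(mem))
      if (apply_survival) {
        eps <- as.numeric(mask[paste(comm$microcosm_id[i], mem, sep = "|")])
        if (anyNA(eps)) stop("survival entry missing for microcosm ",
                             comm$microcosm_id[i])
      }
      sum(a * eps)
    } else {
      iso <- isolates[isolates$microcosm_id == comm$microcosm_id[i], ,
                      drop = FALSE]
      eps <- mask[paste(comm$microcosm_id[i], mem, sep = "|")]
      survivors <- mem[!is.na(eps) & eps == 1]
      missing_iso <- setdiff(survivors, iso$species_id)
      if (length(missing_iso) > 0L) {
        stop("isolate yield missing for surviving species ",
             paste(missing_iso, collapse = ", "), " in microcosm ",
             comm$microcosm_id[i])
      }
      sum(iso$yield[iso$species_id %in% mem])
    }
  }, numeric(1))
}

#' Assemble the community analysis frame for one week
#'
#' One row per community microcosm (richness >= 2) at the given week, with
#' the observed yield, the additive sum of the requested source, environment,
#' log richness and composition factor.
#'
#' @param yields Yield table.
#' @param design Design table.
#' @param week Week of the observed community yields.
#' @param a_week Week of the monoculture yields entering the additive sum.
#' @param source `"mono"` or `"isolate"`.
#' @param survival Survival table (needed for `apply_survival` or isolates).
#' @param apply_survival Mask extinct species out of the additive sum.
#' @param isolates Isolate table (for `source = "isolate"`).
#' @param surviving_richness Use the number of surviving species (rather than
#'   starting richness) for `logS`.
#' @return Data frame with columns `microcosm_id`, `composition_id`,
#'   `environment`, `replicate`, `richness`, `logS`, `yield`, `addsum`.
#' @export
community_frame <- function(yields, design, week = 0, a_week = week,
                            source = "mono", survival = NULL,
                            apply_survival = FALSE, isolates = NULL,
                            surviving_richness = FALSE) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  wk <- yields[yields$week == week, , drop = FALSE]
  comm <- wk[rich[wk$composition_id] >= 2L, , drop = FALSE]
  comm$richness <- unname(rich[comm$composition_id])
  comm$starting_richness <- comm$richness
  comm$addsum <- .eep_addsums(comm, design, yields = yields, a_week = a_week,
                              source = source, survival = survival,
                              apply_survival = apply_survival,
                              isolates = isolates)
  if (surviving_richness) {
    mask <- .eep_survival_mask(survival)
    comm$richness <- vapply(seq_len(nrow(comm)), function(i) {
      mem <- members[[comm$composition_id[i]]]
      max(sum(mask[paste(comm$microcosm_id[i], mem, sep = "|")]), 1L)
    }, numeric(1))
  }
  comm$logS <- log(comm$richness)
  comm$environment <- normalize_environment(comm$environment)
  comm$composition <- factor(comm$composition_id)
  row.names(comm) <- NULL
  comm
}

# ---- stepwise AIC ----------------------------------------------------------

# which terms may be dropped without violating marginality
.eep_droppable <- function(tt) {
  labs <- attr(tt, "term.labels")
  if (length(labs) == 0L) return(logical(0))
  fac <- attr(tt, "factors")
  ord <- attr(tt, "order")
  vars <- lapply(seq_along(labs), function(j) rownames(fac)[fac[, j] > 0])
  vapply(seq_along(labs), function(j) {
    !any(vapply(seq_along(labs), function(k) {
      k != j && ord[k] > ord[j] && all(vars[[j]] %in% vars[[k]])
    }, logical(1)))
  }, logical(1))
}

.eep_step_backward <- function(formula, data, fitter, protect = character()) {
  current_formula <- formula
  current_fit <- fitter(current_formula, data)
  current_aic <- stats::AIC(current_fit)
  dropped <- character(0)
  repeat {
    tt <- stats::terms(current_formula)
    labs <- attr(tt, "term.labels")
    if (length(labs) <= 1L && length(labs) <= length(protect)) break
    cand <- labs[.eep_droppable(tt)]
    cand <- setdiff(cand, protect)
    if (length(cand) == 0L) break
    trials <- lapply(cand, function(lab) {
      f <- stats::update(current_formula, paste(". ~ . -", lab))
      fit <- fitter(f, data)
      list(label = lab, formula = f, fit = fit, aic = stats::AIC(fit),
           order = length(strsplit(lab, ":", fixed = TRUE)[[1]]))
    })
    aics <- vapply(trials, `[[`, numeric(1), "aic")
    if (min(aics) >= current_aic - 1e-10) break
    best_aic <- min(aics)
    tied <- which(aics <= best_aic + 1e-8)
    # ties: drop the higher-order term first
    pick <- tied[which.max(vapply(trials[tied], `[[`, numeric(1), "order"))]
    current_formula <- trials[[pick]]$formula
    current_fit <- trials[[pick]]$fit
    current_aic <- trials[[pick]]$aic
    dropped <- c(dropped, trials[[pick]]$label)
  }
  list(fit = current_fit, formula = current_formula, aic = current_aic,
       dropped = dropped,
       retained = attr(stats::terms(current_formula), "term.labels"))
}

#' Backward AIC simplification of a fitted model
#'
#' Repeatedly removes the term whose removal lowers AIC the most, respecting
#' marginality (a main effect is never removed while one of its interactions
#' remains), and stops when no removal lowers AIC. Ties are broken by
#' removing the higher-order term first.
#'
#' @param object A fitted `lm` (or an `interaction_model`).
#' @param data The data the model was fitted to; defaults to the stored
#'   model frame.
#' @param protect Character vector of term labels never to drop.
#' @return A list with elements `fit`, `formula`, `aic`, `dropped`,
#'   `retained`.
#' @export
simplify_by_aic <- function(object, data = NULL, protect = character()) {
  if (inherits(object, "interaction_model")) object <- object$fit
  stopifnot(inherits(object, "lm"))
  if (is.null(data)) data <- stats::model.frame(object)
  .eep_step_backward(stats::formula(object), data,
                     function(f, d) stats::lm(f, data = d),
                     protect = protect)
}

# ---- the interaction model (models 0, 4, 5) --------------------------------

.eep_new_interaction_model <- function(step, data, time) {
  fit <- step$fit
  sm <- summary(fit)
  structure(list(
    fit = fit, formula = step$formula, time = time, n_obs = nrow(data),
    adjusted_r2 = sm$adj.r.squared, aic = stats::AIC(fit),
    retained_terms = step$retained, dropped_terms = step$dropped),
    class = "interaction_model")
}

#' Fit the baseline interaction model (model 0)
#'
#' Least-squares fit of community yield on the additive sum with slopes and
#' intercepts that may vary with environment and log richness, simplified by
#' backward AIC elimination. Under exactly additive data the fit recovers
#' slope 1 and intercept 0. This is the week-0 baseline whose frozen
#' coefficients all counterfactual predictions reuse.
#'
#' @param data Community frame from [community_frame()] (communities only,
#'   richness >= 2).
#' @param formula Full model before simplification.
#' @param simplify Apply [simplify_by_aic()]?
#' @param allow_aliased Tolerate rank deficiency (aliased coefficients are
#'   dropped with a warning instead of an error); used for the
#'   composition-factor model whose replicate cells can be degenerate.
#' @param time Week label stored on the model.
#' @return Object of class `interaction_model`.
#' @export
fit_baseline <- function(data, formula = yield ~ addsum * environment * logS,
                         simplify = TRUE, allow_aliased = FALSE, time = 0) {
  stopifnot(all(c("yield", "addsum", "environment", "logS") %in% names(data)))
  # design richness decides community status; the sensitivity variant may
  # carry surviving richness 1 for communities reduced to one survivor
  design_rich <- if (!is.null(data$starting_richness)) data$starting_richness
  else data$richness
  if (any(design_rich < 2)) {
    stop("baseline model is fitted on communities only (richness >= 2)")
  }
  n_distinct <- tapply(data$addsum, data$environment,
                       function(x) length(unique(x)))
  if (any(n_distinct < 2, na.rm = TRUE)) {
    stop("need >= 2 distinct additive sums per environment")
  }
  full <- stats::lm(formula, data = data)
  if (anyNA(stats::coef(full))) {
    aliased <- names(stats::coef(full))[is.na(stats::coef(full))]
    if (!allow_aliased) {
      stop("rank-deficient model; collinear terms: ",
           paste(aliased, collapse = ", "))
    }
    warning("aliased coefficients dropped: ",
            paste(utils::head(aliased, 5L), collapse = ", "),
            if (length(aliased) > 5L) " ..." else "")
  }
  step <- if (simplify) {
    .eep_step_backward(formula, data,
                       function(f, d) stats::lm(f, data = d))
  } else {
    list(fit = full, formula = formula, aic = stats::AIC(full),
         dropped = character(0),
         retained = attr(stats::terms(formula), "term.labels"))
  }
  .eep_new_interaction_model(step, data, time)
}

#' @export
predict.interaction_model <- function(object, newdata, ...) {
  unname(stats::predict(object$fit, newdata = newdata))
}

#' @export
print.interaction_model <- function(x, ...) {
  cat("Interaction model (week ", x$time, "), n = ", x$n_obs, "\n",
      "  retained terms: ", paste(x$retained_terms, collapse = ", "), "\n",
      "  adjusted R-squared = ", format(x$adjusted_r2, digits = 4),
      ", AIC = ", format(x$aic, digits = 6), "\n", sep = "")
  invisible(x)
}

#' Effective slope and intercept of an interaction model
#'
#' The model's prediction is linear in the additive sum at any fixed
#' environment and richness; this extracts that line.
#'
#' @param model An `interaction_model`.
#' @param environment Environment label.
#' @param richness Community richness.
#' @param composition Composition id (required by composition-factor models).
#' @return List with `slope` and `intercept`.
#' @export
baseline_slope_intercept <- function(model, environment = "beech",
                                     richness = 2, composition = NULL) {
  nd <- data.frame(addsum = c(0, 1),
                   environment = normalize_environment(rep(environment, 2)),
                   logS = log(richness))
  if (!is.null(composition)) nd$composition <- factor(composition)
  p <- predict(model, nd)
  list(slope = p[2] - p[1], intercept = p[1])
}

# ---- counterfactual predictions --------------------------------------------

.EEP_SCENARIO_TABLE <- data.frame(
  name = c("extinction_only", "additive_mono", "additive_isolate",
           "extinction_plus_additive_mono", "extinction_plus_additive_isolate"),
  a_week = c(0, 5, NA, 5, NA),
  source = c("mono", "mono", "isolate", "mono", "isolate"),
  apply_survival = c(TRUE, FALSE, FALSE, TRUE, TRUE),
  stringsAsFactors = FALSE)

#' Counterfactual week-5 yield predictions under frozen coefficients
#'
#' Applies the week-0 baseline coefficients, unchanged, to the additive sum
#' a named scenario prescribes: `extinction_only` uses week-0 monoculture
#' yields masked by survival; `additive_mono` uses week-5 monoculture yields
#' (no mask); `additive_isolate` uses community-isolate yields (survivors
#' only, so the mask is implicit); the `extinction_plus_*` variants apply the
#' survival mask to the week-5 yields. Coefficients are never re-estimated.
#'
#' @param model0 Week-0 `interaction_model` from [fit_baseline()].
#' @param scenario Scenario name (see above).
#' @param yields,design,survival,isolates The experiment tables.
#' @return Data frame with `microcosm_id`, `addsum` (the scenario sum) and
#'   `predicted` (predicted week-5 yield).
#' @export
counterfactual_prediction <- function(model0, scenario, yields, design,
                                      survival, isolates = NULL) {
  sc <- .EEP_SCENARIO_TABLE[.EEP_SCENARIO_TABLE$name == scenario, ]
  if (nrow(sc) != 1L) {
    stop("unknown counterfactual scenario: ", scenario, " (expected one of ",
         paste(.EEP_SCENARIO_TABLE$name, collapse = ", "), ")")
  }
  if (sc$source == "isolate" && is.null(isolates)) {
    stop("scenario ", scenario, " requires an isolate table")
  }
  # scenario sums are evaluated for the week-5 community roster
  comm <- community_frame(yields, design, week = 5, a_week = 0,
                          source = "mono")
  comm$addsum <- .eep_addsums(comm, design, yields = yields,
                              a_week = if (is.na(sc$a_week)) 5 else sc$a_week,
                              source = sc$source, survival = survival,
                              apply_survival = sc$apply_survival,
                              isolates = isolates)
  data.frame(microcosm_id = comm$microcosm_id, addsum = comm$addsum,
             predicted = predict(model0, comm), stringsAsFactors = FALSE)
}

# ---- evaluation ------------------------------------------------------------

#' Evaluate a counterfactual against the observed change
#'
#' Simple linear regression of the observed change in community yields on
#' the predicted change, summarised by the slope's t test, adjusted
#' R-squared and AIC — one row of the model-comparison table.
#'
#' @param observed_change Observed `A(week 5) - A(week 0)` per community.
#' @param predicted_change Predicted change, same order.
#' @param model Model id for the output row.
#' @param label Human-readable description.
#' @param intercept Include an intercept in the evaluation regression?
#' @return One-row data frame of class `evaluation_row` with columns
#'   `model`, `label`, `n`, `slope`, `intercept`, `t`, `p_value`,
#'   `adjusted_r2`, `aic`, `flag`.
#' @export
evaluate_counterfactual <- function(observed_change, predicted_change,
                                    model = "", label = "",
                                    intercept = TRUE) {
  n <- length(observed_change)
  stopifnot(length(predicted_change) == n)
  if (n < 3L) stop("need at least 3 paired changes")
  if (stats::sd(predicted_change) == 0) {
    return(structure(data.frame(
      model = model, label = label, n = n, slope = NA_real_,
      intercept = NA_real_, t = NA_real_, p_value = NA_real_,
      adjusted_r2 = NA_real_, aic = NA_real_,
      flag = "zero-variance predictions", stringsAsFactors = FALSE),
      class = c("evaluation_row", "data.frame")))
  }
  f <- if (intercept) observed_change ~ predicted_change else
    observed_change ~ predicted_change - 1
  fit <- stats::lm(f)
  sm <- summary(fit)
  cf <- sm$coefficients["predicted_change", ]
  structure(data.frame(
    model = model, label = label, n = n,
    slope = unname(cf["Estimate"]),
    intercept = if (intercept) unname(stats::coef(fit)[1]) else 0,
    t = unname(cf["t value"]), p_value = unname(cf["Pr(>|t|)"]),
    adjusted_r2 = sm$adj.r.squared, aic = stats::AIC(fit),
    flag = "", stringsAsFactors = FALSE),
    class = c("evaluation_row", "data.frame"))
}

#' Refit the interaction model at week 5 (models 4 and 5)
#'
#' Same structure as the baseline but with coefficients estimated at week 5,
#' quantifying changed species interactions. With `grouping = "richness"`
#' (model 4) slopes and intercepts vary with environment and log richness;
#' with `grouping = "composition"` (model 5) the richness covariate is
#' replaced by the composition factor, capturing composition-specific
#' interaction change. The composition model is fitted without stepwise
#' simplification and tolerates aliased cells.
#'
#' @param data Week-5 community frame (additive sums already of the chosen
#'   additive source).
#' @param grouping `"richness"` or `"composition"`.
#' @param simplify Apply backward AIC elimination (model 4 only).
#' @return An `interaction_model` with `time = 5`.
#' @export
refit_with_time <- function(data, grouping = c("richness", "composition"),
                            simplify = TRUE) {
  grouping <- match.arg(grouping)
  if (grouping == "richness") {
    fit_baseline(data, formula = yield ~ addsum * environment * logS,
                 simplify = simplify, time = 5)
  } else {
    if (min(table(data$composition, data$environment)) < 2L) {
      stop("composition model needs >= 2 replicates per composition x ",
           "environment cell")
    }
    fit_baseline(data, formula = yield ~ addsum * environment * composition,
                 simplify = FALSE, allow_aliased = TRUE, time = 5)
  }
}

# ---- the ledger ------------------------------------------------------------

#' Decompose change-in-yield variance into mechanism shares
#'
#' Converts the adjusted R-squared values of the model-comparison table into
#' the variance-decomposition ledger: extinction explains `R2(m1)`; additive
#' evolution of species yields `R2(m2)`; systematic interaction change
#' within environment and richness treatments `R2(m4) - R2(m2)`;
#' composition-specific interaction change `R2(m5) - R2(m4)`; the remainder
#' `1 - R2(m5)` is residual variation among replicates. The additive,
#' systematic, composition and residual shares sum to 100 %; the extinction
#' share is nested within the additive-model baseline and reported
#' separately.
#'
#' @param r2 Named numeric vector with elements `m1`, `m2`, `m4`, `m5`
#'   (adjusted R-squared of the evaluation regressions), or a data frame
#'   with columns `model` and `adjusted_r2` containing those models.
#' @return Object of class `partition_ledger`: a list of the five
#'   percentages.
#' @export
#' @examples
#' decompose_variance(c(m1 = 0.0035, m2 = 0.177, m4 = 0.320, m5 = 0.795))
decompose_variance <- function(r2) {
  if (is.data.frame(r2)) {
    r2 <- stats::setNames(r2$adjusted_r2, paste0("m", r2$model))
  }
  need <- c("m1", "m2", "m4", "m5")
  if (!all(need %in% names(r2))) {
    stop("decompose_variance needs adjusted R-squared for models ",
         paste(setdiff(need, names(r2)), collapse = ", "))
  }
  r2 <- r2[need]
  if (r2[["m5"]] < r2[["m4"]]) {
    warning("adjusted R2 of the composition model is below the richness ",
            "model; negative increment reported as-is")
  }
  structure(list(
    pct_extinction = 100 * r2[["m1"]],
    pct_additive = 100 * r2[["m2"]],
    pct_interaction_systematic = 100 * (r2[["m4"]] - r2[["m2"]]),
    pct_interaction_composition = 100 * (r2[["m5"]] - r2[["m4"]]),
    pct_residual = 100 * (1 - r2[["m5"]])),
    class = "partition_ledger")
}

#' @export
print.partition_ledger <- function(x, ...) {
  cat("Variance decomposition of the change in community yields (%):\n")
  cat(sprintf("  extinction (ecological sorting)      %6.2f  [nested, not summed]\n",
              x$pct_extinction))
  cat(sprintf("  additive evolution of species yields %6.2f\n", x$pct_additive))
  cat(sprintf("  interaction change (systematic)      %6.2f\n",
              x$pct_interaction_systematic))
  cat(sprintf("  interaction change (composition)     %6.2f\n",
              x$pct_interaction_composition))
  cat(sprintf("  residual among replicates            %6.2f\n", x$pct_residual))
  invisible(x)
}

# ---- the full partition analysis -------------------------------------------

#' Partition the change in community yields into mechanism contributions
#'
#' Runs the whole counterfactual analysis: fits the week-0 baseline,
#' predicts week-5 yields under the extinction-only and additive-evolution
#' counterfactuals (models 1-3), selects the additive model by AIC of the
#' evaluation regression, refits the coefficients at week 5 by richness
#' (model 4) and by composition (model 5), and assembles the
#' model-comparison table and variance-decomposition ledger.
#'
#' @param yields,design,survival Experiment tables.
#' @param isolates Isolate table; when `NULL` the isolate-based model 3 row
#'   is reported as unavailable and model 2 is used for additive evolution.
#' @param exclude_extinct Sensitivity variant: mask species extinct by the
#'   end out of the week-0 additive sums and use surviving richness.
#' @return Object of class `partition_result`: models (`model0`, `model4`,
#'   `model5`), the 5-row `evaluation` table, `additive_model` (`"m2"` or
#'   `"m3"`), the `ledger`, and the observed changes.
#' @export
partition_analysis <- function(yields, design, survival, isolates = NULL,
                               exclude_extinct = FALSE) {
  d0 <- community_frame(yields, design, week = 0, a_week = 0, source = "mono",
                        survival = if (exclude_extinct) survival,
                        apply_survival = exclude_extinct,
                        surviving_richness = exclude_extinct)
  d5 <- community_frame(yields, design, week = 5, a_week = 0, source = "mono",
                        survival = if (exclude_extinct) survival,
                        apply_survival = FALSE,
                        surviving_richness = exclude_extinct)
  stopifnot(identical(d0$microcosm_id, d5$microcosm_id))
  obs_change <- d5$yield - d0$yield

  model0 <- fit_baseline(d0, time = 0)

  # scenario sums evaluated on the same frame the baseline was fitted to
  # (so the sensitivity variant keeps its surviving-richness covariate)
  pred_change <- function(scenario) {
    sc <- .EEP_SCENARIO_TABLE[.EEP_SCENARIO_TABLE$name == scenario, ]
    nd <- d5
    nd$addsum <- .eep_addsums(d5, design, yields = yields,
                              a_week = if (is.na(sc$a_week)) 5 else sc$a_week,
                              source = sc$source, survival = survival,
                              apply_survival = sc$apply_survival,
                              isolates = isolates)
    predict(model0, nd) - d0$yield
  }
  ev1 <- evaluate_counterfactual(obs_change, pred_change("extinction_only"),
                                 model = 1, label = "Extinction only")
  ev2 <- evaluate_counterfactual(obs_change, pred_change("additive_mono"),
                                 model = 2, label = "Monoculture changes only")
  ev3 <- if (!is.null(isolates)) {
    evaluate_counterfactual(obs_change, pred_change("additive_isolate"),
                            model = 3,
                            label = "Monoculture changes only (community isolates)")
  } else {
    structure(data.frame(model = 3,
                         label = "Monoculture changes only (community isolates)",
                         n = NA_integer_, slope = NA_real_,
                         intercept = NA_real_, t = NA_real_,
                         p_value = NA_real_, adjusted_r2 = NA_real_,
                         aic = NA_real_, flag = "isolate table unavailable",
                         stringsAsFactors = FALSE),
              class = c("evaluation_row", "data.frame"))
  }
  additive_model <- if (!is.null(isolates) && !is.na(ev3$aic) &&
                        ev3$aic < ev2$aic) "m3" else "m2"

  # week-5 frame with the chosen additive source for the refits
  d5r <- d5
  d5r$addsum <- if (additive_model == "m2") {
    .eep_addsums(d5, design, yields = yields, a_week = 5, source = "mono")
  } else {
    .eep_addsums(d5, design, yields = yields, source = "isolate",
                 survival = survival, isolates = isolates)
  }
  model4 <- refit_with_time(d5r, grouping = "richness")
  model5 <- refit_with_time(d5r, grouping = "composition")
  ev4 <- evaluate_counterfactual(
    obs_change, stats::fitted(model4$fit) - d0$yield, model = 4,
    label = "Monoculture plus interaction changes (richness)")
  ev5 <- evaluate_counterfactual(
    obs_change, stats::fitted(model5$fit) - d0$yield, model = 5,
    label = "Monoculture plus interaction changes (composition)")

  evaluation <- rbind(ev1, ev2, ev3, ev4, ev5)
  class(evaluation) <- "data.frame"
  r2 <- c(m1 = ev1$adjusted_r2,
          m2 = if (additive_model == "m2") ev2$adjusted_r2 else ev3$adjusted_r2,
          m4 = ev4$adjusted_r2, m5 = ev5$adjusted_r2)
  ledger <- decompose_variance(r2)

  structure(list(model0 = model0, model4 = model4, model5 = model5,
                 evaluation = evaluation, additive_model = additive_model,
                 ledger = ledger, observed_change = obs_change,
                 microcosm_id = d0$microcosm_id,
                 exclude_extinct = exclude_extinct),
            class = "partition_result")
}

#' @export
print.partition_result <- function(x, ...) {
  cat("Counterfactual partition of change in community yields\n")
  cat("  additive-evolution model chosen by AIC: ",
      if (x$additive_model == "m2") "monoculture yields (model 2)"
      else "community-isolate yields (model 3)", "\n\n", sep = "")
  ev <- x$evaluation
  ev$adjusted_r2 <- round(ev$adjusted_r2, 4)
  ev$aic <- round(ev$aic, 1)
  print(ev[, c("model", "label", "aic", "adjusted_r2", "t", "p_value")],
        row.names = FALSE, digits = 3)
  cat("\n")
  print(x$ledger)
  invisible(x)
}

#' Sensitivity analysis excluding extinct species from week-0 sums
#'
#' Repeats [partition_analysis()] with species that were extinct by the end
#' removed from the week-0 additive sums and with surviving richness in
#' place of starting richness.
#'
#' @inheritParams partition_analysis
#' @return A `partition_result`.
#' @export
sensitivity_exclude_extinct <- function(yields, design, survival,
                                        isolates = NULL) {
  partition_analysis(yields, design, survival, isolates,
                     exclude_extinct = TRUE)
}

# ---- the all-data mixed-model test -----------------------------------------

#' Likelihood-ratio test for changed species interactions using all data
#'
#' Fits community yields at both weeks against the week-5 additive sum with
#' environment- and log-richness-varying slopes and intercepts, with and
#' without time terms, with a per-microcosm random intercept (maximum
#' likelihood), and compares the two fits by a likelihood-ratio test. Since
#' additive evolution of species yields is absorbed by the week-5 additive
#' sum, a significant time effect indicates changed interaction strengths.
#' If the mixed fit fails (singular random-effect variance), the comparison
#' falls back to fixed-effects least squares with a warning.
#'
#' Optical-density measurement error scales with the signal, so by default
#' the residual standard deviation is modelled as proportional to the
#' additive sum (`nlme::varPower` with power fixed at 1); without this the
#' 30-fold yield range across richness levels makes the likelihood-ratio
#' test strongly anticonservative. `variance = "constant"` gives the
#' unweighted fit.
#'
#' @param yields,design Experiment tables.
#' @param weeks The two weeks compared.
#' @param variance Residual variance model: `"proportional"` (sd
#'   proportional to the additive sum) or `"constant"`.
#' @return List with `statistic` (likelihood ratio), `df`, `p_value`,
#'   `method`, and the two fits.
#' @export
time_interaction_test <- function(yields, design, weeks = c(0, 5),
                                  variance = c("proportional", "constant")) {
  variance <- match.arg(variance)
  frames <- lapply(weeks, function(w) {
    cf <- community_frame(yields, design, week = w, a_week = 5,
                          source = "mono")
    cf$week <- w
    cf
  })
  dat <- do.call(rbind, frames)
  dat <- dat[order(dat$microcosm_id, dat$week), , drop = FALSE]
  full_fixed <- yield ~ addsum * environment + addsum * logS +
    week + week:addsum + week:environment + week:logS
  red_fixed <- yield ~ addsum * environment + addsum * logS
  weights_spec <- if (variance == "proportional") {
    nlme::varPower(fixed = 1, form = ~ addsum)
  }
  res <- tryCatch({
    full <- nlme::lme(full_fixed, random = ~ 1 | microcosm_id, data = dat,
                      method = "ML", weights = weights_spec,
                      control = nlme::lmeControl(returnObject = TRUE))
    red <- nlme::lme(red_fixed, random = ~ 1 | microcosm_id, data = dat,
                     method = "ML", weights = weights_spec,
                     control = nlme::lmeControl(returnObject = TRUE))
    an <- stats::anova(red, full)
    list(statistic = an$L.Ratio[2], df = an$df[2] - an$df[1],
         p_value = an$`p-value`[2], method = "lme (ML) likelihood ratio",
         full = full, reduced = red)
  }, error = function(e) {
    warning("mixed model failed (", conditionMessage(e),
            "); falling back to fixed-effects comparison")
    dat$.wt <- if (variance == "proportional") 1 / dat$addsum^2 else
      rep(1, nrow(dat))
    full <- stats::lm(full_fixed, data = dat, weights = .wt)
    red <- stats::lm(red_fixed, data = dat, weights = .wt)
    lr <- 2 * (as.numeric(stats::logLik(full)) -
                 as.numeric(stats::logLik(red)))
    df <- attr(stats::logLik(full), "df") - attr(stats::logLik(red), "df")
    list(statistic = lr, df = df,
         p_value = stats::pchisq(lr, df, lower.tail = FALSE),
         method = "lm likelihood ratio (fallback)", full = full,
         reduced = red)
  })
  res
}

# ---- per-species sensitivity model -----------------------------------------

#' Mixed model with a separate coefficient for each species
#'
#' Sensitivity check that no single species drives the partition: community
#' yields at both weeks are regressed on one presence-weighted yield
#' covariate per species (the species' week-0 mean monoculture yield in that
#' environment, zero when absent), each interacting with time, with
#' environment main effects and a per-microcosm random intercept. The
#' per-species time-trend coefficients say which species' contributions
#' changed. Species absent from every community are flagged inestimable.
#'
#' @param yields,design Experiment tables.
#' @param weeks The two weeks compared.
#' @return List of class `per_species_fit`: the `lme` fit, the full
#'   coefficient table, the `time_trends` table (one row per estimable
#'   species), and `inestimable` species ids.
#' @export
per_species_coefficient_model <- function(yields, design, weeks = c(0, 5)) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  species <- sort(unique(design$species_id))
  mono <- monoculture_yields(yields, design, week = weeks[1])
  a_mean <- tapply(mono$yield, list(mono$species_id, mono$environment), mean)

  frames <- lapply(weeks, function(w) {
    wk <- yields[yields$week == w, , drop = FALSE]
    comm <- wk[rich[wk$composition_id] >= 2L, , drop = FALSE]
    comm$week <- w
    comm
  })
  dat <- do.call(rbind, frames)
  dat$environment <- normalize_environment(dat$environment)
  xcols <- sprintf("x_%s", species)
  for (k in seq_along(species)) {
    present <- vapply(dat$composition_id,
                      function(cid) species[k] %in% members[[cid]],
                      logical(1))
    dat[[xcols[k]]] <- ifelse(present,
                              a_mean[cbind(species[k],
                                           as.character(dat$environment))], 0)
  }
  inestimable <- species[vapply(xcols, function(cl) all(dat[[cl]] == 0),
                                logical(1))]
  usable <- xcols[!species %in% inestimable]
  f <- stats::as.formula(paste("yield ~ environment +",
                               paste(usable, collapse = " + "), "+ week + (",
                               paste(usable, collapse = " + "), "):week"))
  fit <- nlme::lme(f, random = ~ 1 | microcosm_id, data = dat, method = "ML",
                   control = nlme::lmeControl(returnObject = TRUE))
  tt <- summary(fit)$tTable
  cf <- data.frame(term = rownames(tt), estimate = tt[, "Value"],
                   se = tt[, "Std.Error"], df = tt[, "DF"],
                   t = tt[, "t-value"], p_value = tt[, "p-value"],
                   row.names = NULL)
  trends <- cf[grepl(":week$|^week:", cf$term), , drop = FALSE]
  trends$species_id <- sub("^week:", "", sub(":week$", "", trends$term))
  trends$species_id <- sub("^x_", "", trends$species_id)
  structure(list(fit = fit, coefficients = cf, time_trends = trends,
                 inestimable = inestimable),
            class = "per_species_fit")
}
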