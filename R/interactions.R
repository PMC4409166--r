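# Interaction indices: observed community yield relative to the additive
# (sum-of-monoculture-yields) expectation, and their summaries.

#' Additive expectation of a community's yield
#'
#' The no-interaction null: the sum of the monoculture yields of the
#' community's member species, optionally restricted to survivors.
#'
#' @param a Named numeric vector of monoculture yields, names are species.
#' @param members Character vector of member species.
#' @param survival Optional named 0/1 vector masking extinct members.
#' @return The additive sum (absorbance units).
#' @export
#' @examples
#' additive_expectation(c(sp01 = 0.2, sp02 = 0.3), c("sp01", "sp02"))
additive_expectation <- function(a, members, survival = NULL) {
  miss <- setdiff(members, names(a))
  if (length(miss) > 0L) {
    stop("no monoculture yield for species: ", paste(miss, collapse = ", "))
  }
  w <- rep(1, length(members))
  if (!is.null(survival)) {
    w <- as.numeric(survival[members])
    w[is.na(w)] <- 1
  }
  sum(a[members] * w)
}

#' Interaction index of observed versus additive yield
#'
#' The ratio of observed community yield to its additive expectation: 1
#' means additive growth (no net interaction), < 1 a negative interaction,
#' > 1 synergy. Classification uses a symmetric tolerance band around 1
#' (default 0: any deviation classifies).
#'
#' @param observed Observed community yield(s).
#' @param additive Additive expectation(s); must be positive.
#' @param tolerance Half-width of the "additive" band on the ratio scale.
#' @return Data frame with columns `observed`, `additive`, `ratio`,
#'   `classification` (factor: negative/additive/synergistic).
#' @export
interaction_index <- function(observed, additive, tolerance = 0) {
  if (any(additive <= 0)) {
    stop("interaction index undefined: additive expectation must be > 0")
  }
  ratio <- observed / additive
  cls <- ifelse(ratio < 1 - tolerance, "negative",
                ifelse(ratio > 1 + tolerance, "synergistic", "additive"))
  data.frame(observed = observed, additive = additive, ratio = ratio,
             classification = factor(cls, levels = c("negative", "additive",
                                                     "synergistic")))
}

#' Interaction indices for every community microcosm
#'
#' Computes observed/additive ratios at a given week. Week-0 indices use
#' week-0 monoculture yields (replicate-matched within environment); week-5
#' indices use the yields of community isolates by default (the additive sum
#' of what actually grew there), or week-5 monoculture yields with
#' `additive_source = "mono"`.
#'
#' @param yields Yield table (see [read_yield_table()]) containing both the
#'   community and monoculture rows.
#' @param design Design table from [generate_design()].
#' @param week Observation week of the index.
#' @param additive_source `"mono"` or `"isolate"` (week 5 only).
#' @param isolates Isolate table; required when `additive_source` is
#'   `"isolate"`.
#' @param tolerance Passed to [interaction_index()].
#' @return Data frame with one row per community microcosm: identifiers,
#'   `richness`, `week`, `observed`, `additive`, `ratio`, `classification`.
#' @export
interaction_indices <- function(yields, design, week = 0,
                                additive_source = c("auto", "mono", "isolate"),
                                isolates = NULL, tolerance = 0) {
  additive_source <- match.arg(additive_source)
  if (additive_source == "auto") {
    additive_source <- if (week == 5 && !is.null(isolates)) "isolate" else "mono"
  }
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  wk <- yields[yields$week == week, , drop = FALSE]
  comm <- wk[rich[wk$composition_id] >= 2L, , drop = FALSE]
  mono <- monoculture_yields(yields, design, week = week)
  adds <- vapply(seq_len(nrow(comm)), function(i) {
    mem <- members[[comm$composition_id[i]]]
    if (additive_source == "isolate") {
      iso <- isolates[isolates$microcosm_id == comm$microcosm_id[i], ]
      sum(iso$yield[iso$species_id %in% mem])
    } else {
      a <- mono$yield[mono$environment == comm$environment[i] &
                        mono$replicate == comm$replicate[i]]
      names(a) <- mono$species_id[mono$environment == comm$environment[i] &
                                    mono$replicate == comm$replicate[i]]
      additive_expectation(a, mem)
    }
  }, numeric(1))
  idx <- interaction_index(comm$yield, adds, tolerance = tolerance)
  cbind(comm[, c("microcosm_id", "composition_id", "environment",
                 "replicate", "week")],
        richness = unname(rich[comm$composition_id]), idx,
        row.names = NULL)
}

#' Monoculture yields in long species form
#'
#' Extracts the monoculture rows of a yield table and labels them by the
#' single member species of each monoculture composition.
#'
#' @inheritParams interaction_indices
#' @return Data frame with columns `species_id`, `environment`, `replicate`,
#'   `week`, `yield`.
#' @export
monoculture_yields <- function(yields, design, week = NULL) {
  members <- composition_members(design)
  rich <- vapply(members, length, integer(1))
  mono_comp <- names(rich)[rich == 1L]
  sp <- vapply(members[mono_comp], `[`, character(1), 1L)
  df <- yields[yields$composition_id %in% mono_comp, , drop = FALSE]
  if (!is.null(week)) df <- df[df$week %in% week, , drop = FALSE]
  data.frame(species_id = unname(sp[df$composition_id]),
             environment = df$environment, replicate = df$replicate,
             week = df$week, yield = df$yield, stringsAsFactors = FALSE)
}

#' Summarise interaction indices by treatment group
#'
#' Per environment x richness (x week) group: mean index, Student-t 95 %
#' confidence interval, and a one-sample two-sided t-test against the
#' additive null (ratio = 1) with n - 1 degrees of freedom. Groups with a
#' single index report the mean only, with the CI flagged unavailable.
#'
#' @param indices Data frame from [interaction_indices()] (rows of several
#'   weeks may be concatenated).
#' @param by Grouping columns.
#' @param conf_level Confidence level of the interval.
#' @param log_ratio If `TRUE`, the t-test and CI are computed on log ratios
#'   (against log 1 = 0) and back-transformed.
#' @return Data frame with columns the grouping variables plus `n`, `mean`,
#'   `ci_lower`, `ci_upper`, `t`, `df`, `p_value`, `ci_available`.
#' @export
index_summary <- function(indices, by = c("environment", "richness", "week"),
                          conf_level = 0.95, log_ratio = FALSE) {
  by <- intersect(by, names(indices))
  groups <- split(indices, indices[by], drop = TRUE)
  out <- do.call(rbind, lapply(unname(groups), function(g) {
    x <- if (log_ratio) log(g$ratio) else g$ratio
    null_value <- if (log_ratio) 0 else 1
    n <- length(x)
    head <- g[1L, by, drop = FALSE]
    if (n < 2L || stats::sd(x) == 0) {
      tstat <- if (n >= 2L && stats::sd(x) == 0 &&
                   isTRUE(all.equal(mean(x), null_value))) 0 else NA_real_
      pv <- if (!is.na(tstat)) 1 else NA_real_
      mn <- mean(x)
      return(cbind(head, data.frame(
        n = n, mean = if (log_ratio) exp(mn) else mn,
        ci_lower = NA_real_, ci_upper = NA_real_,
        t = tstat, df = n - 1L, p_value = pv,
        ci_available = FALSE)))
    }
    tt <- stats::t.test(x, mu = null_value, conf.level = conf_level)
    tr <- if (log_ratio) exp else identity
    cbind(head, data.frame(
      n = n, mean = tr(mean(x)),
      ci_lower = tr(tt$conf.int[1]), ci_upper = tr(tt$conf.int[2]),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p_value = tt$p.value, ci_available = TRUE))
  }))
  row.names(out) <- NULL
  out
}

#' Model the proportion of synergistic communities
#'
#' Fits a binomial-error generalised linear model to the indicator
#' `ratio > 1` with the supplied covariates (by default week, environment
#' and log richness), reporting per-term z statistics and P values. Complete
#' or quasi-complete separation is flagged rather than masked.
#'
#' @param indices Data frame from [interaction_indices()] (possibly several
#'   weeks).
#' @param formula RHS formula of covariates.
#' @return List of class `synergy_glm`: the `glm` fit, a coefficient table,
#'   and a `separation` flag.
#' @export
synergy_proportion_model <- function(indices,
                                     formula = ~ week + environment +
                                       log(richness)) {
  indices$synergistic <- as.integer(indices$ratio > 1)
  if (length(unique(indices$synergistic)) < 2L) {
    stop("cannot model synergy proportion: only one outcome class present")
  }
  f <- stats::update(formula, synergistic ~ .)
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(f, family = stats::binomial(), data = indices),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separation) {
    warning("possible complete separation in synergy model; ",
            "coefficients may be unstable")
  }
  cf <- summary(fit)$coefficients
  structure(list(
    fit = fit, separation = separation,
    coefficients = data.frame(term = rownames(cf), estimate = cf[, 1],
                              se = cf[, 2], z = cf[, 3], p_value = cf[, 4],
                              row.names = NULL)),
    class = "synergy_glm")
}
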