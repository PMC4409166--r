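# Core domain helpers: environments, growth-period yield, generation counts,
# and the CSV table formats shared by every other module.

# canonical environment labels (three media treatments)
.EEP_ENVIRONMENTS <- c("beech", "ph5", "spruce")

# weeks at which yields are observed in the standard experiment
.EEP_WEEKS <- c(0L, 1L, 2L, 4L, 5L)

#' Canonical environment labels
#'
#' The three growth environments used throughout the package: standard
#' beech-leaf tea (`"beech"`), beech tea buffered to pH 5 (`"ph5"`), and
#' spruce-needle tea (`"spruce"`). All tables carry exactly these lowercase
#' labels internally.
#'
#' @return Character vector of the three labels, in canonical order.
#' @export
environments <- function() .EEP_ENVIRONMENTS

#' Normalise environment labels
#'
#' Environment labels are matched case-insensitively on input and stored in
#' canonical lowercase form.
#'
#' @param x Character vector of environment labels.
#' @return Factor with levels `environments()`.
#' @export
normalize_environment <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  bad <- setdiff(unique(lx), .EEP_ENVIRONMENTS)
  if (length(bad) > 0L) {
    stop("unknown environment label(s): ", paste(bad, collapse = ", "),
         " (expected one of ", paste(.EEP_ENVIRONMENTS, collapse = ", "), ")")
  }
  factor(lx, levels = .EEP_ENVIRONMENTS)
}

#' Biomass yield of one growth period
#'
#' Yield over a serial-transfer growth period is the maximum optical density
#' (OD 595 nm) reached minus the starting OD. The first reading of the series
#' is taken as the starting OD. Negative differences (possible under
#' measurement noise when the culture never grows) are clamped to zero, since
#' yields are biomass gains and downstream additive sums assume
#' non-negativity.
#'
#' @param od Numeric vector of OD readings for one microcosm-period, starting
#'   OD first.
#' @return Single non-negative yield in absorbance units.
#' @export
#' @examples
#' compute_yield(c(0.05, 0.20, 0.60, 0.58))
compute_yield <- function(od) {
  if (length(od) == 0L) stop("no OD readings")
  if (!is.numeric(od) || anyNA(od)) stop("OD readings must be numeric and non-missing")
  max(max(od) - od[1L], 0)
}

#' Number of generations (doublings) over a transfer history
#'
#' Generations are counted by summing `log2(od_end / od_start)` over growth
#' periods. Periods where the culture shrank (`od_end < od_start`) contribute
#' negatively by default, applying the doubling formula literally;
#' `floor_zero = TRUE` instead floors each period's contribution at zero.
#'
#' @param od_start Numeric vector of period starting ODs (all > 0).
#' @param od_end Numeric vector of period ending ODs (all > 0), same length.
#' @param floor_zero If `TRUE`, per-period contributions are floored at 0.
#' @return Total generations (real; >= 0 when `floor_zero = TRUE`).
#' @export
#' @examples
#' count_generations(c(0.01, 0.02), c(0.64, 0.32))  # 6 + 4 doublings
count_generations <- function(od_start, od_end, floor_zero = FALSE) {
  if (length(od_start) != length(od_end)) {
    stop("od_start and od_end must have the same length")
  }
  if (length(od_start) == 0L) return(0)
  if (any(od_start <= 0) || any(od_end <= 0)) {
    stop("undefined doubling count: non-positive OD")
  }
  g <- log2(od_end / od_start)
  if (floor_zero) g <- pmax(g, 0)
  sum(g)
}

#' Per-period yields from an OD reading table
#'
#' Applies [compute_yield()] to each (microcosm, period) group of a long
#' transfer-readings table.
#'
#' @param transfers Data frame with columns `microcosm_id`, `period_index`,
#'   `day`, `od`; readings are ordered by `day` within each period and the
#'   `day = 0` reading is the starting OD.
#' @return Data frame with columns `microcosm_id`, `period_index`, `yield`.
#' @export
transfer_yields <- function(transfers) {
  stopifnot(all(c("microcosm_id", "period_index", "day", "od") %in% names(transfers)))
  groups <- split(transfers,
                  list(transfers$microcosm_id, transfers$period_index),
                  drop = TRUE)
  out <- do.call(rbind, lapply(unname(groups), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    data.frame(microcosm_id = g$microcosm_id[1L],
               period_index = g$period_index[1L],
               yield = compute_yield(g$od), stringsAsFactors = FALSE)
  }))
  out[order(out$microcosm_id, out$period_index), , drop = FALSE]
}

#' Generations per microcosm from an OD reading table
#'
#' Takes each period's first reading as the starting OD and its last reading
#' as the end-of-period OD, then sums `log2` fold changes per microcosm via
#' [count_generations()].
#'
#' @inheritParams transfer_yields
#' @param floor_zero Passed to [count_generations()].
#' @return Data frame with columns `microcosm_id`, `generations`.
#' @export
transfer_generations <- function(transfers, floor_zero = FALSE) {
  stopifnot(all(c("microcosm_id", "period_index", "day", "od") %in% names(transfers)))
  groups <- split(transfers,
                  list(transfers$microcosm_id, transfers$period_index),
                  drop = TRUE)
  ends <- do.call(rbind, lapply(unname(groups), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    data.frame(microcosm_id = as.character(g$microcosm_id[1L]),
               od_start = g$od[1L], od_end = g$od[nrow(g)],
               stringsAsFactors = FALSE)
  }))
  per_mic <- split(ends, ends$microcosm_id)
  data.frame(
    microcosm_id = names(per_mic),
    generations = vapply(per_mic, function(d) {
      count_generations(d$od_start, d$od_end, floor_zero = floor_zero)
    }, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# ---- CSV I/O ---------------------------------------------------------------

.eep_check_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "))
  }
}

#' Read or write a yield table
#'
#' The yield table is the central long-format data product: one row per
#' microcosm per observation week, community yields (A) and monoculture
#' yields (a) alike. Columns: `microcosm_id`, `composition_id`,
#' `environment`, `replicate`, `week`, `yield`. Yields are written with six
#' decimal places, so a write/read round trip is lossless at that precision.
#'
#' @param path Path to a CSV file (UTF-8, header row, "." decimal separator).
#' @return `read_yield_table()` returns a validated data frame with
#'   environment as a factor with levels `environments()`.
#' @export
read_yield_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .eep_check_cols(df, c("microcosm_id", "composition_id", "environment",
                        "replicate", "week", "yield"), "yield table")
  df$environment <- normalize_environment(df$environment)
  df$week <- as.integer(df$week)
  df$replicate <- as.integer(df$replicate)
  df$yield <- as.numeric(df$yield)
  key <- paste(df$microcosm_id, df$week)
  if (anyDuplicated(key)) {
    stop("duplicate (microcosm_id, week) rows in yield table: ",
         paste(utils::head(unique(key[duplicated(key)]), 3L), collapse = "; "))
  }
  if (any(df$yield < 0)) stop("negative yields in yield table")
  df
}

#' @rdname read_yield_table
#' @param yields Data frame as produced by the simulator or
#'   [read_yield_table()].
#' @export
write_yield_table <- function(yields, path) {
  .eep_check_cols(yields, c("microcosm_id", "composition_id", "environment",
                            "replicate", "week", "yield"), "yield table")
  out <- yields
  out$environment <- as.character(normalize_environment(out$environment))
  out$yield <- round(out$yield, 6L)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a design table
#'
#' Long-format design: one row per (composition, member species) with columns
#' `composition_id`, `species_id`, `richness`, `partition_set`.
#'
#' @param path Path to a CSV file.
#' @return A validated design data frame.
#' @export
read_design_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .eep_check_cols(df, c("composition_id", "species_id", "richness",
                        "partition_set"), "design table")
  df$richness <- as.integer(df$richness)
  sizes <- table(df$composition_id)
  rich <- tapply(df$richness, df$composition_id, unique)
  if (any(lengths(rich) != 1L) ||
      any(unlist(rich)[names(sizes)] != as.integer(sizes))) {
    stop("design table richness does not match member counts")
  }
  df
}

#' @rdname read_design_table
#' @param design Design data frame.
#' @export
write_design_table <- function(design, path) {
  .eep_check_cols(design, c("composition_id", "species_id", "richness",
                            "partition_set"), "design table")
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a survival table
#'
#' One row per (member species, community microcosm) with the end-of-
#' experiment survival indicator: columns `microcosm_id`, `species_id`,
#' `survived` (0/1).
#'
#' @param path Path to a CSV file.
#' @return A validated survival data frame.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .eep_check_cols(df, c("microcosm_id", "species_id", "survived"),
                  "survival table")
  df$survived <- as.integer(df$survived)
  if (!all(df$survived %in% c(0L, 1L))) stop("survived must be 0 or 1")
  df
}

#' @rdname read_survival_table
#' @param survival Survival data frame.
#' @export
write_survival_table <- function(survival, path) {
  .eep_check_cols(survival, c("microcosm_id", "species_id", "survived"),
                  "survival table")
  utils::write.csv(survival, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write an isolate-yield table
#'
#' Monoculture growth-assay yields of isolates re-extracted from final
#' communities (defined only for surviving species): columns `microcosm_id`,
#' `species_id`, `environment`, `source_richness`, `yield`,
#' `ancestral_yield`.
#'
#' @param path Path to a CSV file.
#' @return A validated isolate data frame.
#' @export
read_isolate_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .eep_check_cols(df, c("microcosm_id", "species_id", "environment",
                        "source_richness", "yield", "ancestral_yield"),
                  "isolate table")
  df$environment <- normalize_environment(df$environment)
  df$source_richness <- as.integer(df$source_richness)
  df
}

#' @rdname read_isolate_table
#' @param isolates Isolate data frame.
#' @export
write_isolate_table <- function(isolates, path) {
  .eep_check_cols(isolates, c("microcosm_id", "species_id", "environment",
                              "source_richness", "yield", "ancestral_yield"),
                  "isolate table")
  out <- isolates
  out$environment <- as.character(normalize_environment(out$environment))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
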