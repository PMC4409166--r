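# Random partitioned experimental design: the 12-species pool is split into
# disjoint equal-richness communities, twice per intermediate richness level,
# plus all monocultures and the full mixture.

#' Specify a random partitioned design
#'
#' Defines the species pool and assembly scheme: every species in
#' monoculture, two independent random partitions of the pool at each
#' intermediate richness level, and one full mixture. With the defaults
#' (12 species, levels 1/2/3/6/12) this yields the classic 37-composition
#' design. Morphotypes (colony-morphology labels) are used to keep visually
#' indistinguishable species out of the same community so members can be
#' re-identified at the end of the experiment.
#'
#' @param n_species Number of species in the pool.
#' @param richness_levels Integer richness levels; must include values that
#'   divide `n_species` for the intermediate levels.
#' @param partitions_per_level Independent random partitions per intermediate
#'   level.
#' @param replicates Replicate microcosms per composition per environment.
#' @param morphotypes Named character vector mapping each species to a
#'   morphology label; defaults to four morphotypes spread over the pool.
#' @param seed Integer seed making the design reproducible.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_species = 12L,
                        richness_levels = c(1L, 2L, 3L, 6L, 12L),
                        partitions_per_level = 2L,
                        replicates = 3L,
                        morphotypes = NULL,
                        seed = 1L) {
  n_species <- as.integer(n_species)
  richness_levels <- sort(unique(as.integer(richness_levels)))
  species <- sprintf("sp%02d", seq_len(n_species))
  intermediate <- setdiff(richness_levels, c(1L, n_species))
  bad <- intermediate[n_species %% intermediate != 0L]
  if (length(bad) > 0L) {
    stop("richness level(s) ", paste(bad, collapse = ", "),
         " do not divide the number of species (", n_species, ")")
  }
  if (is.null(morphotypes)) {
    # mostly distinct colony phenotypes with a couple of look-alike pairs,
    # so the swap rule is exercised but remains feasible at every level
    base <- c("white", "white", "yellow", "yellow", "pink", "cream",
              "orange", "beige", "translucent", "rough", "smooth", "mucoid")
    morphotypes <- stats::setNames(
      rep(base, length.out = n_species)[seq_len(n_species)], species)
  }
  if (!all(species %in% names(morphotypes))) {
    stop("morphotype mapping must cover every species")
  }
  structure(
    list(n_species = n_species, species = species,
         richness_levels = richness_levels,
         partitions_per_level = as.integer(partitions_per_level),
         replicates = as.integer(replicates),
         morphotypes = morphotypes[species], seed = as.integer(seed)),
    class = "design_spec")
}

#' Randomly partition a species pool into equal-sized communities
#'
#' Shuffles the pool and cuts it into disjoint communities of size `level`,
#' so each species occurs in exactly one community of the partition.
#'
#' @param species Character vector of species identifiers.
#' @param level Community size; must divide `length(species)`.
#' @return List of character vectors (the communities).
#' @export
random_partition <- function(species, level) {
  n <- length(species)
  level <- as.integer(level)
  if (level < 1L || n %% level != 0L) {
    stop("level ", level, " does not divide the number of species (", n, ")")
  }
  shuffled <- sample(species)
  split(shuffled, rep(seq_len(n %/% level), each = level))
}

.eep_morph_conflicts <- function(partition, morphotypes) {
  which(vapply(partition,
               function(m) anyDuplicated(morphotypes[m]) > 0L, logical(1)))
}

#' Resolve morphotype conflicts within a partition by random swaps
#'
#' If a community contains two species of identical growth morphology (which
#' would make them indistinguishable on agar plates), one of the clashing
#' members is swapped with a randomly chosen member of another community,
#' restricted to swaps that introduce no new conflict. The partition property
#' (each species exactly once) is preserved. If the morphotype counts make a
#' conflict-free assignment impossible (more copies of one morphotype than
#' communities), or no resolution is found within `max_attempts` swaps, an
#' error is raised.
#'
#' @param partition List of species vectors from [random_partition()].
#' @param morphotypes Named character vector of morphology labels.
#' @param max_attempts Bound on the number of swap attempts.
#' @return The conflict-free partition (same shape as the input).
#' @export
resolve_morphotype_conflicts <- function(partition, morphotypes,
                                         max_attempts = 1000L) {
  counts <- table(morphotypes[unlist(partition)])
  if (any(counts > length(partition))) {
    stop("no conflict-free assignment exists: morphotype(s) ",
         paste(names(counts)[counts > length(partition)], collapse = ", "),
         " have more members than there are communities (",
         length(partition), ")")
  }
  attempts <- 0L
  repeat {
    confl <- .eep_morph_conflicts(partition, morphotypes)
    if (length(confl) == 0L) return(partition)
    if (attempts >= max_attempts) {
      stop("could not resolve morphotype conflicts after ", max_attempts,
           " swap attempts; conflicting communities: ",
           paste(confl, collapse = ", "))
    }
    attempts <- attempts + 1L
    ci <- if (length(confl) > 1L) sample(confl, 1L) else confl
    members <- partition[[ci]]
    dup_morphs <- unique(morphotypes[members][duplicated(morphotypes[members])])
    clashing <- members[morphotypes[members] %in% dup_morphs]
    mover <- if (length(clashing) > 1L) sample(clashing, 1L) else clashing
    # enumerate donor (community, member) pairs whose swap creates no conflict
    legal <- list()
    for (dj in setdiff(seq_along(partition), ci)) {
      for (dm in partition[[dj]]) {
        new_ci <- c(setdiff(members, mover), dm)
        new_dj <- c(setdiff(partition[[dj]], dm), mover)
        if (anyDuplicated(morphotypes[new_ci]) == 0L &&
            anyDuplicated(morphotypes[new_dj]) == 0L) {
          legal[[length(legal) + 1L]] <- c(dj, match(dm, partition[[dj]]))
        }
      }
    }
    if (length(legal) == 0L) next  # retry with a different clashing member
    pick <- legal[[if (length(legal) > 1L) sample(length(legal), 1L) else 1L]]
    dj <- pick[1L]; dm <- partition[[dj]][pick[2L]]
    partition[[ci]] <- c(setdiff(members, mover), dm)
    partition[[dj]] <- c(setdiff(partition[[dj]], dm), mover)
  }
}

#' Generate the full random partitioned design
#'
#' Produces all compositions of the design: one monoculture per species (if
#' richness level 1 is requested), `partitions_per_level` independent random
#' partitions at every intermediate richness level (with morphotype conflicts
#' resolved), and the full mixture (if the pool size is a requested level).
#' Compositions are guaranteed distinct as species sets: a partition that
#' duplicates an existing composition is re-drawn. The result is
#' deterministic given `spec$seed`.
#'
#' @param spec A [design_spec()].
#' @return Long-format design data frame of class `eep_design` with columns
#'   `composition_id`, `species_id`, `richness`, `partition_set`.
#' @export
#' @examples
#' d <- generate_design(design_spec(seed = 42))
#' length(unique(d$composition_id))  # 37
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  set.seed(spec$seed)
  comps <- list()     # list of species-set character vectors
  sets <- character() # partition_set label per composition
  add_comp <- function(members, label) {
    comps[[length(comps) + 1L]] <<- sort(members)
    sets[length(sets) + 1L] <<- label
  }
  if (1L %in% spec$richness_levels) {
    for (s in spec$species) add_comp(s, "mono")
  }
  intermediate <- setdiff(spec$richness_levels, c(1L, spec$n_species))
  for (L in intermediate) {
    for (p in seq_len(spec$partitions_per_level)) {
      for (attempt in seq_len(1000L)) {
        part <- random_partition(spec$species, L)
        part <- resolve_morphotype_conflicts(part, spec$morphotypes)
        keys <- vapply(part, function(m) paste(sort(m), collapse = "+"),
                       character(1))
        existing <- vapply(comps, paste, character(1), collapse = "+")
        if (!any(keys %in% existing) && anyDuplicated(keys) == 0L) break
        if (attempt == 1000L) {
          stop("could not draw a duplicate-free partition at level ", L)
        }
      }
      for (m in part) add_comp(m, sprintf("L%dP%d", L, p))
    }
  }
  if (spec$n_species %in% spec$richness_levels && spec$n_species > 1L) {
    add_comp(spec$species, "full")
  }
  ids <- sprintf("C%02d", seq_along(comps))
  out <- data.frame(
    composition_id = rep(ids, lengths(comps)),
    species_id = unlist(comps),
    richness = rep(lengths(comps), lengths(comps)),
    partition_set = rep(sets, lengths(comps)),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("eep_design", "data.frame")
  out
}

#' Members of each composition
#'
#' @param design Design data frame from [generate_design()].
#' @return Named list mapping composition id to its species-id vector.
#' @export
composition_members <- function(design) {
  split(design$species_id, design$composition_id)
}

#' Expand a design into the microcosm roster
#'
#' Crosses compositions with environments and replicates: with the default
#' 37 compositions, 3 replicates and one environment this gives 111
#' microcosms, and 333 after the three-way environmental split.
#'
#' @param design Design data frame from [generate_design()].
#' @param replicates Number of replicates per composition per environment.
#' @param environments Character vector of environment labels.
#' @return Data frame with columns `microcosm_id`, `composition_id`,
#'   `environment`, `replicate`, `richness`.
#' @export
expand_microcosms <- function(design, replicates = 3L,
                              environments = ecoevopart::environments()) {
  stopifnot(nrow(design) > 0L)
  env <- as.character(normalize_environment(environments))
  comp <- unique(design[, c("composition_id", "richness")])
  grid <- expand.grid(replicate = seq_len(replicates),
                      environment = env,
                      composition_id = comp$composition_id,
                      stringsAsFactors = FALSE)
  grid$richness <- comp$richness[match(grid$composition_id,
                                       comp$composition_id)]
  grid$microcosm_id <- sprintf("%s_%s_r%d", grid$composition_id,
                               grid$environment, grid$replicate)
  grid[, c("microcosm_id", "composition_id", "environment", "replicate",
           "richness")]
}
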