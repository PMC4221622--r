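#' Trait-diffusion simulators
#'
#' Seeded generators of presence/absence trait tables with the two
#' covariance structures the inference pipeline is built to detect:
#' geographic-decay sharing (neutral isolation-by-distance: a trait
#' originates somewhere and is adopted by other groups with probability
#' decaying in distance) and lineage-biased retention (a bias transmitted
#' down lineage lines suppresses most variants, leaving a low-diversity,
#' lineage-structured pattern). Transmission is modelled as independent
#' per-trait adoption at equilibrium rather than a time-stepped contagion:
#' the inference uses only the resulting presence/absence covariance, and
#' this is the simplest generator with the required structure.
#'
#' @name simulators
NULL

#' Group layout for simulation
#'
#' Bundles the spatial and lineage scaffolding a simulated trait system
#' lives on: group names, territory centroids, border pairs, and a language
#' classification standing in for lineage membership.
#'
#' @param geo data frame `group`, `lat`, `lon` (decimal degrees).
#' @param borders data frame `group1`, `group2` of border-sharing pairs
#'   (may be `NULL`).
#' @param classification data frame `group`, `family`, `subgroup`.
#' @return an object of class `group_layout` with a precomputed
#'   great-circle distance matrix (km).
#' @export
group_layout <- function(geo, borders = NULL, classification = NULL) {
  geo <- validate_geo_table(geo)
  groups <- geo$group
  if (!is.null(borders)) {
    bad <- !(c(borders$group1, borders$group2) %in% groups)
    if (any(bad)) stop("border list references unknown group")
  }
  if (!is.null(classification)) {
    classification <- as.data.frame(classification)
    if (!setequal(classification$group, groups)) {
      stop("classification group set differs from geo table group set")
    }
    classification <-
      classification[match(groups, classification$group), , drop = FALSE]
  }
  structure(
    list(groups = groups, geo = geo, borders = borders,
         classification = classification,
         distances = greatcircle_matrix(geo)),
    class = "group_layout"
  )
}

#' @export
print.group_layout <- function(x, ...) {
  cat("group_layout: ", length(x$groups), " groups",
      if (!is.null(x$classification))
        paste0(", ", length(unique(x$classification$family)),
               " language families"),
      "\n", sep = "")
  invisible(x)
}

#' Simulation parameters
#'
#' @param n_traits number of traits to simulate.
#' @param decay_length e-folding distance (same units as the layout
#'   distances, km for geographic layouts) of the adoption kernel
#'   `exp(-d / decay_length)`. Default 400 km, on the order of
#'   nearest-neighbour spacing in the nine-group Plains fixture, so that
#'   adjacent groups share most innovations and distal ones few.
#' @param innovation_origin `"uniform"` (each trait originates in a group
#'   chosen uniformly) — the only weighting currently implemented.
#' @param core_fraction (lineage model) fraction of traits retained by all
#'   groups regardless of lineage; default 0.6.
#' @param lineage_retention (lineage model) retention probability of a
#'   lineage-disfavoured trait; default 0.1.
#' @param noise_flip independent per-cell flip probability applied last;
#'   default 0.02.
#' @param seed integer seed.
#' @return a list of class `sim_params`.
#' @export
sim_params <- function(n_traits = 200, decay_length = 400,
                       innovation_origin = "uniform", core_fraction = 0.6,
                       lineage_retention = 0.1, noise_flip = 0.02,
                       seed = 1L) {
  stopifnot(n_traits >= 1, decay_length > 0,
            core_fraction >= 0, core_fraction <= 1,
            lineage_retention >= 0, lineage_retention <= 1,
            noise_flip >= 0, noise_flip <= 1)
  if (!identical(innovation_origin, "uniform")) {
    stop("only uniform innovation origin is implemented")
  }
  structure(
    list(n_traits = as.integer(n_traits), decay_length = decay_length,
         innovation_origin = innovation_origin,
         core_fraction = core_fraction,
         lineage_retention = lineage_retention,
         noise_flip = noise_flip, seed = as.integer(seed)),
    class = "sim_params"
  )
}

apply_noise <- function(cells, noise_flip) {
  if (noise_flip > 0) {
    flip <- matrix(stats::runif(length(cells)) < noise_flip,
                   nrow(cells), ncol(cells))
    cells[flip] <- 1L - cells[flip]
  }
  cells
}

#' Simulate a trait table under neutral isolation-by-distance
#'
#' Each trait originates in one group (always present there) and is adopted
#' independently by every other group with probability
#' `exp(-d / decay_length)`, `d` the pairwise great-circle distance, then
#' independent noise flips are applied. As `decay_length` grows all groups
#' share everything (distances -> 0); as it shrinks every trait is private
#' to its origin (distances -> 1). Lineage fields of the layout are ignored.
#'
#' @param layout a `group_layout` with >= 2 groups.
#' @param params a [sim_params()].
#' @return a `trait_table` (no questionable cells).
#' @export
simulate_neutral_ibd <- function(layout, params = sim_params()) {
  stopifnot(inherits(layout, "group_layout"), inherits(params, "sim_params"))
  n <- length(layout$groups)
  if (n < 2) stop("layout must have at least 2 groups")
  D <- layout$distances$values
  adopt <- exp(-D / params$decay_length)
  withr::with_seed(params$seed, {
    origins <- sample.int(n, params$n_traits, replace = TRUE)
    cells <- matrix(0L, n, params$n_traits)
    for (t in seq_len(params$n_traits)) {
      o <- origins[t]
      cells[, t] <- as.integer(stats::runif(n) < adopt[, o])
      cells[o, t] <- 1L
    }
    cells <- apply_noise(cells, params$noise_flip)
  })
  trait_table(cells, group_labels = layout$groups,
              trait_labels = paste0("T", seq_len(params$n_traits)))
}

#' Simulate a trait table under lineage-biased retention
#'
#' A `core_fraction` of traits is universally retained (present in every
#' group). Each remaining trait is favoured by a random subset of language
#' families (each family independently with probability 1/2, at least one);
#' groups of favouring families retain it with probability 1, others with
#' probability `lineage_retention`. Noise flips are applied last. Because
#' lineage membership is assigned to groups independently of their
#' position, the induced language matrix is uncorrelated with geography in
#' expectation — the configuration under which a language-matrix
#' association is interpretable as lineage-linked bias rather than
#' geography by proxy.
#'
#' @inheritParams simulate_neutral_ibd
#' @return a `trait_table`.
#' @export
simulate_lineage_bias <- function(layout, params = sim_params()) {
  stopifnot(inherits(layout, "group_layout"), inherits(params, "sim_params"))
  if (is.null(layout$classification)) {
    stop("layout must carry a lineage (language) classification")
  }
  n <- length(layout$groups)
  if (n < 2) stop("layout must have at least 2 groups")
  fams <- layout$classification$family
  fam_levels <- unique(fams)
  withr::with_seed(params$seed, {
    n_core <- round(params$core_fraction * params$n_traits)
    cells <- matrix(0L, n, params$n_traits)
    if (n_core > 0) cells[, seq_len(n_core)] <- 1L
    for (t in seq_len(params$n_traits - n_core)) {
      fav <- fam_levels[stats::runif(length(fam_levels)) < 0.5]
      if (length(fav) == 0) fav <- sample(fam_levels, 1)
      in_fav <- fams %in% fav
      keep <- ifelse(in_fav, 1, params$lineage_retention)
      cells[, n_core + t] <- as.integer(stats::runif(n) < keep)
    }
    cells <- apply_noise(cells, params$noise_flip)
  })
  trait_table(cells, group_labels = layout$groups,
              trait_labels = paste0("T", seq_len(params$n_traits)))
}

#' Nine-group High Plains fixture layout
#'
#' The nine equestrian buffalo-hunting groups of the 19th-century High
#' Plains, with a language classification reconstructed from the standard
#' references (Algonquian: Blackfoot, Cheyenne, and the Arapahoan subgroup
#' Arapaho + Gros Ventre; Siouan: Crow and the Dakotan subgroup
#' Assiniboine + Teton; Kiowa-Tanoan: Kiowa; Athabaskan: Sarsi).
#' Coordinates and border pairs are *synthetic placeholders* — plausible
#' territory centroids, not the deposited survey coordinates — and are
#' flagged as such; pass `geo_path`/`border_path` to substitute
#' authoritative tables when reproducing published statistics.
#'
#' @param geo_path optional CSV (`group,lat,lon`) replacing the placeholder
#'   centroids.
#' @param border_path optional CSV (`group1,group2`) replacing the
#'   placeholder border pairs.
#' @return a `group_layout` with attribute `synthetic_coordinates` set to
#'   `TRUE` when placeholders are in use.
#' @export
make_plains_fixture <- function(geo_path = NULL, border_path = NULL) {
  extdata <- function(f) system.file("extdata", f, package = "culturedrift",
                                     mustWork = TRUE)
  cls <- read_classification(extdata("plains_classification_reconstructed.csv"))
  synthetic <- is.null(geo_path)
  geo <- read_geo_table(
    if (is.null(geo_path)) extdata("plains_centroids_synthetic.csv")
    else geo_path)
  borders <- read_border_list(
    if (is.null(border_path)) extdata("plains_borders_synthetic.csv")
    else border_path)
  layout <- group_layout(geo, borders, cls)
  attr(layout, "synthetic_coordinates") <- synthetic
  layout
}
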