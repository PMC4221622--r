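#' Model (hypothesis) matrices
#'
#' Cultural distance matrices are tested against "model matrices" that encode
#' hypothesized determinants of between-group similarity as pairwise
#' matrices: geographic distance between territory centroids, shared
#' territorial borders, tiered linguistic similarity, and scalar controls
#' such as sample size.
#'
#' @name model_matrices
NULL

MEAN_EARTH_RADIUS_KM <- 6371.0088

#' Great-circle distance matrix from group centroids
#'
#' Haversine distances on a sphere between decimal lat/lon centroids, the
#' standard operationalization of geographic proximity when territories are
#' reduced to center points.
#'
#' @param geo data frame with columns `group`, `lat`, `lon` (decimal degrees,
#'   N/E positive), one row per group.
#' @param radius_km sphere radius; default the IUGG mean Earth radius.
#' @return a distance-polarity `pairwise_matrix` in kilometres.
#' @export
greatcircle_matrix <- function(geo, radius_km = MEAN_EARTH_RADIUS_KM) {
  geo <- validate_geo_table(geo)
  n <- nrow(geo)
  if (n < 2) stop("need at least two groups with coordinates")
  if (!is.numeric(radius_km) || radius_km <= 0) stop("radius must be positive")
  # geosphere wants (lon, lat) and a radius in the distance unit (metres by
  # convention; passing km yields km)
  pts <- as.matrix(geo[, c("lon", "lat")])
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    d[i, (i + 1):n] <- geosphere::distHaversine(
      pts[i, , drop = FALSE], pts[(i + 1):n, , drop = FALSE], r = radius_km)
  }
  d <- d + t(d)
  pairwise_matrix(d, geo$group, polarity = "distance")
}

validate_geo_table <- function(geo) {
  geo <- as.data.frame(geo)
  need <- c("group", "lat", "lon")
  if (!all(need %in% names(geo))) {
    stop("geo table needs columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(geo$group)) stop("duplicate groups in geo table")
  if (any(!is.finite(geo$lat)) || any(!is.finite(geo$lon))) {
    stop("non-finite coordinate in geo table")
  }
  if (any(geo$lat < -90 | geo$lat > 90)) {
    stop("latitude out of [-90, 90] for group ",
         geo$group[which(geo$lat < -90 | geo$lat > 90)[1]])
  }
  if (any(geo$lon < -180 | geo$lon > 180)) {
    stop("longitude out of [-180, 180] for group ",
         geo$group[which(geo$lon < -180 | geo$lon > 180)[1]])
  }
  geo$group <- as.character(geo$group)
  geo
}

#' Binary border-sharing matrix
#'
#' Coded as a distance: 0 when two groups share a territorial boundary
#' (proximity), 1 when they do not.
#'
#' @param groups ordered character vector of group names.
#' @param borders data frame (or 2-column matrix) of unordered group pairs
#'   that share a boundary; may be empty.
#' @return a binary distance-polarity `pairwise_matrix`.
#' @export
border_matrix <- function(groups, borders) {
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("duplicate group names")
  m <- matrix(1, length(groups), length(groups))
  diag(m) <- 0
  if (!is.null(borders) && NROW(borders) > 0) {
    borders <- as.matrix(borders)
    if (ncol(borders) != 2) stop("border list must have two columns")
    for (k in seq_len(nrow(borders))) {
      g1 <- as.character(borders[k, 1])
      g2 <- as.character(borders[k, 2])
      if (!(g1 %in% groups) || !(g2 %in% groups)) {
        stop("border pair references unknown group: ", g1, " / ", g2)
      }
      if (g1 == g2) stop("self-border for group ", g1)
      i <- match(g1, groups); j <- match(g2, groups)
      m[i, j] <- m[j, i] <- 0
    }
  }
  pairwise_matrix(m, groups, polarity = "distance")
}

#' Tiered language-similarity scheme
#'
#' Percent similarities assigned by classification tier: groups from
#' different language families, same family but different subgroups, and the
#' same subgroup. Optional per-pair overrides (applied last) express variant
#' codings such as extra similarity within a particularly close subgroup.
#'
#' @param interfamily_pct,intrafamily_pct,intrasubgroup_pct percent
#'   similarities, `interfamily <= intrafamily <= intrasubgroup`, each in
#'   \[0, 100\].
#' @param overrides optional data frame with columns `group1`, `group2`,
#'   `pct`.
#' @return a list of class `language_scheme`.
#' @export
language_scheme <- function(interfamily_pct = 5, intrafamily_pct = 50,
                            intrasubgroup_pct = 80, overrides = NULL) {
  pcts <- c(interfamily_pct, intrafamily_pct, intrasubgroup_pct)
  if (any(pcts < 0 | pcts > 100)) stop("percent similarities must be in [0, 100]")
  if (is.unsorted(pcts)) {
    stop("need interfamily_pct <= intrafamily_pct <= intrasubgroup_pct")
  }
  if (!is.null(overrides)) {
    overrides <- as.data.frame(overrides)
    if (!all(c("group1", "group2", "pct") %in% names(overrides))) {
      stop("overrides need columns group1, group2, pct")
    }
  }
  structure(
    list(interfamily_pct = interfamily_pct,
         intrafamily_pct = intrafamily_pct,
         intrasubgroup_pct = intrasubgroup_pct,
         overrides = overrides),
    class = "language_scheme"
  )
}

#' Language model matrix from a classification and a tier scheme
#'
#' Converts a group -> (family, subgroup) classification into a
#' similarity-polarity matrix: `intrasubgroup_pct` for same family and same
#' named subgroup, `intrafamily_pct` for same family but different (or
#' unnamed) subgroups, `interfamily_pct` otherwise. Groups without a named
#' subgroup (`""` or `NA`) never match another group's subgroup, including
#' each other's. Overrides are applied last. Diagonal is 100.
#'
#' @param cls data frame with columns `group`, `family`, `subgroup`
#'   (`""`/`NA` for none).
#' @param scheme a [language_scheme()].
#' @return a similarity-polarity `pairwise_matrix` (percent scale).
#' @export
language_matrix <- function(cls, scheme = language_scheme()) {
  stopifnot(inherits(scheme, "language_scheme"))
  cls <- as.data.frame(cls)
  if (!all(c("group", "family") %in% names(cls))) {
    stop("classification needs columns group, family (and optionally subgroup)")
  }
  if (is.null(cls$subgroup)) cls$subgroup <- ""
  cls$group <- as.character(cls$group)
  cls$family <- as.character(cls$family)
  cls$subgroup <- as.character(cls$subgroup)
  cls$subgroup[is.na(cls$subgroup)] <- ""
  if (anyDuplicated(cls$group)) stop("duplicate groups in classification")
  if (any(is.na(cls$family) | cls$family == "")) {
    stop("every group must be classified to a language family")
  }
  n <- nrow(cls)
  m <- matrix(scheme$interfamily_pct, n, n)
  same_family <- outer(cls$family, cls$family, "==")
  m[same_family] <- scheme$intrafamily_pct
  named_sub <- cls$subgroup != ""
  same_sub <- outer(cls$subgroup, cls$subgroup, "==") &
    outer(named_sub, named_sub, "&")
  m[same_family & same_sub] <- scheme$intrasubgroup_pct
  if (!is.null(scheme$overrides)) {
    for (k in seq_len(nrow(scheme$overrides))) {
      g1 <- as.character(scheme$overrides$group1[k])
      g2 <- as.character(scheme$overrides$group2[k])
      if (!(g1 %in% cls$group) || !(g2 %in% cls$group)) {
        stop("override pair references unknown group: ", g1, " / ", g2)
      }
      i <- match(g1, cls$group); j <- match(g2, cls$group)
      m[i, j] <- m[j, i] <- scheme$overrides$pct[k]
    }
  }
  diag(m) <- 100
  pairwise_matrix(m, cls$group, polarity = "similarity",
                  diagonal_policy = "excluded")
}

#' Euclidean distance matrix on a scalar group attribute
#'
#' `|v_i - v_j|` — used e.g. as a sample-size control matrix to check that a
#' cultural distance pattern is not an artifact of unequal collection sizes.
#'
#' @param values named numeric vector (names = groups) or data frame with
#'   columns `group`, `value`.
#' @return a distance-polarity `pairwise_matrix`.
#' @export
euclidean_scalar_matrix <- function(values) {
  if (is.data.frame(values)) {
    if (!all(c("group", "value") %in% names(values))) {
      stop("data frame needs columns group, value")
    }
    v <- stats::setNames(values$value, as.character(values$group))
  } else {
    v <- values
  }
  if (is.null(names(v)) || any(names(v) == "")) {
    stop("every value must be named by its group")
  }
  if (any(!is.finite(v))) {
    stop("missing or non-finite value for group ",
         names(v)[which(!is.finite(v))[1]])
  }
  m <- abs(outer(v, v, "-"))
  pairwise_matrix(m, names(v), polarity = "distance")
}

#' Read a group coordinate table (group, lat, lon CSV)
#' @param path file path.
#' @return validated data frame with columns `group`, `lat`, `lon`.
#' @export
read_geo_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  df$lat <- as.numeric(df$lat)
  df$lon <- as.numeric(df$lon)
  validate_geo_table(df)
}

#' Read a border pair list (two-column CSV of group names)
#' @param path file path.
#' @return data frame with columns `group1`, `group2`.
#' @export
read_border_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("border list needs two columns")
  stats::setNames(df[, 1:2], c("group1", "group2"))
}

#' Read a language classification (group, family, subgroup CSV)
#' @param path file path.
#' @return data frame with columns `group`, `family`, `subgroup`.
#' @export
read_classification <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!all(c("group", "family") %in% names(df))) {
    stop("classification needs columns group, family")
  }
  if (is.null(df$subgroup)) df$subgroup <- ""
  df$subgroup[is.na(df$subgroup)] <- ""
  df
}
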