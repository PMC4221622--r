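#' Full matrix-comparison analysis
#'
#' One call that runs the whole inference chain on a set of cultural trait
#' systems and model matrices: cultural-vs-cultural Mantel, each cultural
#' matrix against each model matrix, model-vs-model checks
#' (language vs geography), partial Mantels of each cultural matrix against
#' each language matrix controlling geographic distance, an optional
#' sample-size control, and the diversity-contrast selection test.
#'
#' @name pipeline
NULL

#' Build an analysis configuration
#'
#' @param cultural named list of cultural inputs; each element is either a
#'   distance-polarity `pairwise_matrix` or a `trait_table` (converted via
#'   [jaccard_matrix()] under `missing_policy`).
#' @param geo geographic input: a distance `pairwise_matrix` or a
#'   `group,lat,lon` data frame (converted via [greatcircle_matrix()]).
#' @param borders optional border pair data frame (`group1`, `group2`).
#' @param classification optional language classification data frame.
#' @param schemes named list of [language_scheme()]s; default the three
#'   standard variants: `matrix1` (5/50/80), `matrix2` (5/50/80 with 95
#'   overrides for the Arapahoan and Dakotan subgroup pairs when those
#'   groups are present), `matrix3` (5/30/80).
#' @param sample_sizes optional named numeric vector of per-group collection
#'   sizes; adds a Euclidean control Mantel against each cultural matrix.
#' @param selection length-2 character vector
#'   `c(focal = ..., reference = ...)` naming elements of `cultural` to
#'   contrast for selection; `NULL` skips the selection test.
#' @param missing_policy Jaccard questionable-code policy for trait-table
#'   inputs (`"pairwise_delete"` default; `"recode_present"` re-runs the
#'   whole chain as the sensitivity variant).
#' @param n_perm_mantel,n_rand_wilcoxon,n_rand_mw randomization counts
#'   (defaults 10000, 99999, 10000).
#' @param alpha significance level (default 0.05).
#' @param tail Mantel tail convention (default two-sided).
#' @param seed master seed; every sub-test seed derives from it.
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(cultural, geo = NULL, borders = NULL,
                            classification = NULL, schemes = NULL,
                            sample_sizes = NULL, selection = NULL,
                            missing_policy = "pairwise_delete",
                            n_perm_mantel = 10000, n_rand_wilcoxon = 99999,
                            n_rand_mw = 10000, alpha = 0.05,
                            tail = "two_sided", seed = 1L) {
  if (length(cultural) == 0 || is.null(names(cultural)) ||
      any(names(cultural) == "")) {
    stop("cultural must be a nonempty named list")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(n_perm_mantel >= 1, n_rand_wilcoxon >= 1, n_rand_mw >= 1)
  if (!is.null(selection)) {
    if (length(selection) != 2 || !all(selection %in% names(cultural))) {
      stop("selection must name two elements of cultural")
    }
  }
  if (is.null(schemes) && !is.null(classification)) {
    schemes <- default_language_schemes(classification)
  }
  structure(
    list(cultural = cultural, geo = geo, borders = borders,
         classification = classification, schemes = schemes,
         sample_sizes = sample_sizes, selection = selection,
         missing_policy = missing_policy, n_perm_mantel = n_perm_mantel,
         n_rand_wilcoxon = n_rand_wilcoxon, n_rand_mw = n_rand_mw,
         alpha = alpha, tail = tail, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' The three standard language-matrix variants
#'
#' `matrix1`: 5/50/80. `matrix2`: as matrix1 but 95% within the Arapahoan
#' (Arapaho-Gros Ventre) and Dakotan (Assiniboine-Teton) subgroup pairs,
#' applied only when both members are present in the classification.
#' `matrix3`: interfamily 5, same family 30, same subgroup 80.
#'
#' @param classification data frame with a `group` column, used to decide
#'   whether the matrix2 overrides apply.
#' @return named list of [language_scheme()]s.
#' @export
default_language_schemes <- function(classification) {
  groups <- as.character(classification$group)
  ov <- data.frame(group1 = c("Arapaho", "Assiniboine"),
                   group2 = c("GrosVentre", "Teton"),
                   pct = c(95, 95))
  ov <- ov[ov$group1 %in% groups & ov$group2 %in% groups, , drop = FALSE]
  list(
    matrix1 = language_scheme(5, 50, 80),
    matrix2 = language_scheme(5, 50, 80,
                              overrides = if (nrow(ov)) ov else NULL),
    matrix3 = language_scheme(5, 30, 80)
  )
}

as_cultural_distance <- function(x, name, missing_policy) {
  if (inherits(x, "trait_table")) {
    return(jaccard_matrix(x, missing_policy = missing_policy,
                          polarity = "distance"))
  }
  if (inherits(x, "pairwise_matrix")) {
    if (x$polarity != "distance") {
      stop("cultural matrix '", name, "' must have distance polarity; ",
           "convert explicitly with convert_polarity()")
    }
    return(x)
  }
  stop("cultural input '", name, "' is neither a trait_table nor a ",
       "pairwise_matrix")
}

#' Run the full analysis
#'
#' Executes every comparison implied by the configuration, in a fixed
#' order, with deterministic per-comparison seeds derived from the master
#' seed. Any label misalignment between matrices aborts with the offending
#' comparison named.
#'
#' @param config an [analysis_config()].
#' @return an object of class `analysis_report`: `$mantel` (one row per
#'   comparison: names, control, r, p, n_perm, significance), `$selection`
#'   (a `selection_verdict` or `NULL`), `$config`.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  cultural <- mapply(as_cultural_distance, config$cultural,
                     names(config$cultural),
                     MoreArgs = list(missing_policy = config$missing_policy),
                     SIMPLIFY = FALSE)
  labels <- cultural[[1]]$labels

  models <- list()
  geo_m <- NULL
  if (!is.null(config$geo)) {
    geo_m <- if (inherits(config$geo, "pairwise_matrix")) config$geo
             else greatcircle_matrix(config$geo)
    models$geography <- geo_m
  }
  if (!is.null(config$borders)) {
    models$border_share <- border_matrix(labels, config$borders)
  }
  lang_names <- character(0)
  if (!is.null(config$classification)) {
    schemes <- config$schemes
    if (is.null(schemes)) {
      schemes <- default_language_schemes(config$classification)
    }
    for (nm in names(schemes)) {
      models[[paste0("language_", nm)]] <-
        language_matrix(config$classification, schemes[[nm]])
    }
    lang_names <- paste0("language_", names(schemes))
  }
  # align everything to the cultural label order
  align <- function(m, what) {
    if (!setequal(m$labels, labels)) {
      stop("label misalignment in ", what, ": groups {",
           paste(setdiff(union(m$labels, labels),
                         intersect(m$labels, labels)), collapse = ", "),
           "} are not shared")
    }
    reorder_groups(m, labels)
  }
  for (nm in names(cultural)) cultural[[nm]] <- align(cultural[[nm]], nm)
  for (nm in names(models)) models[[nm]] <- align(models[[nm]], nm)
  if (!is.null(geo_m)) geo_m <- models$geography

  rows <- list()
  seed_k <- config$seed
  add <- function(a_name, b_name, A, B, control_name = "", Cm = NULL) {
    seed_k <<- seed_k + 1L
    res <- if (is.null(Cm)) {
      mantel(A, B, n_perm = config$n_perm_mantel, tail = config$tail,
             seed = seed_k)
    } else {
      partial_mantel(A, B, Cm, n_perm = config$n_perm_mantel,
                     tail = config$tail, seed = seed_k)
    }
    rows[[length(rows) + 1]] <<- data.frame(
      comparison = if (control_name == "")
        paste(a_name, "vs", b_name)
      else paste(a_name, "vs", b_name, "controlling", control_name),
      matrix_a = a_name, matrix_b = b_name, control = control_name,
      r = res$r_observed, p = res$p_value,
      n_permutations = res$n_permutations,
      significant = res$p_value < config$alpha,
      stringsAsFactors = FALSE)
  }

  cult_names <- names(cultural)
  if (length(cult_names) >= 2) {
    for (i in seq_len(length(cult_names) - 1)) {
      for (j in (i + 1):length(cult_names)) {
        add(cult_names[i], cult_names[j],
            cultural[[i]], cultural[[j]])
      }
    }
  }
  for (cn in cult_names) {
    for (mn in names(models)) {
      add(cn, mn, cultural[[cn]], models[[mn]])
    }
  }
  if (!is.null(geo_m)) {
    for (ln in lang_names) add(ln, "geography", models[[ln]], geo_m)
    for (cn in cult_names) {
      for (ln in lang_names) {
        add(cn, ln, cultural[[cn]], models[[ln]],
            control_name = "geography", Cm = geo_m)
      }
    }
  }
  if (!is.null(config$sample_sizes)) {
    ss <- align(euclidean_scalar_matrix(config$sample_sizes),
                "sample_sizes")
    for (cn in cult_names) add(cn, "sample_size_control", cultural[[cn]], ss)
  }

  verdict <- NULL
  if (!is.null(config$selection)) {
    verdict <- diversity_selection_test(
      cultural[[config$selection[1]]], cultural[[config$selection[2]]],
      alpha = config$alpha, n_rand_wilcoxon = config$n_rand_wilcoxon,
      n_rand_mw = config$n_rand_mw, seed = config$seed + 10000L)
  }

  structure(
    list(mantel = do.call(rbind, rows), selection = verdict,
         config = config),
    class = "analysis_report"
  )
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report: ", nrow(x$mantel), " matrix comparisons\n", sep = "")
  df <- x$mantel
  df$r <- round(df$r, 3)
  df$p <- round(df$p, 4)
  print(df[, c("comparison", "r", "p", "significant")], row.names = FALSE)
  if (!is.null(x$selection)) print(x$selection)
  invisible(x)
}

#' Write the Mantel comparison table of a report to CSV
#' @param report an `analysis_report`.
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_analysis_report <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  utils::write.csv(report$mantel, path, row.names = FALSE)
  invisible(path)
}
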