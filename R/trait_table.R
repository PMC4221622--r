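#' Group-by-trait presence/absence table
#'
#' The raw cultural inventory: each cell records whether a group exhibits a
#' trait (`present`), lacks it (`absent`), or was recorded as questionable
#' (`questionable`) by the original ethnographer. Questionable codes are
#' handled at Jaccard time by one of two explicit policies, never imputed.
#'
#' Internally cells are stored as an integer matrix: 1 = present, 0 = absent,
#' NA = questionable.
#'
#' @param cells matrix (integer 0/1/NA, logical, or character "1"/"0"/"?")
#'   with groups as rows and traits as columns.
#' @param group_labels,trait_labels unique names; default to dimnames.
#' @return an object of class `trait_table`.
#' @export
trait_table <- function(cells, group_labels = rownames(cells),
                        trait_labels = colnames(cells)) {
  cells <- as.matrix(cells)
  if (is.character(cells)) {
    cells <- decode_cells(cells, c("1" = 1L, "0" = 0L, "?" = NA_integer_))
  }
  if (is.logical(cells)) storage.mode(cells) <- "integer"
  if (!is.numeric(cells)) stop("cells must be 0/1/NA")
  bad <- !(cells %in% c(0L, 1L)) & !is.na(cells)
  if (any(bad)) {
    w <- which(bad, arr.ind = TRUE)[1, ]
    stop("invalid cell value ", cells[bad][1], " at row ", w[1],
         ", column ", w[2], " (must be 0, 1, or NA/questionable)")
  }
  storage.mode(cells) <- "integer"
  if (nrow(cells) == 0 || ncol(cells) == 0) {
    stop("trait table must have at least one group and one trait")
  }
  if (is.null(group_labels)) group_labels <- paste0("G", seq_len(nrow(cells)))
  if (is.null(trait_labels)) trait_labels <- paste0("T", seq_len(ncol(cells)))
  group_labels <- as.character(group_labels)
  trait_labels <- as.character(trait_labels)
  if (length(group_labels) != nrow(cells) ||
      length(trait_labels) != ncol(cells)) {
    stop("label lengths do not match table dimensions")
  }
  if (anyDuplicated(group_labels)) {
    stop("duplicate group labels: ",
         paste(unique(group_labels[duplicated(group_labels)]), collapse = ", "))
  }
  if (anyDuplicated(trait_labels)) {
    stop("duplicate trait labels: ",
         paste(unique(trait_labels[duplicated(trait_labels)]), collapse = ", "))
  }
  dimnames(cells) <- list(group_labels, trait_labels)
  structure(
    list(group_labels = group_labels, trait_labels = trait_labels,
         cells = cells),
    class = "trait_table"
  )
}

decode_cells <- function(cells, dialect) {
  flat <- trimws(as.vector(cells))
  known <- flat %in% names(dialect)
  if (!all(known)) {
    idx <- arrayInd(which(!known)[1], dim(cells))
    stop("unmappable cell value '", flat[!known][1], "' at row ", idx[1],
         ", column ", idx[2], "; dialect knows: ",
         paste(names(dialect), collapse = ", "))
  }
  out <- unname(dialect[flat])
  dim(out) <- dim(cells)
  dimnames(out) <- dimnames(cells)
  out
}

#' @export
print.trait_table <- function(x, ...) {
  nq <- sum(is.na(x$cells))
  cat("trait_table: ", length(x$group_labels), " groups x ",
      length(x$trait_labels), " traits (", nq, " questionable cells)\n",
      sep = "")
  invisible(x)
}

#' Read a trait table from CSV
#'
#' Layout: header row gives trait labels, first column gives group labels,
#' cells are codes mapped through `dialect` (defaults: `"1"` present, `"0"`
#' absent, `"?"` questionable).
#'
#' @param path file path.
#' @param dialect named integer vector mapping cell strings to 1 (present),
#'   0 (absent), `NA` (questionable).
#' @return a `trait_table`.
#' @export
read_trait_table <- function(path,
                             dialect = c("1" = 1L, "0" = 0L,
                                         "?" = NA_integer_)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        colClasses = "character")
  if (nrow(df) == 0) stop("trait table has no data rows: ", path)
  cells <- decode_cells(as.matrix(df), dialect)
  trait_table(cells, group_labels = rownames(df), trait_labels = colnames(df))
}

#' Write a trait table as CSV (1/0/? dialect)
#' @param tt a `trait_table`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_trait_table <- function(tt, path) {
  stopifnot(inherits(tt, "trait_table"))
  chr <- ifelse(is.na(tt$cells), "?", as.character(tt$cells))
  dim(chr) <- dim(tt$cells)
  dimnames(chr) <- dimnames(tt$cells)
  utils::write.csv(as.data.frame(chr), path)
  invisible(path)
}

#' Jaccard components for one pair of trait vectors
#'
#' Returns the 2x2 presence/absence cross-classification of two groups over
#' the scorable traits: `a` shared presences, `b` present only in the first,
#' `c` present only in the second, `d` joint absences, plus `n_deleted`, the
#' traits excluded by pairwise deletion. Under `"pairwise_delete"` a trait
#' questionable in either vector is excluded from that pair only; under
#' `"recode_present"` questionable codes count as presences.
#'
#' @param row_i,row_j integer/NA vectors of equal length (1 present, 0 absent,
#'   NA questionable).
#' @param missing_policy `"pairwise_delete"` or `"recode_present"`.
#' @return a list of class `jaccard_counts` with fields
#'   `a`, `b`, `c`, `d`, `n_deleted`.
#' @export
jaccard_counts <- function(row_i, row_j,
                           missing_policy = c("pairwise_delete",
                                              "recode_present")) {
  missing_policy <- match.arg(missing_policy)
  if (length(row_i) != length(row_j)) {
    stop("trait vectors differ in length: ", length(row_i), " vs ",
         length(row_j))
  }
  if (missing_policy == "recode_present") {
    row_i[is.na(row_i)] <- 1L
    row_j[is.na(row_j)] <- 1L
    keep <- rep(TRUE, length(row_i))
  } else {
    keep <- !is.na(row_i) & !is.na(row_j)
  }
  x <- row_i[keep]
  y <- row_j[keep]
  structure(
    list(a = sum(x == 1L & y == 1L),
         b = sum(x == 1L & y == 0L),
         c = sum(x == 0L & y == 1L),
         d = sum(x == 0L & y == 0L),
         n_deleted = sum(!keep)),
    class = "jaccard_counts"
  )
}

#' Jaccard pairwise matrix from a trait table
#'
#' Jaccard similarity `S = a / (a + b + c)` over scorable traits: shared
#' presences relative to traits present in at least one of the two groups.
#' Joint absences carry no signal (an absence may merely be an observation
#' gap), so `d` never enters. Distance is `D = 1 - S`.
#'
#' @param table a `trait_table` with at least two groups.
#' @param missing_policy passed to [jaccard_counts()].
#' @param polarity which of the complementary values to store.
#' @return a `pairwise_matrix` (diagonal 0 for distance, 1 for similarity).
#' @export
jaccard_matrix <- function(table,
                           missing_policy = c("pairwise_delete",
                                              "recode_present"),
                           polarity = c("distance", "similarity")) {
  missing_policy <- match.arg(missing_policy)
  polarity <- match.arg(polarity)
  stopifnot(inherits(table, "trait_table"))
  n <- length(table$group_labels)
  if (n < 2) stop("need at least two groups")
  S <- diag(1, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cnt <- jaccard_counts(table$cells[i, ], table$cells[j, ],
                            missing_policy)
      denom <- cnt$a + cnt$b + cnt$c
      if (denom == 0) {
        stop("Jaccard undefined for pair (", table$group_labels[i], ", ",
             table$group_labels[j],
             "): no scorable presences in either group")
      }
      S[i, j] <- S[j, i] <- cnt$a / denom
    }
  }
  vals <- if (polarity == "distance") 1 - S else S
  pairwise_matrix(vals, table$group_labels, polarity = polarity,
                  diagonal_policy = if (polarity == "distance") "zero" else "one")
}
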