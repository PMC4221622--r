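#' Labelled symmetric pairwise matrix with explicit polarity
#'
#' The universal currency of the pipeline: a symmetric group-by-group matrix
#' of either distances or similarities. Polarity is carried explicitly because
#' downstream tests interpret the two differently (a positive Mantel
#' correlation against a similarity matrix means the same thing as a negative
#' one against the corresponding distance matrix), and the selection test
#' refuses anything but distances.
#'
#' @param values square numeric matrix, symmetric up to `tol`.
#' @param labels character vector of group names; defaults to
#'   `rownames(values)`. Order is meaningful and preserved everywhere.
#' @param polarity `"distance"` or `"similarity"`.
#' @param diagonal_policy how the diagonal is to be read: `"zero"`, `"one"`,
#'   or `"excluded"` (stored values ignored). All statistics in this package
#'   use off-diagonal entries only.
#' @param tol absolute tolerance for the symmetry check.
#' @return an object of class `pairwise_matrix`.
#' @export
pairwise_matrix <- function(values, labels = rownames(values),
                            polarity = c("distance", "similarity"),
                            diagonal_policy = c("zero", "one", "excluded"),
                            tol = 1e-8) {
  polarity <- match.arg(polarity)
  diagonal_policy <- match.arg(diagonal_policy)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop("pairwise matrix must be square, got ", nrow(values), "x", ncol(values))
  }
  n <- nrow(values)
  if (is.null(labels)) labels <- paste0("G", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("need exactly one label per row")
  if (anyDuplicated(labels)) {
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  storage.mode(values) <- "double"
  off <- values[row(values) != col(values)]
  if (any(!is.finite(off))) stop("off-diagonal values must all be finite")
  if (max(abs(values - t(values))) > tol) {
    stop("matrix is not symmetric (max asymmetry ",
         format(max(abs(values - t(values)))), ")")
  }
  values <- (values + t(values)) / 2   # remove numeric asymmetry
  if (polarity == "distance" && any(off < -tol)) {
    stop("distance matrix has negative off-diagonal entries")
  }
  dimnames(values) <- list(labels, labels)
  structure(
    list(labels = labels, values = values, polarity = polarity,
         diagonal_policy = diagonal_policy),
    class = "pairwise_matrix"
  )
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix: ", length(x$labels), " groups, polarity=",
      x$polarity, ", diagonal=", x$diagonal_policy, "\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' @export
as.matrix.pairwise_matrix <- function(x, ...) x$values

#' Number of groups in a pairwise matrix
#' @param m a `pairwise_matrix`.
#' @return integer group count.
#' @export
n_groups <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  length(m$labels)
}

#' Off-diagonal vectorization
#'
#' Flattens the unique pairs of a symmetric matrix into the fixed order used
#' by every test in the package: upper triangle, row-major, i < j, i.e.
#' (1,2), (1,3), ..., (1,n), (2,3), ..., (n-1,n). The order is deterministic
#' for a given label order, which is what makes the paired selection tests
#' well-defined: two matrices over the same labels vectorize into aligned
#' pairs.
#'
#' @param m a `pairwise_matrix` with at least two groups.
#' @return numeric vector of length `n*(n-1)/2`, named `"a|b"` by group pair.
#' @export
offdiag_vector <- function(m) {
  stopifnot(inherits(m, "pairwise_matrix"))
  v <- m$values
  n <- nrow(v)
  if (n < 2) stop("need at least 2 groups to vectorize")
  # t(v)[lower.tri(v)] walks the upper triangle in row-major order
  out <- t(v)[lower.tri(v)]
  idx <- which(lower.tri(v), arr.ind = TRUE)   # (j, i) pairs of t(v)
  names(out) <- paste(m$labels[idx[, 2]], m$labels[idx[, 1]], sep = "|")
  out
}

#' Convert a pairwise matrix between distance and similarity polarity
#'
#' Jaccard similarity and distance are complementary on \[0, 1\]
#' (`D = 1 - S`), so conversion is `max_value - x` with `max_value = 1` by
#' default. The diagonal policy flips zero <-> one accordingly.
#'
#' @param m a `pairwise_matrix`.
#' @param polarity target polarity.
#' @param max_value the complement ceiling (1 for Jaccard, 100 for
#'   percent-scaled similarities).
#' @return a `pairwise_matrix` of the requested polarity.
#' @export
convert_polarity <- function(m, polarity = c("distance", "similarity"),
                             max_value = 1) {
  polarity <- match.arg(polarity)
  stopifnot(inherits(m, "pairwise_matrix"))
  if (identical(m$polarity, polarity)) return(m)
  vals <- max_value - m$values
  diagp <- switch(m$diagonal_policy,
                  zero = "one", one = "zero", excluded = "excluded")
  if (diagp != "excluded") {
    diag(vals) <- if (diagp == "zero") 0 else max_value
  }
  pairwise_matrix(vals, m$labels, polarity = polarity,
                  diagonal_policy = diagp)
}

#' Check that two (or more) pairwise matrices share an identical label order
#' @param ... `pairwise_matrix` objects.
#' @return invisibly `TRUE`; otherwise an error naming the mismatch.
#' @export
check_same_labels <- function(...) {
  ms <- list(...)
  stopifnot(length(ms) >= 2)
  ref <- ms[[1]]$labels
  for (k in seq_along(ms)[-1]) {
    if (!identical(ms[[k]]$labels, ref)) {
      stop("label mismatch between matrices (argument 1 vs argument ", k,
           "): matrices must carry the same groups in the same order")
    }
  }
  invisible(TRUE)
}

#' Reorder a pairwise matrix to a new label order
#' @param m a `pairwise_matrix`.
#' @param labels permutation of `m$labels`.
#' @return reordered `pairwise_matrix`.
#' @export
reorder_groups <- function(m, labels) {
  stopifnot(inherits(m, "pairwise_matrix"))
  if (!setequal(labels, m$labels) || length(labels) != length(m$labels)) {
    stop("labels must be a permutation of the matrix labels")
  }
  idx <- match(labels, m$labels)
  pairwise_matrix(m$values[idx, idx], labels, polarity = m$polarity,
                  diagonal_policy = m$diagonal_policy)
}

#' Read a square labelled matrix CSV as a pairwise matrix
#'
#' Expects the conventional square layout: first row and first column carry
#' the group labels, body is numeric. Polarity is not part of the file and
#' must be supplied (or recorded alongside by [write_pairwise_matrix()]'s
#' sidecar comment line, which this reader recognises).
#'
#' @param path file path.
#' @param polarity `"distance"` or `"similarity"`; if `NULL`, taken from a
#'   `# polarity: ...` comment line if present, else an error.
#' @param diagonal_policy see [pairwise_matrix()].
#' @return a `pairwise_matrix`.
#' @export
read_pairwise_matrix <- function(path, polarity = NULL,
                                 diagonal_policy = "zero") {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (grepl("^#\\s*polarity:", first)) {
    file_pol <- trimws(sub("^#\\s*polarity:\\s*", "", first))
    if (is.null(polarity)) polarity <- file_pol
  }
  if (is.null(polarity)) {
    stop("polarity not given and not recorded in ", path)
  }
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        comment.char = "#")
  pairwise_matrix(as.matrix(df), labels = rownames(df),
                  polarity = polarity, diagonal_policy = diagonal_policy)
}

#' Write a pairwise matrix as a square labelled CSV
#'
#' A `# polarity:` comment line is prepended so the file round-trips through
#' [read_pairwise_matrix()] without external metadata.
#'
#' @param m a `pairwise_matrix`.
#' @param path output file path.
#' @return invisibly `path`.
#' @export
write_pairwise_matrix <- function(m, path) {
  stopifnot(inherits(m, "pairwise_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# polarity: ", m$polarity), con)
  utils::write.csv(as.data.frame(m$values), con)
  invisible(path)
}
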