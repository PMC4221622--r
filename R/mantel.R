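#' Mantel and partial Mantel permutation tests
#'
#' Pairwise matrices violate the independence assumptions of ordinary
#' correlation inference: each group contributes to n-1 entries. The Mantel
#' test therefore keeps the observed correlation of the two off-diagonal
#' vectors as the statistic but builds its null distribution by applying
#' random simultaneous row-and-column permutations to one matrix — the
#' exchangeable units are groups, not pairs.
#'
#' Conventions used throughout (all overridable where it makes sense):
#' the first matrix is the one permuted; p-values follow the +1/+1
#' convention (the identity arrangement counts in both numerator and
#' denominator, so p is never 0); the default tail is two-sided on |r|.
#'
#' @name mantel_tests
NULL

new_mantel_result <- function(r, p, n_perm, tail, exact, seed, statistic,
                              n) {
  structure(
    list(r_observed = r, p_value = p, n_permutations = n_perm, tail = tail,
         exact = exact, seed = seed, statistic = statistic, n_groups = n),
    class = "mantel_result"
  )
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(x$statistic, ": r = ", format(round(x$r_observed, 4)),
      ", p = ", format(round(x$p_value, 5)),
      " (", if (x$exact) "exact, " else "sampled, ",
      x$n_permutations, " permutations, tail = ", x$tail, ")\n", sep = "")
  invisible(x)
}

tail_count <- function(null_r, r_obs, tail, eps = 1e-12) {
  switch(tail,
         two_sided = sum(abs(null_r) >= abs(r_obs) - eps),
         greater = sum(null_r >= r_obs - eps),
         less = sum(null_r <= r_obs + eps),
         stop("unknown tail: ", tail))
}

check_mantel_inputs <- function(A, B, min_n = 3) {
  stopifnot(inherits(A, "pairwise_matrix"), inherits(B, "pairwise_matrix"))
  check_same_labels(A, B)
  n <- n_groups(A)
  if (n < min_n) stop("need at least ", min_n, " groups, got ", n)
  a <- offdiag_vector(A)
  b <- offdiag_vector(B)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("off-diagonal values are constant in one matrix; r is undefined")
  }
  list(a = a, b = b, n = n)
}

offdiag_raw <- function(v) t(v)[lower.tri(v)]

#' Mantel test between two pairwise matrices
#'
#' Statistic: Pearson correlation of the two off-diagonal vectors. Null:
#' `n_perm` random simultaneous row+column permutations of `A` (`B` fixed),
#' recomputing r each time. `p = (1 + #{|r_null| >= |r_obs|}) / (n_perm + 1)`
#' for the two-sided default.
#'
#' r is symmetric in the two arguments; the permutation side is not, but the
#' null distribution it induces is the same in distribution either way.
#'
#' @param A,B `pairwise_matrix` objects over identical labels in identical
#'   order, n >= 3.
#' @param n_perm number of random permutations (default 10000).
#' @param tail `"two_sided"`, `"greater"`, or `"less"`.
#' @param seed integer seed; `NULL` draws one (recorded in the result).
#' @return a `mantel_result`.
#' @export
mantel <- function(A, B, n_perm = 10000, tail = c("two_sided", "greater",
                                                  "less"), seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1")
  inp <- check_mantel_inputs(A, B)
  seed <- resolve_seed(seed)
  r_obs <- stats::cor(inp$a, inp$b)
  Av <- A$values
  null_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(inp$n)
      stats::cor(offdiag_raw(Av[p, p]), inp$b)
    }, numeric(1))
  })
  p <- (1 + tail_count(null_r, r_obs, tail)) / (n_perm + 1)
  new_mantel_result(r_obs, p, n_perm, tail, exact = FALSE, seed = seed,
                    statistic = "Mantel", n = inp$n)
}

#' Exact Mantel test by full enumeration
#'
#' Enumerates all n! simultaneous permutations of `A`; feasible for n <= 8.
#' Serves as the oracle against which the sampled test is validated.
#'
#' @inheritParams mantel
#' @return a `mantel_result` with `exact = TRUE` and
#'   `n_permutations = factorial(n)`.
#' @export
mantel_exact <- function(A, B, tail = c("two_sided", "greater", "less")) {
  tail <- match.arg(tail)
  inp <- check_mantel_inputs(A, B)
  if (inp$n > 8) {
    stop("n = ", inp$n, ": ", factorial(inp$n),
         " permutations is too many to enumerate; use the sampled mantel()")
  }
  perms <- all_permutations(inp$n)
  r_obs <- stats::cor(inp$a, inp$b)
  Av <- A$values
  null_r <- apply(perms, 1, function(p) {
    stats::cor(offdiag_raw(Av[p, p]), inp$b)
  })
  # enumeration includes the identity, so no +1 correction is needed
  p <- tail_count(null_r, r_obs, tail) / nrow(perms)
  new_mantel_result(r_obs, p, nrow(perms), tail, exact = TRUE, seed = NULL,
                    statistic = "Mantel (exact)", n = inp$n)
}

#' All permutations of 1..n as a matrix (n! rows)
#' @param n size, n <= 8.
#' @return integer matrix, one permutation per row.
#' @keywords internal
all_permutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (pos in seq_len(n)) {
    block <- nrow(sub)
    out[row:(row + block - 1), pos] <- n
    out[row:(row + block - 1), setdiff(seq_len(n), pos)] <- sub
    row <- row + block
  }
  out
}

#' Partial Mantel test controlling for a third matrix
#'
#' Statistic: the first-order partial correlation
#' `r_AB.C = (r_AB - r_AC r_BC) / sqrt((1 - r_AC^2)(1 - r_BC^2))` over the
#' off-diagonal vectors. Null: simultaneous permutations of `A` with `B` and
#' `C` fixed, recomputing the partial statistic each time (r_BC does not
#' change under the null and is computed once).
#'
#' @param A,B the matrices whose association is tested (A is permuted).
#' @param C the control matrix whose linear effect is removed.
#' @inheritParams mantel
#' @return a `mantel_result`.
#' @export
partial_mantel <- function(A, B, C, n_perm = 10000,
                           tail = c("two_sided", "greater", "less"),
                           seed = NULL) {
  tail <- match.arg(tail)
  if (n_perm < 1) stop("n_perm must be >= 1")
  stopifnot(inherits(C, "pairwise_matrix"))
  check_same_labels(A, B, C)
  inp <- check_mantel_inputs(A, B, min_n = 4)
  cvec <- offdiag_vector(C)
  if (stats::sd(cvec) == 0) {
    stop("control matrix has constant off-diagonal values")
  }
  partial_r <- function(avec) {
    r_ab <- stats::cor(avec, inp$b)
    r_ac <- stats::cor(avec, cvec)
    r_bc <- stats::cor(inp$b, cvec)
    if (abs(r_ac) >= 1 - 1e-12 || abs(r_bc) >= 1 - 1e-12) {
      stop("partial correlation undefined: control matrix is collinear ",
           "with one of the tested matrices (|r| = 1)")
    }
    (r_ab - r_ac * r_bc) / sqrt((1 - r_ac^2) * (1 - r_bc^2))
  }
  r_obs <- partial_r(inp$a)
  seed <- resolve_seed(seed)
  Av <- A$values
  null_r <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(k) {
      p <- sample.int(inp$n)
      partial_r(offdiag_raw(Av[p, p]))
    }, numeric(1))
  })
  p <- (1 + tail_count(null_r, r_obs, tail)) / (n_perm + 1)
  new_mantel_result(r_obs, p, n_perm, tail, exact = FALSE, seed = seed,
                    statistic = "partial Mantel", n = inp$n)
}

resolve_seed <- function(seed) {
  if (is.null(seed)) {
    seed <- sample.int(.Machine$integer.max, 1)
    message("no seed supplied; drew seed ", seed)
  }
  as.integer(seed)
}
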