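#' Diversity-contrast selection tests
#'
#' Under neutral, geographically-mediated transmission, two comparable trait
#' systems measured over the same groups should show similar levels of
#' between-group diversity. A trait system whose intergroup distances are
#' significantly *lower* than a neutrally-patterned reference is a candidate
#' for purifying (negative) selection — some bias is suppressing variants;
#' significantly *higher* distances suggest diversifying (positive)
#' selection. The contrast is run on the paired off-diagonal distance
#' vectors with three conservative nonparametric tests.
#'
#' Caveat (applies to every run): the paired entries are matrix cells, not
#' independent observations — each group contributes to n-1 pairs — so these
#' tests are heuristic screens for a diversity discrepancy, not standalone
#' evidence of selection.
#'
#' @name selection_tests
NULL

new_rank_test_result <- function(method, statistic, p, n_rand, seed,
                                 n_pairs_used) {
  structure(
    list(method = method, statistic = statistic, p_value = p,
         n_randomizations = n_rand, seed = seed,
         n_pairs_used = n_pairs_used),
    class = "rank_test_result"
  )
}

#' @export
print.rank_test_result <- function(x, ...) {
  cat(x$method, ": statistic = ", format(x$statistic), ", p = ",
      format(signif(x$p_value, 3)), " (", x$n_pairs_used, " pairs",
      if (x$n_randomizations > 0) paste0(", ", x$n_randomizations,
                                         " randomizations"),
      ")\n", sep = "")
  invisible(x)
}

#' Wilcoxon signed-rank test with Monte Carlo randomization
#'
#' Paired test on `d = x - y`. Zero differences are dropped; the absolute
#' differences receive midranks; the statistic `W` is the rank sum over
#' positive differences. The null is built by `n_rand` random sign flips of
#' the differences (each equally likely under exchangeability within pairs);
#' two-sided extremeness is distance of W from its null mean m(m+1)/4, with
#' the +1/+1 p-value convention.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param n_rand Monte Carlo randomizations (default 99999).
#' @param seed integer seed; `NULL` draws one.
#' @return a `rank_test_result` (method `"wilcoxon_signed_mc"`). All pairs
#'   tied gives a degenerate result with `p = 1` and a warning.
#' @export
wilcoxon_signed_mc <- function(x, y, n_rand = 99999, seed = NULL) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warning("all paired differences are zero; test is degenerate")
    return(new_rank_test_result("wilcoxon_signed_mc", 0, 1, 0, NULL, 0))
  }
  r <- rank(abs(d))            # midranks for tied |d|
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4        # null mean of W under random signs
  seed <- resolve_seed(seed)
  null_W <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(k) {
      sum(r[stats::runif(m) < 0.5])
    }, numeric(1))
  })
  extreme <- sum(abs(null_W - mu) >= abs(W - mu) - 1e-9)
  p <- (1 + extreme) / (n_rand + 1)
  new_rank_test_result("wilcoxon_signed_mc", W, p, n_rand, seed, m)
}

#' Exact null enumeration for the signed-rank statistic
#'
#' Enumerates all 2^m sign assignments (m <= 20) and returns the exact
#' two-sided p for the observed W. Used as the oracle for
#' [wilcoxon_signed_mc()].
#'
#' @inheritParams wilcoxon_signed_mc
#' @return a `rank_test_result` with `n_randomizations = 0`.
#' @export
wilcoxon_signed_exact <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  d <- (x - y)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    warning("all paired differences are zero; test is degenerate")
    return(new_rank_test_result("wilcoxon_signed_exact", 0, 1, 0, NULL, 0))
  }
  if (m > 20) stop("2^", m, " sign patterns is too many; use the MC test")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- m * (m + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  null_W <- as.vector(signs %*% r)
  p <- mean(abs(null_W - mu) >= abs(W - mu) - 1e-9)
  new_rank_test_result("wilcoxon_signed_exact", W, p, 0, NULL, m)
}

#' Exact sign test for paired observations
#'
#' Statistic: the count of pairs with `x > y` among the m non-tied pairs.
#' p: exact two-sided binomial(m, 1/2) — twice the smaller tail, capped at 1.
#'
#' @param x,y paired numeric vectors of equal length.
#' @return a `rank_test_result` (method `"sign_exact"`,
#'   `n_randomizations = 0`).
#' @export
sign_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 1) stop("need at least 1 pair")
  gt <- sum(x > y)
  lt <- sum(x < y)
  m <- gt + lt
  if (m == 0) {
    warning("all pairs tied; sign test is degenerate")
    return(new_rank_test_result("sign_exact", 0, 1, 0, NULL, 0))
  }
  p <- min(1, 2 * min(stats::pbinom(gt, m, 0.5),
                      stats::pbinom(gt - 1, m, 0.5, lower.tail = FALSE)))
  new_rank_test_result("sign_exact", gt, p, 0, NULL, m)
}

#' Mann-Whitney U test with Monte Carlo randomization
#'
#' Two-sample rank test on the pooled values (midranks for ties). The
#' reported statistic is `U = min(U_x, U_y)`, so its null mean is
#' below `n_x n_y / 2` and small values are extreme in either direction;
#' the two tails are folded by the min. The null is built by `n_rand`
#' random reassignments of the pooled values to the two group sizes;
#' `p = (1 + #{U_null <= U_obs}) / (n_rand + 1)`.
#'
#' @param x,y numeric samples (not paired; sizes may differ).
#' @param n_rand Monte Carlo randomizations (default 10000).
#' @param seed integer seed; `NULL` draws one.
#' @return a `rank_test_result` (method `"mann_whitney_mc"`).
#' @export
mann_whitney_mc <- function(x, y, n_rand = 10000, seed = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  rk <- rank(pooled)           # midranks; fixed under reassignment
  u_min <- function(ord) {
    # ord: logical, TRUE = belongs to sample x
    ux <- sum(rk[ord]) - nx * (nx + 1) / 2
    min(ux, nx * ny - ux)
  }
  in_x <- c(rep(TRUE, nx), rep(FALSE, ny))
  U <- u_min(in_x)
  seed <- resolve_seed(seed)
  null_U <- withr::with_seed(seed, {
    vapply(seq_len(n_rand), function(k) {
      u_min(sample(in_x))
    }, numeric(1))
  })
  p <- (1 + sum(null_U <= U + 1e-9)) / (n_rand + 1)
  new_rank_test_result("mann_whitney_mc", U, p, n_rand, seed, nx + ny)
}

#' Diversity-contrast selection test on two distance matrices
#'
#' Runs the full battery — Monte Carlo Wilcoxon signed ranks, exact sign
#' test, Monte Carlo Mann-Whitney — on the paired off-diagonal distance
#' vectors of a focal and a reference matrix over the same groups, and
#' classifies the direction of selection. The default decision rule is
#' unanimity: all three tests significant at `alpha` *and* a consistent
#' direction of the mean contrast; otherwise `"not_detected"`.
#'
#' @param focal,reference distance-polarity `pairwise_matrix` objects over
#'   identical labels. `focal` is the trait system under scrutiny;
#'   `reference` the system taken to follow the neutral pattern.
#' @param alpha significance level (default 0.05).
#' @param n_rand_wilcoxon,n_rand_mw Monte Carlo randomization counts
#'   (defaults 99999 and 10000).
#' @param seed integer seed; sub-test seeds are derived from it.
#' @param rule `"all"` (unanimity, default), `"majority"`, or `"any"`.
#' @return an object of class `selection_verdict`: the three
#'   `rank_test_result`s, focal/reference means and medians, the call
#'   (`"purifying"`, `"diversifying"`, `"not_detected"`), and `alpha`.
#' @export
diversity_selection_test <- function(focal, reference, alpha = 0.05,
                                     n_rand_wilcoxon = 99999,
                                     n_rand_mw = 10000, seed = NULL,
                                     rule = c("all", "majority", "any")) {
  rule <- match.arg(rule)
  stopifnot(inherits(focal, "pairwise_matrix"),
            inherits(reference, "pairwise_matrix"))
  if (focal$polarity != "distance" || reference$polarity != "distance") {
    stop("selection test requires distance polarity for both matrices; ",
         "convert explicitly with convert_polarity()")
  }
  check_same_labels(focal, reference)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  seed <- resolve_seed(seed)
  x <- offdiag_vector(focal)
  y <- offdiag_vector(reference)
  tests <- list(
    wilcoxon = wilcoxon_signed_mc(x, y, n_rand = n_rand_wilcoxon,
                                  seed = seed),
    sign = sign_test(x, y),
    mann_whitney = mann_whitney_mc(x, y, n_rand = n_rand_mw,
                                   seed = seed + 1L)
  )
  sig <- vapply(tests, function(t) t$p_value < alpha, logical(1))
  n_sig <- sum(sig)
  decided <- switch(rule,
                    all = n_sig == length(tests),
                    majority = n_sig > length(tests) / 2,
                    any = n_sig >= 1)
  fm <- mean(x); rm_ <- mean(y)
  call <- if (!decided || fm == rm_) {
    "not_detected"
  } else if (fm < rm_) {
    "purifying"
  } else {
    "diversifying"
  }
  message("note: paired intergroup distances are not independent ",
          "observations (matrix structure); treat this contrast as a ",
          "screen, not standalone evidence of selection")
  structure(
    list(tests = tests,
         focal_mean = fm, focal_median = stats::median(x),
         reference_mean = rm_, reference_median = stats::median(y),
         call = call, alpha = alpha, rule = rule, seed = seed,
         n_pairs = length(x)),
    class = "selection_verdict"
  )
}

#' @export
print.selection_verdict <- function(x, ...) {
  cat("diversity-contrast selection test (", x$n_pairs, " pairs, alpha = ",
      x$alpha, ", rule = ", x$rule, ")\n", sep = "")
  for (t in x$tests) print(t)
  cat("focal:     mean = ", format(round(x$focal_mean, 4)),
      ", median = ", format(round(x$focal_median, 4)), "\n", sep = "")
  cat("reference: mean = ", format(round(x$reference_mean, 4)),
      ", median = ", format(round(x$reference_median, 4)), "\n", sep = "")
  cat("call: ", x$call, "\n", sep = "")
  invisible(x)
}
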