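# Information-theoretic scoring of two sample partitions: mutual information,
# its normalized and chance-adjusted forms, conditional variants, the expected
# MI under the generalized hypergeometric permutation model, and permutation
# significance. All information quantities are in nats; the normalized scores
# (NMI, AMI) are base-invariant.

as_codes <- function(labels) {
  as.integer(factor(labels))
}

entropy_from_counts <- function(a, n) {
  a <- a[a > 0]
  if (n == 0L) return(0)
  p <- a / n
  -sum(p * log(p))
}

#' Contingency table of two aligned partitions
#'
#' @param x,y partition vectors over the same samples in the same order.
#' @return an integer matrix of joint counts, rows indexed by the distinct
#'   labels of `x` and columns by those of `y`.
#' @export
contingency <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("partitions differ in length (%d vs %d)", length(x), length(y)))
  }
  if (length(x) == 0L) stop("empty partitions")
  as.matrix(table(x = x, y = y))
}

#' Mutual information of a contingency table
#'
#' \deqn{MI = \sum_{ij} \frac{n_{ij}}{n}
#'   \ln\frac{n \, n_{ij}}{a_i b_j}}
#' with the convention \eqn{0 \ln 0 = 0}; equals
#' \eqn{H(X) + H(Y) - H(X,Y)} evaluated on the same table.
#'
#' @param counts contingency matrix of non-negative integer counts.
#' @return mutual information in nats (non-negative).
#' @export
mutual_information <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  if (n < 1) stop("contingency table must contain at least one sample")
  a <- rowSums(counts)
  b <- colSums(counts)
  nz <- which(counts > 0)
  nij <- counts[nz]
  logab <- (log(a)[row(counts)[nz]]) + (log(b)[col(counts)[nz]])
  mi <- sum(nij / n * (log(n) + log(nij) - logab))
  max(mi, 0)
}

#' Expected mutual information under the hypergeometric permutation model
#'
#' Expectation of the MI of two partitions with fixed margins when the label
#' pairing is uniformly random, i.e. when each cell count follows the
#' generalized hypergeometric distribution induced by permuting one set of
#' labels. Computed cell-wise with log-factorials:
#' \deqn{E[MI] = \sum_{ij} \sum_{n_{ij}} \frac{n_{ij}}{n}
#'   \ln\frac{n\,n_{ij}}{a_i b_j} \; P_{hyp}(n_{ij};\, n, a_i, b_j)}
#' where the inner sum runs from \eqn{\max(a_i + b_j - n,\ 1)} (the zero-count
#' term contributes nothing) to \eqn{\min(a_i, b_j)}.
#'
#' @param row_margins,col_margins positive integer margins of the two
#'   partitions.
#' @param n total sample count; both margin vectors must sum to `n`.
#' @return expected MI in nats.
#' @export
expected_mi <- function(row_margins, col_margins, n) {
  a <- as.numeric(row_margins)
  b <- as.numeric(col_margins)
  if (sum(a) != n || sum(b) != n) {
    stop("margins must sum to the total sample count")
  }
  if (any(a < 0) || any(b < 0)) stop("margins must be non-negative")
  a <- a[a > 0]
  b <- b[b > 0]
  emi <- 0
  lfact_n <- lgamma(n + 1)
  for (ai in a) {
    for (bj in b) {
      lo <- max(ai + bj - n, 1)
      hi <- min(ai, bj)
      nij <- lo:hi
      logp <- lgamma(ai + 1) + lgamma(bj + 1) +
        lgamma(n - ai + 1) + lgamma(n - bj + 1) -
        lfact_n - lgamma(nij + 1) - lgamma(ai - nij + 1) -
        lgamma(bj - nij + 1) - lgamma(n - ai - bj + nij + 1)
      emi <- emi + sum((nij / n) * (log(n) + log(nij) - log(ai) - log(bj)) *
                         exp(logp))
    }
  }
  emi
}

score_from_tables <- function(mi, emi, hx, hy, n_x, n_y) {
  max_mi <- (hx + hy) / 2
  denom <- max_mi - emi
  ami <- if (abs(denom) < 1e-12) 0 else (mi - emi) / denom
  nmi <- if (max_mi < 1e-12) 0 else min(mi / max_mi, 1)
  list(mi = mi, nmi = nmi, ami = ami, expected_mi = emi, max_mi = max_mi,
       n_modules_x = n_x, n_modules_y = n_y)
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected association between two partitions of the same samples:
#' \deqn{AMI = \frac{MI - E[MI]}{maxMI - E[MI]}, \qquad
#'   maxMI = \tfrac12 (H(X) + H(Y))}
#' with \eqn{E[MI]} from [expected_mi()]. AMI is 1 when the partitions are
#' identical up to relabelling, 0 in expectation for independent random
#' partitions, and can take small negative values. When the denominator is 0
#' (both partitions constant) no association is detectable and the score is
#' defined as 0. The normalized score \eqn{NMI = MI / maxMI} is also
#' reported.
#'
#' @param x,y partition vectors over the same samples in the same order.
#' @return a list with `mi`, `nmi`, `ami`, `expected_mi`, `max_mi` (all in
#'   nats where dimensioned), `n_modules_x`, `n_modules_y`.
#' @examples
#' ami(c(0, 0, 1, 1), c("a", "a", "b", "b"))$ami # identical partitions: 1
#' @export
ami <- function(x, y) {
  counts <- contingency(x, y)
  n <- sum(counts)
  a <- rowSums(counts)
  b <- colSums(counts)
  score_from_tables(
    mi = mutual_information(counts),
    emi = expected_mi(a, b, n),
    hx = entropy_from_counts(a, n),
    hy = entropy_from_counts(b, n),
    n_x = nrow(counts),
    n_y = ncol(counts)
  )
}

#' Conditional adjusted mutual information given a confounder
#'
#' Stratifies both partitions on a third discrete variable `z` and combines
#' the within-stratum quantities with weights \eqn{p(z)}:
#' \eqn{MI(X,Y|Z) = \sum_z p(z) MI_z}, likewise for the expected MI (each
#' stratum's hypergeometric expectation from its own margins) and
#' \eqn{maxMI(X,Y|Z) = \tfrac12 (H(X|Z) + H(Y|Z))}. The adjusted score is
#' then formed exactly as in [ami()]. Association that is explained by `z`
#' is removed; with a constant `z` the result equals `ami(x, y)`. Strata of
#' size 1 contribute zero to every term.
#'
#' @param x,y partition vectors over the same samples in the same order.
#' @param z confounder partition over the same samples; every stratum must be
#'   non-empty.
#' @return a list as in [ami()], with the conditional quantities.
#' @export
conditional_ami <- function(x, y, z) {
  if (length(z) != length(x) || length(x) != length(y)) {
    stop("x, y and z must cover the same samples")
  }
  n <- length(x)
  strata <- split(seq_len(n), z)
  mi_c <- emi_c <- hx_c <- hy_c <- 0
  for (idx in strata) {
    nz <- length(idx)
    if (nz == 0L) stop("empty confounder stratum")
    if (nz == 1L) next
    pz <- nz / n
    counts <- contingency(x[idx], y[idx])
    a <- rowSums(counts)
    b <- colSums(counts)
    mi_c <- mi_c + pz * mutual_information(counts)
    emi_c <- emi_c + pz * expected_mi(a, b, nz)
    hx_c <- hx_c + pz * entropy_from_counts(a, nz)
    hy_c <- hy_c + pz * entropy_from_counts(b, nz)
  }
  score_from_tables(mi_c, emi_c, hx_c, hy_c,
                    n_x = length(unique(x)), n_y = length(unique(y)))
}

# Fast MI of fixed x-codes against permuted y-codes via joint tabulation.
# Returns a closure precomputing everything that is invariant under
# permutation of y (margins, hence also log-margins).
mi_evaluator <- function(xc, R, C, n) {
  force(xc); force(R); force(C); force(n)
  base <- (xc - 1L) * C
  logn <- log(n)
  function(yc, logab) {
    tab <- tabulate(base + yc, nbins = R * C)
    nz <- which(tab > 0L)
    sum(tab[nz] / n * (logn + log(tab[nz]) - logab[nz]))
  }
}

#' Permutation test of the module-phenotype association
#'
#' Holds the module partition `x` fixed, permutes the phenotype labels `y`
#' uniformly at random `n_perm` times (within the strata of `conditional_on`
#' when given), and recomputes the (conditional) AMI each time. Because the
#' margins are invariant under permutation, the expected MI and the
#' normalizer are computed once. The empirical p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{AMI_{null} \ge AMI_{obs}\}) / (1 + B)}, which
#' never returns 0.
#'
#' @param x module partition (held fixed).
#' @param y phenotype partition (permuted).
#' @param n_perm number of permutations (at least 1).
#' @param seed integer seed.
#' @param conditional_on optional confounder partition; permutations are then
#'   performed within its strata and the score is [conditional_ami()].
#' @return a list with `p_value`, `observed` (the observed score list), and
#'   `null_scores` (numeric vector of null AMI values).
#' @export
permutation_test <- function(x, y, n_perm, seed = 1L, conditional_on = NULL) {
  if (!is_count(n_perm, min = 1L)) stop("n_perm must be a positive integer")
  n <- length(x)
  if (is.null(conditional_on)) {
    observed <- ami(x, y)
    counts <- contingency(x, y)
    a <- rowSums(counts)
    b <- colSums(counts)
    xc <- as_codes(x)
    yc <- as_codes(y)
    R <- length(a)
    C <- length(b)
    logab <- as.vector(t(outer(log(a), log(b), "+"))) # (i-1)*C + j layout
    eval_mi <- mi_evaluator(xc, R, C, n)
    null_mi <- with_seed(seed, {
      vapply(seq_len(n_perm), function(p) {
        eval_mi(yc[sample.int(n)], logab)
      }, numeric(1L))
    })
    denom <- observed$max_mi - observed$expected_mi
    null_scores <- if (abs(denom) < 1e-12) {
      rep(0, n_perm)
    } else {
      (null_mi - observed$expected_mi) / denom
    }
  } else {
    if (length(conditional_on) != n) stop("conditional_on must cover the same samples")
    observed <- conditional_ami(x, y, conditional_on)
    strata <- split(seq_len(n), conditional_on)
    strata <- strata[lengths(strata) > 1L]
    parts <- lapply(strata, function(idx) {
      counts <- contingency(x[idx], y[idx])
      a <- rowSums(counts)
      b <- colSums(counts)
      list(
        idx = idx, nz = length(idx), pz = length(idx) / n,
        yc = as_codes(y[idx]),
        logab = as.vector(t(outer(log(a), log(b), "+"))),
        eval_mi = mi_evaluator(as_codes(x[idx]), length(a), length(b),
                               length(idx))
      )
    })
    null_mi <- with_seed(seed, {
      vapply(seq_len(n_perm), function(p) {
        s <- 0
        for (st in parts) {
          s <- s + st$pz * st$eval_mi(st$yc[sample.int(st$nz)], st$logab)
        }
        s
      }, numeric(1L))
    })
    denom <- observed$max_mi - observed$expected_mi
    null_scores <- if (abs(denom) < 1e-12) {
      rep(0, n_perm)
    } else {
      (null_mi - observed$expected_mi) / denom
    }
  }
  p <- (1 + sum(null_scores >= observed$ami - 1e-12)) / (1 + n_perm)
  list(p_value = p, observed = observed, null_scores = null_scores)
}

# All distinct orderings of a label multiset with class counts `b`,
# lexicographically, as an m x n integer matrix of class codes.
multiset_orderings <- function(b) {
  n <- sum(b)
  m <- round(exp(lgamma(n + 1) - sum(lgamma(b + 1))))
  if (m > 5e5) {
    stop("too many orderings to enumerate; use permutation_test() instead")
  }
  out <- matrix(0L, nrow = m, ncol = n)
  cur <- rep(seq_along(b), b) # sorted = lexicographically first
  for (r in seq_len(m)) {
    out[r, ] <- cur
    # next lexicographic permutation
    i <- n - 1L
    while (i >= 1L && cur[i] >= cur[i + 1L]) i <- i - 1L
    if (i < 1L) break
    j <- n
    while (cur[j] <= cur[i]) j <- j - 1L
    tmp <- cur[i]; cur[i] <- cur[j]; cur[j] <- tmp
    cur[(i + 1L):n] <- rev(cur[(i + 1L):n])
  }
  out
}

#' Exhaustive permutation moments of mutual information
#'
#' Mean and population variance of the MI between two partitions with the
#' given margins, over all `n!` pairings of the labels (equivalently, over
#' all distinct orderings of the second label vector, which are
#' equiprobable). Exact but exponential: intended as a small-`n` oracle for
#' [expected_mi()] and as the exhaustive route to `Var(MI)`; larger problems
#' should use [permutation_test()].
#'
#' @param row_margins,col_margins positive integer margins.
#' @param n total count; margins must sum to `n`.
#' @param max_n refuse enumeration above this total (default 10).
#' @return a list with `mean`, `variance`, and the per-ordering `values`.
#' @export
mi_permutation_moments <- function(row_margins, col_margins, n, max_n = 10L) {
  a <- as.integer(row_margins)
  b <- as.integer(col_margins)
  if (sum(a) != n || sum(b) != n) stop("margins must sum to the total sample count")
  if (n > max_n) {
    stop("n exceeds the exhaustive-enumeration limit; use permutation_test()")
  }
  a <- a[a > 0]
  b <- b[b > 0]
  x <- rep(seq_along(a), a)
  orderings <- multiset_orderings(b)
  m <- nrow(orderings)
  mi <- numeric(m)
  for (i in seq_along(a)) {
    cols <- orderings[, x == i, drop = FALSE]
    for (j in seq_along(b)) {
      nij <- rowSums(cols == j)
      pos <- nij > 0
      mi[pos] <- mi[pos] +
        nij[pos] / n * (log(n) + log(nij[pos]) - log(a[i]) - log(b[j]))
    }
  }
  list(mean = mean(mi), variance = mean(mi^2) - mean(mi)^2, values = mi)
}

#' Exhaustive variance of mutual information under permutation
#'
#' `Var(MI) = E[MI^2] - E[MI]^2` over all label pairings with fixed margins,
#' by exhaustive enumeration. The analytic route through the hypergeometric
#' model involves large sums of tiny terms and is numerically fragile, so
#' this function is an exact small-`n` testing oracle, not a production
#' path; production significance comes from [permutation_test()].
#'
#' @inheritParams mi_permutation_moments
#' @return the population variance of MI (non-negative).
#' @export
mi_variance <- function(row_margins, col_margins, n, max_n = 10L) {
  mi_permutation_moments(row_margins, col_margins, n, max_n)$variance
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion \eqn{\pi_0}
#' estimated from the p-value distribution: a natural-spline smooth of
#' \eqn{\pi_0(\lambda) = \#\{p > \lambda\} / (m (1 - \lambda))} over the
#' grid \eqn{\lambda = 0.05, 0.10, \ldots, 0.95}, evaluated at the largest
#' \eqn{\lambda}. With fewer than 100 p-values the point estimate at
#' \eqn{\lambda = 0.5} is used instead. \eqn{\pi_0} is clipped to (0, 1].
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @param pi0 optional fixed null proportion overriding the estimate.
#' @return q-values in the order of the input, clipped to [0, 1] and
#'   monotone non-decreasing in p.
#' @export
qvalues <- function(p_values, pi0 = NULL) {
  p <- p_values
  m <- length(p)
  if (m == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE) || anyNA(p)) {
    stop("p-values must lie in [0, 1]")
  }
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- mean(p > 0.5) / 0.5
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) mean(p > l) / (1 - l), numeric(1L))
      fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(fit, x = max(lambda))$y
    }
  }
  pi0 <- min(max(pi0, .Machine$double.eps), 1)
  o <- order(p, decreasing = TRUE)
  q <- pi0 * m * p[o] / seq(m, 1)
  q <- pmin(1, cummin(q))
  q[order(o)]
}
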