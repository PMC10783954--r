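# Independent brute-force oracles used across the test files. These stay
# deliberately naive (quadratic scans, explicit set operations, exhaustive
# enumeration) so that they share no code path with the implementation.

# O(n^2) exact kNN: full distance matrix, ties broken by smallest index.
brute_knn <- function(points, k) {
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  rows <- lapply(seq_len(n), function(i) {
    ord <- order(d2[i, ], seq_len(n))
    setdiff(ord, i)[seq_len(k)]
  })
  matrix(unlist(rows), nrow = n, ncol = k, byrow = TRUE)
}

# Shared-neighbour counts by explicit set intersection.
brute_snn_counts <- function(idx) {
  n <- nrow(idx)
  k <- ncol(idx)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    for (t in seq_len(k)) {
      out[i, t] <- length(intersect(idx[i, ], idx[idx[i, t], ]))
    }
  }
  out
}

# Shared-neighbour counts through the adjacency-product identity B = A %*% t(A).
matrix_snn_counts <- function(idx) {
  n <- nrow(idx)
  k <- ncol(idx)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                            x = 1, dims = c(n, n))
  B <- as.matrix(Matrix::tcrossprod(A))
  matrix(B[cbind(rep(seq_len(n), k), as.vector(idx))], n, k)
}

# All set partitions of 1..n (Bell-number many), as lists of integer labels.
all_partitions <- function(n) {
  if (n == 1L) return(list(1L))
  smaller <- all_partitions(n - 1L)
  out <- list()
  for (p in smaller) {
    for (g in seq_len(max(p) + 1L)) {
      out[[length(out) + 1L]] <- c(p, g)
    }
  }
  out
}

# All n! permutations of 1..n (for tiny n).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Rand index between two partitions.
rand_index <- function(x, y) {
  n <- length(x)
  same_x <- outer(x, x, "==")
  same_y <- outer(y, y, "==")
  ut <- upper.tri(same_x)
  mean(same_x[ut] == same_y[ut])
}

# Random strictly-valid kNN adjacency (out-degree k, no self-loops).
random_adjacency <- function(n, k) {
  rows <- lapply(seq_len(n), function(i) sample(setdiff(seq_len(n), i), k))
  matrix(unlist(rows), nrow = n, ncol = k, byrow = TRUE)
}
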