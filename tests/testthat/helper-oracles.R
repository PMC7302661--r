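# Independent oracles used to certify the optimizers. These deliberately
# share no code with the package's network-flow / blossom paths.

# exact minimum-cost assignment of m template rows to distinct pool
# columns, by dynamic programming over pool subsets (m <= n <= ~16)
dp_min_assignment <- function(C) {
  m <- nrow(C); n <- ncol(C)
  stopifnot(m <= n, n <= 20)
  full <- bitwShiftL(1L, n) - 1L
  INF <- Inf
  f <- rep(INF, full + 1L)
  f[1L] <- 0
  popcount <- vapply(0:full, function(x) sum(bitwAnd(x, bitwShiftL(1L, 0:(n - 1))) > 0), 1L)
  for (mask in (0:full)[order(popcount)]) {
    i <- popcount[mask + 1L] # template row being assigned next is i+1
    if (i >= m || !is.finite(f[mask + 1L])) next
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(mask, bit) == 0) {
        nm <- bitwOr(mask, bit)
        v <- f[mask + 1L] + C[i + 1L, j]
        if (v < f[nm + 1L]) f[nm + 1L] <- v
      }
    }
  }
  min(f[popcount == m])
}

# all perfect pairings of 1..n (n even); returns list of 2-column matrices
all_pairings <- function(n) {
  if (n == 0) return(list(matrix(integer(0), 0, 2)))
  rest <- 2:n
  out <- list()
  for (j in rest) {
    sub <- setdiff(rest, j)
    for (p in all_pairings_of(sub))
      out[[length(out) + 1L]] <- rbind(c(1L, j), p)
  }
  out
}
all_pairings_of <- function(v) {
  n <- length(v)
  if (n == 0) return(list(matrix(integer(0), 0, 2)))
  out <- list()
  for (j in 2:n) {
    sub <- v[-c(1, j)]
    for (p in all_pairings_of(sub))
      out[[length(out) + 1L]] <- rbind(c(v[1], v[j]), p)
  }
  out
}

pairing_weight <- function(D, pairing) sum(D[pairing])

# exact min-weight perfect matching by enumeration (n <= 12)
enum_min_matching <- function(D) {
  ps <- all_pairings(nrow(D))
  w <- vapply(ps, pairing_weight, 1, D = D)
  list(weight = min(w), pairing = ps[[which.min(w)]], all = ps,
       weights = w)
}

# greedy comparator: repeatedly pair the globally closest remaining pair
greedy_pairing <- function(D) {
  n <- nrow(D)
  left <- seq_len(n)
  out <- NULL
  while (length(left) > 0) {
    sub <- D[left, left, drop = FALSE]
    diag(sub) <- Inf
    ij <- arrayInd(which.min(sub), dim(sub))
    out <- rbind(out, c(left[ij[1]], left[ij[2]]))
    left <- left[-c(ij[1], ij[2])]
  }
  out
}

# cross-pair count of a pairing under group labels
cross_count <- function(pairing, grp) {
  sum(grp[pairing[, 1]] != grp[pairing[, 2]])
}
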