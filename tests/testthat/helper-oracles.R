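# Independent brute-force oracles. These deliberately share no code with
# the package: direct counting, explicit loops, textbook formulas.

# Average-tie rank of each element by pairwise counting.
bf_rank_column <- function(v) {
  vapply(seq_along(v), function(i) {
    sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
  }, numeric(1))
}

# Direct O(m^2 n l) delta rank matrix.
bf_drm_raw <- function(gem, gene_a, gene_b) {
  out <- matrix(NA_real_, length(gene_a), ncol(gem))
  for (cc in seq_len(ncol(gem))) {
    r <- bf_rank_column(gem[, cc])
    names(r) <- rownames(gem)
    for (e in seq_along(gene_a)) {
      out[e, cc] <- r[[gene_a[e]]] - r[[gene_b[e]]]
    }
  }
  rownames(out) <- paste(gene_a, gene_b, sep = "|")
  colnames(out) <- colnames(gem)
  out
}

# Step-up BH by its definition: q_(i) = min_{k >= i} p_(k) * n / k.
bf_bh <- function(p) {
  n <- length(p)
  ord <- order(p)
  q_sorted <- numeric(n)
  for (i in seq_len(n)) {
    q_sorted[i] <- min(p[ord][i:n] * n / (i:n))
  }
  pmin(1, q_sorted)[order(ord)]
}

# ARI from raw pair-concordance counts.
bf_ari <- function(a, b) {
  n <- length(a)
  s11 <- s10 <- s01 <- s00 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) s11 <- s11 + 1
      else if (sa) s10 <- s10 + 1
      else if (sb) s01 <- s01 + 1
      else s00 <- s00 + 1
    }
  }
  num <- 2 * (s11 * s00 - s10 * s01)
  den <- (s11 + s10) * (s10 + s00) + (s11 + s01) * (s01 + s00)
  if (den == 0) 1 else num / den
}

# NMI (arithmetic-mean normalization) from explicit probability loops.
bf_nmi <- function(a, b) {
  n <- length(a)
  ent <- function(x) {
    p <- as.numeric(table(x)) / n
    -sum(p * log(p))
  }
  mi <- 0
  for (u in unique(a)) {
    for (v in unique(b)) {
      pij <- sum(a == u & b == v) / n
      if (pij > 0)
        mi <- mi + pij * log(pij / (mean(a == u) * mean(b == v)))
    }
  }
  ha <- ent(a); hb <- ent(b)
  if (ha + hb == 0) 1 else 2 * mi / (ha + hb)
}

# All permutations of a vector.
all_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_orderings(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}

# All set partitions of n items as restricted-growth label vectors.
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxv) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(maxv + 1L)) rec(c(prefix, v), max(maxv, v))
  }
  rec(1L, 1L)
  out
}
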