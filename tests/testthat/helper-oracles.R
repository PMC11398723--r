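# Independent oracles and graph fixtures shared across test files.

# All set partitions of n items as membership vectors (restricted growth
# strings); Bell(8) = 4140, cheap enough to enumerate.
enumerate_partitions <- function(n) {
  out <- list()
  recurse <- function(prefix, max_used) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (v in seq_len(max_used + 1L)) {
      recurse(c(prefix, v), max(max_used, v))
    }
  }
  recurse(integer(0), 0L)
  out
}

# exhaustive maximum modularity over all partitions
max_q_enumeration <- function(W, gamma = 1) {
  parts <- enumerate_partitions(nrow(W))
  qs <- vapply(parts, function(p) modularity_q(W, p, gamma), numeric(1))
  list(Q = max(qs), partition = parts[[which.max(qs)]])
}

# weighted graph of k cliques (size m each, internal weight win), optionally
# bridged in a ring by weight wbridge
clique_graph <- function(k, m, win = 1, wbridge = 0) {
  n <- k * m
  W <- matrix(0, n, n)
  for (c in seq_len(k)) {
    idx <- ((c - 1) * m + 1):(c * m)
    W[idx, idx] <- win
  }
  diag(W) <- 0
  if (wbridge > 0 && k > 1) {
    for (c in seq_len(k)) {
      a <- (c - 1) * m + 1
      b <- (c %% k) * m + 2
      if (b > n) b <- 2
      W[a, b] <- W[b, a] <- wbridge
    }
  }
  W
}

# the <= 8-node fixture suite for oracle-equivalence checks
small_graph_suite <- function() {
  set.seed(404)
  rnd <- function(n, density = 0.6) {
    W <- matrix(0, n, n)
    up <- upper.tri(W)
    vals <- stats::runif(sum(up))
    vals[stats::runif(sum(up)) > density] <- 0
    W[up] <- vals
    W + t(W)
  }
  list(
    two_triangles = clique_graph(2, 3, win = 1, wbridge = 0.1),
    two_squares = clique_graph(2, 4, win = 1, wbridge = 0.2),
    four_pairs = clique_graph(4, 2, win = 1, wbridge = 0.15),
    random7 = rnd(7),
    random8 = rnd(8)
  )
}

# independent two-level map-equation evaluation (plain-sum formula)
codelength_direct <- function(W, membership) {
  tw <- sum(W)
  p <- rowSums(W) / tw
  mods <- unique(membership)
  q_m <- sapply(mods, function(mod) {
    idx <- membership == mod
    sum(W[idx, !idx]) / tw
  })
  q <- sum(q_m)
  H <- function(x) {
    x <- x[x > 0]
    -sum(x * log2(x))
  }
  idx_term <- if (q > 0) q * H(q_m / q) else 0
  mod_term <- 0
  for (j in seq_along(mods)) {
    inside <- p[membership == mods[j]]
    tot <- q_m[j] + sum(inside)
    if (tot > 0) mod_term <- mod_term + tot * H(c(q_m[j], inside) / tot)
  }
  idx_term + mod_term
}

# brute-force minimal error-sum-of-squares bipartition of points (rows)
min_ess_bipartition <- function(X) {
  n <- nrow(X)
  ess <- function(rows) {
    if (length(rows) < 2) return(0)
    sum(scale(X[rows, , drop = FALSE], scale = FALSE)^2)
  }
  best <- Inf
  best_split <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    grp <- c(1L, as.integer(intToBits(code))[seq_len(n - 1)] + 1L)
    e <- ess(which(grp == 1)) + ess(which(grp == 2))
    if (e < best) {
      best <- e
      best_split <- grp
    }
  }
  list(ess = best, split = best_split)
}
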