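# Graph community detection on RSFC matrices: gamma-generalised Louvain
# modularity with warm starts, two-level map-equation codelength and an
# Infomap-style greedy minimiser, and partition comparison by adjusted Rand
# index. Negative connectivity edges are thresholded at zero for both
# algorithms (random-walk semantics require nonnegative weights and the
# shared convention keeps the two algorithms comparable).

as_weight_matrix <- function(W, require_nonneg = FALSE) {
  if (inherits(W, "rsfc_matrix")) W <- W$z
  W <- as.matrix(W)
  if (nrow(W) != ncol(W)) stop("W must be square")
  if (any(abs(W - t(W)) > 1e-10)) stop("W must be symmetric")
  if (any(!is.finite(W))) stop("W must be finite")
  if (any(W < 0)) {
    W[W < 0] <- 0
  }
  W
}

relabel_contiguous <- function(m) {
  as.integer(factor(m, levels = unique(m)))
}

#' Modularity Q of a partition
#'
#' `Q = (1/l) * sum_ij (w_ij - gamma * k_i * k_j / l) * delta(m_i, m_j)`,
#' with `l` the total weight (sum over all ordered pairs), `k_i` the weighted
#' degree, and the resolution `gamma` multiplying the null (degree-expected)
#' term. With every node in one module and `gamma = 1`, Q is exactly 0.
#'
#' @param W Symmetric nonnegative weight matrix (zero diagonal; negative
#'   entries are thresholded to zero).
#' @param partition Integer module assignment per node, or a `partition`
#'   object.
#' @param gamma Resolution parameter.
#' @return Scalar Q.
#' @export
modularity_q <- function(W, partition, gamma = 1) {
  W <- as_weight_matrix(W)
  m <- if (inherits(partition, "partition")) partition$assignment else partition
  if (length(m) != nrow(W)) stop("partition length mismatch")
  l <- sum(W)
  if (l == 0) stop("empty graph")
  k <- rowSums(W)
  q <- 0
  for (mod in unique(m)) {
    idx <- which(m == mod)
    q <- q + sum(W[idx, idx]) - gamma * sum(k[idx])^2 / l
  }
  q / l
}

#' Louvain community detection with warm start
#'
#' Greedy two-phase Louvain maximising the gamma-generalised modularity,
#' starting from `init_labels` when given (otherwise singletons). Node sweep
#' order is shuffled by `seed`; greedy ties go to the lowest module id, so
#' the result is deterministic given the seed. The output Q never falls below
#' the Q of the initial assignment.
#'
#' @param W Symmetric weight matrix or `rsfc_matrix`; negative edges are
#'   thresholded to zero.
#' @param gamma Resolution parameter (1 default; 1.25, 1.5, and the
#'   supplementary 2, 2.5 are common choices).
#' @param init_labels Optional initial module assignment (e.g.
#'   [yeo7_init()]).
#' @param seed Integer seed for the sweep order.
#' @param n_restarts Number of seeded sweep-order restarts; the best-Q
#'   partition wins (greedy local moving can stall in shallow local optima
#'   on small graphs). Deterministic given `seed`.
#' @return A `partition`: `assignment` (contiguous ids from 1), `Q`,
#'   `gamma`, `method = "louvain"`, `seed`, `init_labels`.
#' @export
louvain <- function(W, gamma = 1, init_labels = NULL, seed = 1L,
                    n_restarts = 10L) {
  W0 <- as_weight_matrix(W)
  if (!is.null(init_labels) && length(init_labels) != nrow(W0)) {
    stop("init_labels length mismatch")
  }
  best <- NULL
  n <- nrow(W0)
  for (r in seq_len(n_restarts)) {
    seed_r <- as.integer(seed) + 7919L * (r - 1L)
    init_r <- init_labels
    if (is.null(init_labels) && r > 1L && r %% 2L == 0L) {
      # diversify every other restart with a seeded random coarse init
      set.seed(seed_r)
      init_r <- sample.int(max(2L, ceiling(n / 3)), n, replace = TRUE)
    }
    cand <- louvain_once(W0, gamma, init_r, seed = seed_r)
    if (is.null(best) || cand$Q > best$Q + 1e-14) best <- cand
  }
  best$init_labels <- init_labels
  best$seed <- as.integer(seed)
  best
}

louvain_once <- function(W, gamma, init_labels, seed) {
  n <- nrow(W)
  membership <- if (is.null(init_labels)) seq_len(n) else
    relabel_contiguous(init_labels)

  set.seed(as.integer(seed))
  Wl <- W               # current (aggregated) graph
  level_membership <- membership   # node -> community on current graph
  mapping <- seq_len(n)            # original node -> current graph node
  repeat {
    res <- louvain_local_move(Wl, level_membership, gamma)
    level_membership <- res$membership
    # write back to original nodes
    membership <- relabel_contiguous(level_membership[mapping])
    if (!res$moved) break
    # aggregate communities into super-nodes
    comm <- relabel_contiguous(level_membership)
    nc <- max(comm)
    if (nc == nrow(Wl)) break
    agg <- matrix(0, nc, nc)
    for (c1 in seq_len(nc)) {
      idx1 <- which(comm == c1)
      for (c2 in c1:nc) {
        v <- sum(Wl[idx1, comm == c2, drop = FALSE])
        agg[c1, c2] <- v
        agg[c2, c1] <- v
      }
    }
    mapping <- comm[mapping]
    Wl <- agg
    level_membership <- seq_len(nc)
  }
  structure(list(assignment = membership, Q = modularity_q(W, membership, gamma),
                 gamma = gamma, method = "louvain", seed = as.integer(seed),
                 init_labels = init_labels),
            class = "partition")
}

# one local-moving phase; W may carry self-loops on aggregated graphs.
# Convention: l = sum(W) over ordered pairs, k_i = rowSums(W); gain of
# putting node i into community c: k_{i,c\i} - gamma * k_i * tot_{c\i} / l.
louvain_local_move <- function(W, membership, gamma) {
  n <- nrow(W)
  l <- sum(W)
  k <- rowSums(W)
  m <- relabel_contiguous(membership)
  nc <- max(m)
  tot <- numeric(nc)
  tsum <- rowsum(k, m)
  tot[as.integer(rownames(tsum))] <- tsum
  moved_any <- FALSE
  repeat {
    moved <- FALSE
    for (i in sample.int(n)) {
      ci <- m[i]
      # links from i to each community (excluding the self-loop)
      li <- W[i, ]; li[i] <- 0
      k_ic <- numeric(nc)
      ksum <- rowsum(li, m)
      k_ic[as.integer(rownames(ksum))] <- ksum
      cand <- sort(unique(c(ci, which(k_ic > 0))))
      tot_no_i <- tot[cand] - ifelse(cand == ci, k[i], 0)
      gain <- k_ic[cand] - gamma * k[i] * tot_no_i / l
      best <- cand[which.max(gain)]     # which.max takes the first (lowest id)
      if (best != ci && gain[match(best, cand)] >
          gain[match(ci, cand)] + 1e-12) {
        tot[ci] <- tot[ci] - k[i]
        tot[best] <- tot[best] + k[i]
        m[i] <- best
        moved <- TRUE
        moved_any <- TRUE
      }
    }
    if (!moved) break
  }
  list(membership = m, moved = moved_any)
}

#' @export
print.partition <- function(x, ...) {
  cat("Partition (", x$method, "): ", max(x$assignment), " modules over ",
      length(x$assignment), " nodes; ",
      if (x$method == "louvain")
        paste0("Q = ", round(x$Q, 4), " (gamma = ", x$gamma, ")")
      else paste0("L = ", round(x$L, 4), " bits/step"),
      "\n", sep = "")
  invisible(x)
}

plogp <- function(p) {
  ifelse(p > 0, p * log2(p), 0)
}

#' Two-level map-equation codelength
#'
#' Average description length per step of a random walk on the weighted
#' graph under a two-level codebook:
#' `L = q * H(exit) + sum_m (p_m + q_m) * H(module m)`, with node visit
#' rates `p_i = k_i / sum(k)` and module exit rates from the stationary
#' walk. A single-module partition gives the entropy of the visit
#' distribution. Invariant to rescaling all edge weights.
#'
#' @param W Symmetric nonnegative weight matrix (negative entries
#'   thresholded at zero). Disconnected graphs are computed with a warning
#'   (the degree-proportional visit rates remain stationary per component).
#' @param partition Module assignment per node, or a `partition` object.
#' @return Codelength in bits per step.
#' @export
map_equation_codelength <- function(W, partition) {
  W <- as_weight_matrix(W)
  m <- if (inherits(partition, "partition")) partition$assignment else partition
  m <- relabel_contiguous(m)
  if (length(m) != nrow(W)) stop("partition length mismatch")
  if (is_disconnected(W)) {
    warning("graph is disconnected; codelength computed with ",
            "degree-proportional visit rates per component")
  }
  tw <- sum(W)
  if (tw == 0) stop("empty graph")
  p <- rowSums(W) / tw
  mods <- sort(unique(m))
  q_m <- vapply(mods, function(mod) {
    idx <- m == mod
    sum(W[idx, !idx]) / tw
  }, numeric(1))
  p_m <- vapply(mods, function(mod) sum(p[m == mod]), numeric(1))
  q <- sum(q_m)

  index_term <- if (q > 0) q * (-sum(plogp(q_m / q))) else 0
  module_term <- 0
  for (j in seq_along(mods)) {
    tot <- q_m[j] + p_m[j]
    if (tot <= 0) next
    probs <- c(q_m[j], p[m == mods[j]]) / tot
    module_term <- module_term + tot * (-sum(plogp(probs)))
  }
  index_term + module_term
}

is_disconnected <- function(W) {
  n <- nrow(W)
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    i <- queue[1]; queue <- queue[-1]
    nb <- which(W[i, ] > 0 & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  !all(seen)
}

#' Infomap-style partition by greedy codelength minimisation
#'
#' Louvain-style search minimising the two-level map-equation codelength:
#' seeded node sweeps move nodes between neighbouring modules while the
#' codelength decreases, followed by greedy module merges, repeated to
#' convergence. The output codelength never exceeds that of the all-singleton
#' or one-module partitions.
#'
#' @param W Symmetric weight matrix or `rsfc_matrix`; negative edges
#'   thresholded at zero.
#' @param seed Integer seed for the sweep order.
#' @return A `partition` with `method = "infomap"` and codelength `L`.
#' @export
infomap_partition <- function(W, seed = 1L) {
  W <- as_weight_matrix(W)
  n <- nrow(W)
  set.seed(as.integer(seed))
  m <- seq_len(n)
  L <- suppressWarnings(map_equation_codelength(W, m))
  repeat {
    improved <- FALSE
    # node-level moves
    repeat {
      moved <- FALSE
      for (i in sample.int(n)) {
        cand <- sort(unique(m[W[i, ] > 0 & seq_len(n) != i]))
        cand <- setdiff(cand, m[i])
        if (!length(cand)) next
        for (c2 in cand) {
          m2 <- m; m2[i] <- c2
          L2 <- suppressWarnings(map_equation_codelength(W, m2))
          if (L2 < L - 1e-12) {
            m <- m2; L <- L2; moved <- TRUE; improved <- TRUE
            break
          }
        }
      }
      if (!moved) break
    }
    # module-level merges
    repeat {
      mods <- sort(unique(m))
      if (length(mods) < 2) break
      best <- NULL
      for (a in seq_along(mods)) {
        for (b in seq_along(mods)) {
          if (b <= a) next
          ia <- m == mods[a]; ib <- m == mods[b]
          if (sum(W[ia, ib]) <= 0) next
          m2 <- m; m2[ib] <- mods[a]
          L2 <- suppressWarnings(map_equation_codelength(W, m2))
          if (L2 < L - 1e-12 && (is.null(best) || L2 < best$L)) {
            best <- list(m = m2, L = L2)
          }
        }
      }
      if (is.null(best)) break
      m <- best$m; L <- best$L; improved <- TRUE
    }
    if (!improved) break
  }
  # guard: never worse than the one-module partition
  L1 <- suppressWarnings(map_equation_codelength(W, rep(1L, n)))
  if (L1 < L - 1e-12) {
    m <- rep(1L, n); L <- L1
  }
  structure(list(assignment = relabel_contiguous(m), L = L,
                 method = "infomap", seed = as.integer(seed)),
            class = "partition")
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement of two module assignments over the same nodes;
#' 1 for identical partitions, about 0 for independent ones (exactly 0 for
#' the all-singletons vs one-module pair).
#'
#' @param a,b Assignments (integer vectors or `partition` objects).
#' @return ARI in `[-1, 1]`.
#' @export
compare_partitions <- function(a, b) {
  a <- if (inherits(a, "partition")) a$assignment else a
  b <- if (inherits(b, "partition")) b$assignment else b
  if (length(a) != length(b)) stop("partitions cover different node sets")
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  s_tab <- sum_comb(tab)
  s_a <- sum_comb(rowSums(tab))
  s_b <- sum_comb(colSums(tab))
  expected <- s_a * s_b / choose(n, 2)
  max_idx <- (s_a + s_b) / 2
  if (max_idx == expected) return(ifelse(s_tab == expected, 1, 0))
  (s_tab - expected) / (max_idx - expected)
}
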