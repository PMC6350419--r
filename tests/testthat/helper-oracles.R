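# Independent brute-force oracles used to verify the package's
# implementations. These deliberately share no code with the package: path
# measures come from exhaustive simple-path enumeration, eigenvector from
# power iteration, PageRank from a direct linear solve, and the statistics
# from closed-form summation.

# Exhaustive shortest-path oracle (link length = 1/weight). Enumerates all
# simple paths for every ordered pair; feasible for N <= 6.
oracle_path_measures <- function(W) {
  n <- nrow(W)
  len <- ifelse(W > 0, 1 / W, Inf)
  all_paths <- function(s, t) {
    res <- list()
    rec <- function(path, d) {
      v <- path[length(path)]
      if (v == t) {
        res[[length(res) + 1L]] <<- list(path = path, d = d)
        return(invisible())
      }
      for (u in seq_len(n)) {
        if (W[v, u] > 0 && !(u %in% path)) rec(c(path, u), d + len[v, u])
      }
    }
    rec(s, 0)
    res
  }
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  btw <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      ps <- all_paths(s, t)
      if (length(ps) == 0) next
      ds <- vapply(ps, `[[`, numeric(1), "d")
      dmin <- min(ds)
      D[s, t] <- dmin
      shortest <- ps[ds <= dmin + 1e-9]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        on_path <- vapply(shortest, function(p) v %in% p$path, logical(1))
        btw[v] <- btw[v] + mean(on_path)
      }
    }
  }
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  list(distances = D,
       closeness = rowSums(inv) / (n - 1),
       betweenness = if (n > 2) btw / ((n - 1) * (n - 2)) else numeric(n))
}

# Power-iteration oracle for the principal eigenvector (unit 2-norm,
# non-negative). A positive diagonal shift keeps the dominant eigenvalue
# strictly largest in magnitude (bipartite graphs otherwise oscillate
# between the +/- lambda eigenvectors); the shift leaves eigenvectors
# unchanged.
oracle_eigenvector <- function(W, iter = 100000, tol = 1e-14) {
  Ws <- W + diag(1 + max(rowSums(W)), nrow(W))
  v <- rep(1 / sqrt(nrow(W)), nrow(W))
  for (k in seq_len(iter)) {
    v2 <- as.vector(Ws %*% v)
    v2 <- v2 / sqrt(sum(v2^2))
    if (max(abs(v2 - v)) < tol) break
    v <- v2
  }
  abs(v2)
}

# Direct linear-system oracle for PageRank on graphs without zero-strength
# nodes: p = (1-d)/N + d * A p with A[i, j] = w_ij / k_j.
oracle_pagerank <- function(W, damping = 0.85) {
  n <- nrow(W)
  k <- colSums(W)
  A <- sweep(W, 2, k, "/")
  solve(diag(n) - damping * A, rep((1 - damping) / n, n))
}

# Brute-force elementwise strength.
oracle_strength <- function(W) {
  n <- nrow(W)
  out <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) out[i] <- out[i] + W[i, j]
  out
}

# ROC oracle: every threshold enumerated explicitly; AUC from the
# Mann-Whitney pair statistic (ties count 1/2).
oracle_roc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  auc <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  thr <- sort(unique(scores), decreasing = TRUE)
  best <- NULL
  for (t in c(Inf, thr)) {
    tpr <- mean(pos >= t)
    fpr <- mean(neg >= t)
    d2 <- fpr^2 + (1 - tpr)^2
    if (is.null(best) || d2 < best$d2 - 1e-12) {
      best <- list(d2 = d2, threshold = t, sensitivity = tpr,
                   specificity = 1 - fpr,
                   accuracy = (sum(pos >= t) + sum(neg < t)) / length(scores))
    }
  }
  list(auc = auc, optimal = best)
}

# Benjamini-Hochberg flags by the explicit step-up definition.
oracle_bh_flags <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  r_max <- 0L
  for (r in seq_len(m)) {
    if (p[ord[r]] <= r * q / m) r_max <- r
  }
  flags <- logical(m)
  if (r_max > 0) flags[ord[seq_len(r_max)]] <- TRUE
  flags
}

# Random connected symmetric weight matrix: spanning tree plus extra links,
# continuous weights (no ties).
rand_connected_W <- function(n, extra = n, wmin = 0.2, wmax = 3) {
  extra <- min(extra, n * (n - 1) / 2 - (n - 1))  # links left after the tree
  W <- matrix(0, n, n)
  perm <- sample(n)
  for (k in seq_len(n - 1)) {
    w <- runif(1, wmin, wmax)
    W[perm[k], perm[k + 1]] <- w
    W[perm[k + 1], perm[k]] <- w
  }
  added <- 0
  while (added < extra) {
    ij <- sample(n, 2)
    if (W[ij[1], ij[2]] == 0) {
      w <- runif(1, wmin, wmax)
      W[ij[1], ij[2]] <- w
      W[ij[2], ij[1]] <- w
      added <- added + 1
    }
  }
  W
}
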