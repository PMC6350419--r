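# Centrality feature construction.
#
# Each connectome is first rescaled to streamline fractions so that the
# weights of all unique undirected links sum to 1; the five weighted
# centrality measures (strength, betweenness, closeness, eigenvector,
# PageRank) are then computed on the rescaled matrix and z-scaled per
# measure block within the subject. On the default 82-region atlas this
# yields 410 features per subject.

MEASURE_ORDER <- c("strength", "betweenness", "closeness", "eigenvector",
                   "pagerank")

#' Rescale a matrix to streamline fractions
#'
#' Divides every weight by the total streamline count over unique undirected
#' links, so the unique-link weights sum to 1. This makes all downstream
#' centrality features invariant to a subject's total streamline count.
#'
#' @param W Symmetric non-negative matrix with zero diagonal.
#' @return The rescaled matrix.
#' @export
fraction_normalize <- function(W) {
  if (inherits(W, "connectome")) W <- W$W
  total <- sum(W) / 2
  if (total <= 0) stop("cannot fraction-normalize an all-zero matrix",
                       call. = FALSE)
  W / total
}

#' Node strength (weighted degree)
#'
#' @param W Symmetric weight matrix.
#' @return Per-region row sums.
#' @export
strength <- function(W) {
  if (inherits(W, "connectome")) W <- W$W
  rowSums(W)
}

# Build the igraph object used for path-based measures; edge weights carry
# the raw link weights, distances use length = 1/weight (stronger link =
# shorter path).
graph_from_W <- function(W) {
  igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                      weighted = TRUE, diag = FALSE)
}

#' Shortest-path centralities (closeness and betweenness)
#'
#' Path lengths use the weighted-connectivity convention `length = 1/w`.
#' Closeness is harmonic: the mean over other regions of the inverse
#' shortest-path distance (unreachable pairs contribute 0), which stays
#' defined on disconnected graphs. Betweenness is the fraction of shortest
#' paths passing through a region, summed over ordered source-target pairs
#' and normalized by `(N-1)(N-2)`.
#'
#' @param W Symmetric non-negative matrix.
#' @return List with numeric vectors `closeness` and `betweenness`.
#' @export
shortest_path_centralities <- function(W) {
  if (inherits(W, "connectome")) W <- W$W
  n <- nrow(W)
  g <- graph_from_W(W)
  if (igraph::ecount(g) == 0) {
    return(list(closeness = rep(0, n), betweenness = rep(0, n)))
  }
  len <- 1 / igraph::E(g)$weight
  D <- igraph::distances(g, weights = len)
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  closeness <- rowSums(inv) / (n - 1)
  btw <- igraph::betweenness(g, weights = len, directed = FALSE)
  betweenness <- if (n > 2) 2 * btw / ((n - 1) * (n - 2)) else rep(0, n)
  list(closeness = unname(closeness), betweenness = unname(betweenness))
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the weight matrix, sign-fixed to be
#' non-negative and scaled to unit Euclidean norm.
#'
#' @param W Symmetric non-negative matrix.
#' @return Per-region numeric vector.
#' @export
eigenvector_centrality <- function(W) {
  if (inherits(W, "connectome")) W <- W$W
  if (all(W == 0)) stop("eigenvector centrality undefined for a zero matrix",
                        call. = FALSE)
  e <- eigen(W, symmetric = TRUE)
  v <- e$vectors[, 1]
  # Perron-Frobenius: the principal eigenvector of a non-negative matrix can
  # be taken non-negative; abs() also covers disconnected graphs.
  v <- abs(v)
  v / sqrt(sum(v^2))
}

#' PageRank centrality
#'
#' Stationary distribution of the damped weighted random walk whose
#' transition probabilities are proportional to `w_ij / k_i`.
#'
#' @param W Symmetric non-negative matrix.
#' @param damping Damping factor in (0, 1); default 0.85.
#' @return Per-region probabilities summing to 1.
#' @export
pagerank_centrality <- function(W, damping = 0.85) {
  if (inherits(W, "connectome")) W <- W$W
  if (all(W == 0)) stop("PageRank undefined for a zero matrix", call. = FALSE)
  if (damping <= 0 || damping >= 1) stop("`damping` must be in (0, 1)",
                                         call. = FALSE)
  g <- graph_from_W(W)
  pr <- igraph::page_rank(g, damping = damping,
                          weights = igraph::E(g)$weight)$vector
  unname(pr)
}

# z-scale a block of values; a constant block maps to all zeros (keeps
# downstream learners defined).
zscale_block <- function(v) {
  s <- stats::sd(v)
  if (!is.finite(s) || s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Standardized centrality feature vector for one subject
#'
#' Computes the five centrality measures on the fraction-normalized matrix
#' and z-scales each measure block across regions within the subject.
#' Feature order is (strength, betweenness, closeness, eigenvector,
#' pagerank) x regions; length `5 * N` (410 on the default atlas).
#'
#' @param c A [connectome()] (or bare matrix).
#' @param region_labels Optional region labels used to name features.
#' @param damping PageRank damping factor.
#' @return Named numeric vector of length `5 * N`.
#' @export
subject_features <- function(c, region_labels = NULL, damping = 0.85) {
  W <- if (inherits(c, "connectome")) c$W else c
  Wp <- fraction_normalize(W)
  sp <- shortest_path_centralities(Wp)
  blocks <- list(
    strength = strength(Wp),
    betweenness = sp$betweenness,
    closeness = sp$closeness,
    eigenvector = eigenvector_centrality(Wp),
    pagerank = pagerank_centrality(Wp, damping = damping)
  )
  if (is.null(region_labels)) {
    region_labels <- sprintf("r%03d", seq_len(nrow(W)) - 1L)
  }
  out <- unlist(lapply(blocks[MEASURE_ORDER], zscale_block),
                use.names = FALSE)
  names(out) <- as.vector(t(outer(MEASURE_ORDER, region_labels, paste,
                                  sep = "_")))
  out
}

#' Stacked feature matrix for a two-cohort comparison
#'
#' Rows are subjects of `cohortA` (label 0) followed by `cohortB` (label 1);
#' columns are the standardized centrality features.
#'
#' @param cohortA,cohortB Cohorts sharing one atlas; `A` is coded 0
#'   (controls), `B` 1 (patients).
#' @param damping PageRank damping factor.
#' @return List of class `feature_matrix` with elements `X` (matrix), `y`
#'   (0/1 labels) and `feature_info` (tibble of measure / region label).
#' @export
cohort_feature_matrix <- function(cohortA, cohortB, damping = 0.85) {
  if (!identical(cohortA$region_table$label, cohortB$region_table$label)) {
    stop("cohorts must share the same region table", call. = FALSE)
  }
  labels <- cohortA$region_table$label
  feats <- function(ch) t(vapply(ch$subjects, subject_features,
                                 numeric(5L * length(labels)),
                                 region_labels = labels, damping = damping))
  XA <- feats(cohortA)
  XB <- feats(cohortB)
  X <- rbind(XA, XB)
  rownames(X) <- c(cohort_ids(cohortA), cohort_ids(cohortB))
  structure(
    list(X = X,
         y = c(rep(0L, nrow(XA)), rep(1L, nrow(XB))),
         feature_info = tibble::tibble(
           name = colnames(X),
           measure = rep(MEASURE_ORDER, each = length(labels)),
           region_label = rep(labels, times = 5L))),
    class = "feature_matrix")
}
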