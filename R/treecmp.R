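#' Read a tree topology from newick
#'
#' Parses a newick string or file with [ape::read.tree()], drops the rooting
#' (all metrics here are on unrooted topologies), and flags whether the
#' result is fully resolved. Branch lengths, if present, are carried but
#' ignored by every metric in this module.
#'
#' @param x A newick string or a path to a newick file.
#' @return An [ape::phylo] object (unrooted), with attribute `binary`.
#' @export
read_newick <- function(x) {
  tr <- tryCatch({
    if (length(x) == 1L && file.exists(x)) ape::read.tree(x)
    else ape::read.tree(text = x)
  }, error = function(e) NULL)
  if (is.null(tr) || !inherits(tr, "phylo")) {
    stop("format error: cannot parse newick input")
  }
  tr <- if (ape::Ntip(tr) > 2L) ape::unroot(tr) else tr
  attr(tr, "binary") <- ape::is.binary(tr)
  tr
}

# Topological (edge-count) leaf-to-leaf distances of an unrooted tree,
# rows/cols ordered by sorted leaf labels.
.topo_dists <- function(tree) {
  tree <- if (ape::Ntip(tree) > 2L) ape::unroot(tree) else tree
  tree$edge.length <- rep(1, nrow(tree$edge))
  n <- ape::Ntip(tree)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n)]
  ord <- order(tree$tip.label)
  d <- d[ord, ord]
  dimnames(d) <- list(tree$tip.label[ord], tree$tip.label[ord])
  d
}

.check_same_leaves <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label) ||
      ape::Ntip(t1) != ape::Ntip(t2)) {
    stop("leaf-set mismatch between trees")
  }
}

#' Path-difference metric (topology-only)
#'
#' For every unordered leaf pair, the topological path length (number of
#' edges) between the two leaves is computed in each unrooted tree; the
#' metric is the Euclidean norm of the vector of differences. Branch lengths
#' are ignored.
#'
#' @param t1,t2 `phylo` trees over the same leaf set.
#' @return Nonnegative numeric.
#' @examples
#' t1 <- read_newick("((a,b),(c,d));")
#' t2 <- read_newick("((a,c),(b,d));")
#' path_difference(t1, t2)  # 2 * sqrt(2)
#' @export
path_difference <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  d1 <- .topo_dists(t1)
  d2 <- .topo_dists(t2)
  sqrt(sum((d1 - d2)[upper.tri(d1)]^2))
}

#' Uniform random unrooted binary topology
#'
#' Random stepwise addition: starting from the unique 3-leaf topology, each
#' subsequent leaf is attached to an edge chosen uniformly at random. This
#' yields the uniform distribution over the (2n-5)!! labelled unrooted binary
#' topologies.
#'
#' @param n Number of leaves (>= 4).
#' @param labels Leaf labels (default `t1 ... tn`).
#' @return A `phylo` object.
#' @export
random_topology <- function(n, labels = paste0("t", seq_len(n))) {
  n <- as.integer(n)
  if (n < 4L) stop("need at least 4 leaves")
  if (length(labels) != n) stop("labels must have length n")
  # leaves 1..n, internal vertices n+1..(2n-2); start from the 3-leaf star
  edges <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L), ncol = 2,
                  byrow = TRUE)
  nxt <- n + 2L
  for (k in 4:n) {
    e <- sample.int(nrow(edges), 1L)
    a <- edges[e, 1]; b <- edges[e, 2]
    edges <- rbind(edges[-e, , drop = FALSE],
                   c(a, nxt), c(nxt, b), c(nxt, k))
    nxt <- nxt + 1L
  }
  .edges_to_phylo(edges, n, labels)
}

# Orient an undirected edge list away from root n+1 and build a phylo object
# (ape convention: tips 1..n, root n+1).
.edges_to_phylo <- function(edges, n, labels) {
  nv <- max(edges)
  adj <- vector("list", nv)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  out <- matrix(0L, nrow(edges), 2)
  seen <- logical(nv)
  queue <- n + 1L
  seen[n + 1L] <- TRUE
  k <- 0L
  while (length(queue) > 0) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        k <- k + 1L
        out[k, ] <- c(v, w)
        if (w > n) queue <- c(queue, w)
      }
    }
  }
  tr <- list(edge = out, tip.label = labels, Nnode = n - 2L)
  class(tr) <- "phylo"
  attr(tr, "order") <- NULL
  ape::reorder.phylo(tr, "cladewise")
}

#' Mean path difference between random topologies
#'
#' The normalizer of the NPD: the mean path difference over independent
#' uniform random pairs of unrooted binary topologies on `n` leaves.
#'
#' @param n Leaf count.
#' @param pairs Number of random pairs (the study-scale default is 10000).
#' @param seed Optional seed.
#' @return Positive numeric.
#' @export
pd_null_mean <- function(n, pairs = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  labs <- paste0("t", seq_len(n))
  mean(vapply(seq_len(pairs), function(i) {
    path_difference(random_topology(n, labs), random_topology(n, labs))
  }, 0))
}

#' Normalized path difference (NPD)
#'
#' The path difference between two trees divided by the mean path difference
#' of random pairs of unrooted binary topologies with the same number of
#' leaves. 0 means identical topologies; 1 means the pair is as different as
#' a random pair; values above 1 are possible.
#'
#' @param t1,t2 `phylo` trees over the same leaf set (n >= 4).
#' @param null_pairs Number of random pairs for the normalizer (default
#'   10000).
#' @param null_mean Precomputed normalizer from [pd_null_mean()]; when
#'   supplied, `null_pairs` is ignored (use this to amortize the null over
#'   many comparisons at the same leaf count).
#' @param seed Optional seed for the null draw.
#' @return Nonnegative numeric.
#' @export
npd <- function(t1, t2, null_pairs = 10000, null_mean = NULL, seed = NULL) {
  .check_same_leaves(t1, t2)
  n <- ape::Ntip(t1)
  if (n < 4L) stop("need at least 4 leaves")
  pd <- path_difference(t1, t2)
  if (pd == 0) return(0)
  if (is.null(null_mean)) null_mean <- pd_null_mean(n, null_pairs, seed = seed)
  pd / null_mean
}

#' Quartet distance (QD)
#'
#' The fraction of the `choose(n, 4)` leaf quartets whose induced unrooted
#' quartet topology differs between the two trees. Every quartet is scored:
#' the induced topology `ab|cd` is identified by the four-point condition on
#' topological leaf distances (`d(a,b) + d(c,d)` strictly smallest for the
#' true split in a binary tree). Non-binary trees are rejected.
#'
#' @param t1,t2 Binary `phylo` trees over the same leaf set (n >= 4).
#' @return Numeric in `[0, 1]`; 0 for identical topologies, 1 when no
#'   quartet subtree is shared.
#' @export
quartet_distance <- function(t1, t2) {
  .check_same_leaves(t1, t2)
  n <- ape::Ntip(t1)
  if (n < 4L) stop("need at least 4 leaves")
  for (t in list(t1, t2)) {
    tu <- if (ape::Ntip(t) > 2L) ape::unroot(t) else t
    if (!ape::is.binary(tu)) {
      stop("unsupported tree: quartet distance requires binary trees")
    }
  }
  d1 <- .topo_dists(t1)
  d2 <- .topo_dists(t2)
  q <- combn(n, 4)
  mean(.quartet_codes(d1, q) != .quartet_codes(d2, q))
}

# Vectorized quartet topology codes: 1 = ab|cd, 2 = ac|bd, 3 = ad|bc.
.quartet_codes <- function(d, q) {
  a <- q[1, ]; b <- q[2, ]; cc <- q[3, ]; dd <- q[4, ]
  s1 <- d[cbind(a, b)] + d[cbind(cc, dd)]
  s2 <- d[cbind(a, cc)] + d[cbind(b, dd)]
  s3 <- d[cbind(a, dd)] + d[cbind(b, cc)]
  (s1 < s2 & s1 < s3) * 1L + (s2 < s1 & s2 < s3) * 2L +
    (s3 < s1 & s3 < s2) * 3L
}
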