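# Independent brute-force oracles and shared fixtures. These deliberately
# recompute everything with explicit loops / different library routes than
# the package implementation.

nt <- c("A", "C", "G", "T")

# Worked 4x4 divergence matrix used across the symmetry-test checks
# (diagonal 10; upper AC=2, AG=3, AT=4, CG=6, CT=7, GT=1;
#  lower CA=5, GA=8, TA=2, GC=9, TC=3, TG=4).
worked_matrix <- function() {
  matrix(c(10, 2, 3, 4,
           5, 10, 6, 7,
           8, 9, 10, 1,
           2, 3, 4, 10),
         4, 4, byrow = TRUE, dimnames = list(nt, nt))
}

# Bowker statistic by direct summation over unordered state pairs.
oracle_bowker <- function(d) {
  m <- nrow(d); stat <- 0; f <- 0L
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    s <- d[i, j] + d[j, i]
    if (s > 0) {
      stat <- stat + (d[i, j] - d[j, i])^2 / s
      f <- f + 1L
    }
  }
  list(stat = stat, f = f, p = pchisq(stat, f, lower.tail = FALSE))
}

# Stuart statistic by explicit construction of u and V and a linear solve.
oracle_stuart <- function(d) {
  m <- nrow(d)
  r <- rowSums(d); cl <- colSums(d)
  k <- m - 1
  u <- numeric(k)
  V <- matrix(0, k, k)
  for (i in seq_len(k)) {
    u[i] <- r[i] - cl[i]
    for (j in seq_len(k)) {
      V[i, j] <- if (i == j) r[i] + cl[i] - 2 * d[i, i] else -(d[i, j] + d[j, i])
    }
  }
  x <- solve(V, u)
  list(u = u, stat = sum(u * x), df = k)
}

# Random divergence matrix with positive off-diagonal mass.
random_divmat <- function(m = 4, lambda = 8) {
  d <- matrix(rpois(m * m, lambda), m, m)
  dimnames(d) <- list(.states <- LETTERS[seq_len(m)], .states)
  d
}

# Induced quartet topology via ape::keep.tip pruning: returns the sibling of
# the first tip, identifying the split (independent route from the package's
# four-point computation).
oracle_quartet_topology <- function(tree, tips) {
  sub <- ape::unroot(ape::keep.tip(tree, tips))
  d <- ape::dist.nodes(ape::compute.brlen(sub, 1))[1:4, 1:4]
  rownames(d) <- colnames(d) <- sub$tip.label
  others <- setdiff(tips, tips[1])
  others[which.min(d[tips[1], others])]
}

oracle_quartet_distance <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  qs <- combn(tips, 4)
  diffs <- vapply(seq_len(ncol(qs)), function(k) {
    oracle_quartet_topology(t1, qs[, k]) != oracle_quartet_topology(t2, qs[, k])
  }, TRUE)
  mean(diffs)
}

write_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Small standard fixtures
fixture_fasta <- function() {
  write_tmp(c(">a", "ACGTACGTA", ">b", "ACGAACGTA", ">c", "ACTTACGGA"),
            ".fasta")
}

two_taxon_srh_config <- function(n_sites = 1000) {
  sim_config("(a:0.1,b:0.1);",
             root_frequencies = c(0.3, 0.2, 0.2, 0.3),
             exchangeabilities = c(1, 2, 1, 1, 2, 1),
             n_sites = n_sites)
}
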