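#' Nonstationary violation specification
#'
#' Branches inside `clade` (the smallest clade containing the named tips,
#' including its stem edge) evolve under a rate matrix re-targeted to
#' `target_frequencies` with the exchangeabilities unchanged. This is the
#' minimal violation that breaks stationarity: lineages drift toward a new
#' composition, which the marginal-symmetry test is designed to detect.
#'
#' @param target_frequencies Length-m simplex vector.
#' @param clade Character vector of tip labels defining the affected clade.
#' @return A violation spec for [sim_config()].
#' @export
violation_nonstationary <- function(target_frequencies, clade) {
  structure(list(type = "nonstationary",
                 target_frequencies = target_frequencies, clade = clade),
            class = "srh_violation")
}

#' Nonhomogeneous violation specification
#'
#' Branches inside `clade` swap to `alternate_exchangeabilities` while state
#' frequencies are held fixed: relative substitution rates change over the
#' tree but composition does not, which targets internal symmetry.
#'
#' @param alternate_exchangeabilities Symmetric exchangeability parameters
#'   (vector of length m(m-1)/2, upper-triangle row-wise, or symmetric
#'   matrix).
#' @param clade Character vector of tip labels defining the affected clade.
#' @return A violation spec for [sim_config()].
#' @export
violation_nonhomogeneous <- function(alternate_exchangeabilities, clade) {
  structure(list(type = "nonhomogeneous",
                 alternate_exchangeabilities = alternate_exchangeabilities,
                 clade = clade),
            class = "srh_violation")
}

#' Simulation configuration
#'
#' Defines a continuous-time Markov substitution simulation on a fixed tree.
#' Under `violation = NULL` the process is stationary, reversible and
#' homogeneous by construction (a single reversible rate matrix, root states
#' drawn from its equilibrium frequencies).
#'
#' @param tree A `phylo` tree with branch lengths in expected substitutions
#'   per site, or a newick string.
#' @param root_frequencies Length-m simplex (default uniform over 4
#'   nucleotides).
#' @param exchangeabilities Symmetric rate parameters: vector of length
#'   m(m-1)/2 (upper triangle, row-wise; for nucleotides the order is
#'   AC, AG, AT, CG, CT, GT) or a symmetric m-by-m matrix. Default all 1
#'   (equal exchangeabilities).
#' @param n_sites Number of independently evolving sites (>= 1).
#' @param violation `NULL`, [violation_nonstationary()] or
#'   [violation_nonhomogeneous()].
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param seed Optional integer seed.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(tree, root_frequencies = NULL,
                       exchangeabilities = NULL, n_sites = 1000,
                       violation = NULL,
                       alphabet = c("nucleotide", "amino_acid"),
                       seed = NULL) {
  alphabet <- match.arg(alphabet)
  m <- length(.alphabets[[alphabet]])
  if (is.character(tree)) tree <- read_newick(tree)
  if (!inherits(tree, "phylo")) stop("config error: tree must be phylo/newick")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("config error: tree must have nonnegative branch lengths")
  }
  if (is.null(root_frequencies)) root_frequencies <- rep(1 / m, m)
  .check_simplex(root_frequencies, m, "root_frequencies")
  ex <- .as_exchange_matrix(exchangeabilities, m)
  if (!is.null(violation)) {
    if (!inherits(violation, "srh_violation")) {
      stop("config error: violation must come from violation_nonstationary()",
           " or violation_nonhomogeneous()")
    }
    if (!all(violation$clade %in% tree$tip.label)) {
      stop("config error: violation clade tips not in tree")
    }
    if (violation$type == "nonstationary") {
      .check_simplex(violation$target_frequencies, m, "target_frequencies")
    } else {
      violation$alternate_exchangeabilities <-
        .as_exchange_matrix(violation$alternate_exchangeabilities, m)
    }
  }
  n_sites <- as.integer(n_sites)
  if (is.na(n_sites) || n_sites < 1L) {
    stop("config error: n_sites must be a positive integer")
  }
  structure(list(tree = tree, root_frequencies = root_frequencies,
                 exchangeabilities = ex, n_sites = n_sites,
                 violation = violation, alphabet = alphabet, seed = seed),
            class = "sim_config")
}

.check_simplex <- function(p, m, what) {
  if (length(p) != m || any(p <= 0) || abs(sum(p) - 1) > 1e-8) {
    stop("config error: ", what, " must be a length-", m,
         " positive vector summing to 1")
  }
}

.as_exchange_matrix <- function(ex, m) {
  if (is.null(ex)) ex <- rep(1, m * (m - 1) / 2)
  if (is.matrix(ex)) {
    if (nrow(ex) != m || ncol(ex) != m || any(abs(ex - t(ex)) > 1e-12)) {
      stop("config error: exchangeability matrix must be symmetric m x m")
    }
    return(ex)
  }
  if (length(ex) != m * (m - 1) / 2 || any(ex <= 0)) {
    stop("config error: exchangeabilities must be ", m * (m - 1) / 2,
         " positive values")
  }
  # fill the upper triangle row-wise (AC, AG, AT, CG, ... order), mirror down
  M <- matrix(0, m, m)
  k <- 1L
  for (i in seq_len(m - 1)) for (j in seq.int(i + 1, m)) {
    M[i, j] <- ex[k]; M[j, i] <- ex[k]; k <- k + 1L
  }
  M
}

# Reversible rate matrix Q[i,j] = ex[i,j] * pi[j], scaled to one expected
# substitution per unit branch length at the supplied frequencies.
.rate_matrix <- function(ex, freqs) {
  Q <- ex * rep(freqs, each = nrow(ex))
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Transition matrix exp(Q t) via the symmetrized eigendecomposition (exact
# and stable for reversible Q).
.transition_matrix <- function(Q, freqs, t) {
  if (t == 0) return(diag(nrow(Q)))
  sp <- sqrt(freqs)
  S <- Q * (sp %o% (1 / sp))
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  E <- eg$vectors %*% (diag(exp(eg$values * t), nrow(Q)) %*% t(eg$vectors))
  P <- diag(1 / sp) %*% E %*% diag(sp)
  P[P < 0] <- 0
  P / rowSums(P)
}

#' Simulate an alignment under a substitution process
#'
#' Sites evolve independently down the tree by continuous-time Markov
#' substitution. Under `violation = NULL` the process is SRH by
#' construction. Under a nonstationary violation, branches inside the
#' affected clade use a rate matrix with equilibrium re-targeted to the
#' violation's frequencies (same exchangeabilities); under a nonhomogeneous
#' violation those branches use the alternate exchangeabilities with
#' frequencies held fixed.
#'
#' @param cfg A [sim_config()].
#' @return An [srh_alignment] over the tree's tip labels.
#' @export
simulate_alignment <- function(cfg) {
  if (!inherits(cfg, "sim_config")) stop("expected a sim_config")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  m <- length(.alphabets[[cfg$alphabet]])
  states <- .alphabets[[cfg$alphabet]]
  tree <- ape::reorder.phylo(cfg$tree, "cladewise")
  ntip <- ape::Ntip(tree)
  root <- ntip + 1L
  Q0 <- .rate_matrix(cfg$exchangeabilities, cfg$root_frequencies)
  Qv <- NULL
  affected <- integer(0)
  if (!is.null(cfg$violation)) {
    v <- cfg$violation
    Qv <- if (v$type == "nonstationary") {
      .rate_matrix(cfg$exchangeabilities, v$target_frequencies)
    } else {
      .rate_matrix(v$alternate_exchangeabilities, cfg$root_frequencies)
    }
    affected <- .clade_nodes(tree, v$clade)
  }
  freq_for <- function(violated) {
    if (!is.null(cfg$violation) && violated &&
        cfg$violation$type == "nonstationary") {
      cfg$violation$target_frequencies
    } else cfg$root_frequencies
  }
  n <- cfg$n_sites
  node_states <- vector("list", ntip + tree$Nnode)
  node_states[[root]] <- sample.int(m, n, replace = TRUE,
                                    prob = cfg$root_frequencies)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; chd <- tree$edge[e, 2]
    violated <- chd %in% affected
    Q <- if (violated) Qv else Q0
    P <- .transition_matrix(Q, freq_for(violated), tree$edge.length[e])
    ps <- node_states[[par]]
    cs <- integer(n)
    for (s in seq_len(m)) {
      idx <- which(ps == s)
      if (length(idx) > 0) {
        cs[idx] <- sample.int(m, length(idx), replace = TRUE, prob = P[s, ])
      }
    }
    node_states[[chd]] <- cs
  }
  mat <- do.call(rbind, lapply(seq_len(ntip), function(i) {
    states[node_states[[i]]]
  }))
  rownames(mat) <- tree$tip.label
  srh_alignment(mat, alphabet = cfg$alphabet)
}

# Nodes of the smallest clade containing the given tips, stem included
# (edges are "affected" when their child node is in this set).
.clade_nodes <- function(tree, tips) {
  tip_idx <- match(tips, tree$tip.label)
  if (length(tip_idx) == 1L) return(tip_idx)
  mrca <- ape::getMRCA(tree, tip_idx)
  desc <- mrca
  repeat {
    kids <- tree$edge[tree$edge[, 1] %in% desc, 2]
    new <- union(desc, kids)
    if (length(new) == length(desc)) break
    desc <- new
  }
  desc
}

#' Multi-partition benchmark dataset with known ground truth
#'
#' Concatenates `n_partitions` independently simulated partitions, a chosen
#' fraction of which evolve under a nonstationary violation (composition
#' re-targeted toward GC-rich frequencies on the template's affected clade),
#' and returns the alignment, the partition scheme, and per-partition truth
#' labels. Per-partition seeds are derived deterministically from `seed`.
#'
#' @param n_partitions Number of partitions.
#' @param fraction_violating Fraction in `[0, 1]` simulated under violation.
#' @param effect_size In `[0, 1]`: 0 leaves the equilibrium unchanged, 1
#'   re-targets fully to the GC-rich extreme (0.05, 0.45, 0.45, 0.05).
#' @param cfg_template A [sim_config()] providing the tree, frequencies,
#'   exchangeabilities and per-partition `n_sites`; its `violation` slot
#'   must name the affected clade tips via a nonstationary spec (used as the
#'   clade of the induced violations) or be `NULL`, in which case the first
#'   half of the tips is used.
#' @param seed Integer master seed.
#' @return List with `alignment`, `scheme`, and `truth` (data.frame:
#'   partition, violating, seed).
#' @export
make_benchmark_dataset <- function(n_partitions, fraction_violating,
                                   effect_size = 1,
                                   cfg_template = default_benchmark_config(),
                                   seed = 1L) {
  stopifnot(fraction_violating >= 0, fraction_violating <= 1,
            effect_size >= 0, effect_size <= 1)
  if (!inherits(cfg_template, "sim_config")) stop("expected a sim_config")
  set.seed(seed)
  n_viol <- round(n_partitions * fraction_violating)
  violating <- rep(FALSE, n_partitions)
  if (n_viol > 0) violating[sample.int(n_partitions, n_viol)] <- TRUE
  clade <- if (!is.null(cfg_template$violation)) {
    cfg_template$violation$clade
  } else {
    tl <- cfg_template$tree$tip.label
    tl[seq_len(max(1L, floor(length(tl) / 2)))]
  }
  gc_rich <- c(0.05, 0.45, 0.45, 0.05)
  target <- (1 - effect_size) * cfg_template$root_frequencies +
    effect_size * gc_rich
  target <- target / sum(target)
  sub_seeds <- (seed + 7919L * seq_len(n_partitions)) %% 2147483647L
  alns <- vector("list", n_partitions)
  for (i in seq_len(n_partitions)) {
    v <- if (violating[i]) violation_nonstationary(target, clade) else NULL
    cfg_i <- sim_config(cfg_template$tree, cfg_template$root_frequencies,
                        cfg_template$exchangeabilities,
                        n_sites = cfg_template$n_sites, violation = v,
                        alphabet = cfg_template$alphabet,
                        seed = sub_seeds[i])
    alns[[i]] <- simulate_alignment(cfg_i)
  }
  names(alns) <- sprintf("part%03d", seq_len(n_partitions))
  cc <- concatenate_alignments(alns)
  list(alignment = cc$alignment, scheme = cc$scheme,
       truth = data.frame(partition = names(alns), violating = violating,
                          seed = sub_seeds, stringsAsFactors = FALSE))
}

#' Default benchmark simulation template
#'
#' An 8-taxon balanced tree with 0.05-substitutions/site branches, base
#' frequencies (0.3, 0.2, 0.2, 0.3), HKY-like exchangeabilities with a
#' transition/transversion ratio of 2, 1000 sites per partition, and tips
#' t5-t8 as the clade affected by induced violations.
#'
#' @param n_sites Sites per partition (default 1000).
#' @return A [sim_config()].
#' @export
default_benchmark_config <- function(n_sites = 1000) {
  nwk <- paste0("(((t1:0.05,t2:0.05):0.05,(t3:0.05,t4:0.05):0.05):0.05,",
                "((t5:0.05,t6:0.05):0.05,(t7:0.05,t8:0.05):0.05):0.05);")
  sim_config(nwk,
             root_frequencies = c(0.3, 0.2, 0.2, 0.3),
             exchangeabilities = c(1, 2, 1, 1, 2, 1),
             n_sites = n_sites,
             violation = violation_nonstationary(
               c(0.05, 0.45, 0.45, 0.05), paste0("t", 5:8)))
}
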