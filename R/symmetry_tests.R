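#' Divergence matrix for an ordered sequence pair
#'
#' The m-by-m matrix of site counts `d[i, j]` = number of alignment columns
#' with state i in the first sequence and state j in the second. A column
#' contributes only when both residues are determinate alphabet states
#' (A/C/G/T or the 20 amino acids); columns with a gap or ambiguity code in
#' either sequence are tallied in `n_excluded` (pairwise deletion).
#'
#' @param seq1,seq2 Character strings or character vectors of equal length.
#' @param alphabet `"nucleotide"` (m = 4, states A,C,G,T) or `"amino_acid"`
#'   (m = 20, alphabetical one-letter codes).
#' @return An object of class `divergence_matrix`: list with `counts` (m-by-m
#'   integer matrix with state dimnames), `m`, `n_counted`, `n_excluded`.
#' @examples
#' divergence_matrix("AAAA", "AACC")$counts["A", c("A", "C")]
#' @export
divergence_matrix <- function(seq1, seq2,
                              alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  states <- .alphabets[[alphabet]]
  m <- length(states)
  s1 <- .as_chars(seq1); s2 <- .as_chars(seq2)
  if (length(s1) != length(s2)) {
    stop("length mismatch: sequences have lengths ", length(s1), " and ",
         length(s2))
  }
  i1 <- match(s1, states); i2 <- match(s2, states)
  ok <- !is.na(i1) & !is.na(i2)
  counts <- matrix(0L, m, m, dimnames = list(states, states))
  if (any(ok)) {
    tab <- tabulate((i1[ok] - 1L) * m + i2[ok], nbins = m * m)
    counts[] <- matrix(tab, m, m, byrow = TRUE)
  }
  structure(list(counts = counts, m = m, n_counted = sum(ok),
                 n_excluded = sum(!ok)),
            class = "divergence_matrix")
}

.as_chars <- function(x) {
  x <- toupper(x)
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

# Wrap a bare count matrix (used by tests and by callers holding precomputed
# counts).
#' Construct a divergence matrix from a count matrix
#' @param counts Square nonnegative integer matrix (4x4 or 20x20).
#' @param n_excluded Sites excluded by pairwise deletion (bookkeeping only).
#' @return A `divergence_matrix`.
#' @export
as_divergence_matrix <- function(counts, n_excluded = 0L) {
  counts <- as.matrix(counts)
  m <- nrow(counts)
  if (ncol(counts) != m || !(m %in% c(2L, 4L, 20L))) {
    stop("counts must be a square 2x2, 4x4 or 20x20 matrix")
  }
  if (any(counts < 0)) stop("counts must be nonnegative")
  structure(list(counts = counts, m = m, n_counted = sum(counts),
                 n_excluded = as.integer(n_excluded)),
            class = "divergence_matrix")
}

.test_result <- function(test, statistic, df, applicable = TRUE,
                         note = NA_character_) {
  p <- if (applicable) pchisq(statistic, df, lower.tail = FALSE) else NA_real_
  structure(list(test = test, statistic = statistic, df = df, p_value = p,
                 applicable = applicable, note = note),
            class = "srh_test_result")
}

#' @export
print.srh_test_result <- function(x, ...) {
  if (x$applicable) {
    cat(sprintf("%s: statistic = %.6g, df = %d, p = %.4g\n",
                x$test, x$statistic, x$df, x$p_value))
  } else {
    cat(sprintf("%s: not applicable (%s)\n", x$test, x$note))
  }
  invisible(x)
}

#' Bowker's matched-pairs test of symmetry (MPTS)
#'
#' Tests H0: `d[i, j] = d[j, i]` for all state pairs. The statistic is
#' `sum over i < j with d[i,j] + d[j,i] > 0 of (d[i,j] - d[j,i])^2 /
#' (d[i,j] + d[j,i])`, chi-square with f degrees of freedom, where f is the
#' number of unordered pairs with `d[i,j] + d[j,i] > 0`. Rejection indicates
#' that the pair of sequences did not evolve under stationary, reversible and
#' homogeneous (SRH) conditions. When f = 0 (the sequences are identical at
#' every counted site) the test carries no information and is marked
#' inapplicable.
#'
#' @param D A [divergence_matrix].
#' @return An `srh_test_result` with `test = "MPTS"`.
#' @export
bowker_test <- function(D) {
  .check_divmat(D)
  d <- D$counts
  s <- d + t(d)
  diff2 <- (d - t(d))^2
  up <- upper.tri(d)
  use <- up & s > 0
  f <- sum(use)
  if (f == 0L) {
    return(.test_result("MPTS", 0, 0L, applicable = FALSE,
                        note = "sequences identical at counted sites"))
  }
  stat <- sum(diff2[use] / s[use])
  .test_result("MPTS", stat, f)
}

#' Stuart's matched-pairs test of marginal symmetry (MPTMS)
#'
#' Tests H0: the row and column marginals of the divergence matrix are equal,
#' i.e. the two sequences share state frequencies. With `u` the vector of
#' row-sum minus column-sum differences for the first m - 1 states and `V`
#' its estimated covariance matrix under marginal symmetry
#' (`V[i, i] = d[i, .] + d[., i] - 2 d[i, i]`,
#' `V[i, j] = -(d[i, j] + d[j, i])`), the statistic is `t(u) V^-1 u`,
#' chi-square with m - 1 degrees of freedom. Rejection indicates
#' nonstationarity (unequal base/amino-acid composition). When `V` is
#' numerically singular (reciprocal condition number below 1e-12) the
#' statistic is ill-defined and the test is marked inapplicable.
#'
#' @param D A [divergence_matrix].
#' @return An `srh_test_result` with `test = "MPTMS"`.
#' @export
stuart_test <- function(D) {
  .check_divmat(D)
  d <- D$counts
  m <- D$m
  r <- rowSums(d); cl <- colSums(d)
  k <- m - 1L
  u <- (r - cl)[seq_len(k)]
  V <- -(d + t(d))[seq_len(k), seq_len(k), drop = FALSE]
  diag(V) <- (r + cl - 2 * diag(d))[seq_len(k)]
  rc <- tryCatch(rcond(V), error = function(e) 0)
  if (!is.finite(rc) || rc < 1e-12) {
    return(.test_result("MPTMS", NA_real_, k, applicable = FALSE,
                        note = "Stuart statistic ill-defined (V singular)"))
  }
  stat <- drop(crossprod(u, solve(V, u)))
  .test_result("MPTMS", stat, k)
}

#' Matched-pairs test of internal symmetry (MPTIS)
#'
#' The Bowker-minus-Stuart component: `S_I^2 = S_B^2 - S_S^2`, chi-square
#' with `f - m + 1` degrees of freedom, testing symmetry beyond the margins.
#' Rejection indicates nonhomogeneity (changing relative substitution rates
#' over time). Inapplicable when either component is inapplicable, when
#' `f - m + 1 <= 0`, or when the difference is materially negative (the
#' decomposition holds in exact arithmetic only when V is well-conditioned);
#' negative values above -1e-8 are clamped to 0.
#'
#' @param bowker,stuart `srh_test_result`s from [bowker_test()] and
#'   [stuart_test()] computed on the same divergence matrix.
#' @param D The shared [divergence_matrix].
#' @return An `srh_test_result` with `test = "MPTIS"`.
#' @export
internal_test <- function(bowker, stuart, D) {
  .check_divmat(D)
  m <- D$m
  if (!bowker$applicable) {
    return(.test_result("MPTIS", NA_real_, 0L, applicable = FALSE,
                        note = "Bowker test inapplicable"))
  }
  if (!stuart$applicable) {
    return(.test_result("MPTIS", NA_real_, 0L, applicable = FALSE,
                        note = "Stuart test inapplicable"))
  }
  df <- bowker$df - m + 1L
  stat <- bowker$statistic - stuart$statistic
  if (stat < 0) {
    if (stat > -1e-8) stat <- 0 else {
      return(.test_result("MPTIS", stat, df, applicable = FALSE,
                          note = "negative statistic: decomposition unstable"))
    }
  }
  if (df <= 0L) {
    return(.test_result("MPTIS", stat, df, applicable = FALSE,
                        note = "nonpositive degrees of freedom"))
  }
  .test_result("MPTIS", stat, df)
}

#' All three matched-pairs tests for a sequence pair
#'
#' Convenience wrapper running [bowker_test()], [stuart_test()] and
#' [internal_test()] on one divergence matrix.
#'
#' @param D A [divergence_matrix], or `NULL` if `seq1`/`seq2` given.
#' @param seq1,seq2,alphabet Passed to [divergence_matrix()] when `D` is
#'   `NULL`.
#' @return Named list of `srh_test_result`s: `MPTS`, `MPTMS`, `MPTIS`.
#' @export
matched_pairs_tests <- function(D = NULL, seq1 = NULL, seq2 = NULL,
                                alphabet = "nucleotide") {
  if (is.null(D)) D <- divergence_matrix(seq1, seq2, alphabet)
  b <- bowker_test(D)
  s <- stuart_test(D)
  i <- internal_test(b, s, D)
  list(MPTS = b, MPTMS = s, MPTIS = i)
}

.check_divmat <- function(D) {
  if (!inherits(D, "divergence_matrix")) stop("expected a divergence_matrix")
  invisible(D)
}

#' Serialize test results to a data frame
#'
#' @param results Named list of `srh_test_result`s (as from
#'   [matched_pairs_tests()]).
#' @return data.frame with columns test, statistic, df, p_value, applicable,
#'   note.
#' @export
test_results_table <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(test = r$test, statistic = r$statistic, df = r$df,
               p_value = r$p_value, applicable = r$applicable, note = r$note,
               stringsAsFactors = FALSE)
  }))
}
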