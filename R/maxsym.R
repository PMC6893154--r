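# Integer character codes for an alignment (NA for gap/ambiguity), cached
# form used by the pairwise scans.
.char_codes <- function(aln) {
  states <- .alphabets[[aln$alphabet]]
  codes <- match(aln$mat, states)
  dim(codes) <- dim(aln$mat)
  rownames(codes) <- aln$taxa
  codes
}

#' Pairwise divergence score
#'
#' The sum of the off-diagonal elements of the pair's divergence matrix
#' divided by the sum of all elements: the fraction of pairwise-complete
#' sites at which the two sequences differ. By convention 0 when no site is
#' complete in both sequences (flagged via the `"no_counted_sites"`
#' attribute).
#'
#' @param aln An [srh_alignment].
#' @param taxon_i,taxon_j Taxon labels.
#' @return Numeric in `[0, 1]`.
#' @export
divergence_score <- function(aln, taxon_i, taxon_j) {
  .check_alignment(aln)
  for (t in c(taxon_i, taxon_j)) {
    if (!t %in% aln$taxa) stop("unknown taxon: ", t)
  }
  D <- divergence_matrix(aln$mat[taxon_i, ], aln$mat[taxon_j, ],
                         alphabet = aln$alphabet)
  if (D$n_counted == 0L) {
    return(structure(0, no_counted_sites = TRUE))
  }
  (D$n_counted - sum(diag(D$counts))) / D$n_counted
}

# Score every unordered pair at once. Returns data.frame(i, j, score).
.all_pair_scores <- function(aln) {
  codes <- .char_codes(aln)
  nt <- nrow(codes)
  pairs <- combn(nt, 2)
  score <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- codes[pairs[1, k], ]; b <- codes[pairs[2, k], ]
    both <- !is.na(a) & !is.na(b)
    n <- sum(both)
    score[k] <- if (n == 0L) 0 else sum(a[both] != b[both]) / n
  }
  data.frame(i = pairs[1, ], j = pairs[2, ], score = score)
}

#' Select the maximum-divergence sequence pair
#'
#' Scans all unordered taxon pairs, computes each pair's divergence score,
#' and returns one pair drawn uniformly at random from the set of pairs tied
#' at the maximum (ties compared at tolerance 1e-12). Deterministic for a
#' fixed seed; when `seed` is `NULL` the current RNG stream is used, so a
#' caller that seeds once governs all tie-breaks in a run.
#'
#' @param aln An [srh_alignment] with at least two taxa.
#' @param seed Optional integer seed for the tie-break draw.
#' @return List with `pair` (two taxon labels), `score`, and `n_tied`.
#' @export
select_max_divergent_pair <- function(aln, seed = NULL) {
  .check_alignment(aln)
  if (length(aln$taxa) < 2L) stop("need at least 2 taxa")
  if (!is.null(seed)) set.seed(seed)
  sc <- .all_pair_scores(aln)
  mx <- max(sc$score)
  tied <- which(abs(sc$score - mx) < 1e-12)
  pick <- tied[sample.int(length(tied), 1L)]
  list(pair = c(aln$taxa[sc$i[pick]], aln$taxa[sc$j[pick]]),
       score = sc$score[pick], n_tied = length(tied))
}

#' MaxSymTest family for one partition
#'
#' Applies the three matched-pairs tests of homogeneity to the
#' maximum-divergence pair of the alignment: MPTS on the max pair is the
#' MaxSymTest, MPTMS the MaxSymTest_mar, MPTIS the MaxSymTest_int. A test
#' calls the partition `fail` when it is applicable and its p-value is below
#' `alpha`; inapplicable tests call `pass` (no rejection is possible without
#' a defined p-value), with the reason retained in the result.
#'
#' @param aln An [srh_alignment] (the partition's sub-alignment).
#' @param alpha Significance threshold (default 0.05).
#' @param seed Optional seed for the tie-break draw.
#' @param name Partition label carried into the verdict.
#' @return An object of class `partition_verdict`: list with
#'   `partition_name`, `pair`, `score`, `n_tied`, `results` (named list of
#'   `srh_test_result`), `calls` (named character, `"pass"`/`"fail"`), and
#'   `alpha`.
#' @export
max_sym_test <- function(aln, alpha = 0.05, seed = NULL, name = "partition") {
  .check_alignment(aln)
  if (!is.null(seed)) set.seed(seed)
  sel <- select_max_divergent_pair(aln)
  D <- divergence_matrix(aln$mat[sel$pair[1], ], aln$mat[sel$pair[2], ],
                         alphabet = aln$alphabet)
  results <- matched_pairs_tests(D)
  calls <- vapply(results, function(r) {
    if (r$applicable && r$p_value < alpha) "fail" else "pass"
  }, "")
  structure(list(partition_name = name, pair = sel$pair, score = sel$score,
                 n_tied = sel$n_tied, results = results, calls = calls,
                 alpha = alpha),
            class = "partition_verdict")
}

#' @export
print.partition_verdict <- function(x, ...) {
  cat(sprintf("partition_verdict '%s': max pair (%s, %s), score %.4f%s\n",
              x$partition_name, x$pair[1], x$pair[2], x$score,
              if (x$n_tied > 1) sprintf(" (%d tied)", x$n_tied) else ""))
  for (t in names(x$results)) {
    r <- x$results[[t]]
    cat(sprintf("  %-6s %s  (%s)\n", t,
                if (r$applicable) sprintf("p = %.4g", r$p_value)
                else "inapplicable",
                x$calls[[t]]))
  }
  invisible(x)
}

#' Classify every partition of a dataset
#'
#' Runs [max_sym_test()] on each partition of the scheme and, for the
#' selected test, concatenates passing partitions into `D_pass` and failing
#' partitions into `D_fail`. Pass/fail membership is recorded for all three
#' tests. A single seed governs all tie-breaks; the same seed yields an
#' identical classification.
#'
#' @param aln An [srh_alignment].
#' @param scheme A [partition_scheme] valid for `aln`.
#' @param test Which test defines the `D_pass`/`D_fail` concatenations:
#'   `"MPTS"` (MaxSymTest, default), `"MPTMS"` (MaxSymTest_mar) or `"MPTIS"`
#'   (MaxSymTest_int).
#' @param alpha Significance threshold.
#' @param seed Integer seed recorded in the result.
#' @return An object of class `dataset_classification`: `verdicts` (named
#'   list of `partition_verdict`), `pass`/`fail` (per-test lists of
#'   partition names), `D_pass`/`D_fail` (each a list with `alignment` and
#'   `scheme`, or `NULL` when that side is empty), plus `test`, `alpha`,
#'   `seed`.
#' @export
classify_dataset <- function(aln, scheme, test = c("MPTS", "MPTMS", "MPTIS"),
                             alpha = 0.05, seed = 1L) {
  .check_alignment(aln)
  test <- match.arg(test)
  if (!inherits(scheme, "partition_scheme")) stop("expected a partition_scheme")
  set.seed(seed)
  subs <- lapply(scheme$partitions, function(p) extract_partition(aln, p))
  names(subs) <- vapply(scheme$partitions, `[[`, "", "name")
  verdicts <- lapply(seq_along(subs), function(i) {
    max_sym_test(subs[[i]], alpha = alpha, name = names(subs)[i])
  })
  names(verdicts) <- names(subs)
  tests <- c("MPTS", "MPTMS", "MPTIS")
  fail <- lapply(tests, function(t) {
    names(subs)[vapply(verdicts, function(v) v$calls[[t]] == "fail", TRUE)]
  })
  names(fail) <- tests
  pass <- lapply(tests, function(t) setdiff(names(subs), fail[[t]]))
  names(pass) <- tests
  build_side <- function(nm) {
    if (length(nm) == 0L) return(NULL)
    concatenate_alignments(subs[nm], names = nm)
  }
  structure(list(verdicts = verdicts, pass = pass, fail = fail,
                 D_pass = build_side(pass[[test]]),
                 D_fail = build_side(fail[[test]]),
                 test = test, alpha = alpha, seed = seed),
            class = "dataset_classification")
}

#' @export
print.dataset_classification <- function(x, ...) {
  cat(sprintf("dataset_classification: %d partitions, alpha = %g, seed = %d\n",
              length(x$verdicts), x$alpha, x$seed))
  for (t in names(x$fail)) {
    cat(sprintf("  %-6s %d pass / %d fail\n", t, length(x$pass[[t]]),
                length(x$fail[[t]])))
  }
  invisible(x)
}

#' Per-partition verdict table
#'
#' One row per partition and test: chosen pair, divergence score, statistic,
#' df, p-value, applicability, and the pass/fail call.
#'
#' @param cls A `dataset_classification`.
#' @return data.frame.
#' @export
verdict_table <- function(cls) {
  rows <- lapply(cls$verdicts, function(v) {
    do.call(rbind, lapply(names(v$results), function(t) {
      r <- v$results[[t]]
      data.frame(partition = v$partition_name, taxon1 = v$pair[1],
                 taxon2 = v$pair[2], divergence = v$score,
                 n_tied = v$n_tied, test = t, statistic = r$statistic,
                 df = r$df, p_value = r$p_value, applicable = r$applicable,
                 note = r$note, call = v$calls[[t]],
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize a classification
#'
#' Per-test fail counts and proportions, the proportion of partitions failing
#' at least one test (inapplicable tests count as not-failed), and, when
#' genome/context metadata are available on the partitions or supplied as a
#' data frame, a genome-by-context cross-tabulation of the at-least-one
#' failure proportion.
#'
#' @param cls A `dataset_classification`.
#' @param metadata Optional data.frame with columns `partition`, `genome`,
#'   `context`.
#' @return List with `per_test` (data.frame: test, n_fail, n_total,
#'   prop_fail), `any_fail` (list: n_fail, n_total, prop_fail,
#'   fail_partitions), and optionally `by_metadata` (data.frame).
#' @export
summarize_classification <- function(cls, metadata = NULL) {
  tests <- names(cls$fail)
  n_total <- length(cls$verdicts)
  per_test <- data.frame(
    test = tests,
    n_fail = vapply(cls$fail, length, 0L),
    n_total = n_total,
    prop_fail = vapply(cls$fail, length, 0L) / n_total,
    row.names = NULL, stringsAsFactors = FALSE
  )
  any_fail_set <- Reduce(union, cls$fail)
  out <- list(per_test = per_test,
              any_fail = list(n_fail = length(any_fail_set),
                              n_total = n_total,
                              prop_fail = length(any_fail_set) / n_total,
                              fail_partitions = sort(any_fail_set)))
  if (!is.null(metadata)) {
    stopifnot(all(c("partition", "genome", "context") %in% names(metadata)))
    md <- metadata[metadata$partition %in% names(cls$verdicts), ]
    if (nrow(md) > 0) {
      md$failed_any <- md$partition %in% any_fail_set
      agg <- aggregate(failed_any ~ genome + context, data = md,
                       FUN = function(z) mean(z))
      n <- aggregate(failed_any ~ genome + context, data = md, FUN = length)
      agg$n <- n$failed_any
      names(agg)[names(agg) == "failed_any"] <- "prop_fail_any"
      out$by_metadata <- agg
    }
  }
  out
}

#' @importFrom stats aggregate
NULL
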