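#' Run configuration for the end-to-end workflow
#'
#' @param alignment Path to the input alignment.
#' @param format Alignment format: `"fasta"`, `"phylip"`, `"nexus"`.
#' @param partitions Optional path to a partition file; when absent, the
#'   whole alignment is one partition named `"all"`.
#' @param dialect Partition dialect: `"auto"`, `"raxml"`, `"nexus_sets"`.
#' @param test Which test's calls define `D_pass`/`D_fail` (the removal
#'   criterion): `"MPTS"` (default), `"MPTMS"`, `"MPTIS"` — mirrors the
#'   `--symtest-type MAR|INT` switch.
#' @param alpha Significance threshold in `(0, 1)` (mirrors
#'   `--symtest-pval`, default 0.05).
#' @param seed Integer seed governing all tie-breaks.
#' @param outdir Output directory (created if missing).
#' @param metadata Optional path to a TSV with columns partition, genome,
#'   context.
#' @param remove_bad If `TRUE`, write only `D_pass` for the selected test
#'   (mirrors `--symtest-remove-bad`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(alignment, format = "fasta", partitions = NULL,
                       dialect = "auto", test = "MPTS", alpha = 0.05,
                       seed = 1L, outdir = "symtest_out", metadata = NULL,
                       remove_bad = FALSE) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  structure(list(alignment = alignment, format = format,
                 partitions = partitions, dialect = dialect, test = test,
                 alpha = alpha, seed = as.integer(seed), outdir = outdir,
                 metadata = metadata, remove_bad = remove_bad),
            class = "run_config")
}

#' Run the symmetry-test workflow on a dataset
#'
#' End to end: read the alignment and partition scheme, apply the three
#' MaxSymTests to every partition, write the per-partition verdict table and
#' the summary, and write the `D_pass` / `D_fail` concatenations (with
#' companion partition files in both dialects) for the selected test. A side
#' with zero partitions is simply reported as empty in the summary; the run
#' still succeeds.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the `dataset_classification`, the summary,
#'   and the paths written.
#' @export
run_symtest <- function(config) {
  if (!inherits(config, "run_config")) stop("expected a run_config")
  if (!file.exists(config$alignment)) {
    stop("I/O error: cannot read alignment file '", config$alignment, "'")
  }
  aln <- read_alignment(config$alignment, format = config$format)
  scheme <- if (is.null(config$partitions)) {
    partition_scheme(list(partition("all", seq_len(aln$n_sites))))
  } else {
    if (!file.exists(config$partitions)) {
      stop("I/O error: cannot read partition file '", config$partitions, "'")
    }
    parse_partition_scheme(config$partitions, dialect = config$dialect,
                           n_sites = aln$n_sites)
  }
  metadata <- if (!is.null(config$metadata)) {
    utils::read.delim(config$metadata, stringsAsFactors = FALSE)
  } else NULL

  cls <- classify_dataset(aln, scheme, test = config$test,
                          alpha = config$alpha, seed = config$seed)
  summ <- summarize_classification(cls, metadata = metadata)

  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  p <- file.path(config$outdir, "verdicts.tsv")
  .write_tsv(verdict_table(cls), p); paths$verdicts <- p
  p <- file.path(config$outdir, "summary.tsv")
  .write_tsv(summ$per_test, p); paths$summary <- p
  if (!is.null(summ$by_metadata)) {
    p <- file.path(config$outdir, "summary_by_metadata.tsv")
    .write_tsv(summ$by_metadata, p); paths$summary_by_metadata <- p
  }

  sides <- if (config$remove_bad) "D_pass" else c("D_pass", "D_fail")
  for (side in sides) {
    obj <- cls[[side]]
    if (is.null(obj)) next
    base <- file.path(config$outdir, paste0(tolower(side), "_", config$test))
    ext <- switch(config$format, fasta = ".fasta", phylip = ".phy",
                  nexus = ".nex")
    write_alignment(obj$alignment, paste0(base, ext), format = config$format)
    write_partition_scheme(obj$scheme, paste0(base, ".raxml.txt"), "raxml")
    write_partition_scheme(obj$scheme, paste0(base, ".charsets.nex"),
                           "nexus_sets")
    paths[[side]] <- paste0(base, ext)
  }

  n_inapp <- sum(!vapply(unlist(lapply(cls$verdicts, `[[`, "results"),
                                recursive = FALSE),
                         `[[`, TRUE, "applicable"))
  log <- c(sprintf("srhtest %s", as.character(packageVersion("srhtest"))),
           sprintf("seed: %d", cls$seed),
           sprintf("alpha: %g", cls$alpha),
           sprintf("removal test: %s", cls$test),
           sprintf("partitions: %d", length(cls$verdicts)),
           sprintf("fail MPTS/MPTMS/MPTIS: %d/%d/%d",
                   length(cls$fail$MPTS), length(cls$fail$MPTMS),
                   length(cls$fail$MPTIS)),
           sprintf("fail at least one: %d", summ$any_fail$n_fail),
           sprintf("inapplicable test results: %d", n_inapp),
           sprintf("D_pass empty: %s", is.null(cls$D_pass)),
           sprintf("D_fail empty: %s", is.null(cls$D_fail)))
  writeLines(log, file.path(config$outdir, "run.log"))
  paths$log <- file.path(config$outdir, "run.log")

  invisible(list(classification = cls, summary = summ, paths = paths))
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Compare trees inferred from all / pass / fail data sets
#'
#' Computes the path difference (PD), normalized path difference (NPD) and
#' quartet distance (QD) for every pair of the supplied trees. Typical use
#' compares `T_all`, `T_pass` and `T_fail`, the trees inferred externally
#' (e.g. with IQ-TREE) from the full data set and from the concatenations of
#' passing and failing partitions. The NPD null mean is computed once per
#' leaf count and reused across pairs.
#'
#' @param trees Named list or character vector of 2-3 newick files or
#'   strings (e.g. `c(T_all = ..., T_pass = ..., T_fail = ...)`).
#' @param null_pairs Random tree pairs for the NPD normalizer (default
#'   10000).
#' @param seed Seed for the null draw.
#' @param out Optional path to write the table as TSV.
#' @return data.frame with one row per tree pair: tree1, tree2, n_leaves,
#'   pd, npd, qd, null_pairs, seed.
#' @export
compare_trees <- function(trees, null_pairs = 10000, seed = 1L, out = NULL) {
  if (length(trees) < 2L) stop("supply at least two trees")
  nms <- names(trees)
  if (is.null(nms)) nms <- paste0("tree", seq_along(trees))
  parsed <- lapply(trees, read_newick)
  for (i in seq_along(parsed)[-1]) {
    if (!setequal(parsed[[1]]$tip.label, parsed[[i]]$tip.label)) {
      stop("leaf-set mismatch between trees '", nms[1], "' and '", nms[i],
           "'")
    }
  }
  n <- ape::Ntip(parsed[[1]])
  set.seed(seed)
  nullm <- pd_null_mean(n, pairs = null_pairs)
  idx <- combn(length(parsed), 2)
  rows <- lapply(seq_len(ncol(idx)), function(k) {
    a <- idx[1, k]; b <- idx[2, k]
    data.frame(tree1 = nms[a], tree2 = nms[b], n_leaves = n,
               pd = path_difference(parsed[[a]], parsed[[b]]),
               npd = npd(parsed[[a]], parsed[[b]], null_mean = nullm),
               qd = quartet_distance(parsed[[a]], parsed[[b]]),
               null_pairs = null_pairs, seed = seed,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out)) .write_tsv(res, out)
  res
}
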