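#' Alignment partition
#'
#' A named, strictly increasing set of 1-based alignment columns, optionally
#' annotated with genome type and sequence context (used only for summary
#' cross-tabulations).
#'
#' @param name Partition label.
#' @param sites Integer vector of 1-based column indices.
#' @param genome Optional: `"nuclear"`, `"mitochondrial"`, `"plastid"`,
#'   `"virus"`.
#' @param context Optional: e.g. `"codon1"`, `"codon2"`, `"codon3"`, `"rRNA"`,
#'   `"tRNA"`, `"UCE"`, `"other"`.
#' @return An object of class `partition`.
#' @export
partition <- function(name, sites, genome = NA_character_,
                      context = NA_character_) {
  sites <- as.integer(sites)
  if (length(sites) == 0L) stop("partition '", name, "' has no sites")
  if (any(diff(sites) <= 0L)) {
    stop("partition '", name, "' sites must be strictly increasing")
  }
  if (sites[1] < 1L) stop("bounds error: partition '", name, "' has sites < 1")
  structure(list(name = as.character(name), sites = sites,
                 genome = genome, context = context),
            class = "partition")
}

#' Partition scheme
#'
#' A list of non-overlapping [partition]s covering (a subset of) an
#' alignment's columns.
#'
#' @param partitions List of [partition] objects.
#' @param source_dialect `"nexus_sets"`, `"raxml"`, or `"internal"`.
#' @return An object of class `partition_scheme`.
#' @export
partition_scheme <- function(partitions, source_dialect = "internal") {
  if (length(partitions) == 0L) stop("partition scheme must be nonempty")
  nm <- vapply(partitions, function(p) p$name, "")
  if (anyDuplicated(nm)) stop("duplicate partition names")
  all_sites <- unlist(lapply(partitions, function(p) p$sites))
  if (anyDuplicated(all_sites)) {
    stop("overlap error: partitions share alignment columns")
  }
  structure(list(partitions = partitions, source_dialect = source_dialect),
            class = "partition_scheme")
}

#' @export
print.partition_scheme <- function(x, ...) {
  cat(sprintf("partition_scheme: %d partitions, %d sites (%s)\n",
              length(x$partitions),
              length(unlist(lapply(x$partitions, `[[`, "sites"))),
              x$source_dialect))
  invisible(x)
}

# Expand a range token: "12", "1-300", or "1-300\3" (every 3rd column from 1).
# External coordinates are 1-based inclusive, as in RAxML and NEXUS.
.expand_range <- function(tok, where) {
  m <- regmatches(tok, regexec("^(\\d+)(?:-(\\d+))?(?:\\\\(\\d+))?$", tok))[[1]]
  if (length(m) == 0L) stop("cannot parse range '", tok, "' in ", where)
  a <- as.integer(m[2])
  b <- if (nzchar(m[3])) as.integer(m[3]) else a
  s <- if (nzchar(m[4])) as.integer(m[4]) else 1L
  if (b < a || s < 1L) stop("invalid range '", tok, "' in ", where)
  seq.int(a, b, by = s)
}

#' Parse a partition scheme file
#'
#' Supports RAxML-style partition files (`DNA, gene1 = 1-300\3, 400-500`) and
#' NEXUS `sets` blocks (`charset gene1 = 1-300\3 400-500;`). Coordinates in
#' both dialects are 1-based inclusive; `a-b\s` takes every s-th column
#' starting at `a`.
#'
#' @param path Partition file path.
#' @param dialect `"auto"` (sniffed from content), `"raxml"`, or
#'   `"nexus_sets"`.
#' @param n_sites Site count of the companion alignment, used for bounds
#'   checking.
#' @return A [partition_scheme].
#' @export
parse_partition_scheme <- function(path, dialect = c("auto", "raxml",
                                                     "nexus_sets"),
                                   n_sites) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (dialect == "auto") {
    dialect <- if (any(grepl("charset", lines, ignore.case = TRUE)) ||
                   any(grepl("^\\s*#NEXUS", lines, ignore.case = TRUE))) {
      "nexus_sets"
    } else "raxml"
  }
  parts <- if (dialect == "raxml") {
    .parse_raxml_lines(lines)
  } else {
    .parse_nexus_sets_lines(lines)
  }
  for (p in parts) {
    if (max(p$sites) > n_sites) {
      stop("bounds error: partition '", p$name, "' exceeds n_sites = ",
           n_sites)
    }
  }
  partition_scheme(parts, source_dialect = dialect)
}

.parse_raxml_lines <- function(lines) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^[^,]+,\\s*([^=]+?)\\s*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 0L) stop("cannot parse RAxML partition line: '", ln, "'")
    name <- m[2]
    toks <- strsplit(m[3], "\\s*,\\s*")[[1]]
    sites <- sort(unique(unlist(lapply(toks, .expand_range, where = name))))
    parts[[length(parts) + 1L]] <- partition(name, sites)
  }
  if (length(parts) == 0L) stop("no partitions found in RAxML file")
  parts
}

.parse_nexus_sets_lines <- function(lines) {
  txt <- paste(lines, collapse = "\n")
  stmts <- regmatches(
    txt, gregexpr("charset\\s+[^=;]+=[^;]+;", txt, ignore.case = TRUE))[[1]]
  if (length(stmts) == 0L) stop("no charset statements found in NEXUS file")
  parts <- lapply(stmts, function(s) {
    m <- regmatches(
      s, regexec("charset[[:space:]]+([^=[:space:]]+)[[:space:]]*=[[:space:]]*([^;]+);", s,
                 ignore.case = TRUE))[[1]]
    name <- m[2]
    toks <- strsplit(trimws(m[3]), "\\s+")[[1]]
    sites <- sort(unique(unlist(lapply(toks, .expand_range, where = name))))
    partition(name, sites)
  })
  parts
}

#' Write a partition scheme
#'
#' @param scheme A [partition_scheme].
#' @param path Output path.
#' @param dialect `"raxml"` or `"nexus_sets"`.
#' @return Invisibly, `path`.
#' @export
write_partition_scheme <- function(scheme, path,
                                   dialect = c("raxml", "nexus_sets")) {
  dialect <- match.arg(dialect)
  fmt_sites <- function(sites) {
    # compress runs of consecutive columns into a-b ranges
    runs <- split(sites, cumsum(c(1L, diff(sites) != 1L)))
    paste(vapply(runs, function(r) {
      if (length(r) == 1L) as.character(r) else paste0(r[1], "-", r[length(r)])
    }, ""), collapse = if (dialect == "raxml") ", " else " ")
  }
  con <- file(path, "w"); on.exit(close(con))
  if (dialect == "raxml") {
    for (p in scheme$partitions) {
      writeLines(sprintf("DNA, %s = %s", p$name, fmt_sites(p$sites)), con)
    }
  } else {
    writeLines("#NEXUS", con)
    writeLines("begin sets;", con)
    for (p in scheme$partitions) {
      writeLines(sprintf("  charset %s = %s;", p$name, fmt_sites(p$sites)),
                 con)
    }
    writeLines("end;", con)
  }
  invisible(path)
}
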