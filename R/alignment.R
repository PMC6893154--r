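#' @importFrom stats pchisq setNames
#' @importFrom utils combn write.table packageVersion
NULL

# State orderings are fixed so that downstream linear algebra (which drops the
# last state) is bit-reproducible.
.alphabets <- list(
  nucleotide = c("A", "C", "G", "T"),
  amino_acid = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
)

.gap_chars <- c("-", ".", "?")

#' Multiple sequence alignment container
#'
#' Builds an `srh_alignment`, the container used throughout the package: a
#' taxa-by-sites character matrix over a declared alphabet. Residues are
#' uppercased; for nucleotide data `U` is mapped to `T`. `-`, `.` and `?` are
#' treated as gap/unknown; any other symbol outside the alphabet (ambiguity
#' codes such as `N`, `R`, `Y`, `X`) is kept verbatim but treated as
#' indeterminate by the tests.
#'
#' @param seqs Named character vector of sequence strings (one per taxon), or
#'   a character matrix with one row per taxon and rownames as taxon labels.
#' @param alphabet `"nucleotide"`, `"amino_acid"`, or `NULL` to auto-detect
#'   from residue content (>= 90% A/C/G/T/U/N among non-gap characters means
#'   nucleotide).
#' @return An object of class `srh_alignment` with elements `taxa`, `mat`
#'   (character matrix), `alphabet` and `n_sites`.
#' @examples
#' aln <- srh_alignment(c(a = "ACGT", b = "ACGA"))
#' aln$n_sites
#' @export
srh_alignment <- function(seqs, alphabet = NULL) {
  if (is.matrix(seqs)) {
    mat <- seqs
    if (is.null(rownames(mat))) stop("sequence matrix must have taxon rownames")
  } else {
    if (is.null(names(seqs)) || any(!nzchar(names(seqs)))) {
      stop("sequences must be named with nonempty taxon labels")
    }
    lens <- nchar(seqs)
    if (length(unique(lens)) > 1L) {
      stop("length mismatch: sequences have unequal lengths (",
           paste(unique(lens), collapse = ", "), ")")
    }
    mat <- do.call(rbind, strsplit(unname(as.character(seqs)), ""))
    if (is.null(mat)) stop("alignment must contain at least one taxon")
    rownames(mat) <- names(seqs)
  }
  if (anyDuplicated(rownames(mat))) {
    stop("duplicate taxon names: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  }
  mat <- toupper(mat)
  if (is.null(alphabet)) alphabet <- .detect_alphabet(mat)
  alphabet <- match.arg(alphabet, c("nucleotide", "amino_acid"))
  if (alphabet == "nucleotide") mat[mat == "U"] <- "T"
  structure(
    list(taxa = rownames(mat), mat = mat, alphabet = alphabet,
         n_sites = ncol(mat)),
    class = "srh_alignment"
  )
}

.detect_alphabet <- function(mat) {
  res <- mat[!(mat %in% .gap_chars)]
  if (length(res) == 0L) return("nucleotide")
  frac <- mean(res %in% c("A", "C", "G", "T", "U", "N"))
  if (frac >= 0.9) "nucleotide" else "amino_acid"
}

#' @export
print.srh_alignment <- function(x, ...) {
  cat(sprintf("srh_alignment: %d taxa, %d sites (%s)\n",
              length(x$taxa), x$n_sites, x$alphabet))
  invisible(x)
}

#' Number of taxa in an alignment
#' @param aln An `srh_alignment`.
#' @return Integer count.
#' @export
n_taxa <- function(aln) length(aln$taxa)

.check_alignment <- function(aln) {
  if (!inherits(aln, "srh_alignment")) stop("expected an srh_alignment")
  invisible(aln)
}

#' Read a multiple sequence alignment
#'
#' Reads FASTA, relaxed PHYLIP (sequential or interleaved) or NEXUS `data`
#' blocks into an [srh_alignment]. Residues are uppercased and `U` is
#' normalized to `T` for nucleotide data.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"phylip"`, `"nexus"`.
#' @param alphabet Optional override of the auto-detected alphabet.
#' @return An [srh_alignment].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip", "nexus"),
                           alphabet = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- switch(format,
    fasta = {
      recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                                 forceDNAtolower = FALSE)
      setNames(vapply(recs, function(r) as.character(r)[1], ""), names(recs))
    },
    phylip = .read_phylip(path),
    nexus = {
      recs <- tryCatch(ape::read.nexus.data(path),
                       error = function(e) stop("format error reading NEXUS: ",
                                                conditionMessage(e)))
      vapply(recs, function(r) paste(r, collapse = ""), "")
    }
  )
  srh_alignment(seqs, alphabet = alphabet)
}

# Relaxed PHYLIP: "ntaxa nsites" header, then name/sequence records, either
# sequential (possibly wrapped over lines) or interleaved blocks separated by
# blank lines. Whitespace inside sequences is ignored.
.read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | seq_along(lines) > 1]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) < 2 || anyNA(suppressWarnings(as.integer(hdr[1:2])))) {
    stop("format error: PHYLIP header must be 'ntaxa nsites'")
  }
  ntax <- as.integer(hdr[1]); nsit <- as.integer(hdr[2])
  body <- lines[-1]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < ntax) stop("format error: fewer records than header ntaxa")
  nm <- character(ntax); sq <- character(ntax)
  # first block: name + sequence fragment
  for (i in seq_len(ntax)) {
    tok <- strsplit(trimws(body[i]), "\\s+")[[1]]
    nm[i] <- tok[1]
    sq[i] <- paste(tok[-1], collapse = "")
  }
  rest <- body[-seq_len(ntax)]
  if (length(rest) > 0) {
    # continuation lines: sequential wraps append to the last incomplete taxon;
    # interleaved blocks cycle through taxa in order. Both reduce to cycling
    # when each block keeps taxon order, which the format requires.
    i <- 1L
    for (ln in rest) {
      while (nchar(sq[((i - 1L) %% ntax) + 1L]) >= nsit) {
        i <- i + 1L
        if (i > ntax * 10000L) stop("format error: malformed PHYLIP body")
      }
      k <- ((i - 1L) %% ntax) + 1L
      sq[k] <- paste0(sq[k], gsub("\\s+", "", ln))
      i <- i + 1L
    }
  }
  if (any(nchar(sq) != nsit)) {
    stop("length mismatch: PHYLIP sequences do not match header site count")
  }
  setNames(sq, nm)
}

#' Write a multiple sequence alignment
#'
#' Writes FASTA, sequential relaxed PHYLIP, or a sequential NEXUS data block.
#' Round-trips with [read_alignment()] on taxon names, order, and content.
#'
#' @param aln An [srh_alignment].
#' @param path Output file path.
#' @param format One of `"fasta"`, `"phylip"`, `"nexus"`.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip", "nexus")) {
  .check_alignment(aln)
  format <- match.arg(format)
  if (length(aln$taxa) == 0L) stop("cannot write an alignment with no taxa")
  seqs <- apply(aln$mat, 1, paste, collapse = "")
  switch(format,
    fasta = seqinr::write.fasta(as.list(unname(seqs)), names = aln$taxa,
                                file.out = path, nbchar = 80),
    phylip = {
      con <- file(path, "w"); on.exit(close(con))
      writeLines(sprintf("%d %d", length(seqs), aln$n_sites), con)
      pad <- max(nchar(aln$taxa)) + 2L
      writeLines(sprintf("%-*s%s", pad, aln$taxa, seqs), con)
    },
    nexus = {
      recs <- lapply(seq_along(seqs), function(i) strsplit(seqs[i], "")[[1]])
      names(recs) <- aln$taxa
      ape::write.nexus.data(recs, file = path, interleaved = FALSE,
                            format = if (aln$alphabet == "nucleotide") "dna"
                                     else "protein")
    }
  )
  invisible(path)
}

#' Extract the columns of a partition
#'
#' @param aln An [srh_alignment].
#' @param part A [partition] (or bare integer vector of 1-based site indices).
#' @return Sub-alignment over the same taxa, columns restricted to the
#'   partition's sites in order.
#' @export
extract_partition <- function(aln, part) {
  .check_alignment(aln)
  idx <- if (inherits(part, "partition")) part$sites else as.integer(part)
  if (length(idx) == 0L) stop("partition has no sites")
  if (min(idx) < 1L || max(idx) > aln$n_sites) {
    stop("bounds error: partition sites outside [1, ", aln$n_sites, "]")
  }
  srh_alignment(aln$mat[, idx, drop = FALSE], alphabet = aln$alphabet)
}

#' Concatenate alignments column-wise
#'
#' All members must share the same taxon set (order may differ; the first
#' member's order is used). The companion partition scheme records the
#' coordinate block each member occupies in the concatenation.
#'
#' @param alns Nonempty list of [srh_alignment] objects.
#' @param names Optional partition names for the companion scheme; defaults to
#'   list names or `part1`, `part2`, ...
#' @return List with `alignment` (the concatenation) and `scheme` (a
#'   [partition_scheme] of the blocks).
#' @export
concatenate_alignments <- function(alns, names = NULL) {
  if (length(alns) == 0L) {
    stop("empty-set error: cannot concatenate an empty list of alignments")
  }
  lapply(alns, .check_alignment)
  taxa <- alns[[1]]$taxa
  if (is.null(names)) {
    names <- if (!is.null(base::names(alns))) base::names(alns)
             else paste0("part", seq_along(alns))
  }
  mats <- vector("list", length(alns))
  for (i in seq_along(alns)) {
    a <- alns[[i]]
    if (!setequal(a$taxa, taxa) || length(a$taxa) != length(taxa)) {
      stop("taxa error: alignment ", i, " has a different taxon set")
    }
    mats[[i]] <- a$mat[taxa, , drop = FALSE]
  }
  mat <- do.call(cbind, mats)
  widths <- vapply(alns, function(a) a$n_sites, 0L)
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  parts <- lapply(seq_along(alns), function(i) {
    partition(names[i], seq.int(starts[i], ends[i]))
  })
  list(alignment = srh_alignment(mat, alphabet = alns[[1]]$alphabet),
       scheme = partition_scheme(parts))
}

#' GC content of nucleotide sequences
#'
#' `(G + C) / (A + C + G + T)` over the requested scope; gaps and ambiguity
#' codes are ignored.
#'
#' @param aln A nucleotide [srh_alignment].
#' @param taxon A taxon label, or `NULL` for the whole alignment.
#' @return Fraction in `[0, 1]` (`NaN` if no unambiguous bases).
#' @export
gc_content <- function(aln, taxon = NULL) {
  .check_alignment(aln)
  if (aln$alphabet != "nucleotide") {
    stop("gc_content is inapplicable to amino-acid alignments")
  }
  chars <- if (is.null(taxon)) as.vector(aln$mat) else {
    if (!taxon %in% aln$taxa) stop("unknown taxon: ", taxon)
    aln$mat[taxon, ]
  }
  n_gc <- sum(chars %in% c("G", "C"))
  n_acgt <- sum(chars %in% c("A", "C", "G", "T"))
  n_gc / n_acgt
}
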