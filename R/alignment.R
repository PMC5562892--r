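#' Construct a multiple sequence alignment
#'
#' An `msa` is a rectangular character matrix (rows = sequences, columns =
#' alignment positions) over the residue alphabet plus the gap symbol
#' `"-"`. Invariants enforced on construction: all rows share one width,
#' `"."` gaps are normalized to `"-"`, case is normalized to upper, and
#' columns consisting entirely of gaps are deleted (they carry no signal).
#'
#' @param rows character vector of aligned strings, or a character matrix
#'   with one residue per cell.
#' @param ids row identifiers; defaults to `names(rows)`/`rownames(rows)`.
#' @param moltype `"protein"` or `"dna"`.
#' @param warn_allgap warn when all-gap columns are removed.
#' @return An `msa` object (character matrix with class and `moltype`
#'   attributes).
#' @export
msa <- function(rows, ids = NULL, moltype = c("protein", "dna"),
                warn_allgap = FALSE) {
  moltype <- match.arg(moltype)
  if (is.matrix(rows)) {
    mat <- toupper(rows)
    ids <- ids %||% rownames(rows)
  } else {
    ids <- ids %||% names(rows)
    rows <- toupper(as.character(rows))
    w <- nchar(rows)
    if (length(unique(w)) != 1L) {
      bad <- (ids %||% seq_along(rows))[w != max(w)]
      stop("ragged alignment rows (id(s): ", paste(bad, collapse = ", "), ")")
    }
    mat <- do.call(rbind, strsplit(rows, ""))
  }
  if (is.null(ids)) ids <- paste0("seq", seq_len(nrow(mat)))
  rownames(mat) <- ids
  mat[mat == "."] <- GAP
  ok <- c(alphabet(moltype), GAP)
  if (any(!mat %in% ok)) {
    stop("character(s) outside the ", moltype, " alphabet: ",
         paste(setdiff(unique(as.vector(mat)), ok), collapse = ", "))
  }
  mat <- drop_allgap_columns(mat, warn = warn_allgap)
  if (ncol(mat) == 0L) stop("alignment has no non-gap columns")
  if (any(rowSums(mat != GAP) == 0L)) {
    stop("empty sequence (all gaps) for id(s): ",
         paste(ids[rowSums(mat != GAP) == 0L], collapse = ", "))
  }
  structure(mat, moltype = moltype, class = c("msa", "matrix", "array"))
}

# keep only columns holding at least one residue
drop_allgap_columns <- function(mat, warn = FALSE) {
  keep <- colSums(mat != GAP) > 0L
  if (!all(keep)) {
    if (warn) warning(sum(!keep), " all-gap column(s) removed")
    at <- attributes(mat)
    mat <- mat[, keep, drop = FALSE]
    if (!is.null(at$class)) {
      attr(mat, "moltype") <- at$moltype
      class(mat) <- at$class
    }
  }
  mat
}

# rebuild the msa class after raw matrix surgery
as_msa <- function(mat, moltype) {
  structure(drop_allgap_columns(mat), moltype = moltype,
            class = c("msa", "matrix", "array"))
}

#' @export
print.msa <- function(x, ...) {
  cat("msa:", nrow(x), "x", ncol(x), paste0("(", attr(x, "moltype"), ")"), "\n")
  show <- min(ncol(x), 60L)
  for (i in seq_len(nrow(x))) {
    cat(sprintf("  %-12s %s%s\n", rownames(x)[i],
                paste(x[i, seq_len(show)], collapse = ""),
                if (ncol(x) > show) "..." else ""))
  }
  invisible(x)
}

#' Remove gaps from an alignment, recovering the input sequences
#'
#' @param al an [msa].
#' @return A [seq_records] object in row order.
#' @export
msa_strip_gaps <- function(al) {
  seqs <- apply(al, 1L, function(r) paste(r[r != GAP], collapse = ""))
  seq_records(seqs, rownames(al), attr(al, "moltype"))
}

#' Read an alignment from FASTA or Clustal format
#'
#' FASTA parsing is delegated to [Biostrings::readBStringSet()]; Clustal
#' parsing to [seqinr::read.alignment()]. All-gap columns are removed
#' with a warning; ragged rows are an error naming the offending ids.
#'
#' @param path alignment file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @param moltype `"protein"` or `"dna"`.
#' @return An [msa].
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "clustal"),
                           moltype = c("protein", "dna")) {
  format <- match.arg(format)
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clu)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path)
    rows <- as.character(x)
    ids <- sub("\\s.*$", "", names(x))
  } else {
    # the C-level parser copes with single-block files
    x <- seqinr::read.alignment(path, format = "clustal", oldclustal = TRUE)
    rows <- unlist(x$seq)
    ids <- x$nam
  }
  msa(rows, ids, moltype, warn_allgap = TRUE)
}

#' Write an alignment to FASTA or Clustal format
#'
#' @param al an [msa].
#' @param path output file.
#' @param format `"auto"` (by extension), `"fasta"` or `"clustal"`.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(al, path, format = c("auto", "fasta", "clustal")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(aln|clustal|clu)$", path, ignore.case = TRUE))
      "clustal" else "fasta"
  }
  if (format == "fasta") return(write_fasta(al, path))
  ids <- rownames(al)
  wid <- max(nchar(ids)) + 3L
  lines <- c("CLUSTAL W multiple sequence alignment", "")
  for (start in seq(1L, ncol(al), by = 60L)) {
    end <- min(start + 59L, ncol(al))
    for (i in seq_len(nrow(al))) {
      lines <- c(lines, sprintf("%-*s%s", wid, ids[i],
                                paste(al[i, start:end], collapse = "")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Randomly gap-pad sequences into an initial alignment
#'
#' All rows are padded with randomly placed gaps to a common width
#' `h = ceiling(L_max * (1 + gap_fraction))`, where `L_max` is the longest
#' input length; the gap budget is kept below one fifth of the longest
#' sequence, the regime in which the optimizer starts. Residue order is
#' preserved and the construction is reproducible from `seed`.
#'
#' @param records a [seq_records] object with at least 2 sequences.
#' @param gap_fraction proportion of extra width in `(0, 0.20]`;
#'   default 0.19.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return An [msa].
#' @export
initialize_alignment <- function(records, gap_fraction = 0.19, seed = NULL) {
  if (!inherits(records, "seq_records")) stop("`records` must be seq_records")
  if (length(records) < 2L) stop("need at least 2 sequences")
  if (!is.numeric(gap_fraction) || length(gap_fraction) != 1L ||
      gap_fraction <= 0 || gap_fraction > 0.20) {
    stop("`gap_fraction` must lie in (0, 0.20]")
  }
  if (!is.null(seed)) set.seed(seed)
  lens <- nchar(records)
  h <- as.integer(ceiling(max(lens) * (1 + gap_fraction)))
  mat <- matrix(GAP, length(records), h, dimnames = list(names(records), NULL))
  for (i in seq_along(records)) {
    pos <- sort(sample.int(h, lens[i]))
    mat[i, pos] <- strsplit(unclass(records)[[i]], "")[[1]]
  }
  as_msa(mat, attr(records, "moltype"))
}

# TRUE when stripping gaps reproduces `records` exactly (order included)
roundtrip_ok <- function(al, records) {
  s <- msa_strip_gaps(al)
  identical(unclass(s)[names(records)], unclass(records)[names(records)])
}
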