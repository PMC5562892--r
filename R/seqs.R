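#' @importFrom stats runif setNames rgeom wilcox.test
#' @importFrom utils head read.table write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

GAP <- "-"

#' Residue alphabets
#'
#' Core alphabets: 20 amino acids for proteins, 4 nucleotides for DNA.
#' Ambiguity codes (B, Z, X for protein; N for DNA) are accepted on input
#' and scored via the substitution matrix when present, otherwise 0.
#'
#' @param moltype `"protein"` or `"dna"`.
#' @param ambiguity include ambiguity codes in the returned set.
#' @return Character vector of single-letter residue codes.
#' @export
alphabet <- function(moltype = c("protein", "dna"), ambiguity = TRUE) {
  moltype <- match.arg(moltype)
  core <- if (moltype == "protein") {
    c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
      "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  } else {
    c("A", "C", "G", "T")
  }
  if (!ambiguity) return(core)
  c(core, if (moltype == "protein") c("B", "Z", "X") else "N")
}

#' Create a set of unaligned sequence records
#'
#' A `seq_records` object is a named character vector of residue strings
#' (upper case, gap-free) with a molecule-type attribute. It is the input
#' unit for alignment initialization and the ground truth the gap-strip
#' round-trip invariant is checked against.
#'
#' @param seqs character vector of residue strings.
#' @param ids sequence identifiers; defaults to `names(seqs)`.
#' @param moltype `"protein"` or `"dna"`.
#' @return A `seq_records` object.
#' @export
seq_records <- function(seqs, ids = names(seqs), moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (length(seqs) == 0L) stop("no sequences given")
  if (is.null(ids)) ids <- paste0("seq", seq_along(seqs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(seqs))
  if (any(!nzchar(seqs))) {
    stop("empty sequence for id(s): ", paste(ids[!nzchar(seqs)], collapse = ", "))
  }
  if (any(grepl("[-.]", seqs))) {
    stop("gap character in unaligned input (id(s): ",
         paste(ids[grepl("[-.]", seqs)], collapse = ", "), ")")
  }
  alph <- alphabet(moltype)
  bad <- vapply(strsplit(seqs, ""), function(ch) any(!ch %in% alph), logical(1))
  if (any(bad)) {
    chars <- setdiff(unique(unlist(strsplit(seqs[bad], ""))), alph)
    stop("character(s) outside the ", moltype, " alphabet: ",
         paste(chars, collapse = ", "), " (id(s): ",
         paste(ids[bad], collapse = ", "), ")")
  }
  structure(setNames(seqs, ids), moltype = moltype, class = "seq_records")
}

#' @export
print.seq_records <- function(x, ...) {
  cat(length(x), attr(x, "moltype"), "sequence(s), lengths",
      paste(range(nchar(x)), collapse = "-"), "\n")
  for (i in seq_along(x)) {
    s <- unclass(x)[i]
    cat(sprintf("  %-12s %s%s\n", names(s), substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  invisible(x)
}

#' Read unaligned sequences from a FASTA file
#'
#' Wraps [Biostrings::readBStringSet()] and validates the result as
#' gap-free residue strings over the declared alphabet. Offending
#' characters are reported with the file line they occur on.
#'
#' @param path FASTA file.
#' @param moltype `"protein"` or `"dna"`.
#' @return A [seq_records] object, file order preserved.
#' @export
read_fasta <- function(path, moltype = c("protein", "dna")) {
  moltype <- match.arg(moltype)
  if (!file.exists(path)) stop("file not found: ", path)
  x <- tryCatch(Biostrings::readBStringSet(path),
                error = function(e) stop("FASTA parse error in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (length(x) == 0L) stop("no FASTA entries in ", path)
  seqs <- toupper(as.character(x))
  ids <- sub("\\s.*$", "", names(x))
  tryCatch(seq_records(seqs, ids, moltype),
           error = function(e) .refasta_error(path, moltype, conditionMessage(e)))
}

# rescan the raw file to attach a line number to a validation failure
.refasta_error <- function(path, moltype, msg) {
  lines <- readLines(path, warn = FALSE)
  ok <- c(alphabet(moltype), GAP, ".")
  for (ln in seq_along(lines)) {
    l <- trimws(lines[ln])
    if (!nzchar(l) || startsWith(l, ">")) next
    ch <- unique(strsplit(toupper(l), "")[[1]])
    if (any(!ch %in% ok) || any(ch %in% c(GAP, "."))) {
      stop(msg, " [", path, " line ", ln, "]", call. = FALSE)
    }
  }
  stop(msg, " [", path, "]", call. = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param x a [seq_records] object, an [msa] alignment (rows written as
#'   aligned FASTA), or a named character vector.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "msa")) x <- setNames(apply(x, 1L, paste, collapse = ""), rownames(x))
  set <- Biostrings::BStringSet(setNames(as.character(x), names(x)))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}
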