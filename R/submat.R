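.bundled_matrices <- c("BLOSUM30", "BLOSUM45", "BLOSUM62", "BLOSUM80",
                       "PAM100", "PAM200")

#' Load a substitution matrix
#'
#' Accepts either the name of a bundled matrix (BLOSUM30, BLOSUM45,
#' BLOSUM62, BLOSUM80, PAM100, PAM200 -- shipped in NCBI text format
#' under `inst/extdata/matrices/`) or a path to any matrix file in NCBI
#' format (`#` comments, a header row of residues, then one labelled row
#' of integer scores per residue). The result is validated to be
#' symmetric and fully defined over its alphabet.
#'
#' @param name_or_path matrix name or file path.
#' @return A `substitution_matrix`: square numeric matrix with residue
#'   dimnames and a `name` attribute.
#' @export
load_substitution_matrix <- function(name_or_path) {
  if (inherits(name_or_path, "substitution_matrix")) return(name_or_path)
  nm <- toupper(name_or_path)
  if (nm %in% .bundled_matrices) {
    path <- system.file("extdata", "matrices", paste0(nm, ".txt"),
                        package = "bfoga", mustWork = TRUE)
    name <- nm
  } else if (file.exists(name_or_path)) {
    path <- name_or_path
    name <- basename(name_or_path)
  } else {
    stop("unknown substitution matrix: ", name_or_path,
         " (bundled: ", paste(.bundled_matrices, collapse = ", "),
         ", or give a readable NCBI-format file)")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!grepl("^\\s*#", lines)])
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("not an NCBI-format matrix: ", path)
  header <- strsplit(lines[1L], "\\s+")[[1]]
  k <- length(header)
  scores <- matrix(NA_real_, k, k, dimnames = list(header, header))
  for (l in lines[-1L]) {
    tok <- strsplit(l, "\\s+")[[1]]
    res <- tok[1L]
    vals <- suppressWarnings(as.numeric(tok[-1L]))
    if (!res %in% header) stop("row residue ", res, " not in header: ", path)
    scores[res, seq_along(vals)] <- vals
  }
  if (anyNA(scores)) {
    idx <- which(is.na(scores), arr.ind = TRUE)[1L, ]
    stop("matrix entry missing for pair (", header[idx[1L]], ", ",
         header[idx[2L]], ") in ", path)
  }
  asym <- which(scores != t(scores), arr.ind = TRUE)
  if (nrow(asym) > 0L) {
    stop("asymmetric matrix: scores[", header[asym[1L, 1L]], ",",
         header[asym[1L, 2L]], "] != scores[", header[asym[1L, 2L]], ",",
         header[asym[1L, 1L]], "] in ", path)
  }
  structure(scores, name = name,
            class = c("substitution_matrix", "matrix", "array"))
}

#' @export
print.substitution_matrix <- function(x, ...) {
  cat("substitution matrix", attr(x, "name"), "-",
      nrow(x), "x", ncol(x), "\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

# pairwise substitution score with graceful fallback for residues the
# matrix does not cover (ambiguity codes score 0)
submat_score <- function(mat, a, b) {
  out <- numeric(length(a))
  ok <- a %in% rownames(mat) & b %in% colnames(mat)
  out[ok] <- mat[cbind(a[ok], b[ok])]
  out
}

# positive mean residue mismatch score: |mean of off-diagonal entries|
# over the core residues the matrix covers
mean_mismatch_score <- function(mat, moltype = "protein") {
  core <- intersect(alphabet(moltype, ambiguity = FALSE), rownames(mat))
  m <- unclass(mat)[core, core, drop = FALSE]
  abs(mean(m[row(m) != col(m)]))
}
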