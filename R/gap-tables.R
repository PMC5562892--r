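#' Default residue-specific gap-propensity multipliers
#'
#' Relative gap propensities in the Pascarella--Argos style used by
#' progressive aligners: residues frequently observed next to gaps in
#' structural alignments (G, P, S, N ...) get multipliers below 1, those
#' rarely adjacent to gaps get multipliers above 1. Normalized so the
#' mean multiplier over the 20 amino acids is 1; fully overridable in
#' [objective_config()].
#'
#' @return Named numeric vector over the 20 amino acids.
#' @export
default_residue_gap_table <- function() {
  v <- c(A = 1.13, R = 0.72, N = 0.63, D = 0.96, C = 1.13, Q = 1.07,
         E = 1.31, G = 0.61, H = 1.00, I = 1.32, L = 1.21, K = 0.96,
         M = 1.29, F = 1.20, P = 0.74, S = 0.76, T = 0.89, W = 1.23,
         Y = 1.00, V = 1.25)
  v / mean(v)
}

# alignment columns (per sequence) that fall inside a hydrophilic
# stretch: a run of >= min_run consecutive hydrophilic residues of the
# ungapped sequence
.hydrophilic_columns <- function(al, set, min_run) {
  hyd <- strsplit(set, "")[[1]]
  out <- matrix(FALSE, nrow(al), ncol(al))
  for (i in seq_len(nrow(al))) {
    rescol <- which(al[i, ] != GAP)
    ishyd <- al[i, rescol] %in% hyd
    r <- rle(ishyd)
    stretch <- rep(r$values & r$lengths >= min_run, r$lengths)
    out[i, rescol[stretch]] <- TRUE
  }
  out
}

#' Build position-specific gap penalty tables
#'
#' Implements the variable (position-specific) gap penalty scheme. At
#' the pair level, for sequences of ungapped lengths `R` and `T`:
#' the opening cost becomes `(gap_open + log(min(R, T))) * nbar * m`
#' (with `nbar` the positive mean residue mismatch score of the
#' substitution matrix and `m` the pair's fractional percent identity on
#' its current projection), and the extension cost becomes
#' `gap_extend * (1 + |log(R / T)|)`. Along the alignment, a per-column
#' gap-opening modulation is applied with the first matching rule
#' winning:
#' \enumerate{
#'   \item inside an existing gap column: `x 0.3 * (rows without a gap / rows)`;
#'   \item within 8 columns of a gap column (`d` columns in between):
#'     `x (2 + (8 - d) * 2 / 8)`, i.e. 4 adjacent to the gap down to 2 at
#'     distance 8;
#'   \item in a hydrophilic stretch: `x 0.5`;
#'   \item otherwise: `x T[residue]`, the residue-specific propensity.
#' }
#' Extension costs carry no positional modulation. Natural logarithms
#' throughout.
#'
#' @param al an [msa].
#' @param gap_open,gap_extend positive base costs.
#' @param matrix substitution matrix (name, path or object).
#' @param hydrophilic_set,hydrophilic_run see [objective_config()].
#' @param residue_gap_table named multipliers; default
#'   [default_residue_gap_table()].
#' @return A `gap_tables` object: per-sequence-per-column opening
#'   modulation factors (`mod`), pair-level opening (`pair_open`) and
#'   extension (`pair_ext`) costs, and the alignment width they were
#'   built for.
#' @export
gap_penalty_tables <- function(al, gap_open = 10, gap_extend = 1,
                               matrix = "BLOSUM62",
                               hydrophilic_set = "GPSNDQEKR",
                               hydrophilic_run = 5L,
                               residue_gap_table = NULL) {
  stopifnot(gap_open > 0, gap_extend > 0)
  mat <- load_substitution_matrix(matrix)
  tab <- residue_gap_table %||% default_residue_gap_table()
  n <- nrow(al); h <- ncol(al)
  G <- unclass(al) == GAP
  lens <- rowSums(!G)
  if (any(lens == 0L)) stop("zero-length sequence in alignment")
  nbar <- mean_mismatch_score(mat, attr(al, "moltype"))

  # ---- pair-level rescaling -------------------------------------------
  pair_open <- matrix(0, n, n)
  pair_ext <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      R <- lens[i]; T <- lens[j]
      both_res <- !G[i, ] & !G[j, ]
      m <- if (any(both_res)) {
        mean(al[i, both_res] == al[j, both_res])
      } else 1
      if (m == 0) m <- 1 / min(R, T)   # keep the opening cost positive
      po <- (gap_open + log(min(R, T))) * nbar * m
      pe <- gap_extend * (1 + abs(log(R / T)))
      pair_open[i, j] <- pair_open[j, i] <- po
      pair_ext[i, j] <- pair_ext[j, i] <- pe
    }
  }

  # ---- per-column opening modulation ----------------------------------
  gapcol <- colSums(G) > 0L
  nogap_frac <- colSums(!G) / n
  # columns strictly between a position and its nearest gap column
  if (any(gapcol)) {
    gc <- which(gapcol)
    dist <- vapply(seq_len(h), function(y) min(abs(y - gc)) - 1L, integer(1))
  } else {
    dist <- rep.int(.Machine$integer.max, h)
  }
  shared <- rep(NA_real_, h)
  shared[gapcol] <- 0.3 * nogap_frac[gapcol]
  near <- !gapcol & dist <= 8L
  shared[near] <- 2 + (8 - dist[near]) * 2 / 8

  hydmat <- .hydrophilic_columns(al, toupper(hydrophilic_set),
                                 as.integer(hydrophilic_run))
  mod <- matrix(rep(shared, each = n), n, h)
  open_cells <- is.na(mod)                     # rules 3/4 apply per sequence
  if (any(open_cells)) {
    tmul <- tab[unclass(al)[open_cells]]
    tmul[is.na(tmul)] <- 1                     # residues absent from the table
    mod[open_cells] <- ifelse(hydmat[open_cells], 0.5, tmul)
  }
  structure(list(mod = mod, pair_open = pair_open, pair_ext = pair_ext,
                 width = h, n = n), class = "gap_tables")
}

#' Constant gap penalty tables
#'
#' Degenerate tables with no pair-level or positional variation: every
#' pair opens at `gap_open` and extends at `gap_extend`. Under these
#' tables [variable_gap_penalty()] equals [affine_gap_penalty()]
#' exactly, which is the reduction tests rely on.
#'
#' @param al an [msa].
#' @param gap_open,gap_extend constant costs.
#' @return A `gap_tables` object.
#' @export
constant_gap_tables <- function(al, gap_open = 10, gap_extend = 1) {
  n <- nrow(al); h <- ncol(al)
  structure(list(mod = matrix(1, n, h),
                 pair_open = matrix(gap_open, n, n),
                 pair_ext = matrix(gap_extend, n, n),
                 width = h, n = n), class = "gap_tables")
}

#' Variable (position-specific) gap penalty
#'
#' Same pairwise gap-run accounting as [affine_gap_penalty()], but each
#' run in sequence `a` of pair `(a, b)` charges
#' `GOP(a, b) = pair_open/2 * (mod[a, c] + mod[b, c])` at its opening
#' column `c` and the pair's extension cost per additional column.
#' Columns gapped in both rows of a pair are dropped before run
#' detection.
#'
#' @param al an [msa].
#' @param tables a [gap_penalty_tables()] (or [constant_gap_tables()])
#'   object built for this exact alignment.
#' @return Nonnegative penalty; 0 iff the alignment is gap-free.
#' @export
variable_gap_penalty <- function(al, tables) {
  if (!inherits(tables, "gap_tables")) stop("`tables` must be gap_tables")
  if (tables$width != ncol(al) || tables$n != nrow(al)) {
    stop("stale gap tables: built for ", tables$n, "x", tables$width,
         ", alignment is ", nrow(al), "x", ncol(al))
  }
  G <- unclass(al) == GAP
  n <- nrow(G)
  total <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- G[i, ] & G[j, ]
      cols <- which(!both)
      gi <- G[i, cols]; gj <- G[j, cols]
      for (rowpair in list(c(i, j), c(j, i))) {
        a <- rowpair[1L]; b <- rowpair[2L]
        g <- if (a == i) gi else gj
        r <- rle(g)
        if (!any(r$values)) next
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        for (k in which(r$values)) {
          copen <- cols[starts[k]]
          glen <- r$lengths[k]
          total <- total +
            tables$pair_open[a, b] / 2 *
              (tables$mod[a, copen] + tables$mod[b, copen]) +
            tables$pair_ext[a, b] * (glen - 1L)
        }
      }
    }
  }
  total
}
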