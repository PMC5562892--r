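#' Position weight matrix of an alignment
#'
#' For residue `x` and column `y`, `f(x, y)` is the count of `x` in
#' column `y` divided by the number of sequences. Gaps count in the
#' denominator but are not residues, so column frequencies sum to 1
#' minus the column's gap fraction.
#'
#' @param al an [msa].
#' @return A `pwm`: residues-by-columns frequency matrix with a
#'   `gap_fraction` attribute (per-column gap share).
#' @export
position_weight_matrix <- function(al) {
  alph <- alphabet(attr(al, "moltype"))
  n <- nrow(al); h <- ncol(al); k <- length(alph)
  code <- match(as.vector(unclass(al)), alph)    # NA for gaps
  col <- rep(seq_len(h), each = n)
  keep <- !is.na(code)
  cnt <- tabulate(code[keep] + (col[keep] - 1L) * k, nbins = k * h)
  freq <- matrix(cnt / n, nrow = k, ncol = h, dimnames = list(alph, NULL))
  structure(freq, gap_fraction = 1 - colSums(freq),
            class = c("pwm", "matrix", "array"))
}

#' Dominance value of a column
#'
#' The dominance `ce(y)` is the relative frequency of the most common
#' residue in column `y`; gaps never win the maximum.
#'
#' @param pwm a [position_weight_matrix()] result.
#' @param y column index (1-based), or `NULL` for all columns.
#' @return Numeric dominance value(s) in `(0, 1]`.
#' @export
dominance <- function(pwm, y = NULL) {
  if (is.null(y)) return(apply(unclass(pwm), 2L, max))
  if (any(y < 1L | y > ncol(pwm))) stop("column index out of range")
  apply(unclass(pwm)[, y, drop = FALSE], 2L, max)
}

# fast path used inside the optimizer: mean column dominance without
# building the pwm object
.col_dominance <- function(al) {
  alph <- alphabet(attr(al, "moltype"))
  n <- nrow(al); h <- ncol(al); k <- length(alph)
  code <- match(as.vector(unclass(al)), alph)
  col <- rep(seq_len(h), each = n)
  keep <- !is.na(code)
  cnt <- tabulate(code[keep] + (col[keep] - 1L) * k, nbins = k * h)
  cm <- matrix(cnt, nrow = k)
  best <- max.col(t(cm), ties.method = "first")
  cm[cbind(best, seq_len(h))] / n
}

#' Similarity objective
#'
#' The mean over columns of the dominance value: 1 for an alignment
#' whose every column is conserved, approaching `1/n` for unrelated
#' rows. Maximized by the optimizer.
#'
#' @param al an [msa].
#' @return Similarity in `(0, 1]`.
#' @export
similarity <- function(al) mean(.col_dominance(al))

# penalty of one row's gap runs: sum over maximal runs of
# open + extend * (length - 1)
.run_penalty <- function(gaps, open, extend) {
  r <- rle(gaps)
  len <- r$lengths[r$values]
  if (length(len) == 0L) return(0)
  sum(open + extend * (len - 1))
}

#' Affine gap penalty
#'
#' Summed over all unordered row pairs: columns gapped in both rows are
#' dropped from the pair projection (a shared gap carries no signal),
#' then every maximal gap run of length `g` in either projected row
#' contributes `gap_open + gap_extend * (g - 1)`. Grouping gaps into
#' fewer, longer runs therefore lowers the penalty. Minimized by the
#' optimizer.
#'
#' @param al an [msa].
#' @param gap_open,gap_extend positive costs, `gap_open >= gap_extend`.
#' @return Nonnegative penalty; 0 iff the alignment is gap-free.
#' @export
affine_gap_penalty <- function(al, gap_open = 10, gap_extend = 1) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0)
  G <- unclass(al) == GAP
  n <- nrow(G)
  total <- 0
  for (i in seq_len(n - 1L)) {
    gi0 <- G[i, ]
    for (j in (i + 1L):n) {
      gj0 <- G[j, ]
      both <- gi0 & gj0
      if (any(both)) {
        keep <- !both
        gi <- gi0[keep]; gj <- gj0[keep]
      } else {
        gi <- gi0; gj <- gj0
      }
      total <- total + .run_penalty(gi, gap_open, gap_extend) +
        .run_penalty(gj, gap_open, gap_extend)
    }
  }
  total
}

#' Non-gap percentage objective
#'
#' By default the share of alignment cells holding residues, in
#' `(0, 100]`; larger means fewer gaps, so the optimizer maximizes it.
#' `literal = TRUE` instead returns the gaps-to-residues ratio times 100
#' (the reciprocal convention some descriptions use).
#'
#' @param al an [msa].
#' @param literal use the gaps/residues ratio instead of the residue
#'   fraction.
#' @return Percentage.
#' @export
non_gap_percentage <- function(al, literal = FALSE) {
  gaps <- sum(unclass(al) == GAP)
  res <- length(al) - gaps
  if (literal) 100 * gaps / res else 100 * res / length(al)
}

#' Objective-function configuration
#'
#' Bundles the parameters of the three objectives. The substitution
#' matrix is resolved once here so repeated evaluations do not reload
#' it.
#'
#' @param gap_mode `"affine"` (constant costs) or `"variable"`
#'   (position-specific tables; see [gap_penalty_tables()]).
#' @param gap_open,gap_extend base gap costs, `gap_open >= gap_extend > 0`.
#' @param matrix substitution matrix name or path (used by the variable
#'   mode's pair-level rescaling).
#' @param ngp_literal report the literal gaps/residues ratio as the
#'   non-gap objective.
#' @param hydrophilic_set string of residues counted as hydrophilic.
#' @param hydrophilic_run minimum consecutive hydrophilic residues that
#'   form a stretch.
#' @param residue_gap_table named numeric gap-propensity multipliers per
#'   residue; default [default_residue_gap_table()].
#' @return An `objective_config` list.
#' @export
objective_config <- function(gap_mode = c("affine", "variable"),
                             gap_open = 10, gap_extend = 1,
                             matrix = "BLOSUM62", ngp_literal = FALSE,
                             hydrophilic_set = "GPSNDQEKR",
                             hydrophilic_run = 5L,
                             residue_gap_table = NULL) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(gap_open >= gap_extend, gap_extend > 0, hydrophilic_run >= 1)
  structure(list(
    gap_mode = gap_mode, gap_open = gap_open, gap_extend = gap_extend,
    matrix = load_substitution_matrix(matrix), ngp_literal = ngp_literal,
    hydrophilic_set = toupper(hydrophilic_set),
    hydrophilic_run = as.integer(hydrophilic_run),
    residue_gap_table = residue_gap_table %||% default_residue_gap_table()
  ), class = "objective_config")
}

#' Evaluate the three objectives of an alignment
#'
#' Returns the multi-objective fitness: similarity (maximized), gap
#' penalty in the configured mode (minimized), and non-gap percentage
#' (maximized). A pure function of the alignment and configuration.
#'
#' @param al an [msa].
#' @param config an [objective_config()].
#' @return An `objective_vector`: named numeric
#'   `(similarity, gap_penalty, ngp)` with an `orientation` attribute
#'   (`+1` maximize, `-1` minimize).
#' @export
evaluate_alignment <- function(al, config = objective_config()) {
  gap <- if (config$gap_mode == "affine") {
    affine_gap_penalty(al, config$gap_open, config$gap_extend)
  } else {
    variable_gap_penalty(al, gap_penalty_tables(
      al, config$gap_open, config$gap_extend, config$matrix,
      config$hydrophilic_set, config$hydrophilic_run,
      config$residue_gap_table))
  }
  # under the literal convention more gaps raise the ratio, so its
  # optimization direction flips to keep "discourage gaps" semantics
  structure(c(similarity = similarity(al), gap_penalty = gap,
              ngp = non_gap_percentage(al, config$ngp_literal)),
            orientation = c(1, -1, if (config$ngp_literal) -1 else 1),
            class = "objective_vector")
}
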