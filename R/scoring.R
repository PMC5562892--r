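# residue ordinals per cell: k for the k-th residue of its row, NA at gaps
.residue_ordinals <- function(al) {
  res <- unclass(al) != GAP
  ord <- t(apply(res, 1L, cumsum))
  ord[!res] <- NA_integer_
  ord
}

#' Aligned residue pairs of an alignment
#'
#' For every column and every unordered row pair where both rows hold a
#' residue, records the pair of residue ordinals (gap-free positions).
#' Because ordinals are alignment-coordinate independent, two
#' alignments of the same sequences can be compared by set operations
#' on these keys.
#'
#' @param al an [msa].
#' @return Character vector of keys `"rowA:ordA|rowB:ordB"` with
#'   `rowA < rowB`.
#' @export
residue_pair_map <- function(al) {
  ord <- .residue_ordinals(al)
  n <- nrow(ord)
  keys <- character(0)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- !is.na(ord[i, ]) & !is.na(ord[j, ])
      if (any(both)) {
        keys <- c(keys, paste0(i, ":", ord[i, both], "|", j, ":", ord[j, both]))
      }
    }
  }
  keys
}

# both alignments must carry the same sequences (ids and residues)
.check_same_sequences <- function(test, ref) {
  st <- msa_strip_gaps(test); sr <- msa_strip_gaps(ref)
  if (!setequal(names(st), names(sr))) {
    stop("test and reference align different sequence ids")
  }
  if (!identical(unclass(st)[names(sr)], unclass(sr)[names(sr)])) {
    stop("test and reference sequences differ after gap stripping")
  }
  # row order must agree for ordinal keys to be comparable
  ref[rownames(test), , drop = FALSE]
}

#' Sum-of-pairs score against a reference alignment
#'
#' Fraction of the reference's aligned residue pairs that the test
#' alignment reproduces: 1 when every reference pair is recovered.
#'
#' @param test,ref [msa] objects over the same sequences.
#' @return Score in `[0, 1]`.
#' @export
sum_of_pairs <- function(test, ref) {
  refm <- .check_same_sequences(test, ref)
  refm <- as_msa(refm, attr(test, "moltype"))
  rp <- residue_pair_map(refm)
  if (length(rp) == 0L) return(NaN)
  tp <- residue_pair_map(test)
  length(intersect(tp, rp)) / length(rp)
}

#' Total column score against a reference alignment
#'
#' Fraction of test columns whose complete residue-ordinal tuple
#' (including which rows are gapped) occurs as a column of the
#' reference.
#'
#' @param test,ref [msa] objects over the same sequences.
#' @return Score in `[0, 1]`.
#' @export
total_column_score <- function(test, ref) {
  refm <- .check_same_sequences(test, ref)
  refm <- as_msa(refm, attr(test, "moltype"))
  colkey <- function(al) {
    ord <- .residue_ordinals(al)
    ord[is.na(ord)] <- -1L
    apply(ord, 2L, paste, collapse = ",")
  }
  mean(colkey(test) %in% colkey(refm))
}

#' Score a test alignment against a reference
#'
#' @param test,ref [msa] objects over the same sequences.
#' @return A one-row data frame: `sp`, `tcs`, test and reference column
#'   counts, and the number of sequences.
#' @export
score_alignment <- function(test, ref) {
  data.frame(sp = sum_of_pairs(test, ref),
             tcs = total_column_score(test, ref),
             columns_test = ncol(test), columns_ref = ncol(ref),
             n_sequences = nrow(test))
}

#' Wilcoxon matched-pair signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired per-dataset scores.
#' Zero-difference pairs are dropped (the standard procedure); with all
#' pairs tied the p-value is 1. Exact p-values are used whenever
#' [stats::wilcox.test()] can compute them (no ties, n < 50).
#'
#' @param scores_a,scores_b equal-length paired score vectors.
#' @param alpha significance level (default the conventional 5%).
#' @return List: `p_value`, `significant` (`p < alpha`), `statistic`
#'   (signed-rank V), `n_used` (pairs after zero removal).
#' @export
wilcoxon_compare <- function(scores_a, scores_b, alpha = 0.05) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have equal length")
  }
  d <- scores_a - scores_b
  keep <- d != 0
  if (!any(keep)) {
    return(list(p_value = 1, significant = FALSE, statistic = NA_real_,
                n_used = 0L))
  }
  w <- suppressWarnings(stats::wilcox.test(scores_a[keep], scores_b[keep],
                                           paired = TRUE))
  list(p_value = w$p.value, significant = w$p.value < alpha,
       statistic = unname(w$statistic), n_used = sum(keep))
}
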