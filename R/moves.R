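# A move relocates a block of j gap characters within one row.  `src`
# and `dst` are insertion points (0-based) into the row with the block
# removed: the block occupies columns src+1 .. src+j before the move and
# dst+1 .. dst+j after it.  Residue order is untouched by construction,
# and swapping src and dst inverts the move exactly (as long as no
# all-gap column is dropped in between).

#' Construct a gap-relocation move
#'
#' @param kind one of `"gap_shift"`, `"gap_block_shift"`, `"gap_split"`,
#'   `"gap_merge"`, or `"none"` (no-op).
#' @param row row index the move acts on.
#' @param j number of gaps relocated.
#' @param src,dst 0-based insertion points of the block in the gap-less
#'   frame of the row (see details in the source).
#' @param direction `"left"` or `"right"` token recorded for the tumble
#'   statistics.
#' @param magnitude requested shift in columns.
#' @return An `msa_move`.
#' @export
msa_move <- function(kind, row = NA_integer_, j = 0L, src = NA_integer_,
                     dst = NA_integer_, direction = NA_character_,
                     magnitude = NA_integer_) {
  structure(list(kind = kind, row = as.integer(row), j = as.integer(j),
                 src = as.integer(src), dst = as.integer(dst),
                 direction = direction, magnitude = as.integer(magnitude)),
            class = "msa_move")
}

#' Invert a move
#'
#' The inverse relocates the same block back: `src` and `dst` swap and
#' the direction token flips.
#'
#' @param move an [msa_move()].
#' @return The inverse `msa_move`.
#' @export
invert_move <- function(move) {
  msa_move(move$kind, move$row, move$j, src = move$dst, dst = move$src,
           direction = switch(move$direction, left = "right",
                              right = "left", move$direction),
           magnitude = move$magnitude)
}

#' Apply a move to an alignment
#'
#' @param al an [msa].
#' @param move an [msa_move()].
#' @param drop_allgap delete columns left entirely gapped by the move
#'   (the alignment invariant); disable only for transient states inside
#'   a chemotactic swim.
#' @return The moved [msa].
#' @export
apply_move <- function(al, move, drop_allgap = TRUE) {
  if (move$kind == "none" || move$j == 0L || move$src == move$dst) return(al)
  r <- al[move$row, ]
  block <- (move$src + 1L):(move$src + move$j)
  if (any(r[block] != GAP)) stop("move does not address a gap block")
  red <- r[-block]
  al[move$row, ] <- append(red, rep(GAP, move$j), after = move$dst)
  if (drop_allgap) al <- drop_allgap_columns(al)
  al
}

# gap runs of one row: data.frame(start insertion point src, length)
.gap_runs <- function(row) {
  r <- rle(row == GAP)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  # src = retained characters before the block = start column - 1 minus
  # gaps already removed? no: the block is removed as a whole, everything
  # before it is retained, so src = start - 1 counted in retained chars
  # only when no other block precedes... all other gaps ARE retained, so
  # src = start - 1.
  data.frame(src = starts[idx] - 1L, len = r$lengths[idx])
}

#' Sample a random move (tumble)
#'
#' A tumble draws a move kind, an acting row among rows that carry gaps,
#' a gap or gap run, a direction (left/right with equal probability) and
#' a magnitude of at most `max_step` columns, all independently of any
#' previous move. Rows without gaps, or shifts with no room, yield a
#' degenerate move that leaves the alignment unchanged.
#'
#' @param al an [msa].
#' @param max_step largest shift magnitude (unit run length).
#' @return An [msa_move()].
#' @export
tumble <- function(al, max_step = 3L) {
  G <- unclass(al) == GAP
  rows <- which(rowSums(G) > 0L)
  if (length(rows) == 0L) return(msa_move("none"))
  row <- rows[sample.int(length(rows), 1L)]
  runs <- .gap_runs(al[row, ])
  kinds <- c("gap_shift", "gap_block_shift",
             if (any(runs$len >= 2L)) "gap_split",
             if (nrow(runs) >= 2L) "gap_merge")
  kind <- kinds[sample.int(length(kinds), 1L)]
  direction <- c("left", "right")[sample.int(2L, 1L)]
  magnitude <- sample.int(max_step, 1L)
  red_len <- ncol(al) - 0L  # length of row with block removed, set below

  pick_run <- function(subset = seq_len(nrow(runs))) {
    runs[subset[sample.int(length(subset), 1L)], ]
  }
  clamp <- function(x, lo, hi) min(max(x, lo), hi)

  if (kind == "gap_shift") {
    run <- pick_run()
    # move a single gap off one end of the run
    j <- 1L
    src <- if (direction == "left") run$src else run$src + run$len - 1L
    red_len <- ncol(al) - j
    dst <- clamp(src + if (direction == "left") -magnitude else magnitude,
                 0L, red_len)
  } else if (kind == "gap_block_shift") {
    run <- pick_run()
    j <- run$len
    src <- run$src
    red_len <- ncol(al) - j
    dst <- clamp(src + if (direction == "left") -magnitude else magnitude,
                 0L, red_len)
  } else if (kind == "gap_split") {
    run <- pick_run(which(runs$len >= 2L))
    j <- sample.int(run$len - 1L, 1L)
    src <- if (direction == "left") run$src else run$src + (run$len - j)
    red_len <- ncol(al) - j
    dst <- sample.int(red_len + 1L, 1L) - 1L
  } else { # gap_merge: park one run against another
    ri <- sample.int(nrow(runs), 2L)
    run <- runs[ri[1L], ]; target <- runs[ri[2L], ]
    j <- run$len
    src <- run$src
    red_len <- ncol(al) - j
    # insertion point of the target run once `run` is removed
    dst <- if (target$src > run$src) target$src - j else target$src
    dst <- clamp(dst, 0L, red_len)
  }
  msa_move(kind, row, j, src, dst, direction, magnitude)
}
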