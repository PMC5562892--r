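.default_orientation <- c(1, -1, 1)

# objectives as an N x M matrix plus one orientation vector
.obj_matrix <- function(pop) {
  if (is.matrix(pop)) {
    ori <- attr(pop, "orientation") %||% .default_orientation[seq_len(ncol(pop))]
    return(structure(pop, orientation = ori))
  }
  m <- do.call(rbind, lapply(pop, as.numeric))
  ori <- attr(pop[[1L]], "orientation") %||% .default_orientation[seq_len(ncol(m))]
  structure(m, orientation = ori)
}

#' Pareto dominance between two objective vectors
#'
#' `a` dominates `b` when, after orienting every objective so larger is
#' better, `a` is no worse on all objectives and strictly better on at
#' least one. A strict partial order: irreflexive, antisymmetric and
#' transitive.
#'
#' @param a,b numeric objective vectors of equal length.
#' @param orientation `+1` per maximized objective, `-1` per minimized;
#'   taken from `a`'s `orientation` attribute when present, defaulting
#'   to `(max, min, max)`.
#' @return Logical.
#' @export
dominates <- function(a, b, orientation = NULL) {
  ori <- orientation %||% attr(a, "orientation") %||%
    .default_orientation[seq_along(a)]
  d <- (as.numeric(a) - as.numeric(b)) * ori
  all(d >= 0) && any(d > 0)
}

#' Fast non-dominated sorting
#'
#' Partitions a population of objective vectors into fronts: front 1 is
#' the non-dominated set, front 2 the non-dominated set once front 1 is
#' removed, and so on. Every individual appears in exactly one front.
#'
#' @param pop list of objective vectors, or an N x M numeric matrix
#'   (rows = individuals).
#' @param orientation see [dominates()].
#' @return List with `fronts` (list of index vectors) and `rank`
#'   (integer vector; 1 = first front).
#' @export
non_dominated_sort <- function(pop, orientation = NULL) {
  m <- .obj_matrix(pop)
  ori <- orientation %||% attr(m, "orientation")
  n <- nrow(m)
  if (n == 0L) stop("empty population")
  om <- sweep(m, 2L, ori, `*`)
  dom_count <- integer(n)                 # how many dominate me
  dominated <- vector("list", n)          # whom do I dominate
  for (p in seq_len(n)) {
    dp <- sweep(om, 2L, om[p, ], `-`)     # others minus p
    p_dom <- rowSums(dp <= 0) == ncol(om) & rowSums(dp < 0) > 0  # p dominates
    dom_p <- rowSums(dp >= 0) == ncol(om) & rowSums(dp > 0) > 0  # dominates p
    dominated[[p]] <- which(p_dom)
    dom_count[p] <- sum(dom_p)
  }
  rank <- integer(n)
  fronts <- list()
  current <- which(dom_count == 0L)
  f <- 0L
  while (length(current) > 0L) {
    f <- f + 1L
    rank[current] <- f
    fronts[[f]] <- current
    for (p in current) {
      dom_count[dominated[[p]]] <- dom_count[dominated[[p]]] - 1L
    }
    nxt <- which(dom_count == 0L & rank == 0L)
    current <- nxt
  }
  list(fronts = fronts, rank = rank)
}

#' Crowding distance within a front
#'
#' Per objective, individuals are sorted and each interior individual
#' accumulates the gap between its two neighbors, normalized by the
#' front's range on that objective (a zero range contributes nothing).
#' The boundary individuals of every objective get `Inf`, so extreme
#' solutions are always preferred at equal rank.
#'
#' @param front list of objective vectors or numeric matrix (one row per
#'   front member).
#' @return Numeric vector of crowding distances.
#' @export
crowding_distance <- function(front) {
  m <- .obj_matrix(front)
  n <- nrow(m)
  if (n <= 2L) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(m))) {
    v <- m[, k]
    ord <- order(v)
    d[ord[c(1L, n)]] <- Inf
    rng <- v[ord[n]] - v[ord[1L]]
    if (rng > 0) {
      mid <- ord[2:(n - 1L)]
      d[mid] <- d[mid] + (v[ord[3:n]] - v[ord[1:(n - 2L)]]) / rng
    }
  }
  d
}

# ranks and crowding distances for a whole population
pareto_rank <- function(pop, orientation = NULL) {
  m <- .obj_matrix(pop)
  nds <- non_dominated_sort(m, orientation)
  crowd <- numeric(nrow(m))
  for (fr in nds$fronts) crowd[fr] <- crowding_distance(m[fr, , drop = FALSE])
  list(rank = nds$rank, crowding = crowd, fronts = nds$fronts)
}

#' Crowded tournament selection
#'
#' Draws `k` distinct candidates uniformly and returns the index of the
#' winner: lowest Pareto rank, ties broken by largest crowding distance,
#' remaining ties at random.
#'
#' @param rank integer Pareto ranks (1 = best front).
#' @param crowding crowding distances.
#' @param k tournament size (default binary).
#' @return Selected population index.
#' @export
crowded_tournament <- function(rank, crowding, k = 2L) {
  n <- length(rank)
  if (k < 1L || k > n) stop("tournament size k must lie in [1, population size]")
  cand <- sample.int(n, k)
  best <- cand[rank[cand] == min(rank[cand])]
  if (length(best) > 1L) {
    best <- best[crowding[best] == max(crowding[best])]
  }
  if (length(best) > 1L) best <- best[sample.int(length(best), 1L)]
  best
}
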