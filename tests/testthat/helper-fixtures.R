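# shared fixtures, all built in code

make_msa <- function(rows, ids = NULL, moltype = "protein") {
  msa(rows, ids, moltype)
}

# random gap-free protein records with reproducible content
random_records <- function(n, lens, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- alphabet("protein", ambiguity = FALSE)
  seqs <- vapply(rep_len(lens, n),
                 function(L) paste(sample(aa, L, replace = TRUE),
                                   collapse = ""),
                 character(1))
  seq_records(seqs, paste0("s", seq_len(n)), "protein")
}

# random population of 3-objective vectors on the default orientation
random_objectives <- function(n) {
  m <- cbind(similarity = runif(n), gap_penalty = runif(n, 0, 100),
             ngp = runif(n, 0, 100))
  lapply(seq_len(n), function(i) {
    structure(m[i, ], orientation = c(1, -1, 1))
  })
}

# brute-force Pareto front partition by repeated removal
brute_fronts <- function(objs) {
  idx <- seq_along(objs)
  fronts <- list()
  while (length(idx) > 0L) {
    nd <- idx[vapply(idx, function(p) {
      !any(vapply(idx, function(q) dominates(objs[[q]], objs[[p]]),
                  logical(1)))
    }, logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    idx <- setdiff(idx, nd)
  }
  fronts
}

# literal per-column double-loop SP oracle: F_iab = 1 iff the residue
# pair in a test column is aligned in some reference column
brute_sum_of_pairs <- function(test, ref) {
  ords <- function(al) {
    res <- unclass(al) != "-"
    o <- t(apply(res, 1, cumsum)); o[!res] <- NA; o
  }
  to <- ords(test); ro <- ords(ref)
  n <- nrow(test)
  count <- function(om) {
    s <- 0L
    for (col in seq_len(ncol(om))) {
      for (a in seq_len(n - 1L)) {
        for (b in (a + 1L):n) {
          if (!is.na(om[a, col]) && !is.na(om[b, col])) s <- s + 1L
        }
      }
    }
    s
  }
  num <- 0L
  for (col in seq_len(ncol(test))) {
    for (a in seq_len(n - 1L)) {
      for (b in (a + 1L):n) {
        if (is.na(to[a, col]) || is.na(to[b, col])) next
        for (rcol in seq_len(ncol(ref))) {
          if (!is.na(ro[a, rcol]) && !is.na(ro[b, rcol]) &&
              ro[a, rcol] == to[a, col] && ro[b, rcol] == to[b, col]) {
            num <- num + 1L
            break
          }
        }
      }
    }
  }
  num / count(ro)
}

# brute-force TCS oracle: full column tuple must occur in the reference
brute_total_column_score <- function(test, ref) {
  ords <- function(al) {
    res <- unclass(al) != "-"
    o <- t(apply(res, 1, cumsum)); o[!res] <- -1L; o
  }
  to <- ords(test); ro <- ords(ref)
  hits <- 0L
  for (col in seq_len(ncol(test))) {
    for (rcol in seq_len(ncol(ref))) {
      if (all(to[, col] == ro[, rcol])) { hits <- hits + 1L; break }
    }
  }
  hits / ncol(test)
}

# exact two-sided signed-rank p-value by enumerating all sign vectors
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.vector(signs %*% r)
  min(1, 2 * min(mean(v_null <= v_obs), mean(v_null >= v_obs)))
}
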