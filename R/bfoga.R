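#' Optimizer configuration
#'
#' Parameters of the bacterial-foraging / genetic hybrid. Per outer
#' generation the population runs `disp_steps` elimination-dispersal
#' blocks, each holding `repro_steps` reproduction blocks of
#' `chem_steps` chemotactic sweeps, followed by the genetic phase
#' (selection, crossover, mutation) and elimination-dispersal.
#'
#' @param pop_size number of bacteria (candidate alignments); must be
#'   even so reproduction can split the population in half.
#' @param chem_steps chemotactic sweeps per reproduction block.
#' @param swim_length maximum number of times an improving move is
#'   reapplied in the same direction (default 5).
#' @param repro_steps reproduction blocks per dispersal block.
#' @param disp_steps elimination-dispersal blocks per generation.
#' @param disp_prob per-bacterium probability of dispersal to a fresh
#'   random alignment.
#' @param crossover_frac fraction of the population replaced by
#'   crossover offspring (default 0.3).
#' @param mutation_rate per-offspring mutation probability (default 0.8).
#' @param generations outer cycles (default 500).
#' @param gap_fraction initialization gap budget, see
#'   [initialize_alignment()].
#' @param tournament_k crowded-tournament size (default binary).
#' @param max_step largest tumble shift in columns.
#' @param seed integer seed making the whole run reproducible.
#' @param objective an [objective_config()].
#' @return A `bfoga_config` list.
#' @export
bfoga_config <- function(pop_size = 20L, chem_steps = 5L, swim_length = 5L,
                         repro_steps = 2L, disp_steps = 1L,
                         disp_prob = 0.25, crossover_frac = 0.3,
                         mutation_rate = 0.8, generations = 500L,
                         gap_fraction = 0.19, tournament_k = 2L,
                         max_step = 3L, seed = NULL,
                         objective = objective_config()) {
  stopifnot(pop_size >= 2L, chem_steps >= 1L, swim_length >= 0L,
            repro_steps >= 1L, disp_steps >= 1L,
            disp_prob >= 0, disp_prob <= 1,
            crossover_frac >= 0, crossover_frac <= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            generations >= 0L, tournament_k >= 1L, max_step >= 1L)
  if (pop_size %% 2L != 0L) {
    stop("`pop_size` must be even (reproduction duplicates the healthier half)")
  }
  structure(list(pop_size = as.integer(pop_size),
                 chem_steps = as.integer(chem_steps),
                 swim_length = as.integer(swim_length),
                 repro_steps = as.integer(repro_steps),
                 disp_steps = as.integer(disp_steps),
                 disp_prob = disp_prob, crossover_frac = crossover_frac,
                 mutation_rate = mutation_rate,
                 generations = as.integer(generations),
                 gap_fraction = gap_fraction,
                 tournament_k = as.integer(tournament_k),
                 max_step = as.integer(max_step), seed = seed,
                 objective = objective), class = "bfoga_config")
}

new_bacterium <- function(al, config) {
  list(al = al, obj = evaluate_alignment(al, config))
}

#' One chemotactic step of a bacterium
#'
#' Tumble to draw a random move and apply it. If the moved alignment
#' Pareto-dominates the current one the bacterium "swims": the same
#' move (same direction and magnitude) is reapplied while each
#' application keeps dominating, at most `swim_length` times. A
#' non-dominating but non-dominated tumble is kept (sideways step); a
#' dominated one is reverted.
#'
#' @param bact a bacterium: list with elements `al` (the [msa]) and
#'   `obj` (its objective vector).
#' @param cfg a [bfoga_config()].
#' @param move optional fixed move (bypasses the tumble; used in tests).
#' @return The updated bacterium.
#' @export
chemotaxis_step <- function(bact, cfg, move = NULL) {
  mv <- move %||% tumble(bact$al, cfg$max_step)
  if (mv$kind == "none") return(bact)
  config <- cfg$objective
  # keep coordinates stable during the swim: defer all-gap column drops
  cand_al <- apply_move(bact$al, mv, drop_allgap = FALSE)
  cand_obj <- evaluate_alignment(drop_allgap_columns(cand_al), config)
  if (dominates(cand_obj, bact$obj)) {
    cur_al <- cand_al; cur_obj <- cand_obj
    step <- if (mv$direction == "left") -mv$magnitude else mv$magnitude
    src <- mv$dst
    swims <- 0L
    while (swims < cfg$swim_length) {
      dst <- min(max(src + step, 0L), ncol(cur_al) - mv$j)
      if (dst == src) break
      nxt <- msa_move(mv$kind, mv$row, mv$j, src, dst, mv$direction,
                      mv$magnitude)
      nxt_al <- apply_move(cur_al, nxt, drop_allgap = FALSE)
      nxt_obj <- evaluate_alignment(drop_allgap_columns(nxt_al), config)
      if (!dominates(nxt_obj, cur_obj)) break
      cur_al <- nxt_al; cur_obj <- nxt_obj; src <- dst
      swims <- swims + 1L
    }
    al <- drop_allgap_columns(cur_al)
    return(list(al = al, obj = cur_obj))
  }
  if (!dominates(bact$obj, cand_obj)) {
    return(list(al = drop_allgap_columns(cand_al), obj = cand_obj))
  }
  bact
}

#' Distance between two alignments' gap sets
#'
#' Size of the symmetric difference of the (row, column) gap coordinate
#' sets, optionally normalized by the total gap count of both
#' alignments. Zero iff the gap patterns coincide; symmetric in its
#' arguments.
#'
#' @param a,b [msa] objects over the same sequences.
#' @param normalize divide by the summed gap counts.
#' @return Nonnegative distance.
#' @export
gap_set_distance <- function(a, b, normalize = TRUE) {
  key <- function(al) {
    idx <- which(unclass(al) == GAP, arr.ind = TRUE)
    paste(idx[, 1L], idx[, 2L])
  }
  ka <- key(a); kb <- key(b)
  sym <- length(setdiff(ka, kb)) + length(setdiff(kb, ka))
  if (!normalize) return(sym)
  tot <- length(ka) + length(kb)
  if (tot == 0L) 0 else sym / tot
}

#' Swarming penalty of a population
#'
#' The population's fittest bacterium (lowest Pareto rank, ties broken
#' by highest crowding distance) attracts the others: every bacterium
#' is charged its gap-set distance to the fittest, which itself gets 0.
#' The penalty is added to the health tuple so that, at equal rank and
#' crowding, bacteria near the current best are considered healthier.
#'
#' @param pop list of bacteria.
#' @param rank,crowding population ranks and crowding distances (from
#'   the Pareto layer); computed here when missing.
#' @return Numeric penalties, one per bacterium.
#' @export
swarming_penalty <- function(pop, rank = NULL, crowding = NULL) {
  if (is.null(rank) || is.null(crowding)) {
    pr <- pareto_rank(lapply(pop, `[[`, "obj"))
    rank <- pr$rank; crowding <- pr$crowding
  }
  fit <- order(rank, -crowding)[1L]
  vapply(pop, function(b) gap_set_distance(b$al, pop[[fit]]$al), numeric(1))
}

# health ordering: rank, then -crowding, then swarming penalty, then
# index; lower is healthier
health_order <- function(rank, crowding, penalty) {
  order(rank, -crowding, penalty, seq_along(rank))
}

#' Reproduction phase
#'
#' The healthier half of the population (health = Pareto rank, ties by
#' crowding distance then swarming penalty then index) survives and is
#' duplicated in place of the less healthy half, keeping the population
#' size constant.
#'
#' @param pop list of bacteria (even length).
#' @param rank,crowding,penalty health components; computed when missing.
#' @return List of bacteria of the same length.
#' @export
reproduction <- function(pop, rank = NULL, crowding = NULL, penalty = NULL) {
  n <- length(pop)
  if (n %% 2L != 0L) stop("population size must be even for reproduction")
  if (is.null(rank) || is.null(crowding)) {
    pr <- pareto_rank(lapply(pop, `[[`, "obj"))
    rank <- pr$rank; crowding <- pr$crowding
  }
  if (is.null(penalty)) penalty <- swarming_penalty(pop, rank, crowding)
  top <- health_order(rank, crowding, penalty)[seq_len(n %/% 2L)]
  pop[c(top, top)]
}

#' Select crossover parent pairs
#'
#' Draws `ceiling(crossover_frac * pop_size / 2)` parent pairs by
#' crowded tournament; a bacterium may parent several pairs.
#'
#' @param pop list of bacteria.
#' @param cfg a [bfoga_config()].
#' @param rank,crowding Pareto layer results; computed when missing.
#' @return List of length-2 integer vectors (parent indices).
#' @export
select_parents <- function(pop, cfg, rank = NULL, crowding = NULL) {
  npairs <- ceiling(cfg$crossover_frac * cfg$pop_size / 2)
  if (npairs == 0) return(list())
  if (is.null(rank) || is.null(crowding)) {
    pr <- pareto_rank(lapply(pop, `[[`, "obj"))
    rank <- pr$rank; crowding <- pr$crowding
  }
  lapply(seq_len(npairs), function(i) {
    c(crowded_tournament(rank, crowding, cfg$tournament_k),
      crowded_tournament(rank, crowding, cfg$tournament_k))
  })
}

#' Single-point crossover of two alignments
#'
#' The cut is residue-anchored: a random row and residue ordinal are
#' drawn; in each parent the cut column sits right after that residue.
#' Offspring take the left block of one parent and, per row, the part
#' of the other parent holding the remaining residues, gap-padding the
#' junction so rows stay rectangular. Anchoring on residues (not
#' columns) guarantees both offspring strip back to the input
#' sequences without any repair pass.
#'
#' @param a,b [msa] objects over the same sequences.
#' @param anchor optional `c(row, residue_ordinal)` fixing the cut
#'   (residue ordinal 0 = cut before everything); random when `NULL`.
#' @return List of two offspring [msa] objects.
#' @export
crossover_alignments <- function(a, b, anchor = NULL) {
  if (!identical(sort(rownames(a)), sort(rownames(b)))) {
    stop("parents must align the same sequences")
  }
  b <- b[rownames(a), , drop = FALSE]          # consistent row order
  attr(b, "moltype") <- attr(a, "moltype")
  class(b) <- class(a)
  nres <- rowSums(unclass(a) != GAP)
  if (is.null(anchor)) {
    row <- sample.int(nrow(a), 1L)
    q <- sample.int(nres[row] + 1L, 1L) - 1L   # 0 .. nres allowed
  } else {
    row <- anchor[1L]; q <- anchor[2L]
  }
  list(.splice(a, b, row, q), .splice(b, a, row, q))
}

# left block of `left` up to the cut + per-row remainder of `right`
.splice <- function(left, right, row, q) {
  moltype <- attr(left, "moltype")
  cut <- if (q == 0L) 0L else which(cumsum(left[row, ] != GAP) == q)[1L]
  lcount <- if (cut == 0L) integer(nrow(left)) else
    rowSums(unclass(left)[, seq_len(cut), drop = FALSE] != GAP)
  tails <- vector("list", nrow(left))
  for (i in seq_len(nrow(left))) {
    r <- right[i, ]
    bcut <- if (lcount[i] == 0L) 0L else which(cumsum(r != GAP) == lcount[i])[1L]
    tails[[i]] <- if (bcut >= length(r)) character(0) else r[(bcut + 1L):length(r)]
  }
  tlen <- max(lengths(tails))
  mat <- matrix(GAP, nrow(left), cut + tlen,
                dimnames = list(rownames(left), NULL))
  for (i in seq_len(nrow(left))) {
    if (cut > 0L) mat[i, seq_len(cut)] <- left[i, seq_len(cut)]
    ti <- tails[[i]]
    if (length(ti) > 0L) {           # right-pad head with gaps: pad left
      mat[i, (cut + tlen - length(ti) + 1L):(cut + tlen)] <- ti
    }
  }
  as_msa(mat, moltype)
}

#' Mutate an alignment
#'
#' With probability `mu` applies one random gap-relocation move (as in
#' [tumble()]) and, with a further coin flip, a second single-gap
#' relocation within a row; the per-row gap counts are conserved. With
#' probability `1 - mu` the alignment is returned unchanged.
#'
#' @param al an [msa].
#' @param mu mutation rate in `[0, 1]`.
#' @param max_step see [tumble()].
#' @return An [msa].
#' @export
mutate_alignment <- function(al, mu = 0.8, max_step = 3L) {
  stopifnot(mu >= 0, mu <= 1)
  if (mu == 0 || runif(1L) >= mu) return(al)
  al <- apply_move(al, tumble(al, max_step))
  if (runif(1L) < 0.5) al <- apply_move(al, tumble(al, max_step))
  al
}

#' Elimination and dispersal phase
#'
#' First the replacement sweep: while the best remaining offspring
#' either Pareto-dominates or is healthier (joint rank, then crowding)
#' than the worst population member, they swap. Then each surviving
#' bacterium is, independently with probability `disp_prob`, dispersed:
#' replaced by a freshly randomized alignment of the same sequences.
#' Population size is preserved.
#'
#' @param pop list of bacteria.
#' @param cfg a [bfoga_config()].
#' @param offspring list of evaluated offspring bacteria (may be empty).
#' @param records the [seq_records] being aligned (for dispersal).
#' @return List of bacteria, same length as `pop`.
#' @export
eliminate_disperse <- function(pop, cfg, offspring, records) {
  if (length(offspring) > 0L) {
    repeat {
      all_obj <- lapply(c(pop, offspring), `[[`, "obj")
      pr <- pareto_rank(all_obj)
      npop <- length(pop)
      ord_pop <- health_order(pr$rank[seq_len(npop)],
                              pr$crowding[seq_len(npop)], numeric(npop))
      worst <- ord_pop[npop]
      offr <- pr$rank[-seq_len(npop)]
      offc <- pr$crowding[-seq_len(npop)]
      ord_off <- health_order(offr, offc, numeric(length(offspring)))
      best <- ord_off[1L]
      better <- dominates(offspring[[best]]$obj, pop[[worst]]$obj) ||
        offr[best] < pr$rank[worst] ||
        (offr[best] == pr$rank[worst] && offc[best] > pr$crowding[worst])
      if (!better) break
      pop[[worst]] <- offspring[[best]]
      offspring <- offspring[-best]
      if (length(offspring) == 0L) break
    }
  }
  if (cfg$disp_prob > 0) {
    for (i in seq_along(pop)) {
      if (runif(1L) < cfg$disp_prob) {
        pop[[i]] <- new_bacterium(
          initialize_alignment(records, cfg$gap_fraction), cfg$objective)
      }
    }
  }
  pop
}

# non-dominated, deduplicated archive of (alignment, objectives)
.prune_archive <- function(archive, orientation = NULL) {
  if (length(archive$al) == 0L) return(archive)
  keys <- vapply(archive$al, function(a) paste(a, collapse = ""), character(1))
  keep <- !duplicated(keys)
  als <- archive$al[keep]
  objs <- archive$obj[keep, , drop = FALSE]
  nd <- non_dominated_sort(objs, orientation)$rank == 1L
  list(al = als[nd], obj = objs[nd, , drop = FALSE])
}

#' Run the full optimizer
#'
#' Evolves a population of candidate alignments of `records` through
#' the configured number of generations (see [bfoga_config()] for the
#' phase structure) and maintains an external elitist archive of every
#' non-dominated alignment found, so the reported front can only
#' improve over time.
#'
#' @param records a [seq_records] object with at least 3 sequences.
#' @param cfg a [bfoga_config()].
#' @return A `bfoga_result` list: `archive` (non-dominated alignments),
#'   `archive_objectives` (their objective matrix), `best` (the
#'   max-crowding member of the final front, a compromise solution),
#'   `initial_population` (alignments at generation 0), `trace`
#'   (per-generation best objective values and front sizes), and the
#'   resolved `config`.
#' @export
bfoga_align <- function(records, cfg = bfoga_config()) {
  if (!inherits(records, "seq_records")) stop("`records` must be seq_records")
  if (length(records) < 3L) stop("need at least 3 sequences to align")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  config <- cfg$objective
  pop <- lapply(seq_len(cfg$pop_size), function(i) {
    new_bacterium(initialize_alignment(records, cfg$gap_fraction), config)
  })
  initial_population <- lapply(pop, `[[`, "al")
  ori <- attr(pop[[1L]]$obj, "orientation")
  archive <- .prune_archive(list(
    al = lapply(pop, `[[`, "al"),
    obj = do.call(rbind, lapply(pop, `[[`, "obj"))), ori)
  trace <- vector("list", cfg$generations)

  check_pop <- function(pop, phase) {
    if (length(pop) != cfg$pop_size) {
      stop("population size drifted to ", length(pop), " after ", phase)
    }
    pop
  }

  for (gen in seq_len(cfg$generations)) {
    for (e in seq_len(cfg$disp_steps)) {
      for (f in seq_len(cfg$repro_steps)) {
        for (p in seq_len(cfg$chem_steps)) {
          pop <- check_pop(lapply(pop, chemotaxis_step, cfg = cfg),
                           "chemotaxis")
        }
        pr <- pareto_rank(lapply(pop, `[[`, "obj"))
        pen <- swarming_penalty(pop, pr$rank, pr$crowding)
        pop <- check_pop(reproduction(pop, pr$rank, pr$crowding, pen),
                         "reproduction")
      }
      pr <- pareto_rank(lapply(pop, `[[`, "obj"))
      pairs <- select_parents(pop, cfg, pr$rank, pr$crowding)
      offspring <- list()
      for (pp in pairs) {
        kids <- crossover_alignments(pop[[pp[1L]]]$al, pop[[pp[2L]]]$al)
        for (k in kids) {
          k <- mutate_alignment(k, cfg$mutation_rate, cfg$max_step)
          offspring[[length(offspring) + 1L]] <- new_bacterium(k, config)
        }
      }
      pop <- check_pop(eliminate_disperse(pop, cfg, offspring, records),
                       "elimination-dispersal")
    }
    archive <- .prune_archive(list(
      al = c(archive$al, lapply(pop, `[[`, "al")),
      obj = rbind(archive$obj, do.call(rbind, lapply(pop, `[[`, "obj")))), ori)
    pr <- pareto_rank(lapply(pop, `[[`, "obj"))
    trace[[gen]] <- data.frame(
      generation = gen,
      best_similarity = max(archive$obj[, "similarity"]),
      best_gap_penalty = min(archive$obj[, "gap_penalty"]),
      best_ngp = if (config$ngp_literal) min(archive$obj[, "ngp"])
                 else max(archive$obj[, "ngp"]),
      front_size = sum(pr$rank == 1L),
      archive_size = length(archive$al),
      pop_size = length(pop))
  }
  front_crowd <- crowding_distance(archive$obj)
  best_idx <- order(-front_crowd, -archive$obj[, "similarity"])[1L]
  structure(list(archive = archive$al,
                 archive_objectives = archive$obj,
                 best = archive$al[[best_idx]],
                 initial_population = initial_population,
                 trace = do.call(rbind, trace) %||%
                   data.frame(generation = integer(0)),
                 config = cfg),
            class = "bfoga_result")
}

#' @export
print.bfoga_result <- function(x, ...) {
  cat("bfoga result:", length(x$archive), "non-dominated alignment(s)\n")
  o <- x$archive_objectives
  cat(sprintf("  similarity  %.4f .. %.4f\n", min(o[, 1]), max(o[, 1])))
  cat(sprintf("  gap penalty %.2f .. %.2f\n", min(o[, 2]), max(o[, 2])))
  cat(sprintf("  ngp         %.2f .. %.2f\n", min(o[, 3]), max(o[, 3])))
  if (nrow(x$trace) > 0) {
    cat("  generations:", max(x$trace$generation), "\n")
  }
  invisible(x)
}
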