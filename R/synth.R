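#' Specify a synthetic homologous sequence family
#'
#' Describes a star-tree evolution experiment: an ancestor sequence is
#' drawn uniformly over the alphabet and each descendant accumulates
#' point substitutions and indels independently. Because the edit
#' history is recorded, the generator can assemble the true alignment,
#' which serves as the reference for SP/TC scoring.
#'
#' @param n_sequences number of descendants (>= 3).
#' @param ancestor_length ancestor residue count.
#' @param substitution_rate per-site substitution probability per
#'   lineage.
#' @param indel_rate per-site probability of an indel event (insertion
#'   or deletion, equally likely).
#' @param max_indel_length indel lengths are geometric, truncated here.
#' @param moltype `"protein"` or `"dna"`.
#' @param seed integer seed.
#' @param topology `"star"` (ancestor to each leaf directly) or
#'   `"two_level"` (two internal nodes, substitutions only on internal
#'   edges, splitting the leaves into two clades).
#' @param preset `"twilight"` overrides the substitution rate to 0.55,
#'   targeting pairwise identities at or below the ~25% twilight zone.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_sequences = 6L, ancestor_length = 120L,
                        substitution_rate = 0.15, indel_rate = 0.03,
                        max_indel_length = 5L,
                        moltype = c("protein", "dna"), seed = NULL,
                        topology = c("star", "two_level"),
                        preset = c("none", "twilight")) {
  moltype <- match.arg(moltype)
  topology <- match.arg(topology)
  preset <- match.arg(preset)
  if (preset == "twilight") substitution_rate <- 0.55
  stopifnot(n_sequences >= 3L, ancestor_length >= 1L,
            substitution_rate >= 0, substitution_rate <= 1,
            indel_rate >= 0, indel_rate <= 1, max_indel_length >= 1L)
  structure(list(n_sequences = as.integer(n_sequences),
                 ancestor_length = as.integer(ancestor_length),
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate,
                 max_indel_length = as.integer(max_indel_length),
                 moltype = moltype, seed = seed, topology = topology),
            class = "family_spec")
}

# substitute residues in place; replacement always differs from the original
.substitute <- function(res, rate, alph) {
  hit <- which(runif(length(res)) < rate)
  for (p in hit) {
    res[p] <- sample(setdiff(alph, res[p]), 1L)
  }
  res
}

#' Generate a synthetic family and its true alignment
#'
#' Draws the ancestor, evolves each descendant (substitutions first,
#' then indel events at ancestor positions), and assembles the true
#' multiple alignment from the recorded edits: a deletion shows as a
#' gap in its carrier, an insertion after an ancestor position opens
#' gap columns in every non-carrier. Deterministic for a fixed seed;
#' the gap-strip round trip holds by construction.
#'
#' @param spec a [family_spec()].
#' @return List with `records` (a [seq_records]) and `reference`
#'   (the true [msa]).
#' @export
generate_family <- function(spec) {
  if (!inherits(spec, "family_spec")) stop("`spec` must be a family_spec")
  if (!is.null(spec$seed)) set.seed(spec$seed)
  alph <- alphabet(spec$moltype, ambiguity = FALSE)
  L <- spec$ancestor_length
  anc <- sample(alph, L, replace = TRUE)
  n <- spec$n_sequences

  parents <- replicate(n, anc, simplify = FALSE)
  if (spec$topology == "two_level") {
    # substitutions-only internal edges keep ancestor coordinates valid
    int1 <- .substitute(anc, spec$substitution_rate / 2, alph)
    int2 <- .substitute(anc, spec$substitution_rate / 2, alph)
    half <- n %/% 2L
    parents <- c(replicate(half, int1, simplify = FALSE),
                 replicate(n - half, int2, simplify = FALSE))
  }
  leaf_rate <- if (spec$topology == "two_level")
    spec$substitution_rate / 2 else spec$substitution_rate

  residues <- vector("list", n)   # residue (or NA if deleted) per ancestor site
  inserts <- vector("list", n)    # inserted strings after each ancestor site
  for (i in seq_len(n)) {
    res <- .substitute(parents[[i]], leaf_rate, alph)
    del <- rep(FALSE, L)
    ins <- vector("list", L + 1L) # slot p+1 = insertions after site p (0 = before)
    events <- which(runif(L) < spec$indel_rate)
    for (p in events) {
      len <- min(rgeom(1L, 0.5) + 1L, spec$max_indel_length)
      if (runif(1L) < 0.5) {
        del[p:min(p + len - 1L, L)] <- TRUE
      } else {
        ins[[p + 1L]] <- c(ins[[p + 1L]], sample(alph, len, replace = TRUE))
      }
    }
    res[del] <- NA_character_
    residues[[i]] <- res
    inserts[[i]] <- ins
  }

  # assemble true alignment column blocks per ancestor site
  cols <- vector("list", L + 1L)
  for (p in 0:L) {
    block <- NULL
    if (p > 0L) {
      site <- vapply(residues, `[`, character(1), p)
      site[is.na(site)] <- GAP
      block <- matrix(site, ncol = 1L)
    }
    for (i in seq_len(n)) {
      insi <- inserts[[i]][[p + 1L]]
      if (!is.null(insi)) {
        ext <- matrix(GAP, n, length(insi))
        ext[i, ] <- insi
        block <- cbind(block, ext)
      }
    }
    cols[[p + 1L]] <- block
  }
  mat <- do.call(cbind, cols)
  rownames(mat) <- paste0("seq", seq_len(n))
  reference <- as_msa(mat, spec$moltype)
  list(records = msa_strip_gaps(reference), reference = reference)
}

#' Mean pairwise identity of a family's true alignment
#'
#' Fraction of residue-residue columns with identical residues,
#' averaged over all sequence pairs. Used to verify that identity
#' decreases with the substitution rate and that the twilight preset
#' lands at or below ~25%.
#'
#' @param reference a true [msa] from [generate_family()].
#' @return Mean identity in `[0, 1]`.
#' @export
mean_pairwise_identity <- function(reference) {
  n <- nrow(reference)
  ids <- c()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      both <- reference[i, ] != GAP & reference[j, ] != GAP
      if (any(both)) {
        ids <- c(ids, mean(reference[i, both] == reference[j, both]))
      }
    }
  }
  mean(ids)
}
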