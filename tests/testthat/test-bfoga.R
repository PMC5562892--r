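small_cfg <- function(...) {
  args <- utils::modifyList(
    list(pop_size = 10L, chem_steps = 2L, repro_steps = 1L,
         disp_steps = 1L, generations = 3L),
    list(...))
  do.call(bfoga_config, args)
}

test_that("moves are exactly invertible and preserve residue order", {
  set.seed(71)
  rec <- random_records(4, c(12, 10, 9, 11))
  for (trial in 1:40) {
    al <- initialize_alignment(rec, 0.2)
    mv <- tumble(al)
    moved <- apply_move(al, mv, drop_allgap = FALSE)
    expect_true(bfoga:::roundtrip_ok(bfoga:::as_msa(unclass(moved), "protein"),
                                     rec))
    back <- apply_move(moved, invert_move(mv), drop_allgap = FALSE)
    expect_identical(unclass(back), unclass(al))
  }
})

test_that("tumble is seed-deterministic and direction-symmetric", {
  rec <- random_records(4, 10, seed = 73)
  al <- initialize_alignment(rec, 0.2, seed = 73)
  set.seed(5); m1 <- tumble(al)
  set.seed(5); m2 <- tumble(al)
  expect_identical(m1, m2)

  set.seed(79)
  dirs <- replicate(10000, tumble(al)$direction)
  expect_lt(abs(mean(dirs == "left") - 0.5), 0.02)
})

test_that("a gap-free alignment tumbles to a no-op", {
  al <- make_msa(c("ACDE", "ACDE", "ACDE"))
  mv <- tumble(al)
  expect_equal(mv$kind, "none")
  expect_identical(apply_move(al, mv), al)
})

test_that("chemotaxis swims while the move keeps dominating", {
  # row 1's gap block sits 3 shifts from where rows 2-3 have theirs;
  # each unit shift right raises similarity and nothing worsens
  al <- make_msa(c("ACD--EFG", "ACDEFG--", "ACDEFG--"))
  bact <- list(al = al, obj = evaluate_alignment(al))
  mv <- msa_move("gap_block_shift", row = 1L, j = 2L, src = 3L, dst = 4L,
                 direction = "right", magnitude = 1L)

  out <- chemotaxis_step(bact, small_cfg(swim_length = 5L), move = mv)
  # first application plus two swims reaches the optimum; the shared
  # all-gap columns then collapse to the perfect 6-column alignment
  expect_equal(ncol(out$al), 6L)
  expect_equal(unname(out$obj["similarity"]), 1)
  expect_true(dominates(out$obj, bact$obj))

  # swim disabled: a single application only
  out0 <- chemotaxis_step(bact, small_cfg(swim_length = 0L), move = mv)
  expect_equal(unname(which(out0$al[1, ] == "-")), c(5L, 6L))

  # a worsening move is reverted
  bad <- msa_move("gap_block_shift", row = 1L, j = 2L, src = 3L, dst = 2L,
                  direction = "left", magnitude = 1L)
  outb <- chemotaxis_step(bact, small_cfg(), move = bad)
  expect_identical(unclass(outb$al), unclass(al))
})

test_that("gap-set distance is a symmetric, additive displacement count", {
  a <- make_msa(c("AC-DEF", "ACDEF-"))
  expect_equal(gap_set_distance(a, a), 0)

  b <- make_msa(c("ACD-EF", "ACDEF-"))   # one gap moved: symdiff 2
  expect_equal(gap_set_distance(a, b, normalize = FALSE), 2)
  expect_equal(gap_set_distance(b, a, normalize = FALSE), 2)

  c2 <- make_msa(c("ACD-EF", "ACDE-F"))  # two disjoint moves: symdiff 4
  expect_equal(gap_set_distance(a, c2, normalize = FALSE), 4)
})

test_that("swarming charges distance to the fittest bacterium", {
  cfgo <- objective_config()
  mk <- function(rows) {
    al <- make_msa(rows)
    list(al = al, obj = evaluate_alignment(al, cfgo))
  }
  pop <- list(mk(c("ACDEF-", "ACDEF-", "-ACDEF")),
              mk(c("ACDEF-", "ACDEF-", "-ACDEF")),
              mk(c("-ACDEF", "ACDEF-", "ACD-EF")))
  pen <- swarming_penalty(pop)
  fit <- which(pen == 0)
  expect_true(length(fit) >= 1)
  expect_true(all(pen >= 0))
})

test_that("reproduction duplicates the healthier half in order", {
  mk <- function(sm) list(al = make_msa(c("ACDE", "ACDE")),
                          obj = structure(c(similarity = sm, gap_penalty = 0,
                                            ngp = 100),
                                          orientation = c(1, -1, 1)))
  pop <- list(mk(0.4), mk(0.9), mk(0.6), mk(0.2))
  out <- reproduction(pop)
  sms <- vapply(out, function(b) unname(b$obj["similarity"]), numeric(1))
  expect_equal(sms, c(0.9, 0.6, 0.9, 0.6))
  expect_length(out, 4L)
  expect_error(reproduction(pop[1:3]), "even")
})

test_that("parent selection draws ceil(chi * Je / 2) pairs", {
  set.seed(83)
  rec <- random_records(4, 10)
  cfg <- bfoga_config(pop_size = 20L, crossover_frac = 0.3)
  pop <- lapply(1:20, function(i) {
    al <- initialize_alignment(rec, 0.19)
    list(al = al, obj = evaluate_alignment(al))
  })
  pairs <- select_parents(pop, cfg)
  expect_length(pairs, 3L)   # ceil(0.3 * 20 / 2)
  expect_true(all(unlist(pairs) %in% 1:20))

  cfg0 <- bfoga_config(pop_size = 20L, crossover_frac = 0)
  expect_length(select_parents(pop, cfg0), 0L)
})

test_that("crossover splices at a residue anchor and stays valid", {
  set.seed(89)
  rec <- random_records(4, c(10, 9, 8, 10))
  a <- initialize_alignment(rec, 0.2)
  b <- initialize_alignment(rec, 0.2)

  for (trial in 1:20) {
    kids <- crossover_alignments(a, b)
    for (k in kids) expect_true(bfoga:::roundtrip_ok(k, rec))
  }

  # boundary anchor: offspring reproduce the parents
  kids0 <- crossover_alignments(a, b, anchor = c(1L, 0L))
  expect_identical(unclass(kids0[[1]]), unclass(b))
  expect_identical(unclass(kids0[[2]]), unclass(a))

  # self-cross is an identity up to all-gap column removal
  kidsa <- crossover_alignments(a, a, anchor = c(2L, 4L))
  expect_identical(unclass(bfoga:::as_msa(unclass(kidsa[[1]]), "protein")),
                   unclass(bfoga:::as_msa(unclass(a), "protein")))
})

test_that("mutation honours its rate and conserves the sequences", {
  set.seed(97)
  rec <- random_records(3, 10)
  al <- initialize_alignment(rec, 0.2)
  expect_identical(mutate_alignment(al, mu = 0), al)

  set.seed(7); m1 <- mutate_alignment(al, mu = 1)
  set.seed(7); m2 <- mutate_alignment(al, mu = 1)
  expect_identical(unclass(m1), unclass(m2))
  expect_true(bfoga:::roundtrip_ok(m1, rec))
})

test_that("elimination-dispersal swaps in dominating offspring", {
  rec <- random_records(3, 8, seed = 101)
  cfg <- small_cfg(disp_prob = 0)
  set.seed(102)
  pop <- lapply(1:10, function(i) {
    al <- initialize_alignment(rec, 0.19)
    list(al = al, obj = evaluate_alignment(al))
  })

  # no offspring, no dispersal: unchanged
  expect_identical(eliminate_disperse(pop, cfg, list(), rec), pop)

  # an offspring dominating everything must enter the population
  super <- list(al = pop[[1]]$al,
                obj = structure(c(similarity = 1, gap_penalty = 0,
                                  ngp = 100), orientation = c(1, -1, 1)))
  out <- eliminate_disperse(pop, cfg, list(super), rec)
  sms <- vapply(out, function(b) unname(b$obj["similarity"]), numeric(1))
  expect_true(any(sms == 1))
  expect_length(out, 10L)

  # full dispersal keeps the size and the round trip
  cfg1 <- small_cfg(disp_prob = 1)
  out1 <- eliminate_disperse(pop, cfg1, list(), rec)
  expect_length(out1, 10L)
  for (b in out1) expect_true(bfoga:::roundtrip_ok(b$al, rec))
})

test_that("the optimizer run is reproducible and elitist", {
  fam <- generate_family(family_spec(n_sequences = 4, ancestor_length = 40,
                                     seed = 19))
  cfg <- small_cfg(seed = 3L)
  r1 <- bfoga_align(fam$records, cfg)
  r2 <- bfoga_align(fam$records, cfg)
  expect_identical(r1$archive, r2$archive)
  expect_identical(r1$trace, r2$trace)

  expect_true(all(r1$trace$pop_size == cfg$pop_size))
  expect_true(!is.unsorted(r1$trace$best_similarity))
  expect_true(!is.unsorted(rev(r1$trace$best_gap_penalty)))
  expect_true(!is.unsorted(r1$trace$best_ngp))
  for (al in r1$archive) expect_true(bfoga:::roundtrip_ok(al, fam$records))

  # zero generations: archive is the non-dominated initial subset
  r0 <- bfoga_align(fam$records, small_cfg(generations = 0L, seed = 3L))
  expect_equal(nrow(r0$trace), 0L)
  objs <- do.call(rbind, lapply(r0$initial_population, evaluate_alignment))
  nd <- which(non_dominated_sort(objs)$rank == 1L)
  expect_length(r0$archive, length(unique(
    vapply(r0$initial_population[nd], paste, character(1), collapse = ""))))

  expect_error(bfoga_align(fam$records[1:2] |> unclass() |>
                             seq_records(moltype = "protein"),
                           cfg), "at least 3")
})

test_that("disabling stochastic operators leaves pure local search", {
  fam <- generate_family(family_spec(n_sequences = 4, ancestor_length = 30,
                                     seed = 29))
  cfg <- bfoga_config(pop_size = 6L, chem_steps = 2L, repro_steps = 1L,
                      disp_steps = 1L, generations = 4L, swim_length = 0L,
                      crossover_frac = 0, mutation_rate = 0, disp_prob = 0,
                      seed = 31L)
  res <- bfoga_align(fam$records, cfg)
  expect_true(!is.unsorted(res$trace$best_similarity))
  expect_true(!is.unsorted(rev(res$trace$best_gap_penalty)))
  expect_true(all(res$trace$pop_size == 6L))
})
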