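test_that("position weight matrix counts residues against all rows", {
  al <- make_msa(c("AA", "AA", "CA", "-A"))
  pwm <- position_weight_matrix(al)
  expect_equal(unname(pwm["A", 1]), 0.5)
  expect_equal(unname(pwm["C", 1]), 0.25)
  expect_equal(unname(pwm["A", 2]), 1.0)
  # column sums: 1 minus gap share
  expect_equal(unname(colSums(unclass(pwm))), c(0.75, 1))
})

test_that("dominance is the top residue frequency, never the gap", {
  al <- make_msa(c("AA", "AA", "CA", "-A"))
  pwm <- position_weight_matrix(al)
  expect_equal(unname(dominance(pwm, 1)), 0.5)
  expect_equal(unname(dominance(pwm, 2)), 1.0)
  expect_error(dominance(pwm, 3), "out of range")

  # n distinct residues: uniform column
  un <- make_msa(c("A", "C", "D", "E"))
  expect_equal(unname(dominance(position_weight_matrix(un), 1)), 0.25)

  # heavily gapped column: gap majority but a residue still wins the max
  g <- make_msa(c("AC", "-C", "-C", "-C"))
  expect_equal(unname(dominance(position_weight_matrix(g), 1)), 0.25)
})

test_that("similarity averages column dominance", {
  expect_equal(similarity(make_msa(c("ACDE", "ACDE", "ACDE"))), 1)
  expect_equal(similarity(make_msa(c("AC", "AG"))), 0.75)

  # row-reorder invariance
  set.seed(31)
  rec <- random_records(5, 12)
  al <- initialize_alignment(rec, 0.15)
  perm <- sample(5)
  alp <- bfoga:::as_msa(unclass(al)[perm, ], "protein")
  expect_equal(similarity(alp), similarity(al))
})

test_that("affine gap penalty follows open/extend run accounting", {
  expect_equal(affine_gap_penalty(make_msa(c("ACDE", "AC-E")), 10, 1), 10)
  expect_equal(affine_gap_penalty(make_msa(c("ACDEF", "A---F")), 10, 1), 12)
  expect_equal(affine_gap_penalty(make_msa(c("ACDE", "ACDE"))), 0)

  # columns gapped in both rows of a pair are skipped entirely, and the
  # flanking runs merge in the projection
  both <- make_msa(c("A--DE", "A--DE", "ACD-E"))
  # pair (1,2): shared gap columns dropped -> no penalty between them
  expect_equal(affine_gap_penalty(make_msa(c("A--DE", "A--DE")), 10, 1), 0)
  # pairs (1,3) and (2,3): row i has run of 2, row 3 has run of 1 each
  expect_equal(affine_gap_penalty(both, 10, 1), 2 * ((10 + 1) + 10))
})

test_that("splitting a gap run strictly increases the affine penalty", {
  grouped <- make_msa(c("ACDEFGHI", "ACDE----"))
  split2 <- make_msa(c("ACDEFGHI", "AC--DE--"))
  expect_gt(affine_gap_penalty(split2, 10, 1),
            affine_gap_penalty(grouped, 10, 1))
  # same total gaps in both layouts
  expect_equal(sum(unclass(grouped) == "-"), sum(unclass(split2) == "-"))
})

test_that("non-gap percentage has maximization and literal conventions", {
  gapfree <- make_msa(c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(non_gap_percentage(gapfree), 100)

  al <- make_msa(c("AC-EFGHIK-", "-CDEFGHI-L"))  # 2 x 10 with 4 gaps
  expect_equal(non_gap_percentage(al), 100 * 16 / 20)
  expect_equal(non_gap_percentage(al, literal = TRUE), 100 * 4 / 16)

  # an all-gap column cannot raise the gap count: it is removed on entry
  w3 <- make_msa(c("AC-EFGHIK--", "-CDEFGHI-L-", "ACDEFGHIKL-"))
  expect_equal(ncol(w3), 10L)
  # adding a genuine gap at fixed residue content lowers the default NGP
  expect_lt(non_gap_percentage(make_msa(c("A-CD", "AC-D"))),
            non_gap_percentage(make_msa(c("ACD", "ACD"))))
})

test_that("pair-level gap rescaling follows length and identity factors", {
  al <- make_msa(c("ACDEFGHIKL", "ACDEFGHIKL", "ACDEFGHIKV"))
  tb <- gap_penalty_tables(al, gap_open = 10, gap_extend = 1.5)
  # equal lengths: extension factor 1 + |log(R/T)| = 1
  expect_equal(unname(tb$pair_ext[1, 2]), 1.5)
  expect_equal(unname(tb$pair_ext[1, 3]), 1.5)
  # identical pair: m = 1, so opening = (10 + log(10)) * nbar
  nbar <- bfoga:::mean_mismatch_score(load_substitution_matrix("BLOSUM62"))
  expect_equal(unname(tb$pair_open[1, 2]), (10 + log(10)) * nbar * 1)
  # 90% identical pair scales the opening cost by 0.9
  expect_equal(unname(tb$pair_open[1, 3]), (10 + log(10)) * nbar * 0.9)

  # unequal lengths raise the extension factor
  al2 <- make_msa(c("ACDEFGHIKL", "ACDEF-----", "ACDEFGHIKL"))
  tb2 <- gap_penalty_tables(al2, gap_open = 10, gap_extend = 1)
  expect_equal(unname(tb2$pair_ext[1, 2]), 1 + abs(log(10 / 5)))
})

test_that("positional opening modulation applies rules in order", {
  # one gap column at position 3 in a wide alignment
  rows <- c("AC-EFGHIKLMAAAAA",
            "ACDEFGHIKLMAAAAA",
            "ACDEFGHIKLMAAAAA")
  al <- make_msa(rows)
  tb <- gap_penalty_tables(al, 10, 1)
  # inside the gap column: 0.3 * (rows without gap / rows)
  expect_equal(unname(tb$mod[, 3]), rep(0.3 * 2 / 3, 3))
  # adjacent to the gap (0 columns in between): x4; distance 8: x2
  expect_equal(unname(tb$mod[1, 4]), 4)
  expect_equal(unname(tb$mod[1, 2]), 4)
  expect_equal(unname(tb$mod[1, 12]), 2)        # 8 columns in between
  # past the window, residue-specific multipliers apply (A far from gaps)
  tabA <- unname(default_residue_gap_table()["A"])
  expect_equal(unname(tb$mod[1, 13]), tabA)
})

test_that("hydrophilic stretches halve the opening cost", {
  # gap-free: no occupancy rules fire anywhere
  rows <- c("WWWGPSNDQWWWWW",
            "WWWGPSNDQWWWWW")
  al <- make_msa(rows)
  tb <- gap_penalty_tables(al, 10, 1)
  expect_equal(unname(tb$mod[1, 4:9]), rep(0.5, 6))  # GPSNDQ run of 6
  tabW <- unname(default_residue_gap_table()["W"])
  expect_equal(unname(tb$mod[1, 1:3]), rep(tabW, 3))
  # a 4-residue hydrophilic run is below the default threshold
  al2 <- make_msa(c("WWWGPSNWWWWWWW", "WWWGPSNWWWWWWW"))
  tb2 <- gap_penalty_tables(al2, 10, 1)
  expect_equal(unname(tb2$mod[1, 4]),
               unname(default_residue_gap_table()["G"]))
})

test_that("variable penalty reduces exactly to affine under constant tables", {
  set.seed(17)
  for (rep in 1:5) {
    rec <- random_records(4, sample(8:14, 4, replace = TRUE))
    al <- initialize_alignment(rec, 0.2)
    expect_equal(variable_gap_penalty(al, constant_gap_tables(al, 10, 1)),
                 affine_gap_penalty(al, 10, 1))
    expect_equal(variable_gap_penalty(al, constant_gap_tables(al, 7, 0.4)),
                 affine_gap_penalty(al, 7, 0.4))
  }
})

test_that("variable penalty is monotone in the opening table", {
  al <- make_msa(c("AC-EFG", "ACDEFG", "A-DEFG"))
  tb <- constant_gap_tables(al, 10, 1)
  base <- variable_gap_penalty(al, tb)
  tb$mod[1, 3] <- 0.5   # lower one opening entry
  expect_lte(variable_gap_penalty(al, tb), base)
})

test_that("stale tables are rejected", {
  al <- make_msa(c("AC-E", "ACDE"))
  tb <- constant_gap_tables(al, 10, 1)
  al2 <- make_msa(c("AC-EF", "ACDEF"))
  expect_error(variable_gap_penalty(al2, tb), "stale")
})

test_that("evaluate composes the three objectives", {
  perfect <- make_msa(c("ACDEFG", "ACDEFG", "ACDEFG"))
  v <- evaluate_alignment(perfect)
  expect_equal(unname(as.numeric(v)), c(1, 0, 100))

  set.seed(23)
  rec <- random_records(4, 10)
  al <- initialize_alignment(rec, 0.15)
  cfg <- objective_config("affine", gap_open = 8, gap_extend = 2)
  v <- evaluate_alignment(al, cfg)
  expect_equal(unname(v["similarity"]), similarity(al))
  expect_equal(unname(v["gap_penalty"]), affine_gap_penalty(al, 8, 2))
  expect_equal(unname(v["ngp"]), non_gap_percentage(al))
  # deterministic pure function
  expect_identical(v, evaluate_alignment(al, cfg))

  vcfg <- objective_config("variable")
  vv <- evaluate_alignment(al, vcfg)
  expect_equal(unname(vv["gap_penalty"]),
               variable_gap_penalty(al, gap_penalty_tables(al)))
})
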