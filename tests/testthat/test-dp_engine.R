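test_that("boundary rows follow the codon gap formula", {
  lin <- scoring_scheme(gap_mode = "linear")
  st <- fill_tables("ATGAAA", "", lin)
  expect_equal(dp_score(st), -2)            # floor(6/3) * gap_cost
  tb <- traceback_alignment(st)
  expect_identical(tb$a_gapped, "ATGAAA")
  expect_identical(tb$b_gapped, "------")

  aff <- scoring_scheme(gap_mode = "affine")
  expect_equal(dp_score(fill_tables("ATGAAA", "", aff)),
               aff$gap_open_cost + 2 * aff$gap_cost)

  # empty-vs-empty aligns to the empty alignment with score 0
  fit <- cds_align("", "", lin)
  expect_equal(fit$score, 0)
  expect_identical(fit$alignment$L, 0L)
})

test_that("aligning a sequence with itself recovers the diagonal score", {
  sc <- scoring_scheme()
  for (seed in 1:5) {
    s <- random_cds(36, seed = seed)
    fit <- cds_align(s, s, sc)
    diag_sum <- sum(vapply(seq_len(s$codon_count), function(k)
      aa_score(sc, substr(s$nucleotides, 3 * k - 2, 3 * k),
               substr(s$nucleotides, 3 * k - 2, 3 * k)), 0))
    expect_equal(fit$score, diag_sum)
    expect_false(grepl("-", fit$alignment$a_gapped, fixed = TRUE))
    expect_identical(length(fit$classification$a$im), s$codon_count)
  }
})

test_that("table optimum equals the exhaustive maximum on small pairs", {
  # scaled-down version of the acceptance sweep: 30 random pairs, 3 schemes
  schemes <- oracle_schemes()[c(1, 2, 4)]
  set.seed(101)
  for (t in 1:30) {
    a <- random_cds(sample(c(0, 3, 6), 1), avoid_stops = FALSE)
    b <- random_cds(sample(c(0, 3, 6), 1), avoid_stops = FALSE)
    bf <- brute_force_best(a, b, schemes)
    for (s in seq_along(schemes)) {
      st <- fill_tables(a, b, schemes[[s]])
      expect_equal(dp_score(st), bf$scores[s])
    }
  }
})

test_that("traceback alignments score exactly the table optimum", {
  set.seed(211)
  for (t in 1:40) {
    a <- random_cds(3 * sample(0:10, 1), avoid_stops = FALSE)
    b <- random_cds(3 * sample(0:10, 1), avoid_stops = FALSE)
    for (mode in c("linear", "affine")) {
      sc <- scoring_scheme(gap_mode = mode)
      st <- fill_tables(a, b, sc)
      tb <- traceback_alignment(st)
      expect_equal(score_alignment(tb, sc), dp_score(st))
    }
  }
})

test_that("affine-mode optimum equals exhaustive affine maximization", {
  schemes <- list(
    scoring_scheme(gap_mode = "affine"),
    scoring_scheme(gap_mode = "affine", fs_open_cost = -10,
                   fs_extend_cost = -0.5, gap_open_cost = -5))
  set.seed(307)
  for (t in 1:15) {
    a <- random_cds(sample(c(3, 6), 1), avoid_stops = FALSE)
    b <- random_cds(sample(c(0, 3, 6), 1), avoid_stops = FALSE)
    bf <- brute_force_best(a, b, schemes)
    for (s in seq_along(schemes))
      expect_equal(dp_score(fill_tables(a, b, schemes[[s]])), bf$scores[s])
  }
})

test_that("swapping the sequences mirrors the tables and the score", {
  set.seed(401)
  for (t in 1:10) {
    a <- random_cds(3 * sample(2:6, 1), avoid_stops = FALSE)
    b <- random_cds(3 * sample(2:6, 1), avoid_stops = FALSE)
    sc <- scoring_scheme(gap_mode = "linear")
    st_ab <- fill_tables(a, b, sc)
    st_ba <- fill_tables(b, a, sc)
    # the mirrored code paths must produce transposed tables cell for cell
    expect_equal(st_ab$D, t(st_ba$D))
    expect_equal(dp_score(st_ab), dp_score(st_ba))
  }
})

test_that("optimal score is monotone in the frameshift penalties", {
  set.seed(503)
  for (t in 1:8) {
    p <- generate_fs_pair(seed = 600 + t)
    prev <- Inf
    for (fe in c(0, -0.5, -1, -2)) {
      sc <- scoring_scheme(gap_mode = "linear", fs_extend_cost = fe)
      cur <- dp_score(fill_tables(p$base, p$derived, sc))
      expect_lte(cur, prev + 1e-9)
      prev <- cur
    }
    prev <- Inf
    for (fo in c(-5, -10, -20, -30)) {
      sc <- scoring_scheme(gap_mode = "linear", fs_open_cost = fo)
      cur <- dp_score(fill_tables(p$base, p$derived, sc))
      expect_lte(cur, prev + 1e-9)
      prev <- cur
    }
  }
})

test_that("tables have Theta(nm) shape and the census counts evaluations", {
  a <- random_cds(30, seed = 1); b <- random_cds(21, seed = 2)
  st <- fill_tables(a, b, scoring_scheme(gap_mode = "linear"), census = TRUE)
  expect_identical(dim(st$D), c(31L, 22L))
  expect_identical(dim(st$DF), c(31L, 22L))
  cc <- case_census(st)
  expect_identical(cc$n, 30L)
  expect_identical(cc$m, 21L)
  expect_identical(cc$total, sum(unlist(cc$per_class)))
  expect_gt(cc$per_cell, 0)

  # no cells, no evaluations
  cc0 <- case_census(fill_tables("", "", scoring_scheme(gap_mode = "linear"),
                                 census = TRUE))
  expect_identical(cc0$total, 0)
  expect_identical(cc0$per_cell, 0)
})

test_that("the auxiliary table is only defined on codon-boundary lines", {
  a <- random_cds(12, seed = 9); b <- random_cds(12, seed = 10)
  st <- fill_tables(a, b, scoring_scheme(gap_mode = "linear"))
  for (i in 1:12) for (j in 1:12)
    if (i %% 3 != 0 && j %% 3 != 0)
      expect_true(is.na(st$DF[i + 1, j + 1]))
  # and equals D where both indices are codon boundaries
  for (i in seq(0, 12, 3)) for (j in seq(0, 12, 3))
    expect_identical(st$DF[i + 1, j + 1], st$D[i + 1, j + 1])
})
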