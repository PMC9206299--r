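test_that("bliss_expected composes effects like independent probabilities", {
  expect_equal(bliss_expected(0, 0), 0)
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(1.0, 0.3), 1.0)
  expect_equal(bliss_expected(0.2, 0.7), bliss_expected(0.7, 0.2))
  expect_error(bliss_expected(NA, 0.5), "non-finite")
})

test_that("delta matrices match the cell-by-cell loop oracle", {
  set.seed(11)
  for (i in 1:20) {
    v <- matrix(runif(36, 0.05, 1), 6, 6)
    v[1, 1] <- 1
    m <- effect_matrix(assemble_matrix(make_single_matrix_records(v),
                                       "L1", "drugA", "drugB"))
    r <- delta_matrix(m)
    expect_equal(unname(r$delta), delta_loop_oracle(m$effect),
                 tolerance = 1e-12)
  }
})

test_that("an exactly multiplicative surface has zero delta everywhere", {
  va <- c(1, 0.9, 0.75, 0.6, 0.45, 0.3)
  vb <- c(1, 0.95, 0.8, 0.65, 0.5, 0.4)
  m <- effect_matrix(assemble_matrix(make_single_matrix_records(outer(va, vb)),
                                     "L1", "drugA", "drugB"))
  r <- delta_matrix(m)
  expect_equal(unname(r$delta), matrix(0, 6, 6), tolerance = 1e-12)

  # a known excess at one combination cell: alpha_a = alpha_b = 0.5,
  # alpha_obs = 0.9 gives delta 0.15
  v <- outer(c(1, rep(0.5, 5)), c(1, rep(0.5, 5)))
  v[4, 4] <- 0.1
  m2 <- effect_matrix(assemble_matrix(make_single_matrix_records(v),
                                      "L1", "drugA", "drugB"))
  expect_equal(delta_matrix(m2)$delta[4, 4], 0.15, tolerance = 1e-12)
})

test_that("scores aggregate combination cells and classify strictly above 15", {
  # delta == 0.20 on all 25 combination cells
  va <- c(1, rep(0.8, 5))
  vb <- c(1, rep(0.7, 5))
  v <- outer(va, vb)
  v[2:6, 2:6] <- v[2:6, 2:6] - 0.20
  m <- effect_matrix(assemble_matrix(make_single_matrix_records(v),
                                     "L1", "drugA", "drugB"))
  r <- synergy_score(delta_matrix(m))
  expect_equal(r$score, 20.0, tolerance = 1e-10)
  expect_true(r$synergistic)

  # full-matrix aggregation dilutes a constant delta by 25/36
  r_full <- synergy_score(delta_matrix(m), domain = "full_matrix")
  expect_equal(r_full$score, 20.0 * 25 / 36, tolerance = 1e-10)

  # boundary: a score exactly at the threshold is not synergistic (strict
  # inequality); binary-exact values keep the score exactly on the boundary
  vex <- outer(c(1, rep(0.75, 5)), c(1, rep(0.5, 5)))
  vex[2:6, 2:6] <- vex[2:6, 2:6] - 0.25
  rex <- delta_matrix(effect_matrix(
    assemble_matrix(make_single_matrix_records(vex), "L1", "drugA", "drugB")))
  r25 <- synergy_score(rex, threshold = 25)
  expect_identical(r25$score, 25)
  expect_false(r25$synergistic)
  expect_true(synergy_score(rex, threshold = 15)$synergistic)
})

test_that("swapping the compound axes leaves the score unchanged", {
  set.seed(21)
  v <- matrix(runif(36, 0.1, 1), 6, 6)
  v[1, 1] <- 1
  m <- effect_matrix(assemble_matrix(make_single_matrix_records(v),
                                     "L1", "drugA", "drugB"))
  mt <- effect_matrix(assemble_matrix(
    make_single_matrix_records(t(v), compound_a = "drugB2",
                               compound_b = "drugA2"),
    "L1", "drugB2", "drugA2"))
  s1 <- synergy_score(delta_matrix(m))$score
  s2 <- synergy_score(delta_matrix(mt))$score
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("raising observed inhibition at a combination cell raises the score", {
  va <- c(1, 0.9, 0.8, 0.7, 0.6, 0.5)
  v <- outer(va, va)
  m <- effect_matrix(assemble_matrix(make_single_matrix_records(v),
                                     "L1", "drugA", "drugB"))
  base <- synergy_score(delta_matrix(m))$score
  v2 <- v
  v2[3, 5] <- v2[3, 5] - 0.1   # more inhibition at one dose pair
  m2 <- effect_matrix(assemble_matrix(make_single_matrix_records(v2),
                                      "L1", "drugA", "drugB"))
  expect_gt(synergy_score(delta_matrix(m2))$score, base)
})

test_that("replicate summaries give mean and n-1 standard deviation", {
  res <- lapply(c(20, 30), function(s) {
    structure(list(score = s,
                   metadata = list(cell_line = "L1", compound_a = "A",
                                   compound_b = "B", replicate = 1)),
              class = "synergy_result")
  })
  s <- replicate_summary(res)
  expect_equal(s$mean_score, 25.0)
  expect_equal(s$sd_score, sd(c(20, 30)))
  expect_equal(s$n_replicates, 2)

  single <- replicate_summary(res[1])
  expect_equal(single$mean_score, 20)
  expect_true(is.na(single$sd_score))

  mixed <- res
  mixed[[2]]$metadata$cell_line <- "L2"
  expect_error(replicate_summary(mixed), "grouping error")
})

test_that("injected synergy is recovered as mean score near the injection", {
  inj <- data.frame(compound = "c01", genotype = "deficient", delta = 0.25)
  spec <- screen_spec(compounds = "c01", cell_lines = "L1",
                      genotypes = "deficient", injected = inj,
                      sigma = 0.05, replicates = 6, seed = 31)
  rec <- gen_screen(spec)
  results <- lapply(1:6, function(rep) {
    synergy_score(delta_matrix(effect_matrix(
      assemble_matrix(rec, "L1", "c01", "GSK126", replicate = rep))))
  })
  s <- replicate_summary(results)
  se <- s$sd_score / sqrt(s$n_replicates)
  expect_lt(abs(s$mean_score - 25), 3 * se + 1e-9)
})
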