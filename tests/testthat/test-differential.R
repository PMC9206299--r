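test_that("a full synthetic screen yields one summary per condition", {
  spec <- screen_spec(sigma = 0.05, seed = 7)
  rec <- gen_screen(spec)
  sres <- score_screen(rec)
  expect_equal(nrow(sres$summaries), 27 * 4)
  expect_equal(nrow(sres$qc), 0)
})

test_that("an incomplete condition is skipped with a QC entry, not dropped silently", {
  spec <- screen_spec(compounds = c("c01", "c02"), sigma = 0, seed = 8)
  rec <- gen_screen(spec)
  drop_row <- which(rec$cell_line == "KB1P-G3" & rec$compound_a == "c02" &
                      rec$conc_a > 0 & rec$conc_b > 0)[1]
  rec <- rec[-drop_row, ]
  expect_warning(sres <- score_screen(rec), "skipped")
  expect_equal(nrow(sres$summaries), 2 * 4 - 1)
  expect_equal(nrow(sres$qc), 1)
  expect_match(sres$qc$reason, "incomplete grid")
})

test_that("the genotype difference uses unweighted per-genotype means", {
  sm <- data.frame(
    cell_line = c("D1", "D2", "P1", "P2"),
    genotype = c("deficient", "deficient", "proficient", "proficient"),
    compound_a = "cmpX", compound_b = "anchor",
    mean_score = c(26.6, 22.9, 4.0, 4.0),
    sd_score = NA_real_, n_replicates = 1)
  sres <- structure(list(summaries = sm, qc = data.frame(),
                         genotypes = c(D1 = "deficient", D2 = "deficient",
                                       P1 = "proficient", P2 = "proficient")),
                    class = "screen_result")
  rk <- genotype_difference_ranking(sres)
  expect_equal(rk$difference, mean(c(26.6, 22.9)) - 4.0)
  expect_equal(rk$difference, 20.75)
  expect_true(rk$hit)
})

test_that("identical scores rank lexicographically and never flag hits below 15", {
  sm <- expand.grid(cell_line = c("D1", "P1"),
                    compound_a = c("zeta", "alpha", "mid"),
                    stringsAsFactors = FALSE)
  sm$genotype <- ifelse(sm$cell_line == "D1", "deficient", "proficient")
  sm$compound_b <- "anchor"
  sm$mean_score <- 5
  sm$sd_score <- NA_real_
  sm$n_replicates <- 1
  sres <- structure(list(summaries = sm, qc = data.frame(),
                         genotypes = c(D1 = "deficient", P1 = "proficient")),
                    class = "screen_result")
  rk <- genotype_difference_ranking(sres)
  expect_equal(rk$compound, c("alpha", "mid", "zeta"))
  expect_equal(rk$rank, 1:3)
  expect_false(any(rk$hit))
})

test_that("a compound missing one genotype is excluded and reported", {
  sm <- data.frame(cell_line = c("D1", "P1", "D1"),
                   genotype = c("deficient", "proficient", "deficient"),
                   compound_a = c("c01", "c01", "c02"),
                   compound_b = "anchor",
                   mean_score = c(10, 2, 30), sd_score = NA_real_,
                   n_replicates = 1)
  sres <- structure(list(summaries = sm, qc = data.frame(),
                         genotypes = c(D1 = "deficient", P1 = "proficient")),
                    class = "screen_result")
  rk <- genotype_difference_ranking(sres)
  expect_equal(nrow(rk), 1)
  expect_equal(attr(rk, "excluded"), "c02")
})

test_that("ranks are invariant to compound input order and score shifts", {
  inj <- data.frame(compound = "compound05", genotype = "deficient",
                    delta = 0.25)
  spec <- screen_spec(compounds = sprintf("compound%02d", 1:6),
                      injected = inj, sigma = 0.05, seed = 13)
  sres <- score_screen(gen_screen(spec))
  rk <- genotype_difference_ranking(sres)

  shuffled <- sres
  shuffled$summaries <- sres$summaries[sample(nrow(sres$summaries)), ]
  rk2 <- genotype_difference_ranking(shuffled)
  expect_equal(rk2$compound, rk$compound)
  expect_equal(rk2$rank, rk$rank)

  shifted <- sres
  shifted$summaries$mean_score <- shifted$summaries$mean_score + 50
  rk3 <- genotype_difference_ranking(shifted)
  expect_equal(rk3$compound, rk$compound)
  expect_equal(rk3$difference, rk$difference, tolerance = 1e-12)
})

test_that("deficient-only injection puts the injected compound on top", {
  inj <- data.frame(compound = "compound13", genotype = "deficient",
                    delta = 0.25)
  spec <- screen_spec(injected = inj, sigma = 0.05, seed = 17)
  sres <- score_screen(gen_screen(spec))
  rk <- genotype_difference_ranking(sres)
  expect_equal(rk$compound[1], "compound13")
  expect_true(rk$hit[1])
  def <- sres$summaries$mean_score[sres$summaries$compound_a == "compound13" &
                                     sres$summaries$genotype == "deficient"]
  expect_lt(abs(mean(def) - 25), 5)
})

test_that("a zero-noise null screen has all differences zero and no hits", {
  spec <- screen_spec(compounds = sprintf("c%02d", 1:4), sigma = 0, seed = 19)
  sres <- score_screen(gen_screen(spec))
  rk <- genotype_difference_ranking(sres)
  expect_equal(rk$difference, rep(0, 4), tolerance = 1e-10)
  expect_false(any(rk$hit))
})
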