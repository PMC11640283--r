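test_that("comparison records follow the clonal-fraction rule", {
  v <- data.frame(
    patient_id = c("P01", "P01", "P02", "P02", "P03", "P03", "P03"),
    gene = c("JAK2", "TET2", "ASXL1", "SRSF2", "DDX41", "TP53", "EZH2"),
    vaf = c(0.45, 0.20, 0.30, 0.28, 0.45, 0.30, 0.10),
    origin = c("somatic", "somatic", "somatic", "somatic",
               "germline", "somatic", "somatic"),
    pathogenic = TRUE)
  coh <- mn_cohort(toy_clinical(3), v)
  rec <- build_pairwise_comparisons(coh)
  # P01: cf 0.90 vs 0.40 -> JAK2 wins; P02: cf gap 0.04 <= margin -> nothing;
  # P03: germline DDX41 excluded, TP53 (0.6) beats EZH2 (0.2)
  expect_equal(nrow(rec), 2)
  expect_equal(rec$winner[rec$patient_id == "P01"], "JAK2")
  expect_equal(rec$loser[rec$patient_id == "P01"], "TET2")
  expect_equal(rec$winner[rec$patient_id == "P03"], "TP53")
  expect_false("DDX41" %in% c(rec$winner, rec$loser))
  # single-mutation patients contribute nothing
  v1 <- v[1, ]
  expect_equal(nrow(build_pairwise_comparisons(mn_cohort(toy_clinical(1),
                                                         v1))), 0)
})

test_that("symmetric and circular records give zero abilities", {
  rec <- data.frame(winner = c(rep("A", 5), rep("B", 5)),
                    loser = c(rep("B", 5), rep("A", 5)))
  f <- fit_bradley_terry(rec)
  expect_true(f$converged)
  expect_equal(unname(f$abilities), c(0, 0), tolerance = 1e-8)

  circ <- data.frame(winner = c("A", "B", "C"), loser = c("B", "C", "A"))
  f2 <- fit_bradley_terry(circ)
  expect_equal(unname(f2$abilities), c(0, 0, 0), tolerance = 1e-6)
  expect_error(fit_bradley_terry(data.frame(winner = "A", loser = "A")),
               "winner equals loser")
})

test_that("MM fit matches the grid-search oracle", {
  rec <- data.frame(
    winner = c(rep("A", 8), rep("B", 2), rep("B", 8), rep("C", 2)),
    loser = c(rep("B", 8), rep("A", 2), rep("C", 8), rep("B", 2)))
  f <- fit_bradley_terry(rec, ridge = 0.5)
  expect_true(f$converged)
  expect_true(f$abilities["A"] > f$abilities["B"])
  expect_true(f$abilities["B"] > f$abilities["C"])
  oracle <- bt_grid_oracle(f$wins)
  expect_equal(unname(f$abilities), oracle, tolerance = 1e-4)
  expect_equal(mean(f$abilities), 0, tolerance = 1e-12)

  # perfect separation stays finite thanks to the ridge: the two-player MLE
  # with wins (6.5, 0.5) solves p/(p+q) = 6.5/7, so s_A - s_B = log(13)
  sep <- data.frame(winner = rep("A", 6), loser = rep("B", 6))
  fs <- fit_bradley_terry(sep)
  expect_true(all(is.finite(fs$abilities)))
  expect_equal(unname(fs$abilities["A"] - fs$abilities["B"]), log(13),
               tolerance = 1e-5)
})

test_that("abilities are invariant to record duplication", {
  set.seed(1)
  rec <- data.frame(winner = sample(LETTERS[1:4], 40, TRUE),
                    loser = sample(LETTERS[1:4], 40, TRUE))
  rec <- rec[rec$winner != rec$loser, ]
  f1 <- fit_bradley_terry(rec)
  f2 <- fit_bradley_terry(rbind(rec, rec))
  # doubling all counts (including pseudo-wins) rescales nothing structurally,
  # so ability ordering is preserved and values move only slightly
  expect_equal(rank_mutations(f1), rank_mutations(f2))
})

test_that("ranking is by descending ability with alphabetical ties", {
  f <- structure(list(abilities = c(A = 1, B = 0, C = -1),
                      converged = TRUE), class = "bt_fit")
  expect_equal(rank_mutations(f), c("A", "B", "C"))
  f2 <- structure(list(abilities = c(Z = 0, M = 0, A = 0),
                       converged = TRUE), class = "bt_fit")
  expect_equal(rank_mutations(f2), c("A", "M", "Z"))
})

test_that("planted acquisition orders are recovered from VAFs", {
  cfg <- default_paper_config()
  cfg$groups <- cfg$groups["DP1"]
  cfg$noise_feature_prob <- 0
  cfg$groups$DP1$size <- 150
  cfg$groups$DP1$feature_probs <- c(JAK2 = 0.9, TET2 = 0.85, ASXL1 = 0.8)
  cfg$groups$DP1$driver_order <- c("JAK2", "TET2", "ASXL1")

  coh <- generate_cohort(cfg, seed = 21)
  rec <- build_pairwise_comparisons(coh)
  ord <- rank_mutations(fit_bradley_terry(rec))
  expect_equal(ord, c("JAK2", "TET2", "ASXL1"))
  expect_equal(kendall_tau(c("JAK2", "TET2", "ASXL1"), ord), 1)

  taus <- vapply(1:20, function(s) {
    coh <- generate_cohort(cfg, seed = 100 + s)
    ord <- rank_mutations(fit_bradley_terry(build_pairwise_comparisons(coh)))
    kendall_tau(cfg$groups$DP1$driver_order,
                ord[ord %in% cfg$groups$DP1$driver_order])
  }, numeric(1))
  expect_gte(mean(taus), 0.8)
})
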