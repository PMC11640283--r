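test_that("identical patients collapse to a single cluster", {
  x <- matrix(1L, 30, 5, dimnames = list(sprintf("P%02d", 1:30),
                                         paste0("g", 1:5)))
  s <- gibbs_sample_dpmm(mngroups:::new_feature_matrix(x),
                         iterations = 400, burn_in = 200, thin = 5,
                         seed = 13)
  modal_k <- as.integer(names(which.max(table(s$n_clusters))))
  expect_equal(modal_k, 1)
})

test_that("two orthogonal blocks are recovered exactly", {
  fm <- toy_blocks(13)
  s <- gibbs_sample_dpmm(fm, iterations = 500, burn_in = 250, thin = 5,
                         seed = 13)
  psm <- posterior_similarity(s)
  part <- consensus_partition(psm, s)
  truth <- rep(1:2, each = 60)
  expect_equal(length(unique(part)), 2)
  expect_equal(ari(part, truth), 1)
})

test_that("prior-only chain matches the CRP harmonic-sum mean", {
  x <- matrix(0L, 10, 3, dimnames = list(paste0("P", 1:10), paste0("f", 1:3)))
  x[, 1] <- 1L
  s <- gibbs_sample_dpmm(mngroups:::new_feature_matrix(x),
                         iterations = 21000, burn_in = 1000, thin = 1,
                         seed = 29, alpha = 1, prior_only = TRUE)
  expect_equal(mean(s$n_clusters), sum(1 / (1:10)), tolerance = 0.05)
})

test_that("posterior similarity has the required structure", {
  one <- matrix(1L, 1, 5)
  expect_equal(posterior_similarity(one), matrix(1, 5, 5))
  singles <- matrix(1:5, 1, 5)
  expect_equal(posterior_similarity(singles), diag(5))
  two <- rbind(c(1L, 1L, 2L, 2L), c(1L, 2L, 2L, 1L))
  psm <- posterior_similarity(two)
  expect_equal(psm, t(psm))
  expect_equal(diag(psm), rep(1, 4))
  expect_true(all(psm >= 0 & psm <= 1))
  # duplicating the sample list leaves the average unchanged
  expect_equal(posterior_similarity(rbind(two, two)), psm)
  # invariant under any relabelling of clusters within samples
  relab <- two
  relab[1, ] <- c(7L, 7L, 3L, 3L)
  expect_equal(posterior_similarity(relab), psm)
})

test_that("consensus partition honours block and identity psm", {
  s <- matrix(c(1L, 1L, 2L, 2L,
                1L, 2L, 3L, 4L), 2, 4, byrow = TRUE)
  block_psm <- matrix(0, 4, 4); block_psm[1:2, 1:2] <- 1
  block_psm[3:4, 3:4] <- 1
  expect_equal(unname(consensus_partition(block_psm, s)),
               c(1L, 1L, 2L, 2L))
  expect_equal(length(unique(consensus_partition(diag(4), s))), 4)
})

test_that("group profiles follow the Beta(1,1) posterior mean", {
  x <- rbind(matrix(1L, 3, 1), matrix(0L, 8, 1))
  dimnames(x) <- list(paste0("P", 1:11), "+8")
  fm <- mngroups:::new_feature_matrix(x)
  ch <- characterize_groups(rep(c("g1", "g2"), c(3, 8)), fm)
  expect_equal(ch$profile["g1", "+8"], 4 / 5)
  expect_equal(ch$profile["g2", "+8"], 1 / 10)
})

test_that("chains are reproducible given the seed", {
  fm <- toy_blocks(17, n_per = 25, d_per = 6)
  s1 <- gibbs_sample_dpmm(fm, iterations = 200, burn_in = 100, thin = 5,
                          seed = 99)
  s2 <- gibbs_sample_dpmm(fm, iterations = 200, burn_in = 100, thin = 5,
                          seed = 99)
  expect_identical(s1$assignments, s2$assignments)
  expect_identical(s1$alpha, s2$alpha)
  s3 <- gibbs_sample_dpmm(fm, iterations = 200, burn_in = 100, thin = 5,
                          seed = 100)
  expect_false(identical(s1$assignments, s3$assignments))
})

test_that("posterior-predictive assignment reproduces the validation workflow", {
  run <- fixture_default_run()
  fit <- run$fit
  # all-zero and unseen-feature rows fall back to DP0
  zero <- matrix(0L, 1, 3,
                 dimnames = list("Z1", c("JAK2", "TP53", "CALR")))
  expect_equal(unname(predict(fit, zero)), "DP0")
  unseen <- matrix(1L, 1, 2, dimnames = list("U1", c("FOO", "BAR")))
  expect_warning(p_unseen <- predict(fit, unseen), "no overlap")
  expect_equal(unname(p_unseen), "DP0")
  # a group's modal profile row maps back to that group
  groups <- setdiff(rownames(fit$group_profiles), "DP0")
  big <- names(sort(fit$group_sizes[groups], decreasing = TRUE))[1:3]
  for (g in big) {
    modal <- matrix(as.integer(fit$group_profiles[g, ] > 0.5), 1,
                    dimnames = list("M", fit$feature_names))
    expect_equal(unname(predict(fit, modal)), g)
  }
})

test_that("default synthetic cohort structure is recovered", {
  run <- fixture_default_run()
  fit <- run$fit
  expect_gte(ari(fit$labels, run$truth), 0.70)
  # at least 8 of the 10 planted groups map one-to-one by majority overlap:
  # the planted group's modal recovered cluster must have that planted group
  # as its own modal membership (mutual majority)
  planted <- setdiff(unique(run$truth), "DP0")
  tab <- table(run$truth, fit$labels)
  one_to_one <- sum(vapply(planted, function(g) {
    r <- colnames(tab)[which.max(tab[g, ])]
    rownames(tab)[which.max(tab[, r])] == g
  }, logical(1)))
  expect_gte(one_to_one, 8)
  # the largest recovered group is driven by JAK2
  groups <- setdiff(names(fit$group_sizes), "DP0")
  largest <- names(sort(fit$group_sizes[groups], decreasing = TRUE))[1]
  expect_equal(fit$top_features[[largest]][1], "JAK2")
})
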