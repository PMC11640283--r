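# shared fixtures; heavy objects are computed once per test run

.fix <- new.env(parent = emptyenv())

# default synthetic cohort + fitted grouping (the expensive fixture)
fixture_default_run <- function() {
  if (is.null(.fix$run)) {
    cohort <- generate_cohort(default_paper_config(), seed = 7)
    fm <- filter_by_prevalence(build_feature_matrix(cohort))
    fit <- dp_cluster(fm, seed = 7)
    tr <- attr(cohort, "truth")
    truth <- tr$true_group[match(names(fit$labels), tr$patient_id)]
    .fix$run <- list(cohort = cohort, fm = fm, fit = fit, truth = truth)
  }
  .fix$run
}

# small cohort for structural / IO tests: 50 patients, 4 groups
small_config <- function() {
  cfg <- default_paper_config()
  cfg$groups <- cfg$groups[c("DP1", "DP5", "DP2", "DP0")]
  cfg$groups$DP1$size <- 20
  cfg$groups$DP5$size <- 10
  cfg$groups$DP2$size <- 10
  cfg$groups$DP0$size <- 10
  cfg
}

# adjusted Rand index (chance-corrected partition agreement)
ari <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Kendall rank correlation between two orderings of the same items
kendall_tau <- function(order_a, order_b) {
  stopifnot(setequal(order_a, order_b))
  ra <- match(order_a, order_a)
  rb <- match(order_a, order_b)
  stats::cor(ra, rb, method = "kendall")
}

# exhaustive two-sided Fisher oracle: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= that of the observed table
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n2 <- c + d; k <- a + c
  if (m == 0 || n2 == 0 || k == 0 || b + d == 0) return(1)
  lo <- max(0, k - n2); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# two orthogonal feature blocks (the standard clustering toy)
toy_blocks <- function(seed = 13, n_per = 60, d_per = 10,
                       p_in = 0.9, p_out = 0.02) {
  set.seed(seed)
  x1 <- cbind(matrix(rbinom(n_per * d_per, 1, p_in), n_per),
              matrix(rbinom(n_per * d_per, 1, p_out), n_per))
  x2 <- cbind(matrix(rbinom(n_per * d_per, 1, p_out), n_per),
              matrix(rbinom(n_per * d_per, 1, p_in), n_per))
  x <- rbind(x1, x2)
  dimnames(x) <- list(sprintf("P%03d", seq_len(2 * n_per)),
                      sprintf("f%02d", seq_len(2 * d_per)))
  mngroups:::new_feature_matrix(x)
}

# brute-force oracle: maximise the ridged Bradley-Terry log-likelihood over a
# refining grid (two free parameters after mean-centring; 3 items)
bt_grid_oracle <- function(W) {
  N <- W + t(W)
  ll <- function(s) {
    tot <- 0
    for (i in 1:2) for (j in (i + 1):3)
      if (N[i, j] > 0)
        tot <- tot + W[i, j] * (s[i] - log(exp(s[i]) + exp(s[j]))) +
                     W[j, i] * (s[j] - log(exp(s[i]) + exp(s[j])))
    tot
  }
  centre <- c(0, 0)
  width <- 4
  for (pass in 1:6) {
    g1 <- seq(centre[1] - width, centre[1] + width, length.out = 41)
    g2 <- seq(centre[2] - width, centre[2] + width, length.out = 41)
    best <- -Inf
    for (a in g1) for (b in g2) {
      s <- c(a, b, -(a + b))
      v <- ll(s)
      if (v > best) { best <- v; centre <- c(a, b) }
    }
    width <- width / 10
  }
  s <- c(centre, -(sum(centre)))
  s - mean(s)
}

# helper writing an in-memory cohort to a temp dir of TSVs
write_temp_tables <- function(clinical, variants = NULL, karyotype = NULL) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  if (is.null(variants))
    variants <- data.frame(patient_id = character(), gene = character(),
                           vaf = numeric(), origin = character(),
                           pathogenic = logical())
  if (is.null(karyotype))
    karyotype <- data.frame(patient_id = character(), coding = character(),
                            value = character())
  paths <- file.path(dir, c("clinical.tsv", "variants.tsv", "karyotype.tsv"))
  utils::write.table(clinical, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(variants, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(karyotype, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  paths
}

toy_clinical <- function(n = 3) {
  data.frame(patient_id = sprintf("P%02d", seq_len(n)),
             diagnosis = "MDS", subtype = "MDS-LB",
             age_years = 60, sex = "F",
             os_years = seq_len(n), death = FALSE,
             hsct_years = NA_real_)
}
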