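#' Collapsed Gibbs sampling for the Dirichlet-process Bernoulli mixture
#'
#' Samples the posterior over partitions of patients under a Dirichlet-process
#' mixture whose components are products of independent Bernoulli features
#' with Beta(1, 1) priors. Component parameters are marginalised, so each
#' sweep reassigns every patient with probability proportional to
#' `n_k * L_k(x)` for an existing cluster and `alpha * L_new(x)` for a fresh
#' one; the concentration `alpha` is resampled each sweep via the standard
#' Beta auxiliary-variable Gamma-mixture update under a Gamma prior.
#'
#' @param fm an `mn_feature_matrix`; rows with no abnormality are not
#'   eligible and must be removed first (see [split_eligibility()]).
#' @param iterations total Gibbs sweeps.
#' @param burn_in sweeps discarded before retaining samples.
#' @param thin keep every `thin`-th post-burn-in sweep.
#' @param seed integer seed; the chain is fully deterministic given it.
#' @param alpha_prior shape and rate of the Gamma prior on the concentration.
#' @param alpha fixed concentration; when supplied, resampling is disabled.
#' @param prior_only if `TRUE` the likelihood is switched off and the chain
#'   targets the Chinese-restaurant-process prior alone (used for prior
#'   calibration checks).
#' @param init initial partition: `"agglomerative"` (the default — a
#'   deterministic Ward agglomeration on binary distance cut at
#'   `min(n, 30)` clusters; single-site updates merge readily but open new
#'   clusters extremely rarely at this dimension, so the chain is started
#'   over-split and purified), `"singleton"` (every patient its own
#'   cluster), `"single"` (one shared cluster), or an integer vector of
#'   starting labels.
#' @return object of class `dpmm_samples`: list with `assignments`
#'   (matrix, one retained sweep per row, cluster indices per patient),
#'   `alpha` (retained concentration draws), `n_clusters`,
#'   `trace_n_clusters` (per-sweep cluster count), `patient_ids`,
#'   `feature_names`.
#' @export
gibbs_sample_dpmm <- function(fm, iterations = 2000, burn_in = 1000,
                              thin = 10, seed, alpha_prior = c(1, 1),
                              alpha = NULL, prior_only = FALSE,
                              init = "agglomerative") {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  if (ncol(fm$x) == 0L) stop("feature matrix has no features", call. = FALSE)
  if (nrow(fm$x) < 2L) stop("need at least 2 eligible patients", call. = FALSE)
  if (iterations <= burn_in) stop("iterations must exceed burn_in",
                                  call. = FALSE)
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)
  fixed <- !is.null(alpha)
  alpha0 <- if (fixed) alpha else stats::rgamma(1, alpha_prior[1],
                                                alpha_prior[2])
  n <- nrow(fm$x)
  z0 <- if (is.numeric(init)) {
    stopifnot(length(init) == n)
    match(init, unique(init)) - 1L          # compact 0-based labels
  } else switch(match.arg(init, c("agglomerative", "singleton", "single")),
                agglomerative = {
                  if (n <= 30) seq_len(n) - 1L else
                    stats::cutree(stats::hclust(stats::dist(fm$x, "binary"),
                                                method = "ward.D2"),
                                  k = 30) - 1L
                },
                singleton = seq_len(n) - 1L,
                single = rep(0L, n))
  res <- .dpmm_gibbs_cpp(fm$x, as.integer(z0),
                         as.integer(iterations), as.integer(burn_in),
                         as.integer(thin), alpha_prior[1], alpha_prior[2],
                         alpha0, !fixed, prior_only)
  res$patient_ids <- fm$patient_ids
  res$feature_names <- fm$feature_names
  class(res) <- "dpmm_samples"
  res
}

#' Posterior similarity matrix
#'
#' `psm[i, j]` is the fraction of retained posterior samples in which
#' patients `i` and `j` share a cluster; symmetric with unit diagonal and
#' invariant to any relabelling of clusters within samples.
#'
#' @param samples a `dpmm_samples` object (or a bare assignment matrix with
#'   one sample per row).
#' @return an n-by-n numeric matrix.
#' @export
posterior_similarity <- function(samples) {
  a <- if (inherits(samples, "dpmm_samples")) samples$assignments else
    as.matrix(samples)
  if (nrow(a) < 1L) stop("need at least one sample", call. = FALSE)
  psm <- .psm_cpp(a)
  if (inherits(samples, "dpmm_samples"))
    dimnames(psm) <- list(samples$patient_ids, samples$patient_ids)
  psm
}

#' Consensus partition by Dahl's least-squares criterion
#'
#' Among the sampled partitions, returns the one whose co-clustering
#' indicator matrix is closest (in summed squared deviation over pairs) to
#' the posterior similarity matrix; ties break to the earliest sample.
#'
#' @param psm posterior similarity matrix from [posterior_similarity()].
#' @param samples the `dpmm_samples` the psm was computed from.
#' @return integer vector of cluster labels (1-based, relabelled by
#'   decreasing cluster size), named by patient id when available.
#' @export
consensus_partition <- function(psm, samples) {
  a <- if (inherits(samples, "dpmm_samples")) samples$assignments else
    as.matrix(samples)
  stopifnot(nrow(psm) == ncol(a))
  scores <- .dahl_scores_cpp(a, psm)
  best <- a[which.min(scores), ]
  sizes <- sort(table(best), decreasing = TRUE)
  relab <- stats::setNames(seq_along(sizes), names(sizes))
  out <- as.integer(relab[as.character(best)])
  if (inherits(samples, "dpmm_samples")) names(out) <- samples$patient_ids
  out
}

#' Characterise genomic groups by their feature profiles
#'
#' For every group and feature, the posterior mean presence probability under
#' a Beta(1, 1) prior, `(carriers + 1) / (size + 2)`, and its enrichment
#' ratio over the cohort-wide prevalence.
#'
#' @param grouping vector of group labels, one per patient in `fm` (any
#'   labels; typically `"DP1"`, `"DP2"`, ...).
#' @param fm the `mn_feature_matrix` the groups were derived from.
#' @return list with matrices `profile` and `enrichment`
#'   (groups x features), `sizes`, and `top_features` (per group, features
#'   ordered by decreasing enrichment among carried features).
#' @export
characterize_groups <- function(grouping, fm) {
  stopifnot(inherits(fm, "mn_feature_matrix"),
            length(grouping) == nrow(fm$x))
  groups <- sort(unique(as.character(grouping)))
  d <- ncol(fm$x)
  prof <- matrix(NA_real_, length(groups), d,
                 dimnames = list(groups, fm$feature_names))
  sizes <- integer(length(groups)); names(sizes) <- groups
  for (g in groups) {
    rows <- fm$x[grouping == g, , drop = FALSE]
    sizes[g] <- nrow(rows)
    prof[g, ] <- (colSums(rows) + 1) / (nrow(rows) + 2)
  }
  cohort_prev <- pmax(fm$prevalence, 1e-12)
  enr <- sweep(prof, 2, cohort_prev, "/")
  top <- lapply(groups, function(g) {
    carried <- prof[g, ] > 1 / (sizes[g] + 2)   # at least one carrier
    names(sort(enr[g, carried], decreasing = TRUE))
  })
  names(top) <- groups
  list(profile = prof, enrichment = enr, sizes = sizes, top_features = top)
}

# canonical group identity by defining lesion: used to give recovered
# clusters paper-style names (and hence risk categories) via their top
# enriched feature
.canonical_signatures <- function() {
  c(JAK2 = "DP1",
    CALR = "DP5",
    TP53 = "DP2", complex = "DP2", "-5/5q-nonisolated" = "DP2",
    "-7/7q-" = "DP2", "-17/17p-/t17" = "DP2", "-9/9q-" = "DP2",
    "-13/13q-" = "DP2", "-18" = "DP2", "-12/12p-" = "DP2",
    "-16/16q-" = "DP2",
    NPM1 = "DP9", WT1 = "DP9", DNMT3A = "DP9",
    SETBP1 = "DP7", CSF3R = "DP7", NRAS = "DP7", GATA2 = "DP7",
    NF1 = "DP7", PTPN11 = "DP7",
    TET2 = "DP4", SRSF2 = "DP4", STAG2 = "DP4", ZRSR2 = "DP4",
    KRAS = "DP4", IDH2 = "DP4", CUX1 = "DP4",
    U2AF1 = "DP3", "+8" = "DP3", RUNX1 = "DP3", BCOR = "DP3",
    PHF6 = "DP3", EZH2 = "DP3", "+21" = "DP3", "-20/20q-" = "DP3",
    ASXL1 = "DP3",
    CBL = "DP6", ETV6 = "DP6", KMT2D = "DP6",
    SF3B1 = "DP10", DDX41 = "DP10", MPL = "DP10", "-Y" = "DP10",
    isolated_del5q = "DP10",
    "+1/1q+" = "DP8", "der(1;7)" = "DP8")
}

#' Match recovered groups to canonical genomic-group identities
#'
#' Recovered clusters are named `DP1`, `DP2`, ... by size, which carries no
#' biological meaning. This helper walks each cluster's enrichment-ranked
#' carried features and returns the canonical identity of the first
#' group-defining lesion found (JAK2 group, CALR group, TP53/complex
#' group, ...). Several recovered clusters may share an identity; clusters
#' whose features match no signature return `NA`.
#'
#' @param fit a fitted `dpmm`.
#' @return named character vector: recovered group label -> canonical
#'   identity (`"DP0"`..`"DP10"` or `NA`).
#' @export
match_group_identities <- function(fit) {
  stopifnot(inherits(fit, "dpmm"))
  sig <- .canonical_signatures()
  grps <- names(fit$group_sizes)
  out <- stats::setNames(rep(NA_character_, length(grps)), grps)
  out["DP0"] <- "DP0"
  for (g in setdiff(grps, "DP0")) {
    ranked <- fit$top_features[[g]]
    hit <- ranked[ranked %in% names(sig)]
    if (length(hit)) out[g] <- unname(sig[hit[1]])
  }
  out
}

#' Fit the Dirichlet-process genomic grouping model
#'
#' The package's central fit: patients carrying at least one retained genomic
#' abnormality are clustered with the Dirichlet-process Bernoulli mixture
#' ([gibbs_sample_dpmm()]); a consensus partition is extracted from the
#' posterior similarity matrix by Dahl's least-squares criterion; groups are
#' labelled `DP1`, `DP2`, ... by decreasing size and characterised by their
#' enriched features. Patients with an all-zero feature row form the
#' `DP0` ("no abnormality") group outside the mixture.
#'
#' @param fm an `mn_feature_matrix`, typically prevalence-filtered
#'   ([filter_by_prevalence()]). Zero rows are allowed; they go to `DP0`.
#' @inheritParams gibbs_sample_dpmm
#' @return an object of class `dpmm` with components `labels` (named group
#'   label per patient, `DP0` included), `canonical_labels` (paper-style
#'   group identities from [match_group_identities()], used for risk
#'   stratification), `group_identity`, `psm`, `samples`, `group_profiles`,
#'   `group_sizes`, `n_groups` (excluding DP0), `alpha` (posterior draws),
#'   `feature_names`, and the call. Methods: `print`, `summary`, `predict`,
#'   `plot`.
#' @examples
#' cfg <- default_paper_config()
#' cfg$groups <- cfg$groups[c("DP1", "DP5", "DP0")]
#' cfg$groups$DP1$size <- 40; cfg$groups$DP5$size <- 30
#' cfg$groups$DP0$size <- 10
#' coh <- generate_cohort(cfg, seed = 1)
#' fm <- filter_by_prevalence(build_feature_matrix(coh))
#' fit <- dp_cluster(fm, iterations = 300, burn_in = 150, seed = 1)
#' table(fit$labels)
#' @export
dp_cluster <- function(fm, iterations = 2000, burn_in = 1000, thin = 10,
                       seed, alpha_prior = c(1, 1), alpha = NULL) {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  elig <- split_eligibility(fm)
  keep <- fm$patient_ids %in% elig$clustering_ids
  sub <- new_feature_matrix(fm$x[keep, , drop = FALSE],
                            feature_type = fm$feature_type)
  samples <- gibbs_sample_dpmm(sub, iterations = iterations,
                               burn_in = burn_in, thin = thin, seed = seed,
                               alpha_prior = alpha_prior, alpha = alpha)
  psm <- posterior_similarity(samples)
  part <- consensus_partition(psm, samples)
  labels <- stats::setNames(rep("DP0", length(fm$patient_ids)),
                            fm$patient_ids)
  labels[names(part)] <- paste0("DP", part)
  chars <- characterize_groups(labels, fm)
  fit <- structure(list(call = match.call(),
                 labels = labels,
                 psm = psm,
                 samples = samples,
                 group_profiles = chars$profile,
                 group_enrichment = chars$enrichment,
                 group_sizes = chars$sizes,
                 top_features = chars$top_features,
                 n_groups = length(unique(part)),
                 alpha = samples$alpha,
                 feature_names = fm$feature_names,
                 dp0_ids = elig$dp0_ids,
                 seed = seed),
            class = "dpmm")
  ident <- match_group_identities(fit)
  fit$group_identity <- ident
  fit$canonical_labels <- stats::setNames(unname(ident[fit$labels]),
                                          names(fit$labels))
  fit
}

#' @export
print.dpmm <- function(x, ...) {
  cat("Dirichlet-process genomic grouping\n")
  cat(sprintf("  %d patients, %d features, %d groups (+ DP0: %d patients)\n",
              length(x$labels), length(x$feature_names), x$n_groups,
              sum(x$labels == "DP0")))
  cat(sprintf("  posterior mean concentration alpha = %.3f\n",
              mean(x$alpha)))
  invisible(x)
}

#' @export
summary.dpmm <- function(object, n_top = 3, ...) {
  grp <- names(sort(object$group_sizes, decreasing = TRUE))
  lines <- vapply(grp, function(g) {
    tops <- if (g == "DP0") "(no retained abnormality)" else
      paste(utils::head(object$top_features[[g]], n_top), collapse = ", ")
    ident <- object$group_identity[[g]]
    sprintf("%-5s n=%4d  identity %-5s top features: %s",
            g, object$group_sizes[[g]],
            if (is.null(ident) || is.na(ident)) "?" else ident, tops)
  }, character(1))
  out <- list(n_groups = object$n_groups, lines = lines,
              alpha = mean(object$alpha))
  class(out) <- "summary.dpmm"
  out
}

#' @export
print.summary.dpmm <- function(x, ...) {
  cat(sprintf("Genomic groups: %d (plus DP0); mean alpha %.3f\n\n",
              x$n_groups, x$alpha))
  cat(paste(x$lines, collapse = "\n"), "\n")
  invisible(x)
}

#' @export
plot.dpmm <- function(x, ...) {
  ord <- order(x$labels[rownames(x$psm)])
  image(x$psm[ord, ord], axes = FALSE, useRaster = TRUE,
        main = "Posterior co-clustering (patients ordered by group)", ...)
  invisible(x)
}

#' Assign new patients to fitted genomic groups
#'
#' Posterior-predictive classification reproducing the validation-cohort
#' workflow: each new patient's feature row (restricted to the training
#' vocabulary; unseen features are dropped) is scored against every fitted
#' group with size-weighted products of the per-feature posterior Bernoulli
#' means, plus a new-cluster option weighted by the concentration. A patient
#' is assigned to the best group when that group's share of
#' (best group + new cluster) mass reaches `confidence`, and is otherwise
#' `"unassigned"`; an all-zero row is `"DP0"`.
#'
#' @param object a fitted `dpmm`.
#' @param newdata an `mn_feature_matrix`, an `mn_cohort`, or a binary matrix
#'   with feature columns (any subset/superset of the training vocabulary).
#' @param confidence assignment confidence threshold in (0, 1].
#' @param ... unused.
#' @return character vector of group labels (`"DP0"`, `"DP1"`, ...,
#'   `"unassigned"`), named by patient id when available.
#' @export
predict.dpmm <- function(object, newdata, confidence = 0.9, ...) {
  if (inherits(newdata, "mn_cohort"))
    newdata <- build_feature_matrix(newdata)
  x <- if (inherits(newdata, "mn_feature_matrix")) newdata$x else
    as.matrix(newdata)
  if (is.null(colnames(x)))
    stop("newdata must have feature names", call. = FALSE)
  train <- object$feature_names
  aligned <- matrix(0L, nrow(x), length(train),
                    dimnames = list(rownames(x), train))
  common <- intersect(colnames(x), train)
  if (!length(common) && any(x > 0))
    warning("no overlap between newdata features and training vocabulary")
  aligned[, common] <- x[, common, drop = FALSE]

  groups <- setdiff(rownames(object$group_profiles), "DP0")
  prof <- object$group_profiles[groups, , drop = FALSE]
  sizes <- object$group_sizes[groups]
  alpha <- mean(object$alpha)
  d <- length(train)
  lp1 <- log(prof); lp0 <- log1p(-prof)
  out <- character(nrow(aligned))
  for (i in seq_len(nrow(aligned))) {
    xi <- aligned[i, ]
    if (!any(xi > 0)) { out[i] <- "DP0"; next }
    lw <- log(sizes) + lp1 %*% xi + lp0 %*% (1 - xi)
    lw_new <- log(alpha) + d * log(0.5)
    all_lw <- c(lw, lw_new)
    w <- exp(all_lw - max(all_lw))
    w <- w / sum(w)
    top <- which.max(w[seq_along(groups)])
    share <- w[top] / (w[top] + w[length(w)])
    out[i] <- if (share >= confidence) groups[top] else "unassigned"
  }
  names(out) <- rownames(aligned)
  out
}
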