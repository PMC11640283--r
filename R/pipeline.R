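#' Write analysis result tables
#'
#' Emits the standard pipeline artifacts with stable column order:
#' `assignments.tsv` (patient, group, risk category),
#' `associations.tsv` (pairwise test table), `bt_abilities.tsv`
#' (per-group Bradley-Terry abilities with win/loss counts),
#' `survival_summary.json`, and optionally `dag.tsv` (learned network
#' edges). Writing is deterministic: identical inputs give byte-identical
#' files.
#'
#' @param bundle named list; recognised elements: `labels` (named group
#'   labels), `identities` (canonical identities used for the risk-category
#'   column; defaults to `labels`), `associations` (data.frame from [classify_pairs()]),
#'   `bt_fits` (list from [group_acquisition_orders()]), `survival` (list
#'   from [stratified_report()]), `dag` (an `mn_dag`).
#' @param out_dir output directory, created if needed.
#' @return character vector of written paths.
#' @export
write_results <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2) != 0)
    stop("output directory not writable: ", out_dir, call. = FALSE)
  paths <- character(0)
  wt <- function(df, file) {
    p <- file.path(out_dir, file)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  if (!is.null(bundle$labels)) {
    lab <- bundle$labels
    ident <- if (!is.null(bundle$identities)) bundle$identities else lab
    known <- !is.na(ident) & ident %in% paste0("DP", 0:10)
    risk <- rep(NA_character_, length(lab))
    risk[known] <- as.character(map_risk_categories(ident[known]))
    df <- data.frame(patient_id = names(lab), group = unname(lab),
                     identity = unname(ident), risk_category = risk)
    paths <- c(paths, wt(df[order(df$patient_id), ], "assignments.tsv"))
  }
  if (!is.null(bundle$associations))
    paths <- c(paths, wt(bundle$associations, "associations.tsv"))
  if (!is.null(bundle$bt_fits)) {
    rows <- lapply(names(bundle$bt_fits), function(g) {
      f <- bundle$bt_fits[[g]]
      raw_w <- f$wins - f$ridge * (f$n_comparisons > 0)  # drop pseudo-wins
      data.frame(group = g, gene = names(f$abilities),
                 ability = round(unname(f$abilities), 6),
                 n_wins = unname(rowSums(raw_w)),
                 n_losses = unname(colSums(raw_w)))
    })
    paths <- c(paths, wt(do.call(rbind, rows), "bt_abilities.tsv"))
  }
  if (!is.null(bundle$survival)) {
    s <- bundle$survival
    js <- list(
      by_group = lapply(s$by_group, function(k)
        list(n = k$n, events = k$n_events,
             five_year_rate = k$five_year_rate,
             median_years = if (is.na(k$median_years)) NULL else
               k$median_years)),
      by_category = lapply(s$by_category, function(k)
        list(n = k$n, events = k$n_events,
             five_year_rate = k$five_year_rate,
             median_years = if (is.na(k$median_years)) NULL else
               k$median_years)),
      logrank_groups = s$logrank_groups[c("chi2", "df", "p")],
      category_hr = if (!is.null(s$category_hr))
        as.list(s$category_hr$hazard_ratios))
    p <- file.path(out_dir, "survival_summary.json")
    jsonlite::write_json(js, p, auto_unbox = TRUE, digits = 10,
                         pretty = TRUE)
    paths <- c(paths, p)
  }
  if (!is.null(bundle$dag)) {
    df <- as.data.frame(bundle$dag$edges, stringsAsFactors = FALSE)
    paths <- c(paths, wt(df, "dag.tsv"))
  }
  paths
}

#' Run the full genomic-grouping pipeline
#'
#' End-to-end orchestration in the published order: cohort in (or generated),
#' binary feature matrix, prevalence filter, eligibility split,
#' Dirichlet-process clustering with consensus grouping, then per-cohort
#' characterisation — pairwise association testing, Bayesian-network
#' learning, Bradley-Terry acquisition ordering — and survival risk
#' stratification. Every random stage consumes a sub-seed derived
#' deterministically from the master seed and the stage name, so reruns are
#' byte-identical.
#'
#' @param cohort an `mn_cohort`; alternatively `NULL` with
#'   `synthetic = TRUE` to generate a synthetic cohort.
#' @param config `mn_cohort_config` used when `synthetic = TRUE`
#'   (default [default_paper_config()]).
#' @param out_dir directory for artifacts (see [write_results()]); `NULL`
#'   skips writing.
#' @param seed master seed.
#' @param synthetic generate the cohort with [default_paper_config()]?
#' @param threshold prevalence filter cut.
#' @param iterations,burn_in,thin Gibbs sampler controls.
#' @param skip_network skip structure learning (the slowest optional stage)?
#' @param network_restarts hill-climb restarts.
#' @param censor_at_hsct survival censoring rule.
#' @param alpha_level FDR level for pair classification.
#' @return list of class `mn_pipeline` with `cohort`, `fm`, `fit` (the
#'   `dpmm`), `associations`, `dag`, `bt_fits`, `survival`, `manifest`
#'   (written paths), `seed`, `timings`.
#' @export
run_pipeline <- function(cohort = NULL, out_dir = NULL, seed = 1,
                         synthetic = is.null(cohort),
                         config = default_paper_config(), threshold = 0.01,
                         iterations = 2000, burn_in = 1000, thin = 10,
                         skip_network = FALSE, network_restarts = 10,
                         censor_at_hsct = TRUE, alpha_level = 0.05) {
  sub_seed <- function(stage)
    (seed * 1000003L + sum(utf8ToInt(stage)) * 7919L) %% 2147483647L
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  if (synthetic)
    cohort <- generate_cohort(config, seed = sub_seed("generate"))
  stopifnot(inherits(cohort, "mn_cohort"))
  timings["cohort"] <- tic() - t0

  t0 <- tic()
  fm <- filter_by_prevalence(build_feature_matrix(cohort),
                             threshold = threshold)
  timings["feature_matrix"] <- tic() - t0

  t0 <- tic()
  fit <- dp_cluster(fm, iterations = iterations, burn_in = burn_in,
                    thin = thin, seed = sub_seed("gibbs"))
  timings["dp_cluster"] <- tic() - t0

  t0 <- tic()
  assoc <- classify_pairs(fm, alpha = alpha_level)
  timings["association"] <- tic() - t0

  dag <- NULL
  if (!skip_network) {
    t0 <- tic()
    dag <- hill_climb_structure(fm, restarts = network_restarts,
                                seed = sub_seed("network"))
    timings["network"] <- tic() - t0
  }

  t0 <- tic()
  bt_fits <- group_acquisition_orders(cohort, fit$labels)
  timings["clonal_order"] <- tic() - t0

  t0 <- tic()
  surv <- stratified_report(cohort, fit$canonical_labels,
                            censor_at_hsct = censor_at_hsct)
  timings["survival"] <- tic() - t0

  manifest <- character(0)
  if (!is.null(out_dir))
    manifest <- write_results(
      list(labels = fit$labels, identities = fit$canonical_labels,
           associations = assoc, bt_fits = bt_fits,
           survival = surv, dag = dag), out_dir)

  structure(list(cohort = cohort, fm = fm, fit = fit,
                 associations = assoc, dag = dag, bt_fits = bt_fits,
                 survival = surv, manifest = manifest, seed = seed,
                 timings = timings),
            class = "mn_pipeline")
}

#' @export
print.mn_pipeline <- function(x, ...) {
  cat("Genomic-grouping pipeline run\n")
  cat(sprintf("  seed %d; %d patients; %d features; %d genomic groups\n",
              x$seed, nrow(x$cohort$clinical), ncol(x$fm$x),
              x$fit$n_groups))
  sig <- sum(x$associations$relation != "none")
  cat(sprintf("  significant feature pairs: %d of %d\n", sig,
              nrow(x$associations)))
  if (!is.null(x$dag))
    cat(sprintf("  network edges: %d\n", nrow(x$dag$edges)))
  cat(sprintf("  stage timings (s): %s\n",
              paste(sprintf("%s=%.1f", names(x$timings), x$timings),
                    collapse = ", ")))
  invisible(x)
}
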