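#' Build within-patient clonal-fraction comparisons
#'
#' For every patient in `group_ids` and every unordered pair of that
#' patient's somatic pathogenic mutations, converts VAF to clonal fraction
#' `cf = min(1, 2 * vaf)` (heterozygous autosomal assumption) and emits a
#' comparison record with the larger-cf gene as winner — the mutation in more
#' cells is taken to have been acquired earlier. Pairs whose clonal fractions
#' differ by at most `tie_margin` are uninformative and emit nothing.
#' Germline variants never enter the ordering.
#'
#' @param cohort an `mn_cohort`.
#' @param group_ids patient ids to draw comparisons from (default: all).
#' @param tie_margin minimum clonal-fraction gap for a usable comparison.
#' @return data.frame with columns `winner`, `loser`, `patient_id`.
#' @export
build_pairwise_comparisons <- function(cohort, group_ids = NULL,
                                       tie_margin = 0.05) {
  stopifnot(inherits(cohort, "mn_cohort"))
  v <- cohort$variants
  v <- v[v$pathogenic & v$origin == "somatic", , drop = FALSE]
  if (!is.null(group_ids)) v <- v[v$patient_id %in% group_ids, , drop = FALSE]
  if (!nrow(v))
    return(data.frame(winner = character(), loser = character(),
                      patient_id = character()))
  # one cf per patient-gene (max vaf if multiple variants in one gene)
  v$cf <- pmin(1, 2 * v$vaf)
  v <- v[order(v$patient_id, v$gene, -v$cf), ]
  v <- v[!duplicated(v[c("patient_id", "gene")]), ]
  recs <- lapply(split(v, v$patient_id), function(pv) {
    if (nrow(pv) < 2L) return(NULL)
    pairs <- utils::combn(nrow(pv), 2)
    a <- pairs[1, ]; b <- pairs[2, ]
    gap <- pv$cf[a] - pv$cf[b]
    keep <- abs(gap) > tie_margin
    if (!any(keep)) return(NULL)
    a <- a[keep]; b <- b[keep]; gap <- gap[keep]
    data.frame(winner = ifelse(gap > 0, pv$gene[a], pv$gene[b]),
               loser = ifelse(gap > 0, pv$gene[b], pv$gene[a]),
               patient_id = pv$patient_id[1])
  })
  out <- do.call(rbind, recs)
  if (is.null(out))
    out <- data.frame(winner = character(), loser = character(),
                      patient_id = character())
  rownames(out) <- NULL
  out
}

#' Fit a Bradley-Terry model of mutation acquisition order
#'
#' Maximum-likelihood Bradley-Terry abilities under
#' `P(a beats b) = exp(s_a) / (exp(s_a) + exp(s_b))`, fitted with the
#' classical minorise-maximise (MM) iteration. For every pair observed at
#' least once, `ridge` pseudo-wins are added in both directions, which keeps
#' the MLE finite under perfect separation. Abilities are mean-centred
#' (the likelihood is invariant to a common shift).
#'
#' @param records comparison data.frame from [build_pairwise_comparisons()],
#'   or any data.frame with `winner` and `loser` columns.
#' @param ridge pseudo-wins added per direction for each observed pair.
#' @param max_iter,tol MM iteration controls (relative change in abilities).
#' @return object of class `bt_fit`: `abilities` (named, mean-centred log
#'   scores), `wins` (directed win-count matrix including pseudo-wins),
#'   `n_comparisons` (observed counts), `converged`, `iterations`.
#' @export
fit_bradley_terry <- function(records, ridge = 0.5, max_iter = 10000,
                              tol = 1e-8) {
  stopifnot(all(c("winner", "loser") %in% names(records)))
  if (!nrow(records)) stop("no comparison records", call. = FALSE)
  if (any(records$winner == records$loser))
    stop("winner equals loser in a record", call. = FALSE)
  genes <- sort(unique(c(records$winner, records$loser)))
  g <- length(genes)
  if (g < 2L) stop("need at least two distinct genes", call. = FALSE)
  W <- matrix(0, g, g, dimnames = list(genes, genes))  # W[i,j] = i beats j
  tab <- table(factor(records$winner, genes), factor(records$loser, genes))
  W <- W + as.matrix(tab)
  obs <- W + t(W)
  W[obs > 0] <- W[obs > 0] + ridge
  N <- W + t(W)                                        # total per pair

  p <- rep(1, g)                                       # exp(abilities)
  wins <- rowSums(W)
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    denom <- vapply(seq_len(g), function(i) {
      j <- which(N[i, ] > 0)
      sum(N[i, j] / (p[i] + p[j]))
    }, numeric(1))
    p_new <- wins / denom
    p_new[!is.finite(p_new) | p_new <= 0] <- 1e-12
    p_new <- p_new / exp(mean(log(p_new)))             # geometric-mean 1
    if (max(abs(p_new - p) / pmax(p, 1e-12)) < tol) {
      p <- p_new; converged <- TRUE; break
    }
    p <- p_new
  }
  s <- log(p); s <- s - mean(s)
  structure(list(abilities = stats::setNames(s, genes),
                 wins = W, n_comparisons = obs, ridge = ridge,
                 converged = converged, iterations = it),
            class = "bt_fit")
}

#' @export
print.bt_fit <- function(x, ...) {
  cat(sprintf("Bradley-Terry fit: %d genes, %d comparisons (%s in %d iter)\n",
              length(x$abilities), sum(x$n_comparisons) / 2,
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  ab <- sort(x$abilities, decreasing = TRUE)
  cat(paste(sprintf("  %-8s %+.3f", names(ab), ab), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.bt_fit <- function(object, ...) object$abilities

#' Rank mutations from earliest to latest acquisition
#'
#' Higher Bradley-Terry ability means the gene tends to carry the larger
#' clonal fraction within patients, i.e. was acquired earlier. Ties break
#' alphabetically for stability.
#'
#' @param fit a `bt_fit`.
#' @return character vector of genes, earliest acquisition first.
#' @export
rank_mutations <- function(fit) {
  stopifnot(inherits(fit, "bt_fit"))
  ab <- fit$abilities
  names(ab)[order(-ab, names(ab))]
}

#' Per-group mutation acquisition order
#'
#' Convenience wrapper fitting one Bradley-Terry model per genomic group
#' (and one pooled over the whole cohort).
#'
#' @param cohort an `mn_cohort`.
#' @param labels named group label per patient (e.g. from [dp_cluster()]).
#' @param tie_margin,ridge passed through.
#' @param min_comparisons groups with fewer usable comparisons are skipped.
#' @return named list of `bt_fit` objects (`pooled` plus one per group).
#' @export
group_acquisition_orders <- function(cohort, labels, tie_margin = 0.05,
                                     ridge = 0.5, min_comparisons = 5) {
  stopifnot(inherits(cohort, "mn_cohort"))
  fits <- list()
  pooled <- build_pairwise_comparisons(cohort, tie_margin = tie_margin)
  if (nrow(pooled) >= min_comparisons &&
      length(unique(c(pooled$winner, pooled$loser))) >= 2)
    fits$pooled <- fit_bradley_terry(pooled, ridge = ridge)
  for (g in setdiff(sort(unique(labels)), "DP0")) {
    ids <- names(labels)[labels == g]
    recs <- build_pairwise_comparisons(cohort, ids, tie_margin = tie_margin)
    if (nrow(recs) < min_comparisons ||
        length(unique(c(recs$winner, recs$loser))) < 2) next
    fits[[g]] <- fit_bradley_terry(recs, ridge = ridge)
  }
  fits
}
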