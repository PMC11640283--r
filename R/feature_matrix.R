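#' Build the binary patients-by-features genomic matrix
#'
#' One column per gene carrying at least one pathogenic variant anywhere in
#' the cohort and per observed cytogenetic event; a cell is 1 iff the patient
#' carries that abnormality. Variants flagged non-pathogenic (VUS) are
#' ignored; germline pathogenic variants are retained (germline DDX41 is a
#' group-defining lesion).
#'
#' @param cohort an [mn_cohort()].
#' @return an object of class `mn_feature_matrix`: list with `x` (binary
#'   integer matrix, patients in rows), `patient_ids`, `feature_names`,
#'   `feature_type` (`"gene"` or `"cyto"`), and `prevalence` (column means).
#' @export
build_feature_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "mn_cohort"))
  pids <- cohort$clinical$patient_id
  if (!length(pids)) stop("empty cohort", call. = FALSE)
  v <- cohort$variants
  v <- v[v$pathogenic, , drop = FALSE]
  genes <- sort(unique(v$gene))
  evs <- sort(unique(cohort$events$event))
  feats <- c(genes, evs)
  x <- matrix(0L, nrow = length(pids), ncol = length(feats),
              dimnames = list(pids, feats))
  if (nrow(v))
    x[cbind(match(v$patient_id, pids), match(v$gene, feats))] <- 1L
  if (nrow(cohort$events))
    x[cbind(match(cohort$events$patient_id, pids),
            match(cohort$events$event, feats))] <- 1L
  new_feature_matrix(x, feature_type = c(rep("gene", length(genes)),
                                         rep("cyto", length(evs))))
}

new_feature_matrix <- function(x, feature_type = NULL) {
  stopifnot(is.matrix(x), all(x %in% c(0L, 1L)))
  if (anyDuplicated(colnames(x))) stop("duplicate feature names")
  if (is.null(feature_type)) feature_type <- rep(NA_character_, ncol(x))
  structure(list(x = x,
                 patient_ids = rownames(x),
                 feature_names = colnames(x),
                 feature_type = feature_type,
                 prevalence = colMeans(x)),
            class = "mn_feature_matrix")
}

#' @export
print.mn_feature_matrix <- function(x, ...) {
  cat(sprintf("<mn_feature_matrix: %d patients x %d features>\n",
              nrow(x$x), ncol(x$x)))
  if (ncol(x$x)) {
    top <- sort(x$prevalence, decreasing = TRUE)
    top <- utils::head(top, 5)
    cat("  most prevalent: ",
        paste(sprintf("%s (%.1f%%)", names(top), 100 * top),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Drop features at or below a prevalence threshold
#'
#' Retains feature `f` iff `carriers(f) / n_patients > threshold` strictly
#' (the default keeps abnormalities present in more than 1% of patients).
#' Feature order is preserved.
#'
#' @param fm an `mn_feature_matrix`.
#' @param threshold prevalence cut in `[0, 1)`.
#' @return a filtered `mn_feature_matrix`.
#' @export
filter_by_prevalence <- function(fm, threshold = 0.01) {
  stopifnot(inherits(fm, "mn_feature_matrix"),
            threshold >= 0, threshold < 1)
  keep <- fm$prevalence > threshold
  new_feature_matrix(fm$x[, keep, drop = FALSE],
                     feature_type = fm$feature_type[keep])
}

#' Split patients into clustering-eligible and no-abnormality sets
#'
#' Patients whose filtered feature row is all zero carry no retained genomic
#' abnormality and are set aside as the DP0 ("no abnormality") pool; the rest
#' enter Dirichlet-process clustering. The two sets partition the cohort.
#'
#' @param fm a filtered `mn_feature_matrix`.
#' @return list with `clustering_ids` and `dp0_ids` (character vectors).
#' @export
split_eligibility <- function(fm) {
  stopifnot(inherits(fm, "mn_feature_matrix"))
  zero <- rowSums(fm$x) == 0L
  list(clustering_ids = fm$patient_ids[!zero],
       dp0_ids = fm$patient_ids[zero])
}
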