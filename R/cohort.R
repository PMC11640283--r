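#' Construct a myeloid-neoplasm cohort
#'
#' A cohort bundles the three patient-level tables the pipeline consumes:
#' clinical data (diagnosis, demographics, survival), somatic/germline variant
#' calls with variant allele fractions (VAF), and coded cytogenetic events.
#'
#' @param clinical data.frame with columns `patient_id`, `diagnosis`,
#'   `subtype`, `age_years`, `sex`, `os_years`, `death`, `hsct_years`
#'   (`NA` when the patient never underwent transplant).
#' @param variants data.frame with columns `patient_id`, `gene`, `vaf`,
#'   `origin` (`"somatic"` or `"germline"`), `pathogenic` (logical).
#'   Patients without variants simply have no rows.
#' @param events data.frame with columns `patient_id`, `event` holding coded
#'   cytogenetic events (see [cyto_vocabulary()]); long format, zero or more
#'   rows per patient.
#' @param name cohort label used in printing and output file names.
#'
#' @return An object of class `mn_cohort`: a list with elements `clinical`,
#'   `variants`, `events` and `name`.
#'
#' @details Invariants enforced: unique patient ids, non-negative survival
#' times, transplant time not after the end of follow-up, VAF in \[0, 1\],
#' diagnosis from the controlled vocabulary (MPN, MDS, MDS-MPN, AA), and every
#' variant/cytogenetic row referring to a known patient.
#'
#' @seealso [read_cohort_tables()], [write_cohort()], [generate_cohort()]
#' @export
mn_cohort <- function(clinical, variants = NULL, events = NULL, name = "cohort") {
  clinical <- as.data.frame(clinical)
  req <- c("patient_id", "diagnosis", "subtype", "age_years", "sex",
           "os_years", "death", "hsct_years")
  miss <- setdiff(req, names(clinical))
  if (length(miss))
    stop("clinical table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  clinical$patient_id <- as.character(clinical$patient_id)
  if (anyDuplicated(clinical$patient_id))
    stop("duplicate patient_id in clinical table", call. = FALSE)
  if (any(!clinical$diagnosis %in% c("MPN", "MDS", "MDS-MPN", "AA")))
    stop("diagnosis outside controlled vocabulary (MPN, MDS, MDS-MPN, AA)",
         call. = FALSE)
  clinical$death <- as.logical(clinical$death)
  if (any(is.na(clinical$os_years)) || any(clinical$os_years < 0))
    stop("os_years must be present and non-negative", call. = FALSE)
  hs <- clinical$hsct_years
  bad <- !is.na(hs) & (hs < 0 | hs > clinical$os_years)
  if (any(bad))
    stop("hsct_years must lie in [0, os_years]; violated for patient(s): ",
         paste(clinical$patient_id[bad], collapse = ", "), call. = FALSE)

  if (is.null(variants))
    variants <- data.frame(patient_id = character(), gene = character(),
                           vaf = numeric(), origin = character(),
                           pathogenic = logical())
  variants <- as.data.frame(variants)
  vreq <- c("patient_id", "gene", "vaf", "origin", "pathogenic")
  vmiss <- setdiff(vreq, names(variants))
  if (length(vmiss))
    stop("variants table is missing required column(s): ",
         paste(vmiss, collapse = ", "), call. = FALSE)
  variants$patient_id <- as.character(variants$patient_id)
  variants$pathogenic <- as.logical(variants$pathogenic)
  if (nrow(variants)) {
    if (any(!nzchar(variants$gene)))
      stop("empty gene symbol in variants table", call. = FALSE)
    if (any(is.na(variants$vaf)) || any(variants$vaf < 0 | variants$vaf > 1))
      stop("vaf outside [0, 1]", call. = FALSE)
    if (any(!variants$origin %in% c("somatic", "germline")))
      stop("origin must be 'somatic' or 'germline'", call. = FALSE)
    unknown <- setdiff(variants$patient_id, clinical$patient_id)
    if (length(unknown))
      stop("variant rows refer to unknown patient_id: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
  }

  if (is.null(events))
    events <- data.frame(patient_id = character(), event = character())
  events <- as.data.frame(events)
  if (!all(c("patient_id", "event") %in% names(events)))
    stop("events table needs columns patient_id, event", call. = FALSE)
  events$patient_id <- as.character(events$patient_id)
  if (nrow(events)) {
    unknown <- setdiff(events$patient_id, clinical$patient_id)
    if (length(unknown))
      stop("cytogenetic rows refer to unknown patient_id: ",
           paste(unique(unknown), collapse = ", "), call. = FALSE)
    bad <- setdiff(unique(events$event), cyto_vocabulary())
    if (length(bad))
      stop("cytogenetic event(s) outside vocabulary: ",
           paste(bad, collapse = ", "), call. = FALSE)
    events <- unique(events)
  }

  structure(list(clinical = clinical, variants = variants,
                 events = events, name = as.character(name)),
            class = "mn_cohort")
}

#' @export
print.mn_cohort <- function(x, ...) {
  cat(sprintf("<mn_cohort '%s'>\n", x$name))
  cat(sprintf("  patients:  %d\n", nrow(x$clinical)))
  cat(sprintf("  variants:  %d rows (%d genes)\n",
              nrow(x$variants), length(unique(x$variants$gene))))
  cat(sprintf("  cytogenetic events: %d rows (%d event types)\n",
              nrow(x$events), length(unique(x$events$event))))
  tab <- table(x$clinical$diagnosis)
  cat("  diagnoses: ",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.mn_cohort <- function(object, ...) {
  cl <- object$clinical
  out <- list(
    n = nrow(cl),
    diagnoses = table(cl$diagnosis),
    deaths = sum(cl$death),
    hsct = sum(!is.na(cl$hsct_years)),
    mutated = length(unique(object$variants$patient_id[
      object$variants$pathogenic])),
    median_followup = stats::median(cl$os_years)
  )
  class(out) <- "summary.mn_cohort"
  out
}

#' @export
print.summary.mn_cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d patients (%d deaths, %d transplanted)\n",
              x$n, x$deaths, x$hsct))
  cat(sprintf("Patients with >=1 pathogenic mutation: %d (%.1f%%)\n",
              x$mutated, 100 * x$mutated / x$n))
  cat(sprintf("Median follow-up: %.2f years\n", x$median_followup))
  invisible(x)
}

#' Read a cohort from tab-delimited tables
#'
#' Reads the three cohort tables and assembles an [mn_cohort()]. The karyotype
#' table carries a `coding` column selecting one of two dialects per row:
#' `"iscn"` (an ISCN-like karyotype string, parsed with [parse_karyotype()])
#' or `"events"` (a `|`-separated list of pre-coded event tokens).
#'
#' @param clinical_path,variants_path,karyotype_path paths to tab-delimited
#'   files with header rows. Expected columns: clinical —
#'   `patient_id, diagnosis, subtype, age_years, sex, os_years, death,
#'   hsct_years`; variants — `patient_id, gene, vaf, origin, pathogenic`;
#'   karyotype — `patient_id, coding, value`.
#' @param name cohort label.
#' @return an `mn_cohort`.
#' @export
read_cohort_tables <- function(clinical_path, variants_path, karyotype_path,
                               name = "cohort") {
  for (p in c(clinical_path, variants_path, karyotype_path))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  clinical <- utils::read.delim(clinical_path, stringsAsFactors = FALSE,
                                colClasses = c(patient_id = "character"))
  variants <- utils::read.delim(variants_path, stringsAsFactors = FALSE)
  if (nrow(variants)) variants$patient_id <- as.character(variants$patient_id)
  kary <- utils::read.delim(karyotype_path, stringsAsFactors = FALSE)
  kmiss <- setdiff(c("patient_id", "coding", "value"), names(kary))
  if (length(kmiss))
    stop("karyotype table is missing required column(s): ",
         paste(kmiss, collapse = ", "), call. = FALSE)
  ev <- vector("list", nrow(kary))
  for (i in seq_len(nrow(kary))) {
    pid <- as.character(kary$patient_id[i])
    val <- kary$value[i]
    codes <- switch(kary$coding[i],
      iscn = parse_karyotype(val),
      events = {
        # '|'-separated tokens ('; ' would clash with codes like der(1;7))
        toks <- trimws(strsplit(ifelse(is.na(val), "", val), "|",
                                fixed = TRUE)[[1]])
        toks[nzchar(toks)]
      },
      stop("unknown karyotype coding '", kary$coding[i],
           "' (expected 'iscn' or 'events')", call. = FALSE))
    if (length(codes))
      ev[[i]] <- data.frame(patient_id = pid, event = codes)
  }
  events <- do.call(rbind, ev)
  mn_cohort(clinical, variants, events, name = name)
}

#' Write a cohort back to tab-delimited tables
#'
#' Emits `clinical.tsv`, `variants.tsv` and `karyotype.tsv` (events dialect)
#' into `dir`; inverse of [read_cohort_tables()] up to row order.
#'
#' @param cohort an `mn_cohort`.
#' @param dir output directory, created if missing.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "mn_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("clinical.tsv", "variants.tsv", "karyotype.tsv"))
  utils::write.table(cohort$clinical, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  utils::write.table(cohort$variants, paths[2], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  ev <- cohort$events
  agg <- if (nrow(ev))
    stats::aggregate(event ~ patient_id, ev,
                     function(e) paste(sort(e), collapse = "|"))
  else data.frame(patient_id = character(), event = character())
  kary <- data.frame(patient_id = cohort$clinical$patient_id,
                     coding = "events",
                     value = agg$event[match(cohort$clinical$patient_id,
                                             agg$patient_id)])
  kary$value[is.na(kary$value)] <- ""
  utils::write.table(kary, paths[3], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(paths)
}
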