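#' Default synthetic-cohort configuration
#'
#' Study conditions for the synthetic stand-in cohort: 1585 patients in ten
#' genomic groups plus a no-abnormality group (DP0), with the published group
#' sizes, group-defining lesions, mutation acquisition orders, five-year
#' survival rates and transplant rates. 53 binary genomic features are
#' generated: 36 recurrently mutated genes and 17 coded chromosomal events.
#' Within each group, features not given an explicit probability occur at the
#' background rate `noise_feature_prob` (0.02); DP0 patients carry no
#' features at all. The explicit per-group probabilities are plausible
#' reconstructions chosen once, with dominant drivers in 0.6-0.95 — only
#' sizes, driver identities, survival and transplant rates are anchored to
#' published values; DDX41 carriers in DP10 are flagged germline with
#' probability 0.461, calibrating the cohort-wide germline-DDX41 rate to
#' the published 3.9%.
#'
#' @return an object of class `mn_cohort_config`: list with `groups` (named
#'   list of group specifications: `size`, `feature_probs`, `driver_order`,
#'   `germline_probs`, `s5`, `hsct_rate`, `censor_rate`, `diagnosis_mix`),
#'   `features` (data.frame `name`, `type`), `noise_feature_prob`,
#'   `feature_rho` (exchangeable within-patient feature correlation via a
#'   Gaussian copula; 0 = independent, the default), `name`.
#' @export
default_paper_config <- function() {
  genes <- c("JAK2", "CALR", "MPL", "ASXL1", "TET2", "DNMT3A", "TP53",
             "U2AF1", "SF3B1", "SRSF2", "ZRSR2", "RUNX1", "NPM1", "BCOR",
             "BCORL1", "IDH1", "IDH2", "WT1", "SETBP1", "CSF3R", "NRAS",
             "KRAS", "PTPN11", "NF1", "GATA2", "STAG2", "CBL", "ETV6",
             "KMT2D", "PHF6", "EZH2", "CUX1", "DDX41", "SH2B3", "FLT3",
             "PPM1D")
  features <- data.frame(
    name = c(genes, cyto_vocabulary()),
    type = c(rep("gene", length(genes)),
             rep("cyto", length(cyto_vocabulary()))))

  grp <- function(size, feature_probs, driver_order, s5, hsct_rate,
                  diagnosis_mix, germline_probs = numeric(),
                  censor_rate = 0.25)
    list(size = size, feature_probs = feature_probs,
         driver_order = driver_order, germline_probs = germline_probs,
         s5 = s5, hsct_rate = hsct_rate, censor_rate = censor_rate,
         diagnosis_mix = diagnosis_mix)

  groups <- list(
    DP1 = grp(456,
      c(JAK2 = 0.95, TET2 = 0.12, ASXL1 = 0.10, DNMT3A = 0.08,
        BCORL1 = 0.05, IDH1 = 0.05, CUX1 = 0.05, SH2B3 = 0.06,
        FLT3 = 0.05, PPM1D = 0.05, "+9" = 0.05, "-20/20q-" = 0.06),
      c("JAK2", "TET2", "ASXL1", "DNMT3A"),
      s5 = 0.995, hsct_rate = 0.05,
      diagnosis_mix = c(MPN = 0.9, MDS = 0.1)),
    DP5 = grp(148,
      c(CALR = 0.92, ASXL1 = 0.10),
      c("CALR", "ASXL1"),
      s5 = 0.985, hsct_rate = 0.135,
      diagnosis_mix = c(MPN = 0.9, MDS = 0.1)),
    DP2 = grp(118,
      c(TP53 = 0.80, complex = 0.80, "-5/5q-nonisolated" = 0.55,
        "-7/7q-" = 0.45, "-17/17p-/t17" = 0.35, "-9/9q-" = 0.20,
        "-13/13q-" = 0.20, "-18" = 0.15, "-12/12p-" = 0.15,
        "-16/16q-" = 0.12, "+8" = 0.15, "+1/1q+" = 0.10,
        TET2 = 0.12, ASXL1 = 0.15, DNMT3A = 0.12, U2AF1 = 0.10,
        SF3B1 = 0.08),
      c("TP53", "TET2", "ASXL1", "DNMT3A", "U2AF1", "SF3B1"),
      s5 = 0.436, hsct_rate = 0.415,
      diagnosis_mix = c(MDS = 0.7, MPN = 0.15, `MDS-MPN` = 0.1, AA = 0.05)),
    DP9 = grp(21,
      c(NPM1 = 0.90, DNMT3A = 0.40, BCOR = 0.40, IDH2 = 0.35, WT1 = 0.30),
      c("NPM1", "DNMT3A", "IDH2", "BCOR", "WT1"),
      s5 = 0.206, hsct_rate = 0.524,
      diagnosis_mix = c(MDS = 0.9, `MDS-MPN` = 0.1)),
    DP7 = grp(40,
      c(SETBP1 = 0.85, ASXL1 = 0.60, CSF3R = 0.45, NRAS = 0.30,
        GATA2 = 0.20, NF1 = 0.15, PTPN11 = 0.15, "-7/7q-" = 0.15),
      c("ASXL1", "SETBP1", "CSF3R", "NRAS"),
      s5 = 0.557, hsct_rate = 0.475,
      diagnosis_mix = c(MDS = 0.4, `MDS-MPN` = 0.3, MPN = 0.3)),
    DP4 = grp(93,
      c(TET2 = 0.85, SRSF2 = 0.70, STAG2 = 0.25, ZRSR2 = 0.20,
        IDH2 = 0.20, NRAS = 0.20, KRAS = 0.15, CBL = 0.15, JAK2 = 0.10,
        CSF3R = 0.08, CUX1 = 0.12, "-20/20q-" = 0.10),
      c("TET2", "SRSF2", "STAG2", "CBL", "KRAS", "NRAS", "JAK2", "CSF3R"),
      s5 = 0.576, hsct_rate = 0.25,
      diagnosis_mix = c(MDS = 0.5, `MDS-MPN` = 0.3, MPN = 0.2)),
    DP3 = grp(177,
      c(U2AF1 = 0.60, "+8" = 0.45, RUNX1 = 0.40, BCOR = 0.30,
        PHF6 = 0.25, ASXL1 = 0.25, EZH2 = 0.15, JAK2 = 0.08,
        "-20/20q-" = 0.20, "+21" = 0.08),
      c("BCOR", "U2AF1", "RUNX1", "ASXL1", "PHF6", "JAK2"),
      s5 = 0.685, hsct_rate = 0.20,
      diagnosis_mix = c(MDS = 0.8, MPN = 0.15, `MDS-MPN` = 0.05)),
    DP6 = grp(35,
      c(CBL = 0.70, ETV6 = 0.60, KMT2D = 0.60, EZH2 = 0.25, ZRSR2 = 0.20,
        JAK2 = 0.10),
      c("EZH2", "ZRSR2", "ETV6", "KMT2D", "CBL", "JAK2"),
      s5 = 0.800, hsct_rate = 0.15,
      diagnosis_mix = c(MDS = 0.8, MPN = 0.2)),
    DP10 = grp(224,
      c(SF3B1 = 0.60, DDX41 = 0.60, MPL = 0.08, TET2 = 0.10,
        DNMT3A = 0.10, "-Y" = 0.10, isolated_del5q = 0.05),
      c("MPL", "SF3B1", "DDX41", "TET2", "DNMT3A"),
      s5 = 0.826, hsct_rate = 0.10,
      diagnosis_mix = c(MDS = 0.8, MPN = 0.15, `MDS-MPN` = 0.05),
      germline_probs = c(DDX41 = 0.461)),
    DP8 = grp(47,
      c("+1/1q+" = 0.65, "der(1;7)" = 0.33, ASXL1 = 0.15, TET2 = 0.10),
      c("ASXL1", "TET2"),
      s5 = 0.806, hsct_rate = 0.20,
      diagnosis_mix = c(MDS = 0.9, MPN = 0.1)),
    DP0 = grp(226, stats::setNames(numeric(0), character(0)), character(0),
      s5 = 0.886, hsct_rate = 0.05,
      diagnosis_mix = c(AA = 0.45, MDS = 0.3, MPN = 0.2, `MDS-MPN` = 0.05))
  )
  structure(list(groups = groups, features = features,
                 noise_feature_prob = 0.02, feature_rho = 0,
                 name = "synthetic-mn"),
            class = "mn_cohort_config")
}

#' Synthetic validation-cohort configuration
#'
#' A 150-patient companion to [default_paper_config()] mirroring the
#' published validation-cohort composition: 143 patients drawn from the
#' eleven genomic groups in their published validation proportions, plus 7
#' "atypical" patients whose profiles mix lesions across groups and are
#' expected to resist confident assignment.
#'
#' @return an `mn_cohort_config`.
#' @export
default_validation_config <- function() {
  cfg <- default_paper_config()
  sizes <- c(DP1 = 58, DP0 = 17, DP10 = 14, DP3 = 12, DP2 = 11, DP5 = 11,
             DP4 = 5, DP6 = 5, DP8 = 5, DP7 = 3, DP9 = 2)
  for (g in names(sizes)) cfg$groups[[g]]$size <- unname(sizes[g])
  cfg$groups <- cfg$groups[names(sizes)]
  # atypical profiles: equal mixture of two distant group signatures
  atyp <- cfg$groups$DP1
  atyp$size <- 7
  probs <- c(JAK2 = 0.5, TP53 = 0.5, complex = 0.5, CALR = 0.5,
             NPM1 = 0.4, SETBP1 = 0.4, "+1/1q+" = 0.4)
  atyp$feature_probs <- probs
  atyp$driver_order <- c("JAK2", "TP53")
  atyp$s5 <- 0.6
  cfg$groups$atypical <- atyp
  cfg$name <- "synthetic-mn-validation"
  cfg
}

#' Generate a synthetic cohort
#'
#' Draws a cohort under an [default_paper_config()]-style configuration.
#' Group sizes are allocated exactly (not multinomially) so structural checks
#' are deterministic. Per patient: binary features are sampled independently
#' with the group's probabilities (background rate for unspecified features;
#' groups with an empty probability map, like DP0, carry nothing); VAFs
#' encode the planted acquisition order — the i-th driver (1-based) gets
#' clonal fraction `0.9 - 0.15 * (i - 1) + N(0, 0.05)` clipped to
#' (0.02, 1), with `vaf = cf / 2`, while non-driver mutations get subclonal
#' `cf ~ U(0.1, 0.5)`; survival is exponential with rate `-log(s5) / 5`
#' (so the true five-year survivor function equals the group's `s5`), with
#' independent exponential censoring matched to `censor_rate` and a
#' transplant time drawn uniformly before end of follow-up for an
#' `hsct_rate` fraction.
#'
#' @param config an `mn_cohort_config`.
#' @param seed integer seed; the cohort is byte-identical given it.
#' @return an `mn_cohort`; the planted truth (group label and acquisition
#'   order per patient) is attached as `attr(, "truth")` and is not readable
#'   by any pipeline stage.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "mn_cohort_config"))
  feats <- config$features
  for (g in names(config$groups)) {
    sp <- config$groups[[g]]
    if (sp$size < 0) stop("negative group size: ", g, call. = FALSE)
    if (length(sp$feature_probs)) {
      if (any(sp$feature_probs < 0 | sp$feature_probs > 1))
        stop("feature probability outside [0,1] in group ", g, call. = FALSE)
      bad <- setdiff(names(sp$feature_probs), feats$name)
      if (length(bad))
        stop("unknown feature(s) in group ", g, ": ",
             paste(bad, collapse = ", "), call. = FALSE)
    }
    if (sp$s5 <= 0 || sp$s5 > 1)
      stop("s5 must lie in (0, 1] for group ", g, call. = FALSE)
  }
  old_seed <- .save_rng(); on.exit(.restore_rng(old_seed))
  set.seed(seed)

  gene_names <- feats$name[feats$type == "gene"]
  n_total <- sum(vapply(config$groups, `[[`, numeric(1), "size"))
  pid_w <- max(4, nchar(as.character(n_total)))
  clin <- list(); vars <- list(); evs <- list(); truth <- list()
  idx0 <- 0L
  for (g in names(config$groups)) {
    sp <- config$groups[[g]]
    n <- sp$size
    if (n == 0) next
    pids <- sprintf(paste0("P%0", pid_w, "d"), idx0 + seq_len(n))
    idx0 <- idx0 + n

    p <- if (length(sp$feature_probs))
      stats::setNames(rep(config$noise_feature_prob, nrow(feats)),
                      feats$name)
    else stats::setNames(rep(0, nrow(feats)), feats$name)
    p[names(sp$feature_probs)] <- sp$feature_probs
    rho <- if (is.null(config$feature_rho)) 0 else config$feature_rho
    if (rho > 0) {
      # Gaussian copula with exchangeable within-patient correlation:
      # marginals stay Bernoulli(p), features become positively dependent
      shared <- stats::rnorm(n)
      z <- sqrt(rho) * shared +
        sqrt(1 - rho) * matrix(stats::rnorm(n * nrow(feats)), n)
      x <- matrix(0L, n, nrow(feats), dimnames = list(pids, feats$name))
      x[] <- as.integer(z < matrix(stats::qnorm(p), n, nrow(feats),
                                   byrow = TRUE))
    } else {
      x <- matrix(stats::rbinom(n * nrow(feats), 1, rep(p, each = n)),
                  nrow = n, dimnames = list(pids, feats$name))
    }

    # survival: exponential calibrated to the group's 5-year rate
    rate <- -log(sp$s5) / 5
    t_event <- stats::rexp(n, rate)
    cr <- sp$censor_rate
    t_cens <- if (cr > 0) stats::rexp(n, rate * cr / (1 - cr)) else
      rep(Inf, n)
    os <- pmin(t_event, t_cens)
    death <- t_event <= t_cens
    hsct <- rep(NA_real_, n)
    has_hsct <- stats::runif(n) < sp$hsct_rate
    hsct[has_hsct] <- stats::runif(sum(has_hsct)) * os[has_hsct]

    dx <- sample(names(sp$diagnosis_mix), n, replace = TRUE,
                 prob = sp$diagnosis_mix)
    subtype <- vapply(dx, function(d) switch(d,
      MPN = sample(c("PV", "ET", "PMF"), 1),
      MDS = sample(c("MDS-LB", "MDS-IB1", "MDS-IB2", "hypoplastic-MDS"), 1),
      `MDS-MPN` = "CMML",
      AA = "AA"), character(1))
    age_mean <- if (g == "DP0") 48 else 65
    age <- pmin(90, pmax(18, round(stats::rnorm(n, age_mean, 13), 1)))

    clin[[g]] <- data.frame(
      patient_id = pids, diagnosis = dx, subtype = unname(subtype),
      age_years = age,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.45, 0.55)),
      os_years = round(os, 4), death = death,
      hsct_years = round(hsct, 4))

    # variants with planted clonal-fraction order
    for (i in seq_len(n)) {
      carried <- gene_names[x[i, gene_names] == 1L]
      if (!length(carried)) next
      drv <- sp$driver_order[sp$driver_order %in% carried]
      oth <- setdiff(carried, drv)
      cf_d <- if (length(drv))
        pmin(1, pmax(0.02, 0.9 - 0.15 * (seq_along(drv) - 1) +
                             stats::rnorm(length(drv), 0, 0.05)))
      else numeric(0)
      cf_o <- stats::runif(length(oth), 0.1, 0.5)
      gg <- c(drv, oth)
      gl_p <- rep(0, length(gg))
      hit <- gg %in% names(sp$germline_probs)
      gl_p[hit] <- sp$germline_probs[gg[hit]]
      is_gl <- stats::runif(length(gg)) < gl_p
      vars[[length(vars) + 1L]] <- data.frame(
        patient_id = pids[i],
        gene = gg,
        vaf = round(ifelse(is_gl, 0.5, c(cf_d, cf_o) / 2), 4),
        origin = ifelse(is_gl, "germline", "somatic"),
        pathogenic = TRUE)
    }

    ev_mat <- x[, feats$name[feats$type == "cyto"], drop = FALSE]
    hit <- which(ev_mat == 1L, arr.ind = TRUE)
    if (nrow(hit))
      evs[[g]] <- data.frame(patient_id = pids[hit[, 1]],
                             event = colnames(ev_mat)[hit[, 2]])
    truth[[g]] <- data.frame(
      patient_id = pids, true_group = g,
      planted_order = paste(sp$driver_order, collapse = ">"))
  }
  cohort <- mn_cohort(do.call(rbind, clin), do.call(rbind, vars),
                      do.call(rbind, evs), name = config$name)
  tr <- do.call(rbind, truth); rownames(tr) <- NULL
  attr(cohort, "truth") <- tr
  cohort
}

#' Generate a synthetic cohort and write its tables
#'
#' Writes the three cohort TSVs ([write_cohort()]) plus the planted-truth
#' sidecar `truth.tsv` (patient_id, true_group, planted_order), which exists
#' only for recovery benchmarking and is never read by analysis stages.
#'
#' @param config an `mn_cohort_config`.
#' @param seed integer seed.
#' @param dir output directory.
#' @return invisibly, the generated `mn_cohort`.
#' @export
simulate_cohort <- function(config, seed, dir) {
  cohort <- generate_cohort(config, seed)
  write_cohort(cohort, dir)
  utils::write.table(attr(cohort, "truth"), file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(cohort)
}
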