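test_that("reading clinical-only tables yields patients without variants", {
  paths <- write_temp_tables(toy_clinical(3))
  coh <- read_cohort_tables(paths[1], paths[2], paths[3])
  expect_s3_class(coh, "mn_cohort")
  expect_equal(nrow(coh$clinical), 3)
  expect_equal(nrow(coh$variants), 0)
  expect_equal(nrow(coh$events), 0)
})

test_that("malformed tables are rejected with informative errors", {
  cl <- toy_clinical(2)
  paths <- write_temp_tables(cl[, setdiff(names(cl), "sex")])
  expect_error(read_cohort_tables(paths[1], paths[2], paths[3]), "sex")

  vr <- data.frame(patient_id = "P99", gene = "JAK2", vaf = 0.3,
                   origin = "somatic", pathogenic = TRUE)
  paths <- write_temp_tables(toy_clinical(2), vr)
  expect_error(read_cohort_tables(paths[1], paths[2], paths[3]),
               "unknown patient_id")

  vr$patient_id <- "P01"; vr$vaf <- 1.4
  paths <- write_temp_tables(toy_clinical(2), vr)
  expect_error(read_cohort_tables(paths[1], paths[2], paths[3]), "vaf")

  cl <- toy_clinical(2)
  cl$hsct_years[1] <- cl$os_years[1] + 1   # transplant after follow-up end
  expect_error(mn_cohort(cl), "hsct_years")

  cl <- toy_clinical(2)
  cl$diagnosis[2] <- "AML"
  expect_error(mn_cohort(cl), "controlled vocabulary")
})

test_that("generated cohorts round-trip through write_cohort unchanged", {
  coh <- generate_cohort(small_config(), seed = 7)
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  back <- read_cohort_tables(file.path(dir, "clinical.tsv"),
                             file.path(dir, "variants.tsv"),
                             file.path(dir, "karyotype.tsv"),
                             name = coh$name)
  expect_equal(back$clinical, coh$clinical, ignore_attr = TRUE)
  norm <- function(df) {
    df <- df[do.call(order, df), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  expect_equal(norm(back$variants), norm(coh$variants))
  expect_equal(norm(back$events), norm(coh$events))
})

test_that("karyotype strings map to coded events", {
  expect_length(parse_karyotype("46,XY"), 0)
  expect_equal(as.character(parse_karyotype("47,XY,+8")), "+8")
  k <- parse_karyotype("46,XX,der(1;7)(q10;p10)")
  expect_equal(as.character(k), "der(1;7)")
  expect_false("-7/7q-" %in% k)     # der(1;7) is its own entity
  expect_length(parse_karyotype(""), 0)

  # isolated vs non-isolated del(5q)
  expect_equal(as.character(parse_karyotype("46,XX,del(5)(q13q33)")),
               "isolated_del5q")
  k <- parse_karyotype("45,XX,del(5)(q13q33),-7")
  expect_setequal(as.character(k), c("-5/5q-nonisolated", "-7/7q-"))

  # complex = three or more distinct clonal abnormalities
  k <- parse_karyotype("44,XY,-5,-7,del(17p)")
  expect_true("complex" %in% k)
  expect_setequal(as.character(k),
                  c("-5/5q-nonisolated", "-7/7q-", "-17/17p-/t17", "complex"))

  # unrecognised tokens are collected, not fatal, and count toward complexity
  k <- parse_karyotype("46,XY,t(3;3)(q21;q26),inv(16),+8")
  expect_true("+8" %in% k && "complex" %in% k)
  expect_length(attr(k, "unrecognized"), 2)
})

test_that("karyotype parsing is idempotent and order-invariant", {
  strings <- c("44,XY,-5,-7,del(17p)", "47,XX,+8,del(20q)",
               "46,XY,der(1;7)(q10;p10),+8,-18")
  for (s in strings) {
    once <- parse_karyotype(s)
    again <- parse_karyotype(paste(once, collapse = ","))
    expect_setequal(as.character(again), as.character(once))
  }
  toks <- c("-5", "-7", "del(17p)", "+8")
  base <- as.character(parse_karyotype(paste(c("46", "XY", toks),
                                             collapse = ",")))
  for (i in 1:5) {
    perm <- sample(toks)
    k <- parse_karyotype(paste(c("46", "XY", perm), collapse = ","))
    expect_setequal(as.character(k), base)
  }
})

test_that("write_results emits stable, deterministic artifacts", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  empty_assoc <- classify_pairs(
    mngroups:::new_feature_matrix(
      matrix(c(1L, 0L, 0L, 1L), 2, dimnames = list(c("a", "b"),
                                                   c("f1", "f2")))))
  empty_assoc <- empty_assoc[0, ]
  labels <- stats::setNames(c("DP1", "DP1", "DP2", "DP0", "DP2"),
                            paste0("P", 1:5))
  p1 <- write_results(list(labels = labels, associations = empty_assoc),
                      dir1)
  assoc_lines <- readLines(file.path(dir1, "associations.tsv"))
  expect_length(assoc_lines, 1)          # header only
  assign_lines <- readLines(file.path(dir1, "assignments.tsv"))
  expect_length(assign_lines, 6)         # header + 5 patients
  p2 <- write_results(list(labels = labels, associations = empty_assoc),
                      dir2)
  for (f in basename(p1))
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
})
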