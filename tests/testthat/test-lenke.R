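test_that("expected category maps follow the type/modifier correspondence", {
  expect_setequal(expected_vertical_categories(1), c("Thoracic", "Mainly thoracic"))
  expect_setequal(expected_vertical_categories(2), c("Thoracic", "Mainly thoracic"))
  expect_setequal(expected_vertical_categories(3), c("Mainly thoracic", "Thoraco-lumbar"))
  expect_setequal(expected_vertical_categories(5),
                  c("Lumbar", "Mainly lumbar", "Thoraco-lumbar"))
  expect_setequal(expected_vertical_categories(6),
                  c("Thoraco-lumbar", "Mainly lumbar"))
  expect_equal(expected_vertical_categories("Normal"), "n/a")
  expect_error(expected_vertical_categories(7),
               class = "spineclass_validation_error")

  expect_setequal(expected_sagittal_categories("+"),
                  c("Significant kyphosis", "Extreme kyphosis"))
  expect_length(expected_sagittal_categories("-"), 0)
  expect_length(expected_sagittal_categories("−"), 0)  # Unicode minus
  expect_setequal(expected_sagittal_categories("N"),
                  c("Normal spine", "Slight kyphosis", "Slight lordosis"))
  expect_error(expected_sagittal_categories("X"),
               class = "spineclass_validation_error")
})

test_that("per-patient validation applies the documented rules", {
  mk_cls <- function(id, vertical, sagittal, severity = "Slightly significant") {
    structure(list(patient_id = id, vertical = vertical, sagittal = sagittal,
                   severity = severity), class = "spine_classification")
  }
  mk_lenke <- function(id, code) {
    c(list(patient_id = id), parse_lenke_code(code))
  }

  # thoraco-lumbar vs type 6: validated; vs type 1: not validated
  v1 <- validate_patient(mk_cls("1", "Thoraco-lumbar", "Slight kyphosis"),
                         mk_lenke("1", "6BN"))
  expect_equal(v1$v_status, "validated")
  expect_equal(v1$kl_status, "validated")
  v2 <- validate_patient(mk_cls("2", "Thoraco-lumbar", "Significant lordosis"),
                         mk_lenke("2", "1BN"))
  expect_equal(v2$v_status, "not_validated")
  # lordotic output overrides the modifier row: "/" group, never validated
  expect_equal(v2$kl_group, "/")
  expect_equal(v2$kl_status, "not_validated")

  # a Lenke-normal patient validates iff classified as no scoliosis
  v3 <- validate_patient(mk_cls("3", "n/a", "Normal spine", "No scoliosis"),
                         mk_lenke("3", "Normal spine"))
  expect_equal(v3$v_status, "validated")
  expect_equal(v3$kl_status, "validated")   # held to the N expectation
  v4 <- validate_patient(mk_cls("4", "Mainly thoracic", "Normal spine", "Mild"),
                         mk_lenke("4", "Normal"))
  expect_equal(v4$v_status, "not_validated")

  # the hypokyphotic modifier has no counterpart: never validated
  v5 <- validate_patient(mk_cls("5", "Mainly thoracic", "Normal spine"),
                         mk_lenke("5", "1A-"))
  expect_equal(v5$kl_status, "not_validated")

  expect_error(validate_patient(mk_cls("6", "Thoracic", "Normal spine"),
                                mk_lenke("7", "1AN")),
               "mismatch", class = "spineclass_validation_error")
})

test_that("concordance aggregation is order-invariant and sums correctly", {
  tab <- vertical_concordance_fixture()
  expect_equal(sum(tab$validated), 68)
  expect_equal(sum(tab$not_validated), 26)

  recs <- data.frame(
    group = rep(tab$group, times = tab$validated + tab$not_validated),
    status = unlist(mapply(function(v, nv) c(rep("validated", v),
                                             rep("not_validated", nv)),
                           tab$validated, tab$not_validated)))
  rebuilt <- build_concordance(recs, groups = tab$group)
  expect_equal(as.data.frame(rebuilt), as.data.frame(tab))
  set.seed(5)
  shuffled <- build_concordance(recs[sample(nrow(recs)), ], groups = tab$group)
  expect_equal(as.data.frame(shuffled), as.data.frame(tab))

  one <- build_concordance(data.frame(group = "g", status = "validated"))
  expect_equal(one$validated, 1L)
  expect_equal(one$not_validated, 0L)
})

test_that("the chi-square statistic matches the published concordance analyses", {
  r4 <- pearson_chi_square(vertical_concordance_fixture())
  expect_equal(r4$statistic, 29.0, tolerance = 0.05 / 29)  # prints as 29.0
  expect_equal(r4$df, 6)
  expect_lt(r4$p_value, 0.0001)

  r5 <- pearson_chi_square(sagittal_concordance_fixture())
  expect_equal(round(r5$statistic, 2), 48.39)
  expect_equal(r5$df, 3)
  expect_lt(r5$p_value, 0.0001)

  # homogeneous proportions give a statistic of exactly 0
  flat <- concordance_table(c("a", "b"), c(10, 20), c(5, 10))
  expect_equal(pearson_chi_square(flat)$statistic, 0, tolerance = 1e-12)

  # degenerate margins are rejected
  expect_error(pearson_chi_square(concordance_table(c("a", "b"),
                                                    c(3, 4), c(0, 0))),
               class = "spineclass_validation_error")
})

test_that("chi-square agrees with a brute-force loop oracle and chisq.test", {
  set.seed(77)
  for (i in 1:1000) {
    r <- sample(2:6, 1)
    O <- matrix(sample(1:30, 2 * r, replace = TRUE), nrow = r)
    tab <- concordance_table(paste0("g", seq_len(r)), O[, 1], O[, 2])
    res <- pearson_chi_square(tab)
    expect_equal(res$statistic, chisq_loop_oracle(O), tolerance = 1e-9)
  }
  # spot-check against the base-R implementation
  O <- cbind(c(4, 2, 29, 2, 9, 13, 9), c(4, 0, 4, 0, 0, 2, 16))
  ref <- suppressWarnings(stats::chisq.test(O, correct = FALSE))
  mine <- pearson_chi_square(vertical_concordance_fixture())
  expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-12)
})

test_that("chi-square is row-permutation invariant and scales with counts", {
  tab <- sagittal_concordance_fixture()
  base <- pearson_chi_square(tab)$statistic
  perm <- concordance_table(tab$group[c(3, 1, 4, 2)],
                            tab$validated[c(3, 1, 4, 2)],
                            tab$not_validated[c(3, 1, 4, 2)])
  expect_equal(pearson_chi_square(perm)$statistic, base, tolerance = 1e-12)
  k <- 4
  scaled <- concordance_table(tab$group, k * tab$validated,
                              k * tab$not_validated)
  expect_equal(pearson_chi_square(scaled)$statistic, k * base,
               tolerance = 1e-9)
})

test_that("percent agreement reproduces the published rates and its bounds", {
  expect_equal(round(percent_agreement(vertical_concordance_fixture()), 1), 72.3)
  expect_equal(round(percent_agreement(sagittal_concordance_fixture()), 2), 68.09)
  all_ok <- concordance_table(c("a", "b"), c(5, 7), c(0, 0))
  expect_equal(percent_agreement(all_ok), 100)
  set.seed(12)
  for (i in 1:20) {
    tab <- concordance_table(c("a", "b"), sample(0:9, 2), sample(1:9, 2))
    p <- percent_agreement(tab)
    expect_true(p >= 0 && p <= 100)
  }
})

test_that("bundled concordance fixtures load and match the built-in tables", {
  vert <- read_concordance(system.file("extdata",
                                       "lenke_vertical_concordance.csv",
                                       package = "spineclass"))
  expect_equal(as.data.frame(vert),
               as.data.frame(vertical_concordance_fixture()))
  sag <- read_concordance(system.file("extdata",
                                      "lenke_sagittal_concordance.csv",
                                      package = "spineclass"))
  expect_equal(as.data.frame(sag),
               as.data.frame(sagittal_concordance_fixture()))
})

test_that("cohort-level concordance analysis joins, validates and aggregates", {
  # small synthetic cohort with known classifications on both axes
  spines <- list(
    generate_spine(spine_params(lateral_amplitude = 25, apex_level = "T7",
                                noise_sd = 0, seed = 1, patient_id = "p1")),
    generate_spine(spine_params(lateral_amplitude = 25, apex_level = "L2",
                                noise_sd = 0, seed = 2, patient_id = "p2")),
    generate_spine(spine_params(lateral_amplitude = 0, noise_sd = 0,
                                seed = 3, patient_id = "p3")))
  cls <- lapply(spines, classify_patient)
  lenke_path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("patient_id,lenke_code", "p1,1AN", "p2,5BN", "p3,Normal spine",
               "p9,2AN"), lenke_path)
  res <- concordance_analysis(cls, read_lenke_labels(lenke_path),
                              axis = "vertical")
  expect_equal(sum(res$table$validated) + sum(res$table$not_validated), 3)
  expect_equal(res$unmatched, "p9")
  # thoracic curve vs type 1 and lumbar curve vs type 5 both validate;
  # the straight spine validates against Lenke-normal
  expect_equal(sum(res$table$validated), 3)
})
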