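test_that("severity buckets are half-open with inclusive lower bounds", {
  cfg <- default_thresholds()
  sev <- function(m) severity_class(c(tl = 0, tr = m, ll = 0, lr = 0), cfg)
  expect_equal(sev(0), "No scoliosis")
  expect_equal(sev(2.49), "No scoliosis")
  expect_equal(sev(2.5), "Mild")
  expect_equal(sev(4.0), "Slightly significant")
  expect_equal(sev(6.5), "Very significant")
  expect_equal(sev(10.0), "Severe")
  expect_equal(sev(14.5), "Extremely severe")
  expect_equal(sev(100), "Extremely severe")
  # severity is decided by the largest quadrant
  expect_equal(severity_class(c(tl = 11, tr = 1, ll = 0, lr = 0), cfg), "Severe")
})

test_that("side buckets treat the boundary as both-sided", {
  expect_equal(side_class(-0.6), "Left-sided")
  expect_equal(side_class(-0.5), "Both-sided")
  expect_equal(side_class(0.5), "Both-sided")
  expect_equal(side_class(0.51), "Right-sided")
  expect_equal(side_class(1.0), "Right-sided")
  expect_equal(side_class(NA_real_), "n/a")
})

test_that("vertical buckets follow the printed interval conventions", {
  expect_equal(vertical_class(-1.0), "Lumbar")
  expect_equal(vertical_class(-0.6), "Mainly lumbar")    # [-0.6, -0.25)
  expect_equal(vertical_class(-0.25), "Thoraco-lumbar")  # closed bound
  expect_equal(vertical_class(0.25), "Thoraco-lumbar")   # closed bound
  expect_equal(vertical_class(0.26), "Mainly thoracic")
  expect_equal(vertical_class(0.6), "Mainly thoracic")   # (0.25, 0.6]
  expect_equal(vertical_class(0.61), "Thoracic")
  expect_equal(vertical_class(NA_real_), "n/a")
})

test_that("sagittal buckets partition [-1, 1] into the seven categories", {
  expect_equal(sagittal_class(-1.0), "Extreme lordosis")
  expect_equal(sagittal_class(-0.35), "Significant lordosis")  # [-0.35, -0.2)
  expect_equal(sagittal_class(-0.05), "Slight lordosis")
  expect_equal(sagittal_class(0), "Normal spine")
  expect_equal(sagittal_class(0.1), "Normal spine")
  expect_equal(sagittal_class(0.3), "Normal spine")    # [0, 0.3]
  expect_equal(sagittal_class(0.31), "Slight kyphosis")
  expect_equal(sagittal_class(0.5), "Slight kyphosis")
  expect_equal(sagittal_class(0.65), "Significant kyphosis")
  expect_equal(sagittal_class(0.9), "Extreme kyphosis")
  expect_equal(sagittal_class(NA_real_), "n/a")
})

test_that("every index value falls in exactly one bucket (no gaps, no overlaps)", {
  cfg <- default_thresholds()
  eps <- 1e-9
  edges <- function(b) sort(unique(c(b, b - eps, b + eps)))
  sweep_v <- sort(c(seq(-1, 1, by = 0.01), edges(cfg$v_bounds)))
  for (v in sweep_v) expect_true(vertical_class(v, cfg) %in%
                                   spineclass:::VERTICAL_LABELS)
  sweep_kl <- sort(c(seq(-1, 1, by = 0.01), edges(cfg$kl_bounds)))
  for (kl in sweep_kl) expect_true(sagittal_class(kl, cfg) %in%
                                     spineclass:::SAGITTAL_LABELS)
  sweep_s <- sort(c(seq(-1, 1, by = 0.01), edges(c(-cfg$s_bound, cfg$s_bound))))
  for (s in sweep_s) expect_true(side_class(s, cfg) %in%
                                   spineclass:::SIDE_LABELS)
  sweep_std <- sort(c(seq(0, 20, by = 0.1), edges(cfg$std_severity_bounds)))
  for (m in sweep_std)
    expect_true(severity_class(c(tl = m, tr = 0, ll = 0, lr = 0), cfg) %in%
                  spineclass:::SEVERITY_LABELS)
  # categories are monotone along each sweep (ordered buckets, no overlap)
  ord <- match(vapply(sweep_kl, sagittal_class, "", cfg = cfg),
               spineclass:::SAGITTAL_LABELS)
  expect_true(all(diff(ord) >= 0))
  ordv <- match(vapply(sweep_v, vertical_class, "", cfg = cfg),
                spineclass:::VERTICAL_LABELS)
  expect_true(all(diff(ordv) >= 0))
})

test_that("the class estimation text matches the documented exemplars", {
  expect_identical(
    compose_description("Very significant", "Left-sided", "Thoraco-lumbar",
                        "Extreme kyphosis"),
    "Very significant left-sided thoraco-lumbar scoliosis with extreme kyphosis.")
  expect_identical(compose_description("No scoliosis", "n/a", "n/a",
                                       "Normal spine"),
                   "Normal spine.")
  # normal sagittal balance: no sagittal clause
  expect_identical(
    compose_description("Severe", "Right-sided", "Mainly thoracic",
                        "Normal spine"),
    "Severe right-sided, mainly thoracic scoliosis.")
  # no scoliosis but abnormal sagittal balance: the sagittal label stands alone
  expect_identical(compose_description("No scoliosis", "n/a", "n/a",
                                       "Extreme kyphosis"),
                   "Extreme kyphosis.")
})

test_that("the full pipeline classifies canonical synthetic spines", {
  # neutral spine: balanced arcs, no lateral curve
  expect_identical(classify_patient(straight_spine())$description,
                   "Normal spine.")
  neutral <- generate_spine(spine_params(lateral_amplitude = 0, noise_sd = 0,
                                         kyphosis_depth = 30,
                                         lordosis_depth = 30))
  expect_identical(classify_patient(neutral)$description, "Normal spine.")

  # right-convex thoracic curve with max dispersion in the severe band:
  # dispersion is exactly linear in amplitude (noise 0), measured slope
  # 0.569 mm per mm amplitude, so amplitude 20 lands in [10, 14.5)
  sp <- generate_spine(spine_params(lateral_amplitude = 20, apex_level = "T8",
                                    convexity = "right", noise_sd = 0, seed = 1))
  cls <- classify_patient(sp)
  expect_true(max(cls$std) >= 10 && max(cls$std) < 14.5)
  expect_equal(cls$severity, "Severe")
  expect_equal(cls$side, "Right-sided")
  expect_gt(cls$v, 0.25)

  # mirrored laterally: identical text except the side word
  clsm <- classify_patient(mirror_spine(sp))
  expect_identical(clsm$description,
                   sub("right-sided", "left-sided", cls$description))
  expect_equal(clsm$s, -cls$s, tolerance = 1e-9)
  expect_equal(clsm$severity, cls$severity)
})

test_that("no-scoliosis spines report n/a localization but keep the numbers", {
  sp <- generate_spine(spine_params(lateral_amplitude = 1, noise_sd = 0.2,
                                    seed = 14))
  cls <- classify_patient(sp)
  expect_equal(cls$severity, "No scoliosis")
  expect_equal(cls$side, "n/a")
  expect_equal(cls$vertical, "n/a")
  expect_false(is.na(cls$s))  # computed and reported for audit
  expect_false(is.na(cls$v))
})

test_that("classification is deterministic and responds to the threshold config", {
  sp <- generate_spine(spine_params(lateral_amplitude = 6, noise_sd = 0,
                                    seed = 10))
  c1 <- classify_patient(sp)
  c2 <- classify_patient(sp)
  expect_identical(c1[setdiff(names(c1), "apexes")],
                   c2[setdiff(names(c2), "apexes")])
  # tighter severity bounds upgrade the label
  strict <- default_thresholds(std_severity_bounds = c(0.5, 1.0, 1.5, 2.0, 2.5))
  expect_equal(classify_patient(sp, strict)$severity, "Extremely severe")
  expect_false(identical(config_digest(strict),
                         config_digest(default_thresholds())))
})
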