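test_that("canonical cohort reproduces every printed margin", {
  cc <- canonical_cohort()
  expect_equal(nrow(cc), 109)
  expect_length(validate_records(cc), 0)
  expect_equal(sum(!cc$mass_present), 7)
  expect_equal(sum(cc$malignant), 7)

  cls <- classify_cohort(cc)
  expect_identical(unname(orads_tally(cls)), c(7L, 68L, 23L, 2L, 9L))
  mal <- vapply(1:5, function(k)
    sum(cls$malignant[cls$orads_class == k]), numeric(1))
  expect_equal(mal, c(0, 0, 0, 1, 6))

  # class-2 structure: 46 fat-containing (all small components), 63 with
  # cystic morphology, overlap 41
  c2 <- cls[cls$orads_class == 2, ]
  fat <- c2$fat_present %in% TRUE
  cystic <- !is.na(c2$locularity) | (!fat & !(c2$solid_tissue %in% TRUE))
  expect_equal(sum(fat), 46)
  expect_equal(sum(cystic), 63)
  expect_equal(sum(fat & cystic), 41)
  expect_true(all(c2$enhancing_component_mm[fat] < 80))

  # class 3 entirely cystic; class 5 composition 3 + 1 + 5
  c3 <- cls[cls$orads_class == 3, ]
  expect_true(all(!is.na(c3$locularity)))
  expect_equal(sum(c3$locularity == "multilocular"), 12)
  c5 <- cls[cls$orads_class == 5, ]
  expect_equal(sum(c5$peritoneal_disease %in% TRUE), 3)
  expect_equal(sum(c5$fat_present %in% TRUE), 2)   # one of them peritoneal
  expect_equal(sum((c5$fat_present %in% TRUE) &
                     c5$enhancing_component_mm >= 80), 1)

  # the seven malignant histologies
  expect_setequal(cls$histology[cls$malignant],
                  c("dysgerminoma", "dysgerminoma", "malignant teratoma",
                    "mucinous borderline tumor with intraepithelial carcinoma",
                    "malignant granulosa cell tumor", "rhabdoid tumor",
                    "Burkitt lymphoma"))
  # benign high-risk lesions are the histologically verified ones
  c4 <- cls[cls$orads_class == 4, ]
  expect_setequal(c4$histology,
                  c("dysgerminoma", "serous papillary cystadenoma"))
  expect_equal(sum(c5$histology == "fibroma"), 2)

  expect_equal(unname(summarize_continuous(cc$age_years)), c(13, 11, 15))
  sizes <- cc$max_diameter_mm[cc$mass_present]
  expect_equal(unname(summarize_continuous(sizes)), c(62, 45, 110))
  expect_equal(as.integer(table(cc$laterality)[c("right", "left")]),
               c(54L, 48L))
})

test_that("canonical cohort is a pure function of nothing", {
  expect_identical(canonical_cohort(), canonical_cohort())
})

test_that("margin summary mirrors the tabulated feature counts", {
  m <- cohort_margins(canonical_cohort())
  expect_equal(m$features["peritoneal", "orads_5"], 3)
  expect_equal(m$features["fat", "orads_2"], 46)
  expect_equal(m$features["fat_large_enhancing", "orads_5"], 1)
  expect_equal(m$features["dark_dark_solid", ], c(orads_2 = 0, orads_3 = 0,
                                                  orads_4 = 0, orads_5 = 0))
  expect_equal(m$features["cystic", "orads_3"], 23)
  empty <- cohort_margins(empty_records())
  expect_equal(empty$n, 0)
  expect_identical(unname(empty$class_counts), rep(0L, 5))
})

test_that("default parameters encode the canonical frequencies", {
  p <- default_params()
  expect_equal(p$class_probabilities, c(7, 68, 23, 2, 9) / 109)
  expect_equal(p$malignancy_probability[3], 0)
  expect_equal(p$malignancy_probability[4], 0.5)
  expect_equal(p$malignancy_probability[5], 6 / 9)
  expect_equal(sum(p$class2_mixture), 1)
  expect_error(generate_cohort(modifyList(p, list(
    class_probabilities = c(0.5, 0.5, 0.5, 0, 0)))), "sum to 1")
})

test_that("generator is seeded, reproducible and empty-safe", {
  expect_equal(nrow(generate_cohort(default_params(n = 0))), 0)
  a <- generate_cohort(default_params(n = 300, seed = 11))
  b <- generate_cohort(default_params(n = 300, seed = 11))
  expect_identical(a, b)
  c <- generate_cohort(default_params(n = 300, seed = 12))
  expect_false(identical(a, c))
})

test_that("generated records round-trip through the engine to their intended class", {
  cohort <- generate_cohort(default_params(n = 2000, seed = 5))
  expect_length(validate_records(cohort), 0)
  cls <- classify_cohort(cohort)$orads_class
  expect_identical(cls, attr(cohort, "intended_class"))
})

test_that("empirical margins of a large cohort match the generator inputs", {
  n <- 20000
  cohort <- generate_cohort(default_params(n = n, seed = 9))
  cls <- classify_cohort(cohort)$orads_class
  p2 <- 68 / 109
  se <- sqrt(p2 * (1 - p2) / n)
  expect_lt(abs(mean(cls == 2) - p2), 3 * se)
  # malignancy probability within class 5
  in5 <- cls == 5
  p5 <- 6 / 9
  se5 <- sqrt(p5 * (1 - p5) / sum(in5))
  expect_lt(abs(mean(cohort$malignant[in5]) - p5), 3 * se5)
  # demographic targets
  ages <- summarize_continuous(cohort$age_years)
  expect_equal(unname(ages["median"]), 13, tolerance = 0.51)
  sizes <- summarize_continuous(cohort$max_diameter_mm[cohort$mass_present])
  expect_lt(abs(sizes["median"] - 62) / 62, 0.05)
})
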