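test_that("rule engine reproduces the worked single-lesion examples", {
  expect_equal(classify_orads(lf(mass_present = FALSE)), 1L)
  # mature teratoma: fat with a 20-mm enhancing Rokitansky nodule
  expect_equal(classify_orads(lf(TRUE, fat_present = TRUE,
                                 enhancing_component_diameter = 20)), 2L)
  # hemorrhagic unilocular cyst with parietal enhancement
  expect_equal(classify_orads(lf(TRUE, fat_present = FALSE,
                                 solid_tissue_present = FALSE,
                                 locularity = "unilocular",
                                 fluid_type = "hemorrhagic",
                                 wall_enhancement = TRUE)), 3L)
  # solid lesion enhancing less than myometrium
  expect_equal(classify_orads(lf(TRUE, solid_tissue_present = TRUE,
                                 t2_homogeneous_hypointense = FALSE,
                                 dwi_homogeneous_no_restriction = FALSE,
                                 enhancement_grade = "hypo_or_iso")), 4L)
  # solid lesion enhancing more than myometrium
  expect_equal(classify_orads(lf(TRUE, solid_tissue_present = TRUE,
                                 t2_homogeneous_hypointense = FALSE,
                                 dwi_homogeneous_no_restriction = FALSE,
                                 enhancement_grade = "hyper")), 5L)
  # fat-containing lesion with a 90-mm enhancing area
  expect_equal(classify_orads(lf(TRUE, fat_present = TRUE,
                                 enhancing_component_diameter = 90)), 5L)
  # peritoneal disease forces class 5 whatever else is recorded
  expect_equal(classify_orads(lf(TRUE, peritoneal_disease = TRUE,
                                 fat_present = TRUE,
                                 enhancing_component_diameter = 10)), 5L)
})

test_that("large-component threshold is inclusive at 80 mm", {
  cls <- function(enh) classify_orads(lf(TRUE, fat_present = TRUE,
                                         enhancing_component_diameter = enh))
  expect_equal(cls(79.9), 2L)
  expect_equal(cls(80.0), 5L)
  expect_equal(cls(80.1), 5L)
  expect_equal(LARGE_ENHANCING_THRESHOLD, 80)
})

test_that("engine is total, single-valued and deterministic on the valid grid", {
  grid <- grid_valid_records()
  cls <- vapply(seq_len(nrow(grid)), function(i)
    classify_orads(record_features(grid[i, ])), integer(1))
  expect_true(all(cls %in% 1:5))
  cls2 <- vapply(seq_len(nrow(grid)), function(i)
    classify_orads(record_features(grid[i, ])), integer(1))
  expect_identical(cls, cls2)
  # vectorised cohort path agrees with the scalar tree everywhere
  expect_identical(unname(classify_cohort(grid)$orads_class), cls)
})

test_that("branch precedence and dichotomy-consistency invariants hold", {
  grid <- grid_valid_records()
  cls <- classify_cohort(grid)$orads_class
  perit <- !is.na(grid$peritoneal_disease) & grid$peritoneal_disease
  expect_true(all(cls[perit] == 5L))

  non_perit <- !perit & grid$mass_present
  cystic <- non_perit & !(grid$fat_present %in% TRUE) &
    !(grid$solid_tissue %in% TRUE)
  expect_true(all(cls[cystic] <= 3L))
  dark <- (grid$t2_dark %in% TRUE) & (grid$dwi_no_restriction %in% TRUE)
  solid_not_dark <- non_perit & (grid$solid_tissue %in% TRUE) & !dark
  expect_true(all(cls[solid_not_dark] >= 4L))
  # fat short-circuits the solid/cystic branches
  expect_equal(classify_orads(lf(TRUE, fat_present = TRUE,
                                 enhancing_component_diameter = 10,
                                 locularity = "multilocular")), 2L)
})

test_that("classify raises on invalid features, naming the violation", {
  expect_error(classify_orads(lf(TRUE, fat_present = TRUE)),
               "enhancing_component_diameter")
  bad <- rec_row(mass = TRUE, perit = FALSE, fat = TRUE, malignant = FALSE)
  bad$id <- "X42"
  expect_error(classify_cohort(bad), "X42")
})

test_that("cohort classification tallies degenerate cohorts correctly", {
  expect_identical(unname(orads_tally(classify_cohort(
    rbind(rec_row(mass = FALSE), rec_row(mass = FALSE),
          rec_row(mass = FALSE))))), c(3L, 0L, 0L, 0L, 0L))
  empty <- classify_cohort(empty_records())
  expect_equal(nrow(empty), 0)
  expect_identical(unname(attr(empty, "tally")), rep(0L, 5))
})

test_that("risk dichotomization groups classes 1-3 low and 4-5 high", {
  expect_identical(dichotomize_orads(1:5),
                   c("low", "low", "low", "high", "high"))
  expect_error(dichotomize_orads(6), "1..5")
  expect_error(dichotomize_orads(NA_integer_))
})
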