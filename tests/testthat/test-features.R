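test_that("validator accepts consistent descriptor sets", {
  expect_identical(validate_features(lf(mass_present = FALSE)), character(0))
  expect_identical(validate_features(lf(TRUE, fat_present = TRUE,
                                        enhancing_component_diameter = 20)),
                   character(0))
  grid <- grid_valid_records()
  expect_length(validate_records(grid), 0)
})

test_that("validator reports each missing conditional field by name", {
  v <- validate_features(lf(TRUE, fat_present = TRUE))
  expect_length(v, 1)
  expect_match(v, "enhancing_component_diameter")

  v <- validate_features(lf(TRUE, solid_tissue_present = TRUE))
  expect_length(v, 2)
  expect_match(v[1], "t2_homogeneous_hypointense")
  expect_match(v[2], "dwi_homogeneous_no_restriction")

  # solid, not dark-dark, no enhancement grade
  v <- validate_features(lf(TRUE, solid_tissue_present = TRUE,
                            t2_homogeneous_hypointense = FALSE,
                            dwi_homogeneous_no_restriction = FALSE))
  expect_match(v, "enhancement_grade")

  # cystic lesion with non-simple fluid but no wall-enhancement call
  v <- validate_features(lf(TRUE, fat_present = FALSE,
                            solid_tissue_present = FALSE,
                            locularity = "unilocular",
                            fluid_type = "hemorrhagic"))
  expect_length(v, 1)
  expect_match(v, "wall_enhancement")

  v <- validate_features(lf(TRUE, fat_present = FALSE,
                            solid_tissue_present = FALSE))
  expect_length(v, 2)  # locularity and fluid_type both missing
})

test_that("validator rejects lesion-level fields without a mass", {
  v <- validate_features(lf(FALSE, fat_present = TRUE,
                            enhancing_component_diameter = 10))
  expect_true(any(grepl("mass_present is FALSE", v)))
  v <- validate_features(lf(FALSE, peritoneal_disease = TRUE))
  expect_match(v, "peritoneal_disease")
})

test_that("validator rejects bad enums and inconsistent diameters", {
  expect_match(validate_features(lf(TRUE, fat_present = FALSE,
                                    solid_tissue_present = FALSE,
                                    locularity = "bilocular",
                                    fluid_type = "simple"))[1],
               "locularity")
  v <- validate_features(lf(TRUE, fat_present = TRUE,
                            enhancing_component_diameter = 90,
                            max_diameter = 60))
  expect_match(v, "max_diameter")
  v <- validate_features(lf(TRUE, fat_present = TRUE,
                            enhancing_component_diameter = -1))
  expect_match(v, ">= 0")
})

test_that("record rows map onto lesion features field by field", {
  row <- rec_row(mass = TRUE, perit = FALSE, fat = TRUE, enh = 25,
                 size = 60, malignant = FALSE)
  f <- record_features(row)
  expect_s3_class(f, "lesion_features")
  expect_true(f$fat_present)
  expect_equal(f$enhancing_component_diameter, 25)
  expect_equal(f$max_diameter, 60)
  expect_true(is.na(f$locularity))
})
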