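test_that("schema validation enforces the feature invariants", {
  expect_error(feature_spec("x", "static", "categorical", character()), "non-empty")
  expect_error(feature_spec("x", "static", "ordinal", c("a", "a")), "duplicated")
  expect_error(feature_spec("x", "static", "continuous", c("a")), "no levels")
  expect_error(
    cohort_schema(dplyr::bind_rows(
      feature_spec("x", "static", "continuous"),
      feature_spec("x", "temporal", "continuous")
    )),
    "unique"
  )
  expect_error(
    cohort_schema(feature_spec("x", "static", "continuous")),
    "at least one static and one temporal"
  )
  sch <- tiny_schema()
  expect_equal(schema_static_dim(sch), 2)
  expect_equal(schema_temporal_dim(sch), 3)
})

test_that("cohort CSV round trip preserves values and lengths", {
  ch <- tiny_cohort()
  expect_equal(cohort_lengths(ch)$length, c(2, 1, 3))
  expect_equal(cohort_lengths(ch)$dropped, c(FALSE, TRUE, FALSE))

  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  expect_setequal(list.files(dir), c("static.csv", "temporal.csv", "schema.yaml"))
  back <- read_cohort(file.path(dir, "static.csv"), file.path(dir, "temporal.csv"),
                      file.path(dir, "schema.yaml"))
  expect_equal(back$static, ch$static)
  expect_equal(back$temporal$score, ch$temporal$score)
  expect_equal(back$temporal$grade, ch$temporal$grade)
})

test_that("reader rejects gaps, unknown labels and missing values", {
  ch <- tiny_cohort()
  bad <- ch$temporal
  bad$visit[bad$patient_id == "C"] <- c(1, 3, 4)
  expect_error(as_cohort(ch$schema, ch$static, bad), "non-consecutive")

  bad <- ch$temporal
  bad$flag[1] <- "maybe"
  expect_error(as_cohort(ch$schema, ch$static, bad), "maybe")

  bad <- ch$temporal
  bad$score[2] <- NA
  expect_error(as_cohort(ch$schema, ch$static, bad), "missing values")

  bad <- ch$temporal
  bad$dropped_at_visit <- c(1, 0, 1, 0, 0, 0)  # drop flag not at final visit
  expect_error(as_cohort(ch$schema, ch$static, bad), "final visit")
})

test_that("patients present in only one table are excluded with a warning", {
  ch <- tiny_cohort()
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  st <- readr::read_csv(file.path(dir, "static.csv"), show_col_types = FALSE)
  st <- rbind(st, tibble::tibble(patient_id = "Z", age = 50, group = "g0"))
  readr::write_csv(st, file.path(dir, "static.csv"))
  expect_warning(
    back <- read_cohort(file.path(dir, "static.csv"), file.path(dir, "temporal.csv"),
                        file.path(dir, "schema.yaml")),
    "1 patient"
  )
  expect_equal(n_patients(back), 3)
})

test_that("transform fits min-max scaling and equally spaced ordinals", {
  ch <- tiny_cohort()
  ch$static$age <- c(10, 20, 30)
  tr <- fit_transform(ch)
  f <- tr$features$age
  expect_equal(c(f$min, f$max), c(10, 30))
  expect_equal(as.numeric(cohortwin:::encode_column(f, 20)), 0.5)
  g <- tr$features$grade
  expect_equal(as.numeric(cohortwin:::encode_column(g, c("lo", "mid", "hi"))),
               c(0, 0.5, 1))

  ch$static$age <- c(5, 5, 5)
  expect_error(fit_transform(ch), "age")
})

test_that("encode/decode round trips a synthetic cohort", {
  ch <- small_synth(5, seed = 4)$cohort
  tr <- fit_transform(ch)
  b <- encode_batch(ch, tr)
  back <- decode_batch(b, tr, ch$schema)
  expect_lt(max(abs(back$temporal$marker_1 - ch$temporal$marker_1)), 1e-9)
  expect_lt(max(abs(back$static$age - ch$static$age)), 1e-9)
  expect_identical(back$temporal$adverse_event, ch$temporal$adverse_event)
  expect_identical(back$temporal$impairment, ch$temporal$impairment)
  expect_identical(back$static$site, ch$static$site)
  expect_identical(back$temporal$dropped_at_visit, as.numeric(ch$temporal$dropped_at_visit))
})

test_that("padding mask and drop labels follow the placement rules", {
  ch <- tiny_cohort()
  tr <- fit_transform(ch)
  b <- encode_batch(ch, tr, t_max = 4)
  expect_equal(b$mask[1, ], c(1, 1, 0, 0))   # patient A, T = 2
  expect_equal(b$lengths, c(2, 1, 3))
  # dropped patient B: label 1 exactly at its final (first) visit
  expect_equal(b$drop_labels[2, ], c(1, 0, 0, 0))
  expect_equal(rowSums(b$drop_labels), c(0, 1, 0))
  # padded positions carry zero
  expect_true(all(b$x[1, 3:4, ] == 0))
  # one-hot blocks sum to 1 on observed steps
  lay <- cohortwin:::transform_layout(tr, "temporal")
  blk <- lay[lay$feature == "flag", ]
  expect_equal(sum(b$x[1, 1, blk$start:blk$end]), 1)
})

test_that("unseen categories map to the reserved unknown slot", {
  ch <- tiny_cohort()
  tr <- fit_transform(ch)
  test_ch <- ch
  test_ch$schema <- cohort_schema(dplyr::bind_rows(
    dplyr::filter(tibble::as_tibble(ch$schema), name != "flag"),
    feature_spec("flag", "temporal", "categorical", c("no", "yes", "new"))
  ))
  test_ch$temporal$flag[1] <- "new"
  expect_warning(b <- encode_batch(test_ch, tr), "unknown slot")
  lay <- cohortwin:::transform_layout(tr, "temporal")
  blk <- lay[lay$feature == "flag", ]
  expect_equal(b$x[1, 1, blk$end], 1)  # last slot of the block
  back <- decode_batch(b, tr, ch$schema)
  expect_equal(back$temporal$flag[1], "(unknown)")
})

test_that("splits partition patients deterministically with floor rounding", {
  ch <- small_synth(10, seed = 1)$cohort
  sp <- split_cohort(ch, 0.8, seed = 7)
  expect_equal(n_patients(sp$train), 8)
  expect_equal(n_patients(sp$test), 2)
  expect_length(intersect(sp$train$static$patient_id, sp$test$static$patient_id), 0)
  sp2 <- split_cohort(ch, 0.8, seed = 7)
  expect_identical(sp$train$static$patient_id, sp2$train$static$patient_id)

  # floor rule at scale: 1000 patients -> 800/200
  big <- small_synth(1000, seed = 2)$cohort
  spb <- split_cohort(big, 0.8, seed = 1)
  expect_equal(n_patients(spb$train), 800)
  expect_equal(n_patients(spb$test), 200)

  expect_error(split_cohort(ch, 1.2), "train_frac")
})
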