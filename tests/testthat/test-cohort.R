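test_that("cohort composition is exact and deterministic", {
  co <- generate_cohort(618, 166, 345, seed = 1)
  r <- co$records
  expect_equal(nrow(r), 618)
  expect_equal(sum(r$diagnosis == "AD"), 166)
  expect_equal(sum(r$diagnosis == "CN"), 452)
  expect_equal(sum(r$sex == "F"), 345)
  expect_equal(sum(r$sex == "M"), 273)
  expect_false(any(duplicated(r$subject_id)))
  expect_true(all(r$age >= 55 & r$age <= 95))
  # composition identical under a different seed; ages differ
  co2 <- generate_cohort(618, 166, 345, seed = 2)
  expect_equal(table(co2$records$diagnosis, co2$records$sex),
               table(r$diagnosis, r$sex))
  expect_false(isTRUE(all.equal(co2$records$age, r$age)))
  # bit-for-bit reproducibility per seed
  expect_identical(generate_cohort(618, 166, 345, seed = 1)$records, r)
})

test_that("degenerate and infeasible cohort compositions", {
  empty <- generate_cohort(0, 0, 0, seed = 5)
  expect_equal(nrow(empty$records), 0)
  allad <- generate_cohort(10, 10, 0, seed = 7)
  expect_true(all(allad$records$diagnosis == "AD"))
  expect_true(all(allad$records$sex == "M"))
  expect_error(generate_cohort(10, 12, 5), "infeasible")
  expect_error(volume_grid(c(0, 4, 4)), "positive")
})

test_that("zero-signal volume equals the template; generation is deterministic", {
  grid <- volume_grid(c(10, 10, 10))
  rec <- data.frame(subject_id = "X", age = 70, sex = "F", diagnosis = "AD")
  v0 <- generate_volume(rec, grid, signal_model(effect = 0, subject_sd = 0),
                        noise_sd = 0, seed = 3)
  expect_identical(v0$intensities, fedalz:::volume_template(grid))
  v1 <- generate_volume(rec, grid, signal_model(), noise_sd = 0.1, seed = 3)
  v2 <- generate_volume(rec, grid, signal_model(), noise_sd = 0.1, seed = 3)
  expect_identical(v1$intensities, v2$intensities)
  expect_false(identical(v0$intensities, v1$intensities))
})

test_that("AD-CN region contrast matches the effect size (Monte-Carlo)", {
  grid <- volume_grid(c(10, 10, 10))
  sig <- signal_model(effect = 0.2)
  mask <- fedalz:::region_mask(grid, sig)
  region_mean <- function(dg, i) {
    rec <- data.frame(subject_id = "X", age = 72, sex = "F", diagnosis = dg)
    mean(generate_volume(rec, grid, sig, noise_sd = 0.1,
                         seed = derive_seed(900, dg, i))$intensities[mask])
  }
  ad <- vapply(1:200, function(i) region_mean("AD", i), 0)
  cn <- vapply(1:200, function(i) region_mean("CN", i), 0)
  diff_hat <- mean(ad) - mean(cn)
  se <- sqrt(var(ad) / 200 + var(cn) / 200)
  expect_lt(abs(diff_hat - (-sig$effect)), 4 * se)
})

test_that("region contrast grows monotonically with the effect parameter", {
  grid <- volume_grid(c(10, 10, 10))
  gaps <- vapply(c(0.05, 0.2, 0.5), function(e) {
    sig <- signal_model(effect = e, subject_sd = 0)
    mask <- fedalz:::region_mask(grid, sig)
    rec <- function(dg) data.frame(subject_id = "X", age = 72, sex = "F",
                                   diagnosis = dg)
    mean(generate_volume(rec("CN"), grid, sig, 0, seed = 4)$intensities[mask]) -
      mean(generate_volume(rec("AD"), grid, sig, 0, seed = 4)$intensities[mask])
  }, 0)
  expect_true(all(diff(gaps) > 0))
})

test_that("development/test split is balanced, matched and a partition", {
  co <- generate_cohort(618, 166, 345, seed = 1)
  for (s in 1:10) {
    sp <- make_split(co, 50, seed = s)
    r <- co$records[co$records$subject_id %in% sp$test_ids, ]
    expect_equal(nrow(r), 100)
    expect_equal(sum(r$diagnosis == "AD"), 50)
    expect_equal(unname(table(r$diagnosis, r$sex)["AD", ]), c(25, 25),
                 ignore_attr = TRUE)
    expect_equal(unname(table(r$diagnosis, r$sex)["CN", ]), c(25, 25),
                 ignore_attr = TRUE)
    expect_lte(abs(sp$age_gap), sp$age_tolerance)
    # partition property
    expect_length(intersect(sp$dev_ids, sp$test_ids), 0)
    expect_setequal(c(sp$dev_ids, sp$test_ids), co$records$subject_id)
  }
  # different seeds give different test sets
  expect_false(setequal(make_split(co, 50, seed = 1)$test_ids,
                        make_split(co, 50, seed = 2)$test_ids))
})

test_that("split edge cases error out explicitly", {
  co <- generate_cohort(40, 20, 20, seed = 2)
  sp0 <- make_split(co, 0, seed = 1)
  expect_length(sp0$test_ids, 0)
  expect_setequal(sp0$dev_ids, co$records$subject_id)
  expect_error(make_split(co, 5, seed = 1), "even")
  expect_error(make_split(co, 30, seed = 1), "infeasible")
})

test_that("volumes survive a NIfTI round trip", {
  grid <- volume_grid(c(8, 8, 8), spacing = c(1, 1, 2))
  rec <- data.frame(subject_id = "X", age = 70, sex = "M", diagnosis = "CN")
  v <- generate_volume(rec, grid, signal_model(), 0.1, seed = 12)
  path <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(path))
  write_volume_nifti(v, path)
  v2 <- read_volume_nifti(path)
  expect_equal(v2$intensities, v$intensities, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(v2$spacing), c(1, 1, 2), tolerance = 1e-6)
})

test_that("cohort and split CSV writers round trip", {
  co <- generate_cohort(12, 6, 6, seed = 3)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  on.exit(unlink(c(f1, f2)))
  write_cohort_csv(co, f1)
  back <- read_cohort_csv(f1)
  expect_equal(back$subject_id, co$records$subject_id)
  expect_equal(back$diagnosis, co$records$diagnosis)
  sp <- make_split(co, 2, seed = 1)
  write_split_csv(sp, f2)
  df <- utils::read.csv(f2)
  expect_setequal(df$subject_id[df$fold == "test"], sp$test_ids)
})
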