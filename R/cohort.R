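#' Age model for the synthetic cohort generator
#'
#' Ages are drawn from a truncated normal per diagnosis group. Defaults place
#' the AD group a few years above the CN group, with a common spread wide
#' enough that a median split of the cohort yields two age groups roughly a
#' decade apart, as needed by the age-heterogeneous client scenarios.
#'
#' @param ad_mean,cn_mean Group means in years.
#' @param sd Common standard deviation in years.
#' @param bounds Length-2 truncation bounds in years.
#' @return A list with per-diagnosis `mean`, common `sd` and `bounds`.
#' @export
age_model <- function(ad_mean = 76, cn_mean = 72, sd = 8, bounds = c(55, 95)) {
  stopifnot(sd > 0, length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(mean = c(AD = ad_mean, CN = cn_mean), sd = sd, bounds = bounds),
            class = "fedalz_age_model")
}

# truncated-normal draw via inverse CDF (deterministic given the RNG state)
rtruncnorm <- function(n, mean, sd, lo, hi) {
  u <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(u, mean, sd)
}

#' Signal model of the synthetic volumes
#'
#' Each synthetic scan is a fixed smooth 3D template plus, inside a designated
#' ellipsoidal "atrophy" region, a subject-specific intensity shift:
#' a deterministic attenuation of strength `effect` for AD subjects (optionally
#' modulated linearly by age), a zero-mean Gaussian between-subject shift with
#' standard deviation `subject_sd` for everyone, and i.i.d. voxel noise on the
#' whole grid. AD and CN scans therefore differ in expectation only inside the
#' region, by exactly `effect` (at `age_slope = 0`).
#'
#' The defaults (`effect = 0.10`, `subject_sd = 0.05`) put the Bayes-optimal
#' balanced accuracy of the region-mean statistic near `pnorm(1)`, i.e. in the
#' mid-80s percent — the regime the classifier is meant to operate in.
#'
#' @param effect Mean intensity attenuation inside the region for AD subjects.
#' @param subject_sd SD of the per-subject regional intensity shift (both
#'   diagnoses), the main source of class overlap.
#' @param age_slope Relative change of the AD attenuation per year of age above
#'   `age_ref` (0 disables age modulation).
#' @param age_ref Reference age in years for the modulation.
#' @param center,radius Region center and radius as fractions of the grid.
#' @return A `fedalz_signal` parameter list.
#' @export
signal_model <- function(effect = 0.10, subject_sd = 0.05, age_slope = 0,
                         age_ref = 74, center = c(0.55, 0.45, 0.55),
                         radius = 0.18) {
  stopifnot(effect >= 0, subject_sd >= 0, radius > 0)
  structure(list(effect = effect, subject_sd = subject_sd,
                 age_slope = age_slope, age_ref = age_ref,
                 center = center, radius = radius),
            class = "fedalz_signal")
}

#' Voxel grid specification
#'
#' @param shape Integer voxel counts per axis (length 3).
#' @param spacing Voxel size in mm per axis.
#' @return A `fedalz_grid` object.
#' @export
volume_grid <- function(shape = c(32, 32, 32), spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape <= 0)) {
    stop("grid shape must be three positive voxel counts")
  }
  stopifnot(length(spacing) == 3, all(spacing > 0))
  structure(list(shape = shape, spacing = spacing), class = "fedalz_grid")
}

# smooth "brain-like" template on the grid: a broad Gaussian envelope with a
# gentle low-frequency internal modulation, intensities in [0, 1]
volume_template <- function(grid) {
  d <- grid$shape
  ax <- lapply(1:3, function(i) (seq_len(d[i]) - 0.5) / d[i] - 0.5)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  env <- exp(-r2 / (2 * 0.28^2))
  mod <- outer(outer(sin(pi * 3 * ax[[1]]), cos(pi * 2 * ax[[2]]), `*`),
               sin(pi * 2 * ax[[3]]), `*`)
  env * (0.85 + 0.15 * mod)
}

# logical mask of the designated atrophy region (ellipsoid in grid fractions)
region_mask <- function(grid, signal) {
  d <- grid$shape
  ax <- lapply(1:3, function(i) ((seq_len(d[i]) - 0.5) / d[i] - signal$center[i]) /
                 signal$radius)
  r2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  r2 <= 1
}

#' Generate an ADNI-like synthetic cohort
#'
#' Builds the subject metadata table with an exact demographic composition and
#' attaches a deterministic per-subject volume factory. Subject counts are
#' allocated to the four (diagnosis, sex) cells deterministically: the AD/F
#' cell receives `round(n_ad * n_female / n_total)` subjects (clipped to the
#' feasible range) and the remaining cells follow from the margins, so the
#' composition is exact for every seed rather than a Bernoulli draw.
#'
#' Volumes are not materialized here: [cohort_volume()] regenerates any
#' subject's scan bit-for-bit from a sub-seed derived from the cohort seed and
#' the subject id.
#'
#' @param n_total,n_ad,n_female Total subject count and the AD / female counts.
#'   The defaults reproduce the study composition: 618 subjects, 166 AD / 452
#'   CN, 345 women / 273 men.
#' @param ages An [age_model()].
#' @param grid A [volume_grid()].
#' @param signal A [signal_model()].
#' @param noise_sd Voxel-wise Gaussian noise SD.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `fedalz_cohort`: list with `records` (data.frame with columns
#'   `subject_id`, `age`, `sex`, `diagnosis`), the generator parameters and
#'   the seed.
#' @export
generate_cohort <- function(n_total = 618, n_ad = 166, n_female = 345,
                            ages = age_model(), grid = volume_grid(),
                            signal = signal_model(), noise_sd = 0.1,
                            seed = 1) {
  stopifnot(inherits(ages, "fedalz_age_model"), inherits(grid, "fedalz_grid"),
            inherits(signal, "fedalz_signal"), noise_sd >= 0)
  if (n_ad > n_total || n_female > n_total || n_total < 0 || n_ad < 0 ||
      n_female < 0) {
    stop("infeasible composition: need 0 <= n_ad, n_female <= n_total")
  }
  n_cn <- n_total - n_ad
  # deterministic allocation of the one free cell of the 2x2 margin table
  lo <- max(0, n_ad + n_female - n_total)
  hi <- min(n_ad, n_female)
  ad_f <- if (n_total > 0) min(max(round(n_ad * n_female / n_total), lo), hi) else 0
  cells <- c(AD_F = ad_f, AD_M = n_ad - ad_f,
             CN_F = n_female - ad_f, CN_M = n_cn - (n_female - ad_f))
  stopifnot(all(cells >= 0))
  diagnosis <- rep(c("AD", "AD", "CN", "CN"), times = cells)
  sex <- rep(c("F", "M", "F", "M"), times = cells)
  records <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n_total)),
    age = rep(NA_real_, n_total),
    sex = sex,
    diagnosis = diagnosis,
    stringsAsFactors = FALSE
  )
  if (n_total > 0) {
    records$age <- with_seed(derive_seed(seed, "ages"), {
      a <- numeric(n_total)
      for (dg in c("AD", "CN")) {
        idx <- which(records$diagnosis == dg)
        a[idx] <- rtruncnorm(length(idx), ages$mean[[dg]], ages$sd,
                             ages$bounds[1], ages$bounds[2])
      }
      a
    })
  }
  structure(list(records = records, ages = ages, grid = grid, signal = signal,
                 noise_sd = noise_sd, seed = seed),
            class = "fedalz_cohort")
}

#' @export
print.fedalz_cohort <- function(x, ...) {
  r <- x$records
  cat(sprintf("<fedalz_cohort> %d subjects (%d AD / %d CN, %d F / %d M), grid %s\n",
              nrow(r), sum(r$diagnosis == "AD"), sum(r$diagnosis == "CN"),
              sum(r$sex == "F"), sum(r$sex == "M"),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Generate one synthetic volume for a subject record
#'
#' @param record A single-row data.frame with `age` and `diagnosis` (a row of
#'   a cohort's `records`).
#' @param grid A [volume_grid()].
#' @param signal A [signal_model()].
#' @param noise_sd Voxel noise SD (>= 0).
#' @param seed Integer seed; the same record and seed give an identical grid.
#' @return A `fedalz_volume`: list with `intensities` (3D array) and `spacing`.
#' @export
generate_volume <- function(record, grid = volume_grid(),
                            signal = signal_model(), noise_sd = 0.1,
                            seed = 1) {
  stopifnot(inherits(grid, "fedalz_grid"), noise_sd >= 0)
  vol <- volume_template(grid)
  mask <- region_mask(grid, signal)
  with_seed(seed, {
    shift <- if (signal$subject_sd > 0) rnorm(1, 0, signal$subject_sd) else 0
    if (record$diagnosis == "AD" && signal$effect > 0) {
      e <- signal$effect *
        (1 + signal$age_slope * (record$age - signal$age_ref))
      shift <- shift - e
    }
    vol[mask] <- vol[mask] + shift
    if (noise_sd > 0) {
      vol <- vol + array(rnorm(length(vol), 0, noise_sd), dim(vol))
    }
  })
  structure(list(intensities = vol, spacing = grid$spacing),
            class = "fedalz_volume")
}

#' Regenerate the volume of one cohort subject
#'
#' Deterministic per subject: the volume seed is derived from the cohort seed
#' and the subject id.
#'
#' @param cohort A `fedalz_cohort`.
#' @param subject_id Subject id present in the cohort.
#' @return A `fedalz_volume`.
#' @export
cohort_volume <- function(cohort, subject_id) {
  i <- match(subject_id, cohort$records$subject_id)
  if (is.na(i)) stop("unknown subject_id: ", subject_id)
  generate_volume(cohort$records[i, ], cohort$grid, cohort$signal,
                  cohort$noise_sd, derive_seed(cohort$seed, "volume", subject_id))
}

#' Balanced, demographically matched development/test split
#'
#' The test set holds exactly `test_per_class` subjects of each diagnosis,
#' with equal numbers of women and men within each diagnosis. After the
#' initial seeded draw, a greedy swap procedure exchanges selected against
#' unselected subjects of the same (diagnosis, sex) cell until the AD and CN
#' test-set mean ages agree within `age_tolerance` years (or no swap improves
#' the gap further). Everything not in the test set forms the development set.
#'
#' @param cohort A `fedalz_cohort`.
#' @param test_per_class Subjects per diagnosis in the test set (must be even
#'   to allow the within-diagnosis sex balance; 0 gives an empty test set).
#' @param seed Split seed; repeated calls with different seeds give the
#'   repeated-splits protocol.
#' @param age_tolerance Maximum tolerated |mean AD age - mean CN age| in the
#'   test set, in years.
#' @return A `fedalz_split`: list with `seed`, `dev_ids`, `test_ids`,
#'   `age_tolerance` and the achieved `age_gap`.
#' @export
make_split <- function(cohort, test_per_class = 50, seed = 1,
                       age_tolerance = 1) {
  r <- cohort$records
  if (test_per_class == 0) {
    return(structure(list(seed = seed, dev_ids = r$subject_id,
                          test_ids = character(0),
                          age_tolerance = age_tolerance, age_gap = NA_real_),
                     class = "fedalz_split"))
  }
  if (test_per_class %% 2 != 0) {
    stop("test_per_class must be even for the within-diagnosis sex balance")
  }
  half <- test_per_class / 2
  for (dg in c("AD", "CN")) for (sx in c("F", "M")) {
    n_cell <- sum(r$diagnosis == dg & r$sex == sx)
    if (n_cell < half) {
      stop(sprintf("infeasible test balance: need %d %s/%s subjects, have %d",
                   half, dg, sx, n_cell))
    }
  }
  sel <- with_seed(derive_seed(seed, "split"), {
    s <- logical(nrow(r))
    for (dg in c("AD", "CN")) for (sx in c("F", "M")) {
      cell <- which(r$diagnosis == dg & r$sex == sx)
      s[sample(cell, half)] <- TRUE
    }
    s
  })
  gap <- function(s) {
    mean(r$age[s & r$diagnosis == "AD"]) - mean(r$age[s & r$diagnosis == "CN"])
  }
  # greedy: best single same-cell swap per iteration while above tolerance
  repeat {
    g <- gap(sel)
    if (abs(g) <= age_tolerance) break
    best <- NULL
    best_gap <- abs(g)
    for (dg in c("AD", "CN")) for (sx in c("F", "M")) {
      cell_in <- which(sel & r$diagnosis == dg & r$sex == sx)
      cell_out <- which(!sel & r$diagnosis == dg & r$sex == sx)
      if (!length(cell_in) || !length(cell_out)) next
      # swapping `i` out and `o` in changes the dg mean by (age_o - age_i)/n
      n_dg <- test_per_class
      sign_dg <- if (dg == "AD") 1 else -1
      for (i in cell_in) {
        delta <- sign_dg * (r$age[cell_out] - r$age[i]) / n_dg
        j <- which.min(abs(g + delta))
        if (abs(g + delta[j]) < best_gap - 1e-12) {
          best_gap <- abs(g + delta[j])
          best <- c(i, cell_out[j])
        }
      }
    }
    if (is.null(best)) break  # no improving swap left
    sel[best[1]] <- FALSE
    sel[best[2]] <- TRUE
  }
  structure(list(seed = seed, dev_ids = r$subject_id[!sel],
                 test_ids = r$subject_id[sel],
                 age_tolerance = age_tolerance, age_gap = gap(sel)),
            class = "fedalz_split")
}

#' Materialize a labeled volume dataset for a set of subjects
#'
#' Stacks the (regenerated) volumes of the given subjects into a single 4D
#' array in the given id order, with the diagnosis labels and ids attached.
#'
#' @param cohort A `fedalz_cohort`.
#' @param ids Character vector of subject ids (order is preserved).
#' @return A `fedalz_dataset`: list with `x` (array `shape x n`), `y` (factor
#'   with levels AD, CN), `subject_id`.
#' @export
build_dataset <- function(cohort, ids) {
  stopifnot(length(ids) > 0)
  d <- cohort$grid$shape
  x <- array(0, c(d, length(ids)))
  for (k in seq_along(ids)) {
    x[, , , k] <- cohort_volume(cohort, ids[k])$intensities
  }
  i <- match(ids, cohort$records$subject_id)
  structure(list(x = x,
                 y = factor(cohort$records$diagnosis[i], levels = c("AD", "CN")),
                 subject_id = ids),
            class = "fedalz_dataset")
}

#' Write / read a volume as NIfTI-1
#'
#' The affine is diagonal, scaled by the voxel spacing.
#'
#' @param volume A `fedalz_volume`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `write_volume_nifti` returns `path` invisibly; `read_volume_nifti`
#'   returns a `fedalz_volume`.
#' @export
write_volume_nifti <- function(volume, path) {
  arr <- volume$intensities
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(intensities = array(as.numeric(img), dim(img)),
                 spacing = RNifti::pixdim(img)[1:3]),
            class = "fedalz_volume")
}

#' Write / read cohort metadata and split tables as CSV
#'
#' @param cohort A `fedalz_cohort`; `split` a `fedalz_split`.
#' @param path Output path.
#' @return The path, invisibly (writers); a data.frame (readers).
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @param split A `fedalz_split`.
#' @export
write_split_csv <- function(split, path) {
  df <- data.frame(
    subject_id = c(split$dev_ids, split$test_ids),
    fold = rep(c("dev", "test"), c(length(split$dev_ids), length(split$test_ids))),
    seed = split$seed, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
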