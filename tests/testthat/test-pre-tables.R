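test_that("peak tables read, validate and round-trip", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tlabel\tintensity_ox\tintensity_red\treplicate",
               "350\tbb\t89\t100\t1",
               "351\tbb\t110\t100\t1",
               "354\tbb\t77\t100\t1"), f)
  rec <- read_peak_table(f)
  expect_equal(nrow(rec), 3)
  expect_true(all(rec$valid))

  # minimal dialect: replicate and label columns are optional
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("residue,intensity_ox,intensity_red", "1,50,100"), f2)
  rec2 <- read_peak_table(f2)
  expect_equal(rec2$replicate, 1L)
  expect_equal(rec2$label, "bb")

  # zero reduced intensity is flagged invalid, not dropped
  rec3 <- peak_records(1:2, c(50, 60), c(100, 0))
  expect_identical(rec3$valid, c(TRUE, FALSE))
  expect_equal(nrow(rec3), 2)

  # duplicated keys are a hard error
  expect_error(peak_records(c(1, 1), c(50, 60), c(100, 100)),
               "duplicate")

  # schema errors name the missing column
  f4 <- tempfile(fileext = ".tsv")
  writeLines(c("residue\tintensity_ox", "1\t50"), f4)
  expect_error(read_peak_table(f4), "intensity_red")

  # write/read round trip preserves intensities
  f5 <- tempfile(fileext = ".tsv")
  write_peak_table(rec, f5)
  expect_equal(read_peak_table(f5)$intensity_ox, rec$intensity_ox)
})

test_that("compute_pre_profile computes replicate statistics and classes", {
  rec <- peak_records(residue = c(1L, 1L, 2L, 2L, 3L),
                      intensity_ox = c(80, 90, 30, 30, 50),
                      intensity_red = c(100, 100, 100, 100, 100),
                      replicate = c(1L, 2L, 1L, 2L, 1L))
  prof <- compute_pre_profile(rec)
  expect_equal(prof$pre_mean, c(0.85, 0.30, 0.50))
  expect_equal(prof$pre_sd, c(sd(c(0.8, 0.9)), 0, 0))
  expect_equal(prof$pre_sd[1], 0.0707, tolerance = 1e-3)
  expect_equal(prof$n_replicates, c(2L, 2L, 1L))
  expect_equal(prof$class_label, c("baseline", "strong", "intermediate"))

  # region annotation from configured residue sets
  prof2 <- compute_pre_profile(rec, regions = list(primary = 1L,
                                                   tripartite = 3L))
  expect_equal(prof2$region_label, c("primary", "none", "tripartite"))

  # invalid records are excluded but counted
  rec_bad <- peak_records(1:2, c(50, 60), c(100, 0))
  prof3 <- compute_pre_profile(rec_bad)
  expect_equal(nrow(prof3), 1)
  expect_equal(attr(prof3, "n_invalid"), 1L)
  expect_error(compute_pre_profile(peak_records(1, 50, 0)), "no valid")
})

test_that("classification bins are half-open and exhaustive", {
  x <- c(0, 0.3999, 0.4, 0.5999, 0.6, 0.7999, 0.8, 1.1999, 1.2, 5, 100)
  cls <- premodes:::classify_pre(x)
  expect_false(anyNA(cls))
  expect_equal(cls[1:2], c("strong", "strong"))
  expect_equal(cls[3:4], c("intermediate", "intermediate"))
  expect_equal(cls[5:6], c("moderate", "moderate"))
  expect_equal(cls[7:8], c("baseline", "baseline"))
  expect_equal(cls[9:11], c("elevated", "elevated", "elevated"))
})

test_that("summed replicates differ from mean-of-ratios as arithmetic says", {
  # equal denominators: summed == mean
  rec_eq <- peak_records(c(1L, 1L), c(40, 60), c(100, 100),
                         replicate = 1:2)
  expect_equal(summed_replicate_profile(rec_eq)$pre_mean, 0.5)
  expect_equal(compute_pre_profile(rec_eq)$pre_mean, 0.5)

  # identical replicates equal the single-replicate ratio
  rec_id <- peak_records(c(1L, 1L), c(30, 30), c(100, 100),
                         replicate = 1:2)
  expect_equal(summed_replicate_profile(rec_id)$pre_mean, 0.3)

  # unequal denominators: summed (sum ox / sum red) != mean of ratios
  rec_a <- peak_records(c(1L, 1L), c(10, 90), c(20, 180), replicate = 1:2)
  expect_equal(summed_replicate_profile(rec_a)$pre_mean, 0.5)
  expect_equal(compute_pre_profile(rec_a)$pre_mean, 0.5)
  rec_b <- peak_records(c(1L, 1L), c(10, 90), c(20, 100), replicate = 1:2)
  expect_equal(summed_replicate_profile(rec_b)$pre_mean, 100 / 120)
  expect_equal(compute_pre_profile(rec_b)$pre_mean, 0.70)
})

test_that("normalized-ratio perturbation flags the depressed residues", {
  free <- data.frame(residue = 1:4, intensity = rep(100, 4))
  cplx <- data.frame(residue = 1:4, intensity = c(100, 100, 50, 150))
  res <- normalized_ratio_perturbation(free, cplx)
  expect_equal(res$table$normalized, c(1, 1, 0.5, 1.5))
  expect_equal(res$perturbed, 3L)

  # uniform ratios: nothing perturbed
  res0 <- normalized_ratio_perturbation(free,
                                        data.frame(residue = 1:4,
                                                   intensity = rep(40, 4)))
  expect_equal(res0$table$normalized, rep(1, 4))
  expect_length(res0$perturbed, 0)

  # invariant to global rescaling of either spectrum (different sample
  # concentrations)
  for (k in c(0.2, 3, 17)) {
    scaled <- cplx
    scaled$intensity <- scaled$intensity * k
    expect_equal(normalized_ratio_perturbation(free, scaled)$table$normalized,
                 res$table$normalized)
    fscaled <- free
    fscaled$intensity <- fscaled$intensity * k
    expect_equal(normalized_ratio_perturbation(fscaled, cplx)$table$normalized,
                 res$table$normalized)
  }

  expect_error(normalized_ratio_perturbation(
    free, data.frame(residue = 10:12, intensity = 1:3)), "shared")
})

test_that("profiles export as TSV and JSON", {
  prof <- compute_pre_profile(peak_records(1:2, c(30, 90), c(100, 100)))
  f_tsv <- tempfile(fileext = ".tsv")
  write_pre_profile(prof, f_tsv)
  expect_equal(utils::read.delim(f_tsv)$pre_mean, prof$pre_mean)
  f_json <- tempfile(fileext = ".json")
  write_pre_profile(prof, f_json, format = "json")
  back <- jsonlite::read_json(f_json, simplifyVector = TRUE)
  expect_equal(back$pre_mean, prof$pre_mean)
})
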