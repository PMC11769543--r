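# Phantom generator: geometry, determinism, cohort mixes.

test_that("noiseless phantoms are piecewise constant at the spec intensities", {
  ph <- fixture_phantom(noise_sd = 0, seed = 51)
  vals <- sort(unique(as.vector(ph$vol$data)))
  expect_true(all(vals %in% c(-1000, 40, 70, 120, 700)))
  expect_true(all(ph$vol$data[ph$mask$data == 1L] == 120))
  expect_true(all(ph$vol$data[ph$mask$data == 2L] == 70))
  # intensity ordering constraint is enforced
  expect_error(phantom_spec(body_hu = 800), "ordered")
})

test_that("painted tumors hit the requested diameter within one voxel", {
  for (ud in c(1.0, 1.4, 1.8)) {
    ph <- fixture_phantom(ud_cm = ud, noise_sd = 0, seed = 52)
    inst <- instance_components(ph$mask)
    expect_length(inst, 1L)
    expect_lte(abs(inst[[1]]$diameter_cm - ud), 0.1)
  }
})

test_that("the same seed reproduces the identical phantom", {
  a <- fixture_phantom(noise_sd = 10, seed = 53)
  b <- fixture_phantom(noise_sd = 10, seed = 53)
  expect_identical(a$vol$data, b$vol$data)
  expect_identical(a$mask$data, b$mask$data)
  c_ <- fixture_phantom(noise_sd = 10, seed = 54)
  expect_false(identical(a$vol$data, c_$vol$data))
})

test_that("a tumor that touches no kidney is refused", {
  spec <- phantom_spec(noise_sd = 0,
                       tumors = list(list(ud_cm = 0.8,
                                          centre_mm = c(6, 6, 6))))
  expect_error(generate_phantom(spec, rng = 1), "does not touch a kidney")
  expect_error(phantom_spec(tumors = list(list(ud_cm = 12))), "\\[0.5, 10\\]")
})

test_that("cohort counts follow the requested size mix", {
  coh <- generate_cohort(100, size_mix = c(small = 0.54, medium = 0.24,
                                           large = 0.22),
                         difficulty = "easy", seed = 55, preset = "full")
  counts <- table(coh$manifest$category)
  expect_equal(unname(counts[c("small", "medium", "large")]),
               c(54L, 24L, 22L), ignore_attr = TRUE)
  # manifest diameters agree with re-measured masks within one voxel
  for (i in sample.int(100, 6)) {
    inst <- instance_components(coh$cases[[i]]$mask)
    expect_length(inst, 1L)
    expect_lte(abs(inst[[1]]$diameter_cm - coh$manifest$true_ud_cm[i]),
               0.2 + 1e-9)  # one 2 mm voxel
    expect_equal(inst[[1]]$category, coh$manifest$category[i])
  }
})

test_that("cohorts are reproducible and write valid NIfTI pairs", {
  m1 <- generate_cohort(6, difficulty = "easy", seed = 56,
                        preset = "desk")$manifest
  m2 <- generate_cohort(6, difficulty = "easy", seed = 56,
                        preset = "desk")$manifest
  expect_identical(m1, m2)
  dir <- file.path(tempdir(), "cohort_test")
  res <- generate_cohort(2, difficulty = "easy", seed = 57, preset = "desk",
                         out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_volume(res$cases[[1]]$image)
  expect_equal(dim(back$data), c(64L, 64L, 64L))
  mk <- read_volume(res$cases[[1]]$mask, kind = "mask")
  expect_true(all(mk$data %in% c(0L, 1L, 2L)))
  unlink(dir, recursive = TRUE)
})

test_that("phantom cases survive preprocessing and metric round trips", {
  ph <- fixture_phantom(noise_sd = 10, seed = 58)
  st <- compute_intensity_stats(list(ph$vol))
  pre <- preprocess_case(ph$vol, st, ph$mask, target_spacing = 1.0)
  expect_equal(dim(pre$vol$data), dim(ph$vol$data))  # already 1 mm
  inst <- instance_components(pre$mask)
  expect_length(inst, 1L)
  self <- evaluate_case(pre$mask, pre$mask)
  expect_equal(self$detection$matches$iou, 1)
})
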