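blank_mask <- function(dims = c(10, 10, 6)) array(0L, dims)

test_that("connected components respect the neighbourhood order", {
  m <- blank_mask()
  m[2:3, 2:3, 2] <- 1L
  m[7:8, 7:8, 4] <- 1L
  cs <- find_components(label_mask(m), 26)
  expect_equal(nrow(cs$components), 2)
  expect_equal(sort(cs$components$n_voxels), c(4, 4))
  # diagonal touch: one component at 26, two at 6
  d <- blank_mask()
  d[2, 2, 2] <- 1L; d[3, 3, 3] <- 1L
  expect_equal(nrow(find_components(label_mask(d), 26)$components), 1)
  expect_equal(nrow(find_components(label_mask(d), 6)$components), 2)
  # empty mask
  expect_equal(nrow(find_components(label_mask(blank_mask()))$components), 0)
  # per-label separation
  two <- blank_mask(); two[2, 2, 2] <- 1L; two[5, 5, 3] <- 2L
  cs2 <- find_components(label_mask(two))
  expect_equal(cs2$components$label, c(1L, 2L))
})

test_that("noise removal keeps the largest component / applies min-size", {
  m <- blank_mask(c(16, 16, 8))
  m[2:6, 2:6, 2:5] <- 1L          # 100-voxel blob
  m[14, 14, 7] <- 1L; m[14, 15, 7] <- 1L   # 2-voxel speck
  ms <- remove_noise_components(label_mask(m), "min-size", min_size = 10)
  expect_equal(sum(ms$voxels == 1L), 100)
  expect_equal(ms$voxels[14, 14, 7], 0L)
  kl <- remove_noise_components(label_mask(m), "keep-largest")
  expect_identical(kl$voxels, ms$voxels)
  # identity on single-component masks; idempotent
  single <- label_mask(blank_mask()); single$voxels[3:4, 3:4, 2] <- 1L
  expect_identical(remove_noise_components(single, "keep-largest")$voxels,
                   single$voxels)
  expect_identical(
    remove_noise_components(remove_noise_components(label_mask(m),
                                                    "keep-largest"),
                            "keep-largest")$voxels,
    kl$voxels)
  expect_warning(remove_noise_components(
    label_mask(m), "min-size", min_size = 1000), "entirely removed")
  expect_error(remove_noise_components(label_mask(m), "min-size",
                                       min_size = 0), "positive")
})

test_that("hole filling closes cavities but not border-connected channels", {
  m <- blank_mask(c(9, 9, 9))
  m[2:6, 2:6, 2:6] <- 1L
  m[3:5, 3:5, 3:5] <- 0L          # internal cavity
  f <- fill_holes(label_mask(m))
  expect_equal(sum(f$voxels == 1L), 125)
  # idempotent, and a solid blob is unchanged
  expect_identical(fill_holes(f)$voxels, f$voxels)
  # open channel to the border is not a cavity
  ch <- blank_mask(c(9, 9, 9))
  ch[2:6, 2:6, 2:6] <- 1L
  ch[4, 4, ] <- 0L                # tunnel through the whole z extent
  fc <- fill_holes(label_mask(ch))
  expect_identical(fc$voxels, ch)
  # no foreground voxel is ever removed
  expect_true(all(f$voxels[m == 1L] == 1L))
})

test_that("laterality is assigned by world left-right position", {
  m <- blank_mask(c(20, 20, 6))
  # PLI: grid axis 2 increases toward the patient's left
  m[10, 15:16, 3] <- 1L   # left-side blob
  m[10, 4:5, 3] <- 1L     # right-side blob
  lat <- assign_laterality(label_mask(m, orientation = "PLI"))
  expect_equal(unique(lat$voxels[10, 15:16, 3]), 1L)
  expect_equal(unique(lat$voxels[10, 4:5, 3]), 2L)
  # flipping the volume along the left-right axis swaps the labels
  flipped <- label_mask(m[, 20:1, ], orientation = "PLI")
  lat2 <- assign_laterality(flipped)
  expect_equal(unique(lat2$voxels[10, 20 - c(15, 16) + 1, 3]), 2L)
  expect_equal(unique(lat2$voxels[10, 20 - c(4, 5) + 1, 3]), 1L)
  # empty mask passes through
  expect_equal(sum(assign_laterality(label_mask(blank_mask()))$voxels), 0)
  # both components on one side: nearer one is reassigned with a warning
  b <- blank_mask(c(20, 20, 6))
  b[10, 12:13, 3] <- 1L; b[10, 17:18, 3] <- 1L
  expect_warning(lat3 <- assign_laterality(label_mask(b)), "one side")
  expect_setequal(unique(lat3$voxels[lat3$voxels > 0]), c(1L, 2L))
})

test_that("postprocessing never degrades a prediction whose largest components are right", {
  rec <- fixture("rec1", function() make_phantom_record(1))
  truth <- rec$mask
  set.seed(9)
  for (i in 1:20) {
    noisy <- truth$voxels
    # sprinkle small random specks of both labels
    for (lab in 1:2) {
      n <- sample(1:4, 1)
      pos <- cbind(sample(dim(noisy)[1], n), sample(dim(noisy)[2], n),
                   sample(dim(noisy)[3], n))
      ok <- noisy[pos] == 0L
      noisy[pos[ok, , drop = FALSE]] <- lab
    }
    cleaned <- suppressWarnings(postprocess_mask(
      label_mask(noisy, truth$spacing, truth$orientation)))
    sdiff <- function(a) sum(a$voxels != truth$voxels)
    expect_lte(sdiff(cleaned),
               sum(noisy != truth$voxels))
  }
})
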