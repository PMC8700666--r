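test_that("auto-thresholds fall between the grey-level modes", {
  lab <- array(sample(c(0L, 1L, 3L), 30^3, replace = TRUE,
                      prob = c(0.5, 0.2, 0.3)), c(30, 30, 30))
  clean <- render_greyscale(label_volume(lab, 1), c(50, 120, 200), 0, 0)
  thr <- estimate_thresholds(clean)
  expect_gt(thr[1], 50); expect_lt(thr[1], 120)
  expect_gt(thr[2], 120); expect_lt(thr[2], 200)
})

test_that("degenerate histograms are rejected with advice to use manual thresholds", {
  const <- grey_volume(array(7, c(10, 10, 10)), 1)
  expect_error(estimate_thresholds(const),
               class = "icemorph_degenerate_histogram")
  # two-mode (unfrozen) volume
  withr::local_seed(2)
  two <- grey_volume(array(sample(c(50, 200), 20^3, TRUE) +
                             rnorm(20^3, 0, 5), c(20, 20, 20)), 1)
  expect_error(estimate_thresholds(two),
               class = "icemorph_degenerate_histogram")
  # the user recovers by passing a single manual threshold: no ice voxels
  seg <- segment(two, thresholds = 125, closing_radius = 2)
  expect_equal(volume_fractions(seg$labels)$V_ice, 0)
})

test_that("threshold boundaries are lower-inclusive on the brighter class", {
  g <- grey_volume(array(c(99, 100, 149, 150, 151, 10), c(6, 1, 1)), 1)
  lab <- segment_phases(g, c(100, 150))
  expect_equal(as.vector(lab$data), c(0L, 1L, 1L, 3L, 3L, 0L))
})

test_that("closing matches a brute-force ball dilation/erosion oracle", {
  withr::local_seed(31)
  mask <- array(runif(18^3) < 0.35, c(18, 18, 18))
  for (r in c(2L, 4L)) {
    expect_identical(close_matrix(mask, r), brute_close(mask, r))
  }
})

test_that("closing is extensive, increasing in radius, idempotent, and fills narrow gaps", {
  slabs <- array(FALSE, c(40, 40, 40))
  slabs[, , 10:14] <- TRUE
  slabs[, , 25:29] <- TRUE  # 10-voxel gap
  closed <- close_matrix(slabs, 16)
  expect_true(all(closed[slabs]))          # extensive
  # the gap is narrower than the ball and fills away from the volume
  # faces (background padding keeps face corners open by design)
  expect_true(all(closed[17:24, 17:24, 15:24]))
  expect_identical(close_matrix(closed, 16), closed)  # idempotent
  smaller <- close_matrix(slabs, 4)
  expect_true(all(closed[smaller]))        # increasing in radius
  expect_false(any(smaller[, , 17:22]))    # small ball spans no 10-vx gap
  expect_identical(close_matrix(slabs, 0), slabs)
  # border padding: closing cannot manufacture matrix at empty faces
  lone <- array(FALSE, c(20, 20, 20)); lone[10, 10, 10] <- TRUE
  expect_identical(close_matrix(lone, 6), lone)
})

test_that("ice partition is an exact boolean not/and split", {
  withr::local_seed(13)
  for (i in 1:3) {
    ice <- array(runif(12^3) < 0.3, c(12, 12, 12))
    mat <- array(runif(12^3) < 0.5, c(12, 12, 12))
    p <- partition_ice(ice, mat)
    expect_identical(p$inside, ice & mat)
    expect_identical(p$outside, ice & !mat)
    expect_false(any(p$inside & p$outside))
    expect_identical(p$inside | p$outside, ice)
  }
  full <- array(TRUE, c(4, 4, 4))
  expect_false(any(partition_ice(full, full)$outside))
  expect_false(any(partition_ice(full, !full)$inside))
})

test_that("noiseless phantoms segment exactly; noisy ones within 1%", {
  sp <- phantom_preset("fast", shape = c(64, 64, 64), pore_scale = 40,
                       seed = 6, noise_sigma = 0, blur_sigma = 0)
  ph <- generate_phantom(sp)
  seg <- segment(ph$grey, closing_radius = 8)
  merge <- function(a) { a[a == 2L] <- 1L; a }
  expect_equal(mean(merge(seg$labels$data) == merge(ph$truth$data)), 1)
  # noise at one sixth of the smaller mode separation
  spn <- phantom_preset("fast", shape = c(64, 64, 64), pore_scale = 40,
                        seed = 6, noise_sigma = (120 - 50) / 6,
                        blur_sigma = 0)
  phn <- generate_phantom(spn)
  segn <- segment(phn$grey, closing_radius = 8)
  expect_lt(mean(merge(segn$labels$data) != merge(phn$truth$data)), 0.01)
})

test_that("segmentation result invariants hold and phantom fractions are recovered", {
  for (cond in c("fast", "slow")) {
    ph <- cached_phantom(cond, 1)
    seg <- segment(ph$grey, closing_radius = 16)
    lab <- seg$labels$data
    codes <- phase_codes()
    # matrix consistency
    expect_true(all(seg$matrix[lab == codes[["starch"]]]))
    expect_true(all(seg$matrix[lab == codes[["ice_inside"]]]))
    expect_false(any(seg$matrix[lab == codes[["ice_outside"]]]))
    # label partition
    expect_equal(sum(tabulate(as.vector(lab) + 1L, 4L)), length(lab))
    # recovery of the localized ice fractions within +/- 0.02 absolute
    tr <- volume_fractions(ph$truth)
    rc <- volume_fractions(seg$labels)
    if (cond == "fast") {
      expect_lt(abs(rc$phi_ice_inside_in_solid - tr$phi_ice_inside_in_solid),
                0.02)
    } else {
      expect_lt(abs(rc$phi_ice_outside_in_solid - tr$phi_ice_outside_in_solid),
                0.02)
    }
    expect_lt(abs(rc$phi_air - tr$phi_air), 0.02)
  }
})
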