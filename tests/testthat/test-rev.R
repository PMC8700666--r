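label_from_solid <- function(solid, voxel_size = 2) {
  lab <- array(0L, dim(solid))
  lab[solid] <- 3L
  label_volume(lab, voxel_size)
}

test_that("REV curve reduces to exact fractions in degenerate cases", {
  # single-phase volume: fraction 1 at every size
  lv <- label_volume(array(0L, c(32, 32, 32)), 1)
  cv <- rev_curve(lv, "air", sizes = c(8, 16, 32))
  expect_equal(cv$mean_fraction, rep(1, 3))
  expect_equal(smallest_representative_size(cv, tolerance = 0.01), 8L)
  # full-volume size equals the global fraction exactly
  solid <- generate_pore_space(phantom_spec(shape = c(48, 48, 48),
                                            pore_scale = 30, seed = 3))
  lv2 <- label_from_solid(solid)
  cv2 <- rev_curve(lv2, "air", sizes = c(16, 48))
  expect_equal(cv2$mean_fraction[cv2$size_vx == 48],
               volume_fractions(lv2)$phi_air)
  # oversized requests are skipped with a notice, not an error
  expect_message(rev_curve(lv2, "air", sizes = c(32, 64)), "skipped")
  expect_error(suppressMessages(rev_curve(lv2, "air", sizes = 64)),
               class = "icemorph_parameterization_error")
})

test_that("stationary phantoms converge within the reference band", {
  # crop away from the generation volume so the replicate fractions vary
  # naturally (the generator pins the global porosity by construction)
  vols <- lapply(1:4, function(s) {
    lv <- label_from_solid(generate_pore_space(
      phantom_spec(shape = c(72, 72, 72), pore_scale = 24, seed = s)))
    crop_subvolume(lv, 56)
  })
  cv <- rev_curve(vols, "air", sizes = c(16, 24, 32, 48, 56))
  ref <- attr(cv, "ref_mean")
  sdv <- attr(cv, "ref_sd")
  # pore_scale is 12 voxels: sizes >= 4x that stay within 2 sd of reference
  expect_true(all(abs(cv$mean_fraction[cv$size_vx >= 48] - ref) <= 2 * sdv))
  expect_false(is.na(smallest_representative_size(cv, tolerance = "std")))
})

test_that("a dominant macropore pushes the representative size beyond its diameter", {
  # one air ball of ~1/3 the volume edge, centred, in otherwise pure solid
  solid <- !ball_mask(60, c(30, 30, 30), 10)
  cv <- rev_curve(label_from_solid(solid), "air",
                  sizes = c(8, 16, 30, 45, 60))
  rep_size <- smallest_representative_size(cv, tolerance = 0.05)
  expect_gt(rep_size, 20)
  # flat curve at the largest size only
  expect_equal(smallest_representative_size(cv, tolerance = 1e-12), 60L)
})

test_that("across-replicate variance of sub-volume fractions decays with size", {
  fracs <- sapply(1:8, function(s) {
    solid <- generate_pore_space(phantom_spec(shape = c(56, 56, 56),
                                              pore_scale = 20, seed = 100 + s))
    lv <- label_from_solid(solid)
    vapply(c(14, 28, 56), function(sz)
      volume_fractions(crop_subvolume(lv, sz))$phi_air, numeric(1))
  })
  vars <- apply(fracs, 1, stats::var)
  # non-increasing in size, with 10% sampling slack
  expect_true(all(diff(vars) <= 0.1 * vars[-length(vars)]))
})
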