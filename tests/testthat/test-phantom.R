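test_that("pore space hits the target porosity and is deterministic", {
  spec <- phantom_spec(shape = c(64, 64, 64), pore_scale = 30,
                       target_porosity = 0.6, seed = 1)
  solid <- generate_pore_space(spec)
  expect_lt(abs(mean(!solid) - 0.6), 0.02)
  expect_identical(solid, generate_pore_space(spec))
  # near-solid limit
  spec0 <- phantom_spec(shape = c(48, 48, 48), pore_scale = 30,
                        target_porosity = 0.001, seed = 1)
  expect_lte(mean(!generate_pore_space(spec0)), 0.01)
  # unattainable parameterization
  expect_error(generate_pore_space(phantom_spec(shape = c(20, 20, 20),
                                                pore_scale = 80)),
               class = "icemorph_parameterization_error")
})

test_that("wall ice forms a conformal shell of the requested thickness", {
  # spherical cavity of radius 20 in solid; 5-voxel shell
  n <- 51
  solid <- !ball_mask(n, c(26, 26, 26), 20)
  shell <- deposit_wall_ice(solid, thickness_um = 5, voxel_size = 1)
  expect_false(any(shell & solid))
  analytic <- 4 / 3 * pi * (20^3 - 15^3)
  expect_lt(abs(sum(shell) / analytic - 1), 0.1)
  # zero thickness -> empty mask
  expect_false(any(deposit_wall_ice(solid, 0, 1)))
  # thickness reaching the deepest pore radius warns about pore closure
  expect_warning(deposit_wall_ice(solid, 25, 1), "close")
})

test_that("internal crystals are cuboids clipped to the solid phase", {
  solid <- array(TRUE, c(60, 60, 60))
  centers <- as.matrix(expand.grid(c(12, 30, 48), c(15, 45), 30))[1:5, ]
  withr::local_seed(3)
  m <- seed_internal_crystals(solid, 5, c(8, 14), voxel_size = 1,
                              centers = centers)
  expect_equal(n_components(m), 5L)
  # clipping contract on a porous solid
  withr::local_seed(4)
  solid2 <- generate_pore_space(phantom_spec(shape = c(48, 48, 48),
                                             pore_scale = 30, seed = 4))
  m2 <- seed_internal_crystals(solid2, 20, c(8, 20), voxel_size = 2)
  expect_true(all(solid2[m2]))
  # n = 0 is valid and empty
  expect_false(any(seed_internal_crystals(solid, 0, c(8, 14), 1)))
})

test_that("rendering maps phases to grey means with detectable modes", {
  lab <- array(sample(0:3, 40^3, replace = TRUE), c(40, 40, 40))
  truth <- label_volume(lab, 1)
  clean <- render_greyscale(truth, c(50, 120, 200), 0, 0)
  expect_setequal(unique(as.vector(clean$data)), c(50, 120, 200))
  # both ice phases share the ice mean
  expect_true(all(clean$data[lab == 1L] == 120))
  expect_true(all(clean$data[lab == 2L] == 120))
  # with moderate noise the three modes remain separable
  withr::local_seed(9)
  noisy <- render_greyscale(truth, c(50, 120, 200), noise_sigma = 10)
  thr <- estimate_thresholds(noisy)
  expect_gt(thr[1], 50); expect_lt(thr[1], 120)
  expect_gt(thr[2], 120); expect_lt(thr[2], 200)
  # same RNG state -> identical rendering
  r1 <- withr::with_seed(5, render_greyscale(truth, c(50, 120, 200), 10, 2))
  r2 <- withr::with_seed(5, render_greyscale(truth, c(50, 120, 200), 10, 2))
  expect_identical(r1$data, r2$data)
})

test_that("phantom truth labels partition the volume and presets realize both regimes", {
  fast <- cached_phantom("fast", 1)
  slow <- cached_phantom("slow", 1)
  for (ph in list(fast, slow)) {
    cnt <- tabulate(as.vector(ph$truth$data) + 1L, nbins = 4L)
    expect_equal(sum(cnt), length(ph$truth$data))
    expect_identical(dim(ph$grey), dim(ph$truth))
  }
  ffr <- volume_fractions(fast$truth)
  sfr <- volume_fractions(slow$truth)
  # fast freezing: ice mostly inside the matrix; slow: mostly at pore walls
  expect_gt(ffr$V_ice_inside, ffr$V_ice_outside)
  expect_gt(sfr$V_ice_outside, sfr$V_ice_inside)
  # determinism of the full phantom
  sp <- phantom_preset("fast", shape = c(48, 48, 48), pore_scale = 30,
                       seed = 42)
  expect_identical(generate_phantom(sp)$grey$data,
                   generate_phantom(sp)$grey$data)
  # no ice requested -> only air and starch present
  ph0 <- generate_phantom(phantom_spec(shape = c(40, 40, 40),
                                       pore_scale = 24, seed = 2))
  expect_setequal(unique(as.vector(ph0$truth$data)), c(0L, 3L))
})
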