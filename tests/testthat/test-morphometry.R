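test_that("volume fractions satisfy the voxel-count identities exactly", {
  # constructed half air / quarter ice-inside / quarter starch volume
  lab <- array(c(rep(0L, 32), rep(2L, 16), rep(3L, 16)), c(4, 4, 4))
  fr <- volume_fractions(label_volume(lab, 1))
  expect_equal(fr$phi_air, 0.5)
  expect_equal(fr$phi_ice_in_solid, 0.5)
  expect_equal(fr$phi_ice_outside, 0)
  expect_equal(fr$V_air + fr$V_ice + fr$V_starch, fr$V_total)
  expect_equal(fr$V_ice_inside + fr$V_ice_outside, fr$V_ice)
  # all-air volume: porosity 1, ice-outside share undefined (never 0)
  fr0 <- volume_fractions(label_volume(array(0L, c(3, 3, 3)), 1))
  expect_equal(fr0$phi_air, 1)
  expect_true(is.na(fr0$phi_ice_outside))
  # random labels: identities hold on every run
  withr::local_seed(17)
  lab <- array(sample(0:3, 11^3, TRUE), c(11, 11, 11))
  fr <- volume_fractions(label_volume(lab, 1))
  expect_equal(fr$phi_air, fr$V_air / fr$V_total)
  expect_equal(fr$phi_ice_in_solid, fr$V_ice / (fr$V_ice + fr$V_starch))
  expect_equal(fr$phi_ice_outside, fr$V_ice_outside / fr$V_ice)
})

test_that("phantom truth fractions equal generator bookkeeping exactly", {
  ph <- cached_phantom("fast", 1)
  fr <- volume_fractions(ph$truth)
  cnt <- tabulate(as.vector(ph$truth$data) + 1L, nbins = 4L)
  expect_identical(c(fr$V_air, fr$V_ice_outside, fr$V_ice_inside, fr$V_starch),
                   cnt)
})

test_that("vertical profiles reduce to global fractions and flag empty denominators", {
  lab <- array(3L, c(8, 8, 16))
  lab[, , 9:16] <- 0L  # pure air top half
  lv <- label_volume(lab, 2)
  pr <- vertical_profile(lv, "porosity", slab_vx = 4)
  expect_equal(pr$value, c(0, 0, 1, 1))
  # full-height slab equals the global fraction
  pr1 <- vertical_profile(lv, "porosity", slab_vx = 16)
  expect_equal(pr1$value, volume_fractions(lv)$phi_air)
  # slabs of pure air have no solid: ice fraction undefined there
  pri <- vertical_profile(lv, "ice_in_solid", slab_vx = 4)
  expect_equal(is.na(pri$value), c(FALSE, FALSE, TRUE, TRUE))
  # homogeneous phantom: profile flat within sampling noise
  ph <- cached_phantom("fast", 1)
  prh <- vertical_profile(ph$truth, "porosity", slab_vx = 28)
  expect_lt(max(abs(prh$value - mean(prh$value))), 0.15)
})

test_that("Crofton SSA recovers analytic sphere area within 5%", {
  n <- 100
  lab <- array(0L, c(n, n, n))
  lab[ball_mask(n, c(50, 50, 50), 20)] <- 3L
  lv <- label_volume(lab, 1)
  ssa <- specific_surface_area(lv, "starch", "air")
  expect_lt(abs(ssa$area_um2 / (4 * pi * 20^2) - 1), 0.05)
  expect_equal(ssa$ssa_mm, ssa$area_um2 / ssa$volume_um3 * 1000)
  # no ice voxels: zero SSA, not an error
  expect_equal(specific_surface_area(lv, "ice", "air")$ssa_mm, 0)
})

test_that("gradient SSA is exact for an axis-aligned slab interface; Crofton shows its known plane bias", {
  n <- 64
  lab <- array(0L, c(n, n, n))
  lab[, , 1:32] <- 3L
  lv <- label_volume(lab, 0.65)
  true_ssa <- 1 / (n * 0.65) * 1000  # one interface plane per volume
  grad <- specific_surface_area(lv, "starch", "air", method = "gradient")
  expect_lt(abs(grad$ssa_mm / true_ssa - 1), 0.02)
  crof <- specific_surface_area(lv, "starch", "air")
  # 13-direction Crofton underestimates perfectly axis-aligned planes by ~7%
  expect_lt(crof$ssa_mm, true_ssa)
  expect_lt(abs(crof$ssa_mm / true_ssa - 1), 0.10)
})

test_that("SSA is scale-equivariant at fixed physical geometry", {
  s1 <- {
    lab <- array(0L, c(48, 48, 48))
    lab[ball_mask(48, c(24, 24, 24), 14)] <- 3L
    specific_surface_area(label_volume(lab, 2), "starch", "air")$ssa_mm
  }
  s2 <- {
    lab <- array(0L, c(96, 96, 96))
    lab[ball_mask(96, c(48, 48, 48), 28)] <- 3L
    specific_surface_area(label_volume(lab, 1), "starch", "air")$ssa_mm
  }
  expect_lt(abs(s1 / s2 - 1), 0.05)
})

test_that("thickness distributions step, plateau and end at 100%", {
  # uniform-thickness slab: a step at its thickness
  slab <- array(FALSE, c(16, 16, 12)); slab[, , 4:8] <- TRUE
  d <- thickness_distribution(local_thickness(slab, 1))
  expect_equal(max(d$cum_pct), 100)
  expect_equal(sum(d$pct > 0), 1L)
  # two balls: plateau at v1 / (v1 + v2) between the two diameters
  two <- ball_mask(40, c(12, 12, 12), 5) | ball_mask(40, c(28, 28, 28), 9)
  v1 <- sum(ball_mask(40, c(12, 12, 12), 5))
  v2 <- sum(ball_mask(40, c(28, 28, 28), 9))
  d2 <- thickness_distribution(local_thickness(two, 1), bin_width = 1)
  plateau <- d2$cum_pct[d2$thickness_um >= 12 & d2$thickness_um <= 17]
  expect_true(all(abs(plateau - 100 * v1 / (v1 + v2)) < 1))
  expect_equal(max(d2$cum_pct), 100)
  expect_true(all(diff(d2$cum_pct) >= 0))
})

test_that("mean curvature matches analytic sphere, cylinder and slab values", {
  # air pore of diameter 1 mm in solid: concave, C = -2 mm^-1
  n <- 70
  solid <- !ball_mask(n, c(35, 35, 35), 25)
  cf <- mean_curvature_field(solid, voxel_size = 20, sigma_vx = 2)
  expect_lt(abs(weighted_mean_curvature(cf) - (-2)) / 2, 0.10)
  # flat slab: zero within discretization tolerance
  slab <- array(FALSE, c(40, 40, 40)); slab[, , 1:20] <- TRUE
  cfs <- mean_curvature_field(slab, voxel_size = 20, sigma_vx = 2)
  expect_lt(abs(weighted_mean_curvature(cfs)), 0.05)
  # solid cylinder radius r: principal curvatures 1/r and 0, C = +1/(2r)
  co <- as.matrix(expand.grid(y = 1:48, x = 1:48, z = 1:48))
  cyl <- array((co[, 1] - 24)^2 + (co[, 2] - 24)^2 <= 12^2, c(48, 48, 48))
  cfc <- mean_curvature_field(cyl, voxel_size = 10, sigma_vx = 2)
  r_mm <- 12 * 10 / 1000
  expect_lt(abs(weighted_mean_curvature(cfc) - 1 / (2 * r_mm)) / (1 / (2 * r_mm)),
            0.10)
  # principal curvature ordering and the mean-curvature identity
  expect_true(all(cf$f_min_mm <= cf$f_max_mm + 1e-9))
  expect_equal(cf$curvature_mm, (cf$f_min_mm + cf$f_max_mm) / 2)
})

test_that("curvature flips sign under mask complement", {
  n <- 54
  ball <- ball_mask(n, c(27, 27, 27), 16)
  cf1 <- mean_curvature_field(ball, voxel_size = 10, sigma_vx = 2)
  cf2 <- mean_curvature_field(!ball, voxel_size = 10, sigma_vx = 2)
  expect_equal(nrow(cf1), nrow(cf2))
  expect_equal(cf1$curvature_mm, -cf2$curvature_mm, tolerance = 1e-8)
  expect_equal(weighted_mean_curvature(cf1), -weighted_mean_curvature(cf2),
               tolerance = 1e-8)
})

test_that("curvature occurrence distributions are area-normalized and resolve mixtures", {
  n <- 60
  ball <- ball_mask(n, c(30, 30, 42), 10)
  cfb <- mean_curvature_field(ball, voxel_size = 50, sigma_vx = 2)
  db <- curvature_distribution(cfb, bin_width = 0.5)
  expect_equal(sum(db$occurrence_pct), 100)
  # unimodal near +1/r = +2 mm^-1 (r = 10 vx * 50 um)
  expect_lt(abs(db$curvature_mm[which.max(db$occurrence_pct)] - 2), 0.5)
  # slab + ball mixture: masses proportional to surface areas
  mix <- ball | outer(array(TRUE, c(n, n)), c(rep(TRUE, 14), rep(FALSE, n - 14)))
  dim(mix) <- c(n, n, n)
  cfm <- mean_curvature_field(mix, voxel_size = 50, sigma_vx = 2)
  dm <- curvature_distribution(cfm, bin_width = 0.5)
  expect_equal(sum(dm$occurrence_pct), 100)
  flat_mass <- sum(dm$occurrence_pct[abs(dm$curvature_mm) < 1])
  curved_mass <- sum(dm$occurrence_pct[dm$curvature_mm >= 1])
  a_slab <- n^2 * 50^2                 # one free face inside the volume
  a_ball <- 4 * pi * (10 * 50)^2
  expect_lt(abs(flat_mass / curved_mass - a_slab / a_ball) /
              (a_slab / a_ball), 0.35)
})

test_that("degenerate curvature inputs error and small sigma warns", {
  expect_error(mean_curvature_field(array(TRUE, c(8, 8, 8)), 1),
               class = "icemorph_error")
  ball <- ball_mask(30, c(15, 15, 15), 8)
  expect_warning(mean_curvature_field(ball, 1, sigma_vx = 0.5), "sigma")
})
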