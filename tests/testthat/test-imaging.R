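test_that("rendering is deterministic given a seed", {
  cc <- cell_model(center = c(40, 40), radius = 16)
  f1 <- render_frame(cc, dim = c(80, 80), seed = 5)
  f2 <- render_frame(cc, dim = c(80, 80), seed = 5)
  f3 <- render_frame(cc, dim = c(80, 80), seed = 6)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_true(all(f1 == round(f1)))  # integer counts with noise on
})

test_that("a zero potential field reproduces the resting frame", {
  cc <- cell_model(center = c(40, 40), radius = 16)
  resting <- render_frame(cc, dim = c(80, 80), noise = FALSE)
  stim <- render_frame(cc, dim = c(80, 80), noise = FALSE,
                       dv_fun = function(cell, costh) rep(0, length(costh)))
  expect_identical(resting, stim)
})

test_that("membrane pixels scale linearly with the dye response", {
  cc <- cell_model(center = c(40, 40), radius = 16, dye_sens = -0.001)
  resting <- render_frame(cc, dim = c(80, 80), background = 0, noise = FALSE)
  depol10 <- render_frame(cc, dim = c(80, 80), background = 0, noise = FALSE,
                          dv_fun = function(cell, costh)
                            rep(10, length(costh)))
  ring <- resting == max(resting)  # pure membrane pixels
  expect_true(any(ring))
  expect_equal(depol10[ring] / resting[ring],
               rep(0.99, sum(ring)), tolerance = 1e-12)
})

test_that("cells must fit inside the frame and overlaps warn", {
  expect_error(render_frame(cell_model(center = c(5, 40), radius = 16),
                            dim = c(80, 80), noise = FALSE), "fit inside")
  expect_warning(
    render_frame(list(cell_model(center = c(40, 38), radius = 16),
                      cell_model(center = c(40, 52), radius = 16)),
                 dim = c(80, 80), noise = FALSE),
    "overlapping")
})

test_that("a mock experiment with noise off reproduces identical passages", {
  sim <- noiseless_params()
  cells <- withr::with_seed(3, place_cells(sim))
  rec <- simulate_passage_pair(cells, drug = NULL, conc = 0, sim = sim)
  expect_identical(rec$f_pre_ref, rec$f_pre_test)
  expect_identical(rec$f_plateau_ref, rec$f_plateau_test)
})

test_that("dF/F normalization cancels bleaching between passages", {
  sim_b <- noiseless_params(bleach_fraction = 0.1)
  cells <- withr::with_seed(3, place_cells(sim_b))
  rec <- simulate_passage_pair(cells, drug = NULL, conc = 0, sim = sim_b)
  # absolute counts drop by 10%...
  expect_equal(rec$f_pre_test / rec$f_pre_ref,
               matrix(0.9, nrow(rec$f_pre_ref), ncol(rec$f_pre_ref)),
               tolerance = 1e-12)
  # ...but each passage's dF/F is unchanged
  dff_ref <- (rec$f_plateau_ref - rec$f_pre_ref) / rec$f_pre_ref
  dff_test <- (rec$f_plateau_test - rec$f_pre_test) / rec$f_pre_test
  expect_lt(max(abs(dff_test - dff_ref)), 1e-9)
})

test_that("saturating drug scales every membrane response by 1/g_fold", {
  rec <- simulate_area_fold(5)
  d_ref <- rec$f_plateau_ref - rec$f_pre_ref
  d_test <- rec$f_plateau_test - rec$f_pre_test
  idx <- which(abs(d_ref) > 1e-6)
  expect_true(length(idx) > 100)
  expect_lt(max(abs(d_test[idx] / d_ref[idx] - 0.2)), 1e-8)
})

test_that("global illumination gain leaves dF/F unchanged", {
  sim <- noiseless_params()
  cells <- withr::with_seed(9, place_cells(sim))
  pre <- render_frame(cells, dim = sim$frame_dim, noise = FALSE)
  plat <- render_frame(cells, dim = sim$frame_dim, noise = FALSE,
                       dv_fun = function(cell, costh) 20 * costh)
  dff1 <- (plat - pre) / pre
  dff2 <- (plat * 1.7 - pre * 1.7) / (pre * 1.7)
  expect_equal(dff1, dff2, tolerance = 1e-12)
})

test_that("plate simulation is reproducible and order-independent", {
  plate <- plate_map(c(1e-7, 1e-6), areas_per_well = 2, seed = 21)
  drug <- drug_model(ec50 = 1e-6, g_max_fold = 5)
  sim <- sim_params(frame_dim = c(96, 96), n_cells = 2,
                    radius_range = c(16, 20))
  s1 <- simulate_plate(plate, drug, sim = sim)
  s2 <- simulate_plate(plate, drug, sim = sim)
  expect_identical(s1$record, s2$record)
  expect_identical(attr(s1, "config_hash"), attr(s2, "config_hash"))
  # per-(well, area) streams: same area identical under a reordered map
  plate_rev <- plate_map(c(1e-6, 1e-7), areas_per_well = 2, seed = 21)
  s3 <- simulate_plate(plate_rev, drug, sim = sim)
  i1 <- which(s1$concentration == 1e-6 & s1$area == 1)
  i3 <- which(s3$concentration == 1e-6 & s3$area == 1)
  expect_equal(s1$record[[i1]]$truth$g_fold, s3$record[[i3]]$truth$g_fold)
  expect_error(simulate_plate(plate_map(numeric(0)), drug), "empty")
})

test_that("plate map validates the screening layout limits", {
  expect_error(plate_map(c(1e-6), areas_per_well = 10), "between 1 and 9")
  expect_error(plate_map(c(-1e-6)), "nonnegative")
  pm <- plate_map(default_series(), areas_per_well = 5, seed = 3)
  expect_equal(nrow(pm), 8)
  expect_equal(pm$well[1], "A01")
})
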