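stone <- scenario_preset("kidney_stone")
lung <- scenario_preset("lung_nodule")

test_that("run_once reproduces the centered single-position stone count", {
  # brute-force derivation for r/k = 1, center at the voxel center:
  # 1 inside voxel; of the 26 cut voxels only the 6 face voxels (p ~ 0.4)
  # clear the 100/970 stone cutoff; edge (p ~ 0.04) and corner (p ~ 0) do not
  rec <- run_once(sphere(1), stone)
  expect_identical(rec$n_I, 1L)
  expect_identical(rec$n_T, 26L)
  expect_equal(rec$n_sphere, 7)
  expect_equal(rec$P_sim, 7 / (4 / 3 * pi), tolerance = 1e-12)
})

test_that("run_once volume metrics are internally consistent", {
  set.seed(42)
  rec <- run_once(sphere(4, runif(3, -0.5, 0.5)), lung)
  expect_equal(rec$V_r_sphere_norm, 4 / 3 * pi * 64)
  expect_gte(rec$V_m_sphere, rec$n_I)
  expect_lte(rec$V_m_sphere, rec$n_I + rec$n_T)
  expect_equal(rec$P_approx, rec$V_m_sphere / rec$V_r_sphere_norm)
  expect_equal(rec$V_m_CT, rec$n_sphere)
  # geometry-only run carries NA threshold metrics
  g <- run_once(sphere(2))
  expect_true(is.na(g$P_sim) && is.na(g$n_sphere))
})

test_that("single centered run at r/k = 4 approximates the true volume", {
  rec <- run_once(sphere(4))
  expect_lt(abs(rec$P_approx - 1), 0.03)
})

test_that("symmetric cutoff makes threshold volumetry exact by r/k = 17", {
  set.seed(42)
  rec <- run_once(sphere(17, runif(3, -0.5, 0.5)), lung)
  expect_lt(abs(rec$P_sim - 1), 0.001)
})

test_that("threshold counting matches the explicit cutoff-fraction rule", {
  set.seed(42)
  sp <- sphere(3, runif(3, -0.5, 0.5))
  cl <- classify_grid(sp)
  rec <- run_once(sp, lung)
  expect_equal(rec$n_sphere, cl$n_I + sum(cl$cut_fraction >= 0.5))
  rec2 <- run_once(sp, stone)
  expect_equal(rec2$n_sphere, cl$n_I + sum(cl$cut_fraction >= 100 / 970))
})

test_that("identical seeds give bit-identical simulations", {
  cfg <- simulation_config(2, stone, repetitions = 5, seed = 42)
  a <- run_simulation(cfg)
  b <- run_simulation(cfg)
  expect_identical(a$runs, b$runs)
  expect_identical(a$summary, b$summary)
  # and the caller's RNG stream is untouched
  set.seed(7); before <- runif(1)
  set.seed(7); invisible(run_simulation(cfg)); after <- runif(1)
  expect_identical(before, after)
})

test_that("offset modes drive the engine as documented", {
  fixed <- run_simulation(simulation_config(
    1, stone, offset_mode = offset_fixed(c(0, 0, 0))))
  expect_equal(nrow(fixed$runs), 1)
  expect_equal(fixed$summary$n_sphere, 7)
  sweep <- run_simulation(simulation_config(
    1, offset_mode = offset_sweep(step = 0.5)))
  expect_equal(nrow(sweep$runs), 8)  # offsets {-0.5, 0}^3
  expect_error(offset_sweep(0.7), "step")
  expect_error(offset_fixed(c(0.6, 0, 0)), "center_offset")
})

test_that("off-center sweep shows the small-sphere position effect", {
  sw <- offcenter_sweep(1, step = 0.25)
  center <- sw[sw$off_x == 0 & sw$off_y == 0 & sw$off_z == 0, ]
  expect_equal(center$n_crossed, 27)
  # center near (but not on) a lattice corner: 16-20 voxels crossed
  near <- classify_grid(sphere(1, c(0.49, 0.49, 0.49)))
  expect_true(near$n_I + near$n_T >= 16 && near$n_I + near$n_T <= 20)
  # degenerate limit: center exactly on a lattice corner touches neighbors
  # only tangentially, leaving the 8 octant voxels (~1/8 sphere each)
  corner <- sw[sw$off_x == -0.5 & sw$off_y == -0.5 & sw$off_z == -0.5, ]
  expect_equal(corner$n_crossed, 8)
  expect_true(all(sw$n_crossed >= 8 & sw$n_crossed <= 27))
})

test_that("sampling error study validates inputs and reports all schemes", {
  tab <- sampling_error_study(c(5, 10), n_trials = 50, seed = 42)
  expect_equal(names(tab),
               c("points_per_axis", "sampling_points", "mean_abs_error_pct"))
  expect_equal(tab$sampling_points, c(125, 1000))
  expect_true(all(tab$mean_abs_error_pct >= 0))
  expect_error(sampling_error_study(5, n_trials = 10, r_range = c(2, 1)))
  expect_error(sampling_error_study(5, oracle_points_per_axis = 60), "odd")
})
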