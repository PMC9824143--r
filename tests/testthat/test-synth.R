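test_that("zero-noise scattering curve equals the model exactly", {
  truth <- saxd_truth(noise_fraction = 0)
  cv <- generate_saxd_curve(truth, seed = 4)
  expect_equal(cv$y, model_intensity(cv$x, truth$edp, truth$scale,
                                     truth$background))
  expect_null(cv$y_err)
  # scale 0 leaves only the background
  flat <- generate_saxd_curve(saxd_truth(scale = 0, background = 5,
                                         noise_fraction = 0), 1)
  expect_equal(flat$y, rep(5, length(flat$x)))
  expect_error(saxd_truth(q_grid = c(0, 0.1)), "singular")
})

test_that("relative noise level matches its sample moment", {
  truth <- saxd_truth(q_grid = seq(0.05, 0.6, length.out = 500),
                      noise_fraction = 0.02)
  cv <- generate_saxd_curve(truth, seed = 123)
  clean <- model_intensity(cv$x, truth$edp, truth$scale, truth$background)
  rel <- (cv$y - clean) / clean
  expect_lt(abs(sd(rel) - 0.02), 0.005)
  expect_equal(cv$y_err, 0.02 * clean)
  # bit-reproducible under the same seed
  expect_identical(cv$y, generate_saxd_curve(truth, seed = 123)$y)
  expect_false(identical(cv$y, generate_saxd_curve(truth, seed = 124)$y))
})

test_that("thermogram peaks are unit-area normalized and additive", {
  tg <- seq(10, 35, by = 0.01)
  one <- generate_thermogram(thermogram_truth(
    peaks = data.frame(center = 23, width = 0.5, area = 10), T_grid = tg))
  expect_equal(pracma::trapz(one$curve$x, one$curve$y), 10, tolerance = 0.01)
  two <- generate_thermogram(thermogram_truth(
    peaks = data.frame(center = c(18, 25), width = c(0.5, 0.6),
                       area = c(5, 10)), T_grid = tg))
  expect_equal(pracma::trapz(two$curve$x, two$curve$y), 15, tolerance = 0.02)
  expect_error(thermogram_truth(peaks = data.frame(center = 2, width = 1,
                                                   area = 1),
                                T_grid = seq(0, 35, 0.01)),
               "truncated")
})

test_that("infrared band weights hit their single-band limits and shift monotonically", {
  lo <- generate_ftir_series(T_m = 23, temps = 40, weight_range = c(1, 1))
  expect_equal(band_maximum(lo[[1]]), 1728, tolerance = 0.1)
  hi <- generate_ftir_series(T_m = 23, temps = 5, weight_range = c(0, 0))
  expect_equal(band_maximum(hi[[1]]), 1742, tolerance = 0.1)
  # the maximum moves down as temperature rises through the transition
  ser <- generate_ftir_series(T_m = 23, temps = seq(15, 31, by = 2))
  mx <- vapply(ser, band_maximum, numeric(1))
  expect_true(all(diff(mx) <= 1e-9))
  expect_error(generate_ftir_series(temps = numeric(0)), "non-empty")
  expect_error(generate_ftir_series(centers = c(1600, 1728)), "1670")
})

test_that("planted bilayer geometry is exactly recoverable", {
  spec <- bilayer_spec(jitter_sd = 0)
  traj <- generate_bilayer(spec, n_frames = 3, seed = 2)
  expect_equal(pp_thickness(traj)$mean, 3.370, tolerance = 1e-9)
  expect_equal(area_per_lipid(traj)$mean, 6.3499^2 / 64, tolerance = 1e-12)
  lf <- assign_leaflets(traj$frames[[1]])
  expect_equal(sum(lf$leaflet == "upper"), 64)
  expect_equal(sum(lf$leaflet == "lower"), 64)
  # planted hydrogen bonds and clusters recovered exactly
  expect_equal(hydrogen_bonds(traj$frames[[1]])$count, spec$planted_hbonds)
  cl <- cluster_size_distribution(traj)
  expect_equal(cl$monomer_fraction, 4 / 14)
  expect_equal(as.numeric(cl$histogram), c(4, 6, 4))  # sizes 1, 3, 4
})

test_that("all-monomer and zero-bond plants are honored", {
  spec <- bilayer_spec(planted_clusters = as.list(1:14), planted_hbonds = 0,
                       n_hbond_decoys = 3, jitter_sd = 0)
  traj <- generate_bilayer(spec, n_frames = 1, seed = 8)
  cl <- cluster_size_distribution(traj)
  expect_equal(cl$monomer_fraction, 1.0)
  expect_equal(as.numeric(cl$histogram), 14)
  expect_equal(hydrogen_bonds(traj$frames[[1]])$count, 0L)
})

test_that("generators are deterministic under a fixed seed", {
  t1 <- generate_bilayer(bilayer_spec(), n_frames = 2, seed = 77)
  t2 <- generate_bilayer(bilayer_spec(), n_frames = 2, seed = 77)
  expect_identical(t1$frames[[2]]$positions, t2$frames[[2]]$positions)
  s1 <- generate_ftir_series(T_m = 21, temps = c(10, 30), noise_sd = 0.001,
                             seed = 5)
  s2 <- generate_ftir_series(T_m = 21, temps = c(10, 30), noise_sd = 0.001,
                             seed = 5)
  expect_identical(s1[[1]]$y, s2[[1]]$y)
})

test_that("impossible packing demands are refused", {
  expect_error(generate_bilayer(bilayer_spec(box = c(1.5, 1.5, 7),
                                             n_lipids = 4),
                                n_frames = 1, seed = 1),
               "too small")
  expect_error(bilayer_spec(planted_clusters = list(1:3)), "partition")
  expect_error(bilayer_spec(leaflet_z = 4, box = c(6, 6, 7)), "inside the box")
})
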