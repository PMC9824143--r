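gauss_thermo <- function(center = 23.1, width = 0.4, area = 27.2,
                         baseline = c(0, 0), T_grid = seq(15, 30, by = 0.01),
                         noise_sd = 0) {
  generate_thermogram(thermogram_truth(
    peaks = data.frame(center = center, width = width, area = area),
    baseline = baseline, T_grid = T_grid, noise_sd = noise_sd))
}

test_that("linear baseline subtraction flattens the windows and is idempotent", {
  th <- gauss_thermo(baseline = c(2, 0.1))
  cor1 <- subtract_baseline(th, c(15, 18), c(28, 30))
  i_win <- th$curve$x <= 18 | th$curve$x >= 28
  expect_lt(max(abs(cor1$curve$y[i_win])), 1e-6)
  # integral above baseline is restored
  expect_equal(pracma::trapz(cor1$curve$x, cor1$curve$y), 27.2,
               tolerance = 0.05)
  cor2 <- subtract_baseline(cor1, c(15, 18), c(28, 30))
  expect_lt(max(abs(cor2$curve$y - cor1$curve$y)), 1e-9)
  # a flat thermogram just loses its offset
  flat <- thermogram(xy_curve(seq(0, 10, 0.1), rep(3, 101)))
  expect_lt(max(abs(subtract_baseline(flat, c(0, 2), c(8, 10))$curve$y)), 1e-12)
})

test_that("baseline windows must avoid peaks and stay inside the data", {
  th <- gauss_thermo()
  expect_error(subtract_baseline(th, c(15, 17), c(29, 32)), "beyond")
  expect_error(subtract_baseline(th, c(15, 17), c(22, 24)), "peak")
})

test_that("transition detection finds planted peaks and merges overlaps", {
  two <- generate_thermogram(thermogram_truth(
    peaks = data.frame(center = c(10, 23.1), width = c(0.5, 0.4),
                       area = c(3, 27.2)), T_grid = seq(0, 35, 0.01)))
  regs <- detect_transitions(two, min_prominence = 0.5)
  expect_length(regs, 2L)
  expect_equal(vapply(regs, `[[`, numeric(1), "T_peak"), c(10, 23.1),
               tolerance = 0.02)
  expect_false(any(vapply(regs, `[[`, logical(1), "overlapping")))

  flat <- thermogram(xy_curve(seq(0, 10, 0.1), rep(0, 101)))
  expect_length(detect_transitions(flat, 0.5), 0L)

  # two resolvable maxima whose 1%-height regions overlap get merged
  close_pair <- generate_thermogram(thermogram_truth(
    peaks = data.frame(center = c(22.0, 23.5), width = c(0.4, 0.4),
                       area = c(10, 10)), T_grid = seq(15, 30, 0.01)))
  regs <- detect_transitions(close_pair, min_prominence = 0.5)
  expect_length(regs, 1L)
  expect_true(regs[[1]]$overlapping)
})

test_that("tangent construction equals the closed form center -/+ 2 sd", {
  th <- gauss_thermo(center = 23.1, width = 0.4)
  reg <- detect_transitions(th, 0.5)[[1]]
  oc <- onset_completion(th, reg)
  expect_equal(oc[["T_onset"]], 22.3, tolerance = 0.05)
  expect_equal(oc[["T_completion"]], 23.9, tolerance = 0.05)
  # symmetric peak: onset and completion equidistant from the maximum
  expect_lt(abs((reg$T_peak - oc[["T_onset"]]) -
                  (oc[["T_completion"]] - reg$T_peak)), 0.02)
})

test_that("tangent closed form holds across peak widths", {
  for (sd_peak in c(0.2, 0.5, 1.0, 2.0)) {
    th <- gauss_thermo(center = 20, width = sd_peak, area = 15,
                       T_grid = seq(5, 35, by = 0.01))
    reg <- detect_transitions(th, 0.1)[[1]]
    oc <- onset_completion(th, reg)
    expect_equal(oc[["T_onset"]], 20 - 2 * sd_peak, tolerance = 0.05)
    expect_equal(oc[["T_completion"]], 20 + 2 * sd_peak, tolerance = 0.05)
  }
})

test_that("enthalpy integration recovers planted areas", {
  th <- gauss_thermo(area = 27.2)
  reg <- detect_transitions(th, 0.5)[[1]]
  expect_equal(enthalpy(th, reg), 27.2, tolerance = 0.05)
  expect_equal(enthalpy(th, reg) / 27.2, 1, tolerance = 0.002)
  # zero signal integrates to zero; adjacent intervals are additive
  flat <- thermogram(xy_curve(seq(0, 10, 0.1), rep(0, 101)))
  expect_equal(enthalpy(flat, c(2, 8)), 0)
  whole <- enthalpy(th, c(15, 30))
  expect_equal(enthalpy(th, c(15, 23.1)) + enthalpy(th, c(23.1, 30)), whole,
               tolerance = 1e-9)
  expect_error(enthalpy(th, c(10, 20)), "beyond")
})

test_that("thermogram characterization labels pretransition and main events", {
  two <- generate_thermogram(thermogram_truth(), scan_rate = 60)
  res <- analyze_thermogram(two, min_prominence = 0.3)
  expect_equal(nrow(res), 2L)
  expect_identical(res$label, c("pretransition", "main"))
  expect_equal(res$T_onset[res$label == "main"], 22.3, tolerance = 0.05)
  expect_equal(res$delta_H[res$label == "main"], 27.2, tolerance = 0.05)
  expect_equal(res$delta_H[res$label == "pretransition"], 3, tolerance = 0.05)
})

test_that("phase diagram assembly validates, sorts and reports the gap", {
  pd <- build_phase_diagram(data.frame(mole_fraction = 0, onset = 22.3,
                                       completion = 23.9))
  expect_equal(pd$points$solidus, 22.3)
  expect_equal(pd$points$fluidus, 23.9)
  shuffled <- data.frame(mole_fraction = c(0.2, 0, 0.1),
                         onset = c(20, 22.3, 21),
                         completion = c(23.9, 23.9, 23.9))
  pd <- build_phase_diagram(shuffled)
  expect_equal(pd$points$mole_fraction, c(0, 0.1, 0.2))
  expect_true(all(pd$points$fluidus >= pd$points$solidus))
  expect_true(all(diff(pd$points$coexistence_width) > 0))
  expect_error(build_phase_diagram(data.frame(mole_fraction = 0, onset = 24,
                                              completion = 23)),
               "exceeds completion")
  expect_error(build_phase_diagram(shuffled[c(1, 1, 2), ]), "distinct")
})

test_that("immiscibility plateaus are flagged with the expected topology", {
  x <- seq(0, 0.3, by = 0.05)
  # constant fluidus across the whole range: one immiscible segment
  fl <- detect_immiscibility(data.frame(x = x, T = rep(23.9, length(x))))
  expect_equal(nrow(fl), 1L)
  expect_identical(fl$flag, "immiscible")
  expect_equal(c(fl$i_start, fl$i_end), c(1L, length(x)))
  # strictly decreasing solidus: nothing flagged
  dec <- detect_immiscibility(data.frame(x = x, T = 22.3 - 8 * x))
  expect_false(any(dec$flag == "immiscible"))
  # decreasing then constant above x = 0.2: flagged segment starts there
  x2 <- seq(0, 0.4, by = 0.05)
  T2 <- ifelse(x2 < 0.2, 22.3 - 10 * (0.2 - x2), 22.3)
  sol <- detect_immiscibility(data.frame(x = x2, T = T2))
  im <- sol[sol$flag == "immiscible", ]
  expect_equal(nrow(im), 1L)
  expect_equal(im$x_start, 0.2)
  expect_equal(im$x_end, 0.4)
  expect_error(detect_immiscibility(data.frame(x = c(0, 1), T = c(1, 2))),
               "at least 3")
})
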