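test_that("area per lipid is box arithmetic with zero spread for a fixed box", {
  traj <- generate_bilayer(bilayer_spec(jitter_sd = 0.02), n_frames = 4,
                           seed = 1)
  res <- area_per_lipid(traj, 128)
  expect_equal(res$mean, 6.3499^2 / 64, tolerance = 1e-12)
  expect_equal(res$sd, 0)
  big <- generate_bilayer(bilayer_spec(box = c(8, 8, 7), jitter_sd = 0),
                          n_frames = 1, seed = 1)
  expect_equal(area_per_lipid(big, 128)$mean, 1.0)
  expect_error(area_per_lipid(traj, 0), "even|no lipids")
  expect_error(area_per_lipid(traj, 127), "even")
})

test_that("leaflet assignment splits planted leaflets and flags edge cases", {
  conf <- generate_bilayer(bilayer_spec(jitter_sd = 0), 1, 1)$frames[[1]]
  lf <- assign_leaflets(conf)
  expect_equal(sort(as.integer(table(lf$leaflet))), c(64L, 64L))
  expect_false(any(lf$ambiguous))

  # all phosphorus on one side: degenerate split warns
  up <- conf
  sel <- up$role == "phosphorus"
  up$positions[sel, 3] <- abs(up$positions[sel, 3] - up$box[3] / 2) +
    up$box[3] / 2
  expect_warning(lf_up <- assign_leaflets(up), "one side")

  # a phosphorus near the midplane is flagged ambiguous
  amb <- conf
  i_p <- which(amb$role == "phosphorus")[1]
  center <- weighted.mean(amb$positions[amb$mol_kind == "lipid", 3],
                          amb$mass[amb$mol_kind == "lipid"])
  amb$positions[i_p, 3] <- center + 0.05
  expect_true(any(assign_leaflets(amb)$ambiguous))
})

test_that("phosphorus thickness hits planted planes and obeys jitter statistics", {
  t0 <- generate_bilayer(bilayer_spec(jitter_sd = 0), 2, 1)
  expect_equal(pp_thickness(t0)$mean, 3.370, tolerance = 1e-12)
  t1 <- generate_bilayer(bilayer_spec(leaflet_z = 1.645, jitter_sd = 0), 1, 1)
  expect_equal(pp_thickness(t1)$mean, 3.290, tolerance = 1e-12)
  # jittered: mean within 3 standard errors of the planted thickness
  tj <- generate_bilayer(bilayer_spec(jitter_sd = 0.05), n_frames = 25,
                         seed = 42)
  se <- sqrt(2) * 0.05 / sqrt(64)
  expect_lt(abs(pp_thickness(tj)$mean - 3.370), 3 * se)
})

test_that("hydrogen-bond criterion applies inclusive distance and angle cutoffs", {
  mk <- function(dDA, angle_deg) {
    # donor at origin, hydrogen along x, acceptor rotated by angle in xy
    a <- angle_deg * pi / 180
    md_config(positions = rbind(c(1, 1, 1), c(1.1, 1, 1),
                                c(1 + dDA * cos(a), 1 + dDA * sin(a), 1)),
              box = c(3, 3, 3), mol_id = c(1, 1, 2),
              mol_kind = rep("water", 3),
              role = c("donor", "hydrogen", "acceptor"),
              mass = rep(10, 3))
  }
  expect_equal(hydrogen_bonds(mk(0.30, 0))$count, 1L)
  expect_equal(hydrogen_bonds(mk(0.36, 0))$count, 0L)
  expect_equal(hydrogen_bonds(mk(0.30, 29.9))$count, 1L)
  expect_equal(hydrogen_bonds(mk(0.30, 31))$count, 0L)
  # bonded across the periodic boundary (hydrogen wrapped to the far side)
  per <- md_config(positions = rbind(c(0.05, 1, 1), c(2.95, 1, 1),
                                     c(2.80, 1, 1)),
                   box = c(3, 3, 3), mol_id = c(1, 1, 2),
                   mol_kind = rep("water", 3),
                   role = c("donor", "hydrogen", "acceptor"),
                   mass = rep(10, 3))
  expect_equal(hydrogen_bonds(per)$count, 1L)
  # donor with no hydrogen in its molecule errors
  orphan <- md_config(positions = rbind(c(1, 1, 1), c(1.3, 1, 1)),
                      box = c(3, 3, 3), mol_id = c(1, 2),
                      mol_kind = rep("water", 2),
                      role = c("donor", "acceptor"), mass = c(10, 10))
  expect_error(hydrogen_bonds(orphan), "without attached hydrogen")
})

test_that("cell-list hydrogen bonds match the brute-force oracle exactly", {
  for (s in 1:50) {
    conf <- random_hbond_config(seed = s)
    grid <- hydrogen_bonds(conf, method = "grid")$count
    brute <- hydrogen_bonds(conf, method = "brute")$count
    expect_identical(grid, brute)
    expect_identical(grid, oracle_hbond_count(conf))
  }
})

test_that("statistics are invariant under lattice translations", {
  conf <- random_hbond_config(seed = 7)
  shifted <- conf
  shifted$positions <- sweep(conf$positions, 2, conf$box * c(2, -1, 3), `+`)
  expect_identical(hydrogen_bonds(conf)$count, hydrogen_bonds(shifted)$count)

  sol <- random_solute_config(seed = 7)
  sol_sh <- sol
  sol_sh$positions <- sweep(sol$positions, 2, sol$box * c(-1, 2, 1), `+`)
  expect_identical(cluster_size_distribution(sol, cutoff = 0.4)$histogram,
                   cluster_size_distribution(sol_sh, cutoff = 0.4)$histogram)
})

test_that("mass density profile is uniform for uniform particles and conserves mass", {
  set.seed(9)
  n <- 4000
  box <- c(4, 4, 5)
  conf <- md_config(positions = cbind(runif(n, 0, 4), runif(n, 0, 4),
                                      runif(n, 0, 5)),
                    box = box, mol_id = seq_len(n),
                    mol_kind = rep("water", n), role = rep("other", n),
                    mass = rep(18, n))
  prof <- mass_density_profile(conf, bin_width = 0.5)
  mean_density <- 18 * n / prod(box)
  # every bin within 3 Poisson standard deviations of the uniform value
  sd_bin <- 18 * sqrt(n * 0.5 / 5) / (4 * 4 * 0.5)
  expect_true(all(abs(prof$density - mean_density) < 3.5 * sd_bin))
  expect_equal(sum(prof$density) * 4 * 4 * prof$bin_width, 18 * n,
               tolerance = 1e-3)
})

test_that("density profile preserves leaflet asymmetry and total mass", {
  traj <- generate_bilayer(bilayer_spec(jitter_sd = 0.02), n_frames = 3,
                           seed = 6)
  sol <- mass_density_profile(traj, kind = "solute", bin_width = 0.1)
  # solutes were planted in one leaflet only: mirrored band nearly empty
  band <- sol$z > 0.2 & sol$z < 1.0
  mirror <- sol$z < -0.2 & sol$z > -1.0
  m_band <- sum(sol$density[band])
  m_mirror <- sum(sol$density[mirror])
  expect_lt(m_mirror, 0.05 * m_band)
  expect_equal(sum(sol$density) * sol$box[1] * sol$box[2] * sol$bin_width,
               sol$total_mass, tolerance = 1e-3)
  all_prof <- mass_density_profile(traj, bin_width = 0.1)
  expect_equal(sum(all_prof$density) * prod(all_prof$box[1:2]) *
                 all_prof$bin_width, all_prof$total_mass, tolerance = 1e-3)
  expect_error(mass_density_profile(traj, bin_width = 0), "bin_width")
})

test_that("single-linkage clustering matches plants, chains and the oracle", {
  # transitivity: A-B-C chain is one cluster of 3
  chain <- md_config(positions = rbind(c(1, 1, 1), c(1.2, 1, 1), c(1.4, 1, 1)),
                     box = c(3, 3, 3), mol_id = 1:3,
                     mol_kind = rep("solute", 3), role = rep("other", 3),
                     mass = rep(100, 3))
  cl <- cluster_size_distribution(chain, cutoff = 0.25)
  expect_equal(as.numeric(cl$histogram), 3)
  expect_identical(names(cl$histogram), "3")
  expect_equal(cl$monomer_fraction, 0)

  # planted partition {3,3,4,1,1,1,1} recovered exactly
  traj <- generate_bilayer(bilayer_spec(jitter_sd = 0), 1, 1)
  cl <- cluster_size_distribution(traj)
  expect_equal(cl$histogram, c(`1` = 4, `3` = 6, `4` = 4))
  expect_equal(cl$monomer_fraction, 4 / 14)
  sizes <- oracle_cluster_sizes(traj$frames[[1]])
  expect_equal(sizes, c(4, 3, 3, 1, 1, 1, 1))

  # random configurations against the exhaustive oracle
  for (s in 1:50) {
    conf <- random_solute_config(seed = s)
    ours <- cluster_size_distribution(conf, cutoff = 0.3)
    hist_oracle <- table(oracle_cluster_sizes(conf, cutoff = 0.3))
    ours_molecules <- as.numeric(ours$histogram)
    # both histograms are ordered by ascending cluster size
    oracle_molecules <- as.integer(names(hist_oracle)) * as.integer(hist_oracle)
    expect_equal(unname(ours_molecules), unname(oracle_molecules))
    # sum over histogram equals the solute count
    expect_equal(sum(ours_molecules), ours$n_solute)
  }

  # centroid metric differs from atom-pair minimum in principle but both run
  cen <- cluster_size_distribution(chain, cutoff = 0.25, metric = "centroid")
  expect_s3_class(cen, "cluster_distribution")
  expect_error(cluster_size_distribution(chain, cutoff = 0), "cutoff")
})

test_that("discarding initial frames mirrors the production-tail convention", {
  traj <- generate_bilayer(bilayer_spec(n_lipids = 8, n_solute = 2,
                                        planted_clusters = list(1L, 2L)),
                           n_frames = 10, seed = 2)
  tail_ <- discard_initial(traj, 0.8)
  expect_length(tail_, 2L)
  expect_equal(tail_$times, traj$times[9:10])
})
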