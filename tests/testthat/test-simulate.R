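test_that("identical seeds reproduce scenes bit for bit", {
  scen <- scenarioConfig(n_spores = 6, n_debris = 2, seed = 99,
                         duration_min = 200)
  s1 <- simulateScene(scen)
  s2 <- simulateScene(scen)
  expect_identical(labelData(s1$labels), labelData(s2$labels))
  expect_identical(frames(s1$image), frames(s2$image))
  expect_identical(s1$truth$cells, s2$truth$cells)
  s3 <- simulateScene(scenarioConfig(n_spores = 6, n_debris = 2, seed = 100,
                                     duration_min = 200))
  expect_false(identical(labelData(s1$labels), labelData(s3$labels)))
})

test_that("an empty scenario yields a background-only stack and empty truth", {
  s <- simulateScene(scenarioConfig(n_spores = 0, n_debris = 0, seed = 1,
                                    duration_min = 100))
  expect_equal(max(labelData(s$labels)), 0L)
  expect_equal(nrow(s$truth$cells), 0L)
})

test_that("a dead spore keeps a constant rasterized area", {
  s <- simulateScene(scenarioConfig(n_spores = 1, n_debris = 0, seed = 3,
                                    duration_min = 300, noise_sd = 0,
                                    phenotype_mix = c(dead = 1)),
                     render = "labels")
  tab <- measureAll(s$labels)
  expect_equal(length(unique(tab$area_um2)), 1L)
  expect_true(all(tab$aspect_ratio < 1.05))
})

test_that("the truth division frame follows the closed-form kinematics", {
  scen <- scenarioConfig(n_spores = 4, n_debris = 0, seed = 7,
                         phenotype_mix = c(normal = 1))
  s <- simulateScene(scen, render = "labels")
  cells <- s$truth$cells
  for (k in seq_len(nrow(cells))) {
    Ldiv <- divisionLengthForGeometry(cells$r_swollen_um[k],
                                      cells$tube_radius_um[k], targetAR = 3)
    expected <- cells$outgrowth_start_frame[k] +
      ceiling(Ldiv / cells$speed_um_per_frame[k])
    expect_equal(cells$division_frame[k], expected)
    # division length lands near the reported ~4.5 um for normal geometry
    expect_gt(cells$outgrowth_at_division_um[k], 4)
    expect_lt(cells$outgrowth_at_division_um[k], 5.6)
  }
})

test_that("truth division is the first frame the analytic AR reaches 3", {
  sim <- cachedScene("track20",
                     scenarioConfig(n_spores = 20, n_debris = 0, seed = 21,
                                    duration_min = 600,
                                    phenotype_mix = c(normal = 0.8,
                                                      dead = 0.2)))
  tt <- truthTrajectories(sim$truth)
  cells <- sim$truth$cells
  for (k in which(!is.na(cells$division_frame))) {
    tr <- tt[tt$cell_id == cells$cell_id[k], ]
    crossed <- tr$frame[tr$aspect_ratio >= 3]
    expect_equal(min(crossed), cells$division_frame[k])
  }
})

test_that("a rendered isolated disc has raster area within 5 percent", {
  s <- simulateScene(scenarioConfig(n_spores = 1, n_debris = 0, seed = 5,
                                    duration_min = 100,
                                    spore_radius_um = 1.55,
                                    spore_radius_sd_um = 0,
                                    phenotype_mix = c(dead = 1)),
                     render = "labels")
  # r = 1.55 um at 0.18 um/px is ~8.6 px
  tab <- measureAll(s$labels)
  expect_lt(abs(tab$area_um2[1] - pi * 1.55^2) / (pi * 1.55^2), 0.05)
})

test_that("the dye channel splits intensity at exactly the drawn fraction", {
  s <- simulateScene(scenarioConfig(n_spores = 3, n_debris = 0, seed = 19,
                                    duration_min = 400,
                                    phenotype_mix = c(normal = 1),
                                    vacuole_mode = "two_channel",
                                    vacuole_body_fraction = 0.64,
                                    vacuole_noise_sd = 0,
                                    vacuole_bg_level = 0,
                                    noise_sd = 0),
                     render = "both")
  cells <- s$truth$cells
  H <- dim(labelData(s$labels))[1]
  px <- 0.18
  for (k in seq_len(nrow(cells))) {
    f <- cells$division_frame[k] - 1L
    if (is.na(f)) next
    lf <- getFrame(s$labels, f + 1L)
    ch2 <- frames(s$image)[, , f + 1L, 2]
    idx <- which(lf == cells$label[k])
    x <- (((idx - 1) %/% H) + 0.5) * px
    y <- (((idx - 1) %% H) + 0.5) * px
    inBody <- (x - cells$x_um[k])^2 + (y - cells$y_um[k])^2 <=
      cells$r0_um[k]^2
    tot <- sum(ch2[idx])
    expect_gt(tot, 0)
    expect_equal(sum(ch2[idx][inBody]) / tot, 0.64, tolerance = 1e-6)
  }
})

test_that("CFU simulations follow the decay model exactly without noise", {
  md <- decayModel("exponential", halfLifeDays = 10, noiseSdLog = 0)
  s <- normalizeCFU(simulateCFUExperiment(md, c(0, 10), nReps = 1, seed = 1))
  expect_equal(s$normalized, c(1, 0.5))
  md80 <- decayModel("exponential", halfLifeDays = 80, noiseSdLog = 0)
  s80 <- normalizeCFU(simulateCFUExperiment(md80, c(0, 80), nReps = 1,
                                            seed = 1))
  expect_equal(s80$normalized, c(1, 0.5))
  expect_error(simulateCFUExperiment(md, c(10, 20)), "day 0")
  bi <- decayModel("biphasic", halfLifeDays = c(5, 100), mixWeight = 0.4,
                   noiseSdLog = 0)
  expect_equal(survivalFraction(bi, 0), 1)
  expect_lt(survivalFraction(bi, 1000), 0.61)
})

test_that("noisy replicate means converge to the decay curve", {
  md <- decayModel("exponential", halfLifeDays = 10, noiseSdLog = 0.1)
  s <- normalizeCFU(simulateCFUExperiment(md, c(0, 10), nReps = 1000,
                                          seed = 23))
  atHalf <- s$normalized[s$day == 10]
  expect_lt(abs(mean(atHalf) - 0.5) / 0.5, 0.02)
  # identical seeds give identical tables
  s2 <- simulateCFUExperiment(md, c(0, 10), nReps = 1000, seed = 23)
  expect_identical(simulateCFUExperiment(md, c(0, 10), nReps = 1000,
                                         seed = 23), s2)
})

test_that("over-dense scenarios fail with a placement error", {
  expect_error(simulateScene(scenarioConfig(n_spores = 120, n_debris = 0,
                                            seed = 1, duration_min = 100,
                                            field_size_px = 150,
                                            max_place_tries = 30),
                             render = "labels"),
               "over-dense")
})

test_that("scenario invariants are enforced", {
  expect_error(scenarioConfig(phenotype_mix = c(normal = -1, dead = 2)),
               "non-negative")
  expect_error(scenarioConfig(elongated_outgrowth_range_um = c(5, 20)),
               "above elongated_cutoff")
  expect_error(scenarioConfig(not_a_param = 3), "unknown")
})
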