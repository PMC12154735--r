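# build a one-track TrackSet with a prescribed AR (and optional area) series
arTrack <- function(ar, area = rep(9, length(ar)), x = 10, y = 10,
                    frames = seq_along(ar) - 1L) {
  meas <- data.frame(frame = frames, label = 1L, centroid_x_um = x,
                     centroid_y_um = y, area_um2 = area,
                     major_um = sqrt(area * ar), minor_um = sqrt(area / ar),
                     aspect_ratio = ar, orientation_rad = 0,
                     degenerate = FALSE)
  linkTracks(meas, nFramesTotal = max(frames) + 1L, maxAreaChange = 10)
}

test_that("spore gating is strict at AR 1.4 and rejects late appearers", {
  meas <- rbind(
    data.frame(frame = 0L, label = 1L, centroid_x_um = 5, centroid_y_um = 5,
               area_um2 = 8, major_um = sqrt(8 * 1.39),
               minor_um = sqrt(8 / 1.39), aspect_ratio = 1.39,
               orientation_rad = 0, degenerate = FALSE),
    data.frame(frame = 0L, label = 2L, centroid_x_um = 20, centroid_y_um = 5,
               area_um2 = 8, major_um = sqrt(8 * 1.40),
               minor_um = sqrt(8 / 1.40), aspect_ratio = 1.40,
               orientation_rad = 0, degenerate = FALSE),
    data.frame(frame = 1L, label = 3L, centroid_x_um = 40, centroid_y_um = 40,
               area_um2 = 8, major_um = sqrt(8), minor_um = sqrt(8),
               aspect_ratio = 1, orientation_rad = 0, degenerate = FALSE))
  ts <- linkTracks(meas, nFramesTotal = 2)
  g <- gateSpores(ts, pipelineConfig())
  expect_equal(g$gated, 1L)          # AR 1.39 passes (strict <)
  expect_equal(g$rejected, 2L)       # AR 1.40 is on the boundary: rejected
  expect_equal(g$absent_at_t0, 3L)   # appears after time zero
})

test_that("all generated spores gate in and elongated debris gates out", {
  sim <- cachedScene("gate30",
                     scenarioConfig(n_spores = 30, n_debris = 10, seed = 17,
                                    duration_min = 400))
  p <- runPipeline(sim, withLabels = FALSE)
  ids <- matchTruthTracks(p$trackset, sim$truth)
  expect_true(all(p$calls$is_spore[match(ids, p$calls$track_id)]))
  # debris tracks (all generated with AR >= 1.8) are rejected
  debrisIds <- setdiff(p$calls$track_id[p$calls$present_t0], ids)
  expect_true(all(!p$calls$is_spore[match(debrisIds, p$calls$track_id)]))
  expect_equal(length(debrisIds), 10L)
})

test_that("first division is the first strict crossing of AR 3", {
  r <- callFirstDivision(0:4, c(1.1, 1.3, 2.0, 3.05, 3.4))
  expect_equal(r$division_frame, 3L)
  expect_equal(r$division_time_min, 30)
  expect_true(is.na(callFirstDivision(0:4,
                                      c(1.1, 2.0, 2.9, 2.9, 2.9))$division_frame))
  # exact 3.0 does not divide (strict >)
  expect_true(is.na(callFirstDivision(0:2, c(1, 2, 3))$division_frame))
})

test_that("a crossing supported only by an interpolated frame is deferred", {
  r <- callFirstDivision(0:4, c(1.1, 2.0, 3.2, 3.4, 3.5),
                         interpolated = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(r$division_frame, 3L)
})

test_that("no frame before the called division exceeds the threshold", {
  set.seed(42)
  for (rep in 1:25) {
    ar <- cumsum(runif(30, -0.1, 0.25)) + 1
    r <- callFirstDivision(0:29, ar)
    if (!is.na(r$division_frame))
      expect_true(all(ar[seq_len(r$division_frame)] <= 3.0))
  }
})

test_that("raising the division threshold never calls divisions earlier", {
  set.seed(7)
  for (rep in 1:25) {
    ar <- cumsum(runif(40, -0.05, 0.2)) + 1
    f3 <- callFirstDivision(0:39, ar, config = pipelineConfig())$division_frame
    f35 <- callFirstDivision(0:39, ar,
                             config = pipelineConfig(division_ar = 3.5))$division_frame
    if (!is.na(f35)) expect_gte(f35, f3)
    if (is.na(f3)) expect_true(is.na(f35))
  }
})

test_that("germination efficiency is the divided fraction of gated spores", {
  calls <- data.frame(track_id = 1:100, is_spore = TRUE,
                      division_frame = c(rep(50L, 62), rep(NA, 38)))
  r <- suppressWarnings(germinationEfficiency(calls))
  expect_equal(r$efficiency, 0.62)
  expect_equal(r$n_divided, 62L); expect_equal(r$n_spores, 100L)
  none <- calls; none$division_frame <- NA
  expect_equal(suppressWarnings(germinationEfficiency(none))$efficiency, 0)
  expect_error(germinationEfficiency(calls[calls$is_spore == FALSE, ]),
               "undefined")
  expect_warning(germinationEfficiency(calls[1:40, ]), "fewer than 50")
  # non-increasing as the end frame decreases
  e1 <- suppressWarnings(germinationEfficiency(calls, endFrame = 60))$efficiency
  e2 <- suppressWarnings(germinationEfficiency(calls, endFrame = 40))$efficiency
  expect_gte(e1, e2)
  expect_true(e1 >= 0 && e1 <= 1)
})

test_that("swelling window matches a brute-force slope-scan oracle", {
  # area climbs 7 -> 12 um^2 over frames 5..12 with AR flat at ~1
  fr <- 0:19
  area <- c(rep(7, 5), seq(7, 12, length.out = 8), rep(12, 7))
  set.seed(2); ar <- 1 + runif(20, -0.005, 0.005)
  w <- detectSwellingWindow(fr, area, ar, pipelineConfig())
  expect_false(is.null(w))
  # oracle: longest qualifying run on the same smoothed series
  sm <- function(x) vapply(seq_along(x), function(i)
    mean(x[max(1, i - 1):min(length(x), i + 1)]), numeric(1))
  aS <- sm(area); rS <- sm(ar)
  ok <- diff(aS) / head(aS, -1) > 0.01 & abs(diff(rS)) <= 0.02
  runs <- rle(ok)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
  big <- which(runs$values & runs$lengths >= 2)
  best <- big[which.max(runs$lengths[big])]
  expect_equal(w$start_frame, fr[starts[best]])
  expect_equal(w$end_frame, fr[ends[best] + 1])
  expect_true(w$start_frame >= 4 && w$start_frame <= 6)
  expect_true(w$end_frame >= 11 && w$end_frame <= 13)
  expect_gt(w$area_gain_fraction, 0.5)
})

test_that("flat series and joint area+AR growth yield no swelling window", {
  fr <- 0:14
  expect_null(detectSwellingWindow(fr, rep(8, 15), rep(1, 15)))
  # outgrowth phase: area and AR rising together
  area <- seq(8, 20, length.out = 15)
  ar <- seq(1, 3, length.out = 15)
  expect_null(detectSwellingWindow(fr, area, ar))
})

test_that("population curves give per-frame means with SE conventions", {
  meas <- rbind(
    data.frame(frame = 0:2, label = 1L, centroid_x_um = 5, centroid_y_um = 5,
               area_um2 = c(8, 9, 10), major_um = 3, minor_um = 3,
               aspect_ratio = 1, orientation_rad = 0, degenerate = FALSE),
    data.frame(frame = 0:2, label = 2L, centroid_x_um = 25, centroid_y_um = 5,
               area_um2 = c(8, 9, 10), major_um = 3, minor_um = 3,
               aspect_ratio = 1, orientation_rad = 0, degenerate = FALSE))
  ts <- linkTracks(meas, nFramesTotal = 3)
  pc <- populationCurves(ts)
  expect_equal(pc$mean_area, c(8, 9, 10))
  expect_equal(pc$se_area, c(0, 0, 0))      # identical tracks: SE 0
  expect_equal(pc$n, rep(2L, 3))
  one <- populationCurves(ts, trackIds = 1L)
  expect_equal(one$se_area, c(0, 0, 0))     # n = 1 convention: SE 0
  expect_equal(one$n, rep(1L, 3))
  expect_equal(one$time_min, c(0, 10, 20))
})

test_that("mean area of many normal cells follows the analytic kinematics", {
  sim <- cachedScene("pop60",
                     scenarioConfig(n_spores = 60, n_debris = 0, seed = 23,
                                    duration_min = 600,
                                    phenotype_mix = c(normal = 1)))
  p <- runPipeline(sim, withLabels = FALSE)
  ids <- matchTruthTracks(p$trackset, sim$truth)
  pc <- populationCurves(p$trackset, trackIds = ids)
  tt <- truthTrajectories(sim$truth)
  for (f in c(0, 15, 30, 45)) {
    expected <- mean(tt$area_um2[tt$frame == f])
    got <- pc$mean_area[pc$frame == f]
    n_truth <- sum(tt$frame == f)
    if (n_truth == 60)                      # all cells still unsplit
      expect_lt(abs(got - expected) / expected, 0.05)
  }
})

test_that("bipolar outranks elongated whenever both conditions hold", {
  # constructed masks: body disc at t0; later both poles protrude, one > 6 um
  H <- 140; W <- 220; px <- 0.18
  r0 <- 1.8 / px
  a <- array(0L, c(H, W, 3))
  cx <- 110; cy <- 70
  disc <- matrix(0L, H, W)
  disc[rasterDiscPixels(cx, cy, r0, H, W)] <- 1L
  a[, , 1] <- disc
  a[, , 2] <- disc
  # frame 2 (evaluation happens at division - 1 = frame 2): bipolar shape
  m <- matrix(0L, H, W)
  m[rasterDiscPixels(cx, cy, r0, H, W)] <- 1L
  tubeHalf <- round(1.0 / px)
  left <- round(7.2 / px); right <- round(3.5 / px)
  m[(cy - tubeHalf):(cy + tubeHalf), (cx - r0 - left):cx] <- 1L
  m[(cy - tubeHalf):(cy + tubeHalf), cx:(cx + r0 + right)] <- 1L
  a[, , 3] <- m
  labs <- labelStack(a, pixelSizeUm = px)
  meas <- measureAll(labs)
  ts <- linkTracks(meas, nFramesTotal = 3, maxAreaChange = 10)
  cl <- classifyOutgrowth(ts, labs, trackId = 1L, divisionFrame = 3L,
                          config = pipelineConfig())
  expect_equal(cl$phenotype, "bipolar")
  expect_gt(cl$outgrowth_length_um, 6)   # satisfies the elongated test too
  # same cell with only the long pole, grown over two steps, is elongated
  b <- a
  armMask <- function(lpx) {
    mm <- disc
    mm[(cy - tubeHalf):(cy + tubeHalf), (cx - r0 - lpx):cx] <- 1L
    mm
  }
  b[, , 2] <- armMask(round(3.5 / px))
  b[, , 3] <- armMask(left)
  labs2 <- labelStack(b, pixelSizeUm = px)
  ts2 <- linkTracks(measureAll(labs2), nFramesTotal = 3, maxAreaChange = 10)
  cl2 <- classifyOutgrowth(ts2, labs2, trackId = 1L, divisionFrame = 3L,
                           config = pipelineConfig())
  expect_equal(cl2$phenotype, "elongated")
})

test_that("starting-area reporting covers gated spores only", {
  sim <- cachedScene("gate30",
                     scenarioConfig(n_spores = 30, n_debris = 10, seed = 17,
                                    duration_min = 400))
  p <- runPipeline(sim, withLabels = FALSE)
  gated <- p$calls[p$calls$is_spore, ]
  # true dormant areas are ~7-9 um^2; debris would contaminate this
  expect_true(all(gated$starting_area_um2 > 5 & gated$starting_area_um2 < 12))
  expect_equal(nrow(gated), 30L)
})
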