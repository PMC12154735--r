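# construct a disc + tube cell mask in micrometre pixel coordinates
germlingPixels <- function(r0 = 1.8, tube = 5, rt = 1.0, theta = 0,
                           px = 0.18, H = 160, W = 160) {
  cx <- W / 2 * px; cy <- H / 2 * px
  ji <- expand.grid(i = seq_len(H), j = seq_len(W))
  x <- (ji$j - 0.5) * px; y <- (ji$i - 0.5) * px
  s <- (x - cx) * cos(theta) + (y - cy) * sin(theta)
  q <- -(x - cx) * sin(theta) + (y - cy) * cos(theta)
  s0 <- r0 + tube - rt
  inside <- (s^2 + q^2 <= r0^2) |
    (s >= 0 & s <= s0 & abs(q) <= rt) | ((s - s0)^2 + q^2 <= rt^2)
  list(x = x[inside], y = y[inside], cx = cx, cy = cy)
}

test_that("a cell with no outgrowth cannot be partitioned", {
  g <- germlingPixels(tube = 0.2)
  expect_error(defineSporeBody(g$x, g$y, g$cx, g$cy, 1.8, 0),
               "not germinated enough")
})

test_that("the body disc recovers the t0 disc pixel count within 10 percent", {
  g <- germlingPixels(r0 = 1.8, tube = 5)
  bd <- defineSporeBody(g$x, g$y, g$cx, g$cy, 1.8, 0, pixelSizeUm = 0.18)
  t0count <- pi * 1.8^2 / 0.18^2
  expect_lt(abs(sum(bd$body) - t0count) / t0count, 0.10)
  expect_gt(bd$protrusion_um, 4.5)
})

test_that("body definition is rotation-invariant", {
  g <- germlingPixels(r0 = 1.8, tube = 5, theta = 0)
  n0 <- sum(defineSporeBody(g$x, g$y, g$cx, g$cy, 1.8, 0,
                            pixelSizeUm = 0.18)$body)
  # exact rotations of the same pixel set give identical counts
  for (rot in list(function(x, y) list(x = -y, y = x),      # 90 degrees
                   function(x, y) list(x = -x, y = -y))) {  # 180 degrees
    r <- rot(g$x - g$cx, g$y - g$cy)
    th <- if (identical(r$x[1], -(g$y - g$cy)[1])) pi / 2 else pi
    n <- sum(defineSporeBody(r$x + g$cx, r$y + g$cy, g$cx, g$cy, 1.8, th,
                             pixelSizeUm = 0.18)$body)
    expect_identical(n, n0)
  }
  # re-rasterized arbitrary angles agree within raster tolerance
  counts <- vapply(c(0, pi / 3, 1.8), function(th) {
    gg <- germlingPixels(r0 = 1.8, tube = 5, theta = th)
    sum(defineSporeBody(gg$x, gg$y, gg$cx, gg$cy, 1.8, th,
                        pixelSizeUm = 0.18)$body)
  }, numeric(1))
  expect_lt(diff(range(counts)) / mean(counts), 0.15)
})

test_that("partition fractions follow the intensity sums exactly", {
  v <- c(rep(2, 40), rep(1, 60))
  body <- c(rep(TRUE, 40), rep(FALSE, 60))
  pf <- partitionFraction(v, body)
  expect_equal(pf$fraction_in_body, 80 / 140)
  expect_equal(pf$fraction_in_body + pf$fraction_in_outgrowth, 1)
  # all signal in the body
  expect_equal(partitionFraction(c(rep(5, 10), rep(0, 5)),
                                 c(rep(TRUE, 10), rep(FALSE, 5)))$fraction_in_body, 1)
  # uniform intensity: fraction equals the body pixel share
  u <- partitionFraction(rep(3, 100), c(rep(TRUE, 40), rep(FALSE, 60)))
  expect_equal(u$fraction_in_body, 0.40)
  expect_error(partitionFraction(rep(0, 10), rep(TRUE, 10)), "zero total")
})

test_that("fractions are invariant to positive intensity rescaling", {
  set.seed(3)
  v <- runif(200, 0.1, 1)
  body <- runif(200) < 0.4
  p1 <- partitionFraction(v, body, background = 0.05)
  p2 <- partitionFraction(v * 37.5, body, background = 0.05 * 37.5)
  expect_equal(p1$fraction_in_body, p2$fraction_in_body, tolerance = 1e-12)
})

test_that("the pipeline recovers per-cell body fractions from the dye channel", {
  sim <- cachedScene("vac25",
                     scenarioConfig(n_spores = 25, n_debris = 0, seed = 41,
                                    duration_min = 600,
                                    phenotype_mix = c(normal = 1),
                                    vacuole_mode = "two_channel",
                                    vacuole_body_fraction = c(0.3, 0.9)),
                     render = "both")
  p <- runPipeline(sim)
  vac <- vacuolePartition(sim$image, sim$labels, p$trackset, p$calls)
  ids <- matchTruthTracks(p$trackset, sim$truth)
  est <- vac$fraction_in_body[match(ids, vac$track_id)]
  truthF <- sim$truth$cells$vacuole_body_fraction
  expect_gte(sum(!is.na(est)), 23L)
  err <- abs(est - truthF)
  expect_lte(mean(err, na.rm = TRUE), 0.05)
  # conservation is exact
  expect_equal(vac$fraction_in_body + vac$fraction_in_outgrowth,
               rep(1, nrow(vac)))
})
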