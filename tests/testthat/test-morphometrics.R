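# brute-force moment oracle on a pixel set: each pixel is a unit square,
# integrated exactly (square about its centre adds 1/12 per axis)
bruteEllipse <- function(pixels, pxsz) {
  x <- (pixels[, 2] - 0.5) * pxsz
  y <- (pixels[, 1] - 0.5) * pxsz
  n <- nrow(pixels)
  mu20 <- mean((x - mean(x))^2) + pxsz^2 / 12
  mu02 <- mean((y - mean(y))^2) + pxsz^2 / 12
  mu11 <- mean((x - mean(x)) * (y - mean(y)))
  t1 <- (mu20 + mu02) / 2
  t2 <- sqrt(((mu20 - mu02) / 2)^2 + mu11^2)
  list(area = n * pxsz^2, major = 4 * sqrt(t1 + t2), minor = 4 * sqrt(t1 - t2),
       ar = sqrt((t1 + t2) / (t1 - t2)))
}

rasterEllipsePixels <- function(a, b, theta = 0, H = 200, W = 200) {
  cx <- W / 2; cy <- H / 2
  ji <- expand.grid(i = seq_len(H), j = seq_len(W))
  dx <- ji$j - 0.5 - cx; dy <- ji$i - 0.5 - cy
  s <- dx * cos(theta) + dy * sin(theta)
  q <- -dx * sin(theta) + dy * cos(theta)
  keep <- (s / a)^2 + (q / b)^2 <= 1
  as.matrix(ji[keep, c("i", "j")])
}

test_that("a rasterized disc measures its true area and is circular", {
  px <- rasterEllipsePixels(20, 20, H = 60, W = 60)
  e <- fitRegionEllipse(px, pixelSizeUm = 0.2)
  expect_lt(abs(e$area_um2 - 50.265) / 50.265, 0.03)
  expect_lte(e$aspect_ratio, 1.02)
  expect_false(e$degenerate)
})

test_that("a 30x10 px ellipse fits with aspect ratio 3 and matches the oracle", {
  for (th in c(0, 0.4, 1.1)) {
    px <- rasterEllipsePixels(30, 10, theta = th, H = 120, W = 120)
    e <- fitRegionEllipse(px, pixelSizeUm = 0.2)
    o <- bruteEllipse(px, 0.2)
    expect_gte(e$aspect_ratio, 2.9)
    expect_lte(e$aspect_ratio, 3.1)
    expect_equal(e$aspect_ratio, o$ar, tolerance = 1e-10)
    expect_equal(e$major_um, o$major, tolerance = 1e-10)
  }
})

test_that("rotating a region by 90 degrees changes AR by < 2 percent", {
  px <- rasterEllipsePixels(28, 9, theta = 0, H = 120, W = 120)
  px90 <- cbind(px[, 2], px[, 1])   # transpose = 90-degree rotation
  e1 <- fitRegionEllipse(px, 0.18)
  e2 <- fitRegionEllipse(px90, 0.18)
  expect_lt(abs(e1$aspect_ratio - e2$aspect_ratio) / e1$aspect_ratio, 0.02)
  # arbitrary-angle rasterized rotation stays within 2 percent too
  e3 <- fitRegionEllipse(rasterEllipsePixels(28, 9, theta = pi / 5), 0.18)
  expect_lt(abs(e1$aspect_ratio - e3$aspect_ratio) / e1$aspect_ratio, 0.02)
})

test_that("translation by whole pixels preserves area exactly", {
  px <- rasterEllipsePixels(15, 8, theta = 0.7, H = 80, W = 80)
  shifted <- cbind(px[, 1] + 7, px[, 2] + 11)
  expect_identical(fitRegionEllipse(px, 0.18)$area_um2,
                   fitRegionEllipse(shifted, 0.18)$area_um2)
})

test_that("collinear regions are flagged degenerate with a finite AR", {
  px <- cbind(rep(10L, 40), 1:40)   # single-row region, 40 x 1
  e <- fitRegionEllipse(px, 0.18)
  expect_true(e$degenerate)
  expect_true(is.finite(e$aspect_ratio))
  expect_gt(e$minor_um, 0)
  # minor axis floored near one pixel width
  expect_lt(e$minor_um, 2 * 0.18)
  expect_error(fitRegionEllipse(px[1:4, ]), "at least 5")
})

test_that("the ellipse fit agrees with an established image-analysis library", {
  px <- rasterEllipsePixels(22, 8, theta = 0.9, H = 100, W = 100)
  mask <- matrix(0L, 100, 100)
  mask[px] <- 1L
  ft <- EBImage::computeFeatures.moment(mask)
  e <- fitRegionEllipse(px, pixelSizeUm = 1)
  ebAR <- ft[1, "m.majoraxis"] /
    (ft[1, "m.majoraxis"] * sqrt(1 - ft[1, "m.eccentricity"]^2))
  # EBImage omits the pixel-footprint term; agreement to ~1 percent
  expect_equal(e$major_um, unname(ft[1, "m.majoraxis"]), tolerance = 0.02)
  expect_equal(e$aspect_ratio, unname(ebAR), tolerance = 0.02)
})

test_that("measureAll produces one sorted row per (frame, label)", {
  a <- array(0L, c(40, 40, 3))
  a[5:12, 5:12, ] <- 1L           # static object in all frames
  a[25:31, 20:30, 1:2] <- 7L      # second object in two frames
  tab <- measureAll(labelStack(a, pixelSizeUm = 0.2))
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$frame, c(0L, 0L, 1L, 1L, 2L))
  expect_false(is.unsorted(tab$frame))
  # identical object measures identically across frames
  sq <- tab[tab$label == 1L, ]
  expect_equal(length(unique(sq$area_um2)), 1L)
  expect_true(all(tab$major_um >= tab$minor_um))
  # empty stack gives an empty table with the documented columns
  e <- measureAll(labelStack(array(0L, c(10, 10, 2))))
  expect_equal(nrow(e), 0L)
  expect_true(all(c("frame", "label", "area_um2", "aspect_ratio") %in%
                    names(e)))
})
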