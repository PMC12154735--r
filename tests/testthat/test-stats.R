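cfuTab <- function(cfu, condition = "a", replicate = 1,
                   day = seq_along(cfu) * 10 - 10) {
  data.frame(condition = condition, replicate = replicate, day = day,
             cfu = cfu)
}

test_that("CFU normalization divides by the day-zero count", {
  n <- normalizeCFU(cfuTab(c(200, 100, 50)))
  expect_equal(n$normalized, c(1, 0.5, 0.25))
  expect_equal(normalizeCFU(cfuTab(50, day = 0))$normalized, 1)
  expect_error(normalizeCFU(cfuTab(c(0, 10))), "positive")
  expect_error(normalizeCFU(cfuTab(c(10, 5), day = c(5, 10))), "day-0")
})

test_that("trapezoidal AUC matches hand arithmetic and is linear", {
  expect_equal(aucTrapezoid(c(0, 10, 20), c(1, 0.5, 0.25)), 11.25)
  expect_equal(aucTrapezoid(c(0, 30), c(1, 1)), 30)
  expect_equal(aucTrapezoid(c(0, 10), c(1, 0)), 5)
  set.seed(9)
  d <- sort(runif(6, 0, 50)); f <- runif(6)
  expect_equal(aucTrapezoid(d, 3.7 * f), 3.7 * aucTrapezoid(d, f),
               tolerance = 1e-12)
  expect_error(aucTrapezoid(c(10, 0), c(1, 1)), "ascending")
})

test_that("identical survival groups give t = 0, p = 1", {
  a <- rbind(cfuTab(c(100, 50), "a", 1), cfuTab(c(200, 100), "a", 2))
  b <- rbind(cfuTab(c(400, 200), "b", 1), cfuTab(c(80, 40), "b", 2))
  r <- compareSurvivalAUC(normalizeCFU(a), normalizeCFU(b))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
})

test_that("degenerate zero-variance separated groups drive p to zero", {
  a <- do.call(rbind, lapply(1:3, function(i) cfuTab(c(100, 100), "a", i)))
  b <- do.call(rbind, lapply(1:3, function(i) cfuTab(c(100, 25), "b", i)))
  r <- compareSurvivalAUC(normalizeCFU(a), normalizeCFU(b))
  expect_lt(r$p_value, 1e-10)
  expect_error(compareSurvivalAUC(normalizeCFU(cfuTab(c(10, 5))),
                                  normalizeCFU(a)), "2 replicates")
})

test_that("the AUC t-test agrees with the reference t distribution", {
  set.seed(11)
  mk <- function(cond, shift) do.call(rbind, lapply(1:4, function(i)
    cfuTab(c(100, (50 + shift) * exp(rnorm(1, 0, 0.1))), cond, i)))
  a <- normalizeCFU(mk("a", 0)); b <- normalizeCFU(mk("b", 15))
  r <- compareSurvivalAUC(a, b)
  ref <- t.test(cfuAUC(a)$auc, cfuAUC(b)$auc, var.equal = TRUE)
  expect_equal(r$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r$p_value, ref$p.value, tolerance = 1e-12)
  rw <- compareSurvivalAUC(a, b, welch = TRUE)
  refw <- t.test(cfuAUC(a)$auc, cfuAUC(b)$auc)
  expect_equal(rw$p_value, refw$p.value, tolerance = 1e-12)
})

test_that("Fisher's exact test matches symmetry, closed forms and the
           reference implementation", {
  expect_equal(fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p_value, 1)
  expect_equal(fisherExact2x2(matrix(c(10, 0, 0, 10), 2))$p_value,
               2 / choose(20, 10), tolerance = 1e-12)
  set.seed(13)
  for (i in 1:150) {
    tab <- matrix(rpois(4, 8) + 1, 2)
    expect_equal(fisherExact2x2(tab)$p_value, fisher.test(tab)$p.value,
                 tolerance = 1e-10)
  }
  expect_error(fisherExact2x2(matrix(c(1, 2, 3), 3)), "2x2")
  expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
  expect_error(fisherExact2x2(matrix(c(0, 0, 3, 4), 2)), "margins")
})

test_that("one-way ANOVA matches t^2 for two groups and the F reference", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(6 + i %% 3); y <- rnorm(7, 0.8)
    a <- anovaOneway(list(x, y))
    tt <- t.test(x, y, var.equal = TRUE)
    expect_lt(abs(a$statistic - tt$statistic^2) /
                max(abs(tt$statistic^2), 1e-12), 1e-9)
    expect_equal(a$p_value, tt$p.value, tolerance = 1e-9)
  }
  g <- list(rnorm(5), rnorm(6, 1), rnorm(7, 2))
  a3 <- anovaOneway(g)
  ref <- oneway.test(values ~ grp,
                     data = data.frame(values = unlist(g),
                                       grp = rep(1:3, lengths(g))),
                     var.equal = TRUE)
  expect_equal(a3$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(a3$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("degenerate and extreme ANOVA inputs follow the conventions", {
  same <- list(rep(2, 4), rep(2, 5))
  d <- anovaOneway(same)
  expect_equal(d$statistic, 0); expect_equal(d$p_value, 1)
  expect_true(d$degenerate)
  far <- anovaOneway(list(c(1, 2, 3), c(101, 102, 103)))
  expect_lt(far$p_value, 1e-6)
  expect_error(anovaOneway(list(1:3)), "two groups")
  expect_error(anovaOneway(list(1, 1:3)), "at least 2 values")
})

test_that("stress survival is the treated/control percentage, averaged", {
  expect_equal(stressSurvival(400, 100)$mean, 25)
  expect_equal(stressSurvival(c(300, 120), c(300, 120))$mean, 100)
  r <- stressSurvival(c(100, 100, 100), c(50, 60, 70))
  expect_equal(r$mean, 60); expect_equal(r$sd, 10); expect_equal(r$n, 3L)
  expect_error(stressSurvival(c(0, 10), c(1, 2)), "positive")
  expect_error(stressSurvival(1:3, 1:2), "paired")
  cmp <- compareStressSurvival(c(50, 60, 70), c(20, 22, 24))
  expect_lt(cmp$p_value, 0.05)
})
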