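#' Normalize a colony-forming-unit series to its time-zero value
#'
#' Each replicate's counts are divided by its day-0 count, so the
#' normalized series starts at exactly 1.
#'
#' @param cfu data.frame with columns \code{condition, replicate, day, cfu}
#'   (day 0 present in every replicate, with a positive count).
#' @return The input with a \code{normalized} column added, sorted by
#'   condition, replicate, day.
#' @export
normalizeCFU <- function(cfu) {
  need <- c("condition", "replicate", "day", "cfu")
  if (!all(need %in% names(cfu)))
    stop("CFU table must have columns: ", paste(need, collapse = ", "))
  cfu <- cfu[order(cfu$condition, cfu$replicate, cfu$day), , drop = FALSE]
  key <- interaction(cfu$condition, cfu$replicate, drop = TRUE)
  out <- lapply(split(cfu, key), function(s) {
    if (s$day[1L] != 0) stop("replicate without a day-0 time point")
    if (s$cfu[1L] <= 0) stop("day-0 CFU count must be positive")
    s$normalized <- s$cfu / s$cfu[1L]
    s
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Trapezoidal area under a survival curve
#'
#' @param days ascending time points (days).
#' @param fraction normalized survival fractions at those days.
#' @return Area under the curve, in days.
#' @examples
#' aucTrapezoid(c(0, 10, 20), c(1, 0.5, 0.25))  # 11.25
#' @export
aucTrapezoid <- function(days, fraction) {
  stopifnot(length(days) == length(fraction), length(days) >= 2L)
  if (is.unsorted(days, strictly = TRUE)) stop("days must be ascending")
  sum(diff(days) * (head(fraction, -1L) + tail(fraction, -1L)) / 2)
}

#' Per-replicate survival-curve AUCs
#'
#' @param cfu a normalized CFU table (see \code{\link{normalizeCFU}}).
#' @return data.frame: \code{condition, replicate, auc}.
#' @export
cfuAUC <- function(cfu) {
  if (!"normalized" %in% names(cfu)) cfu <- normalizeCFU(cfu)
  key <- interaction(cfu$condition, cfu$replicate, drop = TRUE)
  out <- lapply(split(cfu, key), function(s)
    data.frame(condition = s$condition[1L], replicate = s$replicate[1L],
               auc = aucTrapezoid(s$day, s$normalized)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# two-sample t statistic with a variance floor for degenerate inputs
.twoSampleT <- function(x, y, welch = FALSE) {
  nx <- length(x); ny <- length(y)
  if (nx < 2L || ny < 2L) stop("need at least 2 values per group")
  vx <- var(x); vy <- var(y)
  if (welch) {
    sq <- vx / nx + vy / ny
    if (sq <= 0) sq <- .Machine$double.eps   # degenerate-variance floor
    t <- (mean(x) - mean(y)) / sqrt(sq)
    df <- if (vx > 0 || vy > 0)
      sq^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1)) else nx + ny - 2
  } else {
    sp2 <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    if (sp2 <= 0) sp2 <- .Machine$double.eps
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
    df <- nx + ny - 2
  }
  p <- 2 * pt(-abs(t), df)
  list(statistic = t, df = df, p_value = p)
}

#' Compare survival curves by their areas under the curve
#'
#' Computes the trapezoidal AUC of each replicate's normalized survival
#' curve, then a two-sided two-sample t-test between the two conditions'
#' per-replicate AUCs (Student's pooled-variance test by default, Welch
#' optional). When both groups have zero variance the variance is floored
#' at machine epsilon, so identical groups give p = 1 and separated
#' degenerate groups give p near 0.
#'
#' @param cfuA,cfuB normalized CFU tables (or raw, normalized on the fly)
#'   for the two conditions, each with at least 2 replicates.
#' @param welch use the Welch test instead of Student's.
#' @return list: \code{test}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{auc_a}, \code{auc_b}, \code{n} (group sizes).
#' @export
compareSurvivalAUC <- function(cfuA, cfuB, welch = FALSE) {
  aA <- cfuAUC(cfuA)$auc
  aB <- cfuAUC(cfuB)$auc
  if (length(aA) < 2L || length(aB) < 2L)
    stop("need at least 2 replicates per group")
  if (isTRUE(all.equal(c(aA, aB), rep(mean(c(aA, aB)), length(aA) + length(aB)),
                       tolerance = 1e-12)) && var(c(aA, aB)) == 0) {
    return(list(test = if (welch) "welch_t" else "student_t",
                statistic = 0, df = length(aA) + length(aB) - 2,
                p_value = 1, auc_a = aA, auc_b = aB,
                n = c(length(aA), length(aB))))
  }
  r <- .twoSampleT(aA, aB, welch)
  list(test = if (welch) "welch_t" else "student_t",
       statistic = r$statistic, df = r$df, p_value = r$p_value,
       auc_a = aA, auc_b = aB, n = c(length(aA), length(aB)))
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value by the probability-ordering convention: the sum
#' of hypergeometric probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (within a
#' small relative slack for floating-point ties). Used for
#' germinated/not-germinated fraction comparisons between samples.
#'
#' @param tab 2x2 matrix of non-negative integer counts, rows = outcome,
#'   columns = sample.
#' @return list: \code{test = "fisher_exact"}, \code{p_value},
#'   \code{odds_ratio} (sample odds ratio), \code{table}.
#' @examples
#' fisherExact2x2(matrix(c(5, 5, 5, 5), 2))$p_value    # 1
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stop("table must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("table entries must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive")
  m <- sum(tab[1L, ])          # row-1 margin
  n <- sum(tab[2L, ])          # row-2 margin
  k <- sum(tab[, 1L])          # column-1 margin
  a <- tab[1L, 1L]
  lo <- max(0L, k - n); hi <- min(k, m)
  support <- lo:hi
  pmf <- dhyper(support, m, n, k)
  pObs <- pmf[support == a]
  p <- sum(pmf[pmf <= pObs * (1 + 1e-7)])
  orr <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(test = "fisher_exact", p_value = min(p, 1), odds_ratio = orr,
       table = tab)
}

#' One-way analysis of variance
#'
#' Classical one-way fixed-effects F test, e.g. for comparing division
#' times between samples. With two groups the F statistic equals the square
#' of the pooled two-sample t statistic. If every value is identical across
#' all groups the result is the degenerate convention F = 0, p = 1,
#' flagged.
#'
#' @param groups list of numeric vectors (>= 2 groups, each >= 2 values).
#' @return list: \code{test = "anova_oneway"}, \code{statistic} (F),
#'   \code{df} (c(between, within)), \code{p_value}, \code{n} (group
#'   sizes), \code{degenerate}.
#' @export
anovaOneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stop("each group needs at least 2 values")
  x <- unlist(groups)
  N <- length(x); g <- length(groups)
  if (N <= g) stop("total n must exceed the number of groups")
  gm <- mean(x)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  df1 <- g - 1L; df2 <- N - g
  if (ssw == 0 && ssb == 0) {
    return(list(test = "anova_oneway", statistic = 0, df = c(df1, df2),
                p_value = 1, n = ns, degenerate = TRUE))
  }
  if (ssw == 0) {
    return(list(test = "anova_oneway", statistic = Inf, df = c(df1, df2),
                p_value = 0, n = ns, degenerate = TRUE))
  }
  f <- (ssb / df1) / (ssw / df2)
  list(test = "anova_oneway", statistic = f, df = c(df1, df2),
       p_value = pf(f, df1, df2, lower.tail = FALSE), n = ns,
       degenerate = FALSE)
}

#' Percent survival after an acute stress
#'
#' Per-replicate percent survival is 100 times the CFU count on the
#' stressed plate over the count on the untreated control plate; replicates
#' are paired. Reports the replicate percentages with their mean, standard
#' deviation and n. Conditions are compared with
#' \code{\link{compareStressSurvival}}.
#'
#' @param controlCfu,treatedCfu paired replicate CFU counts; controls must
#'   be positive.
#' @return list: \code{percent} (per replicate), \code{mean}, \code{sd},
#'   \code{n}.
#' @examples
#' stressSurvival(c(400, 400, 400), c(100, 100, 100))$mean  # 25
#' @export
stressSurvival <- function(controlCfu, treatedCfu) {
  if (length(controlCfu) != length(treatedCfu))
    stop("control and treated replicates must be paired")
  if (any(controlCfu <= 0)) stop("control CFU must be positive")
  pct <- 100 * treatedCfu / controlCfu
  list(percent = pct, mean = mean(pct), sd = sd(pct), n = length(pct))
}

#' Compare percent survival between two samples
#'
#' Two-sided two-sample t-test on the per-replicate percent-survival values
#' of two samples (at least 3 replicates each is the figure convention).
#'
#' @param survA,survB results of \code{\link{stressSurvival}} (or numeric
#'   vectors of percentages).
#' @param welch use the Welch test.
#' @return list: \code{test}, \code{statistic}, \code{df}, \code{p_value},
#'   \code{n}.
#' @export
compareStressSurvival <- function(survA, survB, welch = FALSE) {
  pa <- if (is.list(survA)) survA$percent else survA
  pb <- if (is.list(survB)) survB$percent else survB
  r <- .twoSampleT(pa, pb, welch)
  list(test = if (welch) "welch_t" else "student_t",
       statistic = r$statistic, df = r$df, p_value = r$p_value,
       n = c(length(pa), length(pb)))
}
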