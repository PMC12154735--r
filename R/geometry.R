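# Analytic geometry of a germinating spore ("germling"): a circular body of
# radius R with a capsule-shaped germ tube of radius rt whose tip protrudes a
# distance L beyond the body boundary (tip at R + L from the body centre).
# The shape is symmetric about the tube axis, so the moment-matching ellipse
# is axis-aligned and its moments reduce to 1-D integrals over the half-width
# profile, evaluated with fixed-order Gauss-Legendre quadrature. This is the
# closed-form ground truth the synthetic generator and the kinematic tests
# use; it is independent of any rasterization.

.glCache <- new.env(parent = emptyenv())

.gaussLegendre <- function(n) {
  key <- as.character(n)
  if (!is.null(.glCache[[key]])) return(.glCache[[key]])
  i <- seq_len(n - 1L)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- beta
  J[cbind(i + 1L, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  gl <- list(x = e$values, w = 2 * e$vectors[1L, ]^2)
  .glCache[[key]] <- gl
  gl
}

#' Analytic moments of the germling shape
#'
#' Area, centroid and moment-matching-ellipse descriptors of the idealized
#' germinating-spore shape: a disc body (radius \code{bodyRadiusUm}) plus a
#' capsule germ tube (radius \code{tubeRadiusUm}) protruding
#' \code{protrusionUm} beyond the body boundary, from one pole
#' (\code{bipolar = FALSE}) or both poles. Computed by exact 1-D quadrature
#' of the shape's half-width profile, not from any rendered image, so it
#' serves as an independent oracle for rasterized measurements.
#'
#' @param bodyRadiusUm body (spore) radius, um.
#' @param tubeRadiusUm germ-tube radius, um.
#' @param protrusionUm tube-tip protrusion beyond the body boundary, um
#'   (0 gives a plain disc).
#' @param bipolar logical; tubes from both poles.
#' @return list with \code{area} (um^2), \code{xbar} (centroid offset along
#'   the tube axis, um), \code{major}, \code{minor} (full ellipse axes, um),
#'   and \code{ar} (aspect ratio, >= 1).
#' @examples
#' germlingMoments(1.8, 1.0, 0)$ar        # a disc: 1
#' germlingMoments(1.8, 1.0, 5)$ar        # elongating germling
#' @export
germlingMoments <- function(bodyRadiusUm, tubeRadiusUm, protrusionUm,
                            bipolar = FALSE) {
  R <- bodyRadiusUm; rt <- tubeRadiusUm; L <- protrusionUm
  stopifnot(R > 0, rt > 0, L >= 0)
  if (L == 0) {
    return(list(area = pi * R^2, xbar = 0, major = 2 * R, minor = 2 * R,
                ar = 1))
  }
  s0 <- R + L - rt  # tube cap centre along the axis
  xhi <- function(y) {
    xb <- ifelse(abs(y) <= R, sqrt(pmax(R^2 - y^2, 0)), -Inf)
    xc <- ifelse(abs(y) <= rt, s0 + sqrt(pmax(rt^2 - y^2, 0)), -Inf)
    pmax(xb, xc)
  }
  xlo <- function(y) {
    if (bipolar) return(-xhi(y))
    ifelse(abs(y) <= R, -sqrt(pmax(R^2 - y^2, 0)), 0)
  }
  gl <- .gaussLegendre(96L)
  ymax <- max(R, rt)
  brk <- sort(unique(c(0, min(R, rt), ymax)))
  A <- Mx <- Sxx <- Syy <- 0
  for (k in seq_len(length(brk) - 1L)) {
    a <- brk[k]; b <- brk[k + 1L]
    y <- (a + b) / 2 + (b - a) / 2 * gl$x
    w <- (b - a) / 2 * gl$w * 2      # even in y: integrate y>0 and double
    h <- xhi(y); l <- xlo(y)
    bad <- h < l
    h[bad] <- l[bad]
    A   <- A   + sum(w * (h - l))
    Mx  <- Mx  + sum(w * (h^2 - l^2) / 2)
    Sxx <- Sxx + sum(w * (h^3 - l^3) / 3)
    Syy <- Syy + sum(w * y^2 * (h - l))
  }
  xbar <- Mx / A
  Ixx <- Sxx - A * xbar^2   # second central moments (Ixy = 0 by symmetry)
  Iyy <- Syy
  hi <- max(Ixx, Iyy); lo <- min(Ixx, Iyy)
  list(area = A, xbar = xbar,
       major = 4 * sqrt(hi / A), minor = 4 * sqrt(lo / A),
       ar = sqrt(hi / lo))
}

#' Protrusion length at which the germling reaches a given aspect ratio
#'
#' Solves the analytic germling geometry for the tube protrusion at which the
#' moment-ellipse aspect ratio first equals \code{targetAR}. This is the
#' length at which the aspect-ratio division rule fires, so it defines the
#' generator's true division kinematics.
#'
#' @inheritParams germlingMoments
#' @param targetAR aspect ratio to reach (default 3, the division threshold).
#' @return protrusion length in um.
#' @export
divisionLengthForGeometry <- function(bodyRadiusUm, tubeRadiusUm,
                                      bipolar = FALSE, targetAR = 3) {
  f <- function(L) germlingMoments(bodyRadiusUm, tubeRadiusUm, L,
                                   bipolar)$ar - targetAR
  hi <- 60
  if (f(hi) < 0) stop("aspect ratio ", targetAR, " not attainable")
  uniroot(f, c(1e-3, hi), tol = 1e-8)$root
}

#' Tube width for which division occurs at a given protrusion length
#'
#' Inverse problem used for the elongated phenotype: given a target
#' protrusion length at division, find the tube width (diameter) such that
#' the aspect-ratio threshold is crossed exactly at that length. Wider tubes
#' keep the shape compact longer, so long division lengths correspond to
#' wide (cell-cycle-defective) cells. The solution is taken on the
#' decreasing branch of AR as a function of width.
#'
#' @inheritParams germlingMoments
#' @param lengthUm desired protrusion at division, um.
#' @param targetAR aspect ratio defining division (default 3).
#' @return tube width (diameter) in um.
#' @export
tubeWidthForDivisionLength <- function(bodyRadiusUm, lengthUm,
                                       bipolar = FALSE, targetAR = 3) {
  f <- function(rt) germlingMoments(bodyRadiusUm, rt, lengthUm,
                                    bipolar)$ar - targetAR
  grid <- seq(0.4, min(bodyRadiusUm + lengthUm, 9), by = 0.2)
  v <- vapply(grid, f, numeric(1))
  # last radius on the wide side where AR still exceeds the target
  idx <- which(v > 0)
  if (!length(idx))
    stop("no tube width reaches AR ", targetAR, " at length ", lengthUm)
  i <- max(idx)
  if (i == length(grid))
    stop("AR ", targetAR, " at length ", lengthUm,
         " not bracketed; length too short for this body")
  2 * uniroot(f, c(grid[i], grid[i + 1L]), tol = 1e-8)$root
}

# Effective tube radius during emergence: a tube wider than the body does
# not appear at full width; it widens as it extends (radius capped at
# 0.9 R + L/2) and reaches its final width well before the division length.
# Identity for tubes no wider than the body (the normal phenotype).
.effTubeRadius <- function(rt, bodyR, L) {
  min(rt, 0.9 * bodyR + 0.5 * L)
}

# squared distance between two segments p1-p2 and q1-q2 (each n x 2 rows not
# needed; scalars) -- used by the placement sampler's capsule overlap test
.segSegDist <- function(p1, p2, q1, q2) {
  d1 <- p2 - p1; d2 <- q2 - q1; r <- p1 - q1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a <= 1e-12 && e <= 1e-12) return(sqrt(sum(r * r)))
  if (a <= 1e-12) {
    t <- min(max(f / e, 0), 1)
    return(sqrt(sum((p1 - (q1 + t * d2))^2)))
  }
  c1 <- sum(d1 * r)
  if (e <= 1e-12) {
    s <- min(max(-c1 / a, 0), 1)
    return(sqrt(sum(((p1 + s * d1) - q1)^2)))
  }
  b <- sum(d1 * d2)
  den <- a * e - b * b
  s <- if (den > 1e-12) min(max((b * f - c1 * e) / den, 0), 1) else 0
  t <- (b * s + f) / e
  if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
  else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
  sqrt(sum(((p1 + s * d1) - (q1 + t * d2))^2))
}
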