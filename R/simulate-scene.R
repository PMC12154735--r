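.scenarioDefaults <- function() list(
  n_spores = 40L,
  phenotype_mix = c(normal = 0.60, elongated = 0.10, bubble = 0.07,
                    bipolar = 0.08, exploded = 0.05, dead = 0.10),
  phenotype_counts = NULL,       # exact per-class counts (overrides the mix)
  spore_radius_um = 1.55,        # true dormant area ~7.5 um^2
  spore_radius_sd_um = 0.10,
  lag_mean_min = 240,            # dormancy lag before swelling
  lag_sd_min = 60,
  swell_duration_min = 120,
  swell_area_gain = 0.40,        # isotropic area gain during swelling
  tube_width_um = 2.0,           # germ-tube width; AR-3 division at ~4.7 um
  tube_width_sd_um = 0.08,
  tube_speed_um_per_frame = 0.25,
  elongated_speed_multiplier = 2,
  elongated_outgrowth_range_um = c(7, 20),
  elongated_cutoff_um = 6,
  bipolar_side_speed_um_per_frame = 0.25,
  bubble_growth_frac_per_frame = 0.015,
  bubble_split_extra_min_mean = 120,
  bubble_split_extra_min_sd = 30,
  division_ar = 3.0,
  split_delay_frames = 3L,       # septum becomes visible after the AR crossing
  septum_gap_px = 2L,  # 0.36 um at default calibration; resolvable after blur
  n_debris = 6L,
  debris_area_range_um2 = c(3.5, 8),
  debris_ar_range = c(1.8, 3.0),
  noise_sd = 0.02,
  blur_sigma_px = 0.6,
  bg_level = 0.10,
  cell_level = 0.45,
  focus_loss_frames = integer(0),  # 0-based frame indices rendered defocused
  focus_blur_sigma_px = 6,
  jitter_px = 0,
  vacuole_mode = "off",           # "off" or "two_channel"
  vacuole_body_fraction = 0.64,   # scalar, or c(lo, hi) to draw per cell
  vacuole_noise_sd = 0.01,
  vacuole_bg_level = 0.02,
  pregerminated = NA,             # default: TRUE iff two-channel (dye timing)
  duration_min = 1000,
  frame_interval_min = 10,
  pixel_size_um = 0.18,
  field_size_px = NULL,           # auto from content when NULL
  placement_margin_um = 1.0,
  max_place_tries = 300L,
  seed = 1L
)

#' Create a synthetic-scene scenario
#'
#' Builds a validated \linkS4class{ScenarioConfig} for
#' \code{\link{simulateScene}}. Defaults emulate the germination cytology of
#' fission-yeast spores plated under agar: circular dormant spores of true
#' area about 7-9 um^2, a gamma-distributed dormancy lag (mean 240 min),
#' isotropic swelling (+40 percent area over 120 min, aspect ratio flat),
#' then polarized tube outgrowth with the first division when the cell's
#' analytic aspect ratio reaches 3 (around 4.7 um of outgrowth for normal
#' cells), imaging every 10 min for 1000 min. Aberrant classes: elongated
#' cells divide at a drawn outgrowth of 7-20 um (tube width solved so the
#' AR-3 crossing lands there), bubbles keep growing isotropically and split
#' while still circular, bipolar cells grow tubes from both poles, exploded
#' cells fragment and vanish, dead spores never change. Debris are small
#' elongated static blobs. \code{vacuole_mode = "two_channel"} adds a second
#' channel whose per-cell signal is split between spore body and outgrowth
#' at \code{vacuole_body_fraction} (cells then start pre-germinated, as in a
#' stain-after-liquid-germination protocol).
#'
#' @param ... named overrides of the defaults listed above.
#' @return A \linkS4class{ScenarioConfig}.
#' @export
scenarioConfig <- function(...) {
  over <- list(...)
  defs <- .scenarioDefaults()
  bad <- setdiff(names(over), names(defs))
  if (length(bad))
    stop("unknown scenario parameter(s): ", paste(bad, collapse = ", "))
  p <- utils::modifyList(defs, over)
  if (!is.null(over$phenotype_mix)) {
    m <- over$phenotype_mix
    if (is.null(names(m))) stop("phenotype_mix must be named")
    full <- setNames(numeric(6), names(defs$phenotype_mix))
    full[names(m)] <- m
    p$phenotype_mix <- full / sum(full)
    if (sum(m) <= 0) stop("phenotype_mix must have positive mass")
  }
  if (!is.null(p$phenotype_counts)) {
    pc <- p$phenotype_counts
    if (is.null(names(pc)) ||
        !all(names(pc) %in% names(defs$phenotype_mix)))
      stop("phenotype_counts must be named with the six phenotype classes")
    if (any(pc < 0) || any(pc != round(pc)))
      stop("phenotype_counts must be non-negative integers")
    p$n_spores <- as.integer(sum(pc))
  }
  if (is.na(p$pregerminated))
    p$pregerminated <- identical(p$vacuole_mode, "two_channel")
  p$n_spores <- as.integer(p$n_spores)
  p$n_debris <- as.integer(p$n_debris)
  p$seed <- as.integer(p$seed)
  p$split_delay_frames <- as.integer(p$split_delay_frames)
  p$focus_loss_frames <- as.integer(p$focus_loss_frames)
  new("ScenarioConfig", params = p)
}

# deterministic scoped RNG: run expr under a seed, restore global state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(expr)
}

# cell radius at 0-based frame f (analytic)
.cellRadiusAt <- function(cell, f) {
  if (cell$phenotype == "dead") return(cell$r0)
  if (f < cell$lag_frames) return(cell$r0)
  if (cell$swell_frames > 0 && f < cell$outgrowth_start) {
    frac <- (f - cell$lag_frames + 1) / cell$swell_frames
    return(cell$r0 * sqrt(1 + cell$swell_gain * min(frac, 1)))
  }
  r <- cell$r_swollen
  if (cell$phenotype == "bubble" && f >= cell$outgrowth_start) {
    g <- min(f, cell$split_planned) - cell$outgrowth_start
    r <- r * (1 + cell$bubble_growth)^(g / 2)  # area grows at bubble rate
  }
  r
}

# tube protrusion at 0-based frame f (analytic; 0 for non-tube phenotypes)
.cellProtrusionAt <- function(cell, f) {
  if (!cell$phenotype %in% c("normal", "elongated", "bipolar", "exploded"))
    return(0)
  if (f < cell$outgrowth_start) return(0)
  fEff <- min(f, cell$split_planned)
  if (cell$phenotype == "exploded" && !is.na(cell$explode_frame))
    fEff <- min(fEff, cell$explode_frame)
  max(0, cell$speed * (fEff - cell$outgrowth_start))
}

#' Simulate a germination timelapse with ground truth
#'
#' Renders a synthetic transmitted-light timelapse (and optionally a second
#' vacuole-dye channel) of germinating spores together with per-frame ground
#' -truth label masks and a complete event table. Output is deterministic
#' given the scenario seed: the per-cell random draws are consumed in cell-ID
#' order, then debris draws, then placement, then per-frame image noise, so
#' truth and masks are identical whether or not the image is rendered.
#'
#' @param scenario a \linkS4class{ScenarioConfig}.
#' @param render \code{"both"} (default) renders intensity frames and label
#'   masks; \code{"labels"} skips the intensity rendering (fast path for
#'   large scenes where only masks and truth are needed).
#' @return A list with components \code{image} (\linkS4class{ImageStack} or
#'   \code{NULL}), \code{labels} (\linkS4class{LabelStack}, the ground-truth
#'   masks), and \code{truth}: a list with \code{cells} (one row per spore:
#'   phenotype, t0 centre/radius, kinematic parameters, true division /
#'   split / explode frames, true outgrowth at division, vacuole body
#'   fraction, child labels), \code{debris}, \code{focus_loss_frames},
#'   \code{field} and \code{params}. Frame indices in the truth are 0-based
#'   (frame 0 = time point zero).
#' @export
simulateScene <- function(scenario, render = c("both", "labels")) {
  stopifnot(is(scenario, "ScenarioConfig"))
  render <- match.arg(render)
  p <- scenario@params
  validObject(scenario)
  .withSeed(p$seed, .simulateSceneImpl(p, render))
}

.simulateSceneImpl <- function(p, render) {
  pxsz <- p$pixel_size_um
  tInt <- p$frame_interval_min
  nT <- as.integer(floor(p$duration_min / tInt)) + 1L
  nC <- p$n_spores
  twoCh <- identical(p$vacuole_mode, "two_channel")

  ## ---- per-cell draws, consumed in cell-ID order ----
  phenos <- if (nC > 0) {
    if (!is.null(p$phenotype_counts)) {
      # exact composition: the class counts are fixed, positions shuffled
      sample(rep(names(p$phenotype_counts), p$phenotype_counts))
    } else {
      sample(names(p$phenotype_mix), nC, replace = TRUE,
             prob = p$phenotype_mix)
    }
  } else character(0)
  cells <- vector("list", nC)
  lagShape <- (p$lag_mean_min / max(p$lag_sd_min, 1e-6))^2
  lagScale <- p$lag_mean_min / lagShape
  for (i in seq_len(nC)) {
    ph <- phenos[i]
    r0 <- max(0.8, rnorm(1, p$spore_radius_um, p$spore_radius_sd_um))
    lagMin <- rgamma(1, shape = lagShape, scale = lagScale)
    wJit <- rnorm(1, 0, p$tube_width_sd_um)
    thet <- runif(1, 0, 2 * pi)
    extraDraw <- runif(1)       # phenotype-specific draw (one per cell)
    if (p$pregerminated) {
      r0 <- r0 * sqrt(1 + p$swell_area_gain)
      gain <- 0
      lagFrames <- max(0L, as.integer(round(lagMin / (4 * tInt))))
      swellFrames <- 0L
    } else {
      gain <- p$swell_area_gain
      lagFrames <- max(0L, as.integer(round(lagMin / tInt)))
      swellFrames <- max(1L, as.integer(round(p$swell_duration_min / tInt)))
    }
    rSw <- r0 * sqrt(1 + gain)
    tO <- lagFrames + swellFrames
    cell <- list(cell_id = i, phenotype = ph, r0 = r0, r_swollen = rSw,
                 swell_gain = gain, lag_frames = lagFrames,
                 swell_frames = swellFrames, outgrowth_start = tO,
                 theta = thet, tube_radius = NA_real_, speed = NA_real_,
                 division_length = NA_real_, division_frame = NA_integer_,
                 split_planned = nT + p$split_delay_frames + 10L,
                 explode_frame = NA_integer_, bubble_growth = NA_real_,
                 bipolar = FALSE, vac_fraction = NA_real_)
    if (ph %in% c("normal", "exploded")) {
      cell$tube_radius <- max(0.6, p$tube_width_um / 2 + wJit / 2)
      cell$speed <- p$tube_speed_um_per_frame
      cell$division_length <- divisionLengthForGeometry(
        rSw, cell$tube_radius, bipolar = FALSE, targetAR = p$division_ar)
    } else if (ph == "elongated") {
      rng <- p$elongated_outgrowth_range_um
      Ldiv <- rng[1] + extraDraw * (rng[2] - rng[1])
      cell$tube_radius <- tubeWidthForDivisionLength(
        rSw, Ldiv, bipolar = FALSE, targetAR = p$division_ar) / 2
      cell$speed <- p$tube_speed_um_per_frame * p$elongated_speed_multiplier
      cell$division_length <- Ldiv
    } else if (ph == "bipolar") {
      cell$bipolar <- TRUE
      cell$tube_radius <- max(0.6, p$tube_width_um / 2 + wJit / 2)
      cell$speed <- p$bipolar_side_speed_um_per_frame
      cell$division_length <- divisionLengthForGeometry(
        rSw, cell$tube_radius, bipolar = TRUE, targetAR = p$division_ar)
    } else if (ph == "bubble") {
      cell$bubble_growth <- p$bubble_growth_frac_per_frame
      extraMin <- max(tInt, p$bubble_split_extra_min_mean +
                        (extraDraw - 0.5) * 2 * 1.6 *
                        p$bubble_split_extra_min_sd)
      cell$split_planned <- tO + as.integer(round(extraMin / tInt))
      cell$division_frame <- if (cell$split_planned < nT)
        cell$split_planned else NA_integer_
    }
    if (ph %in% c("normal", "elongated", "bipolar")) {
      d <- tO + as.integer(ceiling(cell$division_length / cell$speed))
      cell$split_planned <- d + p$split_delay_frames
      cell$division_frame <- if (d < nT) d else NA_integer_
      cell$division_frame_planned <- d
    } else if (ph == "exploded") {
      d <- tO + as.integer(ceiling(cell$division_length / cell$speed))
      cell$explode_frame <- tO + max(1L, as.integer(floor(
        (0.3 + 0.5 * extraDraw) * (d - tO))))
      if (cell$explode_frame >= nT) cell$explode_frame <- NA_integer_
      cell$division_frame <- NA_integer_
      cell$split_planned <- nT + 10L
    }
    if (twoCh) {
      vf <- p$vacuole_body_fraction
      cell$vac_fraction <- if (length(vf) == 2L)
        vf[1] + runif(1) * (vf[2] - vf[1]) else vf
      if (cell$vac_fraction < 0 || cell$vac_fraction > 1)
        stop("vacuole body fraction outside [0, 1]")
    }
    cells[[i]] <- cell
  }
  # fragment geometry for exploded cells (drawn after the per-cell block)
  for (i in seq_len(nC)) {
    if (cells[[i]]$phenotype == "exploded") {
      k <- 4L
      ang <- runif(k, 0, 2 * pi)
      rad <- runif(k, 0.3, 0.9) * cells[[i]]$r_swollen
      cells[[i]]$frag_dx <- rad * cos(ang)
      cells[[i]]$frag_dy <- rad * sin(ang)
      cells[[i]]$frag_r <- runif(k, 0.55, 0.75)
    }
  }

  ## ---- debris draws ----
  nD <- p$n_debris
  debris <- NULL
  if (nD > 0) {
    dA <- runif(nD, p$debris_area_range_um2[1], p$debris_area_range_um2[2])
    dAR <- runif(nD, p$debris_ar_range[1], p$debris_ar_range[2])
    dTh <- runif(nD, 0, 2 * pi)
    db <- sqrt(dA / (pi * dAR))
    debris <- data.frame(debris_id = seq_len(nD), area_um2 = dA,
                         semi_major_um = dAR * db, semi_minor_um = db,
                         theta = dTh, x_um = NA_real_, y_um = NA_real_)
  }

  ## ---- placement (capsule rejection sampling) ----
  reach <- vapply(seq_len(nC), function(i) {
    cell <- cells[[i]]
    Lmax <- if (!is.na(cell$speed))
      cell$speed * max(0, min(cell$split_planned, nT - 1L) -
                         cell$outgrowth_start) else 0
    rr <- max(.cellRadiusAt(cell, min(cell$split_planned, nT - 1L)),
              cell$r_swollen)
    rr + Lmax
  }, numeric(1))
  capRad <- vapply(seq_len(nC), function(i)
    max(cells[[i]]$r_swollen * 1.3,
        if (is.na(cells[[i]]$tube_radius)) 0 else cells[[i]]$tube_radius) +
      p$placement_margin_um, numeric(1))
  segLen <- vapply(seq_len(nC), function(i) {
    if (is.na(cells[[i]]$speed)) 0 else reach[i]
  }, numeric(1))
  foot <- sum((segLen + 2 * capRad) * 2 * capRad) +
    (if (nD > 0) sum(4 * (debris$semi_major_um + 1)^2) else 0)
  sideUm <- if (is.null(p$field_size_px))
    max(25, sqrt(foot * 3.6)) else p$field_size_px * pxsz
  W <- H <- as.integer(ceiling(sideUm / pxsz))
  sideUm <- W * pxsz

  placed <- list()  # each: p1, p2, rad
  place <- function(rad, len, theta, bip) {
    for (try in seq_len(p$max_place_tries)) {
      cx <- runif(1, rad, sideUm - rad)
      cy <- runif(1, rad, sideUm - rad)
      u <- c(cos(theta), sin(theta))
      p2 <- c(cx, cy) + u * len
      p1 <- if (bip) c(cx, cy) - u * len else c(cx, cy)
      if (any(c(p1, p2) < rad) || any(c(p1, p2) > sideUm - rad)) next
      ok <- TRUE
      for (q in placed) {
        if (.segSegDist(p1, p2, q$p1, q$p2) < rad + q$rad) { ok <- FALSE; break }
      }
      if (ok) return(list(p1 = p1, p2 = p2, rad = rad, cx = cx, cy = cy))
    }
    stop("over-dense placement: could not place all objects; ",
         "reduce counts or enlarge field_size_px")
  }
  for (i in seq_len(nC)) {
    pos <- place(capRad[i], segLen[i], cells[[i]]$theta, cells[[i]]$bipolar)
    cells[[i]]$x <- pos$cx; cells[[i]]$y <- pos$cy
    placed[[length(placed) + 1L]] <- pos
  }
  if (nD > 0) for (j in seq_len(nD)) {
    pos <- place(debris$semi_major_um[j] + 0.5, 0, 0, FALSE)
    debris$x_um[j] <- pos$cx; debris$y_um[j] <- pos$cy
    placed[[length(placed) + 1L]] <- pos
  }

  ## ---- optional per-frame centroid jitter ----
  jit <- NULL
  if (p$jitter_px > 0 && nC > 0) {
    jit <- array(runif(nC * nT * 2, -p$jitter_px, p$jitter_px) * pxsz,
                 c(nC, nT, 2L))
  }

  ## ---- label bookkeeping ----
  childBase <- nC + nD
  fragBase <- childBase + 2L * nC
  for (i in seq_len(nC)) {
    cells[[i]]$label <- i
    cells[[i]]$child1 <- childBase + 2L * i - 1L
    cells[[i]]$child2 <- childBase + 2L * i
  }

  ## ---- rasterize ----
  lab <- array(0L, c(H, W, nT))
  v2 <- if (twoCh) array(0, c(H, W, nT)) else NULL
  gapHalf <- p$septum_gap_px * pxsz / 2 + 1e-9
  HW <- as.double(H) * W

  # build one cell's stamp at frame f: within-frame linear pixel indices,
  # their labels and (optionally) channel-2 values, plus a geometry key so
  # static stretches (dormancy, dead cells, frozen post-split shapes) are
  # rasterized once and reused
  computeStamp <- function(i, f) {
    cell <- cells[[i]]
    if (cell$phenotype == "exploded" && !is.na(cell$explode_frame) &&
        f >= cell$explode_frame) {
      if (f > cell$explode_frame + 1L)
        return(list(key = "gone", idx = integer(0), labv = integer(0),
                    v2v = NULL))
      idx <- integer(0); labv <- integer(0)
      for (k in seq_along(cell$frag_r)) {
        fx <- cell$x + cell$frag_dx[k]; fy <- cell$y + cell$frag_dy[k]
        rr <- cell$frag_r[k]
        j0 <- max(1L, floor((fx - rr - pxsz) / pxsz))
        j1 <- min(W, ceiling((fx + rr + pxsz) / pxsz))
        i0 <- max(1L, floor((fy - rr - pxsz) / pxsz))
        i1 <- min(H, ceiling((fy + rr + pxsz) / pxsz))
        if (j1 < j0 || i1 < i0) next
        xs <- (seq.int(j0, j1) - 0.5) * pxsz - fx
        ys <- (seq.int(i0, i1) - 0.5) * pxsz - fy
        m <- outer(ys^2, xs^2, "+") <= rr^2
        ai <- which(m, arr.ind = TRUE)
        if (nrow(ai)) {
          idx <- c(idx, (j0 - 2L + ai[, 2L]) * H + (i0 - 1L + ai[, 1L]))
          labv <- c(labv, rep(fragBase + 4L * (i - 1L) + k, nrow(ai)))
        }
      }
      return(list(key = "frag", idx = idx, labv = labv, v2v = NULL))
    }
    r <- .cellRadiusAt(cell, f)
    L <- .cellProtrusionAt(cell, f)
    cx <- cell$x; cy <- cell$y
    if (!is.null(jit)) { cx <- cx + jit[i, f + 1L, 1L]; cy <- cy + jit[i, f + 1L, 2L] }
    hasSplit <- f >= cell$split_planned && !is.na(cell$division_frame)
    key <- paste(r, L, hasSplit, cx, cy)
    if (identical(key, cells[[i]]$stamp_key))
      return(NULL)   # geometry unchanged: caller reuses the cached stamp
    rt <- if (is.na(cell$tube_radius)) r else
      .effTubeRadius(cell$tube_radius, r, L)
    ext <- r + L + 2 * pxsz
    j0 <- max(1L, floor((cx - ext) / pxsz)); j1 <- min(W, ceiling((cx + ext) / pxsz))
    i0 <- max(1L, floor((cy - ext) / pxsz)); i1 <- min(H, ceiling((cy + ext) / pxsz))
    if (j1 < j0 || i1 < i0)
      return(list(key = key, idx = integer(0), labv = integer(0), v2v = NULL))
    xs <- (seq.int(j0, j1) - 0.5) * pxsz - cx
    ys <- (seq.int(i0, i1) - 0.5) * pxsz - cy
    ux <- cos(cell$theta); uy <- sin(cell$theta)
    S <- outer(ys * uy, xs * ux, "+")
    Q <- outer(ys * ux, -xs * uy, "+")
    mask <- S * S + Q * Q <= r * r
    if (L > 0) {
      s0 <- r + L - rt
      Sa <- if (cell$bipolar) abs(S) else S
      tube <- (Sa >= 0 & Sa <= max(s0, 0) & abs(Q) <= rt) |
        ((Sa - s0)^2 + Q * Q <= rt * rt)
      mask <- mask | tube
    }
    if (hasSplit) {
      sSep <- cell$septum_s
      side1 <- mask & (S <= sSep - gapHalf)
      side2 <- mask & (S >= sSep + gapHalf)
      mask <- side1 | side2
      labm <- matrix(0L, nrow(mask), ncol(mask))
      labm[side1] <- cell$child1
      labm[side2] <- cell$child2
    } else {
      labm <- NULL
    }
    ai <- which(mask, arr.ind = TRUE)
    if (!nrow(ai))
      return(list(key = key, idx = integer(0), labv = integer(0), v2v = NULL))
    idx <- (j0 - 2L + ai[, 2L]) * H + (i0 - 1L + ai[, 1L])
    labv <- if (is.null(labm)) rep(cell$label, nrow(ai)) else labm[mask]
    v2v <- NULL
    if (twoCh) {
      body <- (S * S + Q * Q <= cell$r0 * cell$r0) & mask
      bodyv <- body[mask]
      nb <- sum(bodyv); no <- length(bodyv) - nb
      Itot <- 0.25 * pi * cell$r0^2 / (pxsz * pxsz)
      fb <- cell$vac_fraction
      vb <- if (nb > 0) fb * Itot / nb else 0
      vo <- if (no > 0) (1 - fb) * Itot / no else 0
      if (no == 0) vb <- Itot / max(nb, 1L)
      sc <- min(1, 0.85 / max(vb, vo))
      v2v <- ifelse(bodyv, vb * sc, vo * sc)
    }
    list(key = key, idx = idx, labv = labv, v2v = v2v)
  }

  # septum position: analytic centroid offset at the division frame
  for (i in seq_len(nC)) {
    cell <- cells[[i]]
    if (!is.na(cell$division_frame)) {
      if (cell$phenotype == "bubble") {
        cells[[i]]$septum_s <- 0
      } else {
        Ld <- .cellProtrusionAt(cell, cell$split_planned)
        cells[[i]]$septum_s <- if (cell$bipolar) 0 else
          germlingMoments(cell$r_swollen, cell$tube_radius, Ld)$xbar
      }
    }
  }

  # debris are static: rasterize once
  dStamp <- NULL
  if (nD > 0) {
    dIdx <- integer(0); dLab <- integer(0)
    for (jd in seq_len(nD)) {
      a <- debris$semi_major_um[jd]; b <- debris$semi_minor_um[jd]
      th <- debris$theta[jd]
      cx <- debris$x_um[jd]; cy <- debris$y_um[jd]
      j0 <- max(1L, floor((cx - a - pxsz) / pxsz))
      j1 <- min(W, ceiling((cx + a + pxsz) / pxsz))
      i0 <- max(1L, floor((cy - a - pxsz) / pxsz))
      i1 <- min(H, ceiling((cy + a + pxsz) / pxsz))
      xs <- (seq.int(j0, j1) - 0.5) * pxsz - cx
      ys <- (seq.int(i0, i1) - 0.5) * pxsz - cy
      ux <- cos(th); uy <- sin(th)
      S <- outer(ys * uy, xs * ux, "+")
      Q <- outer(ys * ux, -xs * uy, "+")
      m <- (S / a)^2 + (Q / b)^2 <= 1
      ai <- which(m, arr.ind = TRUE)
      if (nrow(ai)) {
        dIdx <- c(dIdx, (j0 - 2L + ai[, 2L]) * H + (i0 - 1L + ai[, 1L]))
        dLab <- c(dLab, rep(nC + jd, nrow(ai)))
      }
    }
    dStamp <- list(idx = dIdx, labv = dLab)
  }

  stampCache <- vector("list", nC)
  for (f in seq_len(nT) - 1L) {
    off <- f * HW
    for (i in seq_len(nC)) {
      st <- computeStamp(i, f)
      if (is.null(st)) {
        st <- stampCache[[i]]
      } else {
        stampCache[[i]] <- st
        cells[[i]]$stamp_key <- st$key
      }
      if (length(st$idx)) {
        lab[st$idx + off] <- st$labv
        if (twoCh && !is.null(st$v2v)) v2[st$idx + off] <- st$v2v
      }
    }
    if (!is.null(dStamp) && length(dStamp$idx))
      lab[dStamp$idx + off] <- dStamp$labv
  }

  ## ---- intensity rendering (after all geometry; noise drawn per frame) ----
  img <- NULL
  if (render == "both") {
    dims <- if (twoCh) c(H, W, nT, 2L) else c(H, W, nT)
    img <- array(0, dims)
    focusSet <- p$focus_loss_frames
    for (f in seq_len(nT) - 1L) {
      tt <- f + 1L
      base <- p$bg_level + p$cell_level * (lab[, , tt] > 0L)
      sig <- if (f %in% focusSet) p$focus_blur_sigma_px else p$blur_sigma_px
      if (sig > 0) base <- as.matrix(EBImage::gblur(base, sigma = sig))
      fr1 <- base + rnorm(H * W, 0, p$noise_sd)
      fr1 <- pmin(pmax(fr1, 0), 1)
      if (twoCh) {
        c2 <- p$vacuole_bg_level + v2[, , tt]
        if (sig > 0 && f %in% focusSet)
          c2 <- as.matrix(EBImage::gblur(c2, sigma = sig))
        c2 <- c2 + rnorm(H * W, 0, p$vacuole_noise_sd)
        img[, , tt, 1L] <- fr1
        img[, , tt, 2L] <- pmin(pmax(c2, 0), 1)
      } else {
        img[, , tt] <- fr1
      }
    }
    img <- imageStack(img, pixelSizeUm = pxsz, frameIntervalMin = tInt,
                      channelNames = if (twoCh) c("TL", "FM4-64") else "TL")
  }

  cellDf <- if (nC > 0) do.call(rbind, lapply(cells, function(cell) {
    data.frame(cell_id = cell$cell_id, label = cell$label,
               phenotype = cell$phenotype,
               x_um = cell$x, y_um = cell$y, theta = cell$theta,
               r0_um = cell$r0, r_swollen_um = cell$r_swollen,
               tube_radius_um = cell$tube_radius,
               lag_frames = cell$lag_frames,
               swell_frames = cell$swell_frames,
               outgrowth_start_frame = cell$outgrowth_start,
               speed_um_per_frame = cell$speed,
               division_length_um = cell$division_length,
               division_frame = cell$division_frame,
               split_frame = if (!is.na(cell$division_frame) &&
                                 cell$split_planned < nT)
                 cell$split_planned else NA_integer_,
               explode_frame = cell$explode_frame,
               vacuole_body_fraction = cell$vac_fraction,
               child1_label = cell$child1, child2_label = cell$child2,
               bubble_growth = cell$bubble_growth)
  })) else data.frame()
  # true outgrowth length at the division frame (frame-quantized)
  if (nC > 0) {
    cellDf$outgrowth_at_division_um <- vapply(seq_len(nC), function(i) {
      cell <- cells[[i]]
      if (is.na(cell$division_frame) || cell$phenotype == "bubble")
        return(NA_real_)
      .cellProtrusionAt(cell, cell$division_frame)
    }, numeric(1))
  }

  truth <- list(cells = cellDf, debris = debris,
                focus_loss_frames = p$focus_loss_frames,
                field = list(width_px = W, height_px = H,
                             pixel_size_um = pxsz, n_frames = nT,
                             frame_interval_min = tInt),
                params = p)
  class(truth) <- "SceneGroundTruth"
  list(image = img,
       labels = labelStack(lab, pixelSizeUm = pxsz, frameIntervalMin = tInt),
       truth = truth)
}

#' @export
print.SceneGroundTruth <- function(x, ...) {
  cat(sprintf("SceneGroundTruth: %d cell(s), %d debris, %d frame(s) (%d x %d px)\n",
              nrow(x$cells), if (is.null(x$debris)) 0L else nrow(x$debris),
              x$field$n_frames, x$field$height_px, x$field$width_px))
  if (nrow(x$cells))
    print(table(x$cells$phenotype))
  invisible(x)
}

#' Analytic per-frame trajectories of a simulated scene
#'
#' Evaluates the generator's closed-form kinematics (radius, protrusion,
#' moment-ellipse area and aspect ratio) for every cell at every frame.
#' These are the analytic expectations rasterized measurements are compared
#' against; they never touch the rendered images.
#'
#' @param truth the \code{truth} component returned by
#'   \code{\link{simulateScene}}.
#' @param cellIds optional subset of cell ids.
#' @return data.frame with \code{cell_id, frame, radius_um, protrusion_um,
#'   area_um2, aspect_ratio} (frames 0-based; rows stop at a cell's split or
#'   explosion).
#' @export
truthTrajectories <- function(truth, cellIds = NULL) {
  stopifnot(inherits(truth, "SceneGroundTruth"))
  nT <- truth$field$n_frames
  cd <- truth$cells
  if (!is.null(cellIds)) cd <- cd[cd$cell_id %in% cellIds, , drop = FALSE]
  out <- vector("list", nrow(cd))
  for (k in seq_len(nrow(cd))) {
    row <- cd[k, ]
    cell <- list(phenotype = row$phenotype, r0 = row$r0_um,
                 r_swollen = row$r_swollen_um, swell_gain =
                   (row$r_swollen_um / row$r0_um)^2 - 1,
                 lag_frames = row$lag_frames, swell_frames = row$swell_frames,
                 outgrowth_start = row$outgrowth_start_frame,
                 speed = row$speed_um_per_frame,
                 split_planned = if (!is.na(row$split_frame)) row$split_frame
                 else nT + 10L,
                 explode_frame = if (!is.na(row$explode_frame))
                   row$explode_frame else nT + 10L,
                 bubble_growth = row$bubble_growth,
                 bipolar = identical(row$phenotype, "bipolar"))
    lastF <- nT - 1L
    if (!is.na(row$split_frame)) lastF <- row$split_frame - 1L
    if (!is.na(row$explode_frame)) lastF <- row$explode_frame - 1L
    fr <- 0:lastF
    rad <- vapply(fr, function(f) .cellRadiusAt(cell, f), numeric(1))
    pro <- vapply(fr, function(f) .cellProtrusionAt(cell, f), numeric(1))
    area <- ar <- numeric(length(fr))
    for (j in seq_along(fr)) {
      rtj <- if (is.na(row$tube_radius_um)) rad[j] else
        .effTubeRadius(row$tube_radius_um, rad[j], pro[j])
      m <- germlingMoments(rad[j], rtj, pro[j], bipolar = cell$bipolar)
      area[j] <- m$area; ar[j] <- m$ar
    }
    out[[k]] <- data.frame(cell_id = row$cell_id, frame = fr,
                           radius_um = rad, protrusion_um = pro,
                           area_um2 = area, aspect_ratio = ar)
  }
  do.call(rbind, out)
}

#' Write or read scene ground truth as JSON
#'
#' @param truth a \code{SceneGroundTruth} list.
#' @param path JSON file path.
#' @return \code{writeGroundTruth}: \code{path} invisibly;
#'   \code{readGroundTruth}: the ground-truth list.
#' @export
writeGroundTruth <- function(truth, path) {
  stopifnot(inherits(truth, "SceneGroundTruth"))
  x <- unclass(truth)
  x$params <- x$params[setdiff(names(x$params), "field_size_px")]
  jsonlite::write_json(x, path, dataframe = "columns", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$cells <- as.data.frame(x$cells)
  class(x) <- "SceneGroundTruth"
  x
}
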