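## Ring-geometry analysis of height maps: subunit peak detection with
## topographic prominence, rotational symmetry order by autocorrelation,
## least-squares ring fit, central protrusion/pore scoring, oligomer
## classification and per-patch aggregation.

## bilinear interpolation of a height map at (x, y) in nm (vectorized)
.bilinear <- function(hm, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  g <- hm@grid
  fx <- (x - g@origin[1]) / g@pixelSize + 1
  fy <- (y - g@origin[2]) / g@pixelSize + 1
  i0 <- pmin(pmax(floor(fx), 1), g@nx - 1)
  j0 <- pmin(pmax(floor(fy), 1), g@ny - 1)
  tx <- fx - i0; ty <- fy - j0
  h <- hm@heights
  idx <- function(i, j) h[cbind(i, j)]
  (1 - tx) * (1 - ty) * idx(i0, j0) + tx * (1 - ty) * idx(i0 + 1, j0) +
    (1 - tx) * ty * idx(i0, j0 + 1) + tx * ty * idx(i0 + 1, j0 + 1)
}

## union-find flood from the top: returns candidate peaks (linear pixel
## index) with their topographic prominence (height above the highest
## saddle connecting them to higher ground)
.peakProminence <- function(h) {
  nx <- nrow(h); ny <- ncol(h); n <- nx * ny
  ord <- order(h, decreasing = TRUE)            # ties: scan order
  parent <- integer(n)                          # 0 = unassigned
  peakPix <- integer(n); peakH <- numeric(n)    # per-root component info
  prom <- rep(NA_real_, n)
  isPeak <- logical(n)
  findRoot <- function(i) {
    r <- i
    while (parent[r] != r) r <- parent[r]
    while (parent[i] != r) { nxt <- parent[i]; parent[i] <<- r; i <- nxt }
    r
  }
  di <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
  dj <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  for (p in ord) {
    i <- ((p - 1L) %% nx) + 1L
    j <- ((p - 1L) %/% nx) + 1L
    ni <- i + di; nj <- j + dj
    ok <- ni >= 1L & ni <= nx & nj >= 1L & nj <= ny
    nb <- ni[ok] + (nj[ok] - 1L) * nx
    nb <- nb[parent[nb] != 0L]
    if (length(nb) == 0L) {
      parent[p] <- p; peakPix[p] <- p; peakH[p] <- h[p]; isPeak[p] <- TRUE
    } else {
      roots <- unique(vapply(nb, findRoot, integer(1)))
      win <- roots[which.max(peakH[roots])]
      parent[p] <- win
      for (r in roots[roots != win]) {
        prom[peakPix[r]] <- peakH[r] - h[p]
        parent[r] <- win
      }
    }
  }
  left <- which(isPeak & is.na(prom))
  prom[left] <- h[left] - min(h)
  data.frame(pixel = which(isPeak), prominence = prom[isPeak])
}

#' Detect subunit peaks in a height map
#'
#' Local maxima of the (smoothed) topograph with topographic prominence at
#' least \code{minProminence}, thinned so that no two retained peaks are
#' closer than \code{minSeparation} (the higher peak wins; ties broken by
#' scan order). Peak positions are refined to sub-pixel precision by a
#' separable quadratic fit on the 3 x 3 neighborhood, which matters because
#' rings of interest (2.8 - 4.9 nm diameter) span few pixels at coarse
#' sampling.
#'
#' Maps that are not already low-pass filtered are smoothed with the same
#' 2 nm gaussian cutoff the simulator uses, so experimental-style and
#' simulated maps are treated identically; pass \code{smoothCutoff = 0} to
#' disable.
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param minProminence nm.
#' @param minSeparation nm, must be >= the pixel size.
#' @param smoothCutoff nm; pre-detection low-pass cutoff applied unless the
#'   map provenance is already \code{"filtered"} (0 disables).
#' @return data.frame with one row per peak: \code{x}, \code{y} (nm),
#'   \code{height} (nm), \code{prominence} (nm), ordered by height
#'   (decreasing). A flat or empty map yields zero rows.
#' @export
detectSubunitPeaks <- function(hm, minProminence = 0.15, minSeparation = 1.0,
                               smoothCutoff = 2) {
  ps <- hm@grid@pixelSize
  if (minSeparation < ps)
    stop("minSeparation must be >= pixel size")
  if (smoothCutoff > 0 && hm@provenance != "filtered")
    hm <- lowpassFilter(hm, FilterSpec(max(smoothCutoff, 2 * ps)))
  h <- hm@heights
  cand <- .peakProminence(h)
  cand <- cand[cand$prominence >= minProminence, , drop = FALSE]
  empty <- data.frame(x = numeric(0), y = numeric(0), height = numeric(0),
                      prominence = numeric(0))
  if (nrow(cand) == 0) return(empty)
  nx <- nrow(h)
  ci <- ((cand$pixel - 1L) %% nx) + 1L
  cj <- ((cand$pixel - 1L) %/% nx) + 1L
  hh <- h[cand$pixel]
  o <- order(-hh, ci, cj)
  ci <- ci[o]; cj <- cj[o]; hh <- hh[o]; pr <- cand$prominence[o]
  ax <- gridAxes(hm)
  keep <- integer(0)
  for (k in seq_along(ci)) {
    if (length(keep) > 0) {
      dd <- sqrt((ax$x[ci[keep]] - ax$x[ci[k]])^2 +
                 (ax$y[cj[keep]] - ax$y[cj[k]])^2)
      if (any(dd < minSeparation)) next
    }
    keep <- c(keep, k)
  }
  refine <- function(i, j) {
    off <- function(m1, m0, p1) {
      den <- 2 * (2 * m0 - m1 - p1)
      if (abs(den) < 1e-15) return(0)
      max(-0.5, min(0.5, (p1 - m1) / den))
    }
    dx <- if (i > 1 && i < nrow(h)) off(h[i - 1, j], h[i, j], h[i + 1, j]) else 0
    dy <- if (j > 1 && j < ncol(h)) off(h[i, j - 1], h[i, j], h[i, j + 1]) else 0
    c(ax$x[i] + dx * ps, ax$y[j] + dy * ps)
  }
  pos <- t(mapply(refine, ci[keep], cj[keep]))
  data.frame(x = pos[, 1], y = pos[, 2], height = hh[keep],
             prominence = pr[keep])
}

#' Estimate the rotational symmetry order of a ring
#'
#' Computes the normalized rotational autocorrelation
#' C(n) = cor(h, rotate(h, 2 pi / n)) on an annulus around the ring center,
#' sampled on a polar grid with bilinear interpolation, and returns the
#' winning order together with all C(n) values (used downstream for the
#' classification confidence). A rotationally uniform ring (all C(n) nearly
#' equal) is flagged low-confidence.
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param center 2-vector, nm.
#' @param orders candidate symmetry orders, a subset of 2..8.
#' @param rIn,rOut annulus radii, nm; when \code{NULL} the annulus is
#'   placed around the crest of the azimuthally averaged radial profile
#'   (searched at radii >= 0.6 nm so a central protrusion is not mistaken
#'   for the ring crest).
#' @return list with \code{order} (integer), \code{scores} (named numeric
#'   C(n)), \code{confidence} (margin of the winner over the runner-up,
#'   clipped to [0, 1]) and \code{lowConfidence} (logical).
#' @export
estimateSymmetryOrder <- function(hm, center, orders = 2:8,
                                  rIn = NULL, rOut = NULL) {
  stopifnot(all(orders %in% 2:8), length(orders) >= 2)
  ax <- gridAxes(hm)
  rEdge <- min(center[1] - ax$x[1], ax$x[length(ax$x)] - center[1],
               center[2] - ax$y[1], ax$y[length(ax$y)] - center[2])
  if (rEdge <= hm@grid@pixelSize)
    stop("center too close to the map edge for an annulus")
  if (is.null(rIn) || is.null(rOut)) {
    prof <- radialProfile(hm, center, rMax = rEdge)
    sel <- prof$r >= 0.6
    rc <- prof$r[sel][which.max(prof$h[sel])]
    rIn <- 0.55 * rc
    rOut <- 1.45 * rc
  }
  if (rOut > rEdge)
    stop("annulus (rOut = ", signif(rOut, 3),
         " nm) leaves the map (edge distance ", signif(rEdge, 3), " nm)")
  nth <- 720L
  nr <- 16L
  rr <- seq(rIn, rOut, length.out = nr)
  th <- seq(0, 2 * pi, length.out = nth + 1L)[-(nth + 1L)]
  sample_at <- function(shift) {
    t2 <- outer(th + shift, rep(1, nr))
    r2 <- outer(rep(1, nth), rr)
    .bilinear(hm, center[1] + r2 * cos(t2), center[2] + r2 * sin(t2))
  }
  base <- sample_at(0)
  scores <- vapply(orders, function(n)
    stats::cor(as.vector(base), as.vector(sample_at(2 * pi / n))),
    numeric(1))
  names(scores) <- as.character(orders)
  if (any(!is.finite(scores))) scores[!is.finite(scores)] <- 0
  o <- order(scores, decreasing = TRUE)
  margin <- scores[o[1]] - scores[o[2]]
  list(order = as.integer(orders[o[1]]), scores = scores,
       confidence = max(0, min(1, margin)),
       lowConfidence = margin < 1e-3)
}

#' Azimuthally averaged radial height profile
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param center 2-vector, nm.
#' @param rMax maximum radius, nm (default: distance to the nearest edge).
#' @param nAngles number of azimuthal samples per radius.
#' @return data.frame with \code{r} (nm) and \code{h} (nm).
#' @export
radialProfile <- function(hm, center, rMax = NULL, nAngles = 360L) {
  ax <- gridAxes(hm)
  if (is.null(rMax))
    rMax <- min(center[1] - ax$x[1], ax$x[length(ax$x)] - center[1],
                center[2] - ax$y[1], ax$y[length(ax$y)] - center[2])
  ps <- hm@grid@pixelSize
  rr <- seq(0, rMax, by = ps / 2)
  th <- seq(0, 2 * pi, length.out = nAngles + 1L)[-(nAngles + 1L)]
  hmean <- vapply(rr, function(r)
    mean(.bilinear(hm, center[1] + r * cos(th), center[2] + r * sin(th))),
    numeric(1))
  data.frame(r = rr, h = hmean)
}

#' Fit ring geometry from subunit peaks
#'
#' The ring center and peak-circle diameter come from an algebraic
#' least-squares circle fit through the peak positions. The outer diameter
#' is where the azimuthally averaged radial profile falls to half the
#' ring-crest height above background beyond the crest (both conventions
#' are reported because usage in the field varies). The central feature is
#' the height at the center minus the mean height on the peak circle
#' (positive = protrusion, negative = pore). The rotational symmetry order
#' is estimated on an annulus around the fitted peak circle.
#'
#' @param peaks data.frame from \code{\link{detectSubunitPeaks}} (>= 3 rows).
#' @param hm the \linkS4class{HeightMap} the peaks came from.
#' @param orders candidate symmetry orders.
#' @return A \linkS4class{RingMeasurement}.
#' @export
fitRing <- function(peaks, hm, orders = 2:8) {
  if (nrow(peaks) < 3)
    stop("ring fit needs >= 3 peaks, got ", nrow(peaks))
  x <- peaks$x; y <- peaks$y
  A <- cbind(2 * x, 2 * y, 1)
  qr_ <- qr(A)
  if (qr_$rank < 3)
    stop("degenerate ring fit: peak positions are collinear")
  sol <- qr.coef(qr_, x^2 + y^2)
  center <- sol[1:2]
  Rsq <- sol[3] + sum(center^2)
  if (!is.finite(Rsq) || Rsq <= 0)
    stop("degenerate ring fit: peak positions are collinear")
  R <- sqrt(Rsq)
  sym <- tryCatch(
    estimateSymmetryOrder(hm, center, orders,
                          rIn = 0.55 * R, rOut = 1.45 * R),
    error = function(e) estimateSymmetryOrder(hm, center, orders,
                                              rIn = 0.7 * R, rOut = 1.2 * R))
  ## outer diameter: half-height crossing of the radial profile beyond crest
  prof <- radialProfile(hm, center)
  crestIdx <- {
    sel <- which(prof$r >= 0.6 * R & prof$r <= 1.4 * R)
    sel[which.max(prof$h[sel])]
  }
  tail_ <- prof[prof$r > prof$r[crestIdx], , drop = FALSE]
  outerD <- NA_real_
  if (nrow(tail_) > 1) {
    bg <- min(tail_$h)
    half <- bg + (prof$h[crestIdx] - bg) / 2
    below <- which(tail_$h <= half)
    if (length(below) > 0) {
      k <- below[1]
      if (k == 1) {
        rHalf <- tail_$r[1]
      } else {
        r1 <- tail_$r[k - 1]; r2 <- tail_$r[k]
        h1 <- tail_$h[k - 1]; h2 <- tail_$h[k]
        rHalf <- r1 + (half - h1) * (r2 - r1) / (h2 - h1)
      }
      outerD <- 2 * rHalf
    }
  }
  if (is.na(outerD))
    warning("radial profile never falls to half height inside the map; ",
            "outer diameter is NA")
  th <- seq(0, 2 * pi, length.out = 361L)[-361L]
  onCircle <- mean(.bilinear(hm, center[1] + R * cos(th),
                             center[2] + R * sin(th)))
  centralFeature <- .bilinear(hm, center[1], center[2]) - onCircle
  new("RingMeasurement", center = as.numeric(center),
      nSubunits = nrow(peaks), symmetryOrder = sym$order,
      symmetryScores = sym$scores, diameter = 2 * R,
      outerDiameter = outerD, centralFeature = centralFeature)
}

#' Classify an oligomer from its ring measurement
#'
#' The class follows the symmetry order (3 = trimer, 4 = tetramer,
#' 5 = pentamer, 6 = hexamer, otherwise other). The membrane face is called
#' from the central feature: a protrusion above \code{protrusionThreshold}
#' marks the C-side (pooled C-terminal His-tags at the ring center), a pore
#' below the negative threshold marks the N-side, anything in between is
#' unknown. The confidence is the margin of the symmetry-autocorrelation
#' winner over the runner-up.
#'
#' @param m a \linkS4class{RingMeasurement}.
#' @param protrusionThreshold nm (default 0.2, about four times the
#'   synthetic noise floor).
#' @param patchId optional patch label carried into the call.
#' @return An \linkS4class{OligomerCall}.
#' @export
classifyOligomer <- function(m, protrusionThreshold = 0.2,
                             patchId = NA_character_) {
  cls <- switch(as.character(m@symmetryOrder),
                "3" = "trimer", "4" = "tetramer", "5" = "pentamer",
                "6" = "hexamer", "other")
  face <- if (is.finite(m@centralFeature) &&
              m@centralFeature > protrusionThreshold) "C-side"
          else if (is.finite(m@centralFeature) &&
                   m@centralFeature < -protrusionThreshold) "N-side"
          else "unknown"
  sc <- sort(m@symmetryScores, decreasing = TRUE)
  conf <- if (length(sc) >= 2) max(0, min(1, sc[1] - sc[2])) else 1
  new("OligomerCall", cls = cls, face = face, confidence = conf,
      measurement = m, patchId = patchId)
}

#' Detect, fit and classify one ring in a height map
#'
#' Convenience wrapper: \code{\link{detectSubunitPeaks}} then
#' \code{\link{fitRing}} then \code{\link{classifyOligomer}}. A peak
#' sitting at the ring center (a His-tag-like central protrusion also
#' registers as a local maximum) is recognized by its distance from the
#' peak centroid and excluded from the circle fit; the central feature
#' score still measures it.
#'
#' @inheritParams detectSubunitPeaks
#' @inheritParams fitRing
#' @inheritParams classifyOligomer
#' @return An \linkS4class{OligomerCall}.
#' @export
analyzeHeightMap <- function(hm, minProminence = 0.15, minSeparation = 1.0,
                             orders = 2:8, protrusionThreshold = 0.2,
                             smoothCutoff = 2, patchId = NA_character_) {
  peaks <- detectSubunitPeaks(hm, minProminence, minSeparation, smoothCutoff)
  if (nrow(peaks) >= 4) {
    cen <- c(mean(peaks$x), mean(peaks$y))
    rr <- sqrt((peaks$x - cen[1])^2 + (peaks$y - cen[2])^2)
    ringPeaks <- peaks[rr > 0.5 * stats::median(rr), , drop = FALSE]
    if (nrow(ringPeaks) >= 3) peaks <- ringPeaks
  }
  m <- fitRing(peaks, hm, orders)
  classifyOligomer(m, protrusionThreshold, patchId)
}

#' Aggregate oligomer calls per membrane patch
#'
#' Counts oligomers per patch and reports the sample mean and standard
#' deviation of the per-patch counts (n - 1 denominator; a single patch is
#' reported with sd 0 and flagged \code{"n=1"}), plus the fraction of calls
#' per oligomer class over all patches.
#'
#' @param calls list of \linkS4class{OligomerCall}, each with a
#'   \code{patchId}.
#' @return A \linkS4class{PatchSummary}.
#' @export
aggregatePatchCalls <- function(calls) {
  if (length(calls) == 0) stop("no calls to aggregate")
  ids <- vapply(calls, function(cl) cl@patchId, character(1))
  if (anyNA(ids)) stop("every call needs a patchId")
  counts <- table(ids)
  cnt <- as.integer(counts)
  names(cnt) <- names(counts)
  n <- length(cnt)
  cls <- vapply(calls, function(cl) cl@cls, character(1))
  fr <- table(cls) / length(cls)
  flags <- character(0)
  sdv <- if (n > 1) stats::sd(cnt) else { flags <- "n=1"; 0 }
  new("PatchSummary", nPatches = n, countsPerPatch = cnt,
      mean = mean(cnt), sd = sdv,
      classFractions = stats::setNames(as.numeric(fr), names(fr)),
      flags = flags)
}

#' Write oligomer calls as CSV
#'
#' One row per call: patch_id, center, subunit count, symmetry order, both
#' diameter conventions, central feature, class, face, confidence.
#'
#' @param calls list of \linkS4class{OligomerCall}.
#' @param path output CSV file.
#' @return \code{path}, invisibly.
#' @export
writeCalls <- function(calls, path) {
  rows <- lapply(calls, function(cl) {
    m <- cl@measurement
    data.frame(patch_id = cl@patchId, center_x = m@center[1],
               center_y = m@center[2], n_subunits = m@nSubunits,
               symmetry_order = m@symmetryOrder, diameter_nm = m@diameter,
               outer_diameter_nm = m@outerDiameter,
               central_feature_nm = m@centralFeature, class = cl@cls,
               face = cl@face, confidence = cl@confidence)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
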