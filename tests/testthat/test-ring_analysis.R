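## analytic Gaussian-bump map builder (already at "instrument resolution":
## provenance filtered so detection adds no extra smoothing)
bumpMap <- function(centers, amp = 1, width = 0.5, n = 64, ps = 0.1,
                    origin = c(-3.2, -3.2)) {
  x <- origin[1] + (0:(n - 1)) * ps
  y <- origin[2] + (0:(n - 1)) * ps
  h <- matrix(0, n, n)
  for (k in seq_len(nrow(centers)))
    h <- h + amp * exp(-(outer(x - centers[k, 1], rep(1, n))^2 +
                         outer(rep(1, n), y - centers[k, 2])^2) /
                       (2 * width^2))
  new("HeightMap", grid = ScanGrid(ps, n, n, origin), heights = h,
      provenance = "filtered")
}

ringCenters <- function(n, radius, phase = 0)
  cbind(radius * cos(phase + 2 * pi * (0:(n - 1)) / n),
        radius * sin(phase + 2 * pi * (0:(n - 1)) / n))

test_that("peak detection: flat maps, merging rule, planted-ring recovery", {
  flat <- new("HeightMap", grid = ScanGrid(0.1, 32, 32),
              heights = matrix(0.5, 32, 32), provenance = "filtered")
  expect_equal(nrow(detectSubunitPeaks(flat)), 0)
  ## two bumps 0.3 nm apart with 0.5 nm separation rule -> one peak (higher)
  two <- bumpMap(rbind(c(0, 0)), amp = 1, width = 0.3)
  two@heights <- two@heights +
    0.8 * heights(bumpMap(rbind(c(0.3, 0)), amp = 1, width = 0.3))
  pk <- detectSubunitPeaks(two, minProminence = 0.1, minSeparation = 0.5,
                           smoothCutoff = 0)
  expect_equal(nrow(pk), 1)
  expect_lt(abs(pk$x - 0), 0.15)          # the taller bump wins
  ## seeded noisy C5 ring: exactly 5 peaks within 0.15 nm of planted apices
  ring <- makeRingOligomer(5, 2.15, phase = 0.4)
  hm <- corruptHeightMap(simulateRingMap(ring), sigma = 0.05, seed = 11)
  pk5 <- detectSubunitPeaks(hm, minProminence = 0.15, minSeparation = 1,
                            smoothCutoff = 1.2)
  expect_equal(nrow(pk5), 5)
  gt <- ring$groundTruth$peakPositions
  dmin <- apply(pk5[, c("x", "y")], 1, function(p)
    min(sqrt((gt[, 1] - p[1])^2 + (gt[, 2] - p[2])^2)))
  expect_lt(max(dmin), 0.15)
})

test_that("symmetry order is recovered for C3/C5 and degenerate for a torus", {
  for (n in c(3, 5)) {
    hm <- bumpMap(ringCenters(n, 1.8, 0.3))
    est <- estimateSymmetryOrder(hm, c(0, 0), orders = 2:8)
    expect_equal(est$order, n)
    expect_true(all(est$scores[as.character(n)] >=
                    est$scores[names(est$scores) != as.character(n)]))
  }
  ## rotationally uniform torus: all C(n) equal, flagged low-confidence
  x <- seq(-3.2, 3.1, by = 0.1)
  rr <- sqrt(outer(x^2, rep(1, 64)) + outer(rep(1, 64), x^2))
  torus <- new("HeightMap", grid = ScanGrid(0.1, 64, 64, c(-3.2, -3.2)),
               heights = exp(-(rr - 1.8)^2 / 0.5), provenance = "filtered")
  estT <- estimateSymmetryOrder(torus, c(0, 0), orders = 2:8)
  expect_lt(diff(range(estT$scores)), 1e-4)   # interpolation-limited
  expect_true(estT$lowConfidence)
  expect_error(estimateSymmetryOrder(torus, c(3.1, 0), orders = 2:8),
               "annulus|edge")
})

test_that("ring fit recovers exact circle geometry and rejects degenerate input", {
  hm <- bumpMap(ringCenters(5, 2.15))
  pts <- ringCenters(5, 2.15)
  peaks <- data.frame(x = pts[, 1], y = pts[, 2], height = 1, prominence = 1)
  m <- fitRing(peaks, hm)
  expect_equal(m@diameter, 4.30, tolerance = 1e-9)
  expect_equal(m@center, c(0, 0), tolerance = 1e-9)
  expect_equal(m@nSubunits, 5L)
  collinear <- data.frame(x = c(-1, 0, 1), y = c(-1, 0, 1), height = 1,
                          prominence = 1)
  expect_error(fitRing(collinear, hm), "collinear")
  expect_error(fitRing(peaks[1:2, ], hm), ">= 3")
})

test_that("central feature distinguishes protrusion, pore and flat center", {
  ringC <- ringCenters(5, 2.15)
  pore <- bumpMap(ringC)                       # nothing at the center
  mPore <- fitRing(data.frame(x = ringC[, 1], y = ringC[, 2], height = 1,
                              prominence = 1), pore)
  expect_lt(mPore@centralFeature, 0)
  prot <- bumpMap(rbind(ringC, c(0, 0)))       # tall central bump
  mProt <- fitRing(data.frame(x = ringC[, 1], y = ringC[, 2], height = 1,
                              prominence = 1), prot)
  expect_gt(mProt@centralFeature, 0)
  ## outer diameter sits beyond the peak circle for these smooth rings
  expect_gt(mPore@outerDiameter, mPore@diameter)
})

test_that("classification applies the face rule and follows symmetry order", {
  mk <- function(order, cf) new("RingMeasurement", center = c(0, 0),
    nSubunits = as.integer(order), symmetryOrder = as.integer(order),
    symmetryScores = c("3" = 0.2, "5" = 0.9, "6" = 0.3),
    diameter = 4.3, outerDiameter = 5.5, centralFeature = cf)
  c1 <- classifyOligomer(mk(5, +0.4), 0.2)
  expect_identical(c1@cls, "pentamer")
  expect_identical(c1@face, "C-side")
  c2 <- classifyOligomer(mk(5, -0.3), 0.2)
  expect_identical(c2@face, "N-side")
  c3 <- classifyOligomer(mk(3, 0.05), 0.2)
  expect_identical(c3@cls, "trimer")
  expect_identical(c3@face, "unknown")
  ## deterministic given (measurement, threshold)
  expect_identical(classifyOligomer(mk(5, 0.4), 0.2)@face, c1@face)
})

test_that("patch aggregation computes counts, moments and class fractions", {
  mkCall <- function(cls, patch) new("OligomerCall", cls = cls,
    face = "unknown", confidence = 0.8, patchId = patch,
    measurement = new("RingMeasurement", center = c(0, 0), nSubunits = 5L,
                      symmetryOrder = 5L, symmetryScores = c("5" = 1),
                      diameter = 4.3, outerDiameter = 5,
                      centralFeature = 0))
  calls <- c(lapply(1:3, function(i) mkCall("pentamer", "A")),
             lapply(1:5, function(i) mkCall("pentamer", "B")),
             lapply(1:7, function(i) mkCall("pentamer", "C")))
  ps <- aggregatePatchCalls(calls)
  expect_equal(ps@mean, 5)
  expect_equal(ps@sd, 2)
  ## 76 pentamers + 24 hexamers -> fractions 0.76 / 0.24
  mix <- c(lapply(1:76, function(i) mkCall("pentamer", "P")),
           lapply(1:24, function(i) mkCall("hexamer", "P")))
  fr <- aggregatePatchCalls(mix)@classFractions
  expect_equal(unname(fr[c("pentamer", "hexamer")]), c(0.76, 0.24))
  single <- aggregatePatchCalls(list(mkCall("trimer", "Z")))
  expect_equal(single@sd, 0)
  expect_true("n=1" %in% single@flags)
  expect_error(aggregatePatchCalls(list()), "no calls")
})

test_that("measurements are rotation invariant and scale covariant", {
  ring <- makeRingOligomer(5, 2.15)
  hm <- simulateRingMap(ring)
  m0 <- fitRing(detectSubunitPeaks(hm, smoothCutoff = 0), hm)
  ## rotating the synthetic scene by 2*pi/5 barely changes the measurement
  ringR <- makeRingOligomer(5, 2.15, phase = 2 * pi / 5)
  hmR <- simulateRingMap(ringR)
  mR <- fitRing(detectSubunitPeaks(hmR, smoothCutoff = 0), hmR)
  expect_lt(abs(m0@diameter - mR@diameter), pixelSize(hm))
  expect_lt(abs(m0@centralFeature - mR@centralFeature), pixelSize(hm))
  ## relabelling the lateral scale by s scales both diameters by exactly s
  s <- 1.3
  hmS <- new("HeightMap",
             grid = ScanGrid(pixelSize(hm) * s, hm@grid@nx, hm@grid@ny,
                             hm@grid@origin * s),
             heights = heights(hm), provenance = "filtered")
  mS <- fitRing(detectSubunitPeaks(hmS, minSeparation = 1.3,
                                   smoothCutoff = 0), hmS)
  expect_equal(mS@diameter, m0@diameter * s, tolerance = 1e-9)
  expect_equal(mS@outerDiameter, m0@outerDiameter * s, tolerance = 1e-6)
})
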