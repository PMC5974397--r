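test_that("tip profile follows the sphere cap and tangent cone and blends smoothly", {
  tip <- TipModel(5, 0.5)
  expect_equal(tipProfile(tip, 0), 0)
  expect_equal(tipProfile(tip, 0.3), 0.5 - sqrt(0.25 - 0.09), tolerance = 1e-12)
  a <- 5 * pi / 180
  xt <- 0.5 * cos(a)
  expect_equal(tipProfile(tip, xt), 0.5 * (1 - sin(a)), tolerance = 1e-12)
  ## continuity and matching first derivative at the blend point
  eps <- 1e-7
  expect_lt(abs(tipProfile(tip, xt + eps) - tipProfile(tip, xt - eps)),
            3 * eps / tan(a))
  dLeft <- (tipProfile(tip, xt) - tipProfile(tip, xt - eps)) / eps
  dRight <- (tipProfile(tip, xt + eps) - tipProfile(tip, xt)) / eps
  expect_equal(dLeft, dRight, tolerance = 1e-4)
  expect_equal(dLeft, 1 / tan(a), tolerance = 1e-4)
})

test_that("a grounded sphere images with apex height 2r and footprint 2*sqrt(R*r)", {
  r <- 0.17; R <- 0.5
  s <- bareStructure(0, 0, r, r)
  tip <- TipModel(5, R)
  g <- ScanGrid(0.01, 161, 3, origin = c(-0.8, -0.01))
  hm <- simulateTopograph(s, tip, g)
  expect_equal(max(heights(hm)), 2 * r, tolerance = 1e-9)
  ## footprint radius: boundary of the h > 0 region, found by bisection
  hAt <- function(x) {
    gg <- ScanGrid(1e-4, 2, 2, origin = c(x, 0))
    heights(simulateTopograph(s, tip, gg))[1, 1]
  }
  lo <- 0.4; hi <- 0.8
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (hAt(mid) > 0) lo <- mid else hi <- mid
  }
  expect_equal((lo + hi) / 2, 2 * sqrt(R * r), tolerance = 1e-6)
})

test_that("topograph equals independent contact oracles", {
  tip <- TipModel(8, 0.4)
  g <- ScanGrid(0.12, 32, 32, origin = c(-1.9, -1.9))
  for (seed in 1:6) {
    s <- randomScene(seed)
    hm <- simulateTopograph(s, tip, g)
    expect_lt(max(abs(heights(hm) - heights(bruteForceTopo(s, tip, g)))),
              1e-9)
  }
  ## support-function oracle (1D optimization over the atom sphere surface),
  ## checked at scattered pixels including cone-flank territory
  s <- randomScene(99, nAtoms = 3)
  hm <- simulateTopograph(s, tip, g)
  set.seed(1)
  for (k in 1:25) {
    ix <- sample(g@nx, 1); iy <- sample(g@ny, 1)
    px <- g@origin[1] + (ix - 1) * g@pixelSize
    py <- g@origin[2] + (iy - 1) * g@pixelSize
    hOracle <- max(0, max(vapply(seq_len(nrow(atoms(s))), function(i)
      supportContactHeight(px, py, atoms(s)[i, ], tip), numeric(1))))
    expect_equal(heights(hm)[ix, iy], hOracle, tolerance = 1e-6)
  }
})

test_that("dilation obeys monotonicity, translation equivariance and height fidelity", {
  tip <- TipModel(5, 0.5)
  g <- ScanGrid(0.1, 40, 40, origin = c(-2, -2))
  s <- randomScene(7, nAtoms = 6)
  hm <- simulateTopograph(s, tip, g)
  ## adding an atom never decreases any pixel
  s2 <- s
  s2@atoms <- rbind(s2@atoms, s2@atoms[1, ])
  s2@atoms[nrow(s2@atoms), c("x", "y", "z")] <- c(0.3, -0.2, 0.9)
  expect_true(all(heights(simulateTopograph(s2, tip, g)) >=
                  heights(hm) - 1e-12))
  ## a blunter tip yields pixelwise heights >= a sharper tip
  hmBlunt <- simulateTopograph(s, TipModel(5, 1.2), g)
  expect_true(all(heights(hmBlunt) >= heights(hm) - 1e-12))
  ## shifting the structure by 3 pixels shifts the topograph identically
  shift <- 3 * g@pixelSize
  s3 <- s
  s3@atoms$x <- s3@atoms$x + shift
  hmShift <- simulateTopograph(s3, tip, g)
  expect_lt(max(abs(heights(hmShift)[4:40, ] - heights(hm)[1:37, ])), 1e-12)
  ## max height equals max(z + r) over atoms within a pixel's tolerance
  expect_equal(max(heights(hm)), max(atoms(s)$z + atoms(s)$radius),
               tolerance = g@pixelSize)
})

test_that("low-pass filter preserves DC, passes long and kills short wavelengths", {
  g <- ScanGrid(0.1, 64, 64)
  const <- HeightMap(matrix(1.7, 64, 64), grid = g, provenance = "simulated")
  for (kern in c("gaussian", "ideal", "butterworth")) {
    out <- lowpassFilter(const, FilterSpec(2, kern))
    expect_lt(max(abs(heights(out) - 1.7)), 1e-9)
  }
  x <- (0:63) * 0.1
  ## wavelength 3.2 nm (passband), commensurate with the periodic domain
  long <- HeightMap(outer(sin(2 * pi * x / 3.2), rep(1, 64)), grid = g,
                    provenance = "loaded")
  outL <- lowpassFilter(long, FilterSpec(2, "ideal"), pad = "none")
  expect_lt(max(abs(heights(outL) - heights(long))), 1e-9)
  ## wavelength 0.8 nm (stopband)
  short <- HeightMap(outer(sin(2 * pi * x / 0.8), rep(1, 64)), grid = g,
                     provenance = "loaded")
  outS <- lowpassFilter(short, FilterSpec(2, "ideal"), pad = "none")
  expect_lt(max(abs(heights(outS))), 1e-9)
  ## gaussian reaches attenuation 0.5 at the cutoff wavelength (2 nm fits
  ## the 8 nm periodic domain exactly: 4 periods)
  g80 <- ScanGrid(0.1, 80, 80)
  x80 <- (0:79) * 0.1
  atCut <- HeightMap(outer(sin(2 * pi * x80 / 2), rep(1, 80)), grid = g80,
                     provenance = "loaded")
  outC <- lowpassFilter(atCut, FilterSpec(2, "gaussian"), pad = "none")
  expect_equal(max(heights(outC)) / max(heights(atCut)), 0.5,
               tolerance = 1e-6)
  ## mean approximately preserved with mirror padding too
  s <- randomScene(3)
  hm <- simulateTopograph(s, TipModel(5, 0.5), ScanGrid(0.1, 48, 48,
                                                        c(-2.4, -2.4)))
  expect_equal(mean(heights(lowpassFilter(hm, FilterSpec(2)))),
               mean(heights(hm)), tolerance = 5e-3)
  expect_error(lowpassFilter(hm, FilterSpec(0.15)), "Nyquist")
})

test_that("height maps round-trip through the TSV dialect", {
  s <- randomScene(11)
  hm <- simulateTopograph(s, TipModel(5, 0.5),
                          ScanGrid(0.13, 21, 17, c(-1.3, -1.1)))
  tmp <- tempfile(fileext = ".tsv")
  writeHeightMap(hm, tmp)
  back <- readHeightMap(tmp)
  expect_equal(heights(back), heights(hm), tolerance = 1e-12)
  expect_equal(pixelSize(back), pixelSize(hm))
  expect_identical(back@provenance, "simulated")
})
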