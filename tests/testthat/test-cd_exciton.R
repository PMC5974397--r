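test_that("point-dipole couplings follow the orientation factor", {
  ## side-by-side parallel dipoles perpendicular to the separation: kappa = 1
  ch <- ChromophoreSet(rbind(c(0, 0, 0), c(1, 0, 0)),
                       rbind(c(0, 0, 1), c(0, 0, 1)),
                       siteWavelength = 524, dipoleStrength = 1)
  sys <- buildExcitonSystem(ch)
  expect_equal(sys@couplingMatrix[1, 2], 1, tolerance = 1e-12)
  ## collinear head-to-tail: kappa = 1 - 3 = -2
  ch2 <- ChromophoreSet(rbind(c(0, 0, 0), c(1, 0, 0)),
                        rbind(c(1, 0, 0), c(1, 0, 0)),
                        siteWavelength = 524, dipoleStrength = 1)
  expect_equal(buildExcitonSystem(ch2)@couplingMatrix[1, 2], -2,
               tolerance = 1e-12)
  ## diagonal carries the reduced site energy
  expect_equal(diag(sys@couplingMatrix), rep(1 / 524, 2))
  ## C5 ring of identical tilted dipoles -> circulant coupling matrix
  ring <- makeRingOligomer(5, 2.15, dipoleAzimuthMode = "tail_to_tail")
  H <- buildExcitonSystem(ring$chromophores)@couplingMatrix
  for (k in 1:4)
    expect_equal(H[1, 1 + k], H[2, ((1 + k) %% 5) + 1],
                 tolerance = 1e-12)
  ## guards
  expect_error(buildExcitonSystem(
    ChromophoreSet(rbind(c(0, 0, 0), c(0, 0, 0)),
                   rbind(c(0, 0, 1), c(0, 0, 1)))), "coincide")
  expect_warning(buildExcitonSystem(
    ChromophoreSet(rbind(c(0, 0, 0), c(0.2, 0, 0)),
                   rbind(c(0, 0, 1), c(0, 0, 1)))), "point-dipole")
})

test_that("rotational strengths obey the sum rule, dimer antisymmetry and parallel null", {
  ## parallel dipoles: every cross product vanishes
  ring <- makeRingOligomer(5, 2.15)
  par <- ChromophoreSet(ring$chromophores@positions,
                        matrix(rep(c(0, 0, 1), 5), 5, 3, byrow = TRUE))
  expect_lt(max(abs(rotationalStrengths(
    solveExciton(buildExcitonSystem(par))))), 1e-15)
  ## degenerate dimer: R_+ = -R_-
  dim_ <- ChromophoreSet(rbind(c(0, 0, 0), c(1.2, 0, 0)),
                         rbind(c(0, 1, 1), c(1, 0, 1)))
  Rk <- rotationalStrengths(solveExciton(buildExcitonSystem(dim_)))
  expect_equal(Rk[1], -Rk[2], tolerance = 1e-15)
  ## sum rule + mirror antisymmetry on random geometries
  for (seed in 1:20) {
    ch <- randomChromophores(seed)
    sys <- solveExciton(buildExcitonSystem(ch))
    expect_lt(abs(sum(rotationalStrengths(sys))), 1e-12)
    mir <- ChromophoreSet(ch@positions %*% diag(c(1, 1, -1)),
                          ch@directions %*% diag(c(1, 1, -1)),
                          ch@siteWavelength, ch@dipoleStrength)
    sysM <- solveExciton(buildExcitonSystem(mir))
    expect_equal(rotationalStrengths(sysM), -rotationalStrengths(sys),
                 tolerance = 1e-9)
    ## eigenvector matrix stays orthonormal
    C <- sys@stateCoefficients
    expect_lt(max(abs(crossprod(C) - diag(ncol(C)))), 1e-9)
  }
})

test_that("spectral synthesis: intrinsic-only peak, couplet integral, redshift", {
  ## zero couplings (parallel far dipoles): intrinsic band peaks at lambda_max
  far <- ChromophoreSet(rbind(c(0, 0, 0), c(100, 0, 0)),
                        rbind(c(0, 0, 1), c(0, 0, 1)))
  sysF <- solveExciton(buildExcitonSystem(far))
  spF <- synthesizeCDSpectrum(sysF, 40, intrinsicAmplitude = 1e-4)
  expect_equal(spF@apparentPeak, 524, tolerance = 0.5)
  ## pure couplet integrates to ~0 (sum rule carried into the spectrum)
  ring <- makeRingOligomer(5, 2.15, dipoleAzimuthMode = "tail_to_tail")
  sys <- solveExciton(buildExcitonSystem(ring$chromophores))
  sp <- synthesizeCDSpectrum(sys, 40, intrinsicAmplitude = 0)
  integ <- sum(sp@deltaEps) * diff(sp@wavelengths[1:2])
  expect_lt(abs(integ), 1e-3 * max(abs(sp@deltaEps)) *
                        diff(range(sp@wavelengths)))
  ## weak inverted couplet + positive intrinsic: apparent peak redshifted,
  ## blue side dips but stays positive, shift grows with couplet amplitude
  amp0 <- max(abs(rotationalStrengths(sys)))
  peaks <- vapply(c(0.25, 0.5, 1), function(scale) {
    sysS <- sys
    sysS@rotationalStrengths <- sys@rotationalStrengths * scale
    spS <- synthesizeCDSpectrum(sysS, 40, intrinsicAmplitude = 2 * amp0)
    ## the blue-side dip stays a dip: no appreciable negative lobe, and
    ## the spectrum is never classified as a couplet
    expect_gt(min(spS@deltaEps[spS@wavelengths < 524]),
              -0.1 * max(abs(spS@deltaEps)))
    expect_false(classifyCouplet(spS)$label %in%
                 c("normal_couplet", "inverted_couplet"))
    spS@apparentPeak
  }, numeric(1))
  expect_true(all(peaks > 524))
  expect_true(all(diff(peaks) > 0))
  expect_error(synthesizeCDSpectrum(sys, 40, grid = seq(300, 350, 1)),
               "grid")
})

test_that("couplet classification separates the trimer and pentamer signatures", {
  ## BR-like head-to-tail trimer -> normal couplet (+ blue, - red)
  tri <- makeRingOligomer(3, 1.5, dipoleAzimuthMode = "head_to_tail")
  sysT <- solveExciton(buildExcitonSystem(tri$chromophores))
  clT <- classifyCouplet(synthesizeCDSpectrum(sysT))
  expect_identical(clT$label, "normal_couplet")
  expect_equal(clT$blueLobeSign, 1)
  expect_equal(clT$redLobeSign, -1)
  ## KR2-like tail-to-tail pentamer -> inverted couplet
  pen <- makeRingOligomer(5, 2.15, dipoleAzimuthMode = "tail_to_tail")
  sysP <- solveExciton(buildExcitonSystem(pen$chromophores))
  clP <- classifyCouplet(synthesizeCDSpectrum(sysP))
  expect_identical(clP$label, "inverted_couplet")
  ## all-zero spectrum -> null
  zero <- new("CDSpectrum", wavelengths = seq(400, 650, 1),
              deltaEps = rep(0, 251), lambdaMaxAbs = 524,
              apparentPeak = NA_real_, bandwidth = 40)
  expect_identical(classifyCouplet(zero)$label, "null")
  ## synthesized couplet amplitude decays toward zero as the ring grows:
  ## the exciton splitting collapses as 1/d^3 and the opposite-signed
  ## bands cancel (measured on the spectrum, not on the raw strengths)
  amp <- vapply(c(2.15, 4, 8, 16), function(rr) {
    r <- makeRingOligomer(5, rr, dipoleAzimuthMode = "tail_to_tail")
    sp <- synthesizeCDSpectrum(
      solveExciton(buildExcitonSystem(r$chromophores)), 40, 0)
    max(abs(sp@deltaEps))
  }, numeric(1))
  expect_true(all(diff(amp) < 0))
})
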