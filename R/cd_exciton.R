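## Exciton-coupled circular dichroism from chromophore geometry:
## point-dipole coupling Hamiltonian, rotational strengths by the matrix
## method, spectral synthesis (couplet + intrinsic CD) and couplet
## classification.
##
## Reduced units throughout: energies are reduced wavenumbers 1/lambda
## (nm^-1) and rotational strengths are left unnormalized, because only
## signs, orderings and peak positions are physically contracted here.

#' Build the point-dipole exciton Hamiltonian
#'
#' Off-diagonal couplings follow the point-dipole interaction
#' \eqn{V_{ij} = D \kappa_{ij} / d_{ij}^3} with orientation factor
#' \eqn{\kappa_{ij} = \hat\mu_i\cdot\hat\mu_j -
#' 3(\hat\mu_i\cdot\hat R_{ij})(\hat\mu_j\cdot\hat R_{ij})},
#' \eqn{D} = dipoleStrength squared (reduced units) and \eqn{d_{ij}} in nm.
#' Diagonal entries are the common site energy 1/siteWavelength (the
#' degenerate exciton model: one lambda_max per oligomer). Pair distances
#' below 0.3 nm violate the point-dipole approximation and are recorded as
#' warnings in the returned system; coincident chromophores are an error.
#'
#' @param chromophores a \linkS4class{ChromophoreSet} with >= 2 entries.
#' @return An \linkS4class{ExcitonSystem} with the coupling matrix built
#'   (energies and rotational strengths still unset; see
#'   \code{\link{solveExciton}}).
#' @export
buildExcitonSystem <- function(chromophores) {
  P <- chromophores@positions
  U <- chromophores@directions
  N <- nrow(P)
  if (N < 2) stop("exciton coupling needs >= 2 chromophores")
  D <- chromophores@dipoleStrength^2
  H <- matrix(0, N, N)
  warns <- character(0)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    Rij <- P[j, ] - P[i, ]
    d <- sqrt(sum(Rij^2))
    if (d < 1e-9) stop("chromophores ", i, " and ", j, " coincide")
    if (d < 0.3)
      warns <- c(warns, sprintf(
        "pair (%d,%d) separated by %.3f nm: below the 0.3 nm point-dipole guard",
        i, j, d))
    Rh <- Rij / d
    kappa <- sum(U[i, ] * U[j, ]) - 3 * sum(U[i, ] * Rh) * sum(U[j, ] * Rh)
    H[i, j] <- H[j, i] <- D * kappa / d^3
  }
  diag(H) <- 1 / chromophores@siteWavelength
  if (length(warns) > 0) warning(paste(warns, collapse = "; "))
  new("ExcitonSystem", chromophores = chromophores, couplingMatrix = H,
      stateEnergies = rep(NA_real_, N),
      stateCoefficients = matrix(NA_real_, N, N),
      rotationalStrengths = rep(NA_real_, N), warnings = warns)
}

#' Diagonalize the exciton system and compute rotational strengths
#'
#' Eigen-decomposition of the N x N Hamiltonian. The rotational strength of
#' exciton state k is
#' \deqn{R_k = -\frac{\pi}{\bar\lambda}\sum_{i<j} c_{ik} c_{jk}
#'   \, \mathbf{R}_{ij}\cdot(\boldsymbol\mu_i\times\boldsymbol\mu_j)}
#' with \eqn{\bar\lambda} the mean site wavelength, \eqn{\mathbf R_{ij}}
#' the origin separation (nm) and \eqn{\boldsymbol\mu} the dipole vectors
#' (direction times strength). Because the eigenvectors are orthonormal the
#' strengths of the degenerate manifold sum to zero; this sum rule is
#' checked after the fact and a violation above 1e-9 is an error.
#'
#' @param system an \linkS4class{ExcitonSystem} from
#'   \code{\link{buildExcitonSystem}}.
#' @return The system with \code{stateEnergies}, \code{stateCoefficients}
#'   and \code{rotationalStrengths} filled, states ordered by increasing
#'   energy (decreasing wavelength).
#' @export
solveExciton <- function(system) {
  H <- system@couplingMatrix
  if (max(abs(H - t(H))) > 1e-12 * max(1, max(abs(H))))
    stop("coupling matrix is not symmetric")
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  E <- eig$values[ord]
  C <- eig$vectors[, ord, drop = FALSE]
  ch <- system@chromophores
  P <- ch@positions
  mu <- ch@directions * ch@dipoleStrength
  N <- nrow(P)
  lambdaBar <- ch@siteWavelength
  Rk <- numeric(N)
  for (i in seq_len(N - 1)) for (j in (i + 1):N) {
    Rij <- P[j, ] - P[i, ]
    cr <- c(mu[i, 2] * mu[j, 3] - mu[i, 3] * mu[j, 2],
            mu[i, 3] * mu[j, 1] - mu[i, 1] * mu[j, 3],
            mu[i, 1] * mu[j, 2] - mu[i, 2] * mu[j, 1])
    geo <- sum(Rij * cr)
    Rk <- Rk - (pi / lambdaBar) * C[i, ] * C[j, ] * geo
  }
  if (abs(sum(Rk)) > 1e-9)
    stop("rotational-strength sum rule violated: ", sum(Rk))
  system@stateEnergies <- E
  system@stateCoefficients <- C
  system@rotationalStrengths <- Rk
  system
}

#' Synthesize a CD spectrum from a solved exciton system
#'
#' Each exciton state contributes a unit-area Gaussian band (in wavelength)
#' at \eqn{\lambda_k = 1/E_k} scaled by its rotational strength; the
#' intrinsic (monomer-like) CD of the chromophore adds a band of amplitude
#' \code{intrinsicAmplitude} at the uncoupled lambda_max. A weak inverted
#' couplet riding on a positive intrinsic band shifts the apparent peak to
#' the red of lambda_max without producing a negative lobe, which is the
#' typical single-peak-redshifted signature of pentameric rings.
#'
#' @param system a solved \linkS4class{ExcitonSystem}.
#' @param bandwidth Gaussian full width at half maximum, nm (default 40:
#'   visible retinal bands are broad).
#' @param intrinsicAmplitude reduced units, on the same scale as the
#'   rotational strengths (0, the default, disables the intrinsic band; a
#'   value comparable to \code{max(abs(rotationalStrengths(system)))}
#'   emulates the overlap of intrinsic CD and couplet seen in single-peak
#'   redshifted spectra).
#' @param grid wavelength grid, nm; default lambda_max +/- 150 nm in 0.5 nm
#'   steps.
#' @return A \linkS4class{CDSpectrum}.
#' @export
synthesizeCDSpectrum <- function(system, bandwidth = 40,
                                 intrinsicAmplitude = 0,
                                 grid = NULL) {
  if (anyNA(system@stateEnergies))
    stop("system not solved; call solveExciton() first")
  stopifnot(bandwidth > 0)
  lam0 <- system@chromophores@siteWavelength
  if (is.null(grid)) grid <- seq(lam0 - 150, lam0 + 150, by = 0.5)
  lamK <- 1 / system@stateEnergies
  if (all(lamK < min(grid) | lamK > max(grid)))
    stop("all exciton state wavelengths fall outside the grid")
  sdv <- bandwidth / (2 * sqrt(2 * log(2)))
  de <- numeric(length(grid))
  for (k in seq_along(lamK))
    de <- de + system@rotationalStrengths[k] * stats::dnorm(grid, lamK[k], sdv)
  de <- de + intrinsicAmplitude * stats::dnorm(grid, lam0, sdv)
  peak <- if (all(de == 0)) NA_real_ else grid[which.max(de)]
  new("CDSpectrum", wavelengths = grid, deltaEps = de, lambdaMaxAbs = lam0,
      apparentPeak = peak, bandwidth = bandwidth)
}

#' Classify a CD couplet
#'
#' Looks at the extremal lobe on each side of the uncoupled lambda_max: a
#' positive blue lobe with a negative red lobe is the normal couplet (the
#' trimer signature), the reverse is the inverted couplet (the pentamer
#' signature). Spectra with a single effective lobe are labelled by where
#' the apparent peak sits: redshifted if more than a quarter bandwidth past
#' lambda_max, otherwise at lambda_max. An all-zero spectrum is null.
#'
#' @param spectrum a \linkS4class{CDSpectrum}.
#' @param zeroTolerance reduced units; lobes with |extremum| below this are
#'   treated as absent. Default: 1e-3 of the spectrum's maximum absolute
#'   value (or 1e-12 for an all-zero spectrum).
#' @return list with \code{label} (one of \code{normal_couplet},
#'   \code{inverted_couplet}, \code{single_peak_redshifted},
#'   \code{single_peak_at_max}, \code{null}), \code{blueLobeSign} and
#'   \code{redLobeSign} (each -1, 0 or +1).
#' @export
classifyCouplet <- function(spectrum, zeroTolerance = NULL) {
  w <- spectrum@wavelengths
  v <- spectrum@deltaEps
  lam0 <- spectrum@lambdaMaxAbs
  if (is.null(zeroTolerance))
    zeroTolerance <- max(1e-12, 1e-3 * max(abs(v)))
  lobe <- function(side) {
    vv <- v[side]
    if (length(vv) == 0) return(0)
    ex <- vv[which.max(abs(vv))]
    if (abs(ex) <= zeroTolerance) 0 else sign(ex)
  }
  blue <- lobe(w < lam0)
  red <- lobe(w > lam0)
  label <- if (blue == 0 && red == 0) {
    "null"
  } else if (blue > 0 && red < 0) {
    "normal_couplet"
  } else if (blue < 0 && red > 0) {
    "inverted_couplet"
  } else {
    ## single effective lobe (one side absent or both sides the same sign)
    if (is.na(spectrum@apparentPeak)) "null"
    else if (spectrum@apparentPeak > lam0 + spectrum@bandwidth / 4)
      "single_peak_redshifted"
    else "single_peak_at_max"
  }
  list(label = label, blueLobeSign = blue, redLobeSign = red)
}

#' Write a CD spectrum as two-column TSV
#'
#' @param spectrum a \linkS4class{CDSpectrum}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  utils::write.table(
    data.frame(wavelength_nm = spectrum@wavelengths,
               delta_eps_reduced = spectrum@deltaEps),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
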