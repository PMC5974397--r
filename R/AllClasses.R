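#' @import methods
NULL

## All lengths are nanometres after parsing; the scan normal is +z and the
## support plane (standing in for the membrane surface) is z = 0.

#' MolecularStructure: an atomic (or pseudo-atomic) model of an oligomer
#'
#' Container for the sample being scanned: one row per heavy atom with
#' coordinates in nm, the hard-sphere radius used by the tip model, and
#' chain/residue bookkeeping needed to orient the oligomer and locate
#' chromophores.
#'
#' @slot atoms data.frame with columns \code{element}, \code{x}, \code{y},
#'   \code{z} (nm), \code{radius} (nm, may be \code{NA} before
#'   \code{\link{assignRadii}}), \code{chain_id}, \code{residue_name},
#'   \code{residue_number}, \code{atom_name}.
#' @slot frameLabel one of \code{"raw"}, \code{"membrane-N-up"},
#'   \code{"membrane-C-up"}. In a membrane frame the oligomer symmetry axis
#'   is parallel to +z and the lowest atom sphere touches z = 0.
#' @slot transform list with the rotation matrix \code{R} and translation
#'   \code{t} (nm) last applied by \code{\link{orientOligomer}} (identity for
#'   raw structures); kept so chromophore extraction and orientation commute.
#'
#' @exportClass MolecularStructure
setClass("MolecularStructure",
  representation(atoms = "data.frame", frameLabel = "character",
                 transform = "list"),
  prototype(frameLabel = "raw",
            transform = list(R = diag(3), t = c(0, 0, 0))))

setValidity("MolecularStructure", function(object) {
  need <- c("element", "x", "y", "z", "radius", "chain_id",
            "residue_name", "residue_number", "atom_name")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss) > 0)
    return(paste("atoms is missing columns:", paste(miss, collapse = ", ")))
  if (nrow(object@atoms) == 0)
    return("structure contains zero atoms")
  xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    return("non-finite atom coordinates")
  r <- object@atoms$radius
  if (any(!is.na(r) & r <= 0))
    return("non-positive hard-sphere radius")
  if (!object@frameLabel %in% c("raw", "membrane-N-up", "membrane-C-up"))
    return("frameLabel must be raw, membrane-N-up or membrane-C-up")
  TRUE
})

#' ChromophoreSet: transition dipoles of the retinal chromophores
#'
#' One entry per protomer carrying a retinal: the dipole origin (midpoint of
#' the polyene chain), a unit orientation vector pointing from the Schiff-base
#' end (C15, the "tail") to the beta-ionone end (C5, the "head"), the site
#' wavelength (lambda_max of the uncoupled chromophore, nm) and the dipole
#' strength in reduced units.
#'
#' @slot positions N x 3 matrix, nm.
#' @slot directions N x 3 matrix of unit vectors (tail -> head).
#' @slot siteWavelength numeric(1), nm, in (300, 750).
#' @slot dipoleStrength numeric(1), reduced units.
#'
#' @exportClass ChromophoreSet
setClass("ChromophoreSet",
  representation(positions = "matrix", directions = "matrix",
                 siteWavelength = "numeric", dipoleStrength = "numeric"))

setValidity("ChromophoreSet", function(object) {
  if (ncol(object@positions) != 3 || ncol(object@directions) != 3)
    return("positions and directions must have 3 columns")
  if (nrow(object@positions) != nrow(object@directions))
    return("positions and directions disagree in length")
  nrm <- sqrt(rowSums(object@directions^2))
  if (any(abs(nrm - 1) > 1e-9))
    return("directions must be unit vectors (|d| = 1 within 1e-9)")
  if (object@siteWavelength <= 300 || object@siteWavelength >= 750)
    return("siteWavelength must lie in (300, 750) nm")
  TRUE
})

#' TipModel: the AFM probe geometry
#'
#' A cone of given half angle terminated by a spherical apex, the standard
#' hard tip used for topograph simulation. Defaults follow the common
#' sharp-probe description for high-speed AFM simulation: half angle 5
#' degrees, end radius 0.5 nm.
#'
#' @slot halfAngle cone half angle from the tip axis, degrees, in (0, 90).
#' @slot endRadius apex sphere radius, nm, > 0.
#'
#' @exportClass TipModel
setClass("TipModel",
  representation(halfAngle = "numeric", endRadius = "numeric"),
  prototype(halfAngle = 5, endRadius = 0.5))

setValidity("TipModel", function(object) {
  if (object@halfAngle <= 0 || object@halfAngle >= 90)
    return("halfAngle must be in (0, 90) degrees")
  if (object@endRadius <= 0)
    return("endRadius must be > 0")
  TRUE
})

#' ScanGrid: regular lateral pixel grid of a topograph
#'
#' @slot pixelSize lateral sampling, nm.
#' @slot nx,ny number of pixels along x and y (>= 2).
#' @slot origin 2-vector, nm: position of pixel (1,1).
#'
#' @exportClass ScanGrid
setClass("ScanGrid",
  representation(pixelSize = "numeric", nx = "integer", ny = "integer",
                 origin = "numeric"),
  prototype(origin = c(0, 0)))

setValidity("ScanGrid", function(object) {
  if (object@pixelSize <= 0) return("pixelSize must be > 0")
  if (object@nx < 2L || object@ny < 2L) return("nx and ny must be >= 2")
  if (length(object@origin) != 2) return("origin must be length 2")
  TRUE
})

#' HeightMap: a (simulated or measured) AFM topograph
#'
#' @slot grid ScanGrid.
#' @slot heights nx x ny matrix, nm; rows index x, columns index y.
#' @slot provenance one of \code{"simulated"}, \code{"filtered"},
#'   \code{"synthetic"}, \code{"loaded"}. Simulated maps are clipped at the
#'   support plane so min height >= 0; synthetic (noise-corrupted) maps may
#'   undercut it.
#'
#' @exportClass HeightMap
setClass("HeightMap",
  representation(grid = "ScanGrid", heights = "matrix",
                 provenance = "character"))

setValidity("HeightMap", function(object) {
  if (!all(is.finite(object@heights))) return("heights must be finite")
  if (nrow(object@heights) != object@grid@nx ||
      ncol(object@heights) != object@grid@ny)
    return("heights dimensions disagree with grid")
  if (!object@provenance %in% c("simulated", "filtered", "synthetic", "loaded"))
    return("unknown provenance")
  if (object@provenance == "simulated" && min(object@heights) < 0)
    return("simulated maps must be non-negative (support plane at 0)")
  TRUE
})

#' FilterSpec: resolution-limiting low-pass filter
#'
#' Spatial wavelengths below \code{cutoffWavelength} are attenuated in the
#' Fourier domain. The gaussian kernel reaches attenuation 0.5 at the cutoff;
#' the ideal kernel is a hard annulus; butterworth interpolates.
#'
#' @slot cutoffWavelength nm, > 0. The usual resolution limit for these
#'   topographs is about 2 nm.
#' @slot kernel \code{"gaussian"}, \code{"ideal"} or \code{"butterworth"}.
#' @slot order butterworth order (ignored otherwise).
#'
#' @exportClass FilterSpec
setClass("FilterSpec",
  representation(cutoffWavelength = "numeric", kernel = "character",
                 order = "numeric"),
  prototype(cutoffWavelength = 2, kernel = "gaussian", order = 2))

setValidity("FilterSpec", function(object) {
  if (object@cutoffWavelength <= 0) return("cutoffWavelength must be > 0")
  if (!object@kernel %in% c("gaussian", "ideal", "butterworth"))
    return("kernel must be gaussian, ideal or butterworth")
  TRUE
})

#' RingMeasurement: geometry of one detected oligomer ring
#'
#' Two diameter conventions are computed side by side because usage in the
#' field varies: \code{diameter} is the peak-circle diameter (least-squares
#' circle through the subunit peak maxima) and \code{outerDiameter} is where
#' the azimuthally averaged radial profile falls to half the ring-crest
#' height above background. \code{centralFeature} is the height at the ring
#' center minus the mean height on the peak circle: positive marks a central
#' protrusion (e.g. a pooled His-tag bundle on the C-face), negative a pore.
#'
#' @slot center 2-vector, nm.
#' @slot nSubunits integer, number of detected subunit peaks.
#' @slot symmetryOrder integer, winning rotational symmetry order.
#' @slot symmetryScores named numeric, rotational autocorrelation C(n) for
#'   every candidate order (used for the classification confidence).
#' @slot diameter peak-circle diameter, nm.
#' @slot outerDiameter half-height outer diameter, nm (NA if the profile
#'   never crosses half height inside the map).
#' @slot centralFeature nm; positive = protrusion, negative = pore.
#'
#' @exportClass RingMeasurement
setClass("RingMeasurement",
  representation(center = "numeric", nSubunits = "integer",
                 symmetryOrder = "integer", symmetryScores = "numeric",
                 diameter = "numeric", outerDiameter = "numeric",
                 centralFeature = "numeric"))

setValidity("RingMeasurement", function(object) {
  if (object@nSubunits < 1L) return("nSubunits must be >= 1")
  if (!is.na(object@diameter) && object@diameter <= 0)
    return("diameter must be > 0")
  TRUE
})

#' OligomerCall: classified oligomer with membrane-face assignment
#'
#' @slot cls \code{"trimer"}, \code{"tetramer"}, \code{"pentamer"},
#'   \code{"hexamer"} or \code{"other"}.
#' @slot face \code{"C-side"} (central protrusion), \code{"N-side"}
#'   (central pore) or \code{"unknown"}.
#' @slot confidence in [0, 1], from the margin of the symmetry-order
#'   autocorrelation winner.
#' @slot measurement the underlying RingMeasurement.
#' @slot patchId text label of the membrane patch the ring was observed in.
#'
#' @exportClass OligomerCall
setClass("OligomerCall",
  representation(cls = "character", face = "character",
                 confidence = "numeric", measurement = "RingMeasurement",
                 patchId = "character"),
  prototype(patchId = NA_character_))

setValidity("OligomerCall", function(object) {
  if (!object@cls %in% c("trimer", "tetramer", "pentamer", "hexamer", "other"))
    return("unknown cls")
  if (!object@face %in% c("C-side", "N-side", "unknown"))
    return("unknown face")
  if (object@confidence < 0 || object@confidence > 1)
    return("confidence must be in [0, 1]")
  TRUE
})

#' ExcitonSystem: coupled transition dipoles of an oligomer
#'
#' Point-dipole exciton Hamiltonian in reduced units (energies are reduced
#' wavenumbers, 1/lambda with lambda in nm) plus, once solved, the
#' eigen-decomposition and per-state rotational strengths. The rotational
#' strengths of a degenerate exciton manifold sum to zero.
#'
#' @slot chromophores the ChromophoreSet the system was built from.
#' @slot couplingMatrix N x N symmetric, reduced energy units.
#' @slot stateEnergies N eigenvalues (reduced wavenumber), NA until solved.
#' @slot stateCoefficients N x N orthonormal eigenvector matrix.
#' @slot rotationalStrengths N values, reduced units.
#' @slot warnings character vector of guard warnings recorded at build time.
#'
#' @exportClass ExcitonSystem
setClass("ExcitonSystem",
  representation(chromophores = "ChromophoreSet", couplingMatrix = "matrix",
                 stateEnergies = "numeric", stateCoefficients = "matrix",
                 rotationalStrengths = "numeric", warnings = "character"),
  prototype(warnings = character(0)))

setValidity("ExcitonSystem", function(object) {
  H <- object@couplingMatrix
  if (nrow(H) != ncol(H)) return("couplingMatrix must be square")
  if (max(abs(H - t(H))) > 1e-12 * max(1, max(abs(H))))
    return("couplingMatrix must be symmetric")
  TRUE
})

#' CDSpectrum: synthesized circular dichroism curve
#'
#' @slot wavelengths strictly increasing grid, nm.
#' @slot deltaEps reduced CD units on the grid.
#' @slot lambdaMaxAbs absorption maximum of the uncoupled chromophore, nm.
#' @slot apparentPeak wavelength of the spectrum maximum, nm.
#' @slot bandwidth full width of the Gaussian band shape used, nm.
#'
#' @exportClass CDSpectrum
setClass("CDSpectrum",
  representation(wavelengths = "numeric", deltaEps = "numeric",
                 lambdaMaxAbs = "numeric", apparentPeak = "numeric",
                 bandwidth = "numeric"))

setValidity("CDSpectrum", function(object) {
  if (any(diff(object@wavelengths) <= 0))
    return("wavelengths must be strictly increasing")
  if (length(object@deltaEps) != length(object@wavelengths))
    return("deltaEps and wavelengths disagree in length")
  TRUE
})

#' PatchSummary: per-patch oligomer count statistics
#'
#' @slot nPatches number of membrane patches.
#' @slot countsPerPatch named integer vector, oligomer count per patch.
#' @slot mean,sd sample mean and s.d. (n - 1 denominator) of the counts;
#'   a single patch is reported with sd 0 and flagged.
#' @slot classFractions named numeric, fraction of calls per oligomer class
#'   (sums to 1).
#' @slot flags character vector (e.g. "n=1").
#'
#' @exportClass PatchSummary
setClass("PatchSummary",
  representation(nPatches = "integer", countsPerPatch = "integer",
                 mean = "numeric", sd = "numeric",
                 classFractions = "numeric", flags = "character"),
  prototype(flags = character(0)))

setValidity("PatchSummary", function(object) {
  if (object@nPatches < 1L) return("nPatches must be >= 1")
  if (abs(sum(object@classFractions) - 1) > 1e-9)
    return("classFractions must sum to 1")
  TRUE
})
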