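## Constructors, accessors and show methods.

#' Construct a TipModel
#'
#' @param halfAngle cone half angle from the axis, degrees.
#' @param endRadius apex sphere radius, nm.
#' @return A \linkS4class{TipModel}.
#' @examples
#' TipModel()            # the default sharp probe: 5 degrees, 0.5 nm
#' TipModel(10, 2)
#' @export
TipModel <- function(halfAngle = 5, endRadius = 0.5) {
  new("TipModel", halfAngle = as.numeric(halfAngle),
      endRadius = as.numeric(endRadius))
}

#' Construct a ScanGrid
#'
#' @param pixelSize lateral sampling, nm.
#' @param nx,ny pixel counts.
#' @param origin position of pixel (1,1), nm.
#' @return A \linkS4class{ScanGrid}.
#' @export
ScanGrid <- function(pixelSize = 0.1, nx = 64, ny = 64, origin = c(0, 0)) {
  new("ScanGrid", pixelSize = as.numeric(pixelSize), nx = as.integer(nx),
      ny = as.integer(ny), origin = as.numeric(origin))
}

#' Construct a HeightMap
#'
#' @param heights nx x ny numeric matrix, nm.
#' @param grid a \linkS4class{ScanGrid}; if missing, built from
#'   \code{pixelSize} and the matrix dimensions.
#' @param pixelSize used when \code{grid} is missing.
#' @param origin used when \code{grid} is missing.
#' @param provenance one of "simulated", "filtered", "synthetic", "loaded".
#' @return A \linkS4class{HeightMap}.
#' @export
HeightMap <- function(heights, grid = NULL, pixelSize = 0.1,
                      origin = c(0, 0), provenance = "loaded") {
  heights <- as.matrix(heights)
  if (is.null(grid))
    grid <- ScanGrid(pixelSize, nrow(heights), ncol(heights), origin)
  new("HeightMap", grid = grid, heights = heights, provenance = provenance)
}

#' Construct a FilterSpec
#'
#' @param cutoffWavelength nm.
#' @param kernel "gaussian", "ideal" or "butterworth".
#' @param order butterworth order.
#' @return A \linkS4class{FilterSpec}.
#' @export
FilterSpec <- function(cutoffWavelength = 2, kernel = "gaussian", order = 2) {
  new("FilterSpec", cutoffWavelength = as.numeric(cutoffWavelength),
      kernel = match.arg(kernel, c("gaussian", "ideal", "butterworth")),
      order = as.numeric(order))
}

#' Construct a ChromophoreSet
#'
#' @param positions N x 3 matrix of dipole origins, nm.
#' @param directions N x 3 matrix; normalized to unit length.
#' @param siteWavelength lambda_max of the uncoupled chromophore, nm.
#' @param dipoleStrength reduced units.
#' @return A \linkS4class{ChromophoreSet}.
#' @export
ChromophoreSet <- function(positions, directions, siteWavelength = 524,
                           dipoleStrength = 0.02) {
  positions <- rbind(positions)
  directions <- rbind(directions)
  directions <- directions / sqrt(rowSums(directions^2))
  new("ChromophoreSet", positions = unname(positions),
      directions = unname(directions),
      siteWavelength = as.numeric(siteWavelength),
      dipoleStrength = as.numeric(dipoleStrength))
}

#' @describeIn atoms Atom table of a MolecularStructure
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' Accessors for oligoscope objects
#'
#' \code{atoms} returns the atom data.frame; \code{heights} the topograph
#' matrix (nm); \code{pixelSize} the lateral sampling (nm); \code{nChains}
#' the number of chains; \code{frameLabel} the coordinate-frame tag.
#'
#' @param x an oligoscope object.
#' @name atoms
#' @aliases heights pixelSize nChains frameLabel
#' @export
setMethod("atoms", "MolecularStructure", function(x) x@atoms)

#' @rdname atoms
#' @export
setGeneric("heights", function(x) standardGeneric("heights"))
setMethod("heights", "HeightMap", function(x) x@heights)

#' @rdname atoms
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
setMethod("pixelSize", "HeightMap", function(x) x@grid@pixelSize)
setMethod("pixelSize", "ScanGrid", function(x) x@pixelSize)

#' @rdname atoms
#' @export
setGeneric("nChains", function(x) standardGeneric("nChains"))
setMethod("nChains", "MolecularStructure",
          function(x) length(unique(x@atoms$chain_id)))

#' @rdname atoms
#' @export
setGeneric("frameLabel", function(x) standardGeneric("frameLabel"))
setMethod("frameLabel", "MolecularStructure", function(x) x@frameLabel)

#' @rdname atoms
#' @export
setGeneric("nChromophores", function(x) standardGeneric("nChromophores"))
setMethod("nChromophores", "ChromophoreSet", function(x) nrow(x@positions))

#' @rdname atoms
#' @export
setGeneric("rotationalStrengths", function(x) standardGeneric("rotationalStrengths"))
setMethod("rotationalStrengths", "ExcitonSystem",
          function(x) x@rotationalStrengths)

#' @rdname atoms
#' @export
setGeneric("stateWavelengths", function(x) standardGeneric("stateWavelengths"))
setMethod("stateWavelengths", "ExcitonSystem", function(x) {
  if (anyNA(x@stateEnergies)) stop("system not solved yet; see solveExciton()")
  1 / x@stateEnergies
})

## grid coordinates of a HeightMap: pixel centers along x and y
gridAxes <- function(hm) {
  g <- hm@grid
  list(x = g@origin[1] + (seq_len(g@nx) - 1) * g@pixelSize,
       y = g@origin[2] + (seq_len(g@ny) - 1) * g@pixelSize)
}

setMethod("show", "MolecularStructure", function(object) {
  cat(sprintf("MolecularStructure: %d atoms, %d chain(s), frame '%s'\n",
              nrow(object@atoms), nChains(object), object@frameLabel))
  z <- object@atoms$z
  cat(sprintf("  z range: %.3f .. %.3f nm\n", min(z), max(z)))
})

setMethod("show", "HeightMap", function(object) {
  cat(sprintf("HeightMap: %d x %d px, pixel %.4g nm, provenance '%s'\n",
              object@grid@nx, object@grid@ny, object@grid@pixelSize,
              object@provenance))
  cat(sprintf("  height range: %.3f .. %.3f nm\n",
              min(object@heights), max(object@heights)))
})

setMethod("show", "RingMeasurement", function(object) {
  cat(sprintf(paste0("RingMeasurement: %d subunits, C%d symmetry, ",
                     "peak-circle diameter %.2f nm\n"),
              object@nSubunits, object@symmetryOrder, object@diameter))
  cat(sprintf("  outer diameter %.2f nm, central feature %+.2f nm\n",
              object@outerDiameter, object@centralFeature))
})

setMethod("show", "OligomerCall", function(object) {
  cat(sprintf("OligomerCall: %s, face %s, confidence %.2f\n",
              object@cls, object@face, object@confidence))
})

setMethod("show", "ExcitonSystem", function(object) {
  n <- nrow(object@couplingMatrix)
  cat(sprintf("ExcitonSystem: %d chromophores%s\n", n,
              if (anyNA(object@stateEnergies)) " (unsolved)" else ""))
  if (!anyNA(object@stateEnergies)) {
    cat("  state wavelengths (nm):",
        paste(sprintf("%.1f", 1 / object@stateEnergies), collapse = ", "), "\n")
    cat("  rotational strengths:",
        paste(sprintf("%+.3g", object@rotationalStrengths), collapse = ", "),
        "\n")
  }
})

setMethod("show", "CDSpectrum", function(object) {
  cat(sprintf("CDSpectrum: %d points, lambda_max %.0f nm, apparent peak %.1f nm\n",
              length(object@wavelengths), object@lambdaMaxAbs,
              object@apparentPeak))
})

setMethod("show", "PatchSummary", function(object) {
  cat(sprintf("PatchSummary: %d patches, %.1f +/- %.1f oligomers per patch\n",
              object@nPatches, object@mean, object@sd))
  fr <- object@classFractions
  cat("  class fractions:",
      paste(sprintf("%s %.0f%%", names(fr), 100 * fr), collapse = ", "), "\n")
})
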