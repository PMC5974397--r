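## Ground-truth synthetic ring oligomers (pseudo-atomic structures plus
## chromophores), patch scenes and AFM-like measurement noise. Every
## artifact is emitted together with its exact ground truth so downstream
## recovery tests never re-derive it from the fixture.

## run code with a locally seeded RNG, restoring the caller's state
.withSeed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Generate a synthetic ring oligomer with exact ground truth
#'
#' Builds an n-fold ring of cylinder-like protomers (each a vertical stack
#' of overlapping spheres) already in the membrane frame (symmetry axis =
#' +z, grounded at z = 0), with an optional central protrusion (a thin
#' sphere stack mimicking pooled C-terminal His-tags) or a guaranteed-empty
#' central pore. One chromophore is embedded per protomer at mid-height:
#' \code{dipoleAzimuthMode = "head_to_tail"} orients the dipoles
#' tangentially so each head points toward the tail of the next protomer
#' around the ring (the trimer-like circulating arrangement), while
#' \code{"tail_to_tail"} points all heads radially outward (the
#' pentamer-like arrangement); \code{dipolePolar} tilts them out of the
#' membrane plane. Residue numbers increase from the membrane-distal base
#' to the top of each protomer so \code{\link{orientOligomer}} can tell the
#' two faces apart, and each chromophore is also written as a pseudo-RET
#' residue (atoms C5..C15 along the dipole axis) so
#' \code{\link{extractRetinalChromophores}} works on synthetic structures.
#'
#' Geometry defaults emulate microbial-rhodopsin rings: protomer radius
#' 1.1 nm, transmembrane height 4 nm, ring diameters of interest
#' 2.8 - 4.9 nm, retinal tilt about 20 degrees from the membrane plane.
#'
#' @param n symmetry order (>= 2); rings of interest here are 3, 5, 6.
#' @param ringRadius protomer-center circle radius, nm (ground-truth
#'   peak-circle diameter = 2 * ringRadius).
#' @param protomerHeight,protomerRadius protomer cylinder dimensions, nm.
#' @param centralFeature \code{"none"}, \code{"pore"} or
#'   \code{"protrusion"}.
#' @param protrusionHeight height of the central protrusion above the
#'   protomer tops, nm.
#' @param dipolePolar dipole tilt from the membrane plane, degrees.
#' @param dipoleAzimuthMode \code{"head_to_tail"} or \code{"tail_to_tail"}.
#' @param dipoleAzimuthOffset degrees; azimuthal offset of the
#'   tail-to-tail fan from pure radial (a perfectly radial fan is achiral
#'   and would produce no couplet; near-radial retinal fans in real
#'   pentamers keep such an offset).
#' @param siteWavelength chromophore lambda_max, nm.
#' @param dipoleStrength reduced units.
#' @param phase azimuthal phase of the first protomer, radians.
#' @param seed integer; the structure itself is deterministic, the seed is
#'   recorded in the ground truth for provenance.
#' @return list with \code{structure} (\linkS4class{MolecularStructure},
#'   membrane frame), \code{chromophores} (\linkS4class{ChromophoreSet})
#'   and \code{groundTruth} (list: \code{n}, \code{diameter},
#'   \code{peakPositions} n x 2, \code{dipolePositions},
#'   \code{dipoleDirections}, \code{centralFeature}, \code{cls},
#'   \code{seed}).
#' @export
makeRingOligomer <- function(n, ringRadius,
                             protomerHeight = 4, protomerRadius = 1.1,
                             centralFeature = c("none", "protrusion", "pore"),
                             protrusionHeight = 0.8,
                             dipolePolar = 20,
                             dipoleAzimuthMode = c("head_to_tail",
                                                   "tail_to_tail"),
                             dipoleAzimuthOffset = 25,
                             siteWavelength = 524, dipoleStrength = 0.02,
                             phase = 0, seed = 1L) {
  centralFeature <- match.arg(centralFeature)
  dipoleAzimuthMode <- match.arg(dipoleAzimuthMode)
  stopifnot(n >= 2, ringRadius > protomerRadius / 2, protomerHeight > 0)
  protRadius <- 0.45   # central His-tag-mimic stack radius, nm
  if (centralFeature == "protrusion" &&
      ringRadius - protomerRadius < protRadius)
    stop("protomers overlap the central protrusion: ringRadius - ",
         "protomerRadius must be >= ", protRadius, " nm")
  phi <- phase + 2 * pi * (seq_len(n) - 1) / n
  ## one protomer: stack of spheres from the base to the top
  zc <- seq(protomerRadius, protomerHeight - protomerRadius,
            by = protomerRadius / 2)
  if (length(zc) == 0) zc <- protomerHeight / 2
  rows <- list()
  for (k in seq_len(n)) {
    cx <- ringRadius * cos(phi[k]); cy <- ringRadius * sin(phi[k])
    rows[[k]] <- data.frame(
      element = "C", x = cx, y = cy, z = zc, radius = protomerRadius,
      chain_id = LETTERS[k], residue_name = "PRO",
      residue_number = seq_along(zc),
      atom_name = paste0("PS", seq_along(zc)))
  }
  if (centralFeature == "protrusion") {
    ## His-tag-mimic bundle anchored to the top (C-terminal) face only, so
    ## the opposite face keeps its central pore
    zp <- seq(protomerHeight - 1,
              protomerHeight + protrusionHeight - protRadius,
              by = protRadius / 2)
    rows[[n + 1]] <- data.frame(
      element = "C", x = 0, y = 0, z = zp, radius = protRadius,
      chain_id = "X", residue_name = "TAG",
      residue_number = seq_along(zp),
      atom_name = paste0("PT", seq_along(zp)))
  }
  ## chromophores: mid-height on the protomer circle. head_to_tail points
  ## each head at the tail of the next protomer around the ring (clockwise
  ## circulation viewed from the scan side, the trimer-like arrangement);
  ## tail_to_tail points the heads outward, rotated off pure radial by
  ## dipoleAzimuthOffset -- a perfectly radial fan is achiral (all
  ## rotational strengths vanish), whereas real near-radial retinal fans
  ## keep a fixed azimuthal offset that supplies the chirality.
  tilt <- dipolePolar * pi / 180
  off <- dipoleAzimuthOffset * pi / 180
  pos <- cbind(ringRadius * cos(phi), ringRadius * sin(phi),
               protomerHeight / 2)
  inplane <- if (dipoleAzimuthMode == "head_to_tail")
    cbind(sin(phi), -cos(phi), 0)
  else
    cbind(cos(phi - off), sin(phi - off), 0)
  dir <- cos(tilt) * inplane +
    matrix(rep(c(0, 0, sin(tilt)), each = n), n, 3)
  dir <- dir / sqrt(rowSums(dir^2))
  ## pseudo-retinal residues so extraction works on synthetic structures
  polyLen <- 1.1   # polyene C15..C5 span, nm
  retRows <- list()
  for (k in seq_len(n)) {
    tfrac <- seq(-0.5, 0.5, length.out = 11)   # C15 (tail) .. C5 (head)
    pts <- sweep(outer(tfrac * polyLen, dir[k, ]), 2, pos[k, ], `+`)
    retRows[[k]] <- data.frame(
      element = "C", x = pts[, 1], y = pts[, 2], z = pts[, 3],
      radius = 0.15, chain_id = LETTERS[k], residue_name = "RET",
      residue_number = 900L, atom_name = paste0("C", 15:5))
  }
  atoms <- do.call(rbind, c(rows, retRows))
  structure <- new("MolecularStructure", atoms = atoms,
                   frameLabel = "membrane-N-up")
  chrom <- ChromophoreSet(pos, dir, siteWavelength, dipoleStrength)
  gt <- list(n = n, diameter = 2 * ringRadius,
             peakPositions = pos[, 1:2, drop = FALSE],
             dipolePositions = pos, dipoleDirections = dir,
             centralFeature = centralFeature,
             cls = switch(as.character(n), "3" = "trimer", "4" = "tetramer",
                          "5" = "pentamer", "6" = "hexamer", "other"),
             outerRadius = ringRadius + protomerRadius,
             height = protomerHeight +
               if (centralFeature == "protrusion") protrusionHeight else 0,
             seed = seed)
  list(structure = structure, chromophores = chrom, groundTruth = gt)
}

#' Place several rings in a circular membrane patch
#'
#' Rings are placed with random centers and azimuthal orientations inside a
#' circular patch (emulating oligomers confined in a lipid nanodisc), with
#' pairwise center distances of at least the sum of the two outer radii
#' plus \code{minGap}, by rejection sampling with a bounded retry budget.
#' One RNG stream per artifact, derived from (seed, artifact index), keeps
#' scenes reproducible item by item.
#'
#' @param specs list of argument lists for \code{\link{makeRingOligomer}}
#'   (each element is passed via \code{do.call}).
#' @param patchDiameter nm.
#' @param minGap nm, minimum edge-to-edge clearance between rings.
#' @param seed integer.
#' @param maxTries placement attempts per ring before giving up.
#' @return list with \code{structure} (all rings merged, chains relabelled
#'   per ring), \code{rings} (the individual placed ring objects) and
#'   \code{groundTruth} (data.frame: ring, cls, n, center_x, center_y,
#'   diameter).
#' @export
makePatchScene <- function(specs, patchDiameter, minGap = 1, seed = 1L,
                           maxTries = 1000L) {
  stopifnot(length(specs) >= 1, patchDiameter > 0)
  placed <- list()
  centers <- matrix(numeric(0), 0, 2)
  outer_ <- numeric(0)
  for (k in seq_along(specs)) {
    ring <- do.call(makeRingOligomer, specs[[k]])
    rOut <- ring$groundTruth$outerRadius
    rMaxC <- patchDiameter / 2 - rOut
    if (rMaxC < 0)
      stop("ring ", k, " does not fit in the patch; placed ", k - 1,
           " of ", length(specs))
    ok <- FALSE
    .withSeed(as.integer(seed) + 7919L * k, {
      for (try_ in seq_len(maxTries)) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * rMaxC
        cand <- c(rad * cos(ang), rad * sin(ang))
        if (nrow(centers) > 0) {
          dd <- sqrt(rowSums(sweep(centers, 2, cand)^2))
          if (any(dd < outer_ + rOut + minGap)) next
        }
        theta <- stats::runif(1, 0, 2 * pi)
        ok <- TRUE
        break
      }
      if (ok) {
        Rz <- matrix(c(cos(theta), sin(theta), 0,
                       -sin(theta), cos(theta), 0, 0, 0, 1), 3, 3)
        s <- .applyTransform(ring$structure, Rz, c(cand, 0))
        s@atoms$chain_id <- paste0(s@atoms$chain_id, k)
        ring$structure <- s
        ring$chromophores@positions <-
          sweep(ring$chromophores@positions %*% t(Rz), 2, -c(cand, 0))
        ring$chromophores@directions <- ring$chromophores@directions %*% t(Rz)
        ring$groundTruth$center <- cand
        ring$groundTruth$orientation <- theta
      }
    })
    if (!ok)
      stop("could not place ring ", k, " after ", maxTries,
           " tries; placed ", k - 1, " of ", length(specs))
    placed[[k]] <- ring
    centers <- rbind(centers, ring$groundTruth$center)
    outer_ <- c(outer_, rOut)
  }
  merged <- do.call(rbind, lapply(placed, function(r) r$structure@atoms))
  gt <- do.call(rbind, lapply(seq_along(placed), function(k) {
    g <- placed[[k]]$groundTruth
    data.frame(ring = k, cls = g$cls, n = g$n,
               center_x = g$center[1], center_y = g$center[2],
               diameter = g$diameter)
  }))
  list(structure = new("MolecularStructure", atoms = merged,
                       frameLabel = "membrane-N-up"),
       rings = placed, groundTruth = gt)
}

#' Corrupt a height map with AFM-like measurement noise
#'
#' Adds seeded pixelwise Gaussian noise and independent per-scanline
#' (per y-row) offsets, emulating high-speed AFM line noise. Negative
#' pixels are permitted: noise can undercut the support plane.
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param sigma pixelwise Gaussian s.d., nm.
#' @param lineOffsetSigma per-scanline offset s.d., nm.
#' @param seed integer.
#' @return A \linkS4class{HeightMap} with \code{provenance = "synthetic"}.
#' @export
corruptHeightMap <- function(hm, sigma = 0.05, lineOffsetSigma = 0,
                             seed = 1L) {
  stopifnot(sigma >= 0, lineOffsetSigma >= 0)
  h <- hm@heights
  .withSeed(as.integer(seed), {
    if (sigma > 0)
      h <- h + matrix(stats::rnorm(length(h), 0, sigma), nrow(h))
    if (lineOffsetSigma > 0)
      h <- sweep(h, 2, stats::rnorm(ncol(h), 0, lineOffsetSigma), `+`)
  })
  new("HeightMap", grid = hm@grid, heights = h, provenance = "synthetic")
}

#' Write a synthetic structure as a pseudo-atom PDB file
#'
#' Coordinates are written back in Angstrom per PDB convention. The
#' hard-sphere radius of each pseudo-atom is stored in the B-factor column
#' (in Angstrom) so that \code{assignRadii(s, "bfactor")} restores it after
#' reading; element-table radii would misrepresent these coarse spheres.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeStructurePDB <- function(structure, path) {
  at <- structure@atoms
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(at))) {
    writeLines(sprintf(
      "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00%6.2f          %2s",
      i %% 100000L, substr(at$atom_name[i], 1, 4),
      substr(at$residue_name[i], 1, 3),
      substr(at$chain_id[i], 1, 1), at$residue_number[i] %% 10000L,
      at$x[i] * 10, at$y[i] * 10, at$z[i] * 10,
      if (is.na(at$radius[i])) 0 else at$radius[i] * 10,
      at$element[i]), con)
  }
  writeLines("END", con)
  invisible(path)
}
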