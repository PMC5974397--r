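## Reading atomic structures, hard-sphere radii, membrane-frame orientation
## and retinal chromophore extraction.

## United-atom-like heavy-atom radii (nm). Crystal structures at this
## resolution lack hydrogens; these radii absorb them.
.elementRadii <- c(C = 0.17, N = 0.155, O = 0.152, S = 0.18, P = 0.18)
.defaultElementRadius <- 0.17

#' Read an atomic structure from PDB or mmCIF
#'
#' Parses the first model of a PDB or mmCIF file, keeps one record per
#' non-hydrogen, non-water atom, and converts coordinates from Angstrom to
#' nanometres. The hard-sphere radius column is left \code{NA}; call
#' \code{\link{assignRadii}} before simulating a topograph.
#'
#' @param path file path.
#' @param format \code{"auto"} (by extension), \code{"pdb"} or \code{"cif"}.
#' @return A \linkS4class{MolecularStructure} with \code{frameLabel = "raw"}.
#' @seealso \code{\link{assignRadii}}, \code{\link{orientOligomer}}
#' @export
readStructure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "cif" else "pdb"
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("could not parse '", path, "' as ", format,
                             ": ", conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem) | elem == "")) {
    ## fall back to the first letter of the atom name
    elem <- sub("^[0-9]*", "", at$elety)
    elem <- toupper(substr(elem, 1, 1))
  }
  elem <- toupper(trimws(elem))
  keep <- !(elem %in% c("H", "D")) &
          !(toupper(at$resid) %in% c("HOH", "WAT", "DOD", "H2O"))
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    stop("no atoms left after excluding hydrogens and waters in '", path, "'")
  atoms <- data.frame(
    element = elem[keep],
    x = at$x / 10, y = at$y / 10, z = at$z / 10,   # Angstrom -> nm
    radius = NA_real_,
    chain_id = as.character(at$chain),
    residue_name = toupper(trimws(at$resid)),
    residue_number = as.integer(at$resno),
    atom_name = trimws(at$elety),
    bfactor = suppressWarnings(as.numeric(at$b)),
    stringsAsFactors = FALSE)
  new("MolecularStructure", atoms = atoms, frameLabel = "raw")
}

#' Assign hard-sphere radii to a structure
#'
#' The hard-sphere model needs one radius per atom. The default element
#' table uses united-atom-like heavy-atom radii (C 0.17, N 0.155, O 0.152,
#' S 0.18, P 0.18 nm); elements outside the table fall back to
#' \code{defaultRadius} (0.17 nm) unless that fallback is disabled.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param radiusSet \code{"table"} for the element table, \code{"uniform"}
#'   to give every atom \code{uniformValue}, or \code{"bfactor"} to decode
#'   per-atom radii stored in the PDB B-factor column in Angstrom (the
#'   convention \code{\link{writeStructurePDB}} uses for pseudo-atom
#'   fixtures, whose sphere radii are not element-derived).
#' @param uniformValue nm, used when \code{radiusSet = "uniform"}.
#' @param defaultRadius nm, fallback for elements missing from the table;
#'   set to \code{NA} to turn unknown elements into an error.
#' @return The structure with every atom radius set.
#' @export
assignRadii <- function(structure, radiusSet = c("table", "uniform",
                                                 "bfactor"),
                        uniformValue = 0.15,
                        defaultRadius = .defaultElementRadius) {
  radiusSet <- match.arg(radiusSet)
  at <- structure@atoms
  if (radiusSet == "uniform") {
    stopifnot(uniformValue > 0)
    at$radius <- uniformValue
  } else if (radiusSet == "bfactor") {
    b <- at$bfactor
    if (is.null(b) || anyNA(b) || any(b <= 0))
      stop("bfactor radius decoding needs a positive B-factor on every atom")
    at$radius <- b / 10   # Angstrom -> nm
  } else {
    r <- .elementRadii[at$element]
    unknown <- is.na(r)
    if (any(unknown)) {
      if (is.na(defaultRadius))
        stop("no tabulated radius for element(s): ",
             paste(sort(unique(at$element[unknown])), collapse = ", "))
      r[unknown] <- defaultRadius
    }
    at$radius <- unname(r)
  }
  structure@atoms <- at
  validObject(structure)
  structure
}

## rotation matrix taking unit vector a onto unit vector b
.rotationBetween <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2],
         a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (sum(v^2) < 1e-24) {
    if (c_ > 0) return(diag(3))
    ## 180 degrees: rotate about any axis perpendicular to a
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- p - sum(p * a) * a; v <- v / sqrt(sum(v^2))
    return(2 * tcrossprod(v) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

.applyTransform <- function(structure, R, t = c(0, 0, 0)) {
  xyz <- as.matrix(structure@atoms[, c("x", "y", "z")])
  xyz <- sweep(xyz %*% t(R), 2, -t)   # R %*% x + t, row-wise
  structure@atoms$x <- xyz[, 1]
  structure@atoms$y <- xyz[, 2]
  structure@atoms$z <- xyz[, 3]
  prev <- structure@transform
  structure@transform <- list(R = R %*% prev$R, t = as.numeric(R %*% prev$t + t))
  structure
}

#' Orient a ring oligomer into the membrane/scan frame
#'
#' Aligns the n-fold symmetry axis of the oligomer with the +z scan normal
#' and chooses which terminus faces the probe. The symmetry axis is taken
#' from the chain centroids (the normal of their best-fit plane), which is
#' robust to asymmetric tags and loops; the oligomer ring, not the all-atom
#' inertia tensor, is the feature of interest. The terminus facing +z is
#' decided from the mean z of the first (N) versus last (C)
#' \code{terminalResidues} residues of each chain. The structure is
#' recentred so the symmetry axis passes through (0, 0) and the lowest atom
#' sphere touches the support plane z = 0.
#'
#' @param structure a \linkS4class{MolecularStructure} with assigned radii
#'   and at least two chains related by rotational symmetry.
#' @param side \code{"N"} or \code{"C"}: which terminus side faces the probe.
#' @param terminalResidues how many residues at each chain end are averaged
#'   to locate the termini (configurable for truncated constructs).
#' @return The oriented structure (\code{frameLabel = "membrane-N-up"} or
#'   \code{"membrane-C-up"}); the applied rigid transform is stored in the
#'   \code{transform} slot.
#' @export
orientOligomer <- function(structure, side = c("N", "C"),
                           terminalResidues = 3L) {
  side <- match.arg(side)
  at <- structure@atoms
  if (anyNA(at$radius))
    stop("atom radii not assigned; call assignRadii() first")
  chains <- split(seq_len(nrow(at)), at$chain_id)
  if (length(chains) < 2)
    stop("oligomer orientation needs >= 2 chains related by rotational ",
         "symmetry; structure has ", length(chains))
  cent <- t(vapply(chains, function(i)
    colMeans(as.matrix(at[i, c("x", "y", "z")])), numeric(3)))
  ## plane normal of the chain-centroid ring = smallest principal axis
  cc <- sweep(cent, 2, colMeans(cent))
  ev <- eigen(crossprod(cc), symmetric = TRUE)
  normal <- ev$vectors[, 3]
  R1 <- .rotationBetween(normal, c(0, 0, 1))
  s <- .applyTransform(structure, R1)

  ## decide which face is up from the termini
  termZ <- function(idx, which) {
    a <- s@atoms[idx, ]
    resn <- sort(unique(a$residue_number))
    pick <- if (which == "N") utils::head(resn, terminalResidues)
            else utils::tail(resn, terminalResidues)
    mean(a$z[a$residue_number %in% pick])
  }
  nz <- mean(vapply(chains, termZ, numeric(1), which = "N"))
  cz <- mean(vapply(chains, termZ, numeric(1), which = "C"))
  if (isTRUE(all.equal(nz, cz, tolerance = 1e-12)))
    stop("cannot assign membrane side: N- and C-terminal mean z coincide")
  up <- if (side == "N") nz > cz else cz > nz
  if (!up) {
    ## flip 180 degrees about x
    Rf <- diag(c(1, -1, -1))
    s <- .applyTransform(s, Rf)
  }
  ## recentre: symmetry axis through (0,0), lowest sphere bottom at z = 0
  a <- s@atoms
  chains2 <- split(seq_len(nrow(a)), a$chain_id)
  cent2 <- t(vapply(chains2, function(i)
    colMeans(as.matrix(a[i, c("x", "y", "z")])), numeric(3)))
  shift <- c(-mean(cent2[, 1]), -mean(cent2[, 2]), -min(a$z - a$radius))
  s <- .applyTransform(s, diag(3), shift)
  s@frameLabel <- if (side == "N") "membrane-N-up" else "membrane-C-up"
  validObject(s)
  s
}

#' Extract retinal chromophores as transition dipoles
#'
#' One entry per retinal residue: the dipole origin is the midpoint of the
#' polyene chain (mean of atoms C5..C15) and the direction is the unit
#' vector from the Schiff-base end atom (C15, the "tail") to the beta-ionone
#' end atom (C5, the "head"), so the vector tip is the head in the
#' head-to-tail vocabulary used for retinal packing.
#'
#' @param structure a \linkS4class{MolecularStructure}.
#' @param siteWavelength lambda_max of the uncoupled chromophore, nm.
#' @param dipoleStrength reduced units, copied to every entry.
#' @param residueNames residue names treated as retinal (covalently linked
#'   retinal-lysine variants included by default).
#' @return A \linkS4class{ChromophoreSet} with one entry per retinal.
#' @export
extractRetinalChromophores <- function(structure, siteWavelength = 524,
                                       dipoleStrength = 0.02,
                                       residueNames = c("RET", "LYR")) {
  at <- structure@atoms
  sel <- at$residue_name %in% residueNames
  if (!any(sel))
    stop("no retinal residue (", paste(residueNames, collapse = "/"),
         ") in structure")
  ret <- at[sel, , drop = FALSE]
  key <- paste(ret$chain_id, ret$residue_number)
  pos <- NULL; dir <- NULL
  polyene <- paste0("C", 5:15)
  for (k in unique(key)) {
    a <- ret[key == k, , drop = FALSE]
    c5 <- a[a$atom_name == "C5", c("x", "y", "z")]
    c15 <- a[a$atom_name == "C15", c("x", "y", "z")]
    if (nrow(c5) != 1 || nrow(c15) != 1)
      stop("retinal in chain ", a$chain_id[1],
           " is missing polyene end atom C5 or C15")
    chain <- a[a$atom_name %in% polyene, c("x", "y", "z")]
    pos <- rbind(pos, colMeans(as.matrix(chain)))
    d <- as.numeric(c5) - as.numeric(c15)
    dir <- rbind(dir, d / sqrt(sum(d^2)))
  }
  ChromophoreSet(pos, dir, siteWavelength, dipoleStrength)
}
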