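## Shared fixtures and independent oracles, all built in code.

## write a minimal PDB file from a data.frame with columns
## name, resn, chain, resno, x, y, z (Angstrom), elem
writeTinyPDB <- function(path, df) {
  lines <- vapply(seq_len(nrow(df)), function(i) sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    i, df$name[i], df$resn[i], df$chain[i], df$resno[i],
    df$x[i], df$y[i], df$z[i], df$elem[i]), character(1))
  writeLines(c(lines, "END"), path)
  path
}

## bare pseudo-atom structure from coordinate/radius vectors (nm)
bareStructure <- function(x, y, z, r, chain = "A", frame = "membrane-N-up") {
  n <- length(x)
  new("MolecularStructure",
      atoms = data.frame(element = "C", x = x, y = y, z = z, radius = r,
                         chain_id = rep_len(chain, n), residue_name = "PRO",
                         residue_number = seq_len(n),
                         atom_name = paste0("PS", seq_len(n))),
      frameLabel = frame)
}

## independent per-pixel exhaustive contact scan: plain double loop over
## pixels and atoms, evaluating each contact branch where it is valid
bruteForceTopo <- function(structure, tip, grid) {
  at <- structure@atoms
  a <- tip@halfAngle * pi / 180
  R <- tip@endRadius
  ax <- grid@origin[1] + (seq_len(grid@nx) - 1) * grid@pixelSize
  ay <- grid@origin[2] + (seq_len(grid@ny) - 1) * grid@pixelSize
  H <- matrix(0, grid@nx, grid@ny)
  for (ix in seq_len(grid@nx)) for (iy in seq_len(grid@ny)) {
    best <- 0
    for (k in seq_len(nrow(at))) {
      d <- sqrt((ax[ix] - at$x[k])^2 + (ay[iy] - at$y[k])^2)
      Ra <- R + at$radius[k]
      h <- if (d <= Ra * cos(a))
        at$z[k] - R + sqrt(Ra^2 - d^2)
      else
        at$z[k] + Ra / sin(a) - d / tan(a) - R
      if (h > best) best <- h
    }
    H[ix, iy] <- best
  }
  new("HeightMap", grid = grid, heights = H, provenance = "simulated")
}

## support-function contact height for one atom: maximize over the sphere
## surface point p of p_z - tipProfile(|p_xy - pixel|); fully independent
## of the closed-form contact branches
supportContactHeight <- function(px, py, atom, tip) {
  d <- sqrt((px - atom$x)^2 + (py - atom$y)^2)
  f <- function(theta)
    atom$z + atom$radius * cos(theta) -
      tipProfile(tip, abs(d - atom$radius * sin(theta)))
  gr <- seq(-pi / 2, pi / 2, length.out = 181)
  vals <- vapply(gr, f, numeric(1))
  i <- which.max(vals)
  lo <- gr[max(1, i - 1)]; hi <- gr[min(length(gr), i + 1)]
  stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-10)$objective
}

## random compact atom cloud above the support plane
randomScene <- function(seed, nAtoms = 8, span = 2.2) {
  set.seed(seed)
  r <- stats::runif(nAtoms, 0.12, 0.22)
  bareStructure(x = stats::runif(nAtoms, -span / 2, span / 2),
                y = stats::runif(nAtoms, -span / 2, span / 2),
                z = stats::runif(nAtoms, 0, 1.5) + r,
                r = r)
}

## random chromophore geometry for exciton property tests
randomChromophores <- function(seed, n = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(2:6, 1)
  repeat {
    pos <- matrix(stats::runif(3 * n, -2, 2), n, 3)
    if (n < 2 || min(stats::dist(pos)) > 0.35) break
  }
  dir <- matrix(stats::rnorm(3 * n), n, 3)
  ChromophoreSet(pos, dir, siteWavelength = stats::runif(1, 450, 600),
                 dipoleStrength = stats::runif(1, 0.01, 0.05))
}

## simulate + 2 nm low-pass a generator ring with the standard sharp tip
simulateRingMap <- function(ring, pixel = 0.1, margin = 2.6,
                            tip = TipModel(5, 0.5)) {
  half <- ring$groundTruth$outerRadius + margin
  npx <- ceiling(2 * half / pixel)
  g <- ScanGrid(pixel, npx, npx, origin = c(-half, -half))
  lowpassFilter(simulateTopograph(ring$structure, tip, g), FilterSpec(2))
}
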