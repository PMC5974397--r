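## Hard-sphere AFM topograph simulation: blended sphere/cone tip,
## contact-height maps (grayscale dilation), and the resolution-limiting
## Fourier low-pass filter.

#' Height of the tip surface above its apex
#'
#' The probe is a cone of half angle \code{halfAngle} terminated by a
#' spherical apex of radius R = \code{endRadius}. At lateral offset x the
#' surface height above the apex is the spherical cap
#' \eqn{s(x) = R - \sqrt{R^2 - x^2}} for \eqn{x \le R\cos\alpha}, continued
#' by the tangent cone
#' \eqn{s(x) = R(1 - \sin\alpha) + (x - R\cos\alpha)\cot\alpha}. The two
#' pieces join continuously and once-differentiably at the blend point.
#'
#' @param tip a \linkS4class{TipModel}.
#' @param x lateral offset(s) from the tip axis, nm, >= 0.
#' @return Surface height(s) above the apex, nm.
#' @examples
#' tipProfile(TipModel(5, 0.5), c(0, 0.3, 0.5))
#' @export
tipProfile <- function(tip, x) {
  stopifnot(all(x >= 0))
  a <- tip@halfAngle * pi / 180
  R <- tip@endRadius
  xt <- R * cos(a)
  ifelse(x <= xt,
         R - sqrt(pmax(R^2 - x^2, 0)),
         R * (1 - sin(a)) + (x - xt) / tan(a))
}

## Contact apex height for atoms at lateral distance d (vector), centre
## height za, radius r: the dilation of the atom sphere by the reflected
## tip. Sphere-apex contact while d <= (R+r)cos(alpha), then cone-flank
## contact; the two branches join continuously at the switch point.
.contactHeight <- function(d, za, r, R, a) {
  Ra <- R + r
  sphere <- d <= Ra * cos(a)
  h <- numeric(length(d))
  h[sphere] <- za - R + sqrt(Ra^2 - d[sphere]^2)
  h[!sphere] <- za + Ra / sin(a) - d[!sphere] / tan(a) - R
  h
}

#' Simulate an AFM topograph of an oriented structure
#'
#' Hard-sphere contact imaging: for every pixel the recorded height is the
#' lowest apex position at which the tip surface touches any atom sphere,
#' clipped at the support plane z = 0. This is exactly the grayscale
#' dilation of the union-of-spheres top surface by the reflected tip shape;
#' both the spherical-apex and the cone-flank contact branches are
#' evaluated.
#'
#' @param structure a \linkS4class{MolecularStructure} in a membrane frame
#'   (oriented with \code{\link{orientOligomer}} or built by
#'   \code{\link{makeRingOligomer}}), radii assigned.
#' @param tip a \linkS4class{TipModel}.
#' @param grid a \linkS4class{ScanGrid}.
#' @return A \linkS4class{HeightMap} with \code{provenance = "simulated"}.
#' @export
simulateTopograph <- function(structure, tip, grid) {
  at <- structure@atoms
  if (nrow(at) == 0) stop("empty structure")
  if (anyNA(at$radius)) stop("atom radii not assigned")
  if (!structure@frameLabel %in% c("membrane-N-up", "membrane-C-up"))
    warning("structure is not in a membrane frame; simulating as-is")
  ext <- max(diff(range(at$x)), diff(range(at$y)))
  if (grid@pixelSize >= ext && ext > 0)
    warning("pixel size >= lateral extent of the structure; degenerate grid")
  a <- tip@halfAngle * pi / 180
  R <- tip@endRadius
  ax <- grid@origin[1] + (seq_len(grid@nx) - 1) * grid@pixelSize
  ay <- grid@origin[2] + (seq_len(grid@ny) - 1) * grid@pixelSize
  px <- rep(ax, times = grid@ny)
  py <- rep(ay, each = grid@nx)
  H <- numeric(length(px))
  for (i in seq_len(nrow(at))) {
    d <- sqrt((px - at$x[i])^2 + (py - at$y[i])^2)
    H <- pmax(H, .contactHeight(d, at$z[i], at$radius[i], R, a))
  }
  H <- pmax(H, 0)
  new("HeightMap", grid = grid,
      heights = matrix(H, grid@nx, grid@ny),
      provenance = "simulated")
}

#' Low-pass filter a height map
#'
#' Fourier-domain attenuation of spatial wavelengths below the cutoff,
#' emulating the finite lateral resolution of the instrument (typically
#' about 2 nm for these topographs). The DC component (map mean) is
#' preserved exactly by every kernel. The gaussian kernel (default) reaches
#' attenuation 0.5 at the cutoff wavelength and adds no ringing to the
#' sharp edges of simulated maps; ideal and butterworth kernels are
#' available for spectral unit checks.
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param spec a \linkS4class{FilterSpec}; the cutoff must satisfy the
#'   Nyquist bound \code{cutoffWavelength >= 2 * pixelSize}.
#' @param pad \code{"mirror"} (default) reflects the map by one cutoff
#'   wavelength on each side before the transform, suppressing wrap-around;
#'   \code{"none"} treats the map as periodic.
#' @return A \linkS4class{HeightMap} with \code{provenance = "filtered"}.
#' @export
lowpassFilter <- function(hm, spec, pad = c("mirror", "none")) {
  pad <- match.arg(pad)
  h <- hm@heights
  ps <- hm@grid@pixelSize
  if (spec@cutoffWavelength < 2 * ps)
    stop("cutoff wavelength ", spec@cutoffWavelength,
         " nm is below the Nyquist limit 2 * pixelSize = ", 2 * ps, " nm")
  nx <- nrow(h); ny <- ncol(h)
  if (pad == "mirror") {
    p <- min(ceiling(spec@cutoffWavelength / ps), nx - 1L, ny - 1L)
    ix <- c(rev(seq_len(p) + 1L), seq_len(nx), nx - seq_len(p))
    iy <- c(rev(seq_len(p) + 1L), seq_len(ny), ny - seq_len(p))
    h <- h[ix, iy]
  } else p <- 0L
  Nx <- nrow(h); Ny <- ncol(h)
  fx <- c(0:(Nx %/% 2), -((Nx - Nx %/% 2 - 1):1)) / (Nx * ps)
  fy <- c(0:(Ny %/% 2), -((Ny - Ny %/% 2 - 1):1)) / (Ny * ps)
  f <- sqrt(outer(fx^2, fy^2, `+`))
  fc <- 1 / spec@cutoffWavelength
  Hk <- switch(spec@kernel,
    gaussian = exp(-log(2) * (f / fc)^2),
    ideal = as.numeric(f <= fc * (1 + 1e-12)),
    butterworth = 1 / sqrt(1 + (f / fc)^(2 * spec@order)))
  out <- Re(stats::fft(stats::fft(h) * Hk, inverse = TRUE)) / (Nx * Ny)
  out <- out[p + seq_len(nx), p + seq_len(ny), drop = FALSE]
  new("HeightMap", grid = hm@grid, heights = out, provenance = "filtered")
}

#' Write / read a height map as a TSV matrix
#'
#' Plain-text dialect: three comment header lines
#' (\code{# pixel_size_nm}, \code{# nx ny}, \code{# provenance}) followed by
#' the nx x ny matrix, tab-separated, rows = x index.
#'
#' @param hm a \linkS4class{HeightMap}.
#' @param path output file.
#' @return \code{writeHeightMap} returns \code{path} invisibly;
#'   \code{readHeightMap} returns a \linkS4class{HeightMap} with
#'   \code{provenance = "loaded"} unless the header says otherwise.
#' @export
writeHeightMap <- function(hm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# pixel_size_nm\t%.17g", hm@grid@pixelSize),
               sprintf("# nx ny\t%d\t%d", hm@grid@nx, hm@grid@ny),
               sprintf("# provenance\t%s", hm@provenance)), con)
  utils::write.table(hm@heights, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname writeHeightMap
#' @export
readHeightMap <- function(path) {
  hdr <- readLines(path, n = 3)
  if (length(hdr) < 3 || !all(startsWith(hdr, "#")))
    stop("not a height-map TSV (expected 3 '#' header lines): ", path)
  ps <- as.numeric(strsplit(hdr[1], "\t")[[1]][2])
  dims <- as.integer(strsplit(hdr[2], "\t")[[1]][2:3])
  prov <- strsplit(hdr[3], "\t")[[1]][2]
  m <- as.matrix(utils::read.table(path, sep = "\t", skip = 3))
  dimnames(m) <- NULL
  if (!all(dim(m) == dims)) stop("matrix dimensions disagree with header")
  new("HeightMap", grid = ScanGrid(ps, dims[1], dims[2]),
      heights = m,
      provenance = if (prov %in% c("simulated", "filtered", "synthetic"))
        prov else "loaded")
}
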