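#' @include AllClasses.R
NULL

.gridGeometry <- function(coords, radii, spacing, padding) {
  lo <- apply(coords, 2, min) - padding
  hi <- apply(coords, 2, max) + padding
  dims <- as.integer(ceiling((hi - lo) / spacing)) + 1L
  list(origin = lo, dims = dims)
}

# Mark voxels whose center lies within (radius + inflation) of any atom.
.markSpheres <- function(origin, dims, spacing, coords, radii, inflation) {
  occ <- array(FALSE, dims)
  ax <- origin[1] + (seq_len(dims[1]) - 1) * spacing
  ay <- origin[2] + (seq_len(dims[2]) - 1) * spacing
  az <- origin[3] + (seq_len(dims[3]) - 1) * spacing
  r <- radii + inflation
  for (i in seq_len(nrow(coords))) {
    ri <- r[i]; ri2 <- ri * ri
    xr <- which(abs(ax - coords[i, 1]) <= ri)
    yr <- which(abs(ay - coords[i, 2]) <= ri)
    zr <- which(abs(az - coords[i, 3]) <= ri)
    if (!length(xr) || !length(yr) || !length(zr)) next
    dx2 <- (ax[xr] - coords[i, 1])^2
    dy2 <- (ay[yr] - coords[i, 2])^2
    dz2 <- (az[zr] - coords[i, 3])^2
    mask <- outer(outer(dx2, dy2, "+"), dz2, "+") <= ri2
    occ[xr, yr, zr] <- occ[xr, yr, zr] | mask
  }
  occ
}

# One 6-connected dilation step.
.dilate6 <- function(a) {
  d <- a
  n <- dim(a)
  d[-1, , ] <- d[-1, , ] | a[-n[1], , ]
  d[-n[1], , ] <- d[-n[1], , ] | a[-1, , ]
  d[, -1, ] <- d[, -1, ] | a[, -n[2], ]
  d[, -n[2], ] <- d[, -n[2], ] | a[, -1, ]
  d[, , -1] <- d[, , -1] | a[, , -n[3]]
  d[, , -n[3]] <- d[, , -n[3]] | a[, , -1]
  d
}

# 6-connectivity flood fill of `free` voxels from a logical seed mask.
.floodFill <- function(free, seeds) {
  region <- seeds & free
  repeat {
    grown <- .dilate6(region) & free
    if (sum(grown) == sum(region)) return(region)
    region <- grown
  }
}

.boundaryMask <- function(dims) {
  b <- array(FALSE, dims)
  b[c(1, dims[1]), , ] <- TRUE
  b[, c(1, dims[2]), ] <- TRUE
  b[, , c(1, dims[3])] <- TRUE
  b
}

#' Voxelize a selection onto a cubic grid
#'
#' A voxel is marked protein-occupied when its center lies within
#' `(radius + inflation)` of any selected atom; the grid covers the
#' selection with padding of at least the inflation plus the largest
#' radius, so no sphere is clipped.
#'
#' @param structure a [MolecularStructure-class].
#' @param selection atom indices (must be non-empty).
#' @param spacing voxel edge h in A (default 0.5).
#' @param inflation radius increment in A (e.g. a probe radius for
#'   leak-proof exterior detection; default 0).
#' @param radii per-atom vdW radii, recycled (default 1.7 A).
#' @return a [VoxelGrid-class].
#' @export
voxelize <- function(structure, selection = NULL, spacing = 0.5,
                     inflation = 0, radii = 1.7) {
  stopifnot(spacing > 0, inflation >= 0)
  a <- atoms(structure)
  if (is.null(selection)) selection <- seq_len(nrow(a))
  if (!length(selection)) stop("empty selection", call. = FALSE)
  coords <- cbind(a$x, a$y, a$z)[selection, , drop = FALSE]
  r <- rep(radii, length.out = length(selection))
  geo <- .gridGeometry(coords, r, spacing,
                       padding = max(r) + inflation + 2 * spacing)
  occ <- .markSpheres(geo$origin, geo$dims, spacing, coords, r, inflation)
  new("VoxelGrid", origin = geo$origin, spacing = spacing,
      dims = geo$dims, protein = occ)
}

.voxelOfPoint <- function(point, origin, spacing, dims) {
  idx <- round((point - origin) / spacing) + 1
  if (any(idx < 1 | idx > dims)) return(NULL)
  as.integer(idx)
}

#' Sealed interfacial cavity volume by two-grid flood fill
#'
#' The exterior is found by 6-connected flood fill from the grid boundary
#' over the free voxels of a probe-inflated grid (atom radii + probe), so
#' gaps narrower than the probe cannot leak. The cavity is then the flood
#' fill from the seed point over free voxels of the plain (uninflated)
#' grid, intersected with the non-exterior region; its volume is the
#' voxel count times h^3. If the seed's region connects to the exterior
#' at this probe radius the cavity is open to solvent and an error is
#' raised suggesting a larger probe. A seed falling on an occupied voxel
#' is snapped to the nearest free voxel within 3 A (with a message).
#'
#' @param structure a [MolecularStructure-class].
#' @param wallSel atom indices forming the cavity walls (e.g. the two
#'   protomer chains only, with client and cochaperone excluded).
#' @param seed numeric xyz (A) inside the putative cavity.
#' @param spacing voxel edge h (default 0.5 A).
#' @param probe probe radius sealing the exterior (default 1.4 A).
#' @param radii per-wall-atom vdW radii, recycled (default 1.7 A).
#' @return a [CavityResult-class] (client volume/occupancy NA until
#'   [occupancyFraction()] is applied).
#' @export
luminalCavity <- function(structure, wallSel, seed, spacing = 0.5,
                          probe = 1.4, radii = 1.7) {
  a <- atoms(structure)
  if (!length(wallSel)) stop("empty wall selection", call. = FALSE)
  coords <- cbind(a$x, a$y, a$z)[wallSel, , drop = FALSE]
  r <- rep(radii, length.out = length(wallSel))
  geo <- .gridGeometry(coords, r, spacing,
                       padding = max(r) + probe + 2 * spacing)
  plain <- .markSpheres(geo$origin, geo$dims, spacing, coords, r, 0)
  inflated <- .markSpheres(geo$origin, geo$dims, spacing, coords, r, probe)
  freePlain <- !plain
  freeInfl <- !inflated
  exterior <- .floodFill(freeInfl, .boundaryMask(geo$dims))
  sv <- .voxelOfPoint(seed, geo$origin, spacing, geo$dims)
  snapTo <- function() {
    free <- which(freePlain & freeInfl, arr.ind = TRUE)
    centers <- sweep((free - 1) * spacing, 2, geo$origin, "+")
    d2 <- rowSums(sweep(centers, 2, seed)^2)
    j <- which.min(d2)
    if (d2[j] > 9) stop("no free voxel within 3 A of the seed point",
                        call. = FALSE)
    message(sprintf("seed snapped %.2f A to nearest free voxel", sqrt(d2[j])))
    as.integer(free[j, ])
  }
  if (is.null(sv) || !freePlain[sv[1], sv[2], sv[3]] ||
      !freeInfl[sv[1], sv[2], sv[3]]) sv <- snapTo()
  seedMask <- array(FALSE, geo$dims)
  seedMask[sv[1], sv[2], sv[3]] <- TRUE
  seedRegionInfl <- .floodFill(freeInfl, seedMask)
  if (any(seedRegionInfl & exterior))
    stop("cavity open to solvent at this probe radius; ",
         "consider a larger probe", call. = FALSE)
  cavity <- .floodFill(freePlain, seedMask) & !exterior
  vox <- which(cavity)
  seedCoord <- geo$origin + (sv - 1) * spacing
  new("CavityResult", origin = geo$origin, spacing = spacing,
      dims = geo$dims, cavityVoxels = as.integer(vox),
      cavityVolume = length(vox) * spacing^3,
      clientVolume = NA_real_, occupancy = NA_real_, seedPoint = seedCoord)
}

#' Client volume inside a cavity and occupancy fraction
#'
#' Client-occupied voxels (centers within the client atoms' vdW radii,
#' no inflation) are intersected with the cavity voxel set; the client
#' volume is their count times h^3 and the occupancy fraction is client
#' volume over cavity volume. A client entirely outside the cavity yields
#' fraction 0 with a warning.
#'
#' @param cavity a [CavityResult-class] from [luminalCavity()].
#' @param structure the same [MolecularStructure-class].
#' @param clientSel atom indices of the client segment.
#' @param radii per-client-atom vdW radii, recycled (default 1.7 A).
#' @return the updated [CavityResult-class].
#' @export
occupancyFraction <- function(cavity, structure, clientSel, radii = 1.7) {
  a <- atoms(structure)
  if (!length(clientSel)) {
    warning("no client atoms; occupancy 0", call. = FALSE)
    cavity@clientVolume <- 0; cavity@occupancy <- 0
    return(cavity)
  }
  coords <- cbind(a$x, a$y, a$z)[clientSel, , drop = FALSE]
  r <- rep(radii, length.out = length(clientSel))
  client <- .markSpheres(cavity@origin, cavity@dims, cavity@spacing,
                         coords, r, 0)
  inCav <- array(FALSE, cavity@dims)
  inCav[cavity@cavityVoxels] <- TRUE
  inside <- sum(client & inCav)
  if (inside == 0)
    warning("client lies entirely outside the cavity", call. = FALSE)
  cavity@clientVolume <- inside * cavity@spacing^3
  cavity@occupancy <- if (cavity@cavityVolume > 0)
    cavity@clientVolume / cavity@cavityVolume else 0
  cavity
}
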