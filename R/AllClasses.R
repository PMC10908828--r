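#' @import methods
NULL

# Coulomb constant in kcal * Angstrom / (mol * e^2)
.KE <- 332.0637

#' MolecularStructure: an ordered set of atom records
#'
#' Holds one model's atoms as parsed from a PDB file (or built by the
#' synthetic generators). Atom order is preserved from the source; residues
#' are contiguous spans of atoms keyed by `chain:resno[insert]:resname`.
#' Author (PDB) residue numbering is kept verbatim; insertion codes are
#' appended to the residue key so identity is lossless.
#'
#' @slot atoms data.frame with columns `serial`, `name`, `element`,
#'   `resname`, `resno` (integer, author numbering), `insert` (character,
#'   `""` if none), `chain`, `x`, `y`, `z`, `occupancy`, `b`, `het`
#'   (logical flag for HETATM records such as ATP or Mg).
#' @slot title character, free-text provenance.
#' @export
setClass("MolecularStructure",
  representation(atoms = "data.frame", title = "character"),
  prototype(title = NA_character_))

setValidity("MolecularStructure", function(object) {
  a <- object@atoms
  need <- c("serial", "name", "element", "resname", "resno", "insert",
            "chain", "x", "y", "z", "occupancy", "b", "het")
  if (!all(need %in% names(a)))
    return(paste("atoms is missing columns:",
                 paste(setdiff(need, names(a)), collapse = ", ")))
  if (nrow(a) == 0) return("structure has no atoms")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("non-finite coordinates")
  key <- paste(a$chain, a$resno, a$insert, a$name)
  if (anyDuplicated(key))
    return("duplicate (chain, resno, insert, name) after altloc resolution")
  # residue spans must be contiguous: each residue key forms a single run
  rk <- paste(a$chain, a$resno, a$insert)
  if (length(rle(rk)$values) != length(unique(rk)))
    return("residue atom spans are not contiguous")
  TRUE
})

#' Trajectory: F frames of coordinates over a fixed atom list
#'
#' Coordinates are stored bio3d-style as an F x 3N matrix (x1,y1,z1,x2,...)
#' in Angstrom. Each frame carries a replica label so multi-replica
#' statistics (per-replica mean, SD of means, SEM) can be formed downstream.
#'
#' @slot xyz numeric matrix, F x 3N.
#' @slot template [MolecularStructure-class] supplying atom identities;
#'   its coordinates are frame 1 by convention on read.
#' @slot replica integer vector, one label per frame.
#' @slot time numeric vector of frame times in ps, or NA.
#' @export
setClass("Trajectory",
  representation(xyz = "matrix", template = "MolecularStructure",
                 replica = "integer", time = "numeric"))

setValidity("Trajectory", function(object) {
  f <- nrow(object@xyz)
  if (f < 1) return("trajectory needs at least one frame")
  if (ncol(object@xyz) != 3L * nrow(object@template@atoms))
    return("xyz columns do not match 3 x atom count of template")
  if (!all(is.finite(object@xyz))) return("non-finite frame coordinates")
  if (length(object@replica) != f)
    return("replica labels must have one entry per frame")
  TRUE
})

#' ParameterizedSystem: structure plus per-atom force-field parameters
#'
#' Couples a [MolecularStructure-class] with the per-atom nonbonded
#' parameters every energy routine consumes: partial charge (e),
#' Lennard-Jones sigma (A) and epsilon (kcal/mol), intrinsic Born radius
#' (A) and GB screening factor, plus the exclusion topology derived from a
#' bond list (1-2 and 1-3 pairs excluded, 1-4 pairs scaled by 1/1.2
#' electrostatic and 1/2 Lennard-Jones).
#'
#' @slot structure the [MolecularStructure-class].
#' @slot params data.frame with one row per atom: `charge`, `sigma`,
#'   `epsilon`, `rborn`, `screen`.
#' @slot exclusions integer matrix, 2 columns, i < j atom indices.
#' @slot scaled14 integer matrix, 2 columns, i < j atom indices.
#' @slot coulScale14,ljScale14 numeric 1-4 scale factors.
#' @export
setClass("ParameterizedSystem",
  representation(structure = "MolecularStructure", params = "data.frame",
                 exclusions = "matrix", scaled14 = "matrix",
                 coulScale14 = "numeric", ljScale14 = "numeric"))

setValidity("ParameterizedSystem", function(object) {
  n <- nrow(object@structure@atoms)
  p <- object@params
  if (nrow(p) != n) return("exactly one parameter row per atom is required")
  need <- c("charge", "sigma", "epsilon", "rborn", "screen")
  if (!all(need %in% names(p)))
    return(paste("params missing:", paste(setdiff(need, names(p)), collapse = ", ")))
  if (any(p$epsilon < 0)) return("epsilon must be >= 0")
  if (any(p$sigma <= 0)) return("sigma must be > 0")
  if (any(p$rborn <= 0)) return("Born radii must be > 0")
  for (slot in c("exclusions", "scaled14")) {
    m <- slot(object, slot)
    if (ncol(m) != 2) return(paste(slot, "must have two columns"))
    if (nrow(m)) {
      if (any(m[, 1] == m[, 2])) return(paste(slot, "contains self-pairs"))
      if (any(m < 1 | m > n)) return(paste(slot, "indices out of range"))
      if (any(m[, 1] > m[, 2])) return(paste(slot, "pairs must be stored i < j"))
    }
  }
  TRUE
})

#' EnergyMatrix: residue-group x residue-group interaction energies
#'
#' Rows are residues of group A, columns residues of group B; entries are
#' frame-averaged interaction energies in kcal/mol, split into coulombic
#' and van der Waals components (total = coulomb + vdw elementwise). The
#' stats layer keeps per-replica means and cross-replica mean / SD of the
#' per-replica means / SEM = SD/sqrt(R), the convention used for
#' multi-replica simulation heatmaps. Negative entries are favorable.
#'
#' @slot coulomb,vdw numeric matrices (cross-replica means).
#' @slot rowKeys,colKeys residue identifiers `chain:resno:resname`.
#' @slot perReplica list, one element per replica, each a list with
#'   `coulomb` and `vdw` matrices.
#' @slot sd,sem lists with `coulomb`/`vdw`/`total` matrices, or empty when
#'   fewer than two replicas are present (flagged missing).
#' @export
setClass("EnergyMatrix",
  representation(coulomb = "matrix", vdw = "matrix",
                 rowKeys = "character", colKeys = "character",
                 perReplica = "list", sd = "list", sem = "list"))

setValidity("EnergyMatrix", function(object) {
  d <- dim(object@coulomb)
  if (!identical(d, dim(object@vdw))) return("component dimensions differ")
  if (length(object@rowKeys) != d[1] || length(object@colKeys) != d[2])
    return("row/col keys do not match matrix dimensions")
  if (!all(is.finite(object@coulomb)) || !all(is.finite(object@vdw)))
    return("non-finite energies")
  TRUE
})

#' ModeSet: essential-dynamics principal components
#'
#' Eigen-decomposition of the population (1/F) covariance of mean-centred
#' fitted coordinates, usually over C-alpha atoms. Eigenvalues are in A^2,
#' descending; eigenvectors are orthonormal 3N directions; projections are
#' the centred frames expressed in mode coordinates.
#'
#' @slot values numeric eigenvalues, descending.
#' @slot vectors 3N x K matrix of orthonormal eigenvectors.
#' @slot projections F x K matrix of per-frame mode amplitudes.
#' @slot center mean coordinates (length 3N) the decomposition is about.
#' @slot atomIndices atom indices (into the template) the modes describe.
#' @export
setClass("ModeSet",
  representation(values = "numeric", vectors = "matrix",
                 projections = "matrix", center = "numeric",
                 atomIndices = "integer"))

setValidity("ModeSet", function(object) {
  if (any(object@values < -1e-8)) return("negative eigenvalues")
  if (is.unsorted(rev(object@values))) return("eigenvalues must be descending")
  if (ncol(object@vectors) != length(object@values))
    return("eigenvector count does not match eigenvalues")
  TRUE
})

#' VoxelGrid: cubic lattice classification of space around a structure
#'
#' @slot origin numeric length-3, coordinates of voxel (1,1,1) center (A).
#' @slot spacing voxel edge length h (A).
#' @slot dims integer length-3 grid dimensions.
#' @slot protein logical 3D array; TRUE where the voxel center lies within
#'   (vdW radius + inflation) of a selected atom.
#' @export
setClass("VoxelGrid",
  representation(origin = "numeric", spacing = "numeric",
                 dims = "integer", protein = "array"))

setValidity("VoxelGrid", function(object) {
  if (object@spacing <= 0) return("spacing must be > 0")
  if (!identical(dim(object@protein), as.integer(object@dims)))
    return("protein array does not match dims")
  TRUE
})

#' CavityResult: sealed interfacial cavity volume and client occupancy
#'
#' Produced by [luminalCavity()] and augmented by [occupancyFraction()].
#' Volumes are voxel counts times h^3.
#'
#' @slot origin,spacing,dims grid geometry (see [VoxelGrid-class]).
#' @slot cavityVoxels integer vector of linear voxel indices in the cavity.
#' @slot cavityVolume cavity volume, A^3.
#' @slot clientVolume volume of the client inside the cavity, A^3 (NA until
#'   [occupancyFraction()] is applied).
#' @slot occupancy clientVolume / cavityVolume, in 0..1 (NA as above).
#' @slot seedPoint the (possibly snapped) seed coordinate used.
#' @export
setClass("CavityResult",
  representation(origin = "numeric", spacing = "numeric", dims = "integer",
                 cavityVoxels = "integer", cavityVolume = "numeric",
                 clientVolume = "numeric", occupancy = "numeric",
                 seedPoint = "numeric"))

setValidity("CavityResult", function(object) {
  if (object@cavityVolume < 0) return("negative cavity volume")
  if (!is.na(object@occupancy) &&
      (object@occupancy < 0 || object@occupancy > 1))
    return("occupancy must lie in [0, 1]")
  TRUE
})

#' BindingReport: MM-GBSA binding free energy components
#'
#' Single-trajectory protocol: receptor and ligand frames are
#' sub-selections of the complex frames, so internal bonded terms cancel
#' and the binding energy is the frame average of
#' dEvdw + dEcoul + dGgb + dGnp (kcal/mol). Replica statistics follow the
#' same convention as [EnergyMatrix-class].
#'
#' @slot perFrame data.frame: `replica`, `frame`, `evdw`, `ecoul`, `egb`,
#'   `enp`, `total`.
#' @slot replicaStats data.frame of per-replica means and SDs per component.
#' @slot summary data.frame: cross-replica `mean`, `sd` (of replica means)
#'   and `sem` per component (sd/sem NA when only one replica is present).
#' @export
setClass("BindingReport",
  representation(perFrame = "data.frame", replicaStats = "data.frame",
                 summary = "data.frame"))

setValidity("BindingReport", function(object) {
  pf <- object@perFrame
  need <- c("replica", "frame", "evdw", "ecoul", "egb", "enp", "total")
  if (!all(need %in% names(pf))) return("perFrame is missing components")
  dev <- max(abs(pf$total - (pf$evdw + pf$ecoul + pf$egb + pf$enp)))
  if (is.finite(dev) && dev > 1e-8)
    return("total must equal the sum of components per frame")
  TRUE
})
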