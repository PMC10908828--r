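#' @include AllClasses.R
NULL

#' Accessors for ChaperoneDynamics containers
#'
#' Small accessor family used across the package instead of direct slot
#' access: atom tables, atom/frame counts, frame coordinates, replica
#' labels, energy components and replica statistics, eigen spectra, and
#' cavity volumes.
#'
#' @param x an object of the documented class.
#' @param ... further arguments passed to methods.
#' @name accessors
#' @aliases atoms natoms nframes frameCoords replicaIds residueKeys
NULL

#' @rdname accessors
#' @export
setGeneric("atoms", function(x, ...) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("natoms", function(x, ...) standardGeneric("natoms"))
#' @rdname accessors
#' @export
setGeneric("nframes", function(x, ...) standardGeneric("nframes"))
#' @rdname accessors
#' @param i frame index.
#' @export
setGeneric("frameCoords", function(x, i, ...) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("replicaIds", function(x, ...) standardGeneric("replicaIds"))
#' @rdname accessors
#' @export
setGeneric("residueKeys", function(x, ...) standardGeneric("residueKeys"))

#' @rdname accessors
#' @export
setMethod("atoms", "MolecularStructure", function(x, ...) x@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "Trajectory", function(x, ...) x@template@atoms)
#' @rdname accessors
#' @export
setMethod("atoms", "ParameterizedSystem", function(x, ...) x@structure@atoms)

#' @rdname accessors
#' @export
setMethod("natoms", "MolecularStructure", function(x, ...) nrow(x@atoms))
#' @rdname accessors
#' @export
setMethod("natoms", "Trajectory", function(x, ...) nrow(x@template@atoms))
#' @rdname accessors
#' @export
setMethod("natoms", "ParameterizedSystem",
          function(x, ...) nrow(x@structure@atoms))

#' @rdname accessors
#' @export
setMethod("nframes", "Trajectory", function(x, ...) nrow(x@xyz))

#' @rdname accessors
#' @export
setMethod("frameCoords", "Trajectory", function(x, i, ...) {
  stopifnot(length(i) == 1, i >= 1, i <= nrow(x@xyz))
  matrix(x@xyz[i, ], ncol = 3, byrow = TRUE)
})

#' @rdname accessors
#' @export
setMethod("replicaIds", "Trajectory", function(x, ...) x@replica)

#' Residue keys of a structure
#'
#' Returns one `chain:resno[insert]:resname` key per residue, in atom
#' order. With `perAtom = TRUE` the key of each atom's residue is returned
#' instead (length = number of atoms).
#'
#' @param x a [MolecularStructure-class] (or object holding one).
#' @param perAtom logical.
#' @param ... unused.
#' @return character vector of residue keys.
#' @export
setMethod("residueKeys", "MolecularStructure", function(x, perAtom = FALSE, ...) {
  a <- x@atoms
  k <- paste0(a$chain, ":", a$resno, a$insert, ":", a$resname)
  if (perAtom) k else unique(k)
})
#' @rdname residueKeys-MolecularStructure-method
#' @export
setMethod("residueKeys", "ParameterizedSystem",
          function(x, perAtom = FALSE, ...) residueKeys(x@structure, perAtom))

#' Extract an energy component matrix
#'
#' @param x an [EnergyMatrix-class].
#' @param component one of `"coulomb"`, `"vdw"`, `"total"`.
#' @param ... unused.
#' @return numeric matrix (cross-replica mean) with residue dimnames.
#' @export
setGeneric("energyValues", function(x, component = "total", ...)
  standardGeneric("energyValues"))

#' @rdname energyValues
#' @export
setMethod("energyValues", "EnergyMatrix", function(x, component = "total", ...) {
  component <- match.arg(component, c("coulomb", "vdw", "total"))
  m <- switch(component, coulomb = x@coulomb, vdw = x@vdw,
              total = x@coulomb + x@vdw)
  dimnames(m) <- list(x@rowKeys, x@colKeys)
  m
})

#' Replica statistics layer of an EnergyMatrix
#'
#' @param x an [EnergyMatrix-class].
#' @param ... unused.
#' @return list with `nReplicas`, `perReplica` (per-replica component
#'   matrices), `sd` and `sem` (NULL when fewer than two replicas).
#' @export
setGeneric("replicaStats", function(x, ...) standardGeneric("replicaStats"))

#' @rdname replicaStats
#' @export
setMethod("replicaStats", "EnergyMatrix", function(x, ...) {
  list(nReplicas = length(x@perReplica), perReplica = x@perReplica,
       sd = if (length(x@sd)) x@sd else NULL,
       sem = if (length(x@sem)) x@sem else NULL)
})

#' @rdname replicaStats
#' @export
setMethod("replicaStats", "BindingReport", function(x, ...)
  list(perReplica = x@replicaStats, summary = x@summary))

#' Eigen spectrum accessors for ModeSet
#'
#' @param x a [ModeSet-class].
#' @param ... unused.
#' @name modeset-accessors
NULL

#' @rdname modeset-accessors
#' @export
setGeneric("modeValues", function(x, ...) standardGeneric("modeValues"))
#' @rdname modeset-accessors
#' @export
setGeneric("modeVectors", function(x, ...) standardGeneric("modeVectors"))
#' @rdname modeset-accessors
#' @export
setGeneric("modeProjections", function(x, ...) standardGeneric("modeProjections"))
#' @rdname modeset-accessors
#' @export
setGeneric("varianceFractions", function(x, ...) standardGeneric("varianceFractions"))

#' @rdname modeset-accessors
#' @export
setMethod("modeValues", "ModeSet", function(x, ...) x@values)
#' @rdname modeset-accessors
#' @export
setMethod("modeVectors", "ModeSet", function(x, ...) x@vectors)
#' @rdname modeset-accessors
#' @export
setMethod("modeProjections", "ModeSet", function(x, ...) x@projections)
#' @rdname modeset-accessors
#' @export
setMethod("varianceFractions", "ModeSet", function(x, ...) {
  tot <- sum(x@values)
  if (tot == 0) rep(0, length(x@values)) else x@values / tot
})

#' Cavity volume accessors
#'
#' @param x a [CavityResult-class].
#' @param ... unused.
#' @name cavity-accessors
NULL

#' @rdname cavity-accessors
#' @export
setGeneric("cavityVolume", function(x, ...) standardGeneric("cavityVolume"))
#' @rdname cavity-accessors
#' @export
setGeneric("clientVolume", function(x, ...) standardGeneric("clientVolume"))
#' @rdname cavity-accessors
#' @export
setGeneric("occupancy", function(x, ...) standardGeneric("occupancy"))

#' @rdname cavity-accessors
#' @export
setMethod("cavityVolume", "CavityResult", function(x, ...) x@cavityVolume)
#' @rdname cavity-accessors
#' @export
setMethod("clientVolume", "CavityResult", function(x, ...) x@clientVolume)
#' @rdname cavity-accessors
#' @export
setMethod("occupancy", "CavityResult", function(x, ...) x@occupancy)

setMethod("show", "MolecularStructure", function(object) {
  a <- object@atoms
  cat("MolecularStructure:", nrow(a), "atoms,",
      length(unique(paste(a$chain, a$resno, a$insert))), "residues,",
      "chains:", paste(unique(a$chain), collapse = " "), "\n")
  if (any(a$het))
    cat("  heteroatoms:", sum(a$het), "(",
        paste(unique(a$resname[a$het]), collapse = " "), ")\n")
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nrow(object@xyz), "frames x", natoms(object), "atoms;",
      "replicas:", paste(unique(object@replica), collapse = " "), "\n")
})

setMethod("show", "ParameterizedSystem", function(object) {
  cat("ParameterizedSystem:", natoms(object), "atoms;",
      nrow(object@exclusions), "excluded pairs,",
      nrow(object@scaled14), "scaled 1-4 pairs\n")
})

setMethod("show", "EnergyMatrix", function(object) {
  cat("EnergyMatrix:", length(object@rowKeys), "x", length(object@colKeys),
      "residue pairs;", length(object@perReplica), "replica(s)\n")
  tot <- object@coulomb + object@vdw
  i <- which.min(tot)
  cat(sprintf("  most favorable total: %s x %s = %.3f kcal/mol\n",
              object@rowKeys[(i - 1) %% nrow(tot) + 1],
              object@colKeys[(i - 1) %/% nrow(tot) + 1], tot[i]))
})

setMethod("show", "ModeSet", function(object) {
  vf <- varianceFractions(object)
  cat("ModeSet:", length(object@values), "modes over",
      length(object@atomIndices), "atoms; PC1 variance fraction",
      sprintf("%.3f", vf[1]), "\n")
})

setMethod("show", "CavityResult", function(object) {
  cat(sprintf("CavityResult: cavity %.1f A^3", object@cavityVolume))
  if (!is.na(object@occupancy))
    cat(sprintf("; client %.1f A^3 (occupancy %.3f)",
                object@clientVolume, object@occupancy))
  cat("\n")
})

setMethod("show", "BindingReport", function(object) {
  s <- object@summary
  cat("BindingReport (MM-GBSA, single-trajectory):\n")
  print(s, row.names = FALSE)
})

setMethod("show", "VoxelGrid", function(object) {
  cat("VoxelGrid:", paste(object@dims, collapse = " x "),
      "voxels at h =", object@spacing, "A;",
      sum(object@protein), "protein-occupied\n")
})
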