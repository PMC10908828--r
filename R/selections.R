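#' @include AllClasses.R
NULL

#' Select atoms by chain, residue range, residue name and atom name
#'
#' The selection algebra underlying every analysis stage. All criteria are
#' combined with AND; each accepts a vector (OR within the criterion).
#' `resno` takes integers or inclusive ranges (`342:349`). Evaluation is
#' deterministic and returns a sorted atom-index set, so selections can be
#' combined with `union()`, `intersect()` and `setdiff()`, or inverted
#' with [invertSelection()]. Referencing a chain absent from the structure
#' yields an empty selection with a warning rather than an error, so the
#' same pipeline configuration stays portable across structure dialects.
#'
#' @param structure a [MolecularStructure-class] (or
#'   [ParameterizedSystem-class]/[Trajectory-class], whose atom table is
#'   used).
#' @param chain character vector of chain identifiers.
#' @param resno integer vector of author residue numbers (ranges allowed).
#' @param resname character vector of 3-letter residue names.
#' @param name character vector of atom names (e.g. `"CA"`).
#' @param het logical: TRUE restricts to HETATM records, FALSE to ATOM
#'   records, NULL (default) keeps both.
#' @return sorted integer vector of atom indices.
#' @examples
#' s <- makeCavityPhantom(c(6, 6, 6))
#' length(selectAtoms(s, chain = "W"))
#' @export
selectAtoms <- function(structure, chain = NULL, resno = NULL,
                        resname = NULL, name = NULL, het = NULL) {
  a <- if (is(structure, "MolecularStructure")) structure@atoms else atoms(structure)
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) {
    missing <- setdiff(chain, unique(a$chain))
    if (length(missing))
      warning("chain(s) not present in structure: ",
              paste(missing, collapse = ", "), call. = FALSE)
    keep <- keep & a$chain %in% chain
  }
  if (!is.null(resno)) keep <- keep & a$resno %in% resno
  if (!is.null(resname)) keep <- keep & a$resname %in% resname
  if (!is.null(name)) keep <- keep & a$name %in% name
  if (!is.null(het)) keep <- keep & (a$het == het)
  sort(which(keep))
}

#' Complement of a selection over a structure's atoms
#'
#' @param structure object carrying the atom table.
#' @param selection integer atom indices.
#' @return sorted integer vector of the remaining atom indices.
#' @export
invertSelection <- function(structure, selection) {
  a <- if (is(structure, "MolecularStructure")) structure@atoms else atoms(structure)
  sort(setdiff(seq_len(nrow(a)), selection))
}
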