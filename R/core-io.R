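#' @include AllClasses.R
NULL

# Pre-scan a PDB file so contract errors carry line numbers, then check
# that every model has the same atom count before handing off to bio3d.
.validatePdbLines <- function(lines, path) {
  isAtom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(isAtom)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("malformed fixed-column record at line ", i, " of ", path,
           " (shorter than coordinate fields)", call. = FALSE)
    coords <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(coords))))
      stop("malformed fixed-column record at line ", i, " of ", path,
           " (non-numeric coordinate field)", call. = FALSE)
  }
  modelStarts <- grep("^MODEL", lines)
  if (length(modelStarts) > 1) {
    ends <- c(modelStarts[-1] - 1L, length(lines))
    counts <- vapply(seq_along(modelStarts), function(k)
      sum(isAtom[modelStarts[k]:ends[k]]), integer(1))
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count across models in ", path, ": ",
           paste(counts, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

.atomsFromBio3d <- function(pdb) {
  a <- pdb$atom
  ins <- a$insert; ins[is.na(ins)] <- ""
  ch <- a$chain; ch[is.na(ch)] <- " "
  occ <- a$o; occ[is.na(occ)] <- 1
  b <- a$b; b[is.na(b)] <- 0
  el <- a$elesy; el[is.na(el)] <- ""
  data.frame(serial = a$eleno, name = a$elety, element = trimws(el),
             resname = a$resid, resno = a$resno, insert = ins, chain = ch,
             x = a$x, y = a$y, z = a$z, occupancy = occ, b = b,
             het = a$type == "HETATM", stringsAsFactors = FALSE)
}

# Alternate locations: keep the highest-occupancy conformer of each
# (chain, resno, insert, name); ties go to the first record.
.resolveAltloc <- function(atoms, alt) {
  key <- paste(atoms$chain, atoms$resno, atoms$insert, atoms$name)
  if (!anyDuplicated(key)) return(list(atoms = atoms, dropped = 0L))
  keep <- unlist(lapply(split(seq_len(nrow(atoms)), key), function(idx) {
    idx[which.max(atoms$occupancy[idx])]
  }), use.names = FALSE)
  keep <- sort(keep)
  list(atoms = atoms[keep, , drop = FALSE], dropped = nrow(atoms) - length(keep))
}

#' Read a structure from a PDB file
#'
#' Fixed-column PDB v3.3 `ATOM`/`HETATM` records are parsed (via bio3d)
#' after a format pre-scan that reports malformed records by line number.
#' HETATM ligand records (ATP, Mg, ...) are retained and flagged in the
#' `het` column. When several alternate locations are present the
#' highest-occupancy conformer is kept and the number of dropped records
#' reported via a message. For multi-model files the first model is
#' returned; use [readTrajectory()] to obtain all frames.
#'
#' @param path path to a PDB file.
#' @return a [MolecularStructure-class].
#' @examples
#' pdb <- system.file("examples/1hel.pdb", package = "bio3d")
#' s <- readStructure(pdb)
#' natoms(s)
#' @export
readStructure <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  .validatePdbLines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))
  atoms <- .atomsFromBio3d(pdb)
  res <- .resolveAltloc(atoms, pdb$atom$alt)
  if (res$dropped > 0)
    message("dropped ", res$dropped, " alternate-location record(s), ",
            "keeping highest occupancy")
  rownames(res$atoms) <- NULL
  new("MolecularStructure", atoms = res$atoms, title = basename(path))
}

#' Read a trajectory (multi-model PDB or plain frames file)
#'
#' Multi-model PDB is the mandatory trajectory dialect; a plain
#' whitespace-delimited frames file (header plus F blocks of N x 3
#' coordinates, see [writeFrames()]) is accepted for synthetic
#' trajectories and requires an atom `template`. Frame 1 of a multi-model
#' file equals the coordinates of the returned template structure.
#'
#' @param path input file.
#' @param format `"auto"` (by extension/content), `"pdb"` or `"frames"`.
#' @param template a [MolecularStructure-class]; required for `"frames"`.
#' @param replica optional integer vector of per-frame replica labels
#'   (recycled per frame block); defaults to a single replica, or to the
#'   labels stored in a frames file.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, format = c("auto", "pdb", "frames"),
                           template = NULL, replica = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else {
      first <- readLines(path, n = 1, warn = FALSE)
      if (grepl("^(ATOM|HETATM|MODEL|REMARK|HEADER|CRYST)", first)) "pdb" else "frames"
    }
  }
  if (format == "frames") {
    if (is.null(template))
      stop("a template structure is required to read a frames file")
    return(.readFramesFile(path, template, replica))
  }
  lines <- readLines(path, warn = FALSE)
  .validatePdbLines(lines, path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, verbose = FALSE))
  atoms <- .atomsFromBio3d(pdb)
  res <- .resolveAltloc(atoms, pdb$atom$alt)
  keep <- match(paste(res$atoms$serial, res$atoms$name),
                paste(atoms$serial, atoms$name))
  xyz <- unclass(pdb$xyz)  # bio3d "xyz" class -> plain matrix
  if (!is.matrix(xyz)) xyz <- matrix(xyz, nrow = 1)
  if (res$dropped > 0) {
    cols <- as.vector(rbind(3 * keep - 2, 3 * keep - 1, 3 * keep))
    xyz <- xyz[, cols, drop = FALSE]
    message("dropped ", res$dropped, " alternate-location record(s)")
  }
  rownames(res$atoms) <- NULL
  tmpl <- new("MolecularStructure", atoms = res$atoms, title = basename(path))
  f <- nrow(xyz)
  rep <- if (is.null(replica)) rep.int(1L, f) else as.integer(rep(replica, length.out = f))
  new("Trajectory", xyz = xyz, template = tmpl, replica = rep,
      time = rep(NA_real_, f))
}

#' Write a structure (or trajectory) as fixed-column PDB
#'
#' Optionally replaces the temperature-factor column with a supplied
#' scalar, e.g. a normalized RMSF-based B-factor for visualization. A
#' per-residue scalar is broadcast to every atom of the residue.
#' Round-tripping through [readStructure()] reproduces coordinates to
#' 3 decimals and the scalar column to 2 decimals (PDB fixed-format
#' precision).
#'
#' @param x a [MolecularStructure-class] or [Trajectory-class] (the latter
#'   is written as a multi-model file).
#' @param path output file.
#' @param scalars optional numeric vector, one value per atom or one per
#'   residue (broadcast); written to the B-factor column.
#' @return invisibly, the path.
#' @export
writeStructure <- function(x, path, scalars = NULL) {
  if (is(x, "Trajectory")) {
    a <- atoms(x); xyz <- x@xyz
  } else {
    a <- atoms(x)
    xyz <- matrix(as.vector(t(cbind(a$x, a$y, a$z))), nrow = 1)
  }
  b <- a$b
  if (!is.null(scalars)) {
    if (!all(is.finite(scalars))) stop("scalars must be finite")
    rk <- paste(a$chain, a$resno, a$insert)
    nres <- length(unique(rk))
    if (length(scalars) == nrow(a)) {
      b <- scalars
    } else if (length(scalars) == nres) {
      b <- scalars[match(rk, unique(rk))]
    } else {
      stop("scalars must have one value per atom (", nrow(a),
           ") or per residue (", nres, "), got ", length(scalars))
    }
  }
  ins <- a$insert; ins[ins == ""] <- ""
  bio3d::write.pdb(file = path, xyz = xyz,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno, insert = ins,
                   o = a$occupancy, b = b, elesy = a$element)
  invisible(path)
}

#' Write / read a plain-text frames file
#'
#' A binary-free trajectory dialect for synthetic data: a two-line header
#' (`frames F atoms N` and per-frame replica labels) followed by F blocks
#' of N lines of `x y z` in Angstrom at fixed precision, so identical
#' seeds yield byte-identical files.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @return invisibly, the path.
#' @export
writeFrames <- function(trajectory, path) {
  xyz <- trajectory@xyz
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("frames", nrow(xyz), "atoms", ncol(xyz) %/% 3),
               paste("replica", paste(trajectory@replica, collapse = " "))), con)
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    writeLines(sprintf("%.6f %.6f %.6f", m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

.readFramesFile <- function(path, template, replica = NULL) {
  lines <- readLines(path, warn = FALSE)
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(hdr) != 4 || hdr[1] != "frames" || hdr[3] != "atoms")
    stop("not a frames file (bad header): ", path)
  f <- as.integer(hdr[2]); n <- as.integer(hdr[4])
  if (n != natoms(template))
    stop("frames file atom count (", n, ") does not match template (",
         natoms(template), ")")
  repHdr <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  reps <- as.integer(repHdr[-1])
  nums <- scan(text = paste(lines[-(1:2)], collapse = "\n"), quiet = TRUE)
  if (length(nums) != f * n * 3)
    stop("frames file has ", length(nums), " values; expected ", f * n * 3)
  xyz <- matrix(nums, nrow = f, ncol = 3 * n, byrow = TRUE)
  if (!is.null(replica)) reps <- as.integer(rep(replica, length.out = f))
  new("Trajectory", xyz = xyz, template = template, replica = reps,
      time = rep(NA_real_, f))
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector of one-letter sequences.
#' @export
readFastaSequences <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}
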