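#' @include AllClasses.R
NULL

#' Read a per-atom parameter table
#'
#' TSV with header columns `res_name`, `atom_name`, `charge_e`, `sigma_A`,
#' `epsilon_kcal`, `born_radius_A`, `gb_screen`. A table may instead carry
#' a `serial` column for explicit per-atom assignment. Parameters are
#' inputs of the analysis (they come from a force field such as Amber
#' FF14SB); this package never derives them.
#'
#' @param path TSV file.
#' @return data.frame.
#' @export
readParameterTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("charge_e", "sigma_A", "epsilon_kcal", "born_radius_A", "gb_screen")
  if (!all(need %in% names(tab)))
    stop("parameter table is missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Read a bond list
#'
#' TSV with columns `serial_i`, `serial_j` giving covalent bonds by atom
#' serial number; used to build the exclusion topology.
#'
#' @param path TSV file.
#' @return two-column integer matrix.
#' @export
readBondList <- function(path) {
  tab <- utils::read.delim(path)
  if (!all(c("serial_i", "serial_j") %in% names(tab)))
    stop("bond list needs columns serial_i, serial_j")
  cbind(as.integer(tab$serial_i), as.integer(tab$serial_j))
}

# Graph distances up to 3 bonds give the exclusion topology:
# distance 1 or 2 -> excluded, distance 3 -> scaled 1-4 pair.
.exclusionsFromBonds <- function(bondsIdx, n) {
  if (is.null(bondsIdx) || nrow(bondsIdx) == 0)
    return(list(excl = matrix(integer(0), 0, 2),
                s14 = matrix(integer(0), 0, 2)))
  adj <- vector("list", n)
  for (k in seq_len(nrow(bondsIdx))) {
    i <- bondsIdx[k, 1]; j <- bondsIdx[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  excl <- list(); s14 <- list()
  for (i in seq_len(n)) {
    d1 <- unique(adj[[i]])
    d2 <- setdiff(unique(unlist(adj[d1])), c(i, d1))
    d3 <- setdiff(unique(unlist(adj[d2])), c(i, d1, d2))
    ex <- c(d1, d2); ex <- ex[ex > i]
    sc <- d3[d3 > i]
    if (length(ex)) excl[[length(excl) + 1L]] <- cbind(i, ex)
    if (length(sc)) s14[[length(s14) + 1L]] <- cbind(i, sc)
  }
  toMat <- function(l) if (length(l)) do.call(rbind, l) else matrix(integer(0), 0, 2)
  e <- toMat(excl); s <- toMat(s14)
  storage.mode(e) <- "integer"; storage.mode(s) <- "integer"
  dimnames(e) <- NULL; dimnames(s) <- NULL
  list(excl = e, s14 = s)
}

#' Attach force-field parameters to a structure
#'
#' Every atom must resolve to exactly one parameter row, either through a
#' (`res_name`, `atom_name`) key or an explicit `serial` column; atoms
#' without a row abort with a list of the offenders. The bond list (if
#' any) is walked to exclude 1-2 and 1-3 pairs and scale 1-4 pairs by the
#' conventional Amber-family factors (electrostatic 1/1.2, Lennard-Jones
#' 1/2).
#'
#' @param structure a [MolecularStructure-class].
#' @param table parameter data.frame (see [readParameterTable()]) or path.
#' @param bonds two-column matrix of bonded atom serial pairs, a path to a
#'   bond-list TSV, or NULL for no bonded topology.
#' @param coulScale14,ljScale14 1-4 scale factors.
#' @return a [ParameterizedSystem-class].
#' @export
loadParameters <- function(structure, table, bonds = NULL,
                           coulScale14 = 1 / 1.2, ljScale14 = 0.5) {
  if (is.character(table)) table <- readParameterTable(table)
  if (is.character(bonds)) bonds <- readBondList(bonds)
  a <- structure@atoms
  n <- nrow(a)
  if ("serial" %in% names(table)) {
    idx <- match(a$serial, table$serial)
  } else {
    idx <- match(paste(a$resname, a$name), paste(table$res_name, table$atom_name))
  }
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    stop("no parameter row for atom(s): ",
         paste(sprintf("%s:%s%s:%s", a$chain[bad], a$resno[bad],
                       a$insert[bad], a$name[bad]), collapse = ", "),
         call. = FALSE)
  }
  params <- data.frame(charge = table$charge_e[idx],
                       sigma = table$sigma_A[idx],
                       epsilon = table$epsilon_kcal[idx],
                       rborn = table$born_radius_A[idx],
                       screen = table$gb_screen[idx])
  bondsIdx <- NULL
  if (!is.null(bonds) && nrow(bonds)) {
    bi <- match(bonds[, 1], a$serial); bj <- match(bonds[, 2], a$serial)
    if (anyNA(bi) || anyNA(bj))
      stop("bond list references unknown atom serials")
    bondsIdx <- cbind(bi, bj)
  }
  topo <- .exclusionsFromBonds(bondsIdx, n)
  new("ParameterizedSystem", structure = structure, params = params,
      exclusions = topo$excl, scaled14 = topo$s14,
      coulScale14 = coulScale14, ljScale14 = ljScale14)
}
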