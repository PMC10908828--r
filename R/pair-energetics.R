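#' @include AllClasses.R
NULL

# Scale-factor matrices (nA x nB) encoding the exclusion topology for an
# inter-group computation: 0 for excluded (1-2/1-3) pairs, the 1-4 factors
# for scaled pairs, 1 otherwise.
.pairScaleMasks <- function(system, selA, selB) {
  nA <- length(selA); nB <- length(selB)
  coul <- matrix(1, nA, nB); lj <- matrix(1, nA, nB)
  place <- function(pairs, cval, lval) {
    if (!nrow(pairs)) return()
    for (ord in 1:2) {
      i <- match(pairs[, ord], selA); j <- match(pairs[, 3 - ord], selB)
      ok <- !is.na(i) & !is.na(j)
      if (any(ok)) {
        idx <- cbind(i[ok], j[ok])
        coul[idx] <<- cval; lj[idx] <<- lval
      }
    }
  }
  place(system@scaled14, system@coulScale14, system@ljScale14)
  place(system@exclusions, 0, 0)
  list(coul = coul, lj = lj)
}

# Frame-wise inter-group coulomb and LJ energy matrices (atom x atom).
# Gas-phase point-charge Coulomb (eps_in = 1 by default) and 12-6 LJ with
# arithmetic sigma / geometric epsilon combining; no distance cutoff, as
# appropriate for post-hoc decomposition (and what makes the conservation
# identity exact).
.interEnergyMatrices <- function(system, coords, selA, selB, masks,
                                 epsIn = 1) {
  p <- system@params
  cA <- coords[selA, , drop = FALSE]; cB <- coords[selB, , drop = FALSE]
  dx <- outer(cA[, 1], cB[, 1], "-")
  dy <- outer(cA[, 2], cB[, 2], "-")
  dz <- outer(cA[, 3], cB[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  live <- masks$coul != 0 | masks$lj != 0
  if (any(r[live] < 0.1))
    stop("interatomic distance below 0.1 A (clash or corrupt frame)",
         call. = FALSE)
  r[r == 0] <- Inf  # fully excluded coincident pairs contribute nothing
  qq <- outer(p$charge[selA], p$charge[selB])
  ecoul <- .KE * qq / (epsIn * r) * masks$coul
  sig <- outer(p$sigma[selA], p$sigma[selB], "+") / 2
  eps <- sqrt(outer(p$epsilon[selA], p$epsilon[selB]))
  sr6 <- (sig / r)^6
  evdw <- 4 * eps * (sr6 * sr6 - sr6) * masks$lj
  list(coulomb = ecoul, vdw = evdw)
}

#' Coulomb and van der Waals energy of one atom pair
#'
#' Point-charge Coulomb `k_e q_i q_j / (eps_in r)` with
#' `k_e = 332.0637 kcal A / (mol e^2)` and 12-6 Lennard-Jones
#' `4 eps_ij [(sig_ij/r)^12 - (sig_ij/r)^6]` with arithmetic-mean sigma
#' and geometric-mean epsilon. Excluded (1-2/1-3) pairs contribute zero;
#' 1-4 pairs are multiplied by their scale factors. Distances below 0.1 A
#' abort (clash / corrupt frame).
#'
#' @param system a [ParameterizedSystem-class].
#' @param i,j atom indices (i != j).
#' @param coords N x 3 coordinate matrix; defaults to the structure's own
#'   coordinates.
#' @return named numeric vector `c(coulomb = , vdw = )` in kcal/mol.
#' @export
atomPairEnergy <- function(system, i, j, coords = NULL) {
  stopifnot(i != j)
  if (is.null(coords)) {
    a <- atoms(system)
    coords <- cbind(a$x, a$y, a$z)
  }
  masks <- .pairScaleMasks(system, i, j)
  e <- .interEnergyMatrices(system, coords, i, j, masks)
  c(coulomb = e$coulomb[1, 1], vdw = e$vdw[1, 1])
}

# Direct inter-group nonbonded energy for one frame; the reference the
# residue-pair matrix must conserve.
.interGroupEnergy <- function(system, coords, selA, selB) {
  masks <- .pairScaleMasks(system, selA, selB)
  e <- .interEnergyMatrices(system, coords, selA, selB, masks)
  c(coulomb = sum(e$coulomb), vdw = sum(e$vdw))
}

.replicaLayers <- function(perReplica) {
  r <- length(perReplica)
  mean2 <- function(comp) Reduce(`+`, lapply(perReplica, `[[`, comp)) / r
  coul <- mean2("coulomb"); vdw <- mean2("vdw")
  sd <- list(); sem <- list()
  if (r >= 2) {
    sdOf <- function(get) {
      ms <- lapply(perReplica, get)
      m <- Reduce(`+`, ms) / r
      sqrt(Reduce(`+`, lapply(ms, function(x) (x - m)^2)) / (r - 1))
    }
    sd <- list(coulomb = sdOf(function(x) x$coulomb),
               vdw = sdOf(function(x) x$vdw),
               total = sdOf(function(x) x$coulomb + x$vdw))
    sem <- lapply(sd, function(m) m / sqrt(r))
  }
  list(coulomb = coul, vdw = vdw, sd = sd, sem = sem)
}

#' Residue-pair interaction energy matrix over a trajectory
#'
#' For two disjoint atom selections, every frame's atom-pair coulombic and
#' van der Waals energies are summed over the atoms spanning each residue
#' pair and averaged over frames, giving the decomposition heatmaps of
#' chaperone-client interface analysis. All atom pairs enter (no distance
#' cutoff). With several replicas the main matrices are the cross-replica
#' means of the per-replica frame averages, and the stats layer carries
#' per-replica means, SD of the means and SEM = SD/sqrt(R); with a single
#' replica SD/SEM are flagged missing.
#'
#' @param system a [ParameterizedSystem-class].
#' @param trajectory a [Trajectory-class] over the same atoms (an N x 3
#'   matrix or [MolecularStructure-class] is accepted as a single frame).
#' @param selA,selB disjoint atom-index selections (rows/columns).
#' @param stride frame sampling stride (default 1: every frame).
#' @param epsIn interior dielectric for the coulombic term (default 1,
#'   gas-phase decomposition).
#' @return an [EnergyMatrix-class].
#' @export
residuePairMatrix <- function(system, trajectory, selA, selB, stride = 1,
                              epsIn = 1) {
  if (length(selA) == 0 || length(selB) == 0)
    stop("empty selection", call. = FALSE)
  if (length(intersect(selA, selB)))
    stop("selections must be disjoint at the atom level", call. = FALSE)
  if (is(trajectory, "MolecularStructure")) {
    a <- trajectory@atoms
    xyz <- matrix(as.vector(t(cbind(a$x, a$y, a$z))), nrow = 1)
    trajectory <- new("Trajectory", xyz = xyz, template = trajectory,
                      replica = 1L, time = NA_real_)
  } else if (is.matrix(trajectory) && ncol(trajectory) == 3) {
    xyz <- matrix(as.vector(t(trajectory)), nrow = 1)
    trajectory <- new("Trajectory", xyz = xyz, template = system@structure,
                      replica = 1L, time = NA_real_)
  }
  perAtomKey <- residueKeys(system@structure, perAtom = TRUE)
  rowKeys <- unique(perAtomKey[selA]); colKeys <- unique(perAtomKey[selB])
  fA <- factor(perAtomKey[selA], levels = rowKeys)
  fB <- factor(perAtomKey[selB], levels = colKeys)
  masks <- .pairScaleMasks(system, selA, selB)
  frames <- seq(1, nframes(trajectory), by = stride)
  reps <- replicaIds(trajectory)[frames]
  perReplica <- lapply(unique(reps), function(r) {
    fs <- frames[reps == r]
    accC <- matrix(0, length(rowKeys), length(colKeys))
    accV <- accC
    agg <- function(mat) {  # atom x atom -> residue x residue, key order kept
      m1 <- rowsum(mat, fA)[rowKeys, , drop = FALSE]
      t(rowsum(t(m1), fB)[colKeys, , drop = FALSE])
    }
    for (f in fs) {
      e <- .interEnergyMatrices(system, frameCoords(trajectory, f),
                                selA, selB, masks, epsIn)
      accC <- accC + agg(e$coulomb)
      accV <- accV + agg(e$vdw)
    }
    list(coulomb = accC / length(fs), vdw = accV / length(fs))
  })
  lay <- .replicaLayers(perReplica)
  new("EnergyMatrix", coulomb = lay$coulomb, vdw = lay$vdw,
      rowKeys = rowKeys, colKeys = colKeys, perReplica = perReplica,
      sd = lay$sd, sem = lay$sem)
}

#' Combine per-replica energy matrices into one with replica statistics
#'
#' Input matrices must share row/column residue identities. The result's
#' main values are the average of the per-replica means; SD is the
#' standard deviation of the per-replica means and SEM = SD/sqrt(R).
#' With a single replica SD/SEM are reported missing.
#'
#' @param matrices list of [EnergyMatrix-class], one per replica (each
#'   contributes its own per-replica layers).
#' @return an [EnergyMatrix-class].
#' @export
aggregateReplicas <- function(matrices) {
  stopifnot(length(matrices) >= 1)
  rk <- matrices[[1]]@rowKeys; ck <- matrices[[1]]@colKeys
  for (m in matrices)
    if (!identical(m@rowKeys, rk) || !identical(m@colKeys, ck))
      stop("replica matrices must have identical row/column residues")
  perReplica <- unlist(lapply(matrices, function(m)
    if (length(m@perReplica)) m@perReplica
    else list(list(coulomb = m@coulomb, vdw = m@vdw))), recursive = FALSE)
  lay <- .replicaLayers(perReplica)
  new("EnergyMatrix", coulomb = lay$coulomb, vdw = lay$vdw,
      rowKeys = rk, colKeys = ck, perReplica = perReplica,
      sd = lay$sd, sem = lay$sem)
}

#' Rank residue pairs and partition the matrix into labelled blocks
#'
#' Returns the top-k most favorable (most negative) residue pairs of the
#' requested component, and, when a region map is supplied, per-block
#' energy sums (e.g. luminal vs peripheral client residues against each
#' protomer) plus a protomer-asymmetry score. The asymmetry score is the
#' difference between the two row-label block totals and is zero for a
#' matrix symmetric under protomer swap.
#'
#' @param em an [EnergyMatrix-class].
#' @param k number of top pairs to report.
#' @param component `"coulomb"`, `"vdw"` or `"total"`.
#' @param regionMap named character vector mapping residue keys
#'   (`chain:resno:resname`) to region labels; unlabelled residues are
#'   assigned `"other"` with a warning.
#' @return list with `topPairs` (data.frame), and when `regionMap` is
#'   given, `blockSums` (label x label matrix) and `asymmetry` (numeric,
#'   only when exactly two row labels are present).
#' @export
rankAndPartition <- function(em, k = 10, component = "total",
                             regionMap = NULL) {
  m <- energyValues(em, component)
  ord <- order(m)[seq_len(min(k, length(m)))]
  ri <- (ord - 1) %% nrow(m) + 1; ci <- (ord - 1) %/% nrow(m) + 1
  co <- energyValues(em, "coulomb"); vd <- energyValues(em, "vdw")
  top <- data.frame(rowResidue = em@rowKeys[ri], colResidue = em@colKeys[ci],
                    coulomb = co[cbind(ri, ci)], vdw = vd[cbind(ri, ci)],
                    total = co[cbind(ri, ci)] + vd[cbind(ri, ci)],
                    stringsAsFactors = FALSE)
  out <- list(topPairs = top)
  if (!is.null(regionMap)) {
    lab <- function(keys) {
      l <- unname(regionMap[keys])
      if (anyNA(l)) {
        warning("unlabelled residue(s) assigned region 'other': ",
                paste(keys[is.na(l)], collapse = ", "), call. = FALSE)
        l[is.na(l)] <- "other"
      }
      l
    }
    rl <- lab(em@rowKeys); cl <- lab(em@colKeys)
    block <- rowsum(t(rowsum(m, rl)), cl)
    out$blockSums <- t(block)
    if (length(unique(rl)) == 2) {
      tot <- rowSums(out$blockSums)
      out$asymmetry <- unname(tot[1] - tot[2])
    }
  }
  out
}

#' Export an energy matrix as TSV plus a clipped rendering copy
#'
#' The TSV always keeps full precision (rows are group-A residues as
#' `chain:resno:resname`, columns group B). The returned rendering matrix
#' has values clamped to `[-clip, +clip]` kcal/mol, matching the
#' convention of interaction heatmaps drawn with a +-1 kcal/mol colour
#' threshold where negative (favorable) contacts read blue and positive
#' (unfavorable) read red.
#'
#' @param em an [EnergyMatrix-class].
#' @param path output TSV path.
#' @param clip positive clamp for the rendering copy (default 1 kcal/mol).
#' @param component `"coulomb"`, `"vdw"` or `"total"`.
#' @return invisibly, the clipped rendering matrix.
#' @export
exportHeatmapTable <- function(em, path, clip = 1, component = "total") {
  stopifnot(clip > 0)
  m <- energyValues(em, component)
  utils::write.table(m, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(pmin(pmax(m, -clip), clip))
}
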