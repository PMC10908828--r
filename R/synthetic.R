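#' @include AllClasses.R
NULL

# Run expr with a locally seeded RNG, restoring the caller's RNG state,
# so generators are deterministic without disturbing the session.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.buildStructure <- function(chain, resno, resname, name, xyz, het = FALSE,
                            title = "synthetic") {
  n <- length(chain)
  atoms <- data.frame(serial = seq_len(n), name = name,
                      element = substr(name, 1, 1), resname = resname,
                      resno = as.integer(resno), insert = "", chain = chain,
                      x = round(xyz[, 1], 6), y = round(xyz[, 2], 6),
                      z = round(xyz[, 3], 6),
                      occupancy = 1, b = 0,
                      het = rep(het, length.out = n),
                      stringsAsFactors = FALSE)
  new("MolecularStructure", atoms = atoms, title = title)
}

.paramTable <- function(structure, charge, sigma, epsilon, rborn, screen) {
  a <- atoms(structure)
  n <- nrow(a)
  data.frame(serial = a$serial,
             res_name = a$resname, atom_name = a$name,
             charge_e = rep(charge, length.out = n),
             sigma_A = rep(sigma, length.out = n),
             epsilon_kcal = rep(epsilon, length.out = n),
             born_radius_A = rep(rborn, length.out = n),
             gb_screen = rep(screen, length.out = n))
}

#' Two-atom ion pair system
#'
#' The smallest parameterized system: two unit charges (chains A and B,
#' one residue each) at separation `r` along x, with no exclusions. At
#' `r = 3.320637` A the coulombic energy is exactly -100 kcal/mol for
#' opposite unit charges.
#'
#' @param r separation in A.
#' @param q charges (e) of the two atoms.
#' @param sigma,epsilon,rborn,screen shared nonbonded parameters.
#' @return a [ParameterizedSystem-class].
#' @export
makeIonPair <- function(r = 3.320637, q = c(1, -1), sigma = 3.0,
                        epsilon = 0, rborn = 1.5, screen = 0.8) {
  s <- .buildStructure(chain = c("A", "B"), resno = c(1L, 1L),
                       resname = c("ION", "ION"), name = c("I1", "I2"),
                       xyz = rbind(c(0, 0, 0), c(r, 0, 0)),
                       title = "ion pair")
  tab <- .paramTable(s, charge = q, sigma = sigma, epsilon = epsilon,
                     rborn = rborn, screen = screen)
  loadParameters(s, tab)
}

#' Deterministic parameterized toy complex
#'
#' A multi-chain pseudo-protein with two atoms per residue (`CA` on the
#' backbone curve, `CB` offset), a complete per-serial parameter table
#' and a backbone/side-chain bond list, so the exclusion topology and
#' every downstream energetics stage can be exercised at a scale where
#' brute-force oracles are fast. The same seed yields bit-identical
#' output.
#'
#' @param nChains number of chains (default 2; chain 1 is the designated
#'   receptor, chain 2 the ligand for binding tests).
#' @param residuesPerChain residues per chain.
#' @param geometry `"helix"` (default) or `"slab"`.
#' @param chargePattern `"zero"`, `"alternating"` (+q/-q per residue on
#'   CB), or a numeric vector of per-atom charges (recycled).
#' @param q magnitude used by `"alternating"`.
#' @param jitter Gaussian positional noise in A (seeded).
#' @param seed integer seed.
#' @return list with `structure`, `parameterTable`, `bonds`, `system` (a
#'   ready [ParameterizedSystem-class]), `receptorSel`, `ligandSel`.
#' @export
makeToyComplex <- function(nChains = 2, residuesPerChain = 5,
                           geometry = c("helix", "slab"),
                           chargePattern = "alternating", q = 0.2,
                           jitter = 0, seed = 1) {
  geometry <- match.arg(geometry)
  stopifnot(nChains >= 1, residuesPerChain >= 1)
  .withSeed(seed, {
    chains <- LETTERS[seq_len(nChains)]
    rows <- list()
    for (ci in seq_len(nChains)) {
      for (ri in seq_len(residuesPerChain)) {
        if (geometry == "helix") {
          ang <- ri * 100 * pi / 180
          base <- c(3 * cos(ang), 3 * sin(ang), 1.5 * ri)
          offs <- c(0.8 * cos(ang), 0.8 * sin(ang), 0)
        } else {
          base <- c(3.8 * ri, 0, 0)
          offs <- c(0, 1.5, 0)
        }
        base <- base + c(9 * (ci - 1), 0, 0)
        rows[[length(rows) + 1L]] <-
          data.frame(chain = chains[ci], resno = ri,
                     name = c("CA", "CB"),
                     x = c(base[1], base[1] + offs[1]),
                     y = c(base[2], base[2] + offs[2]),
                     z = c(base[3], base[3] + offs[3]))
      }
    }
    df <- do.call(rbind, rows)
    xyz <- cbind(df$x, df$y, df$z)
    if (jitter > 0) xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, jitter),
                                        ncol = 3)
    s <- .buildStructure(df$chain, df$resno, "ALA", df$name, xyz,
                         title = "toy complex")
    a <- atoms(s)
    charges <- if (is.numeric(chargePattern)) {
      rep(chargePattern, length.out = nrow(a))
    } else if (chargePattern == "zero") {
      rep(0, nrow(a))
    } else {  # alternating on CB atoms, sign by residue parity
      ifelse(a$name == "CB", ifelse(a$resno %% 2 == 0, -q, q), 0)
    }
    tab <- .paramTable(s, charge = charges, sigma = 3.2, epsilon = 0.1,
                       rborn = 1.5, screen = 0.8)
    # backbone CA(i)-CA(i+1) within a chain, plus CA(i)-CB(i)
    caIdx <- which(a$name == "CA")
    bonds <- list()
    for (i in caIdx) {
      bonds[[length(bonds) + 1L]] <- c(a$serial[i], a$serial[i + 1])  # CB
      nxt <- which(a$name == "CA" & a$chain == a$chain[i] &
                     a$resno == a$resno[i] + 1)
      if (length(nxt))
        bonds[[length(bonds) + 1L]] <- c(a$serial[i], a$serial[nxt])
    }
    bonds <- do.call(rbind, bonds)
    sys <- loadParameters(s, tab, bonds)
    list(structure = s, parameterTable = tab, bonds = bonds, system = sys,
         receptorSel = which(a$chain == chains[1]),
         ligandSel = if (nChains >= 2) which(a$chain == chains[2]) else integer(0))
  })
}

#' Multi-replica Gaussian trajectory with planted fluctuation modes
#'
#' Frames are `mean + sum_k eta_k sigma_k d_k + isotropic noise`, with
#' `eta` standard normal, the planted 3N directions `d_k`
#' orthonormalized before use, and per-replica sub-seeds derived as
#' `seed + replica index`, emulating the statistical structure that RMSF
#' and essential-dynamics analyses assume in multi-replica simulation
#' studies.
#'
#' @param structure a [MolecularStructure-class] providing the mean
#'   coordinates and atom template.
#' @param modes 3N x K matrix of planted directions (NULL for pure
#'   isotropic noise).
#' @param sigmas per-mode amplitudes (A), length K.
#' @param noise isotropic per-coordinate noise SD (A).
#' @param nFrames frames per replica.
#' @param nReplicas replica count.
#' @param seed master seed.
#' @return a [Trajectory-class] with `nFrames * nReplicas` frames.
#' @export
makeGaussianTrajectory <- function(structure, modes = NULL, sigmas = NULL,
                                   noise = 0.1, nFrames = 100,
                                   nReplicas = 1, seed = 1) {
  a <- atoms(structure)
  n3 <- 3L * nrow(a)
  mean3 <- as.vector(t(cbind(a$x, a$y, a$z)))
  if (!is.null(modes)) {
    modes <- as.matrix(modes)
    stopifnot(nrow(modes) == n3, length(sigmas) == ncol(modes),
              all(sigmas > 0))
    modes <- qr.Q(qr(modes))[, seq_len(ncol(modes)), drop = FALSE]
  }
  xyz <- matrix(NA_real_, nFrames * nReplicas, n3)
  for (r in seq_len(nReplicas)) {
    block <- .withSeed(seed + r, {
      fr <- matrix(stats::rnorm(nFrames * n3, 0, noise), nFrames, n3)
      if (!is.null(modes)) {
        eta <- matrix(stats::rnorm(nFrames * ncol(modes)), nFrames)
        fr <- fr + eta %*% (t(modes) * sigmas)
      }
      sweep(fr, 2, mean3, "+")
    })
    xyz[(r - 1) * nFrames + seq_len(nFrames), ] <- block
  }
  new("Trajectory", xyz = xyz, template = structure,
      replica = rep(seq_len(nReplicas), each = nFrames),
      time = rep(NA_real_, nFrames * nReplicas))
}

#' Planted fluctuation directions orthogonal to rigid-body motion
#'
#' Draws `nModes` random 3N directions, projects out the six rigid-body
#' modes (translations and infinitesimal rotations about the centroid) of
#' the structure, and orthonormalizes. Rigid components would be removed
#' by the superposition step of any fluctuation analysis, so planted
#' modes must live in the internal-motion subspace to be recoverable.
#'
#' @param structure a [MolecularStructure-class].
#' @param nModes number of directions.
#' @param seed integer seed.
#' @return 3N x nModes matrix of orthonormal internal-motion directions.
#' @export
makePlantedModes <- function(structure, nModes = 1, seed = 1) {
  a <- atoms(structure)
  n <- nrow(a); n3 <- 3L * n
  xyz <- cbind(a$x, a$y, a$z)
  ctr <- sweep(xyz, 2, colMeans(xyz))
  rb <- matrix(0, n3, 6)
  for (k in 1:3) rb[seq(k, n3, 3), k] <- 1
  cross3 <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                             u[3] * v[1] - u[1] * v[3],
                             u[1] * v[2] - u[2] * v[1])
  ex <- diag(3)
  for (k in 1:3)
    rb[, 3 + k] <- as.vector(apply(ctr, 1, function(r) cross3(ex[k, ], r)))
  rb <- qr.Q(qr(rb))
  d <- .withSeed(seed, matrix(stats::rnorm(n3 * nModes), n3, nModes))
  d <- d - rb %*% crossprod(rb, d)
  qr.Q(qr(d))[, seq_len(nModes), drop = FALSE]
}

# Wall pseudo-atom positions enclosing an axis-aligned void box centered
# on the origin (half-dimensions h): all lattice points whose distance to
# the box lies in [inner, outer]. The band is volumetrically filled, so
# edges and corners are sealed. The fine lattice spacing is tuned per
# axis (s_k = (h_k + inner)/(j + 1/2) close to the requested spacing) so
# that the innermost lattice plane sits exactly `inner` outside each
# face: the sphere surfaces are then tangent to the void faces and the
# enclosed cavity volume approaches the analytic box volume. The lattice
# (+-(s/2 + k s)) is mirror-symmetric about every coordinate plane and
# never touches zero, which makes exact two-fold protomer splits
# possible.
.shellPoints <- function(halfDims, inner, outer, fineSpacing, coarseSpacing) {
  boxDist <- function(p) {
    d <- pmax(abs(p) - matrix(halfDims, nrow(p), 3, byrow = TRUE), 0)
    sqrt(rowSums(d^2))
  }
  gridPts <- function(spacings) {
    ax <- lapply(1:3, function(k) {
      s <- spacings[k]
      half <- seq(s / 2, halfDims[k] + outer + s, by = s)
      c(rev(-half), half)
    })
    as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  }
  tuned <- vapply(1:3, function(k) {
    span <- halfDims[k] + inner
    (span) / (round(span / fineSpacing - 0.5) + 0.5)
  }, numeric(1))
  fineBand <- min(inner + fineSpacing, outer)
  fine <- gridPts(tuned)
  df <- boxDist(fine)
  pts <- fine[df >= inner - 1e-9 & df < fineBand, , drop = FALSE]
  if (outer > fineBand) {
    coarse <- gridPts(rep(coarseSpacing, 3))
    dc <- boxDist(coarse)
    pts <- rbind(pts, coarse[dc >= fineBand & dc <= outer, , drop = FALSE])
  }
  pts
}

#' Rectangular cavity phantom of known void volume
#'
#' A sealed shell of pseudo-atoms (vdW radius `rVdw`) enclosing a
#' rectangular void of analytic volume `prod(voidDims)`. The innermost
#' atom layer sits exactly `rVdw` outside the void faces, so the sphere
#' surfaces are tangent to the void and the flood-filled cavity volume
#' approaches the analytic value as the lattice gets denser. Optionally a
#' client block of atoms is placed at the void center to validate
#' occupancy fractions.
#'
#' @param voidDims numeric length-3, interior void dimensions (A).
#' @param wallThickness radial wall thickness (A); must exceed the probe
#'   diameter used downstream, or the void leaks.
#' @param atomSpacing lattice spacing of the innermost (sealing) layer.
#' @param clientDims optional length-3 block dimensions of an interior
#'   client (chain `C`), e.g. `c(5, 5, 4)` for 100 A^3.
#' @param rVdw wall pseudo-atom vdW radius (default 1.7 A).
#' @param probe the probe radius the phantom must stay sealed against
#'   (leak check only; default 1.4 A).
#' @return a [MolecularStructure-class]; walls in chain `W`, client (if
#'   any) in chain `C`; attribute `voidVolume` carries the analytic void
#'   volume and `clientSpec` the client block volume.
#' @export
makeCavityPhantom <- function(voidDims = c(10, 10, 10), wallThickness = 3,
                              atomSpacing = 0.5, clientDims = NULL,
                              rVdw = 1.7, probe = 1.4) {
  stopifnot(length(voidDims) == 3, all(voidDims > 0))
  if (wallThickness < 2 * probe)
    stop("leaky wall: thickness ", wallThickness,
         " A is below the probe diameter ", 2 * probe, " A", call. = FALSE)
  pts <- .shellPoints(voidDims / 2, rVdw, rVdw + wallThickness,
                      fineSpacing = atomSpacing,
                      coarseSpacing = max(2 * atomSpacing, 1.5))
  pts <- sweep(pts, 2, voidDims / 2, "+")  # void spans [0, voidDims]
  ord <- order(pts[, 1], pts[, 2], pts[, 3])
  pts <- pts[ord, , drop = FALSE]
  nW <- nrow(pts)
  resW <- ((seq_len(nW) - 1) %/% 50) + 1L
  chain <- rep("W", nW); resno <- resW
  resname <- rep("WAL", nW)
  name <- sprintf("W%d", ((seq_len(nW) - 1) %% 50) + 1L)
  xyz <- pts
  clientVol <- NULL
  if (!is.null(clientDims)) {
    stopifnot(length(clientDims) == 3, all(clientDims > 1))
    rc <- 0.5
    lo <- (voidDims - clientDims) / 2
    ax <- lapply(1:3, function(k) {
      v <- seq(rc, clientDims[k] - rc, by = 0.5)
      v + lo[k]
    })
    cp <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
    nC <- nrow(cp)
    chain <- c(chain, rep("C", nC))
    resno <- c(resno, ((seq_len(nC) - 1) %/% 50) + 1L)
    resname <- c(resname, rep("CLI", nC))
    name <- c(name, sprintf("C%d", ((seq_len(nC) - 1) %% 50) + 1L))
    xyz <- rbind(xyz, cp)
    clientVol <- prod(clientDims)
  }
  s <- .buildStructure(chain, resno, resname, name, xyz,
                       title = "cavity phantom")
  attr(s, "voidVolume") <- prod(voidDims)
  attr(s, "clientSpec") <- clientVol
  attr(s, "clientRadius") <- if (is.null(clientDims)) NULL else 0.5
  s
}

#' Threaded-dimer scene: an end-to-end synthetic chaperone-client fixture
#'
#' A two-protomer pseudo-chaperone whose half-shells (chains `A` and `B`,
#' exact two-fold images of each other about the channel axis) seal a
#' rectangular luminal channel, with a 9-residue client peptide (chain
#' `C`) threaded along the channel axis. Charges and Lennard-Jones wells
#' are placed so that the scene has a documented ground truth: one known
#' strongest salt-bridge (coulombic) residue pair between the client and
#' protomer A, one known strongest van der Waals pair with protomer B, an
#' analytic channel volume, luminal region labels for every client
#' residue, and protomer asymmetry RMSD exactly 0 by construction. A
#' short multi-replica Gaussian jitter trajectory accompanies the scene.
#' With `plant = FALSE` the planted charges/wells are disabled (client
#' energetically inert), giving the control scene for binding
#' comparisons.
#'
#' @param seed master seed for the jitter trajectory.
#' @param plant logical; plant the favorable interactions (default TRUE).
#' @param nFrames,nReplicas trajectory shape (defaults 4 frames x 2
#'   replicas).
#' @return list with `structure`, `parameterTable`, `system`,
#'   `trajectory`, `regions` (named labels per residue key), selections
#'   (`wallSel`, `clientSel`, `receptorSel`, `ligandSel`) and
#'   `groundTruth` (list: `voidVolume`, `strongestCoulomb`,
#'   `strongestVdw`, `asymmetryRMSD`, `seedPoint`, `luminalResidues`).
#' @export
makeThreadedDimer <- function(seed = 1, plant = TRUE, nFrames = 4,
                              nReplicas = 2) {
  void <- c(8, 4, 4)
  rVdw <- 1.7
  # channel centered on the origin; the two-fold axis is x
  pts <- .shellPoints(void / 2, rVdw, rVdw + 1.2, fineSpacing = 0.6,
                      coarseSpacing = 1.2)
  keepA <- pts[, 3] > 0
  ptsA <- pts[keepA, , drop = FALSE]
  ordA <- order(ptsA[, 1], ptsA[, 2], ptsA[, 3])
  ptsA <- ptsA[ordA, , drop = FALSE]
  ptsB <- ptsA %*% diag(c(1, -1, -1))  # C2 rotation about x
  atomsPerRes <- 10L
  nA <- nrow(ptsA)
  resA <- ((seq_len(nA) - 1) %/% atomsPerRes) + 1L
  nameA <- ifelse((seq_len(nA) - 1) %% atomsPerRes == 0, "CA",
                  sprintf("C%d", ((seq_len(nA) - 1) %% atomsPerRes)))
  # client: 9 residues along the channel axis, two atoms each
  clientRes <- 1:9
  cx <- seq(-3.4, 3.4, length.out = 9)
  clientSeqNames <- c("ALA", "VAL", "PHE", "SER", "GLU", "LYS", "LEU",
                      "GLY", "THR")
  cxyz <- do.call(rbind, lapply(seq_along(cx), function(i)
    rbind(c(cx[i], 0, 0), c(cx[i], 0.8, 0))))
  chain <- c(rep("A", nA), rep("B", nA), rep("C", 18))
  resno <- c(resA, resA, rep(clientRes, each = 2))
  resname <- c(rep("WAL", 2 * nA), rep(clientSeqNames, each = 2))
  name <- c(nameA, nameA, rep(c("CA", "CB"), 9))
  xyz <- rbind(ptsA, ptsB, cxyz)
  s <- .buildStructure(chain, resno, resname, name, xyz,
                       title = "threaded dimer")
  a <- atoms(s)
  n <- nrow(a)
  charge <- rep(0, n); epsv <- rep(0.05, n)
  # planted strongest coulomb: client res 5 CB (-1 e) vs nearest A atom (+1 e)
  cb5 <- which(a$chain == "C" & a$resno == 5 & a$name == "CB")
  dA <- (a$x - a$x[cb5])^2 + (a$y - a$y[cb5])^2 + (a$z - a$z[cb5])^2
  dA[a$chain != "A"] <- Inf
  saltA <- which.min(dA)
  # planted strongest vdW: client res 3 CA vs B atom near the LJ optimum
  ca3 <- which(a$chain == "C" & a$resno == 3 & a$name == "CA")
  dB <- sqrt((a$x - a$x[ca3])^2 + (a$y - a$y[ca3])^2 + (a$z - a$z[ca3])^2)
  dB[a$chain != "B"] <- Inf
  ljB <- which.min(abs(dB - 2^(1 / 6) * 3.0))
  if (plant) {
    charge[cb5] <- -1; charge[saltA] <- 1
    epsv[ca3] <- 1.5; epsv[ljB] <- 1.5
  }
  tab <- .paramTable(s, charge = charge, sigma = 3.0, epsilon = epsv,
                     rborn = 1.5, screen = 0.8)
  sys <- loadParameters(s, tab)
  traj <- makeGaussianTrajectory(s, noise = 0.02, nFrames = nFrames,
                                 nReplicas = nReplicas, seed = seed)
  keys <- residueKeys(s)
  regions <- ifelse(startsWith(keys, "A:"), "protomerA",
                    ifelse(startsWith(keys, "B:"), "protomerB", "luminal"))
  names(regions) <- keys
  perAtomKey <- residueKeys(s, perAtom = TRUE)
  gt <- list(
    voidVolume = prod(void),
    strongestCoulomb = c(row = perAtomKey[saltA], col = perAtomKey[cb5]),
    strongestVdw = c(row = perAtomKey[ljB], col = perAtomKey[ca3]),
    asymmetryRMSD = 0,
    seedPoint = c(0, 0, 0),
    luminalResidues = keys[startsWith(keys, "C:")])
  list(structure = s, parameterTable = tab, system = sys, trajectory = traj,
       regions = regions,
       wallSel = which(a$chain %in% c("A", "B")),
       clientSel = which(a$chain == "C"),
       receptorSel = which(a$chain %in% c("A", "B")),
       ligandSel = which(a$chain == "C"),
       groundTruth = gt)
}
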