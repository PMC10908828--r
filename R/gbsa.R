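#' @include AllClasses.R
NULL

#' Generalized-Born / surface-area parameter set
#'
#' Defaults follow the de-facto conventions of implicit-solvent MM-GBSA
#' tooling: OBC-II rescaling coefficients (alpha 1.0, beta 0.8, gamma
#' 4.85), a 0.09 A dielectric offset, interior dielectric 1, solvent
#' dielectric 78.5, zero salt, and a nonpolar term
#' `gammaNP * SASA + bNP` with surface tension 0.0072 kcal/mol/A^2 and
#' zero offset, evaluated with a 1.4 A water probe and 960 sphere sample
#' points.
#'
#' @param epsIn interior dielectric (>= 1).
#' @param epsOut solvent dielectric (> epsIn).
#' @param alpha,beta,gamma OBC-II tanh-rescaling coefficients.
#' @param offset dielectric offset subtracted from intrinsic radii (A).
#' @param gammaNP surface tension, kcal/mol/A^2 (>= 0).
#' @param bNP nonpolar offset, kcal/mol.
#' @param probe solvent probe radius, A.
#' @param nSphere sphere sample points for Shrake-Rupley SASA.
#' @return a list of class `GBParams`.
#' @export
gbParams <- function(epsIn = 1, epsOut = 78.5, alpha = 1.0, beta = 0.8,
                     gamma = 4.85, offset = 0.09, gammaNP = 0.0072,
                     bNP = 0, probe = 1.4, nSphere = 960) {
  stopifnot(epsOut > epsIn, epsIn >= 1, gammaNP >= 0, probe >= 0,
            nSphere >= 12)
  structure(list(epsIn = epsIn, epsOut = epsOut, alpha = alpha, beta = beta,
                 gamma = gamma, offset = offset, gammaNP = gammaNP,
                 bNP = bNP, probe = probe, nSphere = nSphere),
            class = "GBParams")
}

#' Effective Born radii by pairwise descreening (OBC-II)
#'
#' For each atom the Hawkins-Cramer-Truhlar pairwise descreening integral
#' over its neighbours' screened spheres (screened radius
#' `S_j * (rho_j - offset)`) is accumulated analytically, then rescaled
#' through the OBC tanh form:
#' `1/R_i = 1/rhot_i - tanh(alpha Psi - beta Psi^2 + gamma Psi^3) / rho_i`
#' with `Psi = I_i rhot_i` and `rhot_i = rho_i - offset`. An isolated atom
#' has `R_i = rhot_i`; burial only increases `R_i`.
#'
#' @param system a [ParameterizedSystem-class].
#' @param coords N x 3 coordinates (defaults to structure coordinates).
#' @param params a [gbParams()] list.
#' @param subset optional atom indices: radii are computed for this
#'   subsystem in isolation (used by the binding protocol).
#' @return numeric vector of effective Born radii (A) for the subset.
#' @export
effectiveBornRadii <- function(system, coords = NULL, params = gbParams(),
                               subset = NULL) {
  a <- atoms(system)
  if (is.null(coords)) coords <- cbind(a$x, a$y, a$z)
  if (is.null(subset)) subset <- seq_len(nrow(a))
  p <- system@params[subset, , drop = FALSE]
  x <- coords[subset, , drop = FALSE]
  n <- nrow(x)
  rhot <- p$rborn - params$offset
  if (any(rhot <= 0)) stop("intrinsic Born radius not above the offset")
  if (n == 1) return(rhot)
  dx <- outer(x[, 1], x[, 1], "-"); dy <- outer(x[, 2], x[, 2], "-")
  dz <- outer(x[, 3], x[, 3], "-")
  r <- sqrt(dx * dx + dy * dy + dz * dz)
  sr <- matrix(p$screen * rhot, n, n, byrow = TRUE)  # S_j * rhot_j per column j
  rhoi <- matrix(rhot, n, n)                          # rhot_i per row i
  U <- r + sr
  L <- pmax(rhoi, abs(r - sr))
  term <- 0.5 * (1 / L - 1 / U +
                 0.25 * (r - sr^2 / r) * (1 / U^2 - 1 / L^2) +
                 0.5 * log(L / U) / r +
                 2 * (1 / rhoi - 1 / L) * (sr - r - rhoi > 0))
  term[U <= rhoi] <- 0          # neighbour sphere fully inside atom i
  diag(term) <- 0
  I <- rowSums(term)
  psi <- I * rhot
  Rinv <- 1 / rhot - tanh(params$alpha * psi - params$beta * psi^2 +
                          params$gamma * psi^3) / p$rborn
  R <- 1 / Rinv
  if (any(!is.finite(R) | R <= 0)) {
    bad <- which(!is.finite(R) | R <= 0)[1]
    stop("non-finite effective Born radius for atom index ", subset[bad])
  }
  R
}

# Full ordered-pair GB energy term matrix (diagonal = self terms with
# f_GB = R_i); sums to the GB polar solvation energy.
.gbTermMatrix <- function(q, R, x, epsIn, epsOut) {
  n <- length(q)
  dx <- outer(x[, 1], x[, 1], "-"); dy <- outer(x[, 2], x[, 2], "-")
  dz <- outer(x[, 3], x[, 3], "-")
  r2 <- dx * dx + dy * dy + dz * dz
  RR <- outer(R, R)
  f <- sqrt(r2 + RR * exp(-r2 / (4 * RR)))
  pref <- -.KE / 2 * (1 / epsIn - 1 / epsOut)
  pref * outer(q, q) / f
}

#' Generalized-Born polar solvation energy
#'
#' `E_GB = -k_e/2 (1/eps_in - 1/eps_out) sum_ij q_i q_j / f_GB(r, R_i,
#' R_j)` with `f_GB = sqrt(r^2 + R_i R_j exp(-r^2 / 4 R_i R_j))`,
#' including the `i = j` self terms (`f_GB = R_i`). Non-positive for any
#' nonzero charge set when the solvent dielectric exceeds the interior
#' one; a single ion recovers the Born expression.
#'
#' @param system a [ParameterizedSystem-class].
#' @param coords N x 3 coordinates (defaults to structure coordinates).
#' @param radii effective Born radii from [effectiveBornRadii()] on the
#'   same frame (computed if NULL).
#' @param params a [gbParams()] list.
#' @param subset optional atom indices (subsystem in isolation).
#' @return energy in kcal/mol.
#' @export
gbEnergy <- function(system, coords = NULL, radii = NULL,
                     params = gbParams(), subset = NULL) {
  a <- atoms(system)
  if (is.null(coords)) coords <- cbind(a$x, a$y, a$z)
  if (is.null(subset)) subset <- seq_len(nrow(a))
  if (is.null(radii)) radii <- effectiveBornRadii(system, coords, params, subset)
  q <- system@params$charge[subset]
  x <- coords[subset, , drop = FALSE]
  sum(.gbTermMatrix(q, radii, x, params$epsIn, params$epsOut))
}

# Deterministic, roughly uniform unit sphere points (golden-angle spiral).
.spherePoints <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  phi <- i * pi * (3 - sqrt(5))
  rho <- sqrt(pmax(0, 1 - z * z))
  cbind(rho * cos(phi), rho * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Each atom's accessible sphere (radius `r_i + probe`) is sampled with a
#' deterministic golden-angle point set; a point is accessible when it
#' lies outside every neighbour's accessible sphere. Per-atom area is the
#' accessible fraction times `4 pi (r_i + probe)^2`; the total is the sum.
#'
#' @param coords N x 3 coordinates (A).
#' @param radii per-atom vdW radii (A).
#' @param probe probe radius (default 1.4 A).
#' @param nPoints sample points per sphere (default 960; the point-count
#'   error on an isolated sphere is well under 1 percent).
#' @return numeric vector of per-atom areas (A^2).
#' @export
shrakeRupley <- function(coords, radii, probe = 1.4, nPoints = 960) {
  stopifnot(all(radii > 0))
  n <- nrow(coords)
  radii <- rep(radii, length.out = n)
  pts <- .spherePoints(nPoints)
  ext <- radii + probe
  areas <- numeric(n)
  for (i in seq_len(n)) {
    d2 <- (coords[, 1] - coords[i, 1])^2 + (coords[, 2] - coords[i, 2])^2 +
      (coords[, 3] - coords[i, 3])^2
    nb <- which(d2 < (ext + ext[i])^2 & seq_len(n) != i)
    sp <- pts * ext[i]
    sp <- sweep(sp, 2, coords[i, ], "+")
    alive <- seq_len(nPoints)
    if (length(nb)) {
      nb <- nb[order(d2[nb])]  # closest neighbours bury points fastest
      starts <- seq(1, length(nb), by = 16)
      for (s0 in starts) {
        chunk <- nb[s0:min(s0 + 15, length(nb))]
        nc <- coords[chunk, , drop = FALSE]
        d2m <- outer(sp[alive, 1], nc[, 1], "-")^2 +
          outer(sp[alive, 2], nc[, 2], "-")^2 +
          outer(sp[alive, 3], nc[, 3], "-")^2
        free <- rowSums(d2m <= rep(ext[chunk]^2,
                                   each = length(alive))) == 0
        alive <- alive[free]
        if (!length(alive)) break
      }
    }
    areas[i] <- length(alive) / nPoints * 4 * pi * ext[i]^2
  }
  areas
}

.sasaRadiiDefault <- function(system, subset) {
  # LJ R_min,i / 2 = sigma * 2^(1/6) / 2
  system@params$sigma[subset] * 2^(1 / 6) / 2
}

.frameGbsaComponents <- function(system, coords, selR, selL, selC, params,
                                 sasaRadii, perAtom = FALSE) {
  masks <- .pairScaleMasks(system, selR, selL)
  inter <- .interEnergyMatrices(system, coords, selR, selL, masks,
                                params$epsIn)
  sub <- function(sel) {
    R <- effectiveBornRadii(system, coords, params, sel)
    T <- .gbTermMatrix(system@params$charge[sel], R,
                       coords[sel, , drop = FALSE],
                       params$epsIn, params$epsOut)
    A <- shrakeRupley(coords[sel, , drop = FALSE], sasaRadii[match(sel, selC)],
                      params$probe, params$nSphere)
    list(gbAtom = rowSums(T), sasa = A)
  }
  gC <- sub(selC); gR <- sub(selR); gL <- sub(selL)
  iR <- match(selR, selC); iL <- match(selL, selC)
  dgbAtom <- gC$gbAtom
  dgbAtom[iR] <- dgbAtom[iR] - gR$gbAtom
  dgbAtom[iL] <- dgbAtom[iL] - gL$gbAtom
  dsasaAtom <- gC$sasa
  dsasaAtom[iR] <- dsasaAtom[iR] - gR$sasa
  dsasaAtom[iL] <- dsasaAtom[iL] - gL$sasa
  comp <- c(evdw = sum(inter$vdw), ecoul = sum(inter$coulomb),
            egb = sum(dgbAtom),
            enp = params$gammaNP * sum(dsasaAtom) - params$bNP)
  if (!perAtom) return(comp)
  # half of each cross term to each partner atom; GB/np deltas are per-atom
  vdwAtom <- numeric(length(selC)); coulAtom <- numeric(length(selC))
  vdwAtom[iR] <- rowSums(inter$vdw) / 2
  vdwAtom[iL] <- colSums(inter$vdw) / 2
  coulAtom[iR] <- rowSums(inter$coulomb) / 2
  coulAtom[iL] <- colSums(inter$coulomb) / 2
  npAtom <- params$gammaNP * dsasaAtom
  npAtom[1] <- npAtom[1] - params$bNP
  list(components = comp, atom = cbind(evdw = vdwAtom, ecoul = coulAtom,
                                       egb = dgbAtom, enp = npAtom))
}

.gbsaStats <- function(perFrame) {
  compNames <- c("evdw", "ecoul", "egb", "enp", "total")
  repIds <- unique(perFrame$replica)
  repStats <- do.call(rbind, lapply(repIds, function(r) {
    sub <- perFrame[perFrame$replica == r, compNames, drop = FALSE]
    data.frame(replica = r, component = compNames,
               mean = vapply(sub, mean, numeric(1)),
               sd = vapply(sub, stats::sd, numeric(1)),
               row.names = NULL)
  }))
  summary <- do.call(rbind, lapply(compNames, function(cn) {
    ms <- repStats$mean[repStats$component == cn]
    data.frame(component = cn, mean = mean(ms),
               sd = if (length(ms) >= 2) stats::sd(ms) else NA_real_,
               sem = if (length(ms) >= 2) stats::sd(ms) / sqrt(length(ms))
                     else NA_real_)
  }))
  list(replicaStats = repStats, summary = summary)
}

#' MM-GBSA binding free energy (single-trajectory protocol)
#'
#' Receptor and ligand frames are sub-selections of the complex frames,
#' so internal bonded terms cancel and the per-frame binding energy is
#' `dEvdw + dEcoul + dGgb + dGnp`: the direct inter-group molecular
#' mechanics terms, the change in generalized-Born polar solvation on
#' complexation (Born radii recomputed for each subsystem in isolation),
#' and the surface-tension-weighted change in SASA. No entropy term is
#' included, and no salt screening (zero salt). Replica statistics follow
#' the per-replica mean / SD, cross-replica mean / SD of means / SEM
#' convention.
#'
#' @param system a [ParameterizedSystem-class].
#' @param trajectory a [Trajectory-class] (or a single N x 3 frame).
#' @param selReceptor,selLigand disjoint atom selections whose union is
#'   the complex.
#' @param params a [gbParams()] list.
#' @param sasaRadii optional per-complex-atom vdW radii for SASA
#'   (defaults to LJ `R_min/2`).
#' @param stride frame sampling stride.
#' @return a [BindingReport-class].
#' @export
mmgbsaBinding <- function(system, trajectory, selReceptor, selLigand,
                          params = gbParams(), sasaRadii = NULL, stride = 1) {
  if (length(intersect(selReceptor, selLigand)))
    stop("receptor and ligand selections overlap", call. = FALSE)
  selC <- sort(c(selReceptor, selLigand))
  if (is.matrix(trajectory) && ncol(trajectory) == 3) {
    xyz <- matrix(as.vector(t(trajectory)), nrow = 1)
    trajectory <- new("Trajectory", xyz = xyz, template = system@structure,
                      replica = 1L, time = NA_real_)
  }
  if (is.null(sasaRadii)) sasaRadii <- .sasaRadiiDefault(system, selC)
  frames <- seq(1, nframes(trajectory), by = stride)
  rows <- lapply(frames, function(f) {
    comp <- .frameGbsaComponents(system, frameCoords(trajectory, f),
                                 selReceptor, selLigand, selC, params,
                                 sasaRadii)
    data.frame(replica = replicaIds(trajectory)[f], frame = f,
               evdw = comp["evdw"], ecoul = comp["ecoul"],
               egb = comp["egb"], enp = comp["enp"],
               total = sum(comp), row.names = NULL)
  })
  perFrame <- do.call(rbind, rows)
  st <- .gbsaStats(perFrame)
  new("BindingReport", perFrame = perFrame, replicaStats = st$replicaStats,
      summary = st$summary)
}

#' Per-residue MM-GBSA decomposition
#'
#' Splits every inter-group molecular-mechanics cross term half to each
#' partner atom and assigns GB/self and SASA deltas to their own atoms,
#' then aggregates atoms into residues, so the per-residue contributions
#' sum exactly to the per-frame binding energy.
#'
#' @inheritParams mmgbsaBinding
#' @return data.frame with one row per residue of the complex: `residue`,
#'   `evdw`, `ecoul`, `egb`, `enp`, `total` (frame averages, kcal/mol),
#'   plus attribute `frameTotals` for conservation checks.
#' @export
perResidueGBSA <- function(system, trajectory, selReceptor, selLigand,
                           params = gbParams(), sasaRadii = NULL, stride = 1) {
  if (length(intersect(selReceptor, selLigand)))
    stop("receptor and ligand selections overlap", call. = FALSE)
  selC <- sort(c(selReceptor, selLigand))
  if (is.matrix(trajectory) && ncol(trajectory) == 3) {
    xyz <- matrix(as.vector(t(trajectory)), nrow = 1)
    trajectory <- new("Trajectory", xyz = xyz, template = system@structure,
                      replica = 1L, time = NA_real_)
  }
  if (is.null(sasaRadii)) sasaRadii <- .sasaRadiiDefault(system, selC)
  keys <- residueKeys(system@structure, perAtom = TRUE)[selC]
  resKeys <- unique(keys)
  fac <- factor(keys, levels = resKeys)
  frames <- seq(1, nframes(trajectory), by = stride)
  acc <- matrix(0, length(resKeys), 4,
                dimnames = list(resKeys, c("evdw", "ecoul", "egb", "enp")))
  totals <- numeric(length(frames))
  for (k in seq_along(frames)) {
    out <- .frameGbsaComponents(system, frameCoords(trajectory, frames[k]),
                                selReceptor, selLigand, selC, params,
                                sasaRadii, perAtom = TRUE)
    acc <- acc + rowsum(out$atom, fac)[resKeys, , drop = FALSE]
    totals[k] <- sum(out$components)
  }
  acc <- acc / length(frames)
  res <- data.frame(residue = resKeys, evdw = acc[, "evdw"],
                    ecoul = acc[, "ecoul"], egb = acc[, "egb"],
                    enp = acc[, "enp"],
                    total = rowSums(acc), row.names = NULL)
  attr(res, "frameTotals") <- totals
  res
}
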