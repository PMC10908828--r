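#' @include AllClasses.R
NULL

# Kabsch: optimal proper rotation + translation mapping P onto Q
# (N x 3 each). Returns R (3x3, det +1) and translation so that
# x -> R (x - centroid(P)) + centroid(Q).
.kabsch <- function(P, Q) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  s <- svd(crossprod(Pc, Qc))        # H = t(Pc) Qc = U D t(V)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  if (det(R) < 0) stop("reflection produced by superposition (degenerate input)")
  list(R = R, cp = cp, cq = cq)
}

.applyKabsch <- function(X, k) {
  sweep(sweep(X, 2, k$cp) %*% t(k$R), 2, k$cq, "+")
}

.asCoordMat <- function(row) matrix(row, ncol = 3, byrow = TRUE)
.asXyzRow <- function(m) as.vector(t(m))

# At least 3 non-collinear points are required for a determined fit.
.checkFitAtoms <- function(X) {
  if (nrow(X) < 3) stop("need at least 3 fit atoms", call. = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  if (sum(svd(Xc)$d > 1e-8) < 2)
    stop("fit atoms are collinear", call. = FALSE)
}

#' Rigid-body superposition of trajectory frames
#'
#' Removes overall rotation and translation with a least-squares (Kabsch)
#' fit of each frame's `fitSelection` atoms onto a reference, which is
#' either the first frame or (default) the iteratively refined mean
#' structure (at most `maxIter` rounds, stopping when the mean shifts by
#' less than `tol` A RMS). The RMSD of the fit selection to the reference
#' is non-increasing over iterations.
#'
#' @param trajectory a [Trajectory-class].
#' @param fitSelection atom indices used for the fit (default: all atoms).
#' @param mode `"iterative-mean"` (default) or `"to-first-frame"`.
#' @param maxIter,tol iteration cap and mean-shift convergence threshold.
#' @return the aligned [Trajectory-class]; attribute `iterations` records
#'   the number of mean refinements performed.
#' @export
fitFrames <- function(trajectory, fitSelection = NULL,
                      mode = c("iterative-mean", "to-first-frame"),
                      maxIter = 10, tol = 1e-6) {
  mode <- match.arg(mode)
  n <- natoms(trajectory)
  if (is.null(fitSelection)) fitSelection <- seq_len(n)
  xyz <- trajectory@xyz
  f1 <- .asCoordMat(xyz[1, ])
  .checkFitAtoms(f1[fitSelection, , drop = FALSE])
  fitOnce <- function(xyz, ref) {
    t(apply(xyz, 1, function(row) {
      m <- .asCoordMat(row)
      k <- .kabsch(m[fitSelection, , drop = FALSE], ref)
      .asXyzRow(.applyKabsch(m, k))
    }))
  }
  ref <- f1[fitSelection, , drop = FALSE]
  xyz <- fitOnce(xyz, ref)
  iters <- 0L
  if (mode == "iterative-mean" && nrow(xyz) > 1) {
    repeat {
      mean3 <- .asCoordMat(colMeans(xyz))[fitSelection, , drop = FALSE]
      shift <- sqrt(mean(rowSums((mean3 - ref)^2)))
      iters <- iters + 1L
      ref <- mean3
      xyz <- fitOnce(xyz, ref)
      if (shift < tol || iters >= maxIter) break
    }
  }
  out <- trajectory
  out@xyz <- xyz
  attr(out, "iterations") <- iters
  out
}

#' Root-mean-square fluctuation and raw B-factor
#'
#' `RMSF_i = sqrt(mean over frames of |r_i - <r_i>|^2)` on an aligned
#' trajectory, with the crystallographic conversion
#' `B = (8 pi^2 / 3) RMSF^2` (A^2).
#'
#' @param trajectory an aligned [Trajectory-class] (see [fitFrames()]).
#' @param selection atom indices to profile (default: all).
#' @return data.frame (`atom`, `chain`, `resno`, `name`, `rmsf`, `bRaw`),
#'   one row per selected atom.
#' @export
rmsf <- function(trajectory, selection = NULL) {
  if (nframes(trajectory) < 2)
    stop("RMSF needs at least 2 frames", call. = FALSE)
  n <- natoms(trajectory)
  if (is.null(selection)) selection <- seq_len(n)
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
  X <- trajectory@xyz[, cols, drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  msf <- colMeans(Xc^2)
  perAtom <- msf[seq(1, length(msf), 3)] + msf[seq(2, length(msf), 3)] +
    msf[seq(3, length(msf), 3)]
  a <- atoms(trajectory)[selection, , drop = FALSE]
  data.frame(atom = selection, chain = a$chain, resno = a$resno,
             name = a$name, rmsf = sqrt(perAtom),
             bRaw = (8 * pi^2 / 3) * perAtom, row.names = NULL)
}

#' Joint normalization of B-factor profiles across systems
#'
#' All profiles are divided by the pooled maximum raw B-factor and
#' multiplied by 100, putting e.g. closed-state and semi-open-state
#' fluctuation maps on one shared colour scale while preserving
#' within-system ratios exactly. If the pooled maximum is zero all
#' normalized values are zero.
#'
#' @param profiles a single [rmsf()] data.frame or a list of them.
#' @return the input with a `bNorm` column added to each profile (a list
#'   is returned if a list was given).
#' @export
normalizeBFactors <- function(profiles) {
  single <- is.data.frame(profiles)
  if (single) profiles <- list(profiles)
  pooledMax <- max(vapply(profiles, function(p) max(p$bRaw), numeric(1)))
  profiles <- lapply(profiles, function(p) {
    p$bNorm <- if (pooledMax == 0) 0 * p$bRaw else 100 * p$bRaw / pooledMax
    p
  })
  if (single) profiles[[1]] else profiles
}

#' Essential-dynamics principal component analysis
#'
#' Eigen-decomposition of the population (1/F) covariance matrix of
#' mean-centred, fitted coordinates of the selected atoms (conventionally
#' C-alpha only, mass-unweighted). Eigenvalues (A^2) sum to the total
#' coordinate variance; projections express each centred frame in mode
#' coordinates. Rank-deficient covariances are allowed - trailing
#' eigenvalues are zero - and requesting more modes than the rank
#' truncates with a warning.
#'
#' @param trajectory an aligned [Trajectory-class].
#' @param selection atom indices (default: atoms named `"CA"`, or all
#'   atoms if none are).
#' @param nModes number of modes to keep (default: all).
#' @return a [ModeSet-class].
#' @export
trajectoryPCA <- function(trajectory, selection = NULL, nModes = NULL) {
  if (nframes(trajectory) < 2)
    stop("PCA needs at least 2 frames", call. = FALSE)
  a <- atoms(trajectory)
  if (is.null(selection)) {
    selection <- which(a$name == "CA")
    if (!length(selection)) selection <- seq_len(nrow(a))
  }
  cols <- as.vector(rbind(3 * selection - 2, 3 * selection - 1, 3 * selection))
  X <- trajectory@xyz[, cols, drop = FALSE]
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  C <- crossprod(Xc) / nrow(Xc)
  e <- eigen(C, symmetric = TRUE)
  vals <- pmax(e$values, 0)
  rank <- sum(vals > max(vals[1], 1e-12) * 1e-10)
  if (is.null(nModes)) nModes <- length(vals)
  if (nModes > rank && rank < length(vals)) {
    if (nModes > rank)
      warning("requested ", nModes, " modes but covariance rank is ", rank,
              "; trailing modes have zero variance", call. = FALSE)
  }
  nModes <- min(nModes, length(vals))
  vec <- e$vectors[, seq_len(nModes), drop = FALSE]
  new("ModeSet", values = vals[seq_len(nModes)], vectors = vec,
      projections = Xc %*% vec, center = center,
      atomIndices = as.integer(selection))
}

#' Export a principal mode as a multi-model PDB animation
#'
#' Frames interpolate the mean structure along eigenvector `k` between
#' `-amplitude * sqrt(lambda_k)` and `+amplitude * sqrt(lambda_k)`;
#' `nSteps = 2` gives exactly the two extreme frames and `amplitude = 0`
#' collapses every frame onto the mean.
#'
#' @param modes a [ModeSet-class].
#' @param template the [MolecularStructure-class] the modes refer to.
#' @param path output PDB path.
#' @param k mode index.
#' @param nSteps number of frames.
#' @param amplitude displacement in units of the mode standard deviation.
#' @return invisibly, the [Trajectory-class] that was written.
#' @export
exportModeTrajectory <- function(modes, template, path, k = 1, nSteps = 11,
                                 amplitude = 2) {
  stopifnot(k >= 1, k <= length(modes@values), nSteps >= 1)
  sel <- modes@atomIndices
  scale <- amplitude * sqrt(modes@values[k])
  s <- if (nSteps == 1) 0 else seq(-scale, scale, length.out = nSteps)
  sub <- template@atoms[sel, , drop = FALSE]
  rownames(sub) <- NULL
  tmpl <- new("MolecularStructure", atoms = sub, title = "mode animation")
  xyz <- t(vapply(s, function(si) modes@center + si * modes@vectors[, k],
                  numeric(length(modes@center))))
  traj <- new("Trajectory", xyz = xyz, template = tmpl,
              replica = rep(1L, nrow(xyz)), time = rep(NA_real_, nrow(xyz)))
  writeStructure(traj, path)
  invisible(traj)
}
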