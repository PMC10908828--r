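# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: plain double loops, enumeration, numeric
# quadrature and closed forms.

KE <- 332.0637

# Brute-force residue-pair decomposition: explicit double loop over atom
# pairs with its own exclusion/scale lookup.
bruteForcePairMatrix <- function(system, coords, selA, selB) {
  a <- atoms(system)
  p <- system@params
  key <- paste0(a$chain, ":", a$resno, a$insert, ":", a$resname)
  rows <- unique(key[selA]); cols <- unique(key[selB])
  coul <- matrix(0, length(rows), length(cols), dimnames = list(rows, cols))
  vdw <- coul
  exKey <- character(0); s14Key <- character(0)
  if (nrow(system@exclusions))
    exKey <- paste(system@exclusions[, 1], system@exclusions[, 2])
  if (nrow(system@scaled14))
    s14Key <- paste(system@scaled14[, 1], system@scaled14[, 2])
  for (i in selA) for (j in selB) {
    pk <- paste(min(i, j), max(i, j))
    if (pk %in% exKey) next
    sc <- if (pk %in% s14Key) c(system@coulScale14, system@ljScale14) else c(1, 1)
    r <- sqrt(sum((c(coords[i, 1], coords[i, 2], coords[i, 3]) -
                   c(coords[j, 1], coords[j, 2], coords[j, 3]))^2))
    ec <- KE * p$charge[i] * p$charge[j] / r * sc[1]
    sig <- (p$sigma[i] + p$sigma[j]) / 2
    eps <- sqrt(p$epsilon[i] * p$epsilon[j])
    ev <- 4 * eps * ((sig / r)^12 - (sig / r)^6) * sc[2]
    coul[key[i], key[j]] <- coul[key[i], key[j]] + ec
    vdw[key[i], key[j]] <- vdw[key[i], key[j]] + ev
  }
  list(coulomb = coul, vdw = vdw)
}

structureCoords <- function(x) {
  a <- atoms(x)
  cbind(a$x, a$y, a$z)
}

# Exhaustive global alignment score: enumerate every alignment of two
# short sequences, scoring maximal gap runs as open + len * ext.
bruteForceAlignScore <- function(A, B, mat, open, ext) {
  a <- strsplit(A, "")[[1]]; b <- strsplit(B, "")[[1]]
  best <- -Inf
  scoreCols <- function(cols) {
    sc <- 0; runA <- 0; runB <- 0  # runs of gaps in sequence A / B
    closeA <- function() if (runA > 0) { sc <<- sc - open - runA * ext; runA <<- 0 }
    closeB <- function() if (runB > 0) { sc <<- sc - open - runB * ext; runB <<- 0 }
    for (cl in cols) {
      if (cl[1] == "-") { runA <- runA + 1; closeB() }
      else if (cl[2] == "-") { runB <- runB + 1; closeA() }
      else { closeA(); closeB(); sc <- sc + mat[cl[1], cl[2]] }
    }
    closeA(); closeB()
    sc
  }
  rec <- function(i, j, cols) {
    if (i > length(a) && j > length(b)) {
      best <<- max(best, scoreCols(cols))
      return()
    }
    if (i <= length(a) && j <= length(b))
      rec(i + 1, j + 1, c(cols, list(c(a[i], b[j]))))
    if (i <= length(a)) rec(i + 1, j, c(cols, list(c(a[i], "-"))))
    if (j <= length(b)) rec(i, j + 1, c(cols, list(c("-", b[j]))))
    invisible()
  }
  rec(1, 1, list())
  best
}

# Numeric descreening integral for a two-atom system: (1/4pi) *
# integral of 1/s^4 over the screened sphere (radius sr at distance d),
# restricted to s >= rhot.
numericDescreenI <- function(rhot, d, sr) {
  f <- function(s) {
    cth <- (s^2 + d^2 - sr^2) / (2 * s * d)
    g <- pmin(pmax(1 - cth, 0), 2)
    g / s^2
  }
  lo <- max(rhot, d - sr); hi <- d + sr
  if (hi <= lo) return(0)
  0.5 * stats::integrate(f, lo, hi, rel.tol = 1e-12)$value
}

obcRadiusFromI <- function(I, rho, params) {
  rhot <- rho - params$offset
  psi <- I * rhot
  1 / (1 / rhot - tanh(params$alpha * psi - params$beta * psi^2 +
                       params$gamma * psi^3) / rho)
}

# Accessible area of two identical overlapping spheres (radius R
# including probe, centers d apart): each loses a cap of height R - d/2.
twoSphereAccessibleArea <- function(R, d) {
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

rigidTransform <- function(coords, angle = 37 * pi / 180,
                           axis = c(0, 0, 1), shift = c(4, -7, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  sweep(coords %*% t(R), 2, shift, "+")
}

# Scene cache: expensive fixtures are built once per test run.
.sceneCache <- new.env(parent = emptyenv())
cachedScene <- function(name, builder) {
  if (!exists(name, envir = .sceneCache)) assign(name, builder(), envir = .sceneCache)
  get(name, envir = .sceneCache)
}
threadedDimerScene <- function() cachedScene("td", function() makeThreadedDimer(seed = 1))
phantomScene <- function() cachedScene("phantom", function()
  makeCavityPhantom(c(10, 10, 10), clientDims = c(5, 5, 4)))
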