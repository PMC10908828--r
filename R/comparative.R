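#' @include AllClasses.R fluctuations.R
NULL

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      # unknown residues are scored 0 against everything
      m["X", ] <- 0; m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

#' Global sequence alignment with affine gaps (Needleman-Wunsch)
#'
#' Optimal global alignment under an affine gap model (a gap of length L
#' costs `gapOpen + L * gapExtend`), scored with BLOSUM62 by default;
#' `X` scores 0 against everything. Traceback tie-breaking is
#' deterministic: diagonal, then up (gap in the second sequence), then
#' left. Percent identity is identical pairs over aligned columns
#' excluding terminal overhangs; percent similarity counts pairs with a
#' positive substitution score; the alternative identity over the shorter
#' sequence length is reported alongside.
#'
#' @param seqA,seqB one-letter amino-acid strings (standard alphabet; `X`
#'   allowed).
#' @param matrix substitution matrix (default BLOSUM62 from Biostrings).
#' @param gapOpen,gapExtend affine gap parameters (defaults 10 and 0.5).
#' @return list of class `AlignmentResult`: `alignedA`, `alignedB`
#'   (gapped strings), `score`, `identity`, `similarity`,
#'   `identityShorter` (percent over the shorter sequence),
#'   `correspondence` (data.frame of matched 1-based positions), and the
#'   gap parameters used.
#' @examples
#' al <- globalAlign("ACDE", "ACEE")
#' al$identity
#' @export
globalAlign <- function(seqA, seqB, matrix = NULL, gapOpen = 10,
                        gapExtend = 0.5) {
  if (!nzchar(seqA) || !nzchar(seqB)) stop("empty sequence", call. = FALSE)
  if (is.null(matrix)) matrix <- .blosum62()
  A <- strsplit(toupper(seqA), "")[[1]]
  B <- strsplit(toupper(seqB), "")[[1]]
  bad <- setdiff(c(A, B), rownames(matrix))
  if (length(bad)) stop("unknown residue letter(s): ",
                        paste(bad, collapse = ", "), call. = FALSE)
  n <- length(A); m <- length(B)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  M[1, 1] <- 0
  Ix[-1, 1] <- -gapOpen - seq_len(n) * gapExtend
  Iy[1, -1] <- -gapOpen - seq_len(m) * gapExtend
  sub <- matrix[A, B, drop = FALSE]
  for (i in seq_len(n)) {
    prevBest <- pmax(M[i, ], Ix[i, ], Iy[i, ])
    M[i + 1, -1] <- sub[i, ] + prevBest[seq_len(m)]
    Ix[i + 1, ] <- pmax(pmax(M[i, ], Iy[i, ]) - gapOpen - gapExtend,
                        Ix[i, ] - gapExtend)
    # Iy via running max: gap of length (j-k) opened after column k
    q <- pmax(M[i + 1, ], Ix[i + 1, ]) + (0:m) * gapExtend
    cm <- cummax(q)
    j <- seq_len(m)
    Iy[i + 1, j + 1] <- cm[j] - gapOpen - j * gapExtend
  }
  states <- c(M = M[n + 1, m + 1], Ix = Ix[n + 1, m + 1], Iy = Iy[n + 1, m + 1])
  eps <- 1e-9
  pick <- function(vals) names(vals)[which(vals >= max(vals) - eps)[1]]
  state <- pick(states)
  score <- max(states)
  i <- n; j <- m
  opA <- character(0); opB <- character(0)
  while (i > 0 || j > 0) {
    if (state == "M") {
      opA <- c(A[i], opA); opB <- c(B[j], opB)
      tgt <- M[i + 1, j + 1] - sub[i, j]
      prev <- c(M = M[i, j], Ix = Ix[i, j], Iy = Iy[i, j])
      state <- pick(ifelse(abs(prev - tgt) < eps, prev, NEG))
      i <- i - 1; j <- j - 1
    } else if (state == "Ix") {
      opA <- c(A[i], opA); opB <- c("-", opB)
      v <- Ix[i + 1, j + 1]
      prev <- c(M = M[i, j + 1] - gapOpen - gapExtend,
                Ix = Ix[i, j + 1] - gapExtend,
                Iy = Iy[i, j + 1] - gapOpen - gapExtend)
      state <- pick(ifelse(abs(prev - v) < eps, prev, NEG))
      i <- i - 1
    } else {
      opA <- c("-", opA); opB <- c(B[j], opB)
      v <- Iy[i + 1, j + 1]
      prev <- c(M = M[i + 1, j] - gapOpen - gapExtend,
                Ix = Ix[i + 1, j] - gapOpen - gapExtend,
                Iy = Iy[i + 1, j] - gapExtend)
      state <- pick(ifelse(abs(prev - v) < eps, prev, NEG))
      j <- j - 1
    }
    if (i == 0 && j > 0) state <- "Iy"
    if (j == 0 && i > 0) state <- "Ix"
  }
  gapA <- opA == "-"; gapB <- opB == "-"
  anyGap <- gapA | gapB
  # terminal overhangs: leading/trailing runs of gap columns
  inner <- which(!anyGap)
  if (length(inner)) {
    span <- inner[1]:inner[length(inner)]
  } else span <- integer(0)
  ncols <- length(span)
  matched <- span[!anyGap[span]]
  ident <- sum(opA[matched] == opB[matched])
  simil <- sum(matrix[cbind(opA[matched], opB[matched])] > 0)
  posA <- cumsum(!gapA); posB <- cumsum(!gapB)
  corr <- data.frame(posA = posA[matched], posB = posB[matched])
  structure(list(
    alignedA = paste(opA, collapse = ""), alignedB = paste(opB, collapse = ""),
    score = score,
    identity = if (ncols) 100 * ident / ncols else 0,
    similarity = if (ncols) 100 * simil / ncols else 0,
    identityShorter = 100 * ident / min(n, m),
    correspondence = corr, gapOpen = gapOpen, gapExtend = gapExtend),
    class = "AlignmentResult")
}

#' @export
print.AlignmentResult <- function(x, ...) {
  cat(sprintf("AlignmentResult: score %.1f, identity %.1f%%, similarity %.1f%% (%d matched pairs)\n",
              x$score, x$identity, x$similarity, nrow(x$correspondence)))
  invisible(x)
}

.threeToOne <- function(resnames) {
  out <- suppressWarnings(bio3d::aa321(resnames))
  out[is.na(out) | !out %in% c(LETTERS)] <- "X"
  out
}

#' One-letter sequence of a chain
#'
#' Residue order follows the atom records; residue names are mapped from
#' three-letter codes, unknown names becoming `X`.
#'
#' @param structure a [MolecularStructure-class].
#' @param chain chain identifier.
#' @return character scalar.
#' @export
chainSequence <- function(structure, chain) {
  a <- structure@atoms
  a <- a[a$chain == chain & !a$het, , drop = FALSE]
  if (!nrow(a)) stop("no protein atoms in chain ", chain, call. = FALSE)
  rk <- paste(a$resno, a$insert)
  paste(.threeToOne(a$resname[!duplicated(rk)]), collapse = "")
}

# Representative atom (by name) of each residue of a chain, in order.
.chainResidueAtoms <- function(structure, chain, atomName) {
  a <- structure@atoms
  idx <- which(a$chain == chain & !a$het)
  rk <- paste(a$resno[idx], a$insert[idx])
  resFirst <- idx[!duplicated(rk)]
  ca <- vapply(split(idx, factor(rk, levels = unique(rk))), function(ii) {
    hit <- ii[a$name[ii] == atomName]
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  unname(ca)
}

#' Alignment-guided least-squares superposition and RMSD
#'
#' Matches residues of two structures through a global sequence alignment
#' (BLOSUM62, affine gaps), takes one named atom per matched residue
#' (C-alpha by default), and computes the optimal proper rotation and
#' translation (Kabsch) plus the RMSD over the matched atoms. The
#' rotation is asserted orthonormal with determinant +1 on every call.
#'
#' @param structA,structB [MolecularStructure-class] objects.
#' @param chainA,chainB chains to compare (defaults: all protein chains,
#'   concatenated in file order).
#' @param correspondence optional two-column matrix of atom indices into
#'   A and B, bypassing the sequence alignment.
#' @param atomName atom matched per residue (default `"CA"`).
#' @return list of class `SuperpositionResult`: `rotation` (3 x 3),
#'   `translation`, `rmsd` (A), `n` matched pairs, `deviations`
#'   (data.frame with per-pair distances after superposition), and the
#'   `alignment` used (NULL when a correspondence was supplied).
#' @export
superpose <- function(structA, structB, chainA = NULL, chainB = NULL,
                      correspondence = NULL, atomName = "CA") {
  al <- NULL
  if (is.null(correspondence)) {
    chA <- if (is.null(chainA)) unique(structA@atoms$chain[!structA@atoms$het]) else chainA
    chB <- if (is.null(chainB)) unique(structB@atoms$chain[!structB@atoms$het]) else chainB
    seqA <- paste(vapply(chA, function(c) chainSequence(structA, c), ""),
                  collapse = "")
    seqB <- paste(vapply(chB, function(c) chainSequence(structB, c), ""),
                  collapse = "")
    atomsA <- unlist(lapply(chA, .chainResidueAtoms, structure = structA,
                            atomName = atomName))
    atomsB <- unlist(lapply(chB, .chainResidueAtoms, structure = structB,
                            atomName = atomName))
    al <- globalAlign(seqA, seqB)
    corr <- cbind(atomsA[al$correspondence$posA],
                  atomsB[al$correspondence$posB])
    corr <- corr[stats::complete.cases(corr), , drop = FALSE]
  } else corr <- correspondence
  if (nrow(corr) < 3)
    stop("fewer than 3 matched atom pairs", call. = FALSE)
  aA <- structA@atoms; aB <- structB@atoms
  P <- cbind(aA$x, aA$y, aA$z)[corr[, 1], , drop = FALSE]
  Q <- cbind(aB$x, aB$y, aB$z)[corr[, 2], , drop = FALSE]
  .checkFitAtoms(P)
  k <- .kabsch(P, Q)
  stopifnot(abs(det(k$R) - 1) < 1e-8,
            max(abs(crossprod(k$R) - diag(3))) < 1e-8)
  Pt <- .applyKabsch(P, k)
  d <- sqrt(rowSums((Pt - Q)^2))
  dev <- data.frame(atomA = corr[, 1], atomB = corr[, 2],
                    resnoA = aA$resno[corr[, 1]], resnoB = aB$resno[corr[, 2]],
                    deviation = d)
  structure(list(rotation = k$R,
                 translation = as.numeric(k$cq - k$R %*% k$cp),
                 rmsd = sqrt(mean(d^2)), n = nrow(corr), deviations = dev,
                 alignment = al),
            class = "SuperpositionResult")
}

#' @export
print.SuperpositionResult <- function(x, ...) {
  cat(sprintf("SuperpositionResult: %d matched pairs, RMSD %.3f A\n",
              x$n, x$rmsd))
  invisible(x)
}

#' Protomer asymmetry of a dimer
#'
#' Aligns the sequences of the two protomer chains, superposes one onto
#' the other over matched C-alpha atoms, and reports the RMSD together
#' with the per-residue deviation profile that localizes asymmetric
#' regions (e.g. a displaced loop). Chains sharing less than 30 percent
#' identity trigger a warning (probably not protomers of one dimer).
#'
#' @param structure a [MolecularStructure-class] holding both chains.
#' @param chainA,chainB the two protomer chain identifiers.
#' @param atomName atom matched per residue (default `"CA"`).
#' @return a `SuperpositionResult` (see [superpose()]).
#' @export
protomerAsymmetry <- function(structure, chainA, chainB, atomName = "CA") {
  res <- superpose(structure, structure, chainA = chainA, chainB = chainB,
                   atomName = atomName)
  if (!is.null(res$alignment) && res$alignment$identity < 30)
    warning("protomer sequences share under 30% identity", call. = FALSE)
  res
}
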