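# Idealized 10-10 electrode geometry on the unit sphere.
#
# Electrodes are placed by the standard construction: the midline and the
# ear-to-ear coronal line are great circles sampled at 10% arc steps, the
# outer ring (Fp/AF7/F7/.../O ring) sits at 72 degrees inclination with
# 18-degree azimuth steps, and intermediate electrodes lie on great-circle
# (slerp) arcs between their midline and outer-ring row mates.

.deg <- pi / 180

# slerp between two unit vectors
.slerp <- function(u, v, t) {
  w <- acos(max(-1, min(1, sum(u * v))))
  if (w < 1e-12) return(u)
  (sin((1 - t) * w) * u + sin(t * w) * v) / sin(w)
}

# midline position at percentage p of the nasion->inion arc (50 = vertex)
.midline <- function(p) {
  th <- abs(p - 50) / 50 * 90 * .deg
  c(0, sin(th) * ifelse(p < 50, 1, -1), cos(th))
}

# coronal position at percentage p of the left->right ear arc (50 = vertex)
.coronal <- function(p) {
  th <- abs(p - 50) / 50 * 90 * .deg
  c(sin(th) * ifelse(p < 50, -1, 1), 0, cos(th))
}

# outer-ring position at azimuth az degrees from the front, side -1 left / +1 right
.ring <- function(az, side) {
  th <- 72 * .deg
  a <- az * .deg
  c(side * sin(th) * sin(a), sin(th) * cos(a), cos(th))
}

.build1010table <- function() {
  pos <- list()
  # midline
  mid <- c(Fpz = 10, AFz = 20, Fz = 30, FCz = 40, Cz = 50, CPz = 60,
           Pz = 70, POz = 80, Oz = 90, Iz = 100)
  for (nm in names(mid)) pos[[nm]] <- .midline(mid[[nm]])
  # coronal (C row + temporal)
  cor <- c(T9 = 0, T7 = 10, C5 = 20, C3 = 30, C1 = 40, C2 = 60, C4 = 70,
           C6 = 80, T8 = 90, T10 = 100)
  for (nm in names(cor)) pos[[nm]] <- .coronal(cor[[nm]])
  # outer ring, azimuth from front in 18-degree steps
  ringL <- c(Fp1 = 18, AF7 = 36, F7 = 54, FT7 = 72, TP7 = 108, P7 = 126,
             PO7 = 144, O1 = 162)
  ringR <- c(Fp2 = 18, AF8 = 36, F8 = 54, FT8 = 72, TP8 = 108, P8 = 126,
             PO8 = 144, O2 = 162)
  for (nm in names(ringL)) pos[[nm]] <- .ring(ringL[[nm]], -1)
  for (nm in names(ringR)) pos[[nm]] <- .ring(ringR[[nm]], +1)
  # intermediate rows: slerp between midline electrode and outer-ring mate
  rows <- list(
    list(midn = "Fz",  lat = "F7",  inner = c(F1 = 0.25, F3 = 0.5, F5 = 0.75)),
    list(midn = "FCz", lat = "FT7", inner = c(FC1 = 0.25, FC3 = 0.5, FC5 = 0.75)),
    list(midn = "CPz", lat = "TP7", inner = c(CP1 = 0.25, CP3 = 0.5, CP5 = 0.75)),
    list(midn = "Pz",  lat = "P7",  inner = c(P1 = 0.25, P3 = 0.5, P5 = 0.75)),
    list(midn = "AFz", lat = "AF7", inner = c(AF3 = 0.5)),
    list(midn = "POz", lat = "PO7", inner = c(PO3 = 0.5)))
  for (rw in rows) {
    u <- pos[[rw$midn]]
    vL <- pos[[rw$lat]]
    latR <- sub("7$", "8", rw$lat)
    vR <- pos[[latR]]
    for (nm in names(rw$inner)) {
      t <- rw$inner[[nm]]
      pos[[nm]] <- .slerp(u, vL, t)
      nmR <- chartr("135", "246", nm)
      pos[[nmR]] <- .slerp(u, vR, t)
    }
  }
  do.call(rbind, pos)
}

.std64names <- c(
  "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6",
  "C5", "C3", "C1", "Cz", "C2", "C4", "C6",
  "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6",
  "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FT8", "T7", "T8", "T9", "T10", "TP7", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2", "Iz")

.stdSubsets <- list(
  `8`  = c("F3", "F4", "C3", "C4", "P3", "P4", "O1", "O2"),
  `16` = c("Fp1", "Fp2", "F7", "F3", "F4", "F8", "T7", "C3", "C4", "T8",
           "P7", "P3", "P4", "P8", "O1", "O2"),
  `32` = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F3", "Fz", "F4", "F8",
           "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
           "CP5", "CP1", "CP2", "CP6", "P7", "P3", "Pz", "P4", "P8",
           "PO3", "PO4", "O1", "Oz", "O2"))

# Fibonacci lattice on the upper hemisphere (synthetic grid fallback)
.fibonacciGrid <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - i / n            # upper hemisphere z in (0, 1)
  phi <- i * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Construct a Montage object
#'
#' @param names character electrode labels.
#' @param positions numeric C x 3 matrix of head-frame positions; projected
#'   to the unit sphere.
#' @param rank optional 0-based canonical order; defaults to input order.
#' @return a [Montage-class].
#' @export
Montage <- function(names, positions, rank = seq_along(names) - 1L) {
  positions <- as.matrix(positions)
  nrm <- sqrt(rowSums(positions^2))
  if (any(!is.finite(nrm)) || any(nrm == 0))
    stop("electrode positions must be finite and nonzero")
  new("Montage", names = as.character(names),
      positions = positions / nrm, rank = as.integer(rank))
}

#' Build a standard (or synthetic-grid) electrode montage
#'
#' Channel counts 8, 16, 32, 62 and 64 give named subsets of the idealized
#' 10-10 layout (the 62-channel variant drops the below-ring T9/T10 pair);
#' any other count falls back to a deterministic Fibonacci grid on the upper
#' hemisphere with generated labels, unless \code{allowFallback = FALSE}.
#'
#' @param nChannels requested number of electrodes.
#' @param allowFallback allow the synthetic-grid fallback for non-standard
#'   counts.
#' @return a [Montage-class] with deterministic ordering and unit-norm
#'   positions.
#' @examples
#' m <- buildStandardMontage(64)
#' head(electrodePositions(m))
#' @export
buildStandardMontage <- function(nChannels, allowFallback = TRUE) {
  nChannels <- as.integer(nChannels)
  tab <- .build1010table()
  nm <- switch(as.character(nChannels),
    "64" = .std64names,
    "62" = setdiff(.std64names, c("T9", "T10")),
    "32" = .stdSubsets[["32"]],
    "16" = .stdSubsets[["16"]],
    "8"  = .stdSubsets[["8"]],
    NULL)
  if (is.null(nm)) {
    if (!allowFallback)
      stop(sprintf("no standard montage with %d channels (fallback disabled)",
                   nChannels))
    return(Montage(sprintf("E%02d", seq_len(nChannels)),
                   .fibonacciGrid(nChannels)))
  }
  Montage(nm, tab[nm, , drop = FALSE])
}

#' Great-circle distances between unit-sphere points
#'
#' @param P,Q numeric matrices of unit vectors (rows); \code{Q} defaults to
#'   \code{P}.
#' @return matrix of pairwise angular distances in radians.
#' @export
greatCircleDist <- function(P, Q = P) {
  if (is.null(dim(P))) P <- matrix(P, nrow = 1)
  if (is.null(dim(Q))) Q <- matrix(Q, nrow = 1)
  d <- tcrossprod(P, Q)
  acos(pmin(pmax(d, -1), 1))   # argument order keeps the dim attribute
}

#' Deterministic low-density channel subset (Case-1 style masking)
#'
#' Chooses \code{C/factor} electrodes by greedy farthest-point sampling on
#' the unit sphere, seeded at the electrode nearest the vertex, ties broken
#' by canonical rank. This emulates a practical low-density acquisition that
#' maximizes spatial coverage while preserving temporal continuity.
#'
#' @param montage a [Montage-class].
#' @param factor spatial reduction factor (1, 2, 4 or 8).
#' @return ordered (by rank) integer vector of 1-based channel indices.
#' @export
selectLrSubset <- function(montage, factor) {
  C <- nChannels(montage)
  factor <- as.integer(factor)
  if (factor == 1L) return(order(montage@rank))
  if (C %% factor != 0)
    stop(sprintf(
      "factor %d does not divide %d channels; achievable subset size %d",
      factor, C, floor(C / factor)))
  m <- C %/% factor
  P <- montage@positions
  dVert <- greatCircleDist(P, matrix(c(0, 0, 1), 1))[, 1]
  ord <- order(dVert, montage@rank)
  sel <- ord[1]
  D <- greatCircleDist(P)
  minD <- D[, sel]
  while (length(sel) < m) {
    minD[sel] <- -Inf
    best <- order(-minD, montage@rank)[1]
    sel <- c(sel, best)
    minD <- pmin(minD, D[, best])
  }
  sel[order(montage@rank[sel])]
}

#' Subset a montage, renumbering ranks 0..n-1 in the retained order
#'
#' @param montage a [Montage-class].
#' @param idx 1-based channel indices or electrode names.
#' @export
montageSubset <- function(montage, idx) {
  if (is.character(idx)) idx <- match(idx, montage@names)
  if (anyNA(idx) || any(idx < 1) || any(idx > nChannels(montage)))
    stop("subset indices out of range")
  Montage(montage@names[idx], montage@positions[idx, , drop = FALSE])
}

#' Read / write plain-text electrode files
#'
#' One electrode per line: \code{name x y z}, whitespace separated.
#' Positions are projected to the unit sphere on read.
#'
#' @param path file path.
#' @return [readMontageFile()] returns a [Montage-class].
#' @export
readMontageFile <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("name", "x", "y", "z"),
                           stringsAsFactors = FALSE)
  Montage(tab$name, as.matrix(tab[, c("x", "y", "z")]))
}

#' @rdname readMontageFile
#' @param montage a [Montage-class] to write.
#' @export
writeMontageFile <- function(montage, path) {
  tab <- data.frame(name = montage@names, montage@positions)
  utils::write.table(tab, path, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
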