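#' Idealized 10-20 electrode positions on the unit sphere
#'
#' Returns 3D unit-sphere coordinates for the standard 19-channel 10-20
#' montage (and the T7/T8/P7/P8 aliases of T3/T4/T5/T6). The head is a unit
#' sphere with +x toward the right ear, +y toward the nasion and +z through
#' the vertex (Cz). Outer-ring electrodes sit at 72 degrees of inclination
#' (the 10% ring through Fp1/Fp2 and O1/O2); Fz, Pz, C3 and C4 at 36 degrees;
#' F3/F4/P3/P4 at the spherical midpoints of their 10-20 neighbours, which is
#' how the montage defines them along the transverse arcs.
#'
#' @param labels optional character vector of channel names to look up; the
#'   default returns the full 19-channel template.
#' @return numeric matrix with one row per channel (rownames = labels) and
#'   columns x, y, z. Unknown labels yield `NA` rows with a warning.
#' @examples
#' standardPositions1020(c("Fz", "Cz", "O1"))
#' @export
standardPositions1020 <- function(labels = NULL) {
  deg <- pi / 180
  sph <- function(inclDeg, aziDeg) {
    th <- inclDeg * deg; ph <- aziDeg * deg
    c(sin(th) * sin(ph), sin(th) * cos(ph), cos(th))
  }
  mid <- function(a, b) { v <- a + b; v / sqrt(sum(v^2)) }
  pos <- list(
    Fp1 = sph(72, -18), Fp2 = sph(72, 18),
    F7  = sph(72, -54), F8  = sph(72, 54),
    T3  = sph(72, -90), T4  = sph(72, 90),
    T5  = sph(72, -126), T6 = sph(72, 126),
    O1  = sph(72, -162), O2 = sph(72, 162),
    Fz  = sph(36, 0), Pz = sph(36, 180),
    C3  = sph(36, -90), C4 = sph(36, 90),
    Cz  = c(0, 0, 1)
  )
  pos$F3 <- mid(pos$Fz, pos$F7); pos$F4 <- mid(pos$Fz, pos$F8)
  pos$P3 <- mid(pos$Pz, pos$T5); pos$P4 <- mid(pos$Pz, pos$T6)
  # modern equivalents of the older temporal names
  pos$T7 <- pos$T3; pos$T8 <- pos$T4; pos$P7 <- pos$T5; pos$P8 <- pos$T6
  order19 <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
               "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
  if (is.null(labels)) labels <- order19
  out <- matrix(NA_real_, nrow = length(labels), ncol = 3,
                dimnames = list(labels, c("x", "y", "z")))
  known <- labels %in% names(pos)
  if (any(!known))
    warning("no template position for channel(s): ",
            paste(labels[!known], collapse = ", "))
  for (i in which(known)) out[i, ] <- pos[[labels[i]]]
  out
}

#' The 19 standard 10-20 channel names used throughout the package
#' @return character vector of length 19.
#' @export
standardChannels1020 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3", "Cz",
    "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "O2")
}

# Legendre polynomials P_1..P_nmax evaluated at x (vector), by recurrence.
# Returns length(x) x nmax matrix.
.legendreP <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))   # P_0
  p <- x                     # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
      out[, n] <- pn
      pm1 <- p; p <- pn
    }
  }
  out
}

# Perrin-style spherical-spline g function: g(cos angle) with stiffness m
# truncated at nTerms Legendre terms.
.splineG <- function(cosang, m = 4, nTerms = 50) {
  P <- .legendreP(pmin(pmax(cosang, -1), 1), nTerms)
  n <- seq_len(nTerms)
  w <- (2 * n + 1) / (n^m * (n + 1)^m)
  as.vector(P %*% w) / (4 * pi)
}

#' Spherical-spline interpolation of scalp channels
#'
#' Reconstructs the signal at target electrode locations from the remaining
#' (good) electrodes using spherical splines on the unit sphere: the spline
#' coefficients solve the interpolation system on the good electrodes and the
#' fitted surface is evaluated at the bad locations. Used to replace channels
#' whose amplitudes exceed the artifact threshold.
#'
#' @param goodPos n_good x 3 unit-sphere coordinates of the source electrodes.
#' @param goodData n_good x n_samples matrix of source signals.
#' @param badPos n_bad x 3 coordinates of the electrodes to reconstruct.
#' @param stiffness spline stiffness exponent m; 4 is the conventional choice
#'   for scalp potentials.
#' @param nTerms number of Legendre terms in the spline kernel.
#' @param lambda small ridge added to the kernel diagonal for numerical
#'   stability.
#' @return n_bad x n_samples matrix of interpolated signals.
#' @export
sphericalSplineInterpolate <- function(goodPos, goodData, badPos,
                                       stiffness = 4, nTerms = 50,
                                       lambda = 1e-8) {
  goodPos <- as.matrix(goodPos); badPos <- as.matrix(badPos)
  goodData <- as.matrix(goodData)
  ng <- nrow(goodPos)
  if (ng < 4) stop("spherical spline interpolation needs at least 4 good channels")
  if (nrow(goodData) != ng) stop("goodData rows must match goodPos rows")
  G <- .splineG(tcrossprod(goodPos), m = stiffness, nTerms = nTerms)
  dim(G) <- c(ng, ng)
  G <- G + diag(lambda, ng)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  rhs <- rbind(goodData, 0)
  sol <- solve(A, rhs)                      # coefficients c_1..c_ng, then c0
  Gb <- .splineG(tcrossprod(badPos, goodPos), m = stiffness, nTerms = nTerms)
  dim(Gb) <- c(nrow(badPos), ng)
  Gb %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(badPos), ncol(goodData), byrow = TRUE)
}
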