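# Shrake-Rupley solvent-accessible surface area.
#
# Deterministic: sphere points come from a Fibonacci lattice, so repeated
# calls (and rigid motions of the whole atom set) give identical areas up
# to floating-point rotation error.

# Orthonormal frame for atom i from smooth inverse-distance-weighted
# neighbour moments (rows = basis vectors). The frame rotates rigidly
# with the structure and, being a continuous function of coordinates,
# is insensitive to exact distance ties (regular lattices). Falls back
# to the identity for isolated or perfectly symmetric atoms, whose
# occlusion pattern is orientation-independent anyway.
local_frame <- function(xyz, di, i) {
  r <- sweep(xyz, 2, xyz[i, ])
  d <- pmax(di, 1e-6)
  d[i] <- Inf
  v1 <- colSums(r / d^3)
  n1 <- sqrt(sum(v1^2))
  if (n1 < 1e-8) return(diag(3))
  u1 <- v1 / n1
  v2 <- colSums(r / d^5)
  v2 <- v2 - sum(v2 * u1) * u1
  n2 <- sqrt(sum(v2^2))
  if (n2 < 1e-8) {
    v2 <- if (abs(u1[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v2 <- v2 - sum(v2 * u1) * u1
    n2 <- sqrt(sum(v2^2))
  }
  u2 <- v2 / n2
  u3 <- c(u1[2] * u2[3] - u1[3] * u2[2],
          u1[3] * u2[1] - u1[1] * u2[3],
          u1[1] * u2[2] - u1[2] * u2[1])
  rbind(u1, u2, u3)
}

# n approximately evenly distributed unit-sphere points (golden-spiral).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' The sphere lattice of each atom is oriented by a local frame built
#' from the directions to its two nearest neighbours, so the sample
#' points move rigidly with the structure and the computed areas are
#' invariant under rotation and translation (up to floating point).
#'
#' @param xyz n x 3 matrix of atom coordinates (Angstrom).
#' @param radii length-n van der Waals radii (Angstrom).
#' @param probe_radius probe radius (Angstrom), default 1.4.
#' @param n_points sphere sample points per atom, default 960.
#' @return numeric vector of per-atom areas (Angstrom^2).
#' @export
sasa_atoms <- function(xyz, radii, probe_radius = 1.4, n_points = 960) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  if (n == 0) return(numeric(0))
  stopifnot(length(radii) == n)
  sphere <- fibonacci_sphere(n_points)
  ext <- radii + probe_radius
  area <- numeric(n)
  maxr <- max(ext)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < ext[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < ext[i] + ext[nb]]
    frame <- local_frame(xyz, di, i)
    pts <- sweep(sphere %*% (frame * ext[i]), 2, xyz[i, ], "+")
    if (length(nb) == 0) {
      exposed <- n_points
    } else {
      blocked <- rep(FALSE, n_points)
      for (j in nb) {
        dj2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
          (pts[, 3] - xyz[j, 3])^2
        blocked <- blocked | dj2 < ext[j]^2
        if (all(blocked)) break
      }
      exposed <- sum(!blocked)
    }
    area[i] <- 4 * pi * ext[i]^2 * exposed / n_points
  }
  area
}

#' Buried interface area between two atom groups
#'
#' Half the total solvent-accessible surface area buried on complex
#' formation: `(SASA(a) + SASA(b) - SASA(ab)) / 2`, i.e. the
#' buried-area-per-side convention. The per-monomer (summed) convention
#' is twice this value.
#'
#' @param xyz_a,xyz_b coordinate matrices for the two groups.
#' @param radii_a,radii_b van der Waals radii for the two groups.
#' @param probe_radius,n_points passed to [sasa_atoms()].
#' @return interface area in Angstrom^2 (non-negative up to sampling noise).
#' @export
interface_area <- function(xyz_a, radii_a, xyz_b, radii_b,
                           probe_radius = 1.4, n_points = 960) {
  if (NROW(xyz_a) == 0 || NROW(xyz_b) == 0)
    stop("interface_area: empty atom group")
  sa <- sum(sasa_atoms(xyz_a, radii_a, probe_radius, n_points))
  sb <- sum(sasa_atoms(xyz_b, radii_b, probe_radius, n_points))
  sab <- sum(sasa_atoms(rbind(as.matrix(xyz_a), as.matrix(xyz_b)),
                        c(radii_a, radii_b), probe_radius, n_points))
  (sa + sb - sab) / 2
}

# Atom coordinates + radii for a residue span of one chain.
span_atoms <- function(struct, chain, start = NULL, end = NULL) {
  a <- struct$atoms
  sel <- a$chain == chain
  if (!is.null(start)) sel <- sel & a$seq_index >= start & a$seq_index <= end
  list(xyz = as.matrix(a[sel, c("x", "y", "z")]),
       radii = vdw_radius(a$element[sel]),
       seq_index = a$seq_index[sel])
}
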