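# Deterministic near-uniform sphere points (Fibonacci / golden-section
# spiral). Quadrature error of the Shrake-Rupley scheme scales ~ 1/n.
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from a point quadrature on each atom's solvent
#' sphere (vdW radius + probe), with points occluded by any neighbouring
#' atom's solvent sphere removed. Hydrogens are ignored: areas are computed
#' over heavy atoms with a united-atom style radii table.
#'
#' @param structure A [structure3d].
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Quadrature points per atom sphere.
#' @param radii Named per-element radii table, see [vdw_radii()].
#' @param idx Optional atom indices to restrict the structure to.
#' @return Numeric vector of per-atom areas (A^2) over the heavy atoms
#'   considered, with attribute `idx` giving their atom indices.
#' @export
sasa <- function(structure, probe = 1.4, n_points = 960,
                 radii = vdw_radii(), idx = NULL) {
  stopifnot(inherits(structure, "structure3d"))
  if (probe <= 0) stop("parameter error: probe must be positive")
  if (n_points <= 0) stop("parameter error: n_points must be positive")
  if (is.null(idx)) idx <- seq_len(nrow(structure$atoms))
  el <- structure$atoms$element[idx]
  heavy <- !(el %in% c("H", "D"))
  idx <- idx[heavy]; el <- el[heavy]
  if (!length(idx)) stop("no heavy atoms to compute areas for")
  r <- radii[el]
  if (anyNA(r))
    stop("no radius for element(s): ",
         paste(unique(el[is.na(r)]), collapse = ", "))
  r <- unname(r) + probe
  xyz <- structure$xyz[idx, , drop = FALSE]
  pts <- .sphere_points(n_points)
  n <- length(idx)
  areas <- numeric(n)
  # neighbour lists: spheres i,j can occlude each other iff d < r_i + r_j
  rmax <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    nb <- which(d2 < (r[i] + r)^2 & seq_len(n) != i)
    sp <- sweep(pts * r[i], 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      dj <- sweep(sp, 2, xyz[j, ])
      acc <- acc & (rowSums(dj^2) > r[j]^2)
      if (!any(acc)) break
    }
    areas[i] <- 4 * pi * r[i]^2 * sum(acc) / n_points
  }
  attr(areas, "idx") <- idx
  areas
}

#' Buried interface area between two components of a complex
#'
#' Half the solvent-accessible area buried on complex formation:
#' (SASA(A alone) + SASA(B alone) - SASA(AB)) / 2, the per-side buried
#' surface convention of protein-interface analysis.
#'
#' @param complex A [structure3d] containing both components.
#' @param selA,selB Selection strings for the two components; they must be
#'   disjoint.
#' @inheritParams sasa
#' @return Interface area in A^2.
#' @export
interface_area <- function(complex, selA, selB, probe = 1.4,
                           n_points = 960, radii = vdw_radii()) {
  ia <- select_atoms(complex, selA)
  ib <- select_atoms(complex, selB)
  if (length(intersect(ia, ib)))
    stop("selection error: component selections overlap")
  if (!length(ia) || !length(ib))
    stop("selection error: empty component selection")
  sA <- sum(sasa(complex, probe, n_points, radii, idx = ia))
  sB <- sum(sasa(complex, probe, n_points, radii, idx = ib))
  sAB <- sum(sasa(complex, probe, n_points, radii, idx = c(ia, ib)))
  (sA + sB - sAB) / 2
}
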