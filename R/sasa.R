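## van der Waals radii sets (Angstrom).
## "chothia": protein-specific set distinguishing trigonal (carbonyl,
## aromatic, amide/carboxyl/guanidinium) carbons at 1.76 from tetrahedral
## carbons at 1.87; "bondi": the generic element set.
.sp2_carbon <- list(
  backbone = "C",
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CG", "CD1", "CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
  HIS = c("CG", "CD2", "CE1"),
  ARG = "CZ", ASN = "CG", ASP = "CG", GLN = "CD", GLU = "CD"
)

.radii_bondi <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
  S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90
)
.radii_chothia_base <- c(
  N = 1.65, O = 1.40, S = 1.85, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90, H = 1.00
)

atom_radii <- function(atoms, radii_set = c("chothia", "bondi"),
                       default_radius = NULL) {
  radii_set <- match.arg(radii_set)
  el <- toupper(atoms$element)
  if (radii_set == "bondi") {
    r <- unname(.radii_bondi[el])
  } else {
    r <- unname(.radii_chothia_base[el])
    isC <- el == "C"
    if (any(isC)) {
      sp2 <- atoms$name == "C" & atoms$record == "ATOM"
      for (rn in setdiff(names(.sp2_carbon), "backbone")) {
        sp2 <- sp2 | (atoms$resname == rn & atoms$name %in% .sp2_carbon[[rn]])
      }
      r[isC] <- ifelse(sp2[isC], 1.76, 1.87)
    }
  }
  if (anyNA(r)) {
    if (is.null(default_radius)) {
      stop("no ", radii_set, " radius for element(s): ",
           paste(unique(el[is.na(r)]), collapse = ", "),
           " (supply default_radius)")
    }
    r[is.na(r)] <- default_radius
  }
  r
}

## deterministic molecule-fixed orthonormal frame (principal axes of the
## coordinates, signs and handedness fixed) so the quadrature sphere
## co-rotates with the structure and total SASA is rigid-motion invariant
principal_frame <- function(xyz) {
  if (nrow(xyz) < 3L) return(diag(3))
  cv <- stats::cov(xyz)
  if (!all(is.finite(cv))) return(diag(3))
  ev <- eigen(cv, symmetric = TRUE)
  v <- ev$vectors
  ctr <- colMeans(xyz)
  for (k in 1:2) {
    ## orient each axis by the coordinate skewness along it, which rotates
    ## with the molecule; fall back to a fixed rule for symmetric clouds
    pr <- (xyz[, 1] - ctr[1]) * v[1, k] + (xyz[, 2] - ctr[2]) * v[2, k] +
      (xyz[, 3] - ctr[3]) * v[3, k]
    s3 <- sum(pr^3)
    if (abs(s3) > 1e-6) {
      if (s3 < 0) v[, k] <- -v[, k]
    } else {
      j <- which.max(abs(v[, k]))
      if (v[j, k] < 0) v[, k] <- -v[, k]
    }
  }
  v[, 3] <- c(v[2, 1] * v[3, 2] - v[3, 1] * v[2, 2],
              v[3, 1] * v[1, 2] - v[1, 1] * v[3, 2],
              v[1, 1] * v[2, 2] - v[2, 1] * v[1, 2])
  v
}

## deterministic quasi-uniform points on the unit sphere (golden spiral)
golden_spiral <- function(n) {
  k <- seq_len(n)
  z <- 1 - 2 * (k - 0.5) / n
  theta <- pi * (3 - sqrt(5)) * k
  rho <- sqrt(pmax(0, 1 - z^2))
  cbind(rho * cos(theta), rho * sin(theta), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numerical SASA: each heavy atom's sphere is expanded by the probe radius
#' and sampled with a deterministic golden-spiral point set; a test point is
#' accessible iff it lies outside every neighboring atom's expanded sphere,
#' and the atom's area is the accessible fraction of its expanded-sphere
#' area. Neighbors are restricted to atoms within
#' \eqn{r_i + r_j + 2\,probe}. Hydrogens are ignored.
#'
#' @param x atoms: a `pocket_model`, `pdb_structure`, `ligand_molecule` or
#'   atom data.frame.
#' @param probe probe radius in Angstrom (1.4 = water).
#' @param n_points test points per atom (>= 100).
#' @param radii_set `"chothia"` (protein-specific, default) or `"bondi"`.
#' @param default_radius fallback radius for elements missing from the set;
#'   if `NULL`, unknown elements are an error.
#' @return an object of class `sasa_result`: list with `per_atom` (Angstrom^2
#'   per atom, file order), `per_residue` (data.frame `chain`, `resnum`,
#'   `icode`, `resname`, `area`), `total`, `probe`, `n_points`,
#'   `radii_set`.
#' @examples
#' one_c <- data.frame(record = "ATOM", serial = 1L, name = "CB",
#'   altloc = "", resname = "ALA", chain = "A", resnum = 1L, icode = "",
#'   x = 0, y = 0, z = 0, occupancy = 1, element = "C")
#' shrake_rupley(one_c)$total  # ~ 4*pi*(1.87+1.4)^2
#' @export
shrake_rupley <- function(x, probe = 1.4, n_points = 960L,
                          radii_set = c("chothia", "bondi"),
                          default_radius = NULL) {
  radii_set <- match.arg(radii_set)
  stopifnot(probe > 0, n_points >= 100L)
  atoms <- as_atoms(x)
  atoms <- atoms[is_heavy(atoms$element), , drop = FALSE]
  n <- nrow(atoms)
  if (n == 0L) stop("no heavy atoms to compute SASA for")
  r <- atom_radii(atoms, radii_set, default_radius)
  R <- r + probe
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  pts <- golden_spiral(n_points) %*% t(principal_frame(xyz))
  area <- numeric(n)
  ## pairwise squared distances (fine for pocket-sized inputs)
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    nb <- which(d2[, i] < (R[i] + R)^2 & seq_len(n) != i)
    if (!length(nb)) {
      area[i] <- 4 * pi * R[i]^2
      next
    }
    p <- pts * R[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb[order(d2[nb, i])]) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= R[j]^2
    }
    area[i] <- sum(acc) / n_points * 4 * pi * R[i]^2
  }
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, atoms$resname,
               sep = "|")
  agg <- tapply(area, factor(key, levels = unique(key)), sum)
  first <- match(unique(key), key)
  per_residue <- data.frame(
    chain = atoms$chain[first], resnum = atoms$resnum[first],
    icode = atoms$icode[first], resname = atoms$resname[first],
    area = as.numeric(agg), stringsAsFactors = FALSE
  )
  structure(
    list(per_atom = area, per_residue = per_residue, total = sum(area),
         probe = probe, n_points = as.integer(n_points),
         radii_set = radii_set),
    class = "sasa_result"
  )
}

#' @export
print.sasa_result <- function(x, ...) {
  cat("sasa_result: total ", sprintf("%.2f", x$total), " A^2 over ",
      length(x$per_atom), " atoms (probe ", x$probe, " A, ",
      x$n_points, " points, ", x$radii_set, " radii)\n", sep = "")
  invisible(x)
}
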