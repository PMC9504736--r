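# internal geometry and chemistry helpers

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

## angle A-B-C at vertex B, degrees
angle_deg <- function(a, b, c) {
  u <- a - b
  v <- c - b
  ct <- sum(u * v) / (vnorm(u) * vnorm(v))
  ct <- max(-1, min(1, ct))
  acos(ct) * 180 / pi
}

## torsion a-b-c-d, degrees in (-180, 180]
torsion_deg <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(
    b1[2] * b2[3] - b1[3] * b2[2],
    b1[3] * b2[1] - b1[1] * b2[3],
    b1[1] * b2[2] - b1[2] * b2[1]
  )
  n2 <- c(
    b2[2] * b3[3] - b2[3] * b3[2],
    b2[3] * b3[1] - b2[1] * b3[3],
    b2[1] * b3[2] - b2[2] * b3[1]
  )
  m1 <- c(
    n1[2] * unitv(b2)[3] - n1[3] * unitv(b2)[2],
    n1[3] * unitv(b2)[1] - n1[1] * unitv(b2)[3],
    n1[1] * unitv(b2)[2] - n1[2] * unitv(b2)[1]
  )
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## average atomic masses (Da) for elements seen in protein/ligand structures
.atomic_mass <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
  SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.99,
  K = 39.098, CA = 40.078, MN = 54.938
)

## standard 3-letter -> 1-letter amino acid code
.aa_321 <- c(
  ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
  GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
  LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
  SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V"
)

## residue identifier string used in several tables
res_id <- function(chain, resnum, icode) {
  ic <- ifelse(is.na(icode) | icode == "", "", icode)
  paste0(chain, resnum, ic)
}

## infer element symbol from PDB atom name when columns 77-78 are absent
infer_element <- function(name, record = "ATOM") {
  name <- toupper(trimws(name))
  two_letter <- c(
    "CL", "BR", "FE", "ZN", "MG", "MN", "NA", "SE", "CU", "NI", "CO", "CD"
  )
  vapply(seq_along(name), function(i) {
    nm <- gsub("^[0-9']+", "", name[i])
    if (nchar(nm) == 0L) stop("cannot infer element from atom name '", name[i], "'")
    if (record[i] == "HETATM" && nchar(nm) >= 2L &&
        substr(nm, 1, 2) %in% two_letter) {
      return(substr(nm, 1, 2))
    }
    substr(nm, 1, 1)
  }, character(1))
}

is_heavy <- function(element) !(toupper(element) %in% c("H", "D"))

## rotation matrix taking unit vector u onto unit vector v (Rodrigues)
rotation_between <- function(u, v) {
  u <- unitv(u); v <- unitv(v)
  w <- c(u[2] * v[3] - u[3] * v[2],
         u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  s <- vnorm(w)
  cth <- sum(u * v)
  if (s < 1e-9) {
    if (cth > 0) return(diag(3))
    ## opposite vectors: rotate 180 degrees about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    w <- unitv(p - sum(p * u) * u)
    return(2 * outer(w, w) - diag(3))
  }
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + wx + wx %*% wx * ((1 - cth) / s^2)
}

## restore RNG state on exit; runs expr under a locally seeded stream
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
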