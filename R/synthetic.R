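## internal-coordinate atom placement (natural extension reference frame):
## position D given A-B-C, the B-C-D angle, |C-D| and the A-B-C-D torsion
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  bc <- unitv(c - b)
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- unitv(n)
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
         bond * sin(tor) * sin(ang))
  c + d[1] * bc + d[2] * m + d[3] * n
}

## build an N-CA-C(-O) backbone chain from phi/psi torsions (ideal bond
## lengths and angles); returns list of n x 3 matrices
build_backbone <- function(n, phi, psi, omega = 180) {
  bNCA <- 1.458; bCAC <- 1.525; bCN <- 1.329; bCO <- 1.231
  aNCAC <- 111.0; aCACN <- 116.2; aCNCA <- 121.7; aCACO <- 120.5
  N <- CA <- C <- O <- matrix(NA_real_, n, 3)
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  C[1, ] <- place_atom(c(0, -1, 0), N[1, ], CA[1, ], bCAC, aNCAC, 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bCN,
                           aCACN, psi)
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA,
                            aCNCA, omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi)
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ], bCO, aCACO, psi + 180)
  }
  list(N = N, CA = CA, C = C, O = O)
}

## assemble a backbone atom table into a pdb_structure
backbone_structure <- function(bb, resnames, chain = "A",
                               resnum = seq_len(nrow(bb$N)),
                               source = "synthetic") {
  n <- nrow(bb$N)
  rows <- vector("list", n)
  serial <- 0L
  for (i in seq_len(n)) {
    nm <- c("N", "CA", "C", "O")
    el <- c("N", "C", "C", "O")
    xyz <- rbind(bb$N[i, ], bb$CA[i, ], bb$C[i, ], bb$O[i, ])
    if (!is.null(bb$CB) && !any(is.na(bb$CB[i, ]))) {
      nm <- c(nm, "CB"); el <- c(el, "C"); xyz <- rbind(xyz, bb$CB[i, ])
    }
    rows[[i]] <- data.frame(
      record = "ATOM", serial = serial + seq_along(nm), name = nm,
      altloc = "", resname = resnames[i], chain = chain,
      resnum = resnum[i], icode = "", x = xyz[, 1], y = xyz[, 2],
      z = xyz[, 3], occupancy = 1, element = el, stringsAsFactors = FALSE
    )
    serial <- serial + length(nm)
  }
  structure(list(atoms = do.call(rbind, rows), source = source),
            class = "pdb_structure")
}

## cylindrical offsets of backbone atoms relative to CA in the ideal
## alpha-helix (phi -57, psi -47, ideal internal geometry); derived once
## from the internal-coordinate builder above
.helix_ref <- list(
  ca = c(r = 2.2758, twist = 99.473, rise = 1.5514),
  N = c(r = 1.5497, dtheta = -26.812, dz = -0.9166),
  C = c(r = 1.6642, dtheta = 26.793, dz = 1.0669),
  O = c(r = 1.9209, dtheta = 20.278, dz = 2.2536)
)

#' Ideal alpha-helix fixture
#'
#' Generates an n-residue poly-alanine helix whose C-alpha atoms lie on the
#' parameterized cylinder (consecutive C-alpha distance
#' \eqn{\sqrt{(2 r \sin(t/2))^2 + rise^2}} ~ 3.8 Angstrom at the defaults).
#' Backbone N, C and O are placed at the cylindrical offsets of the ideal
#' (phi = -57, psi = -47) helix, scaled to the requested parameters, so the
#' fixture is recognized as helix by [assign_sse()].
#'
#' @param n number of residues (>= 4 for a recognizable helix).
#' @param radius C-alpha helix radius, Angstrom.
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param chain chain identifier.
#' @return a `pdb_structure` with residues numbered 1..n.
#' @export
ideal_helix <- function(n, radius = 2.3, rise = 1.5, twist = 100,
                        chain = "A") {
  if (n < 1) stop("n must be >= 1")
  ref <- .helix_ref
  sr <- radius / ref$ca[["r"]]
  st <- twist / ref$ca[["twist"]]
  sz <- rise / ref$ca[["rise"]]
  at <- function(r, th_deg, z) {
    th <- th_deg * pi / 180
    c(r * cos(th), r * sin(th), z)
  }
  bb <- list(N = matrix(0, n, 3), CA = matrix(0, n, 3),
             C = matrix(0, n, 3), O = matrix(0, n, 3))
  for (i in seq_len(n)) {
    th0 <- (i - 1) * twist
    z0 <- (i - 1) * rise
    bb$CA[i, ] <- at(radius, th0, z0)
    bb$N[i, ] <- at(ref$N[["r"]] * sr, th0 + ref$N[["dtheta"]] * st,
                    z0 + ref$N[["dz"]] * sz)
    bb$C[i, ] <- at(ref$C[["r"]] * sr, th0 + ref$C[["dtheta"]] * st,
                    z0 + ref$C[["dz"]] * sz)
    bb$O[i, ] <- at(ref$O[["r"]] * sr, th0 + ref$O[["dtheta"]] * st,
                    z0 + ref$O[["dz"]] * sz)
  }
  backbone_structure(bb, rep("ALA", n), chain = chain,
                     source = "ideal_helix")
}

## rigid placement of the antiparallel partner strand, derived numerically
## to maximize inter-strand Kabsch-Sander bonds at 4.8 A separation
.strand_pair_ref <- list(rot_x = -20, tx = 2.5, tz = 0)

## rotate so the chain end-to-end vector lies on +x and center the chain
orient_along_x <- function(bb) {
  all_xyz <- rbind(bb$N, bb$CA, bb$C, bb$O)
  ctr <- colMeans(bb$CA)
  u <- unitv(bb$CA[nrow(bb$CA), ] - bb$CA[1, ])
  ## rotation taking u to x-hat (Rodrigues)
  v <- c(u[2] * 0 - u[3] * 0, u[3] * 1 - u[1] * 0, u[1] * 0 - u[2] * 1)
  v <- c(0, u[3], -u[2])                       # u x xhat
  s <- vnorm(v); cth <- u[1]
  R <- diag(3)
  if (s > 1e-9) {
    vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
                 3, 3, byrow = TRUE)
    R <- diag(3) + vx + vx %*% vx * ((1 - cth) / s^2)
  } else if (cth < 0) {
    R <- diag(c(-1, -1, 1))
  }
  for (nm in names(bb)) {
    bb[[nm]] <- t(R %*% (t(bb[[nm]]) - ctr))
  }
  bb
}

rot_about_x <- function(bb, deg) {
  th <- deg * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), -sin(th), 0, sin(th), cos(th)),
              3, 3, byrow = TRUE)
  for (nm in names(bb)) bb[[nm]] <- t(R %*% t(bb[[nm]]))
  bb
}

#' Ideal antiparallel strand-pair fixture
#'
#' Two n-residue extended chains (phi = -139, psi = 135) arranged as an
#' antiparallel pair: the partner is the first strand rotated 180 degrees
#' about the sheet normal and offset to the requested inter-strand
#' separation, with a registry shift chosen so that the classic alternating
#' N-H...O=C ladder forms. Residues are numbered 1..n and (n+11)..(2n+10)
#' in one chain so the strands are covalently disconnected.
#'
#' @param n residues per strand (>= 2).
#' @param separation inter-strand axis separation, Angstrom (4.8 is the
#'   canonical antiparallel sheet spacing; large values give no H-bonds).
#' @return a `pdb_structure` with `2 n` residues.
#' @export
ideal_strand_pair <- function(n, separation = 4.8) {
  if (n < 2) stop("n must be >= 2")
  bb1 <- orient_along_x(build_backbone(n, phi = -139, psi = 135))
  bb1 <- rot_about_x(bb1, .strand_pair_ref$rot_x)
  ## partner: two-fold rotation about z (x -> -x, y -> -y), then offset
  bb2 <- bb1
  for (nm in names(bb2)) {
    bb2[[nm]][, 1] <- -bb2[[nm]][, 1]
    bb2[[nm]][, 2] <- -bb2[[nm]][, 2]
    bb2[[nm]][, 1] <- bb2[[nm]][, 1] + .strand_pair_ref$tx
    bb2[[nm]][, 2] <- bb2[[nm]][, 2] + separation
    bb2[[nm]][, 3] <- bb2[[nm]][, 3] + .strand_pair_ref$tz
  }
  bb <- list(N = rbind(bb1$N, bb2$N), CA = rbind(bb1$CA, bb2$CA),
             C = rbind(bb1$C, bb2$C), O = rbind(bb1$O, bb2$O))
  backbone_structure(bb, rep("VAL", 2 * n),
                     resnum = c(seq_len(n), seq_len(n) + n + 10L),
                     source = "ideal_strand_pair")
}

## local residue template (CA at origin): backbone + C-beta side chain
.res_template <- list(
  N = c(-1.458, 0, 0),
  CA = c(0, 0, 0),
  C = c(0.551, 1.420, 0),
  O = c(1.767, 1.608, 0),
  CB = c(0.720, -1.050, 0.840)
)

template_residue <- function(resname, origin, serial0, resnum, chain = "A") {
  nm <- names(.res_template)
  if (resname == "GLY") nm <- setdiff(nm, "CB")
  xyz <- t(vapply(nm, function(a) .res_template[[a]] + origin, numeric(3)))
  data.frame(
    record = "ATOM", serial = serial0 + seq_along(nm), name = nm,
    altloc = "", resname = resname, chain = chain, resnum = resnum,
    icode = "", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, element = substr(nm, 1, 1), stringsAsFactors = FALSE
  )
}

#' Toy protein-ligand complex with planted ground truth
#'
#' Builds a small single-chain "pocket" of coarse residues (backbone plus a
#' C-beta side chain) on a wide grid, then plants: residue-residue contacts
#' at specified side-chain centroid distances, backbone N-H...O=C hydrogen
#' bonds at specified donor-acceptor distance and angle, and a hetero-group
#' ligand with specified minimum heavy-atom distances to designated
#' residues. Residues not involved in any plant sit on a 30-Angstrom grid,
#' far beyond every cutoff. All randomness (directions, noise) flows from
#' `seed`; the same spec and seed give byte-identical PDB output.
#'
#' @param n_residues number of pocket residues.
#' @param resnames residue names (recycled; default `"LEU"`, nonpolar).
#' @param contacts list of `list(a =, b =, distance =)` plants: residue `b`
#'   is placed so its side-chain centroid sits `distance` Angstrom from
#'   residue `a`'s. Each residue may be moved by at most one plant.
#' @param hbonds list of `list(donor =, acceptor =, distance =, angle =)`
#'   plants: the acceptor residue is placed so its backbone O lies
#'   `distance` Angstrom from the donor residue's backbone N at the given
#'   CA-N-O angle (degrees).
#' @param ligand list with `elements` (character vector, one ligand atom
#'   each, default 5 carbons) and `near` — a list of `list(residue =,
#'   distance =)` plants placing one ligand atom at that minimum distance
#'   from the residue.
#' @param noise_sigma Gaussian coordinate noise (Angstrom), applied last.
#' @param seed integer seed for all randomness.
#' @return a `pdb_structure` with residues 1..n and a `LIG` hetero group.
#' @export
toy_complex <- function(n_residues, resnames = "LEU",
                        contacts = list(), hbonds = list(),
                        ligand = list(elements = rep("C", 5), near = list()),
                        noise_sigma = 0, seed = 1L) {
  with_seed(seed, {
    resnames <- rep_len(resnames, n_residues)
    ## base grid positions, well separated
    grid <- as.matrix(expand.grid(x = 0:9, y = 0:9, z = 0:9))[
      seq_len(n_residues), , drop = FALSE] * 30
    origin <- grid + 120                     # keep clear of the ligand site
    moved <- rep(FALSE, n_residues)

    ## side-chain centroid offset of the coarse residue: CB, or CA for GLY
    cent_off <- function(i) {
      if (resnames[i] == "GLY") .res_template$CA else .res_template$CB
    }
    place_rel <- function(i, target, dist) {
      if (moved[i]) stop("residue ", i, " is constrained by multiple plants")
      dir <- unitv(stats::rnorm(3))
      origin[i, ] <<- target + dist * dir
      moved[i] <<- TRUE
    }
    for (ct in contacts) {
      a <- ct$a; b <- ct$b
      cen_a <- origin[a, ] + cent_off(a)
      place_rel(b, cen_a - cent_off(b), ct$distance)
    }
    hb_placements <- list()
    for (hb in hbonds) {
      d <- hb$donor; a <- hb$acceptor
      dist <- if (is.null(hb$distance)) 2.9 else hb$distance
      ang <- if (is.null(hb$angle)) 160 else hb$angle
      n_pos <- origin[d, ] + .res_template$N
      ca_pos <- origin[d, ] + .res_template$CA
      ## direction at the requested CA-N-O angle, rotated within the plane
      u <- unitv(ca_pos - n_pos)
      perp <- unitv(c(-u[2], u[1], 0) + c(0, -u[3], u[2]))
      perp <- unitv(perp - sum(perp * u) * u)
      dir <- cos(ang * pi / 180) * u + sin(ang * pi / 180) * perp
      o_pos <- n_pos + dist * dir
      if (moved[a]) stop("residue ", a, " is constrained by multiple plants")
      ## acceptor residue: O lands on o_pos and the rest of the residue is
      ## rotated to point away from the donor, so only the planted
      ## donor-acceptor pair can satisfy the geometric criterion
      u0 <- unitv(.res_template$C - .res_template$O)
      R <- rotation_between(u0, dir)
      acc_xyz <- lapply(.res_template, function(p) {
        as.numeric(o_pos + R %*% (p - .res_template$O))
      })
      hb_placements[[length(hb_placements) + 1L]] <-
        list(residue = a, xyz = acc_xyz)
      moved[a] <- TRUE
    }

    rows <- list()
    serial <- 0L
    explicit <- stats::setNames(
      lapply(hb_placements, `[[`, "xyz"),
      vapply(hb_placements, function(p) as.character(p$residue),
             character(1)))
    for (i in seq_len(n_residues)) {
      xyz <- explicit[[as.character(i)]]
      if (is.null(xyz)) {
        df <- template_residue(resnames[i], origin[i, ], serial, i)
      } else {
        nm <- names(.res_template)
        if (resnames[i] == "GLY") nm <- setdiff(nm, "CB")
        m <- do.call(rbind, xyz[nm])
        df <- data.frame(
          record = "ATOM", serial = serial + seq_along(nm), name = nm,
          altloc = "", resname = resnames[i], chain = "A", resnum = i,
          icode = "", x = m[, 1], y = m[, 2], z = m[, 3],
          occupancy = 1, element = substr(nm, 1, 1),
          stringsAsFactors = FALSE
        )
      }
      serial <- serial + nrow(df)
      rows[[i]] <- df
    }

    ## ligand at the origin region
    lig_el <- if (is.null(ligand$elements)) rep("C", 5) else ligand$elements
    n_lig <- length(lig_el)
    lig_xyz <- matrix(0, n_lig, 3)
    for (k in seq_len(n_lig)[-1]) {
      lig_xyz[k, ] <- lig_xyz[k - 1, ] + 1.5 * unitv(stats::rnorm(3))
    }
    lig_near <- if (is.null(ligand$near)) list() else ligand$near
    ## move planted residues to the requested minimum ligand distance
    dirs <- golden_spiral(max(1L, length(lig_near)))
    lig_ctr <- colMeans(lig_xyz)
    for (k in seq_along(lig_near)) {
      i <- lig_near[[k]]$residue
      dist <- lig_near[[k]]$distance
      if (moved[i]) stop("residue ", i, " is constrained by multiple plants")
      dir <- dirs[k, ]
      ## bisection on the radial scale so min(residue, ligand) == dist
      res_min_d <- function(s) {
        org <- lig_ctr + s * dir - .res_template$CB
        nm <- names(.res_template)
        if (resnames[i] == "GLY") nm <- setdiff(nm, "CB")
        xyz <- t(vapply(nm, function(a) .res_template[[a]] + org,
                        numeric(3)))
        min(sqrt(pmax(0, outer(rowSums(xyz^2), rowSums(lig_xyz^2), `+`) -
                        2 * xyz %*% t(lig_xyz))))
      }
      lo <- 0.5; hi <- dist + 30
      for (it in 1:60) {
        mid <- (lo + hi) / 2
        if (res_min_d(mid) < dist) lo <- mid else hi <- mid
      }
      if (abs(res_min_d(hi) - dist) > 0.05) {
        stop("infeasible ligand-proximity plant for residue ", i)
      }
      origin[i, ] <- lig_ctr + hi * dir - .res_template$CB
      moved[i] <- TRUE
      rows[[i]] <- template_residue(resnames[i], origin[i, ],
                                    rows[[i]]$serial[1] - 1L, i)
    }

    lig_rows <- data.frame(
      record = "HETATM", serial = serial + seq_len(n_lig),
      name = paste0(lig_el, seq_len(n_lig)), altloc = "",
      resname = "LIG", chain = "X", resnum = 1L, icode = "",
      x = lig_xyz[, 1], y = lig_xyz[, 2], z = lig_xyz[, 3],
      occupancy = 1, element = toupper(lig_el), stringsAsFactors = FALSE
    )
    atoms <- rbind(do.call(rbind, rows), lig_rows)
    if (noise_sigma > 0) {
      atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, noise_sigma)
      atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, noise_sigma)
      atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, noise_sigma)
    }
    ## PDB precision
    atoms$x <- round(atoms$x, 3)
    atoms$y <- round(atoms$y, 3)
    atoms$z <- round(atoms$z, 3)
    structure(list(atoms = atoms, source = "toy_complex"),
              class = "pdb_structure")
  })
}

#' Simulate contact distances from a two-component Gaussian mixture
#'
#' Emulates the bimodal distribution of pocket-stabilizing hydrophobic
#' contact distances (maxima near 7.7 and 8.3 Angstrom).
#'
#' @param n number of distances.
#' @param means component means, Angstrom.
#' @param sd common component standard deviation, Angstrom.
#' @param weights mixture weights (normalized internally).
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return numeric vector of length `n`.
#' @export
simulate_contact_distances <- function(n, means = c(7.7, 8.3), sd = 0.2,
                                       weights = c(0.5, 0.5), seed = NULL) {
  with_seed(seed, {
    weights <- weights / sum(weights)
    comp <- sample.int(length(means), n, replace = TRUE, prob = weights)
    stats::rnorm(n, mean = means[comp], sd = sd)
  })
}
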