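## ligand heavy-atom donor/acceptor typing from element + inferred bonds.
## N and O atoms are acceptors; those with a bonded heavy neighbor are also
## potential donors, except sp-hybridized nitrile nitrogens (single neighbor
## at a triple-bond distance < 1.25 A), which cannot carry a hydrogen and are
## typed acceptor-only.
ligand_da_typing <- function(atoms) {
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  n <- nrow(atoms)
  d <- as.matrix(stats::dist(xyz))
  polar <- which(toupper(atoms$element) %in% c("N", "O"))
  donors <- matrix(integer(0), 0, 2)
  acceptors <- integer(0)
  for (i in polar) {
    nb <- which(d[i, ] < 1.8 & seq_len(n) != i)
    acceptors <- c(acceptors, i)
    if (!length(nb)) next
    nitrile <- toupper(atoms$element[i]) == "N" && length(nb) == 1L &&
      d[i, nb] < 1.25
    if (!nitrile) {
      ante <- nb[which.min(d[i, nb])]
      donors <- rbind(donors, c(i, ante))
    }
  }
  list(donors = donors, acceptors = acceptors)
}

#' Protein-ligand hydrogen bonds
#'
#' Scans both directions (protein donor to ligand acceptor and ligand donor
#' to protein acceptor) with the same geometric criterion as
#' [detect_hbonds()]: heavy-atom donor-acceptor distance at most `d_max`
#' and antecedent-donor-acceptor angle at least `angle_min`. Ligand N/O
#' atoms are typed from element and inferred connectivity; nitrile
#' nitrogens are acceptor-only.
#'
#' @param pocket a `pocket_model`.
#' @param ligand a `ligand_molecule`.
#' @param d_max donor-acceptor distance cutoff, Angstrom.
#' @param angle_min minimum donor angle, degrees.
#' @return `hbond_set` data.frame with an added `direction` column
#'   (`"protein_donor"` or `"ligand_donor"`).
#' @export
ligand_hbonds <- function(pocket, ligand, d_max = 3.5, angle_min = 90) {
  patoms <- pocket$atoms[is_heavy(pocket$atoms$element), , drop = FALSE]
  latoms <- ligand$atoms[is_heavy(ligand$atoms$element), , drop = FALSE]
  typing <- ligand_da_typing(latoms)
  a <- geom_hbonds(patoms, protein_donors(patoms),
                   latoms, typing$acceptors,
                   d_max, angle_min, same_table = FALSE)
  b <- geom_hbonds(latoms, typing$donors,
                   patoms, protein_acceptors(patoms),
                   d_max, angle_min, same_table = FALSE)
  if (nrow(a)) a$direction <- "protein_donor"
  else a$direction <- character(0)
  if (nrow(b)) b$direction <- "ligand_donor"
  else b$direction <- character(0)
  out <- rbind(a, b)
  rownames(out) <- NULL
  class(out) <- c("hbond_set", "data.frame")
  out
}

## minimum heavy-atom distance from every pocket residue to the ligand
residue_ligand_distances <- function(pocket, ligand) {
  atoms <- pocket$atoms[is_heavy(pocket$atoms$element), , drop = FALSE]
  lig <- ligand$atoms[is_heavy(ligand$atoms$element), , drop = FALSE]
  lxyz <- cbind(lig$x, lig$y, lig$z)
  res <- pocket$residues
  key <- paste(atoms$resnum, atoms$icode)
  dmin <- vapply(seq_len(nrow(res)), function(k) {
    sub <- atoms[key == paste(res$resnum[k], res$icode[k]), , drop = FALSE]
    m <- cbind(sub$x, sub$y, sub$z)
    d2 <- outer(rowSums(m^2), rowSums(lxyz^2), `+`) - 2 * m %*% t(lxyz)
    sqrt(max(0, min(d2)))
  }, numeric(1))
  data.frame(resnum = res$resnum, icode = res$icode, resname = res$resname,
             distance = dmin, stringsAsFactors = FALSE)
}

#' Hydrophobic protein-ligand contacts
#'
#' For each nonpolar-classified pocket residue, the minimum heavy-atom
#' distance to any ligand heavy atom; the residue is a hydrophobic contact
#' iff that distance is below the cutoff (default 10 Angstrom — the "less
#' than 10 A" rule used for hydrophobic-bond counts in ligand interaction
#' tables).
#'
#' @inheritParams ligand_hbonds
#' @param cutoff distance cutoff, Angstrom (strict `<`).
#' @inheritParams classify_residue
#' @return data.frame `resnum`, `resname`, `distance`, sorted by distance.
#' @export
hydrophobic_contacts <- function(pocket, ligand, cutoff = 10,
                                 table = polarity_classes(), extra = NULL) {
  stopifnot(cutoff > 0)
  dd <- residue_ligand_distances(pocket, ligand)
  cls <- classify_residue(dd$resname, table, extra)
  out <- dd[cls == "nonpolar" & dd$distance < cutoff, , drop = FALSE]
  out <- out[order(out$distance, out$resnum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ligand interaction profile
#'
#' The per-complex interaction summary: hydrogen bonds, hydrophobic
#' contacts under the `< cutoff` rule, the minimum ligand distance of every
#' pocket residue, and the binding-locus residues (the `k_locus` residues
#' closest to the ligand, all polarity classes eligible).
#'
#' @inheritParams hydrophobic_contacts
#' @param d_max,angle_min hydrogen-bond criteria (see [ligand_hbonds()]).
#' @param k_locus number of binding-locus residues to rank.
#' @return object of class `ligand_profile`: list with `ligand` (hetcode),
#'   `hbonds`, `hydrophobic`, `all_distances`, `locus` (data.frame of the
#'   `k_locus` nearest residues), `n_hb`, `n_hydrophobic`, and the
#'   parameters used.
#' @export
ligand_profile <- function(pocket, ligand, d_max = 3.5, angle_min = 90,
                           cutoff = 10, k_locus = 4L,
                           table = polarity_classes(), extra = NULL) {
  hb <- ligand_hbonds(pocket, ligand, d_max, angle_min)
  hc <- hydrophobic_contacts(pocket, ligand, cutoff, table, extra)
  dd <- residue_ligand_distances(pocket, ligand)
  prof <- structure(
    list(ligand = ligand$hetcode, pocket_id = paste0(
           pocket$chain, ":", pocket$start, "-", pocket$end),
         hbonds = hb, hydrophobic = hc, all_distances = dd,
         locus = NULL, n_hb = nrow(hb), n_hydrophobic = nrow(hc),
         params = list(d_max = d_max, angle_min = angle_min,
                       cutoff = cutoff, k_locus = k_locus)),
    class = "ligand_profile"
  )
  prof$locus <- binding_locus(prof, k_locus)
  prof
}

#' Binding-locus residues
#'
#' The `k` pocket residues with the smallest minimum heavy-atom distance to
#' the ligand, over all polarity classes; ties broken by residue number.
#'
#' @param profile a `ligand_profile`.
#' @param k number of residues.
#' @return data.frame `resnum`, `resname`, `distance` (k rows).
#' @export
binding_locus <- function(profile, k = 4L) {
  dd <- profile$all_distances
  if (k > nrow(dd)) {
    warning("k = ", k, " exceeds pocket size ", nrow(dd),
            "; returning all residues")
    k <- nrow(dd)
  }
  ord <- order(dd$distance, dd$resnum)
  out <- dd[ord[seq_len(k)], c("resnum", "resname", "distance")]
  rownames(out) <- NULL
  out
}

#' Tabular interaction sweep
#'
#' One row per protein-ligand interaction: hydrogen bonds (with the atoms
#' involved) followed by hydrophobic contacts, each sorted by distance — a
#' structured stand-in for 2D interaction diagrams.
#'
#' @param profile a `ligand_profile`.
#' @return data.frame `type` (`"hbond"`/`"hydrophobic"`), `resnum`,
#'   `resname`, `protein_atom`, `ligand_atom`, `distance`.
#' @export
interaction_sweep <- function(profile) {
  hb <- profile$hbonds
  rows <- list()
  if (nrow(hb)) {
    prot_don <- hb$direction == "protein_donor"
    rows[[1]] <- data.frame(
      type = "hbond",
      resnum = ifelse(prot_don, hb$donor_resnum, hb$acceptor_resnum),
      resname = ifelse(prot_don, hb$donor_resname, hb$acceptor_resname),
      protein_atom = ifelse(prot_don, hb$donor_atom, hb$acceptor_atom),
      ligand_atom = ifelse(prot_don, hb$acceptor_atom, hb$donor_atom),
      distance = hb$distance, stringsAsFactors = FALSE
    )
  }
  hc <- profile$hydrophobic
  if (nrow(hc)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "hydrophobic", resnum = hc$resnum, resname = hc$resname,
      protein_atom = NA_character_, ligand_atom = NA_character_,
      distance = hc$distance, stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    type = character(0), resnum = integer(0), resname = character(0),
    protein_atom = character(0), ligand_atom = character(0),
    distance = numeric(0), stringsAsFactors = FALSE
  )
  out <- out[order(out$type, out$distance), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.ligand_profile <- function(x, ...) {
  cat("ligand_profile ", x$ligand, " in pocket ", x$pocket_id, ": ",
      x$n_hb, " H-bond(s), ", x$n_hydrophobic,
      " hydrophobic contact(s) (< ", x$params$cutoff, " A)\n",
      "locus: ", paste0(x$locus$resname, x$locus$resnum, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
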