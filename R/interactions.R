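#' Residue polarity classification table
#'
#' The default three-class table used for composition percentages and for
#' selecting the residues that can form hydrophobic (nonpolar) contacts.
#' Glycine counts as nonpolar, consistent with its role in hydrophobic
#' ligand contacts of kinase pockets; histidine is kept with the charged
#' class; arginine stays charged even though it often lines hydrophobic
#' loci through its aliphatic stem.
#'
#' @return named list with components `nonpolar`, `polar`, `charged`.
#' @export
polarity_classes <- function() {
  list(
    nonpolar = c("GLY", "ALA", "VAL", "LEU", "ILE", "PRO", "MET",
                 "PHE", "TRP"),
    polar = c("SER", "THR", "CYS", "ASN", "GLN", "TYR"),
    charged = c("ASP", "GLU", "LYS", "ARG", "HIS")
  )
}

#' Classify residues by polarity
#'
#' @param resname character vector of 3-letter residue codes.
#' @param table classification table as from [polarity_classes()].
#' @param extra optional named character vector mapping nonstandard residue
#'   codes to a class (e.g. `c(MSE = "nonpolar")`).
#' @return factor with levels `nonpolar`, `polar`, `charged`.
#' @export
classify_residue <- function(resname, table = polarity_classes(),
                             extra = NULL) {
  resname <- toupper(resname)
  cls <- rep(NA_character_, length(resname))
  for (k in names(table)) cls[resname %in% table[[k]]] <- k
  if (!is.null(extra)) {
    hit <- is.na(cls) & resname %in% names(extra)
    cls[hit] <- unname(extra[resname[hit]])
  }
  if (anyNA(cls)) {
    stop("unclassified residue(s): ",
         paste(unique(resname[is.na(cls)]), collapse = ", "),
         " (map them via 'extra')")
  }
  factor(cls, levels = c("nonpolar", "polar", "charged"))
}

#' Pocket residue composition by polarity class
#'
#' Counts and percentages of nonpolar / polar / charged residues over the
#' pocket. Percentages are reported raw; printed reports round to one
#' decimal, so the three classes may sum to slightly less than 100.
#'
#' @param pocket a `pocket_model`.
#' @inheritParams classify_residue
#' @return object of class `composition_stats`: list with `counts`,
#'   `percent` (named numeric vectors) and `n_residues`.
#' @export
composition <- function(pocket, table = polarity_classes(), extra = NULL) {
  stopifnot(nrow(pocket$residues) > 0)
  cls <- classify_residue(pocket$residues$resname, table, extra)
  counts <- table(cls)
  counts <- stats::setNames(as.integer(counts), names(counts))
  structure(
    list(counts = counts, percent = 100 * counts / sum(counts),
         n_residues = sum(counts)),
    class = "composition_stats"
  )
}

#' @export
print.composition_stats <- function(x, ...) {
  cat("composition over ", x$n_residues, " residues: ",
      paste(sprintf("%s %.1f%%", names(x$percent), x$percent),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

## donor atom -> antecedent atom, per residue chemistry (heavy atoms only)
.donor_map <- list(
  backbone = c(N = "CA"),
  ARG = c(NE = "CD", NH1 = "CZ", NH2 = "CZ"),
  LYS = c(NZ = "CE"),
  HIS = c(ND1 = "CG", NE2 = "CD2"),
  TRP = c(NE1 = "CD1"),
  ASN = c(ND2 = "CG"),
  GLN = c(NE2 = "CD"),
  SER = c(OG = "CB"),
  THR = c(OG1 = "CB"),
  TYR = c(OH = "CZ"),
  CYS = c(SG = "CB")
)
.acceptor_map <- list(
  backbone = c("O", "OXT"),
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  ASN = "OD1", GLN = "OE1",
  SER = "OG", THR = "OG1", TYR = "OH",
  HIS = c("ND1", "NE2")
)

## table of (atom row index, antecedent row index) donors within an atom df
protein_donors <- function(atoms) {
  out <- list()
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
  for (i in seq_len(nrow(atoms))) {
    rn <- atoms$resname[i]
    nm <- atoms$name[i]
    ante <- NULL
    if (nm == "N" && rn != "PRO") ante <- "CA"
    else if (!is.null(.donor_map[[rn]]) && nm %in% names(.donor_map[[rn]]))
      ante <- .donor_map[[rn]][[nm]]
    if (is.null(ante)) next
    j <- which(key == key[i] & atoms$name == ante)
    if (length(j)) out[[length(out) + 1L]] <- c(i, j[1])
  }
  if (!length(out)) return(matrix(integer(0), 0, 2))
  do.call(rbind, out)
}

protein_acceptors <- function(atoms) {
  acc <- atoms$name %in% .acceptor_map$backbone & atoms$record == "ATOM"
  for (rn in setdiff(names(.acceptor_map), "backbone")) {
    acc <- acc | (atoms$resname == rn & atoms$name %in% .acceptor_map[[rn]])
  }
  which(acc)
}

#' Detect intra-pocket hydrogen bonds
#'
#' Geometric criterion on heavy atoms: a donor-acceptor pair is a hydrogen
#' bond iff the donor-acceptor distance is at most `d_max` and the
#' antecedent-donor-acceptor angle is at least `angle_min`. Donors and
#' acceptors follow standard amino-acid chemistry (backbone N donor except
#' proline, backbone O acceptor, side-chain N/O/S per residue templates).
#' Backbone pairs of sequence neighbors (i, i+1) are excluded.
#'
#' @param pocket a `pocket_model`.
#' @param d_max donor-acceptor heavy-atom distance cutoff, Angstrom.
#' @param angle_min minimum antecedent-donor-acceptor angle, degrees.
#' @return data.frame of class `hbond_set`: one row per bond with donor and
#'   acceptor residue/atom identity, `distance` and `angle`.
#' @export
detect_hbonds <- function(pocket, d_max = 3.5, angle_min = 90) {
  atoms <- as_atoms(pocket)
  atoms <- atoms[is_heavy(atoms$element), , drop = FALSE]
  don <- protein_donors(atoms)
  acc <- protein_acceptors(atoms)
  geom_hbonds(atoms, don, atoms, acc, d_max, angle_min,
              exclude_backbone_neighbors = TRUE)
}

## core geometric H-bond scan: donors in table A, acceptors in table B
geom_hbonds <- function(atoms_d, donors, atoms_a, acceptors,
                        d_max, angle_min,
                        exclude_backbone_neighbors = FALSE,
                        same_table = TRUE) {
  empty <- data.frame(
    donor_chain = character(0), donor_resnum = integer(0),
    donor_resname = character(0), donor_atom = character(0),
    acceptor_chain = character(0), acceptor_resnum = integer(0),
    acceptor_resname = character(0), acceptor_atom = character(0),
    distance = numeric(0), angle = numeric(0), stringsAsFactors = FALSE
  )
  if (!nrow(donors) || !length(acceptors)) {
    class(empty) <- c("hbond_set", "data.frame"); return(empty)
  }
  xyz_d <- cbind(atoms_d$x, atoms_d$y, atoms_d$z)
  xyz_a <- cbind(atoms_a$x, atoms_a$y, atoms_a$z)
  rows <- list()
  for (k in seq_len(nrow(donors))) {
    i <- donors[k, 1]; ia <- donors[k, 2]
    dvec <- sweep(xyz_a[acceptors, , drop = FALSE], 2, xyz_d[i, ], `-`)
    dd <- sqrt(rowSums(dvec^2))
    cand <- which(dd <= d_max & dd > 0.6)
    for (m in cand) {
      j <- acceptors[m]
      if (same_table) {
        same_res <- atoms_d$chain[i] == atoms_a$chain[j] &&
          atoms_d$resnum[i] == atoms_a$resnum[j] &&
          atoms_d$icode[i] == atoms_a$icode[j]
        if (same_res) next
        if (exclude_backbone_neighbors &&
            atoms_d$name[i] == "N" && atoms_a$name[j] %in% c("O", "OXT") &&
            atoms_d$chain[i] == atoms_a$chain[j] &&
            abs(atoms_d$resnum[i] - atoms_a$resnum[j]) == 1L) next
      }
      ang <- angle_deg(xyz_d[ia, ], xyz_d[i, ], xyz_a[j, ])
      if (ang < angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        donor_chain = atoms_d$chain[i], donor_resnum = atoms_d$resnum[i],
        donor_resname = atoms_d$resname[i], donor_atom = atoms_d$name[i],
        acceptor_chain = atoms_a$chain[j],
        acceptor_resnum = atoms_a$resnum[j],
        acceptor_resname = atoms_a$resname[j],
        acceptor_atom = atoms_a$name[j],
        distance = dd[m], angle = ang, stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  out <- out[!duplicated(out[c("donor_chain", "donor_resnum", "donor_atom",
                               "acceptor_chain", "acceptor_resnum",
                               "acceptor_atom")]), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("hbond_set", "data.frame")
  out
}

## per-residue side-chain centroids (Gly and side-chain-less residues -> CA)
residue_centroids <- function(atoms, metric = c("centroid", "cb", "min")) {
  metric <- match.arg(metric)
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
  ukey <- unique(key)
  backbone <- c("N", "CA", "C", "O", "OXT")
  cen <- matrix(NA_real_, length(ukey), 3)
  for (k in seq_along(ukey)) {
    sel <- key == ukey[k]
    sub <- atoms[sel, , drop = FALSE]
    sc <- switch(metric,
      centroid = sub[!(sub$name %in% backbone), , drop = FALSE],
      cb = sub[sub$name == "CB", , drop = FALSE],
      min = sub
    )
    if (nrow(sc) == 0L) sc <- sub[sub$name == "CA", , drop = FALSE]
    if (nrow(sc) == 0L) sc <- sub
    cen[k, ] <- c(mean(sc$x), mean(sc$y), mean(sc$z))
  }
  list(key = ukey, xyz = cen)
}

#' Nonpolar residue-residue contact network
#'
#' Builds the hydrophobic contact set that stabilizes the pocket: every
#' unordered pair of nonpolar residues at sequence separation >= 2 whose
#' inter-residue distance falls below the cutoff. The default distance is
#' between side-chain heavy-atom centroids (glycine uses its C-alpha);
#' `"cb"` uses C-beta atoms and `"min"` the minimum heavy-atom distance.
#' Each contact is labeled `inside` when both residues belong to the same
#' secondary-structure element and `cross` otherwise (contacts involving
#' coil residues count as cross).
#'
#' @param pocket a `pocket_model`.
#' @param elements an `sse_elements` object ([group_elements()]); if `NULL`,
#'   it is derived from the pocket via [assign_sse()].
#' @param cutoff contact distance cutoff in Angstrom (default 10, strict
#'   `<`).
#' @param metric `"centroid"` (default), `"cb"` or `"min"`.
#' @inheritParams classify_residue
#' @return data.frame of class `contact_set`: `resnum_a`, `resname_a`,
#'   `resnum_b`, `resname_b`, `distance`, `kind` (`"cross"`/`"inside"`),
#'   `element_a`, `element_b`; attributes `cutoff` and `metric`.
#' @export
nonpolar_contact_network <- function(pocket, elements = NULL, cutoff = 10,
                                     metric = c("centroid", "cb", "min"),
                                     table = polarity_classes(),
                                     extra = NULL) {
  metric <- match.arg(metric)
  stopifnot(cutoff > 0)
  if (is.null(elements)) elements <- group_elements(assign_sse(pocket))
  res <- pocket$residues
  cls <- classify_residue(res$resname, table, extra)
  np <- which(cls == "nonpolar")
  ## element id per pocket residue (aligned with the annotation order)
  ekey <- paste(elements$annotation$resnum, elements$annotation$icode)
  eid <- elements$residue_element[
    match(paste(res$resnum, res$icode), ekey)]

  atoms <- pocket$atoms[is_heavy(pocket$atoms$element), , drop = FALSE]
  if (metric == "min") {
    key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
  } else {
    cen <- residue_centroids(atoms, metric)
    rkey <- paste(pocket$chain, res$resnum, res$icode, sep = "|")
    cxyz <- cen$xyz[match(rkey, cen$key), , drop = FALSE]
  }
  rows <- list()
  for (ii in seq_along(np)) {
    for (jj in seq_len(ii - 1L)) {
      a <- np[jj]; b <- np[ii]
      if (abs(res$resnum[a] - res$resnum[b]) < 2L) next
      if (metric == "min") {
        ka <- paste(pocket$chain, res$resnum[a], res$icode[a], sep = "|")
        kb <- paste(pocket$chain, res$resnum[b], res$icode[b], sep = "|")
        xa <- atoms[key == ka, c("x", "y", "z"), drop = FALSE]
        xb <- atoms[key == kb, c("x", "y", "z"), drop = FALSE]
        ma <- as.matrix(xa); mb <- as.matrix(xb)
        d2 <- outer(rowSums(ma^2), rowSums(mb^2), `+`) - 2 * ma %*% t(mb)
        d <- sqrt(max(0, min(d2)))
      } else {
        d <- vnorm(cxyz[a, ] - cxyz[b, ])
      }
      if (!is.finite(d) || d >= cutoff) next
      ea <- eid[a]; eb <- eid[b]
      kind <- if (!is.na(ea) && !is.na(eb) && ea == eb) "inside" else "cross"
      rows[[length(rows) + 1L]] <- data.frame(
        resnum_a = res$resnum[a], resname_a = res$resname[a],
        resnum_b = res$resnum[b], resname_b = res$resname[b],
        distance = d, kind = kind,
        element_a = ifelse(is.na(ea), NA_integer_, ea),
        element_b = ifelse(is.na(eb), NA_integer_, eb),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    resnum_a = integer(0), resname_a = character(0),
    resnum_b = integer(0), resname_b = character(0),
    distance = numeric(0), kind = character(0),
    element_a = integer(0), element_b = integer(0),
    stringsAsFactors = FALSE
  )
  ## canonical order: a < b by residue number
  swap <- out$resnum_a > out$resnum_b
  if (any(swap)) {
    tmp <- out[swap, c("resnum_a", "resname_a", "element_a")]
    out[swap, c("resnum_a", "resname_a", "element_a")] <-
      out[swap, c("resnum_b", "resname_b", "element_b")]
    out[swap, c("resnum_b", "resname_b", "element_b")] <- tmp
  }
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "metric") <- metric
  class(out) <- c("contact_set", "data.frame")
  out
}

#' Distance statistics and modes of a contact class
#'
#' Mean and population standard deviation of contact distances, plus a
#' fixed-width histogram and its local maxima after light smoothing — the
#' bimodality report for pocket-stabilizing hydrophobic contacts.
#'
#' @param contacts a `contact_set`, or a bare numeric vector of distances.
#' @param kind `"cross"`, `"inside"` or `"all"` (ignored for numeric input).
#' @param bin_width histogram bin width in Angstrom.
#' @param smooth moving-average window (bins) applied before the mode scan.
#' @return object of class `distance_stats`: list with `n`, `mean`, `sd`
#'   (population), `histogram` (data.frame `center`, `count`, `smoothed`)
#'   and `modes` (bin centers of local maxima). `mean`/`sd` are `NA` when
#'   `n = 0`.
#' @export
contact_statistics <- function(contacts, kind = c("cross", "inside", "all"),
                               bin_width = 0.25, smooth = 3L) {
  kind <- match.arg(kind)
  if (is.numeric(contacts)) {
    d <- contacts
  } else {
    d <- contacts$distance
    if (kind != "all") d <- d[contacts$kind == kind]
  }
  n <- length(d)
  if (n == 0L) {
    return(structure(list(n = 0L, mean = NA_real_, sd = NA_real_,
                          histogram = NULL, modes = numeric(0)),
                     class = "distance_stats"))
  }
  m <- mean(d)
  s <- sqrt(mean((d - m)^2))             # population SD
  hi <- distance_histogram(d, bin_width, smooth)
  structure(
    list(n = n, mean = m, sd = s, histogram = hi,
         modes = distance_modes(d, bin_width, smooth)),
    class = "distance_stats"
  )
}

distance_histogram <- function(d, bin_width = 0.25, smooth = 3L) {
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width + 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  counts <- h$counts
  ## moving average with zero padding so edges stay defined
  pad <- (smooth - 1L) %/% 2L
  padded <- c(rep(0, pad), counts, rep(0, pad))
  sm <- stats::filter(padded, rep(1 / smooth, smooth), sides = 2)
  sm <- as.numeric(sm)[(pad + 1L):(pad + length(counts))]
  data.frame(center = h$mids, count = counts, smoothed = sm)
}

#' Modes of a distance distribution
#'
#' Histogram-based mode detection at bin width `bin_width` with
#' `smooth`-fold shift averaging: the histogram is recomputed on a fine
#' grid of width `bin_width / smooth` and smoothed with the equivalent
#' triangular weights (the averaged-shifted-histogram estimate, which
#' smooths at the stated bin width without the peak-merging bias of a
#' plain moving average over coarse bins). Modes are the local maxima of
#' that curve; maxima within one bin width of a taller one are merged into
#' it, so apex jitter never splits a peak.
#'
#' @param d numeric vector of distances (Angstrom).
#' @param bin_width histogram bin width (Angstrom); also the merge radius.
#' @param smooth smoothing factor (number of averaged shifts).
#' @return numeric vector of mode centers, increasing.
#' @export
distance_modes <- function(d, bin_width = 0.25, smooth = 3L) {
  stopifnot(length(d) >= 1, bin_width > 0, smooth >= 1)
  m <- as.integer(smooth)
  delta <- bin_width / m
  lo <- floor(min(d) / bin_width) * bin_width
  hi <- ceiling(max(d) / bin_width + 1e-9) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo - bin_width, hi + bin_width, by = delta)
  nu <- graphics::hist(d, breaks = breaks, plot = FALSE, right = FALSE)
  counts <- nu$counts
  centers <- nu$mids
  ## triangular weights over the +/- (m-1) neighboring fine bins
  w <- 1 - abs(seq(-(m - 1), m - 1)) / m
  pad <- m - 1L
  padded <- c(rep(0, pad), counts, rep(0, pad))
  s <- vapply(seq_along(counts), function(k) {
    sum(w * padded[k:(k + 2L * pad)])
  }, numeric(1))
  left <- c(-Inf, s[-length(s)])
  right <- c(s[-1], -Inf)
  cand <- which(s > left & s >= right)
  if (!length(cand)) return(numeric(0))
  ## a mode other than the global maximum needs the support of at least
  ## two observations, so isolated tail points never register
  cand <- cand[s[cand] >= 2 | s[cand] == max(s)]
  ## merge candidates within one bin width of a taller candidate
  ord <- cand[order(-s[cand], cand)]
  keep <- integer(0)
  for (i in ord) {
    if (!length(keep) ||
        all(abs(centers[keep] - centers[i]) > bin_width + 1e-9)) {
      keep <- c(keep, i)
    }
  }
  sort(centers[keep])
}

#' @export
print.distance_stats <- function(x, ...) {
  if (x$n == 0L) {
    cat("distance_stats: no contacts\n")
  } else {
    cat(sprintf("distance_stats: n = %d, %.2f +/- %.2f A; modes at %s\n",
                x$n, x$mean, x$sd,
                paste(sprintf("%.3f", x$modes), collapse = ", ")))
  }
  invisible(x)
}

#' Export contacts or hydrogen bonds as TSV
#'
#' @param x a `contact_set` or `hbond_set`.
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_tsv <- function(x, file) {
  utils::write.table(as.data.frame(x), file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}
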