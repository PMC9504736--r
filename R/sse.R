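#' Assign three-state secondary structure
#'
#' Kabsch-Sander-style assignment collapsed to three states: backbone
#' hydrogen bonds are detected by the electrostatic criterion
#' \deqn{E = 0.084 \cdot 332 \,(1/d_{ON} + 1/d_{CH} - 1/d_{OH} - 1/d_{CN})}
#' (kcal/mol, distances in Angstrom) with a bond wherever `E < energy_cutoff`
#' (default -0.5). The amide hydrogen, absent from X-ray inputs, is
#' reconstructed on each nitrogen 1.01 Angstrom along the direction opposite
#' the preceding residue's C=O bond. Runs of i -> i+4 bonds become helix (H),
#' parallel/antiparallel ladder patterns become strand (E), everything else
#' coil (C). Residues lacking a complete N/CA/C/O backbone, prolines as
#' donors, and residues after a chain break (peptide C-N distance > 2.5
#' Angstrom) are handled conservatively.
#'
#' @param pocket a `pocket_model` (or `pdb_structure`, whose polymer atoms
#'   are then used).
#' @param energy_cutoff hydrogen-bond energy threshold in kcal/mol.
#' @return an object of class `sse_annotation`: data.frame with `chain`,
#'   `resnum`, `icode`, `resname`, `state` (one of `"H"`, `"E"`, `"C"`).
#' @examples
#' helix <- ideal_helix(20)
#' ann <- assign_sse(select_pocket(helix, "A", 1, 20))
#' table(ann$state)
#' @export
assign_sse <- function(pocket, energy_cutoff = -0.5) {
  atoms <- as_atoms(pocket)
  atoms <- atoms[atoms$record == "ATOM" & is_heavy(atoms$element), ,
                 drop = FALSE]
  key <- paste(atoms$chain, atoms$resnum, atoms$icode, sep = "|")
  ukey <- unique(key)
  n <- length(ukey)
  first <- match(ukey, key)
  ann <- data.frame(
    chain = atoms$chain[first],
    resnum = atoms$resnum[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    state = rep("C", n),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("sse_annotation", "data.frame")
  if (n < 5L) return(ann)

  ## backbone coordinate matrices, NA rows where an atom is missing
  bb <- function(name) {
    m <- matrix(NA_real_, n, 3)
    sel <- atoms$name == name
    idx <- match(ukey, key[sel])
    hit <- !is.na(idx)
    rows <- which(sel)[idx[hit]]
    m[hit, ] <- cbind(atoms$x[rows], atoms$y[rows], atoms$z[rows])
    m
  }
  N <- bb("N"); CA <- bb("CA"); C <- bb("C"); O <- bb("O")
  complete <- stats::complete.cases(cbind(N, CA, C, O))

  ## chain continuity: peptide bond C(i-1)-N(i) must exist and be short
  contig <- rep(FALSE, n)
  for (i in 2:n) {
    contig[i] <- ann$chain[i] == ann$chain[i - 1] &&
      complete[i] && complete[i - 1] &&
      vnorm(N[i, ] - C[i - 1, ]) < 2.5
  }

  ## reconstructed amide hydrogen (none for chain starts and prolines)
  H <- matrix(NA_real_, n, 3)
  for (i in 2:n) {
    if (contig[i] && ann$resname[i] != "PRO") {
      d <- C[i - 1, ] - O[i - 1, ]
      H[i, ] <- N[i, ] + 1.01 * d / vnorm(d)
    }
  }

  ## B[d, a]: N-H of residue d donates to C=O of residue a
  q <- 0.084 * 332
  B <- matrix(FALSE, n, n)
  for (d in 1:n) {
    if (any(is.na(H[d, ]))) next
    for (a in 1:n) {
      if (abs(d - a) < 2L || !complete[a]) next
      if (vnorm(CA[d, ] - CA[a, ]) > 9) next
      don <- vnorm(O[a, ] - N[d, ])
      dch <- vnorm(C[a, ] - H[d, ])
      doh <- vnorm(O[a, ] - H[d, ])
      dcn <- vnorm(C[a, ] - N[d, ])
      if (min(don, dch, doh, dcn) < 0.5) next
      e <- q * (1 / don + 1 / dch - 1 / doh - 1 / dcn)
      if (e < energy_cutoff) B[d, a] <- TRUE
    }
  }

  ## 4-turns: C=O(i) accepts from N-H(i+4)
  turn4 <- rep(FALSE, n)
  for (i in 1:(n - 4)) turn4[i] <- B[i + 4, i]
  state <- rep("C", n)
  for (i in 2:(n - 3)) {
    if (turn4[i - 1] && turn4[i]) state[i:(i + 3)] <- "H"
  }

  ## bridges (residues i, j with |i-j| > 2)
  hb <- function(acc, don) {                       # Hbond(acc, don) in DSSP terms
    acc >= 1 && don >= 1 && acc <= n && don <= n && B[don, acc]
  }
  for (i in 2:(n - 1)) {
    if (i + 3 > n) break
    for (j in (i + 3):n) {
      para <- (hb(i - 1, j) && hb(j, i + 1)) ||
        (hb(j - 1, i) && hb(i, j + 1))
      anti <- (hb(i, j) && hb(j, i)) ||
        (hb(i - 1, j + 1) && hb(j - 1, i + 1))
      if (para || anti) {
        if (state[i] != "H") state[i] <- "E"
        if (state[j] != "H") state[j] <- "E"
      }
    }
  }
  ann$state <- state
  ann
}

#' Group an annotation into secondary-structure elements
#'
#' Maximal runs of helix (H) and strand (E) states become numbered elements;
#' runs shorter than the minimum lengths are relabeled coil. The returned
#' object carries both the element table and the per-residue element id used
#' to split nonpolar contacts into cross-element vs inside-element classes.
#'
#' @param annotation an `sse_annotation` (from [assign_sse()] or
#'   [load_external_sse()]).
#' @param min_len_H minimum helix run length (default 4).
#' @param min_len_E minimum strand run length (default 2).
#' @return an object of class `sse_elements`: list with `elements`
#'   (data.frame `element_id`, `state`, `start`, `end`, `length` in author
#'   numbering) and `residue_element` (integer vector along the annotation,
#'   `NA` for coil).
#' @export
group_elements <- function(annotation, min_len_H = 4L, min_len_E = 2L) {
  st <- annotation$state
  r <- rle(st)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- (r$values == "H" & r$lengths >= min_len_H) |
    (r$values == "E" & r$lengths >= min_len_E)
  residue_element <- rep(NA_integer_, length(st))
  el <- list()
  id <- 0L
  for (k in which(keep)) {
    id <- id + 1L
    idx <- starts[k]:ends[k]
    residue_element[idx] <- id
    el[[id]] <- data.frame(
      element_id = id, state = r$values[k],
      start = annotation$resnum[starts[k]],
      end = annotation$resnum[ends[k]],
      length = r$lengths[k], stringsAsFactors = FALSE
    )
  }
  elements <- if (id > 0L) do.call(rbind, el) else
    data.frame(element_id = integer(0), state = character(0),
               start = integer(0), end = integer(0), length = integer(0))
  structure(
    list(elements = elements, residue_element = residue_element,
         annotation = annotation,
         min_len_H = min_len_H, min_len_E = min_len_E),
    class = "sse_elements"
  )
}

#' @export
print.sse_elements <- function(x, ...) {
  e <- x$elements
  cat("sse_elements: ", sum(e$state == "H"), " helices, ",
      sum(e$state == "E"), " strands\n", sep = "")
  if (nrow(e)) print.data.frame(e, row.names = FALSE)
  invisible(x)
}

#' Load an external secondary-structure assignment
#'
#' Reads DSSP (columnar) or STRIDE (`ASG` records) output and maps the
#' states to three classes (G, I, H -> H; B, E -> E; everything else -> C),
#' so that assignments from the original tools can override the internal
#' Kabsch-Sander assignment downstream. Residue numbers must be the author
#' numbering used by the structure.
#'
#' @param file path to a DSSP or STRIDE output file.
#' @param format `"auto"` (detect), `"dssp"` or `"stride"`.
#' @return an `sse_annotation` data.frame (`chain`, `resnum`, `icode`,
#'   `resname`, `state`).
#' @export
load_external_sse <- function(file, format = c("auto", "dssp", "stride")) {
  format <- match.arg(format)
  lines <- readLines(file, warn = FALSE)
  if (!length(lines) || all(!nzchar(trimws(lines)))) {
    stop("empty secondary-structure file: ", file)
  }
  if (format == "auto") {
    format <- if (any(startsWith(lines, "ASG "))) "stride" else "dssp"
  }
  map3 <- function(code) {
    code <- toupper(code)
    out <- rep("C", length(code))
    out[code %in% c("G", "I", "H")] <- "H"
    out[code %in% c("B", "E")] <- "E"
    out
  }
  if (format == "stride") {
    asg <- lines[startsWith(lines, "ASG ")]
    if (!length(asg)) stop("no ASG records in STRIDE file: ", file)
    parts <- strsplit(trimws(asg), "[[:space:]]+")
    resname <- vapply(parts, `[`, "", 2)
    chain <- vapply(parts, `[`, "", 3)
    resstr <- vapply(parts, `[`, "", 4)
    code <- vapply(parts, `[`, "", 6)
    resnum <- as.integer(gsub("[^-0-9]", "", resstr))
    icode <- gsub("[-0-9]", "", resstr)
  } else {
    hdr <- grep("^  #  RESIDUE", lines)
    if (!length(hdr)) stop("no residue table header in DSSP file: ", file)
    body <- lines[(hdr[1] + 1):length(lines)]
    body <- body[nchar(body) >= 17]
    resstr <- trimws(substr(body, 6, 10))
    keep <- resstr != ""                       # skip chain-break '!' rows
    body <- body[keep]; resstr <- resstr[keep]
    if (!length(body)) stop("no residues in DSSP file: ", file)
    chain <- trimws(substr(body, 12, 12))
    aa1 <- trimws(substr(body, 14, 14))
    code <- substr(body, 17, 17)
    resnum <- as.integer(gsub("[^-0-9]", "", resstr))
    icode <- substr(body, 11, 11)
    icode[icode == " "] <- ""
    resname <- names(.aa_321)[match(toupper(aa1), .aa_321)]
    resname[is.na(resname)] <- "UNK"
  }
  ann <- data.frame(
    chain = chain, resnum = resnum, icode = icode,
    resname = resname, state = map3(code), stringsAsFactors = FALSE
  )
  class(ann) <- c("sse_annotation", "data.frame")
  ann
}

#' Match an external annotation onto a pocket
#'
#' Restricts an annotation (typically from [load_external_sse()]) to the
#' pocket's residues, warning about residues the annotation does not cover
#' (these become coil).
#'
#' @param pocket a `pocket_model`.
#' @param annotation an `sse_annotation`.
#' @return an `sse_annotation` covering exactly the pocket residues.
#' @export
match_annotation <- function(pocket, annotation) {
  key_p <- paste(pocket$chain, pocket$residues$resnum,
                 pocket$residues$icode, sep = "|")
  key_a <- paste(annotation$chain, annotation$resnum, annotation$icode,
                 sep = "|")
  idx <- match(key_p, key_a)
  if (anyNA(idx)) {
    warning("no external state for residue(s): ",
            paste(pocket$residues$resnum[is.na(idx)], collapse = ", "),
            "; set to C")
  }
  ann <- data.frame(
    chain = pocket$chain,
    resnum = pocket$residues$resnum,
    icode = pocket$residues$icode,
    resname = pocket$residues$resname,
    state = ifelse(is.na(idx), "C", annotation$state[idx]),
    stringsAsFactors = FALSE
  )
  class(ann) <- c("sse_annotation", "data.frame")
  ann
}
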