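#' Read a PDB-format structure
#'
#' Parses fixed-column ATOM/HETATM records into a `pdb_structure`: a single
#' atom table holding polymer residues (ATOM) and hetero groups (HETATM) in
#' file order. Parsing is delegated to [bio3d::read.pdb()]; on top of it this
#' reader validates record syntax (naming the offending line on failure),
#' resolves alternate locations by keeping the highest-occupancy conformer
#' (ties broken by the alphabetically first altloc), and infers element
#' symbols from atom names when columns 77-78 are blank. Only the first MODEL
#' of a multi-model file is used.
#'
#' @param file path to a PDB file. Ignored when `text` is given.
#' @param text optional character vector of PDB lines (parsed instead of
#'   `file`).
#' @param keep_altloc if `TRUE`, all alternate-location conformers are kept.
#' @return an object of class `pdb_structure`: a list with `atoms` (a
#'   data.frame with columns `record`, `serial`, `name`, `altloc`, `resname`,
#'   `chain`, `resnum`, `icode`, `x`, `y`, `z`, `occupancy`, `element`) and
#'   `source` (the file name or `"text"`).
#' @examples
#' helix <- ideal_helix(12)
#' f <- tempfile(fileext = ".pdb")
#' write_pdb(helix, f)
#' m <- read_pdb(f)
#' nrow(m$atoms)
#' @export
read_pdb <- function(file, text = NULL, keep_altloc = FALSE) {
  if (!is.null(text)) {
    file <- tempfile(fileext = ".pdb")
    on.exit(unlink(file))
    writeLines(text, file)
    src <- "text"
  } else {
    if (!file.exists(file)) stop("PDB file not found: ", file)
    src <- basename(file)
  }
  lines <- readLines(file, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("no ATOM or HETATM records found in ", src)
  ## validate coordinate fields before handing off to the parser
  bad <- which(is_atom & (nchar(lines) < 54 |
    is.na(suppressWarnings(as.numeric(substr(lines, 31, 38)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 39, 46)))) |
    is.na(suppressWarnings(as.numeric(substr(lines, 47, 54))))))
  if (length(bad)) {
    stop("malformed ATOM/HETATM record at line ", bad[1], ": ",
         substr(lines[bad[1]], 1, 30), "...")
  }
  pdb <- bio3d::read.pdb(file, multi = FALSE, rm.alt = FALSE,
                         rm.insert = FALSE, verbose = FALSE)
  a <- pdb$atom
  atoms <- data.frame(
    record = ifelse(a$type == "ATOM", "ATOM", "HETATM"),
    serial = as.integer(a$eleno),
    name = trimws(a$elety),
    altloc = ifelse(is.na(a$alt) | a$alt == "", "", a$alt),
    resname = trimws(a$resid),
    chain = ifelse(is.na(a$chain) | a$chain == "", "A", a$chain),
    resnum = as.integer(a$resno),
    icode = ifelse(is.na(a$insert) | a$insert == "", "", a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    stringsAsFactors = FALSE
  )
  elem <- trimws(a$elesy)
  need <- is.na(elem) | elem == ""
  if (any(need)) {
    elem[need] <- infer_element(atoms$name[need], atoms$record[need])
  }
  atoms$element <- toupper(elem)
  atoms$occupancy <- pmin(pmax(atoms$occupancy, 0), 1)
  if (!keep_altloc) atoms <- resolve_altloc(atoms)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates in ", src)
  }
  structure(list(atoms = atoms, source = src), class = "pdb_structure")
}

## keep one conformer per atom: highest occupancy, ties -> first altloc
resolve_altloc <- function(atoms) {
  key <- paste(atoms$record, atoms$chain, atoms$resnum, atoms$icode,
               atoms$resname, atoms$name, sep = "|")
  if (!anyDuplicated(key)) return(atoms)
  ord <- order(key, -atoms$occupancy, atoms$altloc)
  keep <- !duplicated(key[ord])
  idx <- sort(ord[keep])
  atoms[idx, , drop = FALSE]
}

#' @export
print.pdb_structure <- function(x, ...) {
  a <- x$atoms
  pol <- a[a$record == "ATOM", ]
  het <- a[a$record == "HETATM", ]
  nres <- length(unique(res_id(pol$chain, pol$resnum, pol$icode)))
  cat("pdb_structure '", x$source, "': ",
      length(unique(pol$chain)), " chain(s), ",
      nres, " polymer residues, ",
      nrow(het), " hetero atoms (",
      paste(unique(het$resname), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-column ATOM/HETATM records (plus TER/END) so that generated
#' fixtures round-trip through [read_pdb()] at the format's 3-decimal
#' coordinate precision.
#'
#' @param x a `pdb_structure`, `pocket_model`, `ligand_molecule`, or a bare
#'   atom data.frame in the layout produced by [read_pdb()].
#' @param file output path.
#' @return the path, invisibly.
#' @export
write_pdb <- function(x, file) {
  atoms <- as_atoms(x)
  fmt_name <- function(name, element) {
    ifelse(nchar(name) >= 4L | nchar(element) > 1L,
           sprintf("%-4s", name), sprintf(" %-3s", name))
  }
  lines <- sprintf(
    "%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    atoms$record, atoms$serial %% 100000L,
    fmt_name(atoms$name, atoms$element), atoms$altloc,
    atoms$resname, atoms$chain, atoms$resnum, atoms$icode,
    atoms$x, atoms$y, atoms$z, atoms$occupancy, 0,
    substr(atoms$element, 1, 2)
  )
  ## TER after each polymer chain
  out <- character(0)
  pol <- atoms$record == "ATOM"
  if (any(pol)) {
    for (ch in unique(atoms$chain[pol])) {
      sel <- pol & atoms$chain == ch
      out <- c(out, lines[sel], "TER")
    }
  }
  out <- c(out, lines[!pol], "END")
  writeLines(out, file)
  invisible(file)
}

## coerce the package's structure-bearing objects to a plain atom table
as_atoms <- function(x) {
  if (is.data.frame(x)) return(x)
  if (inherits(x, "pdb_structure")) return(x$atoms)
  if (inherits(x, "pocket_model")) return(x$atoms)
  if (inherits(x, "ligand_molecule")) return(x$atoms)
  stop("cannot extract atoms from an object of class ",
       paste(class(x), collapse = "/"))
}

#' Remove solvent and buffer components
#'
#' Drops hetero groups whose chemical component code is in `remove`
#' (water plus common crystallization buffer/cryo components by default).
#' Polymer atoms are never touched; removing an absent code is a no-op, and
#' the operation is idempotent.
#'
#' @param model a `pdb_structure`.
#' @param remove character vector of hetero codes to remove.
#' @return the filtered `pdb_structure`.
#' @export
strip_non_structural <- function(model, remove = solvent_buffer_codes()) {
  stopifnot(inherits(model, "pdb_structure"))
  a <- model$atoms
  drop <- a$record == "HETATM" & a$resname %in% remove
  model$atoms <- a[!drop, , drop = FALSE]
  model
}

#' Default solvent/buffer hetero codes
#'
#' Water models plus buffer, cryoprotectant and ion components commonly
#' deposited alongside crystal structures.
#' @return character vector of PDB chemical component codes.
#' @export
solvent_buffer_codes <- function() {
  c("HOH", "DOD", "SO4", "PO4", "GOL", "EDO", "PEG", "PG4", "ACT",
    "DMS", "MPD", "FMT", "CIT", "TRS", "MES", "EPE", "NO3",
    "CL", "NA", "K", "MG", "BR", "IOD")
}

#' Select a binding-pocket residue range
#'
#' Extracts the contiguous author-numbered residue range `[start, end]` from
#' one polymer chain — the operational definition of the binding "grotto"
#' (e.g. the JH1 kinase-domain fragments 865-1154 of JAK1 and 842-1130 of
#' JAK2). Author numbers absent from the deposited coordinates are recorded
#' in `missing`.
#'
#' @param model a `pdb_structure`.
#' @param chain chain identifier; `NULL` selects the first polymer chain in
#'   file order.
#' @param start,end first and last author residue numbers (inclusive).
#' @return an object of class `pocket_model`: list with `atoms`, `residues`
#'   (one row per residue: `resnum`, `icode`, `resname`), `chain`, `start`,
#'   `end`, `missing` (absent residue numbers) and `source`.
#' @export
select_pocket <- function(model, chain = NULL, start, end) {
  stopifnot(inherits(model, "pdb_structure"), start <= end)
  a <- model$atoms[model$atoms$record == "ATOM", , drop = FALSE]
  if (nrow(a) == 0L) stop("structure has no polymer atoms")
  if (is.null(chain)) chain <- a$chain[1]
  if (!chain %in% a$chain) {
    stop("unknown chain '", chain, "'; available: ",
         paste(unique(a$chain), collapse = ", "))
  }
  sel <- a$chain == chain & a$resnum >= start & a$resnum <= end
  if (!any(sel)) {
    stop("no residues of chain ", chain, " in range ", start, "-", end)
  }
  atoms <- a[sel, , drop = FALSE]
  key <- paste(atoms$resnum, atoms$icode, sep = "|")
  first <- !duplicated(key)
  residues <- data.frame(
    resnum = atoms$resnum[first],
    icode = atoms$icode[first],
    resname = atoms$resname[first],
    stringsAsFactors = FALSE
  )
  missing <- setdiff(seq.int(start, end), residues$resnum)
  structure(
    list(atoms = atoms, residues = residues, chain = chain,
         start = start, end = end, missing = missing,
         source = model$source),
    class = "pocket_model"
  )
}

#' @export
print.pocket_model <- function(x, ...) {
  cat("pocket_model: chain ", x$chain, " ", x$start, "-", x$end, " (",
      nrow(x$residues), " residues, ", length(x$missing), " missing); ",
      x$residues$resname[1], x$residues$resnum[1], " ... ",
      x$residues$resname[nrow(x$residues)],
      x$residues$resnum[nrow(x$residues)], "\n", sep = "")
  invisible(x)
}

#' Extract a ligand from a structure
#'
#' Pulls the heavy atoms of one hetero component (e.g. a bound inhibitor)
#' out of a parsed complex. When several copies of the component are
#' deposited, the first in file order is taken unless `copy` selects another.
#'
#' @param model a `pdb_structure`.
#' @param hetcode 3-letter chemical component code.
#' @param copy integer index among the copies present (file order).
#' @return an object of class `ligand_molecule`: list with `hetcode`,
#'   `atoms` (heavy atoms only), `chain`, `resnum` and `name`.
#' @export
extract_ligand <- function(model, hetcode, copy = 1L) {
  stopifnot(inherits(model, "pdb_structure"))
  het <- model$atoms[model$atoms$record == "HETATM", , drop = FALSE]
  avail <- unique(het$resname)
  if (!hetcode %in% avail) {
    stop("hetero component '", hetcode, "' not present; available: ",
         if (length(avail)) paste(avail, collapse = ", ") else "(none)")
  }
  sel <- het[het$resname == hetcode, , drop = FALSE]
  copies <- unique(paste(sel$chain, sel$resnum, sel$icode, sep = "|"))
  if (copy > length(copies)) {
    stop("requested copy ", copy, " of ", hetcode, " but only ",
         length(copies), " present")
  }
  kc <- strsplit(copies[copy], "|", fixed = TRUE)[[1]]
  kc <- c(kc, rep("", 3 - length(kc)))
  atoms <- sel[sel$chain == kc[1] & sel$resnum == as.integer(kc[2]) &
                 sel$icode == kc[3], , drop = FALSE]
  atoms <- atoms[is_heavy(atoms$element), , drop = FALSE]
  if (nrow(atoms) == 0L) stop("ligand ", hetcode, " has no heavy atoms")
  structure(
    list(hetcode = hetcode, atoms = atoms, chain = kc[1],
         resnum = as.integer(kc[2]), name = hetcode),
    class = "ligand_molecule"
  )
}

#' @export
print.ligand_molecule <- function(x, ...) {
  cat("ligand_molecule ", x$hetcode, ": ", nrow(x$atoms),
      " heavy atoms (", round(ligand_mass(x), 1), " Da from atoms present)\n",
      sep = "")
  invisible(x)
}

#' Molecular mass from the atoms present
#'
#' Sums average atomic masses over the atoms in the record. Crystallographic
#' ligands usually lack hydrogens, in which case this is the heavy-atom mass,
#' not the full molecular weight.
#'
#' @param ligand a `ligand_molecule` (or any atom-bearing object).
#' @return mass in Da.
#' @export
ligand_mass <- function(ligand) {
  el <- toupper(as_atoms(ligand)$element)
  unknown <- setdiff(el, names(.atomic_mass))
  if (length(unknown)) stop("no atomic mass for element(s): ",
                            paste(unknown, collapse = ", "))
  sum(.atomic_mass[el])
}
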