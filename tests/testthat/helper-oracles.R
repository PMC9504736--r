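# independent oracles and small fixture utilities used across tests

## random rigid-body transform applied to an atom table
rigid_transform <- function(atoms, seed = 1) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), -sin(th[1]),
                 0, sin(th[1]), cos(th[1])), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cos(th[2]), 0, sin(th[2]), 0, 1, 0,
                 -sin(th[2]), 0, cos(th[2])), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cos(th[3]), -sin(th[3]), 0, sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3, byrow = TRUE)
  R <- Rx %*% Ry %*% Rz
  t0 <- runif(3, -30, 30)
  xyz <- t(R %*% t(cbind(atoms$x, atoms$y, atoms$z))) +
    matrix(t0, nrow(atoms), 3, byrow = TRUE)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  atoms
}

transform_structure <- function(model, seed = 1) {
  model$atoms <- rigid_transform(model$atoms, seed)
  model
}

## brute-force O(n^2) nonpolar contact enumeration, independent of the
## package's centroid/neighbor machinery
oracle_contacts <- function(pocket, cutoff, nonpolar) {
  atoms <- pocket$atoms[!(toupper(pocket$atoms$element) %in% c("H", "D")), ]
  res <- pocket$residues
  backbone <- c("N", "CA", "C", "O", "OXT")
  cent <- lapply(seq_len(nrow(res)), function(k) {
    sub <- atoms[atoms$resnum == res$resnum[k] &
                   atoms$icode == res$icode[k], ]
    sc <- sub[!(sub$name %in% backbone), ]
    if (nrow(sc) == 0) sc <- sub[sub$name == "CA", ]
    c(mean(sc$x), mean(sc$y), mean(sc$z))
  })
  out <- list()
  for (i in seq_len(nrow(res))) {
    for (j in seq_len(nrow(res))) {
      if (j <= i) next
      if (!(res$resname[i] %in% nonpolar) ||
          !(res$resname[j] %in% nonpolar)) next
      if (abs(res$resnum[i] - res$resnum[j]) < 2) next
      d <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      if (d < cutoff) {
        out[[length(out) + 1]] <- data.frame(
          resnum_a = min(res$resnum[i], res$resnum[j]),
          resnum_b = max(res$resnum[i], res$resnum[j]),
          distance = d
        )
      }
    }
  }
  if (!length(out)) return(data.frame(resnum_a = integer(0),
                                      resnum_b = integer(0),
                                      distance = numeric(0)))
  df <- do.call(rbind, out)
  df[order(df$resnum_a, df$resnum_b), ]
}

## exhaustive run-scanner for secondary-structure elements
oracle_elements <- function(states, min_h, min_e) {
  runs <- list()
  i <- 1
  n <- length(states)
  while (i <= n) {
    j <- i
    while (j < n && states[j + 1] == states[i]) j <- j + 1
    len <- j - i + 1
    if ((states[i] == "H" && len >= min_h) ||
        (states[i] == "E" && len >= min_e)) {
      runs[[length(runs) + 1]] <- list(state = states[i], start = i,
                                       end = j, length = len)
    }
    i <- j + 1
  }
  runs
}

## enumerate every global alignment of a and b, score with affine gaps
## (gap of length L costs open + L * ext, terminal gaps included), return
## the optimal score
oracle_align_score <- function(a, b, mat, open, ext) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, score, gap_state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, score)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb)) {
      rec(i + 1, j + 1, score + mat[ca[i], cb[j]], "none")
    }
    if (i <= length(ca)) {          # ca[i] aligned to a gap
      pen <- if (gap_state == "a") ext else open + ext
      rec(i + 1, j, score - pen, "a")
    }
    if (j <= length(cb)) {
      pen <- if (gap_state == "b") ext else open + ext
      rec(i, j + 1, score - pen, "b")
    }
  }
  rec(1, 1, 0, "none")
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

## independent SASA reference via the biotite Python library
biotite_sasa <- function(pdb_file, n_points = 960) {
  script <- sprintf(paste0(
    "import numpy as np, biotite.structure.io.pdb as pdb, ",
    "biotite.structure as struc\n",
    "s = pdb.PDBFile.read('%s').get_structure(model=1)\n",
    "a = struc.sasa(s, probe_radius=1.4, point_number=%d, ",
    "vdw_radii='Single')\n",
    "print(float(np.nansum(a)))"), pdb_file, n_points)
  out <- system2("python", c("-c", shQuote(script)), stdout = TRUE,
                 stderr = FALSE)
  as.numeric(out[length(out)])
}

## one-line atom-table constructor for geometric micro-fixtures
mk_atom <- function(serial, name, resname, resnum, x, y, z,
                    element = substr(name, 1, 1), chain = "A",
                    record = "ATOM", altloc = "", occupancy = 1) {
  data.frame(record = record, serial = as.integer(serial), name = name,
             altloc = altloc, resname = resname, chain = chain,
             resnum = as.integer(resnum), icode = "", x = x, y = y, z = z,
             occupancy = occupancy, element = element,
             stringsAsFactors = FALSE)
}

as_structure <- function(atoms) {
  structure(list(atoms = atoms, source = "test"), class = "pdb_structure")
}

published_reference <- function() {
  jsonlite::read_json(system.file("extdata", "published_values.json",
                                  package = "pocketprofiler"),
                      simplifyVector = FALSE)
}

## path where users can drop the deposited kinase-domain entries; the
## calibration checks against published Table values need them
reference_entry <- function(id) {
  system.file("extdata", "reference", paste0(id, ".pdb"),
              package = "pocketprofiler")
}
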