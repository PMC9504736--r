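#' Default pipeline configuration
#'
#' One flat key space namespaced by module. Every key has a documented
#' default; unknown keys passed to the pipeline entry points are rejected.
#'
#' @return named list of parameters:
#' \describe{
#'   \item{strip.remove}{hetero codes removed before analysis}
#'   \item{sse.min_helix, sse.min_strand}{minimum element run lengths}
#'   \item{sse.energy_cutoff}{Kabsch-Sander bond energy threshold, kcal/mol}
#'   \item{sasa.probe, sasa.n_points, sasa.radii_set}{SASA parameters}
#'   \item{hbonds.d_max, hbonds.angle_min}{H-bond geometric criteria}
#'   \item{contacts.cutoff, contacts.metric}{nonpolar contact network}
#'   \item{contacts.bin_width, contacts.smooth}{distance histogram/modes}
#'   \item{ligand.cutoff, ligand.k_locus}{ligand profiling}
#' }
#' @export
default_config <- function() {
  list(
    strip.remove = solvent_buffer_codes(),
    sse.min_helix = 4L, sse.min_strand = 2L, sse.energy_cutoff = -0.5,
    sasa.probe = 1.4, sasa.n_points = 960L, sasa.radii_set = "chothia",
    hbonds.d_max = 3.5, hbonds.angle_min = 90,
    contacts.cutoff = 10, contacts.metric = "centroid",
    contacts.bin_width = 0.25, contacts.smooth = 3L,
    ligand.cutoff = 10, ligand.k_locus = 4L
  )
}

merge_config <- function(config) {
  base <- default_config()
  if (is.null(config) || !length(config)) return(base)
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  base[names(config)] <- config
  base
}

#' Full structural characterization of a pocket
#'
#' Runs the whole pipeline on one pocket: strip solvent/buffer, select the
#' residue range, assign and group secondary structure, compute SASA,
#' hydrogen bonds, polarity composition, the nonpolar contact network and
#' its per-class distance statistics (with bimodality modes).
#'
#' @param pdb a `pdb_structure` or a path to a PDB file.
#' @param chain chain identifier (`NULL` = first polymer chain).
#' @param start,end author residue-number range of the pocket.
#' @param config named list overriding [default_config()] keys.
#' @param sse optional external `sse_annotation` (e.g. from
#'   [load_external_sse()]) overriding the internal assignment.
#' @param id label for the report.
#' @return object of class `grotto_report`: list with `id`, `n_residues`,
#'   `missing`, `first_residue`, `last_residue`, `sasa_total`, `hb_count`,
#'   `composition` (percent per class), `n_helices`, `n_strands`,
#'   `n_cross`, `n_inside`, `cross_mean`, `cross_sd`, `inside_mean`,
#'   `inside_sd`, `modes`, `config`, plus the underlying `pocket`,
#'   `elements`, `contacts`, `hbonds` objects.
#' @export
run_characterization <- function(pdb, chain = NULL, start, end,
                                 config = list(), sse = NULL, id = NULL) {
  cfg <- merge_config(config)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("characterization stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  model <- stage("read", if (inherits(pdb, "pdb_structure")) pdb
                 else read_pdb(pdb))
  model <- stage("strip", strip_non_structural(model, cfg$strip.remove))
  pocket <- stage("select_pocket", select_pocket(model, chain, start, end))
  ann <- stage("sse", if (is.null(sse)) {
    assign_sse(pocket, energy_cutoff = cfg$sse.energy_cutoff)
  } else {
    match_annotation(pocket, sse)
  })
  elements <- stage("elements",
                    group_elements(ann, cfg$sse.min_helix, cfg$sse.min_strand))
  sasa <- stage("sasa", shrake_rupley(pocket, probe = cfg$sasa.probe,
                                      n_points = cfg$sasa.n_points,
                                      radii_set = cfg$sasa.radii_set))
  hb <- stage("hbonds", detect_hbonds(pocket, cfg$hbonds.d_max,
                                      cfg$hbonds.angle_min))
  comp <- stage("composition", composition(pocket))
  contacts <- stage("contacts", nonpolar_contact_network(
    pocket, elements, cutoff = cfg$contacts.cutoff,
    metric = cfg$contacts.metric))
  cross <- contact_statistics(contacts, "cross", cfg$contacts.bin_width,
                              cfg$contacts.smooth)
  inside <- contact_statistics(contacts, "inside", cfg$contacts.bin_width,
                               cfg$contacts.smooth)
  all_stats <- contact_statistics(contacts, "all", cfg$contacts.bin_width,
                                  cfg$contacts.smooth)
  nres <- nrow(pocket$residues)
  structure(
    list(
      id = if (is.null(id)) paste0(pocket$chain, ":", start, "-", end)
           else id,
      n_residues = nres, missing = pocket$missing,
      first_residue = paste0(pocket$residues$resname[1],
                             pocket$residues$resnum[1]),
      last_residue = paste0(pocket$residues$resname[nres],
                            pocket$residues$resnum[nres]),
      sasa_total = sasa$total, hb_count = nrow(hb),
      composition = comp$percent,
      n_helices = sum(elements$elements$state == "H"),
      n_strands = sum(elements$elements$state == "E"),
      n_cross = cross$n, n_inside = inside$n,
      cross_mean = cross$mean, cross_sd = cross$sd,
      inside_mean = inside$mean, inside_sd = inside$sd,
      modes = all_stats$modes,
      config = cfg,
      pocket = pocket, elements = elements, contacts = contacts,
      hbonds = hb, sasa = sasa
    ),
    class = "grotto_report"
  )
}

#' @export
print.grotto_report <- function(x, ...) {
  cat("grotto_report ", x$id, " (", x$n_residues, " residues, ",
      x$first_residue, "...", x$last_residue, ")\n", sep = "")
  cat(sprintf("  SASA %.3f A^2 | HB %d | SSE %dH/%dE\n",
              x$sasa_total, x$hb_count, x$n_helices, x$n_strands))
  cat(sprintf("  composition: nonpolar %.1f%% polar %.1f%% charged %.1f%%\n",
              x$composition[["nonpolar"]], x$composition[["polar"]],
              x$composition[["charged"]]))
  cat(sprintf("  contacts: cross %d (%.2f +/- %.2f A), inside %d (%.2f +/- %.2f A)\n",
              x$n_cross, x$cross_mean, x$cross_sd,
              x$n_inside, x$inside_mean, x$inside_sd))
  cat("  distance modes: ",
      paste(sprintf("%.3f", x$modes), collapse = ", "), " A\n", sep = "")
  invisible(x)
}

report_fields <- function(x) {
  list(
    id = x$id, n_residues = x$n_residues,
    first_residue = x$first_residue, last_residue = x$last_residue,
    sasa_total = x$sasa_total, hb_count = x$hb_count,
    nonpolar_pct = unname(x$composition[["nonpolar"]]),
    polar_pct = unname(x$composition[["polar"]]),
    charged_pct = unname(x$composition[["charged"]]),
    n_helices = x$n_helices, n_strands = x$n_strands,
    n_cross = x$n_cross, n_inside = x$n_inside,
    cross_mean = x$cross_mean, cross_sd = x$cross_sd,
    inside_mean = x$inside_mean, inside_sd = x$inside_sd,
    modes = x$modes
  )
}

#' Write a characterization report to disk
#'
#' Emits a machine-readable JSON report (with the full configuration
#' echoed, so every number traces to its parameters) and a one-row TSV.
#'
#' @param report a `grotto_report`.
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>.tsv`.
#' @return paths, invisibly.
#' @export
write_report <- function(report, prefix) {
  fields <- report_fields(report)
  json <- c(fields, list(config = report$config))
  jf <- paste0(prefix, ".json")
  jsonlite::write_json(json, jf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  tf <- paste0(prefix, ".tsv")
  flat <- fields
  flat$modes <- paste(sprintf("%.3f", fields$modes), collapse = ",")
  utils::write.table(as.data.frame(flat), tf, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(c(json = jf, tsv = tf))
}

#' Profile a set of protein-ligand complexes
#'
#' Runs [ligand_profile()] for each (pocket, ligand) pair described in
#' `complexes`. A failing entry (e.g. missing ligand) is reported as a
#' failed row and the run continues.
#'
#' @param complexes a data.frame (or list of lists) with columns/fields
#'   `pdb` (path or `pdb_structure`), `chain`, `start`, `end`, `ligand`
#'   (hetero code) and optional `label`.
#' @param config named list overriding [default_config()] keys.
#' @return object of class `ligand_table`: data.frame with `label`,
#'   `ligand`, `pocket`, `n_hb`, `n_hydrophobic`, `locus`, `failed`;
#'   the full `ligand_profile` objects are in `attr(, "profiles")`.
#' @export
run_ligand_profiles <- function(complexes, config = list()) {
  cfg <- merge_config(config)
  if (is.data.frame(complexes)) {
    complexes <- lapply(seq_len(nrow(complexes)), function(i)
      as.list(complexes[i, , drop = FALSE]))
  }
  rows <- list()
  profiles <- list()
  for (k in seq_along(complexes)) {
    cx <- complexes[[k]]
    label <- if (!is.null(cx$label)) cx$label else paste0("complex_", k)
    row <- data.frame(label = label, ligand = cx$ligand,
                      pocket = paste0(cx$start, "-", cx$end),
                      n_hb = NA_integer_, n_hydrophobic = NA_integer_,
                      locus = NA_character_, failed = TRUE,
                      stringsAsFactors = FALSE)
    prof <- tryCatch({
      model <- if (inherits(cx$pdb, "pdb_structure")) cx$pdb
               else read_pdb(cx$pdb)
      lig <- extract_ligand(model, cx$ligand)
      model <- strip_non_structural(model, cfg$strip.remove)
      chain <- if (is.null(cx$chain) || is.na(cx$chain)) NULL else cx$chain
      pocket <- select_pocket(model, chain, cx$start, cx$end)
      ligand_profile(pocket, lig, d_max = cfg$hbonds.d_max,
                     angle_min = cfg$hbonds.angle_min,
                     cutoff = cfg$ligand.cutoff,
                     k_locus = cfg$ligand.k_locus)
    }, error = function(e) {
      warning("complex '", label, "' failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(prof)) {
      row$n_hb <- prof$n_hb
      row$n_hydrophobic <- prof$n_hydrophobic
      row$locus <- paste0(prof$locus$resname, prof$locus$resnum,
                          collapse = ",")
      row$failed <- FALSE
      profiles[[label]] <- prof
    }
    rows[[k]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else data.frame(
    label = character(0), ligand = character(0), pocket = character(0),
    n_hb = integer(0), n_hydrophobic = integer(0), locus = character(0),
    failed = logical(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "profiles") <- profiles
  class(out) <- c("ligand_table", "data.frame")
  out
}

#' Compare a report against published reference values
#'
#' Computes absolute and relative deviations of report fields against a
#' reference file (JSON: named list of `value` and optional `tolerance`
#' entries, either absolute or with a `"%"` suffix for relative). Fields
#' the report lacks are flagged `unavailable` rather than failing.
#'
#' @param report a `grotto_report`, `ligand_table` row list, or plain named
#'   list of numbers.
#' @param reference path to a reference JSON file, or an equivalent list.
#' @return data.frame `field`, `value`, `reference`, `abs_dev`, `rel_dev`,
#'   `tolerance`, `status` (`pass`/`fail`/`unavailable`/`excluded`).
#' @export
compare_report <- function(report, reference) {
  if (is.character(reference)) {
    reference <- jsonlite::read_json(reference, simplifyVector = FALSE)
  }
  if (!is.list(reference) || is.null(names(reference))) {
    stop("reference must be a named list (or a JSON file holding one)")
  }
  fields <- if (inherits(report, "grotto_report")) report_fields(report)
            else as.list(report)
  rows <- lapply(names(reference), function(nm) {
    ref <- reference[[nm]]
    if (!is.list(ref) || is.null(ref$value)) {
      stop("reference entry '", nm, "' lacks a value: schema mismatch")
    }
    refval <- as.numeric(ref$value)
    excluded <- isTRUE(ref$excluded)
    val <- fields[[nm]]
    if (is.null(val) || !is.numeric(val) || !length(val)) {
      return(data.frame(field = nm, value = NA_real_, reference = refval,
                        abs_dev = NA_real_, rel_dev = NA_real_,
                        tolerance = NA_character_,
                        status = if (excluded) "excluded" else "unavailable",
                        stringsAsFactors = FALSE))
    }
    val <- as.numeric(val)[1]
    adev <- abs(val - refval)
    rdev <- if (refval != 0) adev / abs(refval) else NA_real_
    tol <- ref$tolerance
    status <- if (excluded) "excluded" else if (is.null(tol)) {
      NA_character_
    } else if (grepl("%$", as.character(tol))) {
      ok <- rdev <= as.numeric(sub("%$", "", tol)) / 100
      if (ok) "pass" else "fail"
    } else {
      if (adev <= as.numeric(tol)) "pass" else "fail"
    }
    data.frame(field = nm, value = val, reference = refval,
               abs_dev = adev, rel_dev = rdev,
               tolerance = if (is.null(tol)) NA_character_
                           else as.character(tol),
               status = if (is.na(status)) "reported" else status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
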