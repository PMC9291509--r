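#' Virtual-screening criteria
#'
#' The threefold filter applied to first-front molecules: synthetic
#' accessibility at most `sas_max`, logP inside `[logp_min, logp_max]`
#' (the Ghose drug-likeness range), and binding score at most `bas_max`.
#' All inequalities are inclusive.  The default binding threshold -6.6 is
#' the weakest score observed among ten known ligands of the carbonic
#' anhydrase IX target; recompute it for another receptor with
#' [calibrate_bas_threshold()].
#'
#' @param sas_max maximum synthetic accessibility score.
#' @param logp_min,logp_max logP window.
#' @param bas_max maximum (least negative) binding score.
#' @return object of class `screening_criteria`.
#' @export
screening_criteria <- function(sas_max = 3, logp_min = -0.4,
                               logp_max = 5.6, bas_max = -6.6) {
  if (logp_min > logp_max) {
    stop_delfrag("logp_min must not exceed logp_max", "delfrag_config_error")
  }
  structure(
    list(sas_max = sas_max, logp_min = logp_min, logp_max = logp_max,
         bas_max = bas_max),
    class = "screening_criteria"
  )
}

#' Screen the first Pareto front
#'
#' Returns the rank-1 members that satisfy every screening criterion
#' (inclusively at the bounds).  Idempotent, and monotone in the
#' criteria: loosening any bound never removes a passer.
#'
#' @param pop a `del_population` or a ranked member data.frame.
#' @param criteria a [screening_criteria()].
#' @return data.frame of passing property records.
#' @export
screen_first_front <- function(pop, criteria = screening_criteria()) {
  members <- if (inherits(pop, "del_population")) pop$members else pop
  if (is.null(members$rank)) {
    stop_delfrag("population must be ranked before screening",
                 "delfrag_population_error")
  }
  keep <- !is.na(members$rank) & members$rank == 1 &
    members$sas <= criteria$sas_max &
    members$logp >= criteria$logp_min & members$logp <= criteria$logp_max &
    members$bas <= criteria$bas_max
  members[keep, , drop = FALSE]
}

#' Order property records by binding score
#'
#' Best (most negative) binding score first; ties broken by canonical
#' SMILES so the ordering is deterministic.
#'
#' @param records data.frame with `bas` and `smiles` columns.
#' @return the reordered data.frame.
#' @export
rank_by_bas <- function(records) {
  records[order(records$bas, records$smiles, method = "radix"), , drop = FALSE]
}

#' Calibrate the screening binding threshold from known ligands
#'
#' Given docking scores of known ligands of the target, the screening
#' upper bound is their maximum (weakest) score: a generated molecule
#' must bind at least as well as the weakest known ligand.
#'
#' @param ligand_scores numeric vector of docking scores.
#' @return the threshold (an element of the input).
#' @export
calibrate_bas_threshold <- function(ligand_scores) {
  if (!length(ligand_scores)) {
    stop_delfrag("no ligand scores supplied", "delfrag_invalid_input")
  }
  max(ligand_scores)
}

#' Prepare a ligand file for docking
#'
#' Generates a 3D conformer and writes the molecule in PDBQT format
#' using Open Babel (`obabel --gen3d`, pH-adjusted protonation).
#'
#' @param smiles a single SMILES string.
#' @param out_path output file path (`.pdbqt`).
#' @param ph protonation pH.
#' @return `out_path`, invisibly.
#' @export
prepare_ligand <- function(smiles, out_path, ph = 7.4) {
  if (!is_valid_smiles(smiles)) {
    stop_delfrag(sprintf("invalid SMILES: '%s'", smiles),
                 "delfrag_docking_error")
  }
  obabel <- Sys.which("obabel")
  if (!nzchar(obabel)) {
    stop_delfrag("obabel executable not found on PATH", "delfrag_docking_error")
  }
  log <- suppressWarnings(system2(
    obabel, c(paste0("-:", shQuote(smiles)), "-opdbqt", "-O",
              shQuote(out_path), "--gen3d", "-p", ph),
    stdout = TRUE, stderr = TRUE
  ))
  if (!file.exists(out_path) || !file.size(out_path)) {
    stop_delfrag(paste0("ligand preparation failed:\n",
                        paste(log, collapse = "\n")),
                 "delfrag_docking_error")
  }
  invisible(out_path)
}

#' Dock one molecule and return its best pose score
#'
#' Runs the configured AutoDock-Vina-compatible engine on a prepared
#' ligand and parses the best (lowest) affinity from the result table.
#' Deterministic for a fixed engine seed.  Any engine or preparation
#' failure raises a docking error carrying the engine log.
#'
#' @param smiles a single SMILES string.
#' @param cfg a [docking_config()].
#' @return best pose affinity (kcal/mol).
#' @export
dock_one <- function(smiles, cfg) {
  stopifnot(inherits(cfg, "docking_config"))
  engine <- Sys.which(cfg$engine)
  if (!nzchar(engine)) engine <- cfg$engine
  if (!file.exists(engine)) {
    stop_delfrag(sprintf("docking engine not found: %s", cfg$engine),
                 "delfrag_docking_error")
  }
  if (!file.exists(cfg$receptor_path)) {
    stop_delfrag(sprintf("receptor file not found: %s", cfg$receptor_path),
                 "delfrag_docking_error")
  }
  lig <- tempfile(fileext = ".pdbqt")
  on.exit(unlink(lig))
  prepare_ligand(smiles, lig)
  args <- c("--receptor", shQuote(cfg$receptor_path),
            "--ligand", shQuote(lig),
            "--center_x", cfg$box_center[1],
            "--center_y", cfg$box_center[2],
            "--center_z", cfg$box_center[3],
            "--size_x", cfg$box_size[1],
            "--size_y", cfg$box_size[2],
            "--size_z", cfg$box_size[3],
            "--seed", cfg$engine_seed,
            "--exhaustiveness", cfg$exhaustiveness)
  log <- suppressWarnings(system2(engine, args, stdout = TRUE, stderr = TRUE))
  score <- parse_vina_score(log)
  if (is.na(score)) {
    stop_delfrag(paste0("docking failed; engine log:\n",
                        paste(log, collapse = "\n")),
                 "delfrag_docking_error")
  }
  score
}

# best affinity from a Vina-style result table ("   1   -9.3   0.000   0.000")
parse_vina_score <- function(log) {
  hits <- regmatches(log, regexec("^\\s*(\\d+)\\s+(-?\\d+\\.\\d+)\\s", log))
  scores <- vapply(hits, function(h) {
    if (length(h) == 3) as.numeric(h[3]) else NA_real_
  }, numeric(1))
  if (all(is.na(scores))) NA_real_ else min(scores, na.rm = TRUE)
}
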