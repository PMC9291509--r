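#' Synthetic accessibility score
#'
#' The Ertl-Schuffenhauer synthetic accessibility score as shipped with
#' the cheminformatics toolkit (fragment-contribution term from a fixed
#' frequency table plus complexity penalties), ranging from about 1 (easy
#' to synthesize) to 10 (hard).  One of the three minimized objectives.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
#' @examples \dontrun{compute_sas("c1ccccc1")}
compute_sas <- function(smiles) {
  property_column(smiles, "sas")
}

#' Octanol-water partition coefficient (logP)
#'
#' Crippen atom-contribution logP, the toolkit's standard estimate.
#' Minimized as an objective during evolution; range-filtered at
#' screening time (see [screening_criteria()]).
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector.
#' @export
compute_logp <- function(smiles) {
  property_column(smiles, "logp")
}

# molecular descriptors used by the surrogate binding score
molecule_descriptors <- function(smiles) {
  res <- bridge_cached("props", smiles)
  bad <- vapply(res, is.null, logical(1))
  if (any(bad)) {
    stop_delfrag(sprintf("invalid SMILES: '%s'", smiles[which(bad)[1]]),
                 "delfrag_property_error")
  }
  data.frame(
    smiles = as.character(smiles),
    sas = vapply(res, function(x) x$sas, numeric(1)),
    logp = vapply(res, function(x) x$logp, numeric(1)),
    mw = vapply(res, function(x) x$mw, numeric(1)),
    rings = vapply(res, function(x) x$rings, numeric(1)),
    heavy = vapply(res, function(x) x$heavy, numeric(1)),
    stringsAsFactors = FALSE
  )
}

property_column <- function(smiles, col) {
  molecule_descriptors(smiles)[[col]]
}

#' Docking-based binding affinity score (BAS)
#'
#' Runs an AutoDock-Vina-compatible engine (QVina recommended) on each
#' molecule against the receptor configured in `dock` and returns the best
#' (lowest) pose affinity in kcal/mol.  Requires an external engine
#' executable and a prepared receptor PDBQT file; see [docking_config()].
#' More negative scores mean stronger predicted binding; BAS is minimized.
#'
#' @param smiles character vector of SMILES.
#' @param dock a [docking_config()] object.
#' @return numeric vector of best pose scores.
#' @export
compute_bas <- function(smiles, dock) {
  stopifnot(inherits(dock, "docking_config"))
  vapply(smiles, function(s) dock_one(s, dock), numeric(1), USE.NAMES = FALSE)
}

#' Deterministic surrogate binding score
#'
#' A fixed, documented stand-in scoring function used to exercise the
#' evolutionary machinery reproducibly: a smooth decreasing function of
#' ring count and heavy-atom count plus a small deterministic per-molecule
#' offset derived from a hash of the canonical SMILES and `seed`, clipped
#' to the range of typical docking scores `[-12, -2]`.  It rewards larger
#' ring systems (molecules with more rings score strictly lower) and is
#' not claimed to approximate physical docking.
#'
#' @param smiles character vector of SMILES.
#' @param seed integer; offsets are deterministic given (molecule, seed).
#' @return numeric vector of surrogate scores.
#' @export
surrogate_bas <- function(smiles, seed = 0L) {
  d <- molecule_descriptors(canonical_smiles(smiles))
  u <- vapply(d$smiles, smiles_hash01, numeric(1), seed = seed,
              USE.NAMES = FALSE)
  raw <- -(1.1 * d$rings + 0.6 * sqrt(d$heavy)) + 0.8 * (u - 0.5)
  pmin(pmax(raw, -12), -2)
}

# deterministic hash of a string into [0, 1)
smiles_hash01 <- function(s, seed = 0L) {
  codes <- utf8ToInt(s)
  h <- (as.numeric(seed) * 2654435761) %% 2147483647
  for (c in codes) {
    h <- (h * 131 + c) %% 2147483647
  }
  h / 2147483647
}

#' Evaluate the three optimization objectives for a batch of molecules
#'
#' Computes SAS and logP with the toolkit and the binding score with the
#' supplied scorer, returning one property record per valid molecule
#' (invalid inputs are dropped with a message, preserving input order).
#'
#' @param smiles character vector.
#' @param scorer function mapping a character vector of SMILES to BAS
#'   values, e.g. [surrogate_bas()] or a closure around [compute_bas()].
#' @return data.frame with columns `smiles` (canonical), `sas`, `logp`,
#'   `bas`, `mw`.
#' @export
evaluate_objectives <- function(smiles, scorer = surrogate_bas) {
  if (!length(smiles)) {
    return(data.frame(smiles = character(0), sas = numeric(0),
                      logp = numeric(0), bas = numeric(0), mw = numeric(0)))
  }
  canon <- canonical_smiles(smiles)
  if (anyNA(canon)) {
    message(sprintf("evaluate_objectives: dropped %d invalid molecules",
                    sum(is.na(canon))))
    canon <- canon[!is.na(canon)]
  }
  if (!length(canon)) {
    return(evaluate_objectives(character(0), scorer))
  }
  d <- molecule_descriptors(canon)
  bas <- tryCatch(scorer(canon), error = function(e) rep(Inf, length(canon)))
  bad <- !is.finite(bas)
  if (any(bad)) {
    message(sprintf("evaluate_objectives: %d molecules got a non-finite binding score",
                    sum(bad)))
    bas[bad] <- Inf
  }
  data.frame(smiles = canon, sas = d$sas, logp = d$logp, bas = bas,
             mw = d$mw, stringsAsFactors = FALSE)
}
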