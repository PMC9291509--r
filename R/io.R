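#' Read molecules from a SMILES file
#'
#' Plain text, one molecule per line with an optional tab-separated
#' identifier; lines starting with `#` and blank lines are skipped.
#' Malformed (unparseable) entries are skipped with a message.
#'
#' @param path file path.
#' @return character vector of canonical SMILES; identifiers, when
#'   present, are kept as names.
#' @export
read_smiles <- function(path) {
  if (!file.exists(path)) {
    stop_delfrag(sprintf("file not found: %s", path), "delfrag_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(character(0))
  parts <- strsplit(lines, "\t")
  smi <- vapply(parts, `[[`, character(1), 1)
  ids <- vapply(parts, function(p) if (length(p) > 1) p[[2]] else NA_character_,
                character(1))
  canon <- canonical_smiles(smi)
  bad <- is.na(canon)
  if (any(bad)) {
    message(sprintf("read_smiles: skipped %d malformed line(s)", sum(bad)))
  }
  out <- canon[!bad]
  if (any(!is.na(ids[!bad]))) names(out) <- ids[!bad]
  out
}

#' Write molecules to a SMILES file
#'
#' @param smiles character vector (names, when present, are written as a
#'   tab-separated second column).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smiles <- function(smiles, path) {
  lines <- if (!is.null(names(smiles)) && any(nzchar(names(smiles)))) {
    paste(smiles, names(smiles), sep = "\t")
  } else {
    as.character(smiles)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Serialize fragment sequences as JSON lines
#'
#' One JSON object per line: `{"source": smiles, "fragments": [...]}`.
#'
#' @param seqs list of `fragment_sequence` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(seqs, path) {
  lines <- vapply(seqs, function(fs) {
    as.character(jsonlite::toJSON(
      list(source = fs$source, fragments = as.list(fs$fragments)),
      auto_unbox = TRUE
    ))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) {
    stop_delfrag(sprintf("file not found: %s", path), "delfrag_io_error")
  }
  lapply(readLines(path, warn = FALSE), function(ln) {
    obj <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    structure(list(source = obj$source, fragments = unlist(obj$fragments)),
              class = "fragment_sequence")
  })
}

#' Specification for the synthetic fixture library
#'
#' The fixture generator emulates a small drug-like screening library:
#' decorated aromatic/heteroaromatic scaffolds joined to a second ring
#' system through ether, amide or related linkers, so that every
#' generated molecule parses, carries at least two BRICS fragments and
#' spans a useful range of lipophilicity.  It stands in for external
#' compound collections; it is a synthetic library, not a sample of any
#' external dataset.
#'
#' @param n_molecules number of molecules to generate.
#' @param scaffolds character vector of scaffold SMILES templates, each
#'   containing the literal placeholder `X` at the substitution point.
#' @param substituents character vector of substituent SMILES (linker
#'   plus terminal ring, using ring-closure digits 8 and 9).
#' @param seed integer seed for the down-sampling step.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 200L,
                         scaffolds = default_fixture_scaffolds(),
                         substituents = default_fixture_substituents(),
                         seed = 1L) {
  if (!length(scaffolds) || !length(substituents)) {
    stop_delfrag("scaffold and substituent sets must be non-empty",
                 "delfrag_config_error")
  }
  structure(
    list(n_molecules = as.integer(n_molecules), scaffolds = scaffolds,
         substituents = substituents, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

#' @rdname fixture_spec
#' @export
default_fixture_scaffolds <- function() {
  c("c1ccc(X)cc1",
    "Cc1ccc(X)cc1",
    "COc1ccc(X)cc1",
    "Fc1ccc(X)cc1",
    "Clc1ccc(X)cc1",
    "c1ccc2cc(X)ccc2c1",
    "Cc1cccc(X)c1",
    "c1ccc(CX)cc1")
}

#' @rdname fixture_spec
#' @export
default_fixture_substituents <- function() {
  linkers <- c("O", "CO", "C(=O)N", "CC(=O)N", "CNC(=O)", "OCC(=O)N")
  rings <- c("c8ccccc8", "c8ccc(C)cc8", "c8ccc(F)cc8", "c8ccc(Cl)cc8",
             "C8CCCCC8", "C8CCOCC8", "c8cccs8", "c8ccncc8")
  as.vector(outer(linkers, rings, paste0))
}

#' Generate the synthetic fixture library
#'
#' Enumerates every scaffold x substituent combination, keeps the valid,
#' unique molecules with at least two BRICS fragments, and draws
#' `n_molecules` of them without replacement (deterministically under
#' the spec's seed).
#'
#' @param spec a [fixture_spec()].
#' @return character vector of canonical SMILES.
#' @export
generate_fixtures <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  combos <- as.vector(t(outer(spec$scaffolds, spec$substituents,
                              Vectorize(function(sc, su) sub("X", su, sc, fixed = TRUE)))))
  canon <- canonical_smiles(combos)
  canon <- unique(canon[!is.na(canon)])
  canon <- canon[fragment_count(canon) >= 2]
  if (length(canon) < spec$n_molecules) {
    stop_delfrag(sprintf(
      "only %d feasible fixture molecules available, %d requested",
      length(canon), spec$n_molecules), "delfrag_config_error")
  }
  set.seed(spec$seed)
  sort(sample(canon, spec$n_molecules), method = "radix")
}
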