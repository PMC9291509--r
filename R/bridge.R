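#' @keywords internal
"_PACKAGE"

# Batched interface to the RDKit worker (inst/python/chembridge.py).
#
# All primitive chemistry (SMILES parsing, canonicalization, BRICS bond
# perception, SSSR, synthetic-accessibility and Crippen logP scoring) is
# delegated to RDKit through a one-shot JSON subprocess per batch.  Results
# for pure functions of a SMILES string are memoised for the session, so
# repeated scoring of the same molecules costs one call.

.delfrag_env <- new.env(parent = emptyenv())

bridge_python <- function() {
  py <- getOption("delfrag.python", "")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) {
    stop_delfrag("no python interpreter found for the RDKit bridge",
                 "delfrag_bridge_error")
  }
  py
}

bridge_script <- function() {
  path <- system.file("python", "chembridge.py", package = "delfrag")
  if (!nzchar(path)) {
    stop_delfrag("chembridge.py not found in the installed package",
                 "delfrag_bridge_error")
  }
  path
}

#' Low-level call into the RDKit worker
#'
#' @param requests list of request objects (`op` plus arguments).
#' @return list of results, one per request.
#' @keywords internal
chem_bridge <- function(requests) {
  payload <- jsonlite::toJSON(list(requests = requests),
                              auto_unbox = TRUE, null = "null", digits = NA)
  out <- suppressWarnings(system2(
    bridge_python(), shQuote(bridge_script()),
    input = as.character(payload), stdout = TRUE, stderr = FALSE
  ))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    stop_delfrag("RDKit bridge failed (see python traceback on stderr)",
                 "delfrag_bridge_error")
  }
  jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)$results
}

# Memoised single-op batch over character keys.  `fun` is the bridge op
# name; `field` the cache name; values are stored as-is (NULL for parse
# failures, kept distinct from "not yet computed").
bridge_cached <- function(op, keys, payload_name = "smiles") {
  cache_name <- paste0("cache_", op)
  if (is.null(.delfrag_env[[cache_name]])) {
    .delfrag_env[[cache_name]] <- new.env(parent = emptyenv())
  }
  cache <- .delfrag_env[[cache_name]]
  keys <- as.character(keys)
  miss <- unique(keys[!vapply(keys, function(k) {
    exists(k, envir = cache, inherits = FALSE)
  }, logical(1))])
  if (length(miss)) {
    req <- list(op = op)
    req[[payload_name]] <- as.list(miss)
    res <- chem_bridge(list(req))[[1]]
    for (i in seq_along(miss)) {
      assign(miss[[i]], if (is.null(res[[i]])) list(NULL) else res[[i]],
             envir = cache)
    }
  }
  lapply(keys, function(k) {
    v <- get(k, envir = cache, inherits = FALSE)
    if (identical(v, list(NULL))) NULL else v
  })
}

stop_delfrag <- function(msg, class) {
  stop(structure(
    class = c(class, "delfrag_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}
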