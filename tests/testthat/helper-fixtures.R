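# Shared fixtures, memoised so expensive objects are built once per run.

.memo <- new.env(parent = emptyenv())

memoised <- function(key, builder) {
  if (is.null(.memo[[key]])) .memo[[key]] <- builder()
  .memo[[key]]
}

tiny_model_config <- function(...) {
  args <- list(embedding_size = 16L, hidden_size = 64L, latent_size = 16L,
               recurrent_layers = 1L, learning_rate = 5e-3, batch_size = 16L)
  over <- list(...)
  args[names(over)] <- over
  do.call(model_config, args)
}

fixture_library <- function(n = 200L, seed = 11L) {
  memoised(sprintf("fixtures_%d_%d", n, seed), function() {
    generate_fixtures(fixture_spec(n_molecules = n, seed = seed))
  })
}

tiny_jt_model <- function() {
  memoised("tiny_jt_model", function() {
    fragment_vae(fixture_library(60), variant = "jt",
                 config = tiny_model_config(), epochs = 25, seed = 42)
  })
}

tiny_del_run <- function() {
  memoised("tiny_del_run", function() {
    run_del(fixture_library(100),
            del_config(generations = 3, population_size = 40,
                       initial_epochs = 15, subsequent_epochs = 5, seed = 5),
            tiny_model_config(), variant = "jt")
  })
}

# the reference-scale surrogate run: population 100, 5 generations
surrogate_del_run <- function() {
  memoised("surrogate_del_run", function() {
    run_del(fixture_library(200),
            del_config(generations = 5, population_size = 100,
                       initial_epochs = 15, subsequent_epochs = 5, seed = 7),
            tiny_model_config(batch_size = 32L), variant = "jt")
  })
}

front1_clipped <- function(members, ref) {
  front <- as.matrix(members[!is.na(members$rank) & members$rank == 1,
                             c("sas", "logp", "bas")])
  keep <- apply(front <= matrix(ref, nrow(front), 3, byrow = TRUE), 1, all)
  front[keep, , drop = FALSE]
}

# --- independent oracles -----------------------------------------------------

# Pareto ranks by iterative peeling of maximal elements (pairwise checks
# only; independent of the NSGA-II bookkeeping in the implementation).
oracle_pareto_ranks <- function(objs) {
  objs <- as.matrix(objs)
  n <- nrow(objs)
  rank <- rep(NA_integer_, n)
  r <- 0L
  left <- seq_len(n)
  dom <- function(a, b) all(objs[a, ] <= objs[b, ]) && any(objs[a, ] < objs[b, ])
  while (length(left)) {
    r <- r + 1L
    front <- left[vapply(left, function(i) {
      !any(vapply(left, function(j) j != i && dom(j, i), logical(1)))
    }, logical(1))]
    rank[front] <- r
    left <- setdiff(left, front)
  }
  rank
}

# W1 via sorted matching after replicating both samples to a common size.
oracle_w1 <- function(a, b) {
  k <- length(a) * length(b)  # common multiple of both lengths
  aa <- sort(rep(sort(a), each = k / length(a)))
  bb <- sort(rep(sort(b), each = k / length(b)))
  mean(abs(aa - bb))
}

# Monte-Carlo hypervolume (minimization, boxes towards `ref`).
oracle_hv_mc <- function(front, ref, n = 1e5, seed = 1) {
  set.seed(seed)
  front <- as.matrix(front)
  d <- length(ref)
  lo <- apply(front, 2, min)
  pts <- matrix(stats::runif(n * d), n, d)
  pts <- sweep(sweep(pts, 2, ref - lo, "*"), 2, lo, "+")
  inside <- rep(FALSE, n)
  for (i in seq_len(nrow(front))) {
    dominated <- rowSums(pts >= matrix(front[i, ], n, d, byrow = TRUE)) == d
    inside <- inside | dominated
  }
  box <- prod(ref - lo)
  list(hv = mean(inside) * box, se = stats::sd(inside) * box / sqrt(n))
}

# fragment count recomputed directly from BRICS bond enumeration in a
# separate RDKit call (bypasses the packaged worker and its conventions)
oracle_fragment_count <- function(smiles) {
  script <- paste(
    "import sys, json",
    "from rdkit import Chem",
    "from rdkit.Chem import BRICS",
    "out = []",
    "for s in json.load(sys.stdin):",
    "    m = Chem.MolFromSmiles(s)",
    "    cuts = {tuple(sorted(ij)) for ij, _ in BRICS.FindBRICSBonds(m)",
    "            if m.GetAtomWithIdx(max(ij)).IsInRing()}",
    "    out.append(len(cuts) + 1)",
    "json.dump(out, sys.stdout)",
    sep = "\n")
  f <- tempfile(fileext = ".py")
  writeLines(script, f)
  on.exit(unlink(f))
  out <- system2(Sys.which("python"), shQuote(f),
                 input = as.character(jsonlite::toJSON(smiles)), stdout = TRUE)
  unlist(jsonlite::fromJSON(paste(out, collapse = "")))
}

# a fake Vina-style engine that prints a fixed result table
make_mock_engine <- function(dir = tempdir()) {
  path <- file.path(dir, "mock-vina")
  writeLines(c(
    "#!/bin/sh",
    "echo 'mode |   affinity | dist from best mode'",
    "echo '-----+------------+--------------------'",
    "echo '   1       -9.3      0.000      0.000'",
    "echo '   2       -8.1      1.200      2.100'"
  ), path)
  Sys.chmod(path, "0755")
  path
}
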