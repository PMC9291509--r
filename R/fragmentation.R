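#' Canonical SMILES
#'
#' Canonicalizes SMILES strings with the toolkit's default canonical form
#' (aromatic perception, stereochemistry preserved, no kekulization).  The
#' same canonical dialect is used everywhere uniqueness or novelty of
#' molecules is decided, so set membership is consistent across the package.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector; `NA` where a string does not parse.
#' @export
#' @examples \dontrun{canonical_smiles("OCC")  # "CCO"}
canonical_smiles <- function(smiles) {
  res <- bridge_cached("canonical", smiles)
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Test chemical validity of SMILES strings
#'
#' A string is valid when it parses to a chemically sane structure under
#' the toolkit's sanitization rules.
#'
#' @param smiles character vector.
#' @return logical vector.
#' @export
is_valid_smiles <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

#' Fragment a molecule into a BRICS fragment sequence
#'
#' Scanning the SMILES left to right, the molecule is cleaved at every
#' BRICS-breakable bond that enters a ring system (the bond's later-scanned
#' atom is a ring atom).  Acyclic linkers therefore stay attached to the
#' fragment on their left, which keeps the granularity coarse: typical
#' drug-like molecules split into 2-4 fragments.  Attachment points are
#' marked with bare `*` dummy atoms.  Fragments are emitted in scan order
#' (preorder of the fragment tree); within each fragment after the first,
#' the first `*` is the attachment back towards the root and any further
#' `*`s attach the fragments that follow, so [reassemble()] can invert the
#' cleavage exactly.
#'
#' @param smiles a single SMILES string.
#' @return an object of class `fragment_sequence`: list with `source`
#'   (canonical SMILES of the parent) and `fragments` (character vector).
#' @seealso [reassemble()], [fragment_count()]
#' @export
#' @examples \dontrun{
#' brics_fragment("CC(=O)Oc1ccccc1C(=O)O")  # aspirin -> 2 fragments
#' }
brics_fragment <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  res <- bridge_cached("fragment", smiles)[[1]]
  if (is.null(res)) {
    stop_delfrag(sprintf("invalid SMILES: '%s'", smiles),
                 "delfrag_invalid_input")
  }
  structure(
    list(source = res$source, fragments = unlist(res$fragments)),
    class = "fragment_sequence"
  )
}

#' @export
print.fragment_sequence <- function(x, ...) {
  cat("BRICS fragment sequence of", x$source, "\n")
  cat(sprintf("  [%d] %s\n", seq_along(x$fragments), x$fragments), sep = "")
  invisible(x)
}

#' Reassemble a fragment sequence into its parent molecule
#'
#' Inverts [brics_fragment()]: fragments are joined leaves-to-root (right
#' to left), bonding each fragment's parent-facing attachment point to the
#' corresponding `*` of the fragment it was cleaved from.  For sequences
#' produced by [brics_fragment()] the result has the parent's canonical
#' SMILES.
#'
#' @param frags a `fragment_sequence` or a character vector of fragment
#'   SMILES.
#' @return canonical SMILES of the assembled molecule.
#' @export
reassemble <- function(frags) {
  if (inherits(frags, "fragment_sequence")) frags <- frags$fragments
  frags <- as.character(frags)
  if (!length(frags)) {
    stop_delfrag("empty fragment sequence", "delfrag_assembly_error")
  }
  res <- chem_bridge(list(list(op = "reassemble",
                               fragments = list(as.list(frags)))))[[1]][[1]]
  if (is.null(res)) {
    stop_delfrag("fragments are not chemically compatible at their attachment points",
                 "delfrag_assembly_error")
  }
  res
}

# Left-to-right chain assembly used by the sequence decoder; vectorised
# over sequences.  Returns NA where assembly or sanitization fails.
assemble_chain <- function(sequences, allow_open = FALSE) {
  if (!length(sequences)) return(character(0))
  res <- chem_bridge(list(list(
    op = "assemble_chain",
    fragments = lapply(sequences, as.list),
    allow_open = allow_open
  )))[[1]]
  vapply(res, function(x) if (is.null(x)) NA_character_ else x, character(1))
}

#' Number of BRICS fragments of a molecule
#'
#' @param smiles character vector of SMILES.
#' @return integer vector of fragment counts (`NA` for unparseable input).
#' @export
fragment_count <- function(smiles) {
  res <- bridge_cached("fragment", smiles)
  vapply(res, function(x) {
    if (is.null(x)) NA_integer_ else length(x$fragments)
  }, integer(1))
}

#' Junction-tree decomposition of a molecular graph
#'
#' Decomposes a molecule into clusters -- simple rings (smallest set of
#' smallest rings), with rings sharing three or more atoms merged into
#' bridged clusters, plus every non-ring bond, plus singleton atoms at
#' junctions where three or more clusters meet.  Clusters that share atoms
#' are connected in a cluster graph weighted by shared-atom count, and the
#' junction tree is its maximum spanning tree (ties broken by lowest node
#' index pair, so the construction is deterministic).
#'
#' @param smiles a single SMILES string.
#' @return object of class `junction_tree`: list with `nodes` (each a list
#'   with `atoms`, 0-based atom indices, and `label` among `"ring"`,
#'   `"bridged-ring"`, `"bond"`, `"atom"`), `edges` (2-column matrix of
#'   node indices), `smiles`, and `is_tree`.
#' @export
tree_decompose <- function(smiles) {
  stopifnot(length(smiles) == 1L)
  g <- bridge_cached("graph", smiles)[[1]]
  if (is.null(g)) {
    stop_delfrag(sprintf("invalid SMILES: '%s'", smiles),
                 "delfrag_invalid_input")
  }
  rings <- lapply(g$rings, function(r) sort(unlist(r)))
  # merge rings sharing >= 3 atoms (bridged systems), to a fixed point
  labels <- rep("ring", length(rings))
  repeat {
    merged <- FALSE
    if (length(rings) >= 2) {
      for (i in seq_len(length(rings) - 1)) {
        for (j in seq(i + 1, length(rings))) {
          if (length(intersect(rings[[i]], rings[[j]])) >= 3) {
            rings[[i]] <- sort(union(rings[[i]], rings[[j]]))
            labels[i] <- "bridged-ring"
            rings <- rings[-j]
            labels <- labels[-j]
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
    }
    if (!merged) break
  }
  clusters <- rings
  bonds <- g$bonds
  for (b in bonds) {
    b <- unlist(b)
    if (b[3] == 0) {  # non-ring bond
      clusters <- c(clusters, list(sort(b[1:2])))
      labels <- c(labels, "bond")
    }
  }
  if (!length(clusters)) {  # single atom molecule
    clusters <- list(0L)
    labels <- "atom"
  }
  # atoms shared by >= 3 clusters become singleton junction clusters
  atoms <- 0:(g$n - 1)
  membership <- vapply(atoms, function(a) {
    sum(vapply(clusters, function(cl) a %in% cl, logical(1)))
  }, numeric(1))
  for (a in atoms[membership >= 3]) {
    clusters <- c(clusters, list(a))
    labels <- c(labels, "atom")
  }
  # cluster graph: edges between intersecting clusters, weight = overlap
  k <- length(clusters)
  edges <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in seq(i + 1, k)) {
        w <- length(intersect(clusters[[i]], clusters[[j]]))
        if (w >= 1) edges <- rbind(edges, c(i, j, w))
      }
    }
  }
  tree_edges <- max_spanning_tree(k, edges)
  structure(
    list(
      nodes = Map(function(cl, lb) list(atoms = as.integer(cl), label = lb),
                  clusters, labels),
      edges = tree_edges,
      smiles = canonical_smiles(smiles),
      is_tree = nrow(tree_edges) == k - 1L
    ),
    class = "junction_tree"
  )
}

# Kruskal maximum spanning tree; deterministic tie-break on (i, j).
max_spanning_tree <- function(n_nodes, edges) {
  out <- matrix(integer(0), ncol = 2, dimnames = list(NULL, c("from", "to")))
  if (is.null(edges) || !nrow(edges)) return(out)
  ord <- order(-edges[, 3], edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (r in seq_len(nrow(edges))) {
    a <- find(edges[r, 1]); b <- find(edges[r, 2])
    if (a != b) {
      parent[a] <- b
      out <- rbind(out, edges[r, 1:2])
    }
  }
  rownames(out) <- NULL
  out
}

#' @export
print.junction_tree <- function(x, ...) {
  cat("Junction tree of", x$smiles, "\n")
  cat(sprintf("  %d clusters (%s), %d edges, tree: %s\n",
              length(x$nodes),
              paste(names(table(vapply(x$nodes, `[[`, "", "label"))),
                    table(vapply(x$nodes, `[[`, "", "label")),
                    sep = ":", collapse = ", "),
              nrow(x$edges), x$is_tree))
  invisible(x)
}

#' Build the cluster vocabulary of a training set
#'
#' Collects the canonical SMILES of every junction-tree cluster occurring
#' in the input molecules.  Entries are ordered by occurrence count
#' (descending) then lexicographically, and given dense integer ids
#' starting at 0.
#'
#' @param smiles character vector of valid SMILES.
#' @return object of class `cluster_vocabulary`: list with `entries`
#'   (named integer vector, names are cluster SMILES, values ids) and
#'   `counts` (named integer vector).
#' @export
build_cluster_vocabulary <- function(smiles) {
  if (!length(smiles)) {
    stop_delfrag("cannot build a cluster vocabulary from an empty set",
                 "delfrag_empty_vocabulary")
  }
  items <- lapply(smiles, function(s) {
    jt <- tree_decompose(s)
    list(smiles = s,
         clusters = lapply(jt$nodes, function(nd) as.list(nd$atoms)))
  })
  res <- chem_bridge(list(list(op = "cluster_smiles", items = items)))[[1]]
  all_clusters <- unlist(lapply(res, function(r) {
    vapply(r, function(x) if (is.null(x)) NA_character_ else x, character(1))
  }))
  all_clusters <- all_clusters[!is.na(all_clusters)]
  counts <- table(all_clusters)
  ord <- order(-as.integer(counts), names(counts), method = "radix")
  counts <- counts[ord]
  entries <- stats::setNames(seq_along(counts) - 1L, names(counts))
  structure(
    list(entries = entries, counts = as.integer(counts)),
    class = "cluster_vocabulary"
  )
}

#' @export
print.cluster_vocabulary <- function(x, ...) {
  cat("Cluster vocabulary:", length(x$entries), "entries\n")
  show <- utils::head(seq_along(x$entries), 10)
  cat(sprintf("  %3d %s (n=%d)\n", x$entries[show] ,
              names(x$entries)[show], x$counts[show]), sep = "")
  if (length(x$entries) > 10) cat("  ...\n")
  invisible(x)
}

#' Preprocess a molecule dataset
#'
#' Drops unparseable entries (with a message), removes duplicate molecules
#' (by canonical SMILES, keeping the first occurrence) and removes
#' molecules with fewer than two BRICS fragments.  Idempotent.
#'
#' @param smiles character vector of SMILES.
#' @param min_fragments minimum fragment count to keep (default 2).
#' @return character vector of canonical SMILES, in first-occurrence order.
#' @export
preprocess_dataset <- function(smiles, min_fragments = 2L) {
  if (!length(smiles)) return(character(0))
  canon <- canonical_smiles(smiles)
  bad <- sum(is.na(canon))
  if (bad) message(sprintf("preprocess_dataset: dropped %d unparseable entries", bad))
  canon <- canon[!is.na(canon)]
  canon <- canon[!duplicated(canon)]
  if (!length(canon)) return(character(0))
  keep <- fragment_count(canon) >= min_fragments
  canon[keep]
}
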