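# Fragment representation layer: BRICS sequences, reassembly, junction trees.

nafcillin <- "CCOc1ccc2ccccc2c1C(=O)NC1C(=O)N2C1SC(C)(C)C2C(=O)O"

test_that("canonicalization is idempotent and flags invalid input", {
  smis <- c("OCC", "c1ccccc1", "C[C@H](N)C(=O)O")
  canon <- canonical_smiles(smis)
  expect_identical(canonical_smiles(canon), canon)
  expect_true(is.na(canonical_smiles("not-a-molecule")))
  expect_identical(is_valid_smiles(c("CC", "C1CC")), c(TRUE, FALSE))
})

test_that("nafcillin splits into the three expected fragments and reassembles", {
  fs <- brics_fragment(nafcillin)
  expect_s3_class(fs, "fragment_sequence")
  expect_length(fs$fragments, 3)
  got <- canonical_smiles(fs$fragments)
  want <- canonical_smiles(c("*OCC",
                             "*NC(=O)c1c(*)ccc2ccccc12",
                             "*C1C(=O)N2C1SC(C)(C)C2C(=O)O"))
  expect_setequal(got, want)
  expect_identical(reassemble(fs), canonical_smiles(nafcillin))
})

test_that("molecules without cleavable bonds are a single star-free fragment", {
  for (s in c("C", "CC", "c1ccccc1")) {
    fs <- brics_fragment(s)
    expect_length(fs$fragments, 1)
    expect_false(grepl("*", fs$fragments, fixed = TRUE))
    expect_identical(reassemble(fs), canonical_smiles(s))
  }
  expect_error(brics_fragment("C1CC"), class = "delfrag_invalid_input")
})

test_that("fragmentation round-trips over the whole fixture library", {
  fx <- fixture_library(100)
  seqs <- lapply(fx, brics_fragment)
  back <- vapply(seqs, reassemble, character(1))
  expect_identical(back, fx)
  # every non-terminal fragment carries attachment points
  for (fs in seqs[1:20]) {
    expect_true(all(grepl("*", fs$fragments, fixed = TRUE)))
  }
})

test_that("fragment counts agree with direct BRICS bond enumeration", {
  fx <- fixture_library(100)[seq(1, 100, by = 4)]
  expect_identical(fragment_count(fx), as.integer(oracle_fragment_count(fx)))
  expect_identical(fragment_count(nafcillin), 3L)
  expect_identical(fragment_count("CC"), 1L)
  counts <- vapply(fx, function(s) length(brics_fragment(s)$fragments), integer(1))
  expect_identical(unname(counts), fragment_count(fx))
})

test_that("junction trees of simple molecules match hand constructions", {
  benzene <- tree_decompose("c1ccccc1")
  expect_length(benzene$nodes, 1)
  expect_identical(benzene$nodes[[1]]$label, "ring")
  expect_identical(nrow(benzene$edges), 0L)
  expect_true(benzene$is_tree)

  ethane <- tree_decompose("CC")
  expect_length(ethane$nodes, 1)
  expect_identical(ethane$nodes[[1]]$label, "bond")

  norbornane <- tree_decompose("C1CC2CCC1C2")
  labels <- vapply(norbornane$nodes, `[[`, "", "label")
  expect_identical(sum(labels %in% c("ring", "bridged-ring")), 1L)
  expect_identical(labels[labels != "bond"], "bridged-ring")
})

test_that("chlorprothixene decomposes into three ring clusters plus chain bonds", {
  jt <- tree_decompose("CN(C)CCC=C1c2ccccc2Sc2ccc(Cl)cc21")
  labels <- vapply(jt$nodes, `[[`, "", "label")
  expect_identical(sum(labels == "ring"), 3L)
  expect_true(sum(labels == "bond") >= 6)
  expect_true(jt$is_tree)
})

test_that("junction-tree invariants hold across the fixture library", {
  for (s in fixture_library(100)[seq(1, 100, by = 5)]) {
    jt <- tree_decompose(s)
    k <- length(jt$nodes)
    expect_true(jt$is_tree)
    expect_identical(nrow(jt$edges), k - 1L)
    # covering: every atom and every bond inside some cluster
    g <- delfrag:::bridge_cached("graph", s)[[1]]
    cl_atoms <- lapply(jt$nodes, `[[`, "atoms")
    expect_setequal(sort(unique(unlist(cl_atoms))), 0:(g$n - 1))
    for (b in g$bonds) {
      b <- unlist(b)
      holders <- sum(vapply(cl_atoms, function(a) all(b[1:2] %in% a), logical(1)))
      expect_true(holders >= 1)
    }
    # adjacency implies a shared atom
    if (nrow(jt$edges)) {
      for (r in seq_len(nrow(jt$edges))) {
        shared <- intersect(cl_atoms[[jt$edges[r, 1]]], cl_atoms[[jt$edges[r, 2]]])
        expect_true(length(shared) >= 1)
      }
    }
    # merging fixed point: no two ring clusters share >= 3 atoms
    ringish <- which(vapply(jt$nodes, `[[`, "", "label") %in%
                       c("ring", "bridged-ring"))
    if (length(ringish) >= 2) {
      for (i in ringish) for (j in ringish) {
        if (i < j) {
          expect_lt(length(intersect(cl_atoms[[i]], cl_atoms[[j]])), 3)
        }
      }
    }
  }
})

test_that("cluster vocabulary covers its inputs with dense deterministic ids", {
  v1 <- build_cluster_vocabulary("c1ccccc1")
  expect_length(v1$entries, 1)
  v2 <- build_cluster_vocabulary(c("c1ccccc1", "Cc1ccccc1"))
  expect_true(length(v2$entries) >= 2)
  expect_identical(unname(v2$entries), seq_along(v2$entries) - 1L)
  expect_identical(v2$counts, sort(v2$counts, decreasing = TRUE))
  # closure: re-scanning the same input finds no new clusters
  v3 <- build_cluster_vocabulary(c("c1ccccc1", "Cc1ccccc1"))
  expect_identical(v2$entries, v3$entries)
  expect_error(build_cluster_vocabulary(character(0)),
               class = "delfrag_empty_vocabulary")
})

test_that("preprocessing removes duplicates and single-fragment molecules", {
  expect_identical(preprocess_dataset(c(nafcillin, nafcillin, "CC")),
                   canonical_smiles(nafcillin))
  expect_identical(preprocess_dataset(character(0)), character(0))

  fx <- fixture_library(30)
  planted <- c(fx, fx[1:5], rep("CCO", 3), "c1ccccc1")
  expect_message(out <- preprocess_dataset(c(planted, "bad-smiles")),
                 "unparseable")
  expect_identical(out, fx)  # fixtures are canonical and unique already
  expect_identical(preprocess_dataset(out), out)  # idempotent
})
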