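# Molecular graph model: parsing, canonicalization, matching, MCS.

test_that("SMILES parsing reads chains, rings and branches correctly", {
  g <- parse_smiles("CCO")
  expect_equal(heavy_atoms(g), 3L)
  expect_equal(sort(g$elem), c("C", "C", "O"))
  expect_equal(nrow(g$bond), 2L)
  expect_true(all(g$bond[, "order"] == 1L))

  ring <- parse_smiles("C1CC1")
  expect_equal(heavy_atoms(ring), 3L)
  expect_equal(nrow(ring$bond), 3L)
  expect_true(all(ring$bond[, "order"] == 1L))

  # the parser accepts unstable motifs; stability filtering is a
  # space-enumeration concern, not a parsing concern
  expect_equal(heavy_atoms(parse_smiles("COOOC")), 5L)

  gly <- parse_smiles("NCC(=O)O")
  expect_equal(sort(gly$elem), c("C", "C", "N", "O", "O"))
  expect_equal(sort(gly$bond[, "order"]), c(1L, 1L, 1L, 2L))
})

test_that("parse errors are structured and name the offending position", {
  expect_error(parse_smiles("CC("), "unbalanced")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("CQC"), "position 2")
  expect_error(parse_smiles("C(C)(C)(C)(C)C"), "valence.*atom index 1")
  expect_error(parse_smiles("O=C=O=C"), "valence")
})

test_that("aromatic input is kekulized to alternating bond orders", {
  benz <- parse_smiles("c1ccccc1")
  expect_equal(sort(benz$bond[, "order"]), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(mol_to_smiles(benz), canonical_smiles("C1=CC=CC=C1"))

  pyr <- parse_smiles("c1ccncc1")
  expect_equal(sum(pyr$bond[, "order"] == 2L), 3L)

  # pyrrole-type nitrogen carries the H and no double bond
  pyrrole <- parse_smiles("c1cc[nH]c1")
  nb <- bond_order_sums <- rowSums(sapply(seq_len(nrow(pyrrole$bond)),
    function(r) {
      v <- integer(5)
      v[pyrrole$bond[r, 1:2]] <- pyrrole$bond[r, 3]
      v
    }))
  n_idx <- which(pyrrole$elem == "N")
  expect_equal(nb[n_idx], 2)  # two single bonds
  expect_equal(implicit_hydrogens(pyrrole)[n_idx], 1L)

  # odd all-carbon aromatic ring admits no alternating assignment
  expect_error(parse_smiles("c1cccc1"), "kekulize")
})

test_that("charges and explicit hydrogens are normalized away", {
  expect_identical(canonical_smiles("CC(=O)[O-]"), canonical_smiles("CC(=O)O"))
  expect_identical(canonical_smiles("C([H])([H])O"), canonical_smiles("CO"))
})

test_that("multi-component input follows the component argument", {
  expect_error(parse_smiles("CCO.[Na]"), "disconnected")
  g <- parse_smiles("CC(=O)[O-].[Na+]", component = "largest")
  expect_equal(heavy_atoms(g), 4L)
  comps <- parse_smiles("CCO.O", component = "all")
  expect_length(comps, 2L)
})

test_that("canonicalization is a fixed point and invariant to atom order", {
  smis <- c("CCO", "NCC(=O)O", "c1ccccc1", "CC(C)(C)C", "C1CC1O",
            "O=S(=O)(O)O", "c1ccc2ccccc2c1", "CC(=O)OC1=CC=CC=C1C(=O)O")
  for (s in smis) {
    cs <- canonical_smiles(s)
    expect_identical(canonical_smiles(cs), cs)
  }
  set.seed(11)
  for (i in 1:40) {
    g <- random_test_molecule(sample(4:10, 1))
    expect_identical(mol_to_smiles(permute_molgraph(g)), mol_to_smiles(g))
  }
})

test_that("canonical equality agrees with OpenBabel canonical SMILES", {
  smis <- c("CCO", "OCC", "C(C)O", "NCC(=O)O", "C(N)C(O)=O",
            "c1ccccc1", "C1=CC=CC=C1", "CC(C)CC", "CCC(C)C", "CCCCC")
  ob <- sapply(smis, function(s) {
    out <- ChemmineOB::convertFormat("SMI", "CAN", source = s)
    trimws(sub("\t.*$", "", out))
  })
  mine <- sapply(smis, canonical_smiles)
  for (i in seq_along(smis)) for (j in seq_along(smis)) {
    expect_identical(mine[i] == mine[j], ob[i] == ob[j])
  }
})

test_that("valence model matches the allowed states", {
  # S accepts 2, 4 and 6; P accepts 3 and 5
  expect_silent(parse_smiles("CSC"))
  expect_silent(parse_smiles("CS(=O)C"))
  expect_silent(parse_smiles("OS(=O)(=O)O"))
  expect_error(parse_smiles("CS(C)(C)(C)(C)(C)C"), "valence")
  expect_silent(parse_smiles("OP(O)O"))
  expect_silent(parse_smiles("OP(=O)(O)O"))
  expect_equal(implicit_hydrogens(parse_smiles("C"))[1], 4L)
  expect_equal(implicit_hydrogens(parse_smiles("O=S=O")), c(0L, 0L, 0L))
})

test_that("is_subgraph matches the spec examples and the VF2 oracle", {
  expect_true(is_subgraph("CCO", "CCCO"))
  expect_false(is_subgraph("CCN", "CCCO"))
  expect_true(is_subgraph("CC=O", "CC(=O)O"))
  expect_true(is_subgraph("CCC", "C1CC1"))  # non-induced semantics
  expect_false(is_subgraph("CC=O", "CCO"))  # bond order must match

  set.seed(23)
  for (i in 1:60) {
    pat <- random_test_molecule(sample(2:5, 1))
    tgt <- random_test_molecule(sample(4:9, 1))
    expect_identical(is_subgraph(pat, tgt), oracle_is_subgraph(pat, tgt),
                     info = paste(mol_to_smiles(pat), "in", mol_to_smiles(tgt)))
  }
})

test_that("count_embeddings counts distinct atom/bond subsets", {
  expect_equal(count_embeddings("CCC", "CCCCC"), 3L)
  expect_equal(count_embeddings("CCCO", "CCCO"), 1L)
  expect_equal(count_embeddings("CC=O", "CC(=O)C"), 2L)
  # symmetric pattern in symmetric target still counted per subset
  expect_equal(count_embeddings("CC", "CCC"), 2L)
  expect_equal(count_embeddings("C1CC1", "C1CC1"), 1L)

  set.seed(31)
  for (i in 1:40) {
    pat <- random_test_molecule(sample(2:4, 1))
    tgt <- random_test_molecule(sample(4:8, 1))
    mine <- count_embeddings(pat, tgt)
    expect_identical(mine, oracle_count_embeddings(pat, tgt),
                     info = paste(mol_to_smiles(pat), "in", mol_to_smiles(tgt)))
    expect_identical(mine >= 1L, is_subgraph(pat, tgt))
  }
})

test_that("maximum common subgraph matches examples and brute force", {
  m <- max_common_subgraph("CCCO", "CCCN")
  expect_identical(mol_to_smiles(m), canonical_smiles("CCC"))
  g <- parse_smiles("NCC(=O)O")
  expect_identical(mol_to_smiles(max_common_subgraph(g, g)), mol_to_smiles(g))
  expect_equal(heavy_atoms(max_common_subgraph("C", "O")), 0L)

  set.seed(41)
  for (i in 1:25) {
    a <- random_test_molecule(sample(3:8, 1))
    b <- random_test_molecule(sample(3:8, 1))
    m <- max_common_subgraph(a, b)
    if (heavy_atoms(m) > 0L) {
      expect_true(is_subgraph(m, a))
      expect_true(is_subgraph(m, b))
    }
    expect_equal(heavy_atoms(m), oracle_mcs_size(a, b),
                 info = paste(mol_to_smiles(a), "|", mol_to_smiles(b)))
    expect_equal(mcs_size(b, a), heavy_atoms(m))  # symmetry
  }
})
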