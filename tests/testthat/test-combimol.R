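# Chemical-space enumeration: exhaustiveness, filters, sampling.

spec_c_acyclic <- function(n) {
  chem_space_spec(elements = "C", max_size = n, bond_orders = 1L,
                  rings = FALSE, banned = character(0))
}

test_that("saturated acyclic carbon counts match the Pruefer tree oracle", {
  space <- enumerate_space(spec_c_acyclic(7L))
  counts <- as.integer(table(factor(space$heavy_atoms, levels = 1:7)))
  expect_equal(counts, c(1L, 1L, 1L, 2L, 3L, 5L, 9L))
  expect_equal(counts, vapply(1:7, oracle_alkane_count, integer(1)))
})

test_that("small spaces enumerate exactly the expected molecules", {
  # C, max 2, single bonds: methane + ethane
  sp <- enumerate_space(chem_space_spec(elements = "C", max_size = 2L,
                                        bond_orders = 1L, rings = FALSE,
                                        banned = character(0)))
  expect_setequal(sp$smiles, c("C", "CC"))

  # O, max 2, orders 1-2: water, peroxide, dioxygen
  sp <- enumerate_space(chem_space_spec(elements = "O", max_size = 2L,
                                        bond_orders = c(1L, 2L),
                                        banned = character(0)))
  expect_setequal(sp$smiles, c("O", "OO", "O=O"))

  # exactly five carbons, acyclic saturated: the three pentane isomers
  sp <- enumerate_space(spec_c_acyclic(5L))
  expect_setequal(sp$smiles[sp$heavy_atoms == 5L],
                  sapply(c("CCCCC", "CC(C)CC", "CC(C)(C)C"),
                         canonical_smiles, USE.NAMES = FALSE))
})

test_that("everything emitted re-parses and canonicalizes to itself", {
  sp <- enumerate_space(chem_space_spec(elements = c("C", "O"), max_size = 4L,
                                        bond_orders = c(1L, 2L), rings = TRUE,
                                        banned = character(0)))
  expect_false(any(duplicated(sp$smiles)))
  for (s in sp$smiles) expect_identical(canonical_smiles(s), s)
})

test_that("ring policy and quaternary centres are honoured", {
  sp <- enumerate_space(chem_space_spec(elements = "C", max_size = 5L,
                                        bond_orders = 1L, rings = TRUE,
                                        banned = character(0)))
  # cyclic structures present when rings allowed
  expect_true(canonical_smiles("C1CC1") %in% sp$smiles)
  # neopentane's quaternary carbon is not under-represented
  expect_true(canonical_smiles("CC(C)(C)C") %in% sp$smiles)
  # acyclic-only space contains no rings
  sp2 <- enumerate_space(spec_c_acyclic(5L))
  expect_false(canonical_smiles("C1CC1") %in% sp2$smiles)
  # min_ring_size excludes small rings
  sp3 <- enumerate_space(chem_space_spec(elements = "C", max_size = 5L,
                                         bond_orders = 1L, rings = TRUE,
                                         min_ring_size = 5L,
                                         banned = character(0)))
  expect_false(canonical_smiles("C1CC1") %in% sp3$smiles)
  expect_true(canonical_smiles("C1CCCC1") %in% sp3$smiles)
})

test_that("stability filters remove banned substructures and are idempotent", {
  mols <- mol_set(c(a = "COOOC", b = "CCO", c = "CCOC"))
  out <- apply_stability_filters(mols, c("OOO"))
  expect_setequal(out$id, c("b", "c"))
  expect_identical(apply_stability_filters(out, c("OOO")), out)
  # empty ban list is the identity
  expect_identical(apply_stability_filters(mols, character(0)),
                   tibble::as_tibble(mols))
  # direct self-match empties the set
  expect_equal(nrow(apply_stability_filters(mol_set("CCO"), "CCO")), 0L)
  # default bans exclude COOOC from an enumerated space
  sp <- enumerate_space(chem_space_spec(elements = c("C", "O"), max_size = 5L,
                                        bond_orders = 1L, rings = FALSE))
  expect_false(canonical_smiles("COOOC") %in% sp$smiles)
  expect_true(canonical_smiles("COOC") %in% sp$smiles)
})

test_that("enlarging max_size never removes previously enumerated molecules", {
  s4 <- enumerate_space(chem_space_spec(elements = c("C", "N"), max_size = 4L,
                                        bond_orders = c(1L, 2L)))
  s5 <- enumerate_space(chem_space_spec(elements = c("C", "N"), max_size = 5L,
                                        bond_orders = c(1L, 2L)))
  expect_true(all(s4$smiles %in% s5$smiles))
})

test_that("enumeration refuses specs beyond the safety cap", {
  expect_error(enumerate_space(chem_space_spec(elements = "C", max_size = 12L)),
               "cap")
})

test_that("sulfur above S(II) requires a sulfone/sulfate context", {
  sp <- enumerate_space(chem_space_spec(elements = c("O", "S"), max_size = 5L,
                                        bond_orders = c(1L, 2L),
                                        banned = character(0)))
  expect_true(canonical_smiles("OS(=O)(=O)O") %in% sp$smiles)  # sulfate
  expect_true(canonical_smiles("OSO") %in% sp$smiles)           # S(II)
  expect_false(canonical_smiles("O=S=O") %in% sp$smiles)        # bare S(IV)
})

test_that("sample_space is deterministic, supported and near-uniform", {
  spec <- spec_c_acyclic(5L)
  s1 <- sample_space(spec, 20L, seed = 99L)
  s2 <- sample_space(spec, 20L, seed = 99L)
  expect_identical(s1, s2)

  tiny <- chem_space_spec(elements = "C", max_size = 2L, bond_orders = 1L,
                          rings = FALSE, banned = character(0))
  draws <- sample_space(tiny, 50L, seed = 3L)
  expect_true(all(draws$smiles %in% c("C", "CC")))

  # 1000 draws from the 8-molecule C<=5 acyclic space: each frequency
  # within 3 binomial sigma of uniform
  space <- enumerate_space(spec)
  expect_equal(nrow(space), 8L)
  big <- sample_space(spec, 1000L, seed = 17L)
  p <- 1 / 8
  sigma <- sqrt(1000 * p * (1 - p))
  freq <- table(factor(big$smiles, levels = space$smiles))
  expect_true(all(abs(freq - 1000 * p) <= 3 * sigma))
})
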