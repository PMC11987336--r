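# SMILES toolkit: parsing, canonicalization, matching, fingerprints.

test_that("parser counts atoms, hydrogens and components correctly", {
  m <- parse_smiles("CCO")
  expect_equal(m$n_atoms, 3L)
  expect_equal(m$nH, c(3L, 2L, 1L))

  benz <- parse_smiles("c1ccccc1")
  expect_equal(benz$n_atoms, 6L)
  expect_true(all(benz$arom))
  expect_true(all(benz$in_ring))
  expect_equal(benz$nH, rep(1L, 6))
  expect_true(all(vapply(benz$ring_sizes, function(s) 6 %in% s, TRUE)))

  expect_equal(mol_components(parse_smiles("CCO")), 1L)
  expect_equal(length(parse_molecule_set("CCO.CC")), 2L)

  amm <- parse_smiles("[NH4+]")
  expect_equal(amm$charge, 1L)
  expect_equal(amm$nH, 4L)

  expect_error(parse_smiles("C(Q)C"), "unrecognized")
  expect_error(parse_smiles("C1CC"), "unclosed ring")
  expect_error(parse_smiles("C(CC"), "unbalanced")
})

test_that("directional bonds are perceived as E/Z", {
  trans <- parse_smiles("C/C=C/C")
  cis <- parse_smiles("C/C=C\\C")
  get_stereo <- function(m) m$bstereo[m$order == 2 & !m$barom]
  expect_equal(get_stereo(trans), "E")
  expect_equal(get_stereo(cis), "Z")
  expect_equal(get_stereo(parse_smiles("CC=CC")), "")
})

test_that("canonical SMILES is invariant to input spelling", {
  same <- list(
    c("CCO", "OCC", "C(O)C"),
    c("CC(=O)OCC", "CCOC(C)=O", "O=C(C)OCC"),
    c("c1ccc(Cl)cc1", "Clc1ccccc1", "c1cc(Cl)ccc1"),
    c("CC(C)(C)O", "OC(C)(C)C"),
    c("N#Cc1ccccc1C", "Cc1ccccc1C#N"),
    c("CC(=O)[O-]", "[O-]C(=O)C"))
  for (grp in same) {
    canon <- vapply(grp, canonical_smiles, "")
    expect_length(unique(canon), 1L)
  }
  # distinct molecules stay distinct
  expect_false(canonical_smiles("CCO") == canonical_smiles("CCN"))
  expect_false(canonical_smiles("CCC") == canonical_smiles("CC(C)C"))
})

test_that("canonical SMILES round-trips through the parser", {
  for (s in c("CCO", "c1ccccc1", "CC(=O)OCC", "C1CC1CC2CCC2",
              "FC(F)(F)c1ccc(Br)cc1", "OS(=O)(=O)O", "c1ccc2ccccc2c1",
              "CCN(CC)CC", "[Na+]", "CC#N", "C(Cl)CC(=O)NCC")) {
    canon <- canonical_smiles(s)
    expect_identical(canonical_smiles(canon), canon)
  }
})

test_that("substructure matching is a monomorphism test", {
  expect_true(has_substructure("c1ccccc1", "Cc1ccccc1"))
  expect_true(has_substructure("CCO", "CCOC(C)=O"))
  expect_false(has_substructure("Cc1ccccc1", "c1ccccc1"))   # too big
  expect_false(has_substructure("CCN", "CCOC(C)=O"))
  expect_true(has_substructure("C(F)C", "CC(F)COC"))
  # aromatic pattern does not match aliphatic ring
  expect_false(has_substructure("c1ccccc1", "C1CCCCC1"))
  expect_true(set_has_substructure("CO", "CCN.CCOC"))
  expect_false(set_has_substructure("Br", "CCN.CCOC"))
})

test_that("halogen sets and fingerprints behave", {
  expect_equal(mol_halogen_set(parse_smiles("FC(Cl)Br")),
               c("Br", "Cl", "F"))
  expect_equal(mol_halogen_set(parse_smiles("CCO")), character(0))

  expect_equal(tanimoto(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  # set-arithmetic oracle on explicit bit sets
  a <- c(1, 5, 9, 12); b <- c(5, 9, 20)
  expect_equal(tanimoto(a, b), length(intersect(a, b)) / length(union(a, b)))

  # fingerprints are canonical-spelling invariant and discriminate molecules
  expect_identical(circular_fingerprint("CCOC(C)=O"),
                   circular_fingerprint("CC(=O)OCC"))
  expect_gt(length(setdiff(circular_fingerprint("CCO"),
                           circular_fingerprint("CCN"))), 0L)
  expect_equal(max_tanimoto("CCO", c("CCN", "CCO")), 1)
})
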