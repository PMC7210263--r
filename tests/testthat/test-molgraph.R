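test_that("construction validates atoms and bonds", {
  g <- mol_graph(c("O", "H", "H"), rbind(c(1, 2), c(3, 1)))
  expect_equal(n_atoms(g), 3)
  expect_equal(g$bonds, matrix(c(1L, 1L, 2L, 3L), ncol = 2,
                               dimnames = list(NULL, c("i", "j"))))
  expect_error(mol_graph(c("S", "H")), class = "rxnforge_unsupported_element")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 1))), class = "rxnforge_error")
  expect_error(mol_graph(c("C", "C"), rbind(c(1, 2), c(2, 1))),
               class = "rxnforge_error")
  expect_error(mol_graph("C", rbind(c(1, 2))), class = "rxnforge_error")
})

test_that("symmetry classes match chemical equivalence on anchor molecules", {
  methane <- mol_from_smiles("C")
  cl <- symmetry_classes(methane)
  expect_length(unique(cl[methane$elements == "H"]), 1)
  expect_false(cl[1] %in% cl[-1])

  methanol <- mol_from_smiles("CO")
  cl <- symmetry_classes(methanol)
  h_on_c <- which(methanol$elements == "H" &
                    vapply(seq_len(n_atoms(methanol)), function(a) {
                      any(methanol$bonds[methanol$bonds[, 1] == a, 2] == 1) ||
                        any(methanol$bonds[methanol$bonds[, 2] == a, 1] == 1)
                    }, logical(1)))
  h_on_o <- setdiff(which(methanol$elements == "H"), h_on_c)
  expect_length(unique(cl[h_on_c]), 1)
  expect_false(cl[h_on_o] %in% cl[h_on_c])

  ethane <- mol_from_smiles("CC")
  cl <- symmetry_classes(ethane)
  expect_length(unique(cl[ethane$elements == "H"]), 1)
})

test_that("symmetry classes agree with brute-force automorphism orbits", {
  for (smi in c("C", "O", "CC", "CO", "C=O", "[H][H]", "NN", "OO")) {
    g <- mol_from_smiles(smi)   # all <= 8 atoms, so brute force is exact
    expect_equal(symmetry_classes(g), brute_orbits(g), label = smi)
  }
})

test_that("symmetry classes are relabeling-invariant and element-pure", {
  for (smi in c("CC", "CCO", "CC=O", "C1CCC1")) {
    g <- mol_from_smiles(smi)
    cl <- symmetry_classes(g)
    # no class mixes elements
    expect_true(all(tapply(g$elements, cl, function(e) length(unique(e))) == 1))
    for (s in 1:10) {
      p <- random_permutation(g, 100 * s)
      gp <- permute_atoms(g, p)
      clp <- symmetry_classes(gp)
      # permuting indices permutes classes: partition must transport along p
      expect_equal(outer(clp[p], clp[p], "=="), outer(cl, cl, "=="),
                   label = paste(smi, s))
    }
  }
})

test_that("apply_changes performs exact set arithmetic and validates", {
  w <- mol_graph(c("O", "H", "H"), rbind(c(1, 2), c(1, 3)))
  out <- apply_changes(w, breaks = rbind(c(1, 2)), forms = rbind(c(2, 3)))
  expect_equal(out$bonds, matrix(c(1L, 2L, 3L, 3L), ncol = 2,
                                 dimnames = list(NULL, c("i", "j"))))
  expect_equal(apply_changes(w)$bonds, w$bonds)
  expect_error(apply_changes(w, forms = rbind(c(1, 2))),
               class = "rxnforge_invalid_change")
  expect_error(apply_changes(w, breaks = rbind(c(2, 3))),
               class = "rxnforge_invalid_change")
})

test_that("apply_changes then bond_changes recovers the applied sets", {
  set.seed(42)
  for (smi in c("CC", "CCO", "CC(C)C", "CCN")) {
    g <- mol_from_smiles(smi)
    nb <- nonbonded_pairs_for_test(g)
    for (rep in 1:5) {
      br <- g$bonds[sample(nrow(g$bonds), 2), , drop = FALSE]
      fm <- nb[sample(nrow(nb), 1), , drop = FALSE]
      prod <- apply_changes(g, br, fm)
      ch <- bond_changes(g, prod)
      expect_equal(bond_key_vec(ch$broken), bond_key_vec(br))
      expect_equal(bond_key_vec(ch$formed), bond_key_vec(fm))
    }
  }
})

test_that("valence feasibility follows the element degree limits", {
  # carbon with one neighbor: below carbon minimum of two
  expect_false(is_valence_feasible(mol_graph(c("C", "H"), rbind(c(1, 2)))))
  # water: oxygen degree two, hydrogens degree one
  expect_true(is_valence_feasible(mol_graph(c("O", "H", "H"),
                                            rbind(c(1, 2), c(1, 3)))))
  # nitrogen with four neighbors: above nitrogen maximum of three
  expect_false(is_valence_feasible(
    mol_graph(c("N", "H", "H", "H", "H"),
              rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)))))
})

test_that("connectivity isomorphism finds maps and respects tie-breaking", {
  g <- mol_from_smiles("CO")
  expect_equal(connectivity_isomorphism(g, g)[1:2], c(1L, 2L))
  # permuted copy: composed map must be an automorphism of g
  for (s in 1:10) {
    p <- random_permutation(g, s)
    gp <- permute_atoms(g, p)
    phi <- connectivity_isomorphism(g, gp)
    expect_false(is.null(phi))
    expect_true(adjacency_preserved(g, gp, phi))
    # lexicographically smallest image sequence among all brute-force maps
    all_maps <- brute_isomorphisms(g, gp)
    seqs <- do.call(rbind, all_maps)
    expect_equal(phi, all_maps[[order_of_rows(seqs)[1]]])
  }
  expect_null(connectivity_isomorphism(mol_from_smiles("CN"),
                                       mol_from_smiles("CO")))
})

test_that("bond_changes rejects mismatched atom spaces", {
  expect_error(bond_changes(mol_from_smiles("C"), mol_from_smiles("CC")),
               class = "rxnforge_mapping_mismatch")
  g <- mol_from_smiles("O")
  expect_equal(nrow(bond_changes(g, g)$broken), 0)
  expect_equal(nrow(bond_changes(g, g)$formed), 0)
})

test_that("fragments preserves atoms and parent indices", {
  g <- mol_from_smiles("O.[H][H]")
  frs <- fragments(g)
  expect_length(frs, 2)
  all_idx <- sort(unlist(lapply(frs, attr, "parent_indices")))
  expect_equal(all_idx, seq_len(n_atoms(g)))
})
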