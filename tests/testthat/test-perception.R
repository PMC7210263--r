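test_that("covalent-radius connectivity follows the pinned radii table", {
  # O-H at 0.96 A: 0.96 <= 1.2 * (0.66 + 0.31) = 1.164 -> bonded
  g <- perceive_connectivity(c("O", "H"), rbind(c(0, 0, 0), c(0.96, 0, 0)))
  expect_equal(nrow(g$bonds), 1)
  # two hydrogens 2.0 A apart: 2.0 > 1.2 * 0.62 -> not bonded
  g2 <- perceive_connectivity(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(nrow(g2$bonds), 0)
  expect_error(
    perceive_connectivity(c("H", "H"), rbind(c(0, 0, 0), c(0.2, 0, 0))),
    class = "rxnforge_geometry")
})

test_that("bond orders maximize valence saturation", {
  expect_equal(assign_bond_orders(mol_from_smiles("CC")), rep(1L, 7))
  # ethylene connectivity: the unique saturating assignment is C=C
  ethylene <- mol_graph(c("C", "C", "H", "H", "H", "H"),
                        rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 5), c(2, 6)))
  expect_equal(assign_bond_orders(ethylene), c(2L, 1L, 1L, 1L, 1L))
  # ethyl radical: leftover unsaturation stays radical, C-C stays single
  ethyl <- mol_graph(c("C", "C", "H", "H", "H", "H", "H"),
                     rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(2, 6), c(2, 7)))
  expect_equal(assign_bond_orders(ethyl), rep(1L, 6))
})

test_that("bond orders agree with exhaustive assignment search", {
  for (smi in c("CC", "C=C", "C#C", "C=O", "N=N", "C#N", "C=CC")) {
    g <- mol_from_smiles(smi)
    got <- assign_bond_orders(g)
    oracle <- brute_order_assignments(g)
    expect_equal(sum(got - 1L) * 2L, oracle$best, label = smi)
    expect_true(any(vapply(oracle$assignments, function(a) {
      all(unname(a) == got)
    }, logical(1))), label = smi)
  }
})

test_that("identity keys are canonical, tautomer-distinguishing, stable", {
  for (smi in c("CO", "CC=O", "C1=CC=CC=C1")) {
    g <- mol_from_smiles(smi)
    k0 <- identity_key(g)
    for (s in 1:25) {
      gp <- permute_atoms(g, random_permutation(g, 900 + s))
      expect_identical(identity_key(gp), k0, label = smi)
    }
  }
  # keto/enol: same formula, different hydrogen placement, different keys
  expect_false(identical(identity_key(mol_from_smiles("CC=O")),
                         identity_key(mol_from_smiles("C=CO"))))
  # any geometry of water perceives to the same key
  w1 <- perceive_molecule(c("O", "H", "H"),
                          rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)))
  w2 <- perceive_molecule(c("H", "O", "H"),
                          rbind(c(0.97, 0, 0), c(0, 0, 0), c(-0.3, 0.91, 0)))
  expect_identical(w1$identity_key, w2$identity_key)
})

test_that("identity key equivalence matches an independent InChI backend", {
  # obabel with the fixed-hydrogen option is an independent oracle for the
  # induced equivalence classes (not for the string itself)
  smis <- c("CC=O", "C=CO", "CO", "OCC", "CC(=O)O", "O")
  inchis <- vapply(smis, function(s) {
    out <- suppressWarnings(system2("obabel",
                                    c(paste0("-:", s), "-oinchi", "-xF"),
                                    stdout = TRUE, stderr = FALSE))
    paste(grep("^InChI=", out, value = TRUE), collapse = "")
  }, character(1))
  keys <- vapply(smis, function(s) identity_key(mol_from_smiles(s)),
                 character(1))
  same_inchi <- outer(inchis, inchis, "==")
  same_key <- outer(keys, keys, "==")
  expect_equal(same_key, same_inchi)
})

test_that("atom maps are reconstructed through graph isomorphism", {
  w <- mol_from_smiles("O")
  pm <- perceive_molecule(w$elements, embed_geometry(w, seed = 2))
  smi <- atom_mapped_smiles(pm, w)
  back <- mapped_graph(smi)
  expect_identical(bond_key_vec(back$graph$bonds), bond_key_vec(w$bonds))
  expect_equal(back$map, 1:3)
  # permuted methane: parse-back reproduces the original up to automorphism
  m <- mol_from_smiles("C")
  for (s in 1:5) {
    p <- random_permutation(m, 40 + s)
    mp <- permute_atoms(m, p)
    pm <- list(graph = mp, orders = rep(1L, 4))
    class(pm) <- "perceived_mol"
    smi <- atom_mapped_smiles(pm, m)
    back <- mapped_graph(smi)
    expect_identical(back$graph$elements, m$elements)
    expect_identical(bond_key_vec(back$graph$bonds), bond_key_vec(m$bonds))
  }
  expect_error(atom_mapped_smiles(list(graph = mol_from_smiles("CO"),
                                       orders = NULL), mol_from_smiles("CN")),
               class = "rxnforge_mapping_failure")
})

test_that("reaction SMILES conserve the atom map", {
  g <- mol_from_smiles("C")
  sets <- enumerate_driving_coordinates(g)
  pg <- apply_changes(g, sets$breaks[[1]], sets$forms[[1]])
  frs <- fragments(pg)
  frs_p <- lapply(frs, function(fr) {
    structure(list(graph = fr, orders = assign_bond_orders(fr)),
              class = "perceived_mol")
  })
  rp <- perceive_molecule(g$elements, embed_geometry(g, seed = 4))
  smis <- reaction_smiles(rp, frs_p, g, frs)
  r_maps <- mapped_graph(smis$rsmi)$map
  p_maps <- mapped_graph(smis$psmi)$map
  expect_equal(sort(p_maps), sort(r_maps))
  expect_equal(length(strsplit(smis$psmi, ".", fixed = TRUE)[[1]]), 2)
  # a product missing an atom is rejected
  expect_error(reaction_smiles(rp, frs_p[1], g, frs[1]),
               class = "rxnforge_mapping_failure")
})

test_that("geometry -> perception round-trip recovers the source identity", {
  for (smi in c("C", "CC", "CO", "C=O", "CCO", "C1CC1")) {
    g <- mol_from_smiles(smi)
    xyz <- embed_geometry(g, seed = 11)
    pm <- perceive_molecule(g$elements, xyz, charges = g$charges)
    expect_identical(pm$identity_key, identity_key(g), label = smi)
  }
})

test_that("TS geometries are never perceived implicitly by the pipeline", {
  # the perception entry points require explicit geometry; this guards the
  # contract that identity applies only to minima (no perceive call takes
  # an optfreq TS record)
  expect_error(perceive_molecule(c("H", "H"), matrix(c(0, 0, 0, NA, 0, 0), 2, 3)),
               class = "rxnforge_geometry")
})
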