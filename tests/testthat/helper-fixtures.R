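# Fixture molecules, built in code from SMILES (explicit-H graphs).

# ~25 molecules with <= 4 heavy atoms (enumeration / oracle fixtures)
fixture_smiles_small <- function() {
  c("C", "N", "O",
    "[H][H]",
    "CC", "C=C", "C#C", "CN", "CO", "C=O", "NN", "N=N", "NO", "OO", "C#N",
    "CCC", "CCO", "CC=O", "COC", "CNC", "CCN", "C=CC", "OCO", "NC=O",
    "CCCC", "CC(C)C", "C1CCC1")
}

# ~40 molecules for perception round-trips (up to 7 heavy atoms)
fixture_smiles_perception <- function() {
  c(fixture_smiles_small(),
    "CC(C)O", "CC(=O)C", "CC(=O)O", "CCCCC", "CCOC", "CCNC",
    "C1CC1", "C1COC1", "C1CCNC1",
    "C1=CC=CC=C1", "C1=CC=CO1", "C1=CC=CC=N1",
    "NCC=O", "OCC=O", "CC#N")
}

# a deterministic random element-preserving permutation
random_permutation <- function(g, seed) {
  set.seed(seed)
  sample(n_atoms(g))
}

# stable small seed from a fixture label
derive_seed_for_test <- function(key) {
  sum(utf8ToInt(key) * seq_along(utf8ToInt(key))) %% 100000L + 1L
}
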