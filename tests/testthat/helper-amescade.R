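# Shared fixtures, oracles and graph utilities for the test suite.

# cache expensive objects across test files within one run
.cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.cache[[key]])) .cache[[key]] <- builder()
  .cache[[key]]
}

# small labelled fixture set + fitted cascade, reused by several files
small_fixture <- function() cached("small_fixture", function() {
  generate_molecules(fixture_spec(n = 150, seed = 101))
})

small_fit <- function() cached("small_fit", function() {
  ames_cascade(small_fixture(), seed = 101)
})

default_rulebase <- function() cached("rulebase", function() load_rulebase())

# 2-D separable Gaussian clouds for the SVM layer tests
make_clouds <- function(n = 100, sep = 3, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(n), ncol = 2),
             matrix(rnorm(n, mean = sep), ncol = 2))
  colnames(x) <- c("d1", "d2")
  list(x = x, y = rep(c("mutagen", "nonmutagen"), each = n / 2))
}

# apply a random atom renumbering to a mol_graph (invariance tests)
permute_graph <- function(g, seed = 1) {
  set.seed(seed)
  pos <- sample(g$n_atoms)                 # old atom i becomes atom pos[i]
  inv <- order(pos)
  bonds <- g$bonds
  bonds$a1 <- pos[g$bonds$a1]
  bonds$a2 <- pos[g$bonds$a2]
  structure(list(n_atoms = g$n_atoms,
                 element = g$element[inv],
                 aromatic = g$aromatic[inv],
                 charge = g$charge[inv],
                 nh = g$nh[inv],
                 bonds = bonds,
                 fragment = g$fragment[inv]),
            class = "mol_graph")
}

as_graph <- function(smiles) amescade:::.as_graph(smiles)

# 20+ molecule oracle panel; reference E-state minima and atom-contribution
# logP values computed with RDKit 2024.09.2 (Chem.EState.EStateIndices,
# Crippen.MolLogP), ring counts by definition
oracle_panel <- function() {
  data.frame(
    name = c("ethane", "propane", "isobutane", "neopentane", "benzene",
             "toluene", "naphthalene", "anthracene", "phenol", "ethanol",
             "acetic_acid", "acetone", "diethyl_ether", "nitrobenzene",
             "aniline", "pyridine", "furan", "thiophene", "ethylene_oxide",
             "chlorobutane", "chloroform", "nitrosodimethylamine"),
    smiles = c("CC", "CCC", "CC(C)C", "CC(C)(C)C", "c1ccccc1", "Cc1ccccc1",
               "c1ccc2ccccc2c1", "c1ccc2cc3ccccc3cc2c1", "Oc1ccccc1", "CCO",
               "CC(=O)O", "CC(C)=O", "CCOCC", "c1ccccc1[N+](=O)[O-]",
               "Nc1ccccc1", "c1ccncc1", "c1ccoc1", "c1ccsc1", "C1CO1",
               "CCCCCl", "ClC(Cl)Cl", "CN(C)N=O"),
    logp = c(1.02620, 1.41630, 1.66230, 2.05240, 1.68660, 1.99502, 2.83980,
             3.99300, 1.39220, -0.00140, 0.09090, 0.59530, 1.04280, 1.59480,
             1.26880, 1.08160, 1.27960, 1.74810, 0.01660, 2.02530, 1.98640,
             0.22940),
    gmin = c(2.0, 1.25, 0.8333333, 0.5, 2.0, 1.3217593, 1.3101852,
             1.3112963, 0.3217593, 0.25, -0.8333333, 0.1666667, 0.84375,
             -0.4166667, 0.8217593, 1.75, 1.625, 1.7129630, 1.0, 0.8159722,
             -0.75, 1.1944444),
    nrings = c(0L, 0L, 0L, 0L, 1L, 1L, 2L, 3L, 1L, 0L, 0L, 0L, 0L, 1L, 1L,
               1L, 1L, 1L, 1L, 0L, 0L, 0L),
    stringsAsFactors = FALSE)
}

# full E-state vectors (same RDKit reference) for three panel members
oracle_estate <- function() {
  list(propane = c(2.125, 1.25, 2.125),
       ethanol = c(1.6805556, 0.25, 7.5694444),
       nitrobenzene = c(1.4583333, 1.6370370, 1.7430556, 1.6370370,
                        1.4583333, 0.1365741, -0.4166667, 10.0064815,
                        10.0064815))
}
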