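test_that("E-state indices match hand evaluation of the Kier-Hall formulas", {
  # ethane: both carbons delta = 1, delta_v = 3, I = (3+1)/1 ... wait
  # CH3 carbon: delta_v = 4 - 3 = 1, I = (1+1)/1 = 2; no perturbation
  es <- estate_indices("CC")
  expect_equal(es$S, c(2, 2))
  # propane: terminal I = 2, central CH2 I = (2+1)/2 = 1.5
  # S(terminal) = 2 + 0/4 + 0.5/9... hand: 2 + (2-2)/9 + (2-1.5)/4 = 2.125
  es3 <- estate_indices("CCC")
  expect_equal(es3$I, c(2, 1.5, 2))
  expect_equal(es3$S, c(2.125, 1.25, 2.125))
  expect_equal(gmin("CC"), 2)
  expect_equal(gmin("CCC"), 1.25)
})

test_that("symmetric atoms receive equal E-state values", {
  for (smi in c("c1ccccc1", "CC(C)(C)C", "ClC(Cl)Cl", "CCOCC")) {
    s <- estate_indices(smi)$S
    expect_true(length(unique(round(s[duplicated(round(s, 9))], 9))) <=
                  length(unique(round(s, 9))))
  }
  expect_equal(length(unique(estate_indices("c1ccccc1")$S)), 1L)
  s <- estate_indices("CCOCC")$S
  expect_equal(s[1], s[5])
  expect_equal(s[2], s[4])
})

test_that("E-state perturbations cancel pairwise: sum(S) == sum(I)", {
  ms <- generate_molecules(fixture_spec(n = 40, seed = 9))
  for (g in ms$graphs) {
    es <- estate_indices(g)
    expect_equal(sum(es$S), sum(es$I), tolerance = 1e-10)
  }
})

test_that("single-heavy-atom molecules are handled, not divided by zero", {
  es <- estate_indices("C")
  expect_true(is.finite(es$S))
  expect_true(attr(es, "single_atom"))
  expect_true(is.finite(gmin("C")))
  expect_equal(idwbar("C"), 0)
})

test_that("idwbar matches hand evaluation of the distance distribution", {
  expect_equal(idwbar("CC"), 0)           # single pair at distance 1
  expect_equal(idwbar("CCC"), 1.5)        # (4*2 - 2*1)/4
  # isobutane: g1 = 3, g2 = 3, W = 9 -> (9*log2(9) - 6)/9
  expect_equal(idwbar("CC(C)C"), (9 * log2(9) - 6) / 9, tolerance = 1e-9)
  # equality-based variant: propane has 2 pairs at d=1, 1 pair at d=2
  p <- c(2, 1) / 3
  expect_equal(idwbar("CCC", variant = "equality"), -sum(p * log2(p)))
})

test_that("nrings is the cyclomatic number", {
  expect_identical(nrings("CCC"), 0L)
  expect_identical(nrings("c1ccccc1"), 1L)
  expect_identical(nrings("c1ccc2ccccc2c1"), 2L)   # 11 bonds - 10 atoms + 1
  expect_identical(nrings("C1CC1.C1CC1"), 2L)      # two components
})

test_that("atom-type counts follow the configured fragment table", {
  expect_identical(atom_type_counts("CCC")[["sCH3"]], 2L)
  expect_identical(atom_type_counts("CCC")[["ssCH2"]], 1L)
  expect_identical(atom_type_counts("c1ccccc1")[["aaCH"]], 6L)
  expect_identical(atom_type_counts("CCO")[["sOH"]], 1L)
  # each atom maps to at most one type
  counts <- atom_type_counts("Cc1ccc(O)cc1")
  expect_true(sum(counts) <= as_graph("Cc1ccc(O)cc1")$n_atoms)
})

test_that("overlapping or duplicated atom-type definitions are load errors", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("- {name: t1, element: C, aromatic: false, nh: 3, single: 1}",
               "- {name: t2, element: C, aromatic: false, nh: 3, single: 1}"),
             tf)
  expect_error(load_atom_types(tf), "overlapping")
  tf2 <- tempfile(fileext = ".yaml")
  writeLines(c("- {name: t1, element: C, aromatic: false, nh: 3, single: 1}",
               "- {name: t1, element: O, aromatic: false, nh: 1, single: 1}"),
             tf2)
  expect_error(load_atom_types(tf2), "duplicate")
})

test_that("ALOGP is additive over fragments and ranks O-for-C substitution", {
  expect_equal(alogp("CC.CCO"), alogp("CC") + alogp("CCO"), tolerance = 1e-12)
  expect_lt(alogp("CCO"), alogp("CC"))
  # an atom outside the contribution tables fails loudly
  expect_error(alogp("CC[Si](C)(C)C"), "not classifiable")
})

test_that("descriptors are invariant to atom renumbering and SMILES order", {
  smis <- c("Oc1ccccc1", "c1ccccc1[N+](=O)[O-]", "CC(=O)Nc1ccc(Cl)cc1",
            "C1CO1", "CCCCOc1ccccc1")
  tt <- load_atom_types()
  for (smi in smis) {
    g <- as_graph(smi)
    for (sd in 1:3) {
      gp <- permute_graph(g, seed = sd)
      expect_equal(sort(estate_indices(gp)$S), sort(estate_indices(g)$S),
                   tolerance = 1e-10)
      expect_equal(alogp(gp), alogp(g), tolerance = 1e-12)
      expect_equal(idwbar(gp), idwbar(g), tolerance = 1e-12)
      expect_identical(nrings(gp), nrings(g))
      expect_identical(atom_type_counts(gp, tt), atom_type_counts(g, tt))
    }
  }
  # alternative SMILES writings of the same molecule
  a <- compute_descriptors(molecules_from_smiles("Oc1ccccc1"))
  b <- compute_descriptors(molecules_from_smiles("c1ccc(O)cc1"))
  expect_equal(descriptor_matrix(a), descriptor_matrix(b),
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("compute_descriptors keeps failures per-record and width fixed", {
  ms <- molecules_from_smiles(c("CCO", "bad_smiles", "c1ccccc1"))
  d <- compute_descriptors(ms)
  expect_equal(d$computed_ok, c(TRUE, FALSE, TRUE))
  expect_true(all(is.na(descriptor_matrix(d)[2, ])))
  expect_false(anyNA(descriptor_matrix(d)[c(1, 3), ]))
  # 4 global + 21 atom-type descriptors
  expect_equal(ncol(descriptor_matrix(d)), 25L)
  expect_equal(d$mol_id, ms$records$mol_id)
})

test_that("max-abs scaling matches its definition and bounds training data", {
  expect_equal(unname(fit_scaling(cbind(a = c(1, 2, 4)))), 4)
  expect_equal(unname(apply_scaling(cbind(a = c(1, 2, 4)),
                                    fit_scaling(cbind(a = c(1, 2, 4))))[, 1]),
               c(0.25, 0.5, 1))
  expect_equal(unname(fit_scaling(cbind(a = c(-2, 1)))), 2)
  expect_equal(unname(fit_scaling(cbind(a = c(0, 0)))), 1)  # degenerate col
  set.seed(4)
  m <- matrix(rnorm(60, sd = 10), 20, 3,
              dimnames = list(NULL, c("a", "b", "c")))
  sc <- apply_scaling(m, fit_scaling(m))
  expect_true(all(abs(sc) <= 1 + 1e-12))
  expect_error(apply_scaling(cbind(zz = 1), fit_scaling(m)), "columns")
})
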