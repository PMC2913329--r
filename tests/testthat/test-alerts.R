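test_that("the shipped rulebase loads: 30 alerts, compiled, all unused", {
  rb <- default_rulebase()
  expect_s3_class(rb, "alert_rulebase")
  expect_length(rb$alerts, 30L)
  expect_true(all(rb$partition == "unused"))
  expect_output(print(rb), "30 alerts")
})

test_that("malformed rulebases fail loudly naming the culprit", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - alert_id: ok1",
               "    name: epoxide",
               "    patterns: ['C1OC1']",
               "  - alert_id: bad1",
               "    name: broken",
               "    patterns: ['C1OC']"), tf)
  expect_error(load_rulebase(tf), "bad1")
  tf2 <- tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - {alert_id: dup, name: a, patterns: ['C1OC1']}",
               "  - {alert_id: dup, name: b, patterns: ['CCl']}"), tf2)
  expect_error(load_rulebase(tf2), "duplicate")
  tf3 <- tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - {alert_id: np, name: empty}"), tf3)
  expect_error(load_rulebase(tf3), "patterns")
})

test_that("an explicit partition block is honoured and validated", {
  tf <- tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - {alert_id: e1, name: epoxide, patterns: ['C1OC1']}",
               "  - {alert_id: h1, name: halide, patterns: ['[CX4][Cl,Br,I]']}",
               "  - {alert_id: n1, name: nitroarene, patterns: ['a[N+](=O)[O-]']}",
               "partition:",
               "  enhancing: [e1]",
               "  suspicious: [n1]"), tf)
  rb <- load_rulebase(tf)
  expect_equal(unname(rb$partition[c("e1", "h1", "n1")]),
               c("enhancing", "unused", "suspicious"))
  tf2 <- tempfile(fileext = ".yaml")
  writeLines(c("alerts:",
               "  - {alert_id: e1, name: epoxide, patterns: ['C1OC1']}",
               "partition:",
               "  enhancing: [e1]",
               "  suspicious: [e1]"), tf2)
  expect_error(load_rulebase(tf2), "both")
})

test_that("known toxicophores fire and clean molecules do not", {
  rb <- default_rulebase()
  ms <- molecules_from_smiles(c(
    "c1ccccc1[N+](=O)[O-]",   # aromatic nitro
    "C1CO1",                  # epoxide
    "CCCCCl",                 # aliphatic halide
    "CCN(CC)N=O",             # nitrosamine
    "Nc1ccccc1",              # primary aromatic amine
    "CCO",                    # ethanol: nothing
    "CCCCCC"))                # alkane: nothing
  fired <- screen_alerts(rb, ms, "all")
  expect_true("sa27" %in% fired[[1]])
  expect_true("sa07" %in% fired[[2]])
  expect_true("sa08" %in% fired[[3]])
  expect_true("sa21" %in% fired[[4]])
  expect_true("sa28" %in% fired[[5]])
  expect_length(fired[[6]], 0L)
  expect_length(fired[[7]], 0L)
})

test_that("plain alkanes and benign scaffolds fire none of the 30 alerts", {
  rb <- default_rulebase()
  ms <- molecules_from_smiles(c("C", "CC", "CCCCCCCC", "CC(C)CC",
                                "C1CCCCC1", "c1ccccc1", "CCOCC"))
  expect_true(all(lengths(screen_alerts(rb, ms, "all")) == 0))
})

test_that("exception SMARTS veto a matching pattern", {
  rb <- default_rulebase()
  ms <- molecules_from_smiles(c(
    "Nc1ccccc1",                               # aniline: fires sa28
    "Nc1ccc(cc1)S(=O)(=O)O",                   # sulfanilic acid: vetoed
    "CCNNCC",                                  # dialkyl hydrazine: fires sa13
    "CCNNC(C)=O"))                             # hydrazide: vetoed
  fired <- screen_alerts(rb, ms, "all")
  expect_true("sa28" %in% fired[[1]])
  expect_false("sa28" %in% fired[[2]])
  expect_true("sa13" %in% fired[[3]])
  expect_false("sa13" %in% fired[[4]])
})

test_that("subset screening equals full screening filtered by partition", {
  rb <- set_partition(default_rulebase(),
                      enhancing = c("sa07", "sa27"),
                      suspicious = c("sa08", "sa11"))
  ms <- generate_molecules(fixture_spec(n = 60, seed = 33))
  all_f <- screen_alerts(rb, ms, "all")
  enh <- screen_alerts(rb, ms, "enhancing")
  sus <- screen_alerts(rb, ms, "suspicious")
  for (i in seq_along(all_f)) {
    expect_identical(enh[[i]], intersect(all_f[[i]], c("sa07", "sa27")))
    expect_identical(sus[[i]], intersect(all_f[[i]], c("sa08", "sa11")))
    expect_true(all(c(enh[[i]], sus[[i]]) %in% all_f[[i]]))
  }
})

test_that("matching is invariant to how the SMILES is written", {
  rb <- default_rulebase()
  variants <- list(
    c("c1ccccc1[N+](=O)[O-]", "[O-][N+](=O)c1ccccc1", "C1=CC=CC=C1[N+]([O-])=O"),
    c("C1CO1", "O1CC1"),
    c("ClCCCC", "CCCCCl"))
  for (v in variants) {
    ms <- molecules_from_smiles(v)
    fired <- screen_alerts(rb, ms, "all")
    for (i in seq_along(v)[-1]) expect_identical(fired[[i]], fired[[1]])
  }
})

test_that("set_partition validates ids and disjointness", {
  rb <- default_rulebase()
  expect_error(set_partition(rb, enhancing = "nope"), "unknown")
  expect_error(set_partition(rb, enhancing = "sa01", suspicious = "sa01"),
               "disjoint")
  rb2 <- set_partition(rb, enhancing = "sa01")
  expect_equal(sum(rb2$partition == "enhancing"), 1L)
})
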