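test_that("SMILES libraries parse, skipping invalid records", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tethanol", "c1ccccc1\tbenzene", "CC(=O)O\tacetic"), f)
  lib <- parse_library(f)
  expect_equal(nrow(lib), 3)
  expect_equal(lib$id, c("ethanol", "benzene", "acetic"))

  writeLines(c("CCO\ta", "C1CC(\tbroken", "CCN\tb", "xyzzy)(\tworse",
               "CCC\tc", "CO\td"), f)
  expect_message(lib2 <- parse_library(f), "skipped 2")
  expect_equal(nrow(lib2), 4)
  expect_equal(attr(lib2, "n_skipped"), 2)

  writeLines(c("((((\tonly_bad"), f)
  expect_message(expect_error(parse_library(f), "empty-library"))
})

test_that("SDF and SMILES spellings canonicalise identically", {
  smi_f <- withr::local_tempfile(fileext = ".smi")
  writeLines("OCC\tethanol_rev", smi_f)
  lib_smi <- parse_library(smi_f)
  sdf <- ChemmineR::smiles2sdf(as(c(ethanol = "CCO"), "SMIset"))
  sdf_f <- withr::local_tempfile(fileext = ".sdf")
  ChemmineR::write.SDF(sdf, sdf_f)
  lib_sdf <- parse_library(sdf_f)
  expect_equal(lib_smi$cansmi, lib_sdf$cansmi)
})

test_that("descriptor counting rules hold on reference molecules", {
  d <- mol_descriptors(c(benzene = "c1ccccc1", ethanol = "CCO"))
  bz <- d[d$id == "benzene", ]
  expect_equal(bz$hbd, 0); expect_equal(bz$hba, 0)
  expect_equal(bz$tpsa, 0); expect_equal(bz$rotb, 0)
  expect_equal(bz$net_charge, 0); expect_equal(bz$n_aromatic_rings, 1)
  et <- d[d$id == "ethanol", ]
  expect_equal(et$hbd, 1); expect_equal(et$hba, 1)
  expect_equal(et$rotb, 0); expect_equal(et$net_charge, 0)
})

test_that("descriptors match an independent toolkit on a fixture set", {
  # reference values computed with RDKit 2024.09 (Crippen MolLogP,
  # CalcTPSA, Lipinski NumHDonors / NOCount, strict rotatable bonds,
  # GetFormalCharge, CalcNumAromaticRings) and frozen here
  ref <- read.table(header = TRUE, text = "
id smiles mw clogp tpsa hbd hba rotb chg nar
glycerol OCC(O)CO 92.09 -1.67 60.69 3 3 2 0 0
lactic CC(O)C(=O)O 90.08 -0.55 57.53 2 3 1 0 0
octane CCCCCCCC 114.23 3.37 0.00 0 0 5 0 0
teg OCCOCCOCCO 150.17 -1.00 58.92 2 4 7 0 0
sorbitol OCC(O)C(O)C(O)C(O)CO 182.17 -3.59 121.38 6 6 5 0 0
pyridine c1ccncc1 79.10 1.08 12.89 0 1 0 0 1
toluene Cc1ccccc1 92.14 2.00 0.00 0 0 0 0 1
catechol Oc1ccccc1O 110.11 1.10 40.46 2 2 0 0 1
succinate O=C([O-])CCC(=O)[O-] 116.07 -2.73 80.26 0 4 3 -2 0
glucuronic OC1OC(C(=O)O)C(O)C(O)C1O 194.14 -3.13 127.45 5 7 1 0 0")
  d <- mol_descriptors(setNames(ref$smiles, ref$id))
  expect_equal(d$mw, ref$mw, tolerance = 1e-4)
  expect_equal(d$clogp, ref$clogp, tolerance = 0.01)
  expect_equal(d$tpsa, ref$tpsa, tolerance = 1e-4)
  expect_equal(d$hbd, ref$hbd)
  expect_equal(d$hba, ref$hba)
  expect_equal(d$rotb, ref$rotb)
  expect_equal(d$net_charge, ref$chg)
  expect_equal(d$n_aromatic_rings, ref$nar)
  expect_equal(d$sfi, d$clogp + d$n_aromatic_rings)
})

test_that("monoisotopic masses reproduce printed HRMS values", {
  expect_equal(round(monoisotopic_mass("C25H37N4O9"), 4), 537.2561)
  expect_equal(round(monoisotopic_mass("C32H41N4O10"), 4), 641.2823)
  expect_equal(monoisotopic_mass(""), 0)
  expect_error(monoisotopic_mass("C3Xx2"), "formula error")
  # additivity over formula union
  set.seed(61)
  for (rep in 1:5) {
    f1 <- c(C = sample(30, 1), H = sample(40, 1), N = sample(5, 1))
    f2 <- c(C = sample(10, 1), O = sample(8, 1), S = sample(2, 1))
    joint <- tapply(c(f1, f2), names(c(f1, f2)), sum)
    expect_equal(monoisotopic_mass(joint),
                 monoisotopic_mass(f1) + monoisotopic_mass(f2))
  }
  # adduct arithmetic: [M+H]+ from the neutral molecule
  expect_equal(monoisotopic_mass("C25H36N4O9", adduct = "H"),
               monoisotopic_mass("C25H37N4O9"))
})

test_that("dedup collapses spellings, keeps first, is idempotent", {
  f <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\ta", "OCC\tb", "c1ccccc1\tc", "CCN\td"), f)
  lib <- parse_library(f)
  dd <- dedup_library(lib)
  expect_equal(nrow(dd$unique), 3)
  expect_equal(dd$duplicates$id, "b")
  expect_equal(dd$duplicates$duplicate_of, "a")
  expect_equal(nrow(dd$unique) + nrow(dd$duplicates), nrow(lib))
  dd2 <- dedup_library(dd$unique)
  expect_equal(dd2$unique, dd$unique)

  writeLines(c("CCO\tx", "CCN\ty"), f)
  distinct <- parse_library(f)
  expect_equal(nrow(dedup_library(distinct)$duplicates), 0)
})

test_that("filter violations are recorded per rule, not first-only", {
  # raffinose breaks many bounds at once; every one must be listed
  audit <- apply_filters(c(raffinose = paste0(
    "OCC1OC(OCC2OC(OC3(CO)OC(CO)C(O)C3O)C(O)C(O)C2O)C(O)C(O)C1O")))
  v <- strsplit(audit$molecules$violated_rules, ",")[[1]]
  expect_true(all(c("mw<450", "tpsa<110", "hba_0_5", "rotb_0_6") %in% v))
  expect_false(audit$molecules$pass)

  ok <- apply_filters(c(ethanol = "CCO"))
  expect_true(ok$molecules$pass)
  expect_equal(ok$molecules$violated_rules, "")
})

test_that("planted library composition is recovered exactly", {
  gen <- make_library(n_compliant = 4,
                      violators = c("rotb_0_6", "charge_-1_1", "mw<450"),
                      n_duplicates = 1, n_pains = 2, n_reactive = 1,
                      seed = 67)
  dd <- dedup_library(gen$library)
  expect_equal(nrow(dd$duplicates), gen$expected$n_duplicates)
  audit <- apply_filters(dd$unique)
  expect_equal(audit$n_pass, gen$expected$n_pass)
  exp_counts <- gen$expected$rule_counts
  for (rule in names(exp_counts))
    expect_equal(unname(audit$rule_counts[rule]),
                 unname(exp_counts[[rule]]), info = rule)
  # rules not planted reject nothing
  extra <- setdiff(names(audit$rule_counts)[audit$rule_counts > 0],
                   names(exp_counts))
  expect_length(extra, 0)
})

test_that("audit totals are invariant to rule application order", {
  gen <- make_library(n_compliant = 3, violators = c("tpsa<110"),
                      n_pains = 1, seed = 71)
  audit <- apply_filters(gen$library)
  # permute the molecules; per-rule totals and pass count must not move
  lib2 <- gen$library[rev(seq_len(nrow(gen$library))), ]
  class(lib2) <- class(gen$library)
  audit2 <- apply_filters(lib2)
  expect_equal(sort(audit2$rule_counts), sort(audit$rule_counts))
  expect_equal(audit2$n_pass, audit$n_pass)
  # pass set equals the intersection of single-rule pass sets
  d <- mol_descriptors(gen$library)
  only_bounds <- apply_filters(gen$library, descriptors = d)
  expect_setequal(only_bounds$molecules$id[only_bounds$molecules$pass],
                  audit$molecules$id[audit$molecules$pass])
})

test_that("PAINS and reactive decoys are caught by pattern matching", {
  hits <- match_patterns(c(quinone = "O=C1C=CC(=O)C=C1",
                           ethanol = "CCO"), pains_patterns())
  expect_true(any(hits["quinone", ]))
  expect_false(any(hits["ethanol", ]))
  rhits <- match_patterns(c(bzcl = "O=C(Cl)c1ccccc1", ethanol = "CCO"),
                          reactive_patterns())
  expect_true(any(rhits["bzcl", ]))
  expect_false(any(rhits["ethanol", ]))
})
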