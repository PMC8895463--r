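record <- function(id, smiles, cc, eff = NA_real_, pot = NA_real_) {
  tibble::tibble(compound_id = id, smiles = smiles, curve_class = cc,
                 efficacy = eff, potency = pot)
}

test_that("labeling follows the curve-class and efficacy rules", {
  recs <- dplyr::bind_rows(
    record("a1", "CCO", -1.1, 85),
    record("a2", "CCN", -1.1, 79),   # high-quality curve but efficacy < 80
    record("i1", "CCC", 4.0),
    record("x1", "CCCl", -2.2, 85),  # inconclusive code
    record("x2", "CC(C)O", NA, 90),  # missing curve class
    record("f1", "CCO.CCN", -1.1, 95), # two organic fragments: a mixture
    record("s1", "CCCCN.Cl", -1.1, 95) # salt: desalted, kept
  )
  lab <- label_records(recs)
  expect_setequal(lab$compound_id, c("a1", "i1", "s1"))
  expect_equal(as.character(lab$label[lab$compound_id == "a1"]), "active")
  expect_equal(as.character(lab$label[lab$compound_id == "i1"]), "inactive")
  expect_equal(as.character(lab$label[lab$compound_id == "s1"]), "active")
  rem <- removed_compounds(lab)
  expect_setequal(
    rem$reason,
    c("inconclusive", "missing curve class", "fragmented")
  )
  expect_equal(rem$reason[rem$compound_id == "f1"], "fragmented")
  # a2 is inconclusive: right code, insufficient efficacy
  expect_equal(rem$reason[rem$compound_id == "a2"], "inconclusive")
})

test_that("duplicate resolution keeps one same-label copy, drops conflicts", {
  recs <- dplyr::bind_rows(
    record("b2", "CCO", -1.1, 90),
    record("b1", "OCC", -1.1, 95),   # same structure as b2, same label
    record("c1", "CCN", -1.1, 90),
    record("c2", "NCC", 4.0),        # same structure as c1, conflicting label
    record("d1", "CCC", 4.0)
  )
  out <- label_records(recs) |> resolve_duplicates()
  expect_setequal(out$compound_id, c("b1", "d1"))
  expect_equal(out$source_record_ids[out$compound_id == "b1"], "b1;b2")
  # idempotent on its own output
  again <- resolve_duplicates(out)
  expect_equal(again$compound_id, out$compound_id)
  expect_equal(again$smiles_canonical, out$smiles_canonical)
})

test_that("stratified split reproduces per-class rounding arithmetic", {
  # the published curated dataset sizes: 1760 actives / 8893 inactives
  big <- tibble::tibble(
    compound_id = sprintf("c%05d", 1:10653),
    label = factor(rep(c("active", "inactive"), c(1760, 8893)),
                   levels = c("active", "inactive"))
  )
  sp <- stratified_split(big, fraction_train = 0.75, seed = 7)
  tab <- table(sp$label, sp$split)
  expect_equal(tab["active", "train"], 1320)
  expect_equal(tab["inactive", "train"], 6670)
  expect_equal(tab["active", "validation"], 440)
  expect_equal(tab["inactive", "validation"], 2223)
  # determinism
  sp2 <- stratified_split(big, fraction_train = 0.75, seed = 7)
  expect_identical(sp$split, sp2$split)
  sp3 <- stratified_split(big, fraction_train = 0.75, seed = 8)
  expect_false(identical(sp$split, sp3$split))
})

test_that("split class ratio holds across random datasets and seeds", {
  for (seed in 1:5) {
    set.seed(100 + seed)
    n_a <- sample(10:200, 1); n_i <- sample(10:200, 1)
    d <- tibble::tibble(
      compound_id = seq_len(n_a + n_i),
      label = factor(rep(c("active", "inactive"), c(n_a, n_i)))
    )
    frac <- sample(c(0.5, 0.7, 0.75, 0.8), 1)
    sp <- stratified_split(d, frac, seed = seed)
    tab <- table(sp$label, sp$split)
    expect_equal(unname(tab["active", "train"]), floor(frac * n_a + 0.5))
    expect_equal(unname(tab["inactive", "train"]), floor(frac * n_i + 0.5))
    expect_equal(sum(tab), n_a + n_i) # disjoint and exhaustive
  }
})

test_that("degenerate splits are refused", {
  d <- tibble::tibble(compound_id = 1:10,
                      label = factor(rep(c("active", "inactive"), 5)))
  expect_error(stratified_split(d, fraction_train = 1.0), class = "cyp_split_error")
  expect_error(
    stratified_split(dplyr::filter(d, label == "active")),
    class = "cyp_split_error"
  )
  one <- tibble::tibble(compound_id = 1:3,
                        label = factor(c("active", "inactive", "inactive")))
  expect_error(stratified_split(one), class = "cyp_split_error")
})

test_that("library curation removes duplicates, inorganics and excluded rows", {
  # constructed fixture: 82 unique organics + 10 duplicates + 5 inorganics
  # + 3 exclusion-list members = 100 rows, 82 survivors
  base <- sprintf("C%sO", strrep("C", 1:82)) # unambiguous homologous series
  dup <- base[seq(1, 19, 2)]                 # 10 repeats of distinct members
  inorg <- c("[Na+].[Cl-]", "O", "OP(=O)(O)O", "[K+].[Br-]", "OS(=O)(=O)O")
  excl <- c("c1ccccc1N(C)C", "Clc1ccc(Cl)cc1", "CCOP(=S)(OCC)Oc1ccccc1")
  lib <- tibble::tibble(
    compound_id = sprintf("L%03d", 1:100),
    smiles = c(base, dup, inorg, excl)
  )
  out <- curate_library(lib,
                        exclusion = tibble::tibble(smiles = excl))
  expect_equal(nrow(out), 82)
  log <- curation_log(out)
  expect_equal(log$n[log$reason == "duplicate structure"], 10)
  expect_equal(log$n[log$reason == "inorganic"], 5)
  expect_equal(log$n[log$reason == "exclusion list"], 3)
  # survivors are unique canonical structures
  expect_equal(anyDuplicated(out$smiles_canonical), 0)
})
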