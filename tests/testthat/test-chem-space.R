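test_that("catalog CSV loading preserves order, drops bad rows, is deterministic", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "b1,CC(=O)O", "b2,CN", "b3,c1ccccc1Br"), csv)
  lib <- loadCatalog(csv)
  expect_s4_class(lib, "BlockLibrary")
  expect_equal(blockIds(lib), c("b1", "b2", "b3"))

  csv2 <- tempfile(fileext = ".csv")
  writeLines(c("id,smiles", "b1,CC(=O)O", "bad,xxxx", "b3,CN"), csv2)
  expect_message(lib2 <- loadCatalog(csv2), "dropped 1")
  expect_equal(blockIds(lib2), c("b1", "b3"))

  lib3 <- loadCatalog(csv)
  expect_identical(blockFingerprints(lib), blockFingerprints(lib3))
  expect_identical(blockSmiles(lib), blockSmiles(lib3))

  csv3 <- tempfile(fileext = ".csv")
  writeLines(c("name,structure", "a,CC"), csv3)
  expect_error(loadCatalog(csv3), "columns")
})

test_that("amide template couples acid and amine; role mismatch yields empty", {
  amide <- defaultReactions()[[1]]
  expect_equal(templateArity(amide), 2L)
  p <- applyTemplate(amide, c("CC(=O)O", "CN"))
  expect_equal(p, canonicalSmiles("CC(=O)NC"), ignore_attr = TRUE)
  expect_equal(attr(p, "dropped"), 0L)
  ## reactants swapped against roles
  expect_length(applyTemplate(amide, c("CN", "CC(=O)O")), 0)
})

test_that("atom protection restricts a polyfunctional reactant to one site", {
  amide <- defaultReactions()[[1]]
  ## asymmetric diamine: one primary, one secondary amine site
  all <- applyTemplate(amide, c("CC(=O)O", "NCCNC"))
  expect_length(all, 2)
  one <- applyTemplate(amide, c("CC(=O)O", "NCCNC"), protect = TRUE, sites = c(1, 1))
  expect_length(one, 1)
  expect_true(one %in% all)
  other <- applyTemplate(amide, c("CC(=O)O", "NCCNC"), protect = TRUE, sites = c(1, 2))
  expect_length(other, 1)
  expect_false(identical(one[1], other[1]))
})

test_that("all four built-in couplings produce the expected bond", {
  tmpl <- defaultReactions()
  names(tmpl) <- vapply(tmpl, templateId, character(1))
  sulf <- applyTemplate(tmpl$sulfonamide, c("CS(=O)(=O)Cl", "CN"))
  expect_equal(sulf, canonicalSmiles("CNS(C)(=O)=O"), ignore_attr = TRUE)
  ram <- applyTemplate(tmpl$reductive_amination, c("CC=O", "CN"))
  expect_equal(ram, canonicalSmiles("CCNC"), ignore_attr = TRUE)
  suz <- applyTemplate(tmpl$suzuki_coupling, c("Brc1ccccc1", "OB(O)c1ccncc1"))
  expect_equal(suz, canonicalSmiles("c1ccc(cc1)c1ccncc1"), ignore_attr = TRUE)
})

test_that("route replay reproduces products and flags corrupted routes", {
  tmpl <- defaultReactions()
  amide <- tmpl[[1]]
  p1 <- applyTemplate(amide, c("CC(=O)O", "CN"))[1]
  r1 <- syntheticRoute(list(list(
    template = "amide_coupling",
    reactants = list(blockRef("a", "CC(=O)O"), blockRef("b", "CN")),
    product = p1)))
  expect_equal(replayRoute(r1), p1)

  ## 3-step route: successive couplings, each product feeding the next step
  diacid <- canonicalSmiles("OC(=O)CCC(=O)O")
  s1 <- applyTemplate(amide, c(diacid, "CN"))[1]
  s2 <- applyTemplate(amide, c(s1, "NCCN"))[1]
  s3 <- applyTemplate(tmpl[[2]], c("CS(=O)(=O)Cl", s2))[1]
  r3 <- syntheticRoute(list(
    list(template = "amide_coupling",
         reactants = list(blockRef("d", diacid), blockRef("m", "CN")), product = s1),
    list(template = "amide_coupling",
         reactants = list(stepRef(1), blockRef("e", "NCCN")), product = s2),
    list(template = "sulfonamide",
         reactants = list(blockRef("s", "CS(=O)(=O)Cl"), stepRef(2)), product = s3)
  ))
  expect_equal(replayRoute(r3), s3)

  rBad <- syntheticRoute(list(list(
    template = "amide_coupling",
    reactants = list(blockRef("a", "CC(=O)O"), stepRef(5)),
    product = p1)))
  expect_error(replayRoute(rBad), "route-invalid")
})

test_that("space size estimate is the sum over templates of role-count products", {
  tmpl <- defaultReactions()
  names(tmpl) <- vapply(tmpl, templateId, character(1))
  counts <- c(carboxylic_acid = 1000, amine = 1000,
              aryl_halide = 10, aryl_boronic_acid = 10)
  expect_equal(spaceSizeEstimate(counts, list(tmpl$amide_coupling)), 1e6)
  expect_equal(spaceSizeEstimate(counts, list(tmpl$amide_coupling,
                                              tmpl$suzuki_coupling)), 1000100)
  expect_equal(spaceSizeEstimate(counts, list()), 0)
})

test_that("canonicalization is idempotent over generated structures", {
  ps <- probeProducts(40)
  expect_identical(canonicalSmiles(ps), ps)
})

test_that("reaction template files round-trip; unknown SMARTS are rejected", {
  tmpl <- defaultReactions()
  f <- tempfile(fileext = ".txt")
  writeReactionTemplates(tmpl, f)
  back <- readReactionTemplates(f)
  expect_equal(vapply(back, templateId, character(1)),
               vapply(tmpl, templateId, character(1)))
  writeLines("[C:1]>>[C:1]O", f)
  expect_error(readReactionTemplates(f), "repertoire")
})
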