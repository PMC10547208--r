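# Reading and writing the standard formats: expression tables, phenotype
# tables and SBML models.

test_that("expression tables round-trip and reject malformed input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tWT\tEv1", "cyoC\t8.42\t10.18", "cydB\t12.24\t10.60"), f)
  profs <- read_expression_table(f)
  expect_named(profs, c("WT", "Ev1"))
  expect_equal(profs$WT$values[["cyoC"]], 8.42)
  expect_equal(profs$WT$values[["cydB"]], 12.24)
  expect_equal(profs$Ev1$values[["cydB"]], 10.60)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_expression_table(profs, f2)
  again <- read_expression_table(f2)
  expect_equal(again$WT$values, profs$WT$values)
  expect_equal(again$Ev1$values, profs$Ev1$values)

  fd <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tWT", "g1\t1.0", "g1\t2.0"), fd)
  expect_error(read_expression_table(fd), "duplicated gene")

  fn <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tWT\tEv1", "g1\t1.0\tabc"), fn)
  expect_error(read_expression_table(fn), "row 1, column 'Ev1'")
})

test_that("phenotype tables parse, validate columns, and keep NAs", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tgrowth_rate", "WT\t0.5"), f)
  tab <- read_phenotype_table(f)
  expect_equal(tab$growth_rate, 0.5)

  fe <- withr::local_tempfile(fileext = ".tsv")
  writeLines("strain\tgrowth_rate", fe)
  expect_error(read_phenotype_table(fe), "no strains")

  fu <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("strain\tbiomass_color", "WT\t3"), fu)
  expect_error(read_phenotype_table(fu), "growth_rate")

  # 8 strains x 3 quantities, with one missing cell
  set.seed(42)
  strains <- paste0("S", 1:8)
  vals <- matrix(round(runif(24, 0.1, 20), 3), 8, 3)
  lines <- c("strain\tgrowth_rate\tgrowth_yield\toxygen_uptake",
             vapply(1:8, function(i)
               paste(c(strains[i], format(vals[i, ], trim = TRUE)),
                     collapse = "\t"), ""))
  lines[3] <- sub("\t[0-9.]+$", "\t", lines[3])   # drop S2's oxygen value
  fb <- withr::local_tempfile(fileext = ".tsv")
  writeLines(lines, fb)
  tab <- read_phenotype_table(fb)
  expect_equal(dim(tab), c(8, 4))
  expect_true(is.na(tab$oxygen_uptake[tab$strain == "S2"]))
  for (i in c(1, 4, 8))
    expect_equal(tab$growth_rate[tab$strain == strains[i]], vals[i, 1])
})

test_that("a minimal one-metabolite, one-exchange SBML round-trips", {
  m <- stoich_model("A", "EX_A", matrix(1, 1, 1), lb = 0, ub = 1000)
  expect_true(m$exchange)
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(m, f)
  m2 <- read_sbml_model(f)
  expect_equal(length(m2$met_ids), 1L)
  expect_equal(length(m2$rxn_ids), 1L)
  expect_true(m2$exchange)
})

test_that("SBML round-trip preserves every model field", {
  for (spec in list(toy_spec("toy1"), random_toy_spec(3),
                    random_toy_spec(11))) {
    m <- make_toy_model(spec)
    f <- withr::local_tempfile(fileext = ".xml")
    write_sbml_model(m, f)
    m2 <- read_sbml_model(f)
    expect_identical(m2$rxn_ids, m$rxn_ids)
    expect_identical(m2$met_ids, m$met_ids)
    expect_equal(as.matrix(m2$S), as.matrix(m$S), ignore_attr = TRUE)
    expect_identical(m2$lb, m$lb)
    expect_identical(m2$ub, m$ub)
    expect_identical(m2$gene_rules, m$gene_rules)
    expect_identical(m2$exchange, m$exchange)
  }
  # biomass objective survives
  g <- make_toy_model("toy1_growth")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(g, f)
  expect_identical(read_sbml_model(f)$biomass, "EX_C")
})

test_that("SBML without flux bounds is an error, not a silent default", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level2" level="2" version="1">',
    '<model id="m"><listOfSpecies>',
    '<species id="A" compartment="c"/></listOfSpecies>',
    '<listOfReactions><reaction id="R1">',
    '<listOfReactants><speciesReference species="A"/></listOfReactants>',
    '</reaction></listOfReactions></model></sbml>'), f)
  expect_error(read_sbml_model(f), "no flux bounds")
  expect_error(read_sbml_model(withr::local_tempfile(fileext = ".xml")),
               "file not found")
})

test_that("gene identifier mapping renames without collisions", {
  p <- expression_profile("WT", c(cyoC = 8.42, cydB = 12.24, other = 1))
  mapped <- map_gene_identifiers(
    p, data.frame(symbol = c("cyoC", "cydB"), locus = c("b0430", "b0734")))
  expect_equal(mapped$values[["b0430"]], 8.42)
  expect_equal(mapped$values[["other"]], 1)
  expect_error(
    map_gene_identifiers(p, data.frame(a = c("cyoC", "cydB"),
                                       b = c("x", "x"))),
    "collide")
})

test_that("a converted model exports to SBML with provenance notes", {
  conv <- convert_model(make_toy_model("toy1"))
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(conv, f)
  txt <- readLines(f)
  expect_true(any(grepl("SOURCE:R3 DIRECTION:bwd", txt)))
  back <- read_sbml_model(f)
  expect_identical(back$rxn_ids, conv$rxn_ids)
  expect_equal(as.matrix(back$S), as.matrix(conv$S), ignore_attr = TRUE)
  expect_identical(back$lb, conv$lb)
})

test_that("an independent SBML reader agrees on the written model", {
  py <- Sys.which("python")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml_model(make_toy_model("toy1"), f)
  out <- system2(py, c("-c", shQuote(sprintf(
    "import warnings; warnings.filterwarnings('ignore')
import cobra
m = cobra.io.read_sbml_model('%s')
r3 = m.reactions.get_by_id('R3')
print(len(m.reactions), len(m.metabolites), len(m.genes))
print(r3.lower_bound, r3.upper_bound, r3.gene_reaction_rule)
print(sorted((mm.id, v) for mm, v in r3.metabolites.items()))", f))),
    stdout = TRUE, stderr = FALSE)
  expect_equal(out[1], "5 3 3")
  expect_equal(out[2], "-1000.0 1000.0 g3")
  expect_equal(out[3], "[('B', -1.0), ('C', 1.0)]")
})
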