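test_that("toy fixture survives an SBML L3/FBC round trip", {
  m <- fixtureModel()
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(m, path)
  m2 <- readSBMLModel(path)

  expect_equal(nReactions(m2), 7L)
  expect_equal(nMetabolites(m2), 6L)
  expect_setequal(geneIds(m2), sprintf("G%d", 1:7))
  expect_identical(m2@reactions, m@reactions)
  expect_equal(as.matrix(stoichiometricMatrix(m2)),
               as.matrix(stoichiometricMatrix(m)))
  expect_identical(lapply(m2@gpr, gprToString), lapply(m@gpr, gprToString))
  ## reversibility normalized from bounds
  expect_identical(reactionBounds(m2)$reversible,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  ## R_in has no gene association
  expect_null(gprRules(m2)[["R_in"]])
})

test_that("gzip-compressed SBML is read transparently", {
  m <- fixtureModel()
  path <- withr::local_tempfile(fileext = ".xml.gz")
  writeSBMLModel(m, path)
  m2 <- readSBMLModel(path)
  expect_equal(nReactions(m2), 7L)
  expect_equal(as.matrix(stoichiometricMatrix(m2)),
               as.matrix(stoichiometricMatrix(m)))
})

test_that("SBML Level 2 with kinetic-law bounds and notes GPR is supported", {
  l2 <- '<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
 <model id="l2toy">
  <listOfCompartments><compartment id="c"/></listOfCompartments>
  <listOfSpecies>
   <species id="A" compartment="c"/>
   <species id="B" compartment="c"/>
   <species id="X_ext" compartment="c" boundaryCondition="true"/>
  </listOfSpecies>
  <listOfReactions>
   <reaction id="R1" reversible="false">
    <notes><body xmlns="http://www.w3.org/1999/xhtml">
      <p>GENE_ASSOCIATION: G1 or (G2 and G3)</p>
    </body></notes>
    <listOfReactants><speciesReference species="A"/></listOfReactants>
    <listOfProducts><speciesReference species="B" stoichiometry="2"/></listOfProducts>
    <kineticLaw>
     <listOfParameters>
      <parameter id="LOWER_BOUND" value="0"/>
      <parameter id="UPPER_BOUND" value="50"/>
     </listOfParameters>
    </kineticLaw>
   </reaction>
   <reaction id="R2" reversible="true">
    <listOfReactants><speciesReference species="B"/></listOfReactants>
    <listOfProducts><speciesReference species="X_ext"/></listOfProducts>
   </reaction>
  </listOfReactions>
 </model>
</sbml>'
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(l2, path)
  m <- readSBMLModel(path)
  b <- reactionBounds(m)
  expect_equal(b$upper_bound[b$id == "R1"], 50)
  expect_equal(b$lower_bound[b$id == "R1"], 0)
  ## no explicit bounds + reversible attribute -> symmetric defaults
  expect_equal(b$lower_bound[b$id == "R2"], -1000)
  expect_true(b$reversible[b$id == "R2"])
  ## parentheses redundant under precedence are dropped by the serializer
  expect_identical(gprRules(m)[["R1"]], parseGPR("G1 or (G2 and G3)"))
  expect_equal(unname(as.matrix(stoichiometricMatrix(m))["B", "R1"]), 2)
  ## boundary species kept as a row but dropped from the internal matrix
  expect_true("X_ext" %in% rownames(stoichiometricMatrix(m)))
  expect_false("X_ext" %in% rownames(stoichiometricMatrix(m, internalOnly = TRUE)))
})

test_that("SBML errors name the offending element", {
  expect_error(readSBMLModel(file.path(tempdir(), "nope.xml")), "not found")

  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<sbml><model><listOfSpecies>", bad)
  expect_error(readSBMLModel(bad), "invalid SBML")

  orphan <- '<?xml version="1.0"?>
<sbml level="3" version="1"><model id="x">
 <listOfSpecies><species id="A"/></listOfSpecies>
 <listOfReactions><reaction id="R9">
  <listOfReactants><speciesReference species="GHOST"/></listOfReactants>
 </reaction></listOfReactions>
</model></sbml>'
  p2 <- withr::local_tempfile(fileext = ".xml")
  writeLines(orphan, p2)
  expect_error(readSBMLModel(p2), "R9.*GHOST")
})

test_that("written SBML is readable by an independent SBML implementation", {
  m <- fixtureModel()
  path <- withr::local_tempfile(fileext = ".xml")
  writeSBMLModel(m, path)
  script <- paste(
    "import warnings; warnings.filterwarnings('ignore')",
    "import cobra",
    sprintf("m = cobra.io.read_sbml_model('%s')", path),
    "print(len(m.reactions), len(m.metabolites), len(m.genes))",
    "print(m.reactions.get_by_id('R4').lower_bound)",
    "print(m.reactions.get_by_id('R2').gene_reaction_rule)",
    sep = "\n")
  out <- suppressWarnings(system2("python", c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  expect_equal(out[length(out) - 2L], "7 6 7")
  expect_equal(as.numeric(out[length(out) - 1L]), -1000)
  expect_equal(out[length(out)], "G2 or G3")
})

test_that("flux tables round trip bit-exactly", {
  m <- fixtureModel()
  sol <- asFluxSolution(m, fixtureTruth(), "truth")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeFluxTable(sol, path)
  tab <- read.delim(path)
  expect_equal(nrow(tab), 7L)
  expect_identical(names(tab), c("reaction_id", "flux", "lower_bound",
                                 "upper_bound", "data_value", "in_objective"))
  back <- readFluxTable(path, label = "truth")
  expect_identical(fluxes(back), fluxes(sol))
  expect_error(readFluxTable(withr::local_tempfile()), "not found")
})
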