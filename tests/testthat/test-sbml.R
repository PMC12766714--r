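toy_sbml_lines <- function(lb_ex = "-10") {
  # minimal hand-written 5-reaction SBML: uptake -> transport ->
  # biomass, with ATP boilerplate
  c('<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" ',
           'xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/',
           'version2" level="3" version="1" fbc:required="false">'),
    '  <model id="toy" fbc:strict="false">',
    '    <notes><body xmlns="http://www.w3.org/1999/xhtml">',
    '      <p>maintenance_reaction: ATPM</p>',
    '      <p>carbon_exchanges: EX_A</p>',
    '    </body></notes>',
    '    <listOfCompartments>',
    '      <compartment id="e" constant="true"/>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    paste0('      <species id="A_e" compartment="e" constant="false" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
           'fbc:chemicalFormula="C2"/>'),
    paste0('      <species id="A_c" compartment="c" constant="false" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="false" ',
           'fbc:chemicalFormula="C2"/>'),
    paste0('      <species id="atp" compartment="c" constant="false" ',
           'hasOnlySubstanceUnits="false" boundaryCondition="false"/>'),
    '    </listOfSpecies>',
    '    <listOfParameters>',
    sprintf('      <parameter id="lb" value="%s" constant="true"/>', lb_ex),
    '      <parameter id="zero" value="0" constant="true"/>',
    '      <parameter id="ub" value="1000" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    paste0('      <reaction id="EX_A" reversible="true" fast="false" ',
           'fbc:lowerFluxBound="lb" fbc:upperFluxBound="ub">'),
    '        <listOfReactants>',
    paste0('          <speciesReference species="A_e" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfReactants>',
    '      </reaction>',
    paste0('      <reaction id="T_A" reversible="false" fast="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">'),
    '        <listOfReactants>',
    paste0('          <speciesReference species="A_e" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfReactants>',
    '        <listOfProducts>',
    paste0('          <speciesReference species="A_c" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfProducts>',
    '      </reaction>',
    paste0('      <reaction id="GROWTH" reversible="false" fast="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">'),
    '        <listOfReactants>',
    paste0('          <speciesReference species="A_c" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfReactants>',
    '      </reaction>',
    paste0('      <reaction id="ATPS" reversible="false" fast="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">'),
    '        <listOfReactants>',
    paste0('          <speciesReference species="A_c" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfReactants>',
    '        <listOfProducts>',
    paste0('          <speciesReference species="atp" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfProducts>',
    '      </reaction>',
    paste0('      <reaction id="ATPM" reversible="false" fast="false" ',
           'fbc:lowerFluxBound="zero" fbc:upperFluxBound="ub">'),
    '        <listOfReactants>',
    paste0('          <speciesReference species="atp" stoichiometry="1" ',
           'constant="true"/>'),
    '        </listOfReactants>',
    '      </reaction>',
    '    </listOfReactions>',
    '    <fbc:listOfObjectives fbc:activeObjective="obj">',
    '      <fbc:objective fbc:id="obj" fbc:type="maximize">',
    '        <fbc:listOfFluxObjectives>',
    paste0('          <fbc:fluxObjective fbc:reaction="GROWTH" ',
           'fbc:coefficient="1"/>'),
    '        </fbc:listOfFluxObjectives>',
    '      </fbc:objective>',
    '    </fbc:listOfObjectives>',
    '  </model>',
    '</sbml>')
}

test_that("a hand-written toy SBML file loads with inferred tags", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines(toy_sbml_lines(), f)
  m <- read_sbml(f)
  expect_s3_class(m, "gem_model")
  expect_equal(nrow(m$reactions), 5)
  expect_equal(tagged_reactions(m, "exchange"), "EX_A")
  expect_equal(m$biomass_reaction, "GROWTH")
  expect_equal(m$maintenance_reaction, "ATPM")
  expect_equal(get_bounds(m, "EX_A"), c(-10, 1000))
  expect_equal(m$metabolites$carbon_atoms[m$metabolites$id == "A_e"], 2L)
  expect_equal(solve_fba(m)$objective_value, 10, tolerance = 1e-8)
})

test_that("SBML writing and re-reading is a structural identity", {
  m <- make_pao_model(c("His-biosynthesis", "lactate-transporter"),
                      id = "roundtrip")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  m2 <- read_sbml(f)
  expect_identical(m$metabolites, m2$metabolites)
  expect_identical(m$reactions$id, m2$reactions$id)
  expect_equal(m$reactions$lower_bound, m2$reactions$lower_bound)
  expect_equal(m$reactions$upper_bound, m2$reactions$upper_bound)
  expect_identical(m$reactions$tags, m2$reactions$tags)
  expect_true(all(m$stoichiometry == m2$stoichiometry))
  expect_identical(m$carbon_exchanges, m2$carbon_exchanges)
  expect_identical(m$amino_acid_exchanges, m2$amino_acid_exchanges)
  expect_identical(m$biomass_reaction, m2$biomass_reaction)
  expect_identical(m$maintenance_reaction, m2$maintenance_reaction)
  expect_identical(m$id, m2$id)

  # and writing the re-read model reproduces the file byte for byte
  f2 <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("invalid SBML is rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".xml")
  # bounds inverted: lb 10 > ub ... use lb parameter value 2000
  writeLines(toy_sbml_lines(lb_ex = "2000"), f)
  expect_error(read_sbml(f), "lower_bound > upper_bound")

  # missing biomass objective
  lines <- toy_sbml_lines()
  lines <- lines[!grepl("fbc:(listOfObjectives|objective|listOfFluxObjectives|fluxObjective)", lines)]
  writeLines(lines, f)
  expect_error(read_sbml(f), "biomass objective")

  # malformed XML names the broken element
  writeLines(c(toy_sbml_lines()[1:10], "<unclosed"), f)
  expect_error(read_sbml(f))
})

test_that("written SBML is readable by an external FBC implementation", {
  m <- make_pao_model(id = "xcheck")
  f <- withr::local_tempfile(fileext = ".xml")
  write_sbml(m, f)
  py <- paste0(
    "import cobra, warnings\n",
    "warnings.filterwarnings('ignore')\n",
    sprintf("m = cobra.io.read_sbml_model('%s')\n", f),
    "print(len(m.reactions), len(m.metabolites))\n")
  out <- tryCatch(system2("python", "-", input = py, stdout = TRUE,
                          stderr = FALSE),
                  error = function(e) NULL)
  skip_if(is.null(out) || !length(out), "python/cobrapy not runnable")
  got <- as.integer(strsplit(out[length(out)], " ")[[1]])
  expect_equal(got, c(nrow(m$reactions), nrow(m$metabolites)))
})
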