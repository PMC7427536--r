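# Tiny models assembled in code for unit tests.

# linear chain: EX_A (uptake up to `uptake`), A -> B, EX_B (secretion)
chain_model <- function(uptake = 10) {
  mets <- list(
    metabolite("A_e", formula = "C1", compartment = "e"),
    metabolite("A_c", formula = "C1", compartment = "c"),
    metabolite("B_c", formula = "C1", compartment = "c"),
    metabolite("B_e", formula = "C1", compartment = "e")
  )
  rxns <- list(
    reaction("EX_A_e", c(A_e = -1), -uptake, 0, is_exchange = TRUE),
    reaction("At", c(A_e = -1, A_c = 1), -1000, 1000),
    reaction("AB", c(A_c = -1, B_c = 1), 0, 1000),
    reaction("Bt", c(B_c = -1, B_e = 1), 0, 1000),
    reaction("EX_B_e", c(B_e = -1), 0, 1000, is_exchange = TRUE)
  )
  stoich_model(mets, rxns, objective = c(EX_B_e = 1), id = "chain")
}

# minimal hand-written SBML fixture: 2 species, 1 reaction
sbml_fixture_minimal <- function(path) {
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"',
    '      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"',
    '      level="3" version="1" fbc:required="false">',
    '  <model id="mini" fbc:strict="true">',
    '    <listOfCompartments>',
    '      <compartment id="c" constant="true"/>',
    '    </listOfCompartments>',
    '    <listOfSpecies>',
    '      <species id="m1" compartment="c" hasOnlySubstanceUnits="false"',
    '               boundaryCondition="false" constant="false"',
    '               fbc:chemicalFormula="C2H6O" fbc:charge="0"/>',
    '      <species id="m2" compartment="c" hasOnlySubstanceUnits="false"',
    '               boundaryCondition="false" constant="false"',
    '               fbc:chemicalFormula="C2H6O" fbc:charge="0"/>',
    '    </listOfSpecies>',
    '    <listOfParameters>',
    '      <parameter id="lb1" value="-7.5" constant="true"/>',
    '      <parameter id="ub1" value="42" constant="true"/>',
    '    </listOfParameters>',
    '    <listOfReactions>',
    '      <reaction id="r1" reversible="true" fast="false"',
    '                fbc:lowerFluxBound="lb1" fbc:upperFluxBound="ub1">',
    '        <listOfReactants>',
    '          <speciesReference species="m1" stoichiometry="1" constant="true"/>',
    '        </listOfReactants>',
    '        <listOfProducts>',
    '          <speciesReference species="m2" stoichiometry="1" constant="true"/>',
    '        </listOfProducts>',
    '      </reaction>',
    '    </listOfReactions>',
    '  </model>',
    '</sbml>'), path)
  path
}

# curated model variants reused by several test files (built once per run)
core_extended <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- extend_with_rhamnolipid_pathway(build_core_model())
    }
    cache
  }
})
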