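<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="mini" name="minimal uptake-conversion-secretion chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="b" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_b" name="substrate (boundary)" compartment="b"
               fbc:charge="0" fbc:chemicalFormula="CH2O"
               boundaryCondition="true" hasOnlySubstanceUnits="false"
               constant="false"/>
      <species id="A_c" name="substrate" compartment="c"
               fbc:charge="0" fbc:chemicalFormula="CH2O"
               boundaryCondition="false" hasOnlySubstanceUnits="false"
               constant="false"/>
      <species id="B_c" name="product" compartment="c"
               fbc:charge="0" fbc:chemicalFormula="CH2O"
               boundaryCondition="false" hasOnlySubstanceUnits="false"
               constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="lb_uptake" value="-1" constant="true"/>
      <parameter id="lb_zero" value="0" constant="true"/>
      <parameter id="ub_default" value="1000" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_A" name="substrate exchange" reversible="true"
                fast="false" fbc:lowerFluxBound="lb_uptake"
                fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A_b" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="CONV" name="isomerisation" reversible="false"
                fast="false" fbc:lowerFluxBound="lb_zero"
                fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_B" name="product exchange" reversible="false"
                fast="false" fbc:lowerFluxBound="lb_zero"
                fbc:upperFluxBound="ub_default">
        <listOfReactants>
          <speciesReference species="B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
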