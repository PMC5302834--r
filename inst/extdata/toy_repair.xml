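<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="model">
    <listOfSpecies>
      <species id="S" boundaryCondition="false"/>
      <species id="u" boundaryCondition="false"/>
      <species id="T2" boundaryCondition="false"/>
      <species id="m1" boundaryCondition="false"/>
      <species id="x4" boundaryCondition="false"/>
      <species id="m2" boundaryCondition="false"/>
      <species id="T1" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="R1" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="u" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false">
        <listOfReactants>
          <speciesReference species="u" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R3" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R4" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="m1" stoichiometry="1"/>
          <speciesReference species="x4" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R5" reversible="false">
        <listOfReactants>
          <speciesReference species="x4" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R6" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="m2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R7" reversible="false">
        <listOfReactants>
          <speciesReference species="m2" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="m1" stoichiometry="1"/>
          <speciesReference species="T1" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R8" reversible="false">
        <listOfReactants>
          <speciesReference species="T1" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="R9" reversible="false">
        <listOfReactants>
          <speciesReference species="m2" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="m1" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
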