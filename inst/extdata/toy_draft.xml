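<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="model">
    <listOfSpecies>
      <species id="m1" boundaryCondition="false"/>
      <species id="m2" boundaryCondition="false"/>
      <species id="p" boundaryCondition="false"/>
      <species id="T3" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="D1" reversible="false">
        <listOfReactants>
          <speciesReference species="m1" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="m2" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="D2" reversible="false">
        <listOfReactants>
          <speciesReference species="m1" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="p" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="D3" reversible="false">
        <listOfReactants>
          <speciesReference species="p" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T3" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
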