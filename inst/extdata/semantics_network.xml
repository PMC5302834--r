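<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="model">
    <listOfSpecies>
      <species id="S" boundaryCondition="false"/>
      <species id="a" boundaryCondition="false"/>
      <species id="b" boundaryCondition="false"/>
      <species id="d" boundaryCondition="false"/>
      <species id="c" boundaryCondition="false"/>
      <species id="T1" boundaryCondition="false"/>
      <species id="e" boundaryCondition="false"/>
      <species id="T2" boundaryCondition="false"/>
      <species id="f" boundaryCondition="false"/>
      <species id="j" boundaryCondition="false"/>
      <species id="k" boundaryCondition="false"/>
      <species id="l" boundaryCondition="false"/>
      <species id="g" boundaryCondition="false"/>
      <species id="T3" boundaryCondition="false"/>
      <species id="T4" boundaryCondition="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="v1" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="a" stoichiometry="2"/>
          <speciesReference species="b" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v2" reversible="false">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1"/>
          <speciesReference species="b" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="d" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v3" reversible="false">
        <listOfReactants>
          <speciesReference species="a" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="c" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v4" reversible="false">
        <listOfReactants>
          <speciesReference species="c" stoichiometry="1"/>
          <speciesReference species="d" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T1" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v5" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="e" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v6" reversible="false">
        <listOfReactants>
          <speciesReference species="e" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T2" stoichiometry="1"/>
          <speciesReference species="f" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v7" reversible="false">
        <listOfReactants>
          <speciesReference species="j" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="k" stoichiometry="2"/>
        </listOfProducts>
      </reaction>
      <reaction id="v8" reversible="false">
        <listOfReactants>
          <speciesReference species="k" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="l" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v9" reversible="false">
        <listOfReactants>
          <speciesReference species="l" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="j" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v10" reversible="false">
        <listOfReactants>
          <speciesReference species="S" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="g" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v11" reversible="false">
        <listOfReactants>
          <speciesReference species="g" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T3" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="v12" reversible="false">
        <listOfReactants>
          <speciesReference species="g" stoichiometry="1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="T4" stoichiometry="1"/>
        </listOfProducts>
      </reaction>
      <reaction id="consume_T1" reversible="false">
        <listOfReactants>
          <speciesReference species="T1" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="consume_T2" reversible="false">
        <listOfReactants>
          <speciesReference species="T2" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="consume_T3T4" reversible="false">
        <listOfReactants>
          <speciesReference species="T3" stoichiometry="1"/>
          <speciesReference species="T4" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
      <reaction id="consume_k" reversible="false">
        <listOfReactants>
          <speciesReference species="k" stoichiometry="1"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
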