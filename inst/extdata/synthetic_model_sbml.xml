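<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic curated reaction model used in examples and tests:
     an ethylene-signaling-like toy network, not a real repository entry. -->
<sbml xmlns="http://www.sbml.org/sbml/level2/version4" level="2" version="4">
  <model id="synthetic_ethylene_toy" name="Synthetic ethylene signaling toy model">
    <listOfSpecies>
      <species id="s_erf1" name="ERF1" compartment="cell"/>
      <species id="s_ein3" name="EIN3" compartment="cell"/>
      <species id="s_eil1" name="EIL1" compartment="cell"/>
      <species id="s_acs2" name="ACS2" compartment="cell"/>
      <species id="s_ctr1" name="CTR1" compartment="cell"/>
      <species id="s_ein2" compartment="cell"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" name="EIN3/EIL1 activate ERF1 transcription">
        <listOfReactants>
          <speciesReference species="s_ein3"/>
          <speciesReference species="s_eil1"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="s_erf1"/>
        </listOfProducts>
        <listOfModifiers>
          <modifierSpeciesReference species="s_acs2"/>
        </listOfModifiers>
      </reaction>
      <reaction id="r2" name="CTR1 represses EIN2">
        <listOfReactants>
          <speciesReference species="s_ein2"/>
        </listOfReactants>
        <listOfModifiers>
          <modifierSpeciesReference species="s_ctr1"/>
        </listOfModifiers>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
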