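<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version2/core" level="3" version="2">
  <model id="mirna_tf" name="micro-RNA transcription-factor interaction model">
    <listOfCompartments>
      <compartment id="cell" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="TF1" name="Transcription factor 1" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="TF2" name="Transcription factor for miR synthesis" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="miR" name="micro RNA" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="miR_gene" name="gene of micro RNA" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="Sink" name="EmptySet" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="Signal" name="signal of TF1 transcription" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="miR_gene_TF2" name="miR_gene_TF2 complex" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="miR_gene_TF1" name="miR_gene_TF1 complex" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="TF1_mRNA" name="TF1_mRNA complex" compartment="cell" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfReactions>
      <reaction id="r1" reversible="false">
        <listOfReactants>
          <speciesReference species="miR_gene" stoichiometry="1" constant="true"/>
          <speciesReference species="TF1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR_gene_TF1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r2" reversible="false">
        <listOfReactants>
          <speciesReference species="miR_gene_TF1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR_gene" stoichiometry="1" constant="true"/>
          <speciesReference species="TF1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r3" reversible="false">
        <listOfReactants>
          <speciesReference species="miR_gene" stoichiometry="1" constant="true"/>
          <speciesReference species="TF2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR_gene_TF2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r4" reversible="false">
        <listOfReactants>
          <speciesReference species="miR_gene_TF2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR_gene" stoichiometry="1" constant="true"/>
          <speciesReference species="TF2" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r5" reversible="false">
        <listOfReactants>
          <speciesReference species="miR_gene_TF2" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR_gene_TF2" stoichiometry="1" constant="true"/>
          <speciesReference species="miR" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r6" reversible="false">
        <listOfReactants>
          <speciesReference species="miR" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Sink" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r7" reversible="false">
        <listOfReactants>
          <speciesReference species="Signal" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Signal" stoichiometry="1" constant="true"/>
          <speciesReference species="TF1_mRNA" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r8" reversible="false">
        <listOfReactants>
          <speciesReference species="TF1_mRNA" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Sink" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r9" reversible="false">
        <listOfReactants>
          <speciesReference species="TF1_mRNA" stoichiometry="1" constant="true"/>
          <speciesReference species="miR" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="miR" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r10" reversible="false">
        <listOfReactants>
          <speciesReference species="TF1_mRNA" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="TF1_mRNA" stoichiometry="1" constant="true"/>
          <speciesReference species="TF1" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="r11" reversible="false">
        <listOfReactants>
          <speciesReference species="TF1" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="Sink" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
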