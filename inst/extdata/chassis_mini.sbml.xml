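<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic miniature chassis metabolome in BiGG-like SBML: 10 species,
     8 carry resolvable structure annotations (InChI text or identifiers.org
     InChIKey URIs), 2 deliberately lack any structure. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" level="3" version="1">
  <model id="mini_chassis" name="synthetic miniature chassis metabolome">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_h2o_c" name="H2O" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#M_h2o_c">
              <bqbiol:is>
                <rdf:Bag>
                  <rdf:li rdf:resource="https://identifiers.org/inchikey/XLYOFNOQVPJJNP-UHFFFAOYSA-N"/>
                </rdf:Bag>
              </bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="M_ac_c" name="Acetate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <structureInfo xmlns="https://pathsense.invalid/annotation">
            <inchi>InChI=1S/C2H4O2/c1-2(3)4/h1H3,(H,3,4)</inchi>
          </structureInfo>
        </annotation>
      </species>
      <species id="M_etoh_c" name="Ethanol" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <structureInfo xmlns="https://pathsense.invalid/annotation">
            <inchi>InChI=1S/C2H6O/c1-2-3/h3H,2H2,1H3</inchi>
          </structureInfo>
        </annotation>
      </species>
      <species id="M_pyr_c" name="Pyruvate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#M_pyr_c">
              <bqbiol:is>
                <rdf:Bag>
                  <rdf:li rdf:resource="https://identifiers.org/inchikey/LCTONWCANYUPML-UHFFFAOYSA-N"/>
                </rdf:Bag>
              </bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="M_glc_c" name="Glucose" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#M_glc_c">
              <bqbiol:is>
                <rdf:Bag>
                  <rdf:li rdf:resource="https://identifiers.org/inchikey/WQZGKKKJIJFFOK-UHFFFAOYSA-N"/>
                </rdf:Bag>
              </bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="M_glyc_c" name="Glycerol" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <structureInfo xmlns="https://pathsense.invalid/annotation">
            <inchi>InChI=1S/C3H8O3/c4-1-3(6)2-5/h3-6H,1-2H2</inchi>
          </structureInfo>
        </annotation>
      </species>
      <species id="M_succ_c" name="Succinate" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <structureInfo xmlns="https://pathsense.invalid/annotation">
            <inchi>InChI=1S/C4H6O4/c5-3(6)1-2-4(7)8/h1-2H2,(H,5,6)(H,7,8)</inchi>
          </structureInfo>
        </annotation>
      </species>
      <species id="M_nh3_c" name="Ammonia" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#" xmlns:bqbiol="http://biomodels.net/biology-qualifiers/">
            <rdf:Description rdf:about="#M_nh3_c">
              <bqbiol:is>
                <rdf:Bag>
                  <rdf:li rdf:resource="https://identifiers.org/inchikey/QGZKDVFQNNGYKY-UHFFFAOYSA-N"/>
                </rdf:Bag>
              </bqbiol:is>
            </rdf:Description>
          </rdf:RDF>
        </annotation>
      </species>
      <species id="M_orphan1_c" name="Uncharacterised metabolite 1" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_orphan2_c" name="Uncharacterised metabolite 2" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false">
        <annotation>
          <note xmlns="https://pathsense.invalid/annotation">no structure recorded</note>
        </annotation>
      </species>
    </listOfSpecies>
  </model>
</sbml>
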