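<?xml version="1.0" encoding="UTF-8"?>
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:owl="http://www.w3.org/2002/07/owl#">
  <owl:Class rdf:about="http://example.org/mouse#Heart">
    <rdfs:label>Heart</rdfs:label>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/mouse#CardiacMuscleTissue">
    <rdfs:label>Cardiac Muscle Tissue</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://example.org/mouse#Heart"/>
  </owl:Class>
  <owl:Class rdf:about="http://example.org/mouse#MitralValve">
    <rdfs:label>Mitral Valve</rdfs:label>
    <rdfs:subClassOf rdf:resource="http://example.org/mouse#Heart"/>
  </owl:Class>
  <owl:ObjectProperty rdf:about="http://example.org/mouse#hasPart">
    <rdfs:label>has part</rdfs:label>
    <rdfs:domain rdf:resource="http://example.org/mouse#Heart"/>
    <rdfs:range rdf:resource="http://example.org/mouse#MitralValve"/>
  </owl:ObjectProperty>
</rdf:RDF>
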