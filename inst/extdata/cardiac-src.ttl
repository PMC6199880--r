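@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix h: <http://example.org/human#> .

h:Heart a owl:Class ;
    rdfs:label "Heart" .

h:Myocardium a owl:Class ;
    rdfs:label "Myocardium" ;
    rdfs:comment "Muscle Tissue" ;
    rdfs:subClassOf h:Heart .

h:MitralValve a owl:Class ;
    rdfs:label "Mitral Valve" ;
    rdfs:subClassOf h:Heart .

h:hasPart a owl:ObjectProperty ;
    rdfs:label "has part" ;
    rdfs:domain h:Heart ;
    rdfs:range h:MitralValve .
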