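<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic miniature of a remote-sensing RDFS ontology, constructed for
     this package's examples and tests. Nodes/edges under the documented
     counting convention (subjects+objects, one edge per triple):
     subjects: Image, CloudCover, City, ImageQuality; typed-node triples add
     rdf:type edges; see tests for the enumerated counts. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:rdfs="http://www.w3.org/2000/01/rdf-schema#"
         xmlns:ersm="http://example.org/ontology/ersm#">
  <rdfs:Class rdf:about="ersm:Image">
    <rdfs:label>Remote sensing image</rdfs:label>
  </rdfs:Class>
  <rdf:Description rdf:about="ersm:CloudCover">
    <rdfs:domain rdf:resource="ersm:Image"/>
    <rdfs:range rdf:resource="ersm:Percentage"/>
  </rdf:Description>
  <rdf:Description rdf:about="ersm:City">
    <rdfs:domain rdf:resource="ersm:Image"/>
  </rdf:Description>
  <rdf:Description rdf:about="ersm:ImageQuality">
    <rdfs:domain rdf:resource="ersm:Image"/>
    <rdfs:subPropertyOf rdf:resource="ersm:QualityInformation"/>
  </rdf:Description>
</rdf:RDF>
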