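<?xml version="1.0" encoding="UTF-8"?>
<!-- Synthetic RDF/XML instance of a remote sensing image annotation,
     constructed for this package's examples and tests. -->
<rdf:RDF xmlns:rdf="http://www.w3.org/1999/02/22-rdf-syntax-ns#"
         xmlns:ersm="http://example.org/ontology/ersm#"
         xmlns:xsd="http://www.w3.org/2001/XMLSchema#">
  <rdf:Description rdf:about="http://example.org/image/E1EB7">
    <ersm:cty rdf:datatype="http://www.w3.org/2001/XMLSchema#string">GZ</ersm:cty>
    <ersm:qa rdf:datatype="http://www.w3.org/2001/XMLSchema#string">E</ersm:qa>
    <ersm:cc rdf:datatype="http://www.w3.org/2001/XMLSchema#integer" ersm:unit="%">0</ersm:cc>
  </rdf:Description>
</rdf:RDF>
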