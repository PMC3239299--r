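Prefix(:=<http://example.org/ggprel/onto#>)
Prefix(owl:=<http://www.w3.org/2002/07/owl#>)
Prefix(rdf:=<http://www.w3.org/1999/02/22-rdf-syntax-ns#>)
Prefix(rdfs:=<http://www.w3.org/2000/01/rdf-schema#>)
Prefix(xsd:=<http://www.w3.org/2001/XMLSchema#>)

Ontology(<http://example.org/ggprel/onto/so-genia-stub>
Declaration(Class(:DNA))
Declaration(Class(:RNA))
Declaration(Class(:Protein))
Declaration(Class(:Protein_family_or_group))
Declaration(Class(:Protein_complex))
Declaration(Class(:Protein_domain_or_region))
Declaration(Class(:DNA_domain_or_region))
Declaration(ObjectProperty(:transcribed-from))
Declaration(ObjectProperty(:translated-from))
AnnotationAssertion(rdfs:comment :transcribed-from "stub for the Sequence Ontology derivation relation (synthetic in-repo import; no file is fetched)")
AnnotationAssertion(rdfs:comment :translated-from "stub for the Sequence Ontology derivation relation (synthetic in-repo import; no file is fetched)")
DisjointClasses(:DNA :RNA :Protein)
)
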