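# Mapping from standoff relation labels to formal relation identifiers.
#
# The left-hand label strings are conventions of this repository's standoff
# dialect (corpus releases do not fix them); edit this file to match the
# labels of your own annotation. "is-a" marks the class-subclass relation,
# which is converted directly to a SubClassOf axiom rather than through an
# ontology design pattern.
labels:
  Subclass: is-a
  Object-Component: GGP-subclass-has-part
  Component-Object: GGP-subclass-part-of
  Member-Collection: GGP-subclass-member-of
  Object-Region: GGP-subclass-region-of
  Object-Variant: GGP-has-variant
  Object-Variant-Modified-Protein: GGP-has-modified-protein
  Object-Variant-Isoform: GGP-has-isoform
  Object-Variant-Mutant: GGP-has-mutant
  Object-Variant-Recombinant: GGP-has-recombinant
  Object-Variant-Precursor: GGP-has-precursor
  Object-Variant-Experimental-Material: GGP-has-experimental-material

# Term-ontology classes whose mentions denote gene/gene-product (GGP)
# classes; mentions of these classes anchor the design patterns.
ggp_term_classes: [Protein, DNA, RNA]

# The kind subclasses a GGP class unifies (the D_1 ... D_n of the first
# design pattern), in disjunction order.
kinds: [DNA, RNA, Protein]

# Overrides for the kind restriction of variant sub-relations (which kind
# subclass of the GGP class the variant primitive points into). Defaults are
# carried by the shipped taxonomy: isoform, mutant, precursor and
# modified-protein restrict to Protein; recombinant to DNA;
# experimental-material is unrestricted.
kind_restrictions: {}
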