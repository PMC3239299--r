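# ggprel

Relation ontology, ontology design patterns and closed-world finite-model
checking for gene/gene-product (GGP) relation annotations.

## The problem

Biomedical named-entity annotation deliberately does not decide whether a
name like *CD19* refers to a gene, a transcript or a protein — the three
are unified into a single *gene/gene-product* class `G_C`, defined from a
DNA seed class `C` through chains of transcription and translation between
individuals:

    x ∈ G_C  ⇔  C(x) ∨ ∃y (transcribed-from(x,y) ∧ C(y))
                     ∨ ∃y ∃z (translated-from(x,y) ∧ transcribed-from(y,z) ∧ C(z))

Relation annotations anchored at such names are ambiguous at the class
level. Reading an annotated class-level parthood with the generic schema
`C ⊑ ∃II-part-of.D` licenses false inferences: from *CD19 promoter
part-of CD19* and *CD19 part-of CD19/CD21/CD81/Leu-13 complex*, transitive
parthood derives that a **promoter is part of a protein complex** — false,
since protein complexes have no promoter parts.

The repair is an ontology design pattern that quantifies over the GGP
class's kind subclasses: `GGP-subclass-R(G_C, X)` holds when for at least
one kind `K ∈ {DNA, RNA, Protein}` every instance of `G_C ⊓ K` stands in
the individual-level primitive `II-R` to some instance of `X`. In OWL 2,
where a disjunction of axioms is not syntax, this becomes a single
subclass axiom into `owl:Nothing` via the universal property:

    ⊓_K ∃top.(G_C ⊓ K ⊓ ¬∃II-R.X)  ⊑  ⊥

A second pattern handles variance: `GGP-has-variant(G_C, D)` means every
instance of `D` is a variant of some instance of `G_C` (kind-restricted
for isoforms, mutants, precursors, modified proteins and recombinants).

The package ships:

- `genia_taxonomy()` — the full relation taxonomy (II-/CC-/GGP-level) with
  per-relation axiom flags (reflexivity, transitivity, antisymmetry,
  symmetry, irreflexivity, asymmetry, strong supplementation, and explicit
  *non*-assertions of transitivity), plus `validate_flags()` for joint
  satisfiability of a flag set;
- `parse_annotation()` / `write_annotation()` — BioNLP-style standoff I/O
  with span validation;
- `convert_abstract()` — standoff document → OWL 2 axioms, via the two
  patterns (or the generic schema, for verification experiments);
- `write_ontology()` / `parse_ontology()` / `write_turtle()` — deterministic
  OWL 2 functional-syntax output (Turtle secondary), respecting OWL 2 DL's
  ban on reflexivity/symmetry characteristics for non-simple properties;
- `closure()` / `check()` — deductive closure (transitivity, symmetry,
  sub-properties, property chains, inverses) and closed-world verification
  with witnesses and derivation chains, no external reasoner;
- `worked_examples()` / `random_corpus()` — downloadless fixtures
  reproducing the worked examples plus seeded valid/corrupted corpora;
- a command-line script (`exec/ggprel`) with `convert`, `validate`,
  `taxonomy` and `fixtures` commands (exit codes: 0 consistent,
  1 violations, 2 input error).

## Worked example

The headline verification: the same annotated facts, read with the generic
class-level schema and with the GGP-subclass pattern.

```r
library(ggprel)
ex <- worked_examples()[["cd19-faulty"]]
# "The CD19 promoter is part of CD19 , and CD19 is part of the
#  CD19/CD21/CD81/Leu-13 complex ."

check(ex$model, convert_abstract(ex$annotation, schema = "generic"))
#> 1 violation(s):
#>  - subclass | SubClassOf(ObjectIntersectionOf(:DNA_domain_or_region
#>    ObjectSomeValuesFrom(:II-part-of :Protein_complex)) owl:Nothing) | witness: pr
#>     pr is in ObjectIntersectionOf(...) but not in owl:Nothing
#>     via: II-part-of(pr, cx) <= transitivity[II-part-of(pr, g) <=
#>          inverse[II-has-part(g, pr)]; II-part-of(g, cx)]

check(ex$pattern_model, convert_abstract(ex$annotation, schema = "pattern"))
#> No violations: model is consistent with the axioms.
```

Under the generic schema the promoter individual `pr` is derived, by
transitivity through the single CD19 individual `g`, to be a part of the
complex `cx` — exactly the faulty inference, caught with its derivation
chain. Under the pattern the part-bearing subclass of `G_CD19` is its DNA
subclass and the complex-bound one its protein subclass, so no faulty
chain exists and the report is empty.

Converting a document to OWL from the shell:

```sh
Rscript exec/ggprel fixtures /tmp/fx
Rscript exec/ggprel convert /tmp/fx --out /tmp/owl          # one .ofn per abstract
Rscript exec/ggprel validate /tmp/fx/cd19-faulty.txt --generic-schema
# exit status 1, with the promoter/complex witness
```

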