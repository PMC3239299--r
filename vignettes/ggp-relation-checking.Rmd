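---
title: "Formalizing and verifying gene/gene-product relation annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Formalizing and verifying gene/gene-product relation annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggprel)
```

## The problem

Named-entity annotation of biomedical abstracts deliberately refuses to
decide whether a name such as *CD19* denotes a gene, a transcript or a
protein. The three referents are treated as indistinguishable within the
annotation task and unified into a single *gene/gene-product* (GGP) class.
Relation annotations anchored at such names are then ambiguous at the class
level: *CD19 promoter* is a part of the CD19 **gene**, while the CD19
**protein** is a member of complexes and families. A naive class-level
reading of parthood (`C SubClassOf some(II-part-of, D)` for every annotated
`CC-part-of(C, D)`) over the unified class licenses false inferences --
from "the promoter is part of CD19" and "CD19 is part of the
CD19/CD21/CD81/Leu-13 complex" it derives that a promoter is part of a
protein complex, which is false because protein complexes have no promoter
parts.

`ggprel` implements three layers that make such annotations formally
checkable:

1. a **relation taxonomy** with per-relation axioms (reflexivity,
   transitivity, antisymmetry, symmetry, irreflexivity, asymmetry, strong
   supplementation, and deliberate *non*-assertions of transitivity);
2. two **ontology design patterns** that disambiguate class-level relation
   statements whose argument is a GGP class;
3. a **converter** from standoff annotation documents to OWL 2 ontologies,
   and a **closed-world finite-model checker** that verifies annotations
   against the axioms with explicit witnesses, without an external
   reasoner.

## The GGP class

A GGP class `G_C` is defined from a seed class `C` assumed to be a subclass
of `DNA`: an individual belongs to `G_C` exactly when it is an instance of
`C`, or transcribed from an instance of `C`, or translated from something
transcribed from an instance of `C`. In the IR this is one class
equivalence,

```
EquivalentClasses(G_C, ObjectUnionOf(C,
  ObjectSomeValuesFrom(transcribed-from, C),
  ObjectSomeValuesFrom(translated-from,
    ObjectSomeValuesFrom(transcribed-from, C))))
```

with `transcribed-from` / `translated-from` drawn from the Sequence
Ontology namespace. When an equivalence group contains no DNA-typed
mention, the GGP class is declared primitively (a plain subclass of `GGP`);
the converter never invents a DNA seed a document does not contain.

```{r ggp}
wx <- worked_examples()
ax <- convert_abstract(wx[["cd19-equiv"]]$annotation)
cm <- closure(wx[["cd19-equiv"]]$model, ax)
eval_expr("G_CD19", cm)  # gene, transcript and protein individuals
```

## The relation taxonomy

`genia_taxonomy()` ships the full relation inventory: individual-level
(`II-`) primitives, class-level (`CC-`) schemata, and GGP-level relations
defined through the patterns.

```{r tax}
tibble::as_tibble(genia_taxonomy())
```

Axiom flags follow the prose characterization of each relation:
`II-part-of` is reflexive, transitive and antisymmetric; `II-oc-part-of`
(component-object parthood) additionally satisfies **strong
supplementation** (if every part of `y` overlaps `x`, then `y` is part of
`x` -- the characteristic principle of extensional mereology, and the
reading compatible with the Sequence Ontology); `II-member-of` is
irreflexive, asymmetric, non-transitive and a sub-relation of
`II-proper-part-of`; `II-has-variant` is reflexive, symmetric and
non-transitive; `II-has-mutant` is irreflexive and symmetric. Three
encoding decisions deserve a note:

* **`NON_TRANSITIVE` is an explicit flag**, not the mere absence of
  `TRANSITIVE`. The formalization deliberately distinguishes "transitivity
  is not asserted" (membership, variance) from "nothing was said"; the
  explicit flag lets the OWL writer document the deliberate omission as an
  annotation, and the flag-consistency checker reject `TRANSITIVE +
  NON_TRANSITIVE`.
* **`II-member-of` is flagged irreflexive** although its prose
  characterization is "non-reflexive": the relation is also asymmetric, and
  asymmetry already entails irreflexivity, so the stronger flag is forced
  and recorded once here.
* **Direction of `II-region-of`**: `x II-region-of y` reads "`x` is located
  at region/locus `y`" (CD19 is located at the CD19 locus). This convention
  is fixed here and used everywhere (converter, chains, checker).

`validate_flags()` checks joint satisfiability of a flag set by a
*nonempty* relation on a two-element domain, analytically; the test suite
verifies the analysis against brute-force enumeration of all 16 binary
relations on two elements. Flag sets that force the relation empty (e.g.
symmetry + antisymmetry + irreflexivity) are reported as conflicts even
though the empty relation technically satisfies them: a relation ontology
whose relation can never hold is a specification error.

## The two design patterns

**Kind-disjunction pattern** (`expand_subclass_pattern()`). A statement
`GGP-subclass-R(G_C, X)` means: for *at least one* kind `K` among the kind
subclasses (`DNA`, `RNA`, `Protein` by default), every instance of
`G_C ⊓ K` stands in the primitive `II-R` to some instance of `X`. A
disjunction of axioms is not OWL syntax, so the OWL encoding uses the
universal (top) property to turn each disjunct's negation into a refutable
nonemptiness claim:

```
ObjectIntersectionOf over kinds K of
  ObjectSomeValuesFrom(owl:topObjectProperty,
    ObjectIntersectionOf(G_C, K,
      ObjectComplementOf(ObjectSomeValuesFrom(II-R, X))))
SubClassOf owl:Nothing
```

`some(top, C)` evaluates to everything when `C` is nonempty and to nothing
otherwise, so the intersection is empty exactly when some kind has no
counterexample -- the intended disjunction. The emitted axiom carries the
machine-readable pattern parameters as an annotation, and the checker
evaluates the disjunction natively; the test suite verifies that the native
verdict, the encoded-expression verdict and a brute-force evaluation agree
on enumerated and sampled models. Note that a kind with an *empty*
intersection `G_C ⊓ K` satisfies its disjunct vacuously -- this is the
intended first-order semantics, and it is exactly how the pattern blocks
the promoter/complex inference: nothing forces any single individual to be
both promoter-bearing and complex-bound.

The pattern's point rests on kind disjointness, so
`DisjointClasses(DNA, RNA, Protein)` is emitted by default
(`disjointness = FALSE` switches it off). A second background constraint --
no DNA domain/region is a part of a protein complex -- is emitted when a
document mentions both kinds of classes, making the counterexample
machine-detectable.

**Variant pattern** (`expand_variant_pattern()`). A statement
`GGP-has-variant(G_C, D)` means every instance of `D` is a variant of some
instance of `G_C`: `SubClassOf(D, some(II-has-variant, G_C))`. The
sub-relations restrict the filler to a kind subclass of `G_C` according to
a configurable table whose defaults are: isoform, mutant, precursor and
modified-protein restrict to `Protein`; recombinant to `DNA`;
experimental-material is unrestricted. Only the isoform case is fixed by
the source characterization; the other assignments follow the stated "same
pattern" with the biologically sensible kind (a recombinant expression
vector is DNA; a modified or precursor form is a protein), and the table is
editable in `relation_map.yaml` because they are defaults, not doctrine.
`II-has-experimental-material` itself is declared without axioms -- its
formal characterization is left open -- but the class-level pattern is
still applied so the annotation is convertible.

The generalized form accepts chain relations `T_1 … T_m`: the variant may
alternatively be reachable through the chain from an instance of the
target. Whether the chain is an ordered composition or any permutation is
genuinely open; the default is the ordered chain (the conservative reading,
and the one whose OWL encoding stays linear in `m`), with
`permutations = TRUE` expanding the union over all orders.

**Proper parthood and location.** `II-proper-part-of` is defined as
parthood excluding coincidence: `x` is a proper part of `y` iff
`x II-part-of y` and not `y II-part-of x`. The definition is not
first-order expressible in OWL 2 and, more importantly here, its "if"
direction is *non-monotone* (adding a parthood pair can retract a proper
parthood). It is therefore not a closure rule: `closure()` only propagates
the monotone direction (proper parts are parts, via the sub-property edge),
`check()` verifies asserted proper-part pairs against the definition, and
`proper_part_extension()` computes the full defined extension for
cross-checks. On a reflexive-transitive-antisymmetric parthood the defined
extension is exactly parthood minus the identity pairs, which the test
suite verifies on random partial orders. Location interacts with parthood
through two property chains: a part of something located at `z` is located
at `z`, and something located inside a part of `z` is located at `z`.

## OWL 2 output

The writer emits deterministic OWL 2 functional syntax (and Turtle as a
secondary, write-only format): fixed prefixes, ontology header with
imports, declarations, then axioms in canonical sorted order, so identical
input yields identical bytes. Imports default to a small in-repo stub
ontology (marked synthetic) declaring the term-ontology classes and the two
derivation relations, so no file is ever fetched; `owl_config(stub =
FALSE)` switches to the remote Sequence Ontology / term ontology IRIs.

OWL 2 DL forbids reflexivity, irreflexivity, symmetry and asymmetry
characteristics on *non-simple* properties (those declared transitive or
concluding a property chain, closed under super-properties and inverses).
The writer computes the non-simple set, drops such characteristics from the
output and records each as an annotation comment; antisymmetry and strong
supplementation, which OWL 2 cannot express at all, are always carried as
tagged annotations. `parse_ontology()` reads the emitted dialect back
(reconstructing pattern axioms from their annotations), so the round trip
is identity modulo the dropped characteristics -- a property the test suite
asserts for every fixture.

## Closed-world finite-model checking

`closure()` computes the least fixpoint of a finite model under the
monotone rules: symmetry, transitivity (delta-based: only newly derived
pairs are re-joined), sub-property propagation, property chains, inverse
synchronisation, asserted facts, and class propagation along
subclass/equivalence axioms whose firing side contains no complement and
whose receiving side is a named class. Derived pairs remember their rule
and premises, so violation reports can print derivation chains such as

```
II-part-of(pr, cx) <= transitivity[II-part-of(pr, g) <= inverse[II-has-part(g, pr)]; II-part-of(g, cx)]
```

`check()` then evaluates every axiom and flag on the closed model and
returns a tibble of violations with witnesses. Two deliberate divergences
from open-world OWL semantics are documented rather than hidden:

* **Existential obligations are violations, not skolems.** A
  `SubClassOf(C, some(R, D))` with a `C`-instance lacking an `R`-successor
  in `D` is reported, witness attached, instead of being satisfied by an
  invented anonymous individual. Annotation verification wants witnesses.
* **Reflexivity is checked over a restricted domain** -- the relation's
  declared domain-class extension, falling back to the individuals
  occurring in the relation -- because whether reflexivity of parthood is
  global or domain-restricted is left open by the source characterization;
  `reflexivity = "global"` switches to all individuals.

For file-level validation, where no hand-built model exists,
`canonical_model()` builds one by a bounded chase: one individual per
mention-denoted class, existential repairs that prefer existing filler
members over fresh individuals (keeping the model minimal and the
verification desk-scale), kind-aware repair of the GGP equivalence along
the transcription/translation chain, and reflexivity padding. The
preference for existing members is what makes a mutant relation whose
argument resolves to the GGP's own class collapse into a self-loop and
surface as an irreflexivity violation.

No external DL reasoner is used anywhere; the checker is decidable by
construction and produces witnesses, which a tableau reasoner's
"inconsistent" verdict does not.

## What the synthetic data emulates -- and what it does not

`worked_examples()` rebuilds the in-text cases as standoff documents with
hand-built finite models: the CD19 equivalence trio, promoter component,
locus location, human-gene subclass, HOXA1 and Lck memberships, the six
variance cases (35S-TR alpha 1, G-Actin, dominant-negative mutant TNFRI,
Oct-2 expression vector, pro-IL-16, antisense GATA-3 RNA), a plain variant
document, a consistent component-of-complex document, and the
faulty-schema document. The faulty document carries two models: a
single-CD19-individual model on which the generic schema derives the false
promoter-in-complex conclusion, and a split DNA/protein model realizing the
same class-level facts the way the pattern reads them. The two models
differ by necessity -- the pattern's entire point is that the class-level
facts are realized by different individuals -- so "the same facts" are
compared at class level.

`random_corpus()` draws documents from thirteen fixed sentence templates
(one per relation in the vocabulary) over a pool of real gene symbols, each
paired with a satisfying model, and optionally injects one labeled
corruption per document from a typed menu: mutant self-loop, membership
cycle, kind-disjointness clash, dangling relation argument. Template choice
and corruption type are drawn uniformly; the generator is deterministic per
seed.

Passing tests on these corpora show that the converter, axioms and checker
agree with their specification on annotation-shaped input, that the checker
flags every injected corruption type and stays silent on uncorrupted
documents. They do **not** show robustness to real corpus text: fixture
sentences are short and synthetic, mention spans never cross sentence
boundaries, surface forms are clean (no abbreviations, no discontinuous
mentions), class assignments are correct by construction, and the
distribution over templates is uniform rather than corpus-like. Real
GENIA-style annotation exercises none of these simplifications.

## Problem sizes and numerical choices

The oracle-equivalence tests run closure and checking against an
independent naive fixpoint and a direct first-order evaluator on every
model of the two-class/two-relation signature with up to two individuals
and of the one-class/one-relation signature with three, plus 1,000 seeded
random models of up to five individuals over the real relation vocabulary
with the full background axioms, a kind-disjunction instance, a mutant
instance and a GGP definition in force. Corpus recovery uses 200 clean and
80 fully corrupted documents. These sizes are chosen so the whole suite
runs comfortably on a laptop while still exhausting the small-scope
envelope where logical bugs live; the exhaustive bound grows as
`2^(n·c + n²·r)` and is guarded in `enumerate_models()` (default cap
`2^16` models), with `sample_models()` taking over beyond it.

Other fixed choices: class IRIs are minted deterministically from
normalized surface strings (runs of non-alphanumerics collapse to `_`), so
identical mentions across documents denote the same class; equivalence
groups merge transitively and a group's GGP class is named after its
shortest surface; the chase creates at most 50 fresh individuals per
document; exit codes of the command layer are fixed at 0 = consistent,
1 = violations, 2 = input error.

## Known limitations

* The checker is closed-world by design; it does not perform open-world DL
  entailment, and a document flagged here can still be satisfiable under
  open-world semantics (the mutant self-loop is the canonical example).
* Protein families are plain subclasses of the family term class; no
  mereology of families is asserted.
* `II-has-experimental-material` carries no individual-level axioms.
* Event structure (binding, regulation) is out of scope; only binary
  relation mentions are converted.
* `parse_ontology()` covers exactly the emitted functional-syntax dialect;
  Turtle is write-only.
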