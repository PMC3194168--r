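---
title: "Higher-order category typing for metadata registries: the ontomdr model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Higher-order category typing for metadata registries: the ontomdr model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontomdr)
```

## The problem

Clinical and epidemiological studies document their variables as *items*
on case report forms: a blood-pressure reading, a subject's weight, a
questionnaire answer. Metadata registries in the ISO/IEC 11179 style
describe such items through four interlocking notions — the data element
concept (what is measured, on what kind of thing), the conceptual domain
(what the possible values *mean*), the value domain (how those meanings
are *written*), and the data element that pairs semantics with
representation. The standard's own semantics is thin: it does not say
what kind of entity a "metadata object" is, what distinguishes it from
its instances, or how a value relates to its meaning.

`ontomdr` rebuilds this metamodel on an explicit ontological substrate: a
finite graph of **categories** (instantiable entities) and
**individuals** (non-instantiable, order 0), with typed relation edges.
Every definition that quantifies over instances is evaluated
closed-world over this graph, so the semantics is executable and every
invariant is checkable.

## Order typing

The spine of the model is the inductive order:

* every individual has order 0;
* a category all of whose instances have order $n$ has order $n+1$.

So the category *dog* (instances: individual dogs) has order 1, and the
category *species* (instances: order-1 taxa such as *dog*) has order 2.
Three design questions arise that the induction itself does not settle,
and we resolved them as follows:

* **Empty categories.** The induction quantifies over instances, so a
  category without asserted instances has no computable order. We allow
  an explicit `declared_order`; without one, `order_of()` raises
  `UndeterminedOrder` and the validator reports a finding. Declared
  orders are never trusted blindly: as soon as instances exist, the
  computed order must agree or `DECLARED_ORDER_MISMATCH` is reported.
* **Mixed categories.** A category with instances of differing orders is
  rejected (`MixedOrderCategory`) rather than assigned the maximum plus
  one: the induction is stated for uniform categories only, and a mixed
  assignment would silently break the soundness law
  `order(category) = order(instance) + 1` that downstream checks rely
  on.
* **Acyclicity.** Instantiation must be acyclic, otherwise no order
  assignment exists; cycles are detected through strongly connected
  components and reported as `CYCLIC_INSTANTIATION`, suppressing all
  order-dependent checks so that one defect yields one root-cause
  finding.

```{r orders}
g <- ontology_graph()
g <- add_individual(g, "fido")
g <- add_individual(g, "bella")
g <- add_category(g, "dog", kind = "universal")
g <- add_category(g, "species", kind = "concept")
g <- add_edge(g, "instance_of", "fido", "dog")
g <- add_edge(g, "instance_of", "bella", "dog")
g <- add_edge(g, "instance_of", "dog", "species")
c(dog = order_of(g, "dog"), species = order_of(g, "species"))
```

## Lifted relations

Relations asserted between individuals (inherence, parthood,
participation, dependency, specification) lift to categories through a
universal-existential scheme: the lifted relation holds of categories
$X, Y$ iff every instance of $X$ is related to *some* instance of $Y$.
Two named instances of this scheme connect the descriptive level of a
registry to the models it describes:

* `categorial_instance_of(x, y)`: every instance of x instantiates some
  instance of y;
* `categorial_specifies(x, y)`: every instance of x `specifies` some
  instance of y.

`specifies` itself is kept primitive, asserted from a model object to
the model class it specifies; only its lifted form is defined. An empty
$X$ satisfies any lifted relation vacuously — we kept the logical
reading rather than special-casing it, but the integration demo filters
vacuous pairs out of its link report because they carry no information.

Because these evaluators are the package's semantic core, every one of
them is tested against an independently coded nested-loop oracle over
hundreds of random graphs, in addition to the worked examples.

## The metamodel on the graph

A registry embeds the graph and adds typed record tables. The
reconstruction keeps each ISO notion an ordinary graph citizen:

* a **DEC** is an order-1 category instantiating the DEC metaclass
  (order 2); its instances are facts (order 0). A property is a triple
  (P, R, Q): property category, connecting relation, bearer category —
  and the validator checks that the relation actually lifts.
* a **conceptual domain** is a set of value meanings. For measured
  properties, meanings arise from a *measurement partition*:
  `partition_property()` bins attributive magnitudes (after unit
  conversion) and returns disjoint, covering equivalence classes — all
  weights measured as 70 kg form the class "70 kg". Binning precision is
  a parameter; the default rounds half-to-even to integer units, which
  is base R's rounding and the usual choice for measurement data.
* a **permissible value** is a genuine relator individual with exactly
  two roles: a meaning role played by a value meaning and a value role
  played by a token (an instance of a symbol structure). Within one
  value domain the token-to-meaning map is functional; the converse may
  be many-to-one ("70" and "70.0" may both designate the 70-kg class),
  which is why decoding is defined and representation picks the first
  token in the domain's stable order.
* **facts** (instances of a DEC) bundle a bearer, an attributive
  connected to it by the property's relation, and a value meaning;
  **fact-representations** (instances of a data element) pair a fact
  with a token. `represent_fact()` followed by `decode_value()` is the
  identity on the fact's meaning — a property the tests exercise on 200
  randomly partitioned facts.

Items extend data elements with a default (which must be a permissible
value), a range constraint, and a data-acquisition process (type,
ISO-8601 temporal extension compared lexicographically — no calendar
arithmetic — and participants with at most one result fact). An item
category is an *extensional* subcategory of its data element: the
validator checks that item instances instantiate the data element
rather than assuming it. Complex concepts are composed from elementary
ones by `categorial_part`, `has_facet`, `part_of`, `has_function` and
any relation added by a vertical metamodel extension; variants of items
are derived through facets and inherit the parent's fields without
mutating it. In the blood-pressure example the two categorial parts are
the systolic and diastolic concepts; since only one part is fixed by
the narrative we name the second `DEC:Subject_Diastolic_BP`, and the
two facet names (`resting_state`, `measurement_site`) are likewise
fixture conventions of this package, not published facts.

## Phenotypic property nexus

A property nexus is a triple (property, bearer category, relation).
Phenotypic nexus classify purely by the relation: inherence →
qualitative, parthood → structural, participation → processual; the
bare `prop_dependent` relation (the default when only dependency is
known) stays unclassified. Validation evaluates the lifted relation;
`prop_dependent` is evaluated through `depends_on` edges. Because
inherence, parthood and participation are species of dependency, the
fixture generator emits a `depends_on` edge alongside every specialized
edge — this makes the weakening law testable: a nexus that validates
under a specialized relation also validates under bare dependency. The
taxonomy of dependency subtypes is left open in the literature; we
hard-code the three exemplified subtypes and keep the classifier total
via the `unclassified` value.

## Persistence, generation and mutation testing

Registries serialize to a canonical JSON dialect: UTF-8, fixed key
order, id-sorted tables. Canonicality buys a strong test: save ∘ load
is byte-identical, so any silent loss in either direction fails loudly.
CSV is used only for item catalogs at the CLI surface; time points are
ISO-8601 strings.

The fixture generator emulates a small clinical registry — object
classes with individual bearers, inherence-connected properties,
enumerated integer-kilogram domains (meanings drawn between 40 and
200 kg, a realistic adult-weight span), one fact and representation per
data element, items with a 0–300 kg range and a measuring acquisition.
Generation is a pure function of its spec (including the seed), which
the tests check by byte-comparing repeated runs. What the generator
does *not* emulate: missing data, free-text values, longitudinal
acquisitions, multi-bearer facts, non-enumerated domains. Passing
property suites on these fixtures therefore demonstrates the
correctness of the evaluators and validators, not coverage of every
registry shape occurring in practice.

`mutate_fixture()` is the adversarial half: for each of the twelve
injectable finding codes it breaks exactly one invariant at a seeded
site. The suite asserts that each injection is detected with exactly
its code and no collateral findings — which is also why dependent
checks are guarded (a DEC with no conceptual domain reports
`MISSING_CD` once, not a cascade). Injection sites are chosen to keep
the fault single: for instance, instantiation-cycle injection avoids
item categories, whose reversal would additionally corrupt the
extensional-subcategory invariant.

## Numerical and engineering choices

* Quantifiers range over asserted entities and edges only; nothing is
  inferred. This is deliberate: the definitions are *evaluated*, not
  proved.
* Entity identity is by id; labels are display-only. Ids are
  case-sensitive strings.
* Unit conversion covers mass and length prefixes; anything else is a
  `UnitMismatch`. Conversions never cross dimensions.
* Problem sizes in the test suite (500 random graphs of at most 30
  entities, 200 round-trip facts, 50 persisted registries, 50
  injections per violation code) were chosen so the whole suite
  exercises each property broadly while running in about a minute.
* The command-line interface is a thin dispatcher over the exported
  functions; machine output is JSON lines on stdout, logs go to stderr,
  and `validate` exits 0 only on a clean registry.

## Known limitations

Temporal semantics beyond kind tags (continuant/presential/process) is
out of scope, as are situation axioms, automated reasoning, and
imports of external phenotype ontologies. Registration/administration
metadata of the ISO standard (stewardship, versioning) is not modelled.
File persistence stands in for a database backend; relational or ODM
export would be additional serializers over the same document model.
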