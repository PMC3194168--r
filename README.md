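# ontomdr

An ontologically founded metadata registry for clinical and
epidemiological research, as an R package.

Study items — a subject's weight, a blood-pressure reading, a
questionnaire answer — are the basic documentation units of clinical
trials, and ISO/IEC 11179-style metadata registries describe them
through data element concepts, conceptual domains, value domains and
data elements. `ontomdr` gives that metamodel an executable semantics by
rebuilding it on a finite ontology graph of **categories** and
**individuals** with typed relation edges, governed by two ideas:

* **Inductive order typing.** Every individual has order 0; a category
  all of whose instances have order *n* has order *n* + 1. The category
  *dog* has order 1, the category *species* (whose instances are taxa
  like *dog*) has order 2. Metadata types sit at order 2, metadata items
  at order 1, application data at orders 1 and 0 — and the package
  computes and checks all of these.
* **Relation lifting.** A relation asserted between individuals (x
  inheres in y, x depends on y, x specifies y, ...) lifts to categories
  X, Y by the universal-existential condition

  &nbsp;&nbsp;&nbsp;&nbsp;lifted(X, Y) ⇔ ∀a (instance_of(a, X) → ∃b (instance_of(b, Y) ∧ r(a, b)))

  evaluated closed-world over the graph. `categorial_instance_of`,
  `categorial_specifies`, `prop_depends` and the phenotype-nexus
  validator are all instances of this scheme, and each is tested against
  an independent brute-force oracle.

On top of the graph the package provides the ISO metamodel (DECs as
object class + property triples, measurement partitions into value
meanings, permissible values as two-role relators, facts and
fact-representations), clinical-trial item extensions (defaults, ranges,
acquisition processes, complex-concept composition, item variants,
horizontal/vertical metamodel extensions), phenotypic property-nexus
classification (qualitative / structural / processual), a canonical JSON
registry dialect, a seeded fixture generator with violation injection
for mutation testing, item queries, DOT export and a CLI.

## Worked example

The subject's-weight registry builds the full chain: object class
*subject* with the individual John, property *weight* connected by
inherence, the measurement partition that puts John's 70.2 kg weight
into the integer-kilogram meaning "70 kg", a value domain mapping
meanings to tokens, the data element, the fact "John's weight being
70 kg" and its representation:

```r
library(ontomdr)
reg <- subject_weight_example()
reg
#> <mdr_registry v1.0: 26 entities, 1 DECs, 1 conceptual domains, 1 value domains,
#>   1 data elements, 1 facts, 1 representations, 1 items, 0 groups,
#>   0 complex concepts, 0 nexus>

validate_registry(reg)
#> <validation report: 0 findings>

order_of(reg, "DEC:subjects_weight")   # the concept is an order-1 category
#> [1] 1
order_of(reg, "FACT:johns_weight_70")  # its fact instance has order 0
#> [1] 0

constituents(reg, "DE:subjects_weight_kg")  # semantics + representation
#> [1] "DEC:subjects_weight" "VD:weight_kg"

decode_value(reg, "70", "VD:weight_kg")     # a value designates its meaning
#> [1] "VM:weight_70_kg"
```

The measurement partition is the bridge from raw magnitudes to value
meanings — 70.2, 69.8 and 70.4 kg all fall into one equivalence class:

```r
partition_property(data.frame(attributive = c("w1", "w2", "w3"),
                              magnitude = c(70.2, 69.8, 70.4),
                              unit = "kg"))[[1]][c("label", "members")]
#> $label
#> [1] "70 kg"
#> $members
#> [1] "w1" "w2" "w3"
```

Phenotypic property nexus classify by their connecting relation:

```r
phenotype_examples()$nexus$qualitative
#> <property nexus (Red, RedOb, inheres_in) [phenotypic]: qualitative>
```

Other entry points worth exploring: `metadata_levels_example()` (the
description / model / real-world order hierarchy), `integration_demo()`
(categorial-instantiation links between information-model and registry
vocabularies), `blood_pressure_example()` (complex concepts, item
variants, function realization), `generate_fixture()` /
`mutate_fixture()` (seeded registries and single-fault injection), and
the CLI:

```sh
Rscript inst/cli/mdr.R validate registry.json
Rscript inst/cli/mdr.R fixture --spec spec.json --out registry.json
Rscript inst/cli/mdr.R export registry.json --format dot
```

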