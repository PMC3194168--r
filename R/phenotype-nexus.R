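# Property nexus: a property, its bearer category, and the dependency
# relation connecting their instances. Phenotypic nexus classify by that
# relation (inherence -> qualitative, parthood -> structural,
# participation -> processual).

NEXUS_RELATIONS <- c("inheres_in", "part_of", "participates_in",
                     "prop_dependent")

#' Lifted property dependency
#'
#' Attributives and properties are dependent entities: they depend on
#' bearers. The individual-level relation `depends_on` lifts to categories
#' as `prop_depends(X, Y)`: every instance of X depends on some instance
#' of Y.
#'
#' @inheritParams add_category
#' @param X,Y Category ids.
#' @return `TRUE` or `FALSE`.
#' @export
prop_depends <- function(x, X, Y) {
  lift_relation(x, "depends_on", X, Y)
}

#' Construct a property nexus
#'
#' A property nexus is a triple (property, bearer category, relation).
#' When the connecting relation is left unspecified it defaults to
#' `prop_dependent`, recording only that the property depends on the
#' bearer category within the given context.
#'
#' @inheritParams add_category
#' @param property Id of the property category.
#' @param bearer_category Id of the bearer category.
#' @param relation One of `"inheres_in"`, `"part_of"`,
#'   `"participates_in"`, `"prop_dependent"`.
#' @param phenotypic Whether the property is a phenotypic property.
#' @return A list of class `mdr_property_nexus`.
#' @export
make_nexus <- function(x, property, bearer_category,
                       relation = "prop_dependent", phenotypic = TRUE) {
  graph <- as_ontology_graph(x)
  entity_of(graph, property)
  entity_of(graph, bearer_category)
  relation <- match.arg(relation, NEXUS_RELATIONS)
  structure(
    list(property = property, bearer_category = bearer_category,
         relation = relation, phenotypic = isTRUE(phenotypic)),
    class = "mdr_property_nexus"
  )
}

#' Classify a property nexus
#'
#' Classification is a total function of the nexus relation alone:
#' inherence yields a qualitative nexus, parthood a structural one,
#' participation a processual one; the bare dependency relation carries no
#' subtype and stays unclassified.
#'
#' @param nexus An [make_nexus()] object.
#' @return One of `"qualitative"`, `"structural"`, `"processual"`,
#'   `"unclassified"`.
#' @export
classify_nexus <- function(nexus) {
  if (!inherits(nexus, "mdr_property_nexus")) {
    mdr_abort("InvalidNexus", "expected an mdr_property_nexus")
  }
  switch(nexus$relation,
         inheres_in = "qualitative",
         part_of = "structural",
         participates_in = "processual",
         prop_dependent = "unclassified")
}

#' Validate a property nexus against a graph
#'
#' Evaluates the lifted form of the nexus relation: every instance of the
#' property must be connected by the relation to some instance of the
#' bearer category. `prop_dependent` is evaluated through `depends_on`
#' edges.
#'
#' @inheritParams add_category
#' @param nexus An [make_nexus()] object.
#' @return `TRUE` or `FALSE`.
#' @export
validate_nexus <- function(x, nexus) {
  if (!inherits(nexus, "mdr_property_nexus")) {
    mdr_abort("InvalidNexus", "expected an mdr_property_nexus")
  }
  rel <- if (identical(nexus$relation, "prop_dependent")) "depends_on" else
    nexus$relation
  lift_relation(x, rel, nexus$property, nexus$bearer_category)
}

#' @export
print.mdr_property_nexus <- function(x, ...) {
  cat(sprintf("<property nexus (%s, %s, %s)%s: %s>\n",
              x$property, x$bearer_category, x$relation,
              if (x$phenotypic) " [phenotypic]" else "",
              classify_nexus(x)))
  invisible(x)
}

#' Worked phenotype nexus examples
#'
#' Builds a toy graph with three phenotypic property nexus: the quality
#' property Red whose individual reds inhere in red objects; the category
#' Heart whose individual hearts are parts of human bodies; and the
#' endocrine pancreatic cells participating in insulin-production
#' processes. Every individual-level edge is accompanied by a `depends_on`
#' edge, since inherence, parthood and participation are species of
#' dependency.
#'
#' @return A list with elements `graph` and `nexus` (a named list of three
#'   [make_nexus()] objects).
#' @export
phenotype_examples <- function() {
  g <- ontology_graph()
  # qualitative: (Red, RedOb, inheres_in)
  g <- add_category(g, "Red", kind = "universal", declared_order = 1L)
  g <- add_category(g, "RedOb", kind = "universal", declared_order = 1L,
                    label = "red objects")
  g <- add_individual(g, "red_1", concrete_kind = "attributive")
  g <- add_individual(g, "rose_1", concrete_kind = "continuant")
  g <- add_edge(g, "instance_of", "red_1", "Red")
  g <- add_edge(g, "instance_of", "rose_1", "RedOb")
  g <- add_edge(g, "inheres_in", "red_1", "rose_1")
  g <- add_edge(g, "depends_on", "red_1", "rose_1")
  # structural: (Heart, HB, part_of)
  g <- add_category(g, "Heart", kind = "universal", declared_order = 1L)
  g <- add_category(g, "HB", kind = "universal", declared_order = 1L,
                    label = "human bodies")
  g <- add_individual(g, "heart_1", concrete_kind = "continuant")
  g <- add_individual(g, "body_1", concrete_kind = "continuant")
  g <- add_edge(g, "instance_of", "heart_1", "Heart")
  g <- add_edge(g, "instance_of", "body_1", "HB")
  g <- add_edge(g, "part_of", "heart_1", "body_1")
  g <- add_edge(g, "depends_on", "heart_1", "body_1")
  # processual: (EPC, IPP, participates_in)
  g <- add_category(g, "EPC", kind = "universal", declared_order = 1L,
                    label = "endocrine pancreatic cells")
  g <- add_category(g, "IPP", kind = "universal", declared_order = 1L,
                    label = "insulin production processes")
  g <- add_individual(g, "epc_1", concrete_kind = "continuant")
  g <- add_individual(g, "ipp_1", concrete_kind = "process")
  g <- add_edge(g, "instance_of", "epc_1", "EPC")
  g <- add_edge(g, "instance_of", "ipp_1", "IPP")
  g <- add_edge(g, "participates_in", "epc_1", "ipp_1")
  g <- add_edge(g, "depends_on", "epc_1", "ipp_1")
  list(
    graph = g,
    nexus = list(
      qualitative = make_nexus(g, "Red", "RedOb", "inheres_in"),
      structural = make_nexus(g, "Heart", "HB", "part_of"),
      processual = make_nexus(g, "EPC", "IPP", "participates_in")
    )
  )
}
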