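# The metadata registry: an ontology graph plus typed record tables for
# the ISO-style metamodel (DECs, conceptual domains, value domains, data
# elements, facts, fact-representations, items, groups, complex concepts,
# property nexus, metamodel extensions).

MDR_SCHEMA_VERSION <- "1.0"

# Bootstrap metaclass and support-category ids.
META_DEC <- "ISO:DEC"
META_DE <- "ISO:DataElement"
META_ITEM <- "ISO:Item"
REL_MV <- "R_mv"
SYM_STRING <- "SYM:String"

#' Create an empty metadata registry
#'
#' The registry embeds an ontology graph bootstrapped with the metamodel:
#' the metaclasses of data element concepts, data elements and items (all
#' of order 2), the value-meaning/value relation whose instances are
#' permissible-value relators, and a generic symbol-structure category
#' whose instances are tokens. Concrete concepts created by the
#' constructors below instantiate these metaclasses, so the whole registry
#' is one graph on which the order axioms can be checked.
#'
#' @return An object of class `mdr_registry`.
#' @seealso [make_dec()], [make_conceptual_domain()], [make_value_domain()],
#'   [make_data_element()], [make_fact()], [make_item()],
#'   [validate_registry()]
#' @export
mdr_registry <- function() {
  g <- ontology_graph()
  g <- add_category(g, META_DEC, kind = "concept", declared_order = 2L,
                    label = "data element concept (metaclass)")
  g <- add_category(g, META_DE, kind = "concept", declared_order = 2L,
                    label = "data element (metaclass)")
  g <- add_category(g, REL_MV, kind = "concept", declared_order = 1L,
                    label = "value meaning/value relation")
  g <- add_category(g, SYM_STRING, kind = "symbol_structure",
                    declared_order = 1L, label = "character string symbol")
  reg <- structure(
    list(
      schema_version = MDR_SCHEMA_VERSION,
      seed = NULL,
      graph = g,
      decs = list(),
      conceptual_domains = list(),
      value_domains = list(),
      data_elements = list(),
      facts = list(),
      representations = list(),
      items = list(),
      groups = list(),
      complex_concepts = list(),
      nexus = list(),
      extensions = list()
    ),
    class = "mdr_registry"
  )
  # the item metaclass is itself a (pre-registered) horizontal extension
  register_extension(reg, "horizontal", META_ITEM,
                     label = "item (metaclass)")
}

stopifnot_registry <- function(x) {
  if (!inherits(x, "mdr_registry")) {
    mdr_abort("NotARegistry", "expected an mdr_registry")
  }
  invisible(x)
}

lookup <- function(registry, table, id, what) {
  rec <- registry[[table]][[id]]
  if (is.null(rec)) {
    mdr_abort("UnknownEntity", sprintf("%s '%s' is not registered", what, id))
  }
  rec
}

#' Retrieve registered records
#'
#' Accessors for the registry's record tables. Each returns the stored
#' record (a named list) or raises `UnknownEntity`.
#'
#' @param registry An `mdr_registry`.
#' @param id Record id.
#' @return The stored record.
#' @name registry-accessors
NULL

#' @rdname registry-accessors
#' @export
get_dec <- function(registry, id) lookup(registry, "decs", id, "data element concept")

#' @rdname registry-accessors
#' @export
get_conceptual_domain <- function(registry, id)
  lookup(registry, "conceptual_domains", id, "conceptual domain")

#' @rdname registry-accessors
#' @export
get_value_domain <- function(registry, id)
  lookup(registry, "value_domains", id, "value domain")

#' @rdname registry-accessors
#' @export
get_data_element <- function(registry, id)
  lookup(registry, "data_elements", id, "data element")

#' @rdname registry-accessors
#' @export
get_fact <- function(registry, id) lookup(registry, "facts", id, "fact")

#' @rdname registry-accessors
#' @export
get_representation <- function(registry, id)
  lookup(registry, "representations", id, "fact representation")

#' @rdname registry-accessors
#' @export
get_item <- function(registry, id) lookup(registry, "items", id, "item")

#' @rdname registry-accessors
#' @export
get_complex_concept <- function(registry, id)
  lookup(registry, "complex_concepts", id, "complex concept")

#' Constituents of a registered concept
#'
#' Returns the targets of `constituent_part` edges from the given entity.
#' A data element has exactly two constituents (its data element concept
#' and its value domain); a data element concept has exactly two (its
#' object class and its property).
#'
#' @param registry An `mdr_registry` (or `ontology_graph`).
#' @param id Entity id.
#' @return A sorted character vector of entity ids.
#' @export
constituents <- function(registry, id) {
  graph <- as_ontology_graph(registry)
  sort(edge_targets(graph, "constituent_part", id))
}

#' @export
print.mdr_registry <- function(x, ...) {
  cat(sprintf(
    paste0("<mdr_registry v%s: %d entities, %d DECs, %d conceptual domains, ",
           "%d value domains,\n  %d data elements, %d facts, %d representations, ",
           "%d items, %d groups,\n  %d complex concepts, %d nexus>\n"),
    x$schema_version, length(x$graph$entities), length(x$decs),
    length(x$conceptual_domains), length(x$value_domains),
    length(x$data_elements), length(x$facts), length(x$representations),
    length(x$items), length(x$groups), length(x$complex_concepts),
    length(x$nexus)))
  invisible(x)
}
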