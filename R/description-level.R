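# The descriptive level: metadata types/items and application-level data
# types/items as higher-order categories in the same graph as the model
# entities they describe, plus the two lifted categorial relations that
# connect description-level categories through their instances.

#' Categorial instantiation
#'
#' `categorial_instance_of(x, y)` holds iff every instance a of x has some
#' instance b of y such that a is an instance of b:
#' for all a (instance_of(a, x) -> exists b (instance_of(b, y) &
#' instance_of(a, b))). The condition is evaluated over the finite graph;
#' an x without instances satisfies it vacuously.
#'
#' @inheritParams add_category
#' @param cx,cy Category ids.
#' @return `TRUE` or `FALSE`.
#' @export
categorial_instance_of <- function(x, cx, cy) {
  graph <- as_ontology_graph(x)
  xs <- instances_of(graph, cx)
  ys <- instances_of(graph, cy)
  for (a in xs) {
    bs <- edge_targets(graph, "instance_of", a)
    if (!any(bs %in% ys)) return(FALSE)
  }
  TRUE
}

#' Categorial specification
#'
#' `categorial_specifies(x, y)` holds iff every instance a of x has some
#' instance b of y with an asserted `specifies` edge from a to b. The
#' `specifies` edge is primitive here and runs from a model object (order
#' 0) to the model class (order 1) it specifies.
#'
#' @inheritParams categorial_instance_of
#' @return `TRUE` or `FALSE`.
#' @export
categorial_specifies <- function(x, cx, cy) {
  graph <- as_ontology_graph(x)
  xs <- instances_of(graph, cx)
  ys <- instances_of(graph, cy)
  for (a in xs) {
    bs <- edge_targets(graph, "specifies", a)
    if (!any(bs %in% ys)) return(FALSE)
  }
  TRUE
}

#' Worked example: metadata and application data
#'
#' Builds the three-level worked example relating descriptive entities,
#' model entities and real-world entities. The description level holds the
#' four descriptive categories (`metadata_type` and
#' `application_level_data_type` of order 2; `metadata_item` and
#' `application_level_data_item` of order 1). The model level holds
#' `Object_Class` (a model class, order 1), the model object `Person_object`
#' (order 0) that is an instance of both `metadata_item` and
#' `Object_Class`, the model class `Person_class` (order 1) and the model
#' object `John_object` (order 0). `Person_object` specifies
#' `Person_class`. The real-world level holds the category of object
#' classes (order 2), the category Person (order 1) and the individual John
#' (order 0), linked by instantiation; `models` edges connect each model
#' entity to the real-world entity it models — both `Person_object` and
#' `Person_class` model the same real-world category Person.
#'
#' @return An `ontology_graph` that passes [well_typed()] with 0 findings.
#' @export
metadata_levels_example <- function() {
  g <- ontology_graph()
  # description level
  g <- add_category(g, "metadata_type", declared_order = 2L,
                    label = "metadata type", level = "description",
                    descriptive_role = "metadata_type")
  g <- add_category(g, "metadata_item", declared_order = 1L,
                    label = "metadata item", level = "description",
                    descriptive_role = "metadata_item")
  g <- add_category(g, "application_level_data_type", declared_order = 2L,
                    label = "application level data type",
                    level = "description",
                    descriptive_role = "application_level_data_type")
  g <- add_category(g, "application_level_data_item", declared_order = 1L,
                    label = "application level data item",
                    level = "description",
                    descriptive_role = "application_level_data_item")
  # model level
  g <- add_category(g, "Object_Class", declared_order = 1L,
                    label = "Object_Class (model class)", level = "model")
  g <- add_category(g, "Person_class", declared_order = 1L,
                    label = "Person (model class)", level = "model")
  g <- add_individual(g, "Person_object", concrete_kind = "abstract",
                      label = "Person (model object)", level = "model")
  g <- add_individual(g, "John_object", concrete_kind = "abstract",
                      label = "John (model object)", level = "model")
  # real world
  g <- add_category(g, "object_class_rw", declared_order = 2L,
                    label = "object class", level = "real_world")
  g <- add_category(g, "Person_rw", declared_order = 1L, label = "Person",
                    level = "real_world")
  g <- add_individual(g, "John_rw", concrete_kind = "continuant",
                      label = "John", level = "real_world")
  # descriptive instantiation
  g <- add_edge(g, "instance_of", "Object_Class", "metadata_type")
  g <- add_edge(g, "instance_of", "Person_object", "metadata_item")
  g <- add_edge(g, "instance_of", "Person_class", "application_level_data_type")
  g <- add_edge(g, "instance_of", "John_object", "application_level_data_item")
  # model-level instantiation
  g <- add_edge(g, "instance_of", "Person_object", "Object_Class")
  g <- add_edge(g, "instance_of", "John_object", "Person_class")
  # specification: model object -> model class
  g <- add_edge(g, "specifies", "Person_object", "Person_class")
  # real-world instantiation
  g <- add_edge(g, "instance_of", "John_rw", "Person_rw")
  g <- add_edge(g, "instance_of", "Person_rw", "object_class_rw")
  # modelling links
  g <- add_edge(g, "models", "Object_Class", "object_class_rw")
  g <- add_edge(g, "models", "Person_object", "Person_rw")
  g <- add_edge(g, "models", "Person_class", "Person_rw")
  g <- add_edge(g, "models", "John_object", "John_rw")
  g
}

#' Compute all non-vacuous categorial-instantiation links
#'
#' For every ordered pair of distinct categories (x, y) where x has at
#' least one instance, records a link when [categorial_instance_of()]
#' holds. Pairs with an empty x are omitted: they hold vacuously and carry
#' no integration information.
#'
#' @inheritParams add_category
#' @return A data frame with columns `source` and `target`, ordered by
#'   (source, target).
#' @export
categorial_instance_links <- function(x) {
  graph <- as_ontology_graph(x)
  cats <- names(graph$entities)[vapply(graph$entities, function(e)
    identical(e$type, "category"), logical(1))]
  cats <- sort(cats)
  src <- character()
  tgt <- character()
  for (a in cats) {
    if (length(instances_of(graph, a)) == 0L) next
    for (b in cats) {
      if (a == b) next
      if (categorial_instance_of(graph, a, b)) {
        src <- c(src, a)
        tgt <- c(tgt, b)
      }
    }
  }
  data.frame(source = src, target = tgt, stringsAsFactors = FALSE)
}

#' Toy semantic-integration demonstration
#'
#' Builds a small model in which an application-level information-model
#' category `observation` (as used by clinical information models) and a
#' metadata-registry category `data_element` are embedded in one graph: the
#' concrete data element `blood_pressure` is an instance of
#' `data_element`, and the individual reading
#' `bp_john_2001_01_01` is an instance of both `observation` and
#' `blood_pressure`. The category `entry` has an instance that belongs to
#' no concrete data element. The demo computes all non-vacuous
#' categorial-instantiation links; interoperability between the two
#' vocabularies shows up as the link observation -> data_element.
#'
#' @return A list with elements `graph` (the toy `ontology_graph`) and
#'   `links` (the data frame from [categorial_instance_links()]).
#' @export
integration_demo <- function() {
  g <- ontology_graph()
  g <- add_category(g, "data_element", declared_order = 2L,
                    label = "data element")
  g <- add_category(g, "observation", declared_order = 1L)
  g <- add_category(g, "entry", declared_order = 1L)
  g <- add_category(g, "blood_pressure", declared_order = 1L,
                    label = "blood pressure")
  g <- add_edge(g, "instance_of", "blood_pressure", "data_element")
  g <- add_individual(g, "bp_john_2001_01_01", concrete_kind = "presential",
                      label = "blood pressure of John on 01.01.2001")
  g <- add_edge(g, "instance_of", "bp_john_2001_01_01", "observation")
  g <- add_edge(g, "instance_of", "bp_john_2001_01_01", "blood_pressure")
  g <- add_individual(g, "entry_record_1", concrete_kind = "presential",
                      label = "an entry without a data element")
  g <- add_edge(g, "instance_of", "entry_record_1", "entry")
  list(graph = g, links = categorial_instance_links(g))
}

#' The three levels of the metadata-repository architecture
#'
#' The repository architecture stacks an abstract level (the ontologically
#' founded metamodel), a level of elementary concepts (concrete data
#' element concepts, object classes, properties and items instantiating the
#' metamodel) and a level of complex concepts (elementary concepts combined
#' by relations such as categorial parthood and facets).
#'
#' @return A character vector of length 3.
#' @export
mdr_levels <- function() {
  c("abstract", "elementary_concepts", "complex_concepts")
}
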