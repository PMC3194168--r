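# Item extensions of the metamodel: items (data elements with default,
# range and data-acquisition specification), item groups and variants,
# complex-concept composition, and horizontal/vertical metamodel
# extensions.

ACQUISITION_TYPES <- c("questioning", "counting", "measuring", "observation")
ACQUISITION_ROLES <- c("subject", "examiner", "instrument", "result_fact")
COMPONENT_RELATIONS <- c("categorial_part", "has_facet", "part_of",
                         "has_function")

#' Define a range constraint
#'
#' @param lower,upper Optional numeric bounds; `lower <= upper` when both
#'   are given.
#' @param unit Measurement unit of the bounds.
#' @param inclusive Logical pair: whether the lower/upper bound is
#'   inclusive.
#' @return A list of class `mdr_range`.
#' @export
range_constraint <- function(lower = NULL, upper = NULL, unit = "",
                             inclusive = c(TRUE, TRUE)) {
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    mdr_abort("InvalidRange", "lower bound exceeds upper bound")
  }
  if (length(inclusive) != 2L || !is.logical(inclusive)) {
    mdr_abort("InvalidRange", "inclusive must be a logical pair")
  }
  structure(list(lower = lower, upper = upper, unit = unit,
                 inclusive = as.logical(inclusive)),
            class = "mdr_range")
}

# Normalize an ISO-8601 time string for lexicographic comparison: trim and
# uppercase the designators. No calendar arithmetic is performed.
normalize_time <- function(x) toupper(trimws(x))

#' Specify a data-acquisition process
#'
#' Data acquisition is the process through which an item's values arise.
#' It has a type (questioning, counting, measuring or observation), a
#' temporal extension of non-zero duration given as two ISO-8601 time
#' points, and participants playing the roles subject, examiner,
#' instrument and (at most once) result_fact.
#'
#' @param type One of `"questioning"`, `"counting"`, `"measuring"`,
#'   `"observation"`.
#' @param start,end ISO-8601 time strings with `start < end`
#'   (lexicographic comparison after normalization).
#' @param participants A data frame with columns `role` and `entity`, or
#'   `NULL`.
#' @return A list of class `mdr_acquisition`.
#' @export
data_acquisition <- function(type, start, end, participants = NULL) {
  type <- match.arg(type, ACQUISITION_TYPES)
  start <- normalize_time(start)
  end <- normalize_time(end)
  if (!(start < end)) {
    mdr_abort("InvalidTemporalExtension",
              "acquisition must have a non-zero duration (start < end)")
  }
  if (!is.null(participants)) {
    if (!all(c("role", "entity") %in% names(participants))) {
      mdr_abort("InvalidParticipants",
                "participants need columns 'role' and 'entity'")
    }
    bad <- setdiff(participants$role, ACQUISITION_ROLES)
    if (length(bad)) {
      mdr_abort("InvalidParticipants",
                sprintf("unknown participant role(s): %s",
                        paste(bad, collapse = ", ")))
    }
    if (sum(participants$role == "result_fact") > 1L) {
      mdr_abort("InvalidParticipants", "at most one result_fact participant")
    }
  }
  structure(list(type = type, start = start, end = end,
                 participants = participants),
            class = "mdr_acquisition")
}

#' Create an item from a data element
#'
#' An item is a special data element: the basic documentation unit of a
#' clinical trial, extending a data element with an optional default
#' value, range constraint and data-acquisition specification. The item is
#' registered as an order-1 category instantiating the item metaclass and
#' is an extensional subcategory of its data element: every instance of
#' the item category must also instantiate the data-element category
#' (checked by [validate_registry()], not assumed).
#'
#' @inheritParams make_dec
#' @param data_element Id of the underlying data element.
#' @param default Optional default value (lexical form); must occur among
#'   the value domain's permissible values.
#' @param range Optional [range_constraint()].
#' @param acquisition Optional [data_acquisition()].
#' @return The updated registry.
#' @export
make_item <- function(registry, id, data_element, default = NULL,
                      range = NULL, acquisition = NULL, label = id) {
  stopifnot_registry(registry)
  de <- get_data_element(registry, data_element)
  if (!is.null(default)) {
    vd <- get_value_domain(registry, de$value_domain)
    lex <- vapply(vd$permissible_values, `[[`, character(1), "lexical")
    if (!default %in% lex) {
      mdr_abort("DefaultNotInValueDomain", sprintf(
        "default '%s' is not a permissible value of '%s'",
        default, de$value_domain))
    }
  }
  if (!is.null(range) && !inherits(range, "mdr_range")) {
    mdr_abort("InvalidRange", "range must be built with range_constraint()")
  }
  if (!is.null(acquisition) && !inherits(acquisition, "mdr_acquisition")) {
    mdr_abort("InvalidAcquisition",
              "acquisition must be built with data_acquisition()")
  }
  registry <- add_category(registry, id, kind = "concept",
                           declared_order = 1L, label = label)
  registry <- add_edge(registry, "instance_of", id, META_ITEM)
  registry$items[[id]] <- list(
    id = id, label = label, data_element = data_element,
    default = default,
    range = if (is.null(range)) NULL else unclass(range),
    acquisition = if (is.null(acquisition)) NULL else unclass(acquisition),
    parent = NULL, facet = NULL
  )
  registry
}

#' Check a magnitude against a range constraint
#'
#' @param magnitude Numeric magnitude.
#' @param unit Unit of the magnitude; must be convertible to the range's
#'   unit.
#' @param range A [range_constraint()].
#' @return `TRUE` iff the magnitude lies within the bounds under the
#'   stated inclusivity; absent bounds are unconstrained.
#' @export
check_range <- function(magnitude, unit, range) {
  if (!inherits(range, "mdr_range")) {
    mdr_abort("InvalidRange", "range must be built with range_constraint()")
  }
  v <- convert_unit(magnitude, unit, range$unit)
  if (!is.null(range$lower)) {
    ok <- if (range$inclusive[[1L]]) v >= range$lower else v > range$lower
    if (!ok) return(FALSE)
  }
  if (!is.null(range$upper)) {
    ok <- if (range$inclusive[[2L]]) v <= range$upper else v < range$upper
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Compose elementary concepts into a complex concept
#'
#' Complex concepts are built from elementary ones by connecting a base
#' concept to components through composition relations: categorial
#' parthood, facets, parthood and function, plus any relation added by a
#' vertical metamodel extension. Duplicate (relation, target) pairs are
#' rejected. The edges are asserted from the base concept, so component
#' counts can be recovered from the graph.
#'
#' @inheritParams make_dec
#' @param base Id of the base concept.
#' @param components A list of pairs `list(relation = , target = )`.
#' @return The updated registry.
#' @export
compose_complex <- function(registry, id, base, components, label = id) {
  stopifnot_registry(registry)
  entity_of(registry$graph, base)
  allowed <- union(COMPONENT_RELATIONS,
                   setdiff(registry$graph$relations, BASE_BINARY_RELATIONS))
  seen <- character()
  for (cmp in components) {
    if (is.null(cmp$relation) || is.null(cmp$target)) {
      mdr_abort("UnknownComponent",
                "each component needs elements 'relation' and 'target'")
    }
    if (!cmp$relation %in% allowed) {
      mdr_abort("UnknownRelation", sprintf(
        "'%s' is not a composition relation", cmp$relation))
    }
    if (!graph_has(registry$graph, cmp$target)) {
      mdr_abort("UnknownComponent", sprintf(
        "component target '%s' is not registered", cmp$target))
    }
    key <- paste(cmp$relation, cmp$target, sep = "\r")
    if (key %in% seen) {
      mdr_abort("DuplicateComponent", sprintf(
        "duplicate component (%s, %s)", cmp$relation, cmp$target))
    }
    seen <- c(seen, key)
  }
  if (!is.null(registry$complex_concepts[[id]])) {
    mdr_abort("DuplicateId", sprintf("complex concept '%s' already exists", id))
  }
  for (cmp in components) {
    registry <- add_edge(registry, cmp$relation, base, cmp$target)
  }
  registry$complex_concepts[[id]] <- list(
    id = id, label = label, base = base,
    components = lapply(components, function(cmp)
      list(relation = cmp$relation, target = cmp$target))
  )
  registry
}

#' Count a complex concept's components by relation
#'
#' @inheritParams make_dec
#' @return A named integer vector, one entry per composition relation used.
#' @export
component_counts <- function(registry, id) {
  cc <- get_complex_concept(registry, id)
  rel <- vapply(cc$components, `[[`, character(1), "relation")
  table_out <- table(rel)
  out <- as.integer(table_out)
  names(out) <- names(table_out)
  out
}

#' Derive an item variant through a facet
#'
#' A variant is a new item linked to a facet concept by a `has_facet`
#' edge. It inherits the parent's data element, default and range unless
#' overridden; the parent item is not modified.
#'
#' @inheritParams make_dec
#' @param item Parent item id.
#' @param facet Id of a registered facet concept.
#' @param id Id for the variant.
#' @param default,range,acquisition Optional overrides.
#' @return The updated registry.
#' @export
derive_variant <- function(registry, item, facet, id,
                           default = NULL, range = NULL, acquisition = NULL,
                           label = id) {
  stopifnot_registry(registry)
  parent <- get_item(registry, item)
  if (!graph_has(registry$graph, facet)) {
    mdr_abort("UnknownFacet", sprintf("facet '%s' is not registered", facet))
  }
  registry <- make_item(
    registry, id, parent$data_element,
    default = if (is.null(default)) parent$default else default,
    range = if (is.null(range)) {
      if (is.null(parent$range)) NULL else
        structure(parent$range, class = "mdr_range")
    } else range,
    acquisition = if (is.null(acquisition)) {
      if (is.null(parent$acquisition)) NULL else
        structure(parent$acquisition, class = "mdr_acquisition")
    } else acquisition,
    label = label
  )
  registry <- add_edge(registry, "has_facet", id, facet)
  registry$items[[id]]$parent <- item
  registry$items[[id]]$facet <- facet
  registry
}

#' Group items into an ordered item group
#'
#' @inheritParams make_dec
#' @param members Ordered character vector of item ids; distinct and
#'   non-empty.
#' @return The updated registry.
#' @export
make_item_group <- function(registry, id, members, label = id) {
  stopifnot_registry(registry)
  if (length(members) == 0L) {
    mdr_abort("EmptyGroup", "an item group needs at least one member")
  }
  if (anyDuplicated(members)) {
    mdr_abort("DuplicateId", "item group members must be distinct")
  }
  for (m in members) get_item(registry, m)
  if (!is.null(registry$groups[[id]])) {
    mdr_abort("DuplicateId", sprintf("item group '%s' already exists", id))
  }
  registry$groups[[id]] <- list(id = id, label = label,
                                members = as.character(members))
  registry
}

#' Extend the metamodel horizontally or vertically
#'
#' A horizontal extension adds a new metaclass (an order-2 category
#' available for instantiation, like the item metaclass); a vertical
#' extension adds a new relation, an instance of the metaclass relation,
#' usable in [compose_complex()] and [lift_relation()].
#'
#' @inheritParams make_dec
#' @param kind `"horizontal"` or `"vertical"`.
#' @param id Id of the new metaclass or relation.
#' @param declared_order Order of a horizontal metaclass; must be 2.
#' @param label Display label (horizontal extensions only).
#' @return The updated registry.
#' @export
register_extension <- function(registry, kind, id, declared_order = 2L,
                               label = id) {
  stopifnot_registry(registry)
  kind <- match.arg(kind, c("horizontal", "vertical"))
  if (kind == "horizontal") {
    if (!identical(as.integer(declared_order), 2L)) {
      mdr_abort("WrongOrder", "a horizontal metaclass must have order 2")
    }
    registry <- add_category(registry, id, kind = "concept",
                             declared_order = 2L, label = label)
  } else {
    if (id %in% registry$graph$relations) {
      mdr_abort("DuplicateId", sprintf("relation '%s' already exists", id))
    }
    registry$graph$relations <- c(registry$graph$relations, id)
  }
  registry$extensions[[id]] <- list(kind = kind, added = id)
  registry
}
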