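# The ISO 11179 core reconstructed on the ontology graph: data element
# concepts as object class + property triples, conceptual domains of value
# meanings (measurement partitions), value domains as sets of
# permissible-value relators, facts and fact-representations.

#' Specify a property with its connecting relation and bearer category
#'
#' A property is fully specified by a triple (P, R, Q): the property
#' category P whose instances are attributives, the connecting relation R
#' (by default inherence) and the bearer category Q whose instances carry
#' the attributives.
#'
#' @param category Id of the property category.
#' @param bearer_class Id of the bearer (object class) category.
#' @param connecting_relation Relation name connecting attributives to
#'   bearers (e.g. `"inheres_in"`, `"part_of"`, `"participates_in"`).
#' @return A list of class `mdr_property_spec`.
#' @export
property_spec <- function(category, bearer_class,
                          connecting_relation = "inheres_in") {
  structure(
    list(category = category, bearer_class = bearer_class,
         connecting_relation = connecting_relation),
    class = "mdr_property_spec"
  )
}

#' Create a data element concept
#'
#' A data element concept (DEC) pairs an object class with a property whose
#' bearer category is that object class. The DEC is registered as an
#' order-1 category instantiating the DEC metaclass; its instances are
#' facts. `constituent_part` edges record the two constituents (object
#' class and property).
#'
#' @param registry An `mdr_registry`.
#' @param id Id for the new DEC.
#' @param object_class Id of an order-1 category whose instances are
#'   real-world individuals.
#' @param property An [property_spec()] whose `bearer_class` equals
#'   `object_class`.
#' @param label Display label.
#' @return The updated registry.
#' @export
make_dec <- function(registry, id, object_class, property, label = id) {
  stopifnot_registry(registry)
  if (!inherits(property, "mdr_property_spec")) {
    mdr_abort("InvalidProperty", "property must be built with property_spec()")
  }
  entity_of(registry$graph, object_class)
  entity_of(registry$graph, property$category)
  if (!identical(property$bearer_class, object_class)) {
    mdr_abort("BearerMismatch", sprintf(
      "property bearer class '%s' does not match object class '%s'",
      property$bearer_class, object_class))
  }
  registry <- add_category(registry, id, kind = "concept",
                           declared_order = 1L, label = label)
  registry <- add_edge(registry, "instance_of", id, META_DEC)
  registry <- add_edge(registry, "constituent_part", id, object_class)
  registry <- add_edge(registry, "constituent_part", id, property$category)
  registry$decs[[id]] <- list(
    id = id, label = label, object_class = object_class,
    property = unclass(property), conceptual_domain = NULL
  )
  registry
}

#' Define a value meaning
#'
#' A value meaning is the semantic content of a value: here, an equivalence
#' class of property instances (attributives), typically induced by a
#' measurement partition ("70 kg" names the class of all weight instances
#' measured as 70 kg). The member set may be empty for described domains.
#'
#' @param id Meaning id.
#' @param label Human-readable label, e.g. `"70 kg"`.
#' @param members Character vector of attributive ids in the class.
#' @param magnitude Optional numeric magnitude carried by the meaning.
#' @param unit Optional measurement unit.
#' @return A list of class `mdr_value_meaning`.
#' @export
value_meaning <- function(id, label = id, members = character(),
                          magnitude = NULL, unit = NULL) {
  check_id(id)
  structure(
    list(id = id, label = label, members = as.character(members),
         magnitude = magnitude, unit = unit),
    class = "mdr_value_meaning"
  )
}

#' Create a conceptual domain
#'
#' A conceptual domain is specified by an enumerated list of value meanings
#' and/or a textual description (the two subtypes are non-exclusive, but at
#' least one must be given). The domain and its meanings are added to the
#' graph as abstract individuals so that meanings can play relator roles.
#'
#' @inheritParams make_dec
#' @param meanings Optional list of [value_meaning()] objects.
#' @param description Optional textual description.
#' @return The updated registry.
#' @export
make_conceptual_domain <- function(registry, id, meanings = NULL,
                                   description = NULL, label = id) {
  stopifnot_registry(registry)
  if (is.null(meanings) && is.null(description)) {
    mdr_abort("InvalidDomain",
              "a conceptual domain needs an enumeration and/or a description")
  }
  if (!is.null(meanings)) {
    for (m in meanings) {
      if (!inherits(m, "mdr_value_meaning")) {
        mdr_abort("InvalidDomain", "meanings must be value_meaning() objects")
      }
    }
  }
  registry <- add_individual(registry, id, concrete_kind = "abstract",
                             label = label)
  if (!is.null(meanings)) {
    for (m in meanings) {
      registry <- add_individual(registry, m$id, concrete_kind = "abstract",
                                 label = m$label)
    }
  }
  rec <- list(id = id, label = label, description = description,
              meanings = list())
  if (!is.null(meanings)) {
    for (m in meanings) rec$meanings[[m$id]] <- unclass(m)
  }
  registry$conceptual_domains[[id]] <- rec
  registry
}

#' Bind a conceptual domain to a data element concept
#'
#' Every DEC is associated with exactly one conceptual domain; a second
#' binding is rejected with `AlreadyBound`.
#'
#' @inheritParams make_dec
#' @param dec DEC id.
#' @param cd Conceptual domain id.
#' @return The updated registry.
#' @export
bind_conceptual_domain <- function(registry, dec, cd) {
  stopifnot_registry(registry)
  rec <- get_dec(registry, dec)
  get_conceptual_domain(registry, cd)
  if (!is.null(rec$conceptual_domain)) {
    mdr_abort("AlreadyBound", sprintf(
      "DEC '%s' is already bound to conceptual domain '%s'",
      dec, rec$conceptual_domain))
  }
  registry$decs[[dec]]$conceptual_domain <- cd
  registry
}

# Scale factors relative to each dimension's base unit; conversion is only
# defined within a dimension.
UNIT_TABLE <- list(
  mass = c(mg = 1e-6, g = 1e-3, kg = 1),
  length = c(mm = 1e-3, cm = 1e-2, m = 1)
)

convert_unit <- function(value, from, to) {
  if (identical(from, to)) return(value)
  for (dim in UNIT_TABLE) {
    if (from %in% names(dim) && to %in% names(dim)) {
      return(value * dim[[from]] / dim[[to]])
    }
  }
  mdr_abort("UnitMismatch",
            sprintf("cannot convert from unit '%s' to '%s'", from, to))
}

#' Partition property instances into value meanings by measurement
#'
#' A measuring process induces a natural partition of a property's
#' instances into equivalence classes: all attributives measured as the
#' same value form one class, which becomes a value meaning of the
#' conceptual domain. Binning is parameterised by the target unit and a
#' rounding precision; rounding is round-half-to-even (the default bins to
#' integer units, so magnitudes 70.2, 69.8 and 70.4 kg all fall into the
#' class labelled "70 kg"). Classes are pairwise disjoint and cover the
#' input.
#'
#' @param measurements A data frame with columns `attributive` (ids),
#'   `magnitude` (numeric) and `unit` (character), or an empty data
#'   frame/`NULL` for no measurements.
#' @param unit Target unit of the measure.
#' @param digits Rounding precision in decimal digits of the target unit.
#' @param id_prefix Prefix used to build meaning ids.
#' @return A list of [value_meaning()] objects ordered by magnitude, each
#'   carrying its bin magnitude, unit and member attributives.
#' @export
partition_property <- function(measurements, unit = "kg", digits = 0L,
                               id_prefix = "vm") {
  if (is.null(measurements) || nrow(measurements) == 0L) return(list())
  needed <- c("attributive", "magnitude", "unit")
  if (!all(needed %in% names(measurements))) {
    mdr_abort("InvalidMeasurements",
              "measurements need columns attributive, magnitude, unit")
  }
  conv <- mapply(convert_unit, measurements$magnitude, measurements$unit,
                 MoreArgs = list(to = unit))
  bins <- round(conv, digits)
  out <- list()
  for (b in sort(unique(bins))) {
    members <- measurements$attributive[bins == b]
    lab <- paste(format(b, trim = TRUE, scientific = FALSE), unit)
    vm_id <- sprintf("%s_%s_%s", id_prefix,
                     gsub("[^0-9A-Za-z.-]", "_", format(b, trim = TRUE,
                                                        scientific = FALSE)),
                     unit)
    out[[length(out) + 1L]] <- value_meaning(
      vm_id, label = lab, members = members, magnitude = b, unit = unit)
  }
  out
}

#' Create a value domain of permissible values
#'
#' A value domain represents a conceptual domain through a set of
#' permissible values. Each permissible value is a relator instance of the
#' value-meaning/value relation with exactly two roles: the meaning role,
#' played by a value meaning of the represented conceptual domain, and the
#' value role, played by a token (an instance of a symbol structure). The
#' token-to-meaning mapping is functional within one value domain: each
#' lexical value designates exactly one meaning.
#'
#' @inheritParams make_dec
#' @param represents Id of the represented conceptual domain.
#' @param values A list of pairs `list(meaning = <meaning id>, lexical =
#'   <string>)`.
#' @return The updated registry.
#' @export
make_value_domain <- function(registry, id, represents, values, label = id) {
  stopifnot_registry(registry)
  cd <- get_conceptual_domain(registry, represents)
  lex_seen <- list()
  registry <- add_individual(registry, id, concrete_kind = "abstract",
                             label = label)
  pvs <- list()
  for (v in values) {
    if (is.null(v$meaning) || is.null(v$lexical)) {
      mdr_abort("InvalidPermissibleValue",
                "each value needs elements 'meaning' and 'lexical'")
    }
    if (!v$meaning %in% names(cd$meanings)) {
      mdr_abort("MeaningNotInDomain", sprintf(
        "meaning '%s' is not in conceptual domain '%s'", v$meaning, represents))
    }
    prev <- lex_seen[[v$lexical]]
    if (!is.null(prev) && !identical(prev, v$meaning)) {
      mdr_abort("NonfunctionalTokenMap", sprintf(
        "lexical '%s' would designate two meanings in value domain '%s'",
        v$lexical, id))
    }
    lex_seen[[v$lexical]] <- v$meaning
    token_id <- sprintf("%s__tok_%s",
                        id, gsub("[^0-9A-Za-z._-]", "_", v$lexical))
    if (!graph_has(registry$graph, token_id)) {
      registry <- add_individual(registry, token_id, concrete_kind = "token",
                                 label = v$lexical, lexical = v$lexical)
      registry <- add_edge(registry, "instance_of", token_id, SYM_STRING)
    }
    made <- make_relator(registry, REL_MV,
                         list(c("meaning", v$meaning), c("value", token_id)),
                         id = sprintf("%s__pv_%d", id, length(pvs) + 1L))
    registry <- made$graph
    pvs[[length(pvs) + 1L]] <- list(relator = made$id, meaning = v$meaning,
                                    token = token_id, lexical = v$lexical)
  }
  registry$value_domains[[id]] <- list(
    id = id, label = label, represents = represents,
    permissible_values = pvs
  )
  registry
}

#' Create a data element
#'
#' A data element pairs a data element concept (its semantics) with a
#' value domain (its representation); the value domain must represent the
#' DEC's conceptual domain. The data element is registered as an order-1
#' category instantiating the data-element metaclass; its instances are
#' fact-representations. `constituent_part` edges record the two
#' constituents.
#'
#' @inheritParams make_dec
#' @param dec DEC id (with a bound conceptual domain).
#' @param value_domain Value domain id.
#' @return The updated registry.
#' @export
make_data_element <- function(registry, id, dec, value_domain, label = id) {
  stopifnot_registry(registry)
  drec <- get_dec(registry, dec)
  vrec <- get_value_domain(registry, value_domain)
  if (is.null(drec$conceptual_domain)) {
    mdr_abort("MissingConceptualDomain", sprintf(
      "DEC '%s' has no bound conceptual domain", dec))
  }
  if (!identical(vrec$represents, drec$conceptual_domain)) {
    mdr_abort("DomainMismatch", sprintf(
      "value domain '%s' represents '%s', not the DEC's domain '%s'",
      value_domain, vrec$represents, drec$conceptual_domain))
  }
  registry <- add_category(registry, id, kind = "concept",
                           declared_order = 1L, label = label)
  registry <- add_edge(registry, "instance_of", id, META_DE)
  registry <- add_edge(registry, "constituent_part", id, dec)
  registry <- add_edge(registry, "constituent_part", id, value_domain)
  registry$data_elements[[id]] <- list(
    id = id, label = label, dec = dec, value_domain = value_domain
  )
  registry
}

cd_is_enumerated <- function(cd) length(cd$meanings) > 0L

#' Record a fact as an instance of a data element concept
#'
#' A fact combines an instance of the DEC's object class (the bearer), an
#' instance of its property (the attributive, connected to the bearer by
#' the property's connecting relation) and a value meaning from the DEC's
#' conceptual domain. For enumerated domains the attributive must be a
#' member of the meaning's equivalence class. The fact is registered as an
#' order-0 individual instantiating the DEC.
#'
#' @inheritParams make_dec
#' @param object_individual Id of the bearer individual.
#' @param attributive Id of the attributive individual.
#' @param meaning Id of the value meaning.
#' @param dec DEC id.
#' @return The updated registry.
#' @export
make_fact <- function(registry, id, object_individual, attributive, meaning,
                      dec, label = id) {
  stopifnot_registry(registry)
  drec <- get_dec(registry, dec)
  g <- registry$graph
  if (!has_edge(g, "instance_of", object_individual, drec$object_class)) {
    mdr_abort("NotInstanceOfObjectClass", sprintf(
      "'%s' is not an instance of object class '%s'",
      object_individual, drec$object_class))
  }
  if (!has_edge(g, "instance_of", attributive, drec$property$category)) {
    mdr_abort("NotInstanceOfProperty", sprintf(
      "'%s' is not an instance of property '%s'",
      attributive, drec$property$category))
  }
  if (!has_edge(g, drec$property$connecting_relation, attributive,
                object_individual)) {
    mdr_abort("AttributiveNotConnected", sprintf(
      "attributive '%s' is not connected to '%s' by '%s'",
      attributive, object_individual, drec$property$connecting_relation))
  }
  if (is.null(drec$conceptual_domain)) {
    mdr_abort("MissingConceptualDomain", sprintf(
      "DEC '%s' has no bound conceptual domain", dec))
  }
  cd <- get_conceptual_domain(registry, drec$conceptual_domain)
  if (cd_is_enumerated(cd)) {
    vm <- cd$meanings[[meaning]]
    if (is.null(vm)) {
      mdr_abort("MeaningMismatch", sprintf(
        "meaning '%s' is not in conceptual domain '%s'",
        meaning, drec$conceptual_domain))
    }
    if (!attributive %in% vm$members) {
      mdr_abort("MeaningMismatch", sprintf(
        "attributive '%s' is not a member of value meaning '%s'",
        attributive, meaning))
    }
  }
  registry <- add_individual(registry, id, concrete_kind = "fact",
                             label = label)
  registry <- add_edge(registry, "instance_of", id, dec)
  registry$facts[[id]] <- list(
    id = id, label = label, object_individual = object_individual,
    attributive = attributive, value_meaning = meaning, of_dec = dec
  )
  registry
}

#' Represent a fact as a fact-representation in a value domain
#'
#' Pairs a fact with the token whose permissible value carries the fact's
#' value meaning. The value domain must represent the conceptual domain of
#' the fact's DEC, and the meaning must occur among the domain's
#' permissible values; when several tokens designate the meaning, the
#' first in the domain's stable order is used. The representation is
#' registered as an instance of the data element.
#'
#' @inheritParams make_dec
#' @param fact Fact id.
#' @param data_element Data element id whose value domain represents the
#'   fact's conceptual domain.
#' @param id Optional representation id; generated when `NULL`.
#' @return A list with elements `registry`, `id` (representation id),
#'   `token` (token entity id) and `lexical` (the written value).
#' @export
represent_fact <- function(registry, fact, data_element, id = NULL) {
  stopifnot_registry(registry)
  frec <- get_fact(registry, fact)
  de <- get_data_element(registry, data_element)
  vd <- get_value_domain(registry, de$value_domain)
  drec <- get_dec(registry, frec$of_dec)
  if (!identical(vd$represents, drec$conceptual_domain)) {
    mdr_abort("DomainMismatch", sprintf(
      "value domain '%s' does not represent conceptual domain '%s'",
      de$value_domain, drec$conceptual_domain))
  }
  hit <- NULL
  for (pv in vd$permissible_values) {
    if (identical(pv$meaning, frec$value_meaning)) { hit <- pv; break }
  }
  if (is.null(hit)) {
    mdr_abort("NoPermissibleValue", sprintf(
      "no permissible value in '%s' carries meaning '%s'",
      de$value_domain, frec$value_meaning))
  }
  if (is.null(id)) id <- sprintf("%s__rep_%s", data_element, fact)
  registry <- add_individual(registry, id, concrete_kind = "abstract",
                             label = sprintf("representation of %s", fact))
  registry <- add_edge(registry, "instance_of", id, data_element)
  registry <- add_edge(registry, "constituent_part", id, fact)
  registry <- add_edge(registry, "constituent_part", id, hit$token)
  registry$representations[[id]] <- list(
    id = id, fact = fact, token = hit$token, lexical = hit$lexical,
    of_data_element = data_element
  )
  list(registry = registry, id = id, token = hit$token, lexical = hit$lexical)
}

#' Decode a value to its value meaning
#'
#' A value designates its value meaning: within one value domain the
#' mapping from lexical values to meanings is functional, so decoding is a
#' lookup. Several distinct tokens may designate the same meaning.
#'
#' @inheritParams make_dec
#' @param lexical The written value (lexical form of the token).
#' @param value_domain Value domain id.
#' @return The meaning id.
#' @export
decode_value <- function(registry, lexical, value_domain) {
  stopifnot_registry(registry)
  vd <- get_value_domain(registry, value_domain)
  for (pv in vd$permissible_values) {
    if (identical(pv$lexical, lexical)) return(pv$meaning)
  }
  mdr_abort("UnknownToken", sprintf(
    "no permissible value in '%s' has lexical '%s'", value_domain, lexical))
}
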