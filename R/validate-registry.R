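# Registry-level validation. Aggregates the graph-level report with the
# metamodel invariants. Dependent checks are guarded by their
# prerequisites so a single injected defect yields a single finding with
# its root-cause code.

#' Validate a metadata registry
#'
#' Runs [well_typed()] on the embedded graph and then checks the
#' metamodel invariants. Finding codes, beyond the graph-level ones:
#'
#' * `MISSING_CD` — a DEC without a bound conceptual domain.
#' * `BEARER_MISMATCH` — a DEC whose property's bearer category differs
#'   from its object class.
#' * `PROPERTY_NOT_LIFTED` — a property whose instances are not all
#'   connected to bearers by the property's connecting relation.
#' * `OVERLAPPING_MEANINGS` — two value meanings of one enumerated
#'   conceptual domain with intersecting member sets.
#' * `VD_CD_MISMATCH` — a data element whose value domain does not
#'   represent its DEC's conceptual domain.
#' * `ORPHAN_CONSTITUENT` — a data element or DEC lacking one of its two
#'   `constituent_part` edges.
#' * `NONFUNCTIONAL_TOKEN_MAP` — a lexical value designating two distinct
#'   meanings within one value domain.
#' * `PV_MEANING_NOT_IN_CD` — a permissible value whose meaning is not in
#'   the represented conceptual domain.
#' * `FACT_OBJECT_NOT_TYPED`, `FACT_ATTRIBUTIVE_NOT_TYPED`,
#'   `FACT_NOT_CONNECTED`, `FACT_MEANING_MISMATCH` — fact records
#'   violating the DEC typing invariants.
#' * `REPRESENTATION_NOT_PERMISSIBLE` — a fact-representation whose
#'   (meaning, token) pair is not a permissible value of its data
#'   element's value domain.
#' * `RANGE_VIOLATION` — a represented magnitude outside an item's range.
#' * `DEFAULT_NOT_IN_VD` — an item default that is not a permissible
#'   value.
#' * `ITEM_NOT_SUBCATEGORY` — an item category with an instance that does
#'   not instantiate the item's data-element category.
#' * `MISSING_REFERENCE` — a record referencing an unregistered id.
#' * `NEXUS_NOT_LIFTED` — a stored property nexus whose lifted relation
#'   does not hold.
#'
#' @param registry An `mdr_registry`.
#' @return An `mdr_validation_report`; zero rows means the registry is
#'   valid (and in particular the graph is well-typed).
#' @export
validate_registry <- function(registry) {
  stopifnot_registry(registry)
  base <- well_typed(registry$graph)
  findings <- list()
  note <- function(code, entity, message) {
    findings[[length(findings) + 1L]] <<- list(code = code, entity = entity,
                                               message = message)
  }
  g <- registry$graph

  # --- data element concepts ---------------------------------------------
  for (dec in registry$decs) {
    if (is.null(dec$conceptual_domain)) {
      note("MISSING_CD", dec$id,
           sprintf("DEC '%s' has no bound conceptual domain", dec$id))
    } else if (is.null(registry$conceptual_domains[[dec$conceptual_domain]])) {
      note("MISSING_REFERENCE", dec$id,
           sprintf("DEC '%s' references unknown conceptual domain '%s'",
                   dec$id, dec$conceptual_domain))
    }
    if (!identical(dec$property$bearer_class, dec$object_class)) {
      note("BEARER_MISMATCH", dec$id, sprintf(
        "DEC '%s': property bearer '%s' differs from object class '%s'",
        dec$id, dec$property$bearer_class, dec$object_class))
    } else if (graph_has(g, dec$property$category) &&
               graph_has(g, dec$object_class) &&
               dec$property$connecting_relation %in% g$relations &&
               !lift_relation(g, dec$property$connecting_relation,
                              dec$property$category, dec$object_class)) {
      note("PROPERTY_NOT_LIFTED", dec$id, sprintf(
        "property '%s' does not lift to bearer class '%s' via '%s'",
        dec$property$category, dec$object_class,
        dec$property$connecting_relation))
    }
    cons <- constituents(registry, dec$id)
    if (!all(c(dec$object_class, dec$property$category) %in% cons)) {
      note("ORPHAN_CONSTITUENT", dec$id, sprintf(
        "DEC '%s' is missing a constituent_part edge", dec$id))
    }
  }

  # --- conceptual domains ------------------------------------------------
  for (cd in registry$conceptual_domains) {
    ms <- cd$meanings
    ids <- names(ms)
    if (length(ids) >= 2L) {
      for (i in seq_len(length(ids) - 1L)) {
        for (j in seq((i + 1L), length(ids))) {
          ov <- intersect(ms[[ids[i]]]$members, ms[[ids[j]]]$members)
          if (length(ov)) {
            note("OVERLAPPING_MEANINGS", cd$id, sprintf(
              "meanings '%s' and '%s' share member(s): %s",
              ids[i], ids[j], paste(ov, collapse = ", ")))
          }
        }
      }
    }
  }

  # --- value domains -----------------------------------------------------
  for (vd in registry$value_domains) {
    cd <- registry$conceptual_domains[[vd$represents]]
    if (is.null(cd)) {
      note("MISSING_REFERENCE", vd$id, sprintf(
        "value domain '%s' represents unknown conceptual domain '%s'",
        vd$id, vd$represents))
      next
    }
    lex_map <- list()
    for (pv in vd$permissible_values) {
      prev <- lex_map[[pv$lexical]]
      if (is.null(prev)) {
        lex_map[[pv$lexical]] <- pv$meaning
      } else if (!identical(prev, pv$meaning)) {
        note("NONFUNCTIONAL_TOKEN_MAP", vd$id, sprintf(
          "lexical '%s' designates both '%s' and '%s' in value domain '%s'",
          pv$lexical, prev, pv$meaning, vd$id))
        lex_map[[pv$lexical]] <- pv$meaning  # report each offending pair once
      }
      if (cd_is_enumerated(cd) && !pv$meaning %in% names(cd$meanings)) {
        note("PV_MEANING_NOT_IN_CD", vd$id, sprintf(
          "permissible value meaning '%s' is not in domain '%s'",
          pv$meaning, cd$id))
      }
    }
  }

  # --- data elements -----------------------------------------------------
  for (de in registry$data_elements) {
    dec <- registry$decs[[de$dec]]
    vd <- registry$value_domains[[de$value_domain]]
    if (is.null(dec) || is.null(vd)) {
      note("MISSING_REFERENCE", de$id, sprintf(
        "data element '%s' references an unregistered DEC or value domain",
        de$id))
      next
    }
    if (!is.null(dec$conceptual_domain) &&
        !identical(vd$represents, dec$conceptual_domain)) {
      note("VD_CD_MISMATCH", de$id, sprintf(
        "value domain '%s' represents '%s' but DEC '%s' is bound to '%s'",
        vd$id, vd$represents, dec$id, dec$conceptual_domain))
    }
    cons <- constituents(registry, de$id)
    if (!all(c(de$dec, de$value_domain) %in% cons)) {
      note("ORPHAN_CONSTITUENT", de$id, sprintf(
        "data element '%s' is missing a constituent_part edge", de$id))
    }
  }

  # --- facts -------------------------------------------------------------
  for (fact in registry$facts) {
    dec <- registry$decs[[fact$of_dec]]
    if (is.null(dec)) {
      note("MISSING_REFERENCE", fact$id, sprintf(
        "fact '%s' references unregistered DEC '%s'", fact$id, fact$of_dec))
      next
    }
    if (!has_edge(g, "instance_of", fact$object_individual,
                  dec$object_class)) {
      note("FACT_OBJECT_NOT_TYPED", fact$id, sprintf(
        "fact '%s': '%s' is not an instance of '%s'",
        fact$id, fact$object_individual, dec$object_class))
    }
    if (!has_edge(g, "instance_of", fact$attributive,
                  dec$property$category)) {
      note("FACT_ATTRIBUTIVE_NOT_TYPED", fact$id, sprintf(
        "fact '%s': '%s' is not an instance of property '%s'",
        fact$id, fact$attributive, dec$property$category))
    } else if (!has_edge(g, dec$property$connecting_relation,
                         fact$attributive, fact$object_individual)) {
      note("FACT_NOT_CONNECTED", fact$id, sprintf(
        "fact '%s': attributive not connected to bearer by '%s'",
        fact$id, dec$property$connecting_relation))
    }
    cd <- if (!is.null(dec$conceptual_domain))
      registry$conceptual_domains[[dec$conceptual_domain]]
    if (!is.null(cd) && cd_is_enumerated(cd)) {
      vm <- cd$meanings[[fact$value_meaning]]
      if (is.null(vm) || !fact$attributive %in% vm$members) {
        note("FACT_MEANING_MISMATCH", fact$id, sprintf(
          "fact '%s': attributive is not a member of meaning '%s'",
          fact$id, fact$value_meaning))
      }
    }
  }

  # --- fact representations ---------------------------------------------
  for (rep in registry$representations) {
    de <- registry$data_elements[[rep$of_data_element]]
    fact <- registry$facts[[rep$fact]]
    if (is.null(de) || is.null(fact)) {
      note("MISSING_REFERENCE", rep$id, sprintf(
        "representation '%s' references an unregistered fact or data element",
        rep$id))
      next
    }
    vd <- registry$value_domains[[de$value_domain]]
    ok <- FALSE
    if (!is.null(vd)) {
      for (pv in vd$permissible_values) {
        if (identical(pv$meaning, fact$value_meaning) &&
            identical(pv$token, rep$token)) { ok <- TRUE; break }
      }
    }
    if (!ok) {
      note("REPRESENTATION_NOT_PERMISSIBLE", rep$id, sprintf(
        "representation '%s': (meaning '%s', token '%s') is not permissible",
        rep$id, fact$value_meaning, rep$token))
      next
    }
    # range constraints of items over this data element
    dec <- registry$decs[[de$dec]]
    cd <- if (!is.null(dec) && !is.null(dec$conceptual_domain))
      registry$conceptual_domains[[dec$conceptual_domain]]
    vm <- if (!is.null(cd)) cd$meanings[[fact$value_meaning]]
    if (!is.null(vm) && !is.null(vm$magnitude) && !is.null(vm$unit)) {
      for (item in registry$items) {
        if (!identical(item$data_element, de$id) || is.null(item$range)) next
        inside <- tryCatch(
          check_range(vm$magnitude, vm$unit,
                      structure(item$range, class = "mdr_range")),
          mdr_error = function(e) NA)
        if (isFALSE(inside)) {
          note("RANGE_VIOLATION", rep$id, sprintf(
            "representation '%s': %s %s violates range of item '%s'",
            rep$id, format(vm$magnitude), vm$unit, item$id))
        }
      }
    }
  }

  # --- items -------------------------------------------------------------
  for (item in registry$items) {
    de <- registry$data_elements[[item$data_element]]
    if (is.null(de)) {
      note("MISSING_REFERENCE", item$id, sprintf(
        "item '%s' references unregistered data element '%s'",
        item$id, item$data_element))
      next
    }
    if (!is.null(item$default)) {
      vd <- registry$value_domains[[de$value_domain]]
      lex <- if (is.null(vd)) character() else
        vapply(vd$permissible_values, `[[`, character(1), "lexical")
      if (!item$default %in% lex) {
        note("DEFAULT_NOT_IN_VD", item$id, sprintf(
          "item '%s' default '%s' is not a permissible value",
          item$id, item$default))
      }
    }
    # extensional subcategory: item instances must instantiate the DE
    if (graph_has(g, item$id) && graph_has(g, de$id)) {
      inst <- edge_sources(g, "instance_of", item$id)
      de_inst <- edge_sources(g, "instance_of", de$id)
      stray <- setdiff(inst, de_inst)
      for (s in stray) {
        note("ITEM_NOT_SUBCATEGORY", item$id, sprintf(
          "item instance '%s' does not instantiate data element '%s'",
          s, de$id))
      }
    }
  }

  # --- groups and nexus --------------------------------------------------
  for (grp in registry$groups) {
    for (m in grp$members) {
      if (is.null(registry$items[[m]])) {
        note("MISSING_REFERENCE", grp$id, sprintf(
          "item group '%s' references unregistered item '%s'", grp$id, m))
      }
    }
  }
  for (nx in registry$nexus) {
    if (!graph_has(g, nx$property) || !graph_has(g, nx$bearer_category)) {
      note("MISSING_REFERENCE", nx$property,
           "nexus references entities not in the graph")
      next
    }
    obj <- structure(
      list(property = nx$property, bearer_category = nx$bearer_category,
           relation = nx$relation, phenotypic = isTRUE(nx$phenotypic)),
      class = "mdr_property_nexus")
    ok <- tryCatch(validate_nexus(g, obj), mdr_error = function(e) NA)
    if (isFALSE(ok)) {
      note("NEXUS_NOT_LIFTED", nx$property, sprintf(
        "property nexus (%s, %s, %s) does not hold over the graph",
        nx$property, nx$bearer_category, nx$relation))
    }
  }

  rbind(base, new_validation_report(findings))
}
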