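# Registry persistence: a canonical JSON dialect (UTF-8, fixed key order,
# id-sorted tables) so that save(load(x)) is byte-identical for
# canonicalized documents.

drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

entity_to_record <- function(ent) {
  rec <- list(
    id = ent$id, label = ent$label, type = ent$type,
    kind = ent$kind, concrete_kind = ent$concrete_kind,
    declared_order = ent$declared_order, level = ent$level,
    descriptive_role = ent$descriptive_role, lexical = ent$lexical,
    relation = ent$relation
  )
  if (!is.null(ent$roles)) {
    rec$roles <- lapply(ent$roles, function(r)
      list(role = r$role, player = r$player))
  }
  drop_null(rec)
}

edges_to_records <- function(e) {
  if (nrow(e) == 0L) return(list())
  ord <- order(e$relation, e$source, e$target)
  e <- e[ord, , drop = FALSE]
  lapply(seq_len(nrow(e)), function(i)
    list(relation = e$relation[i], source = e$source[i], target = e$target[i]))
}

ternary_to_records <- function(te) {
  if (nrow(te) == 0L) return(list())
  ord <- order(te$relation, te$x, te$y, te$z)
  te <- te[ord, , drop = FALSE]
  lapply(seq_len(nrow(te)), function(i)
    list(relation = te$relation[i], x = te$x[i], y = te$y[i], z = te$z[i]))
}

sorted_records <- function(tbl, f) {
  ids <- sort(names(tbl))
  lapply(ids, function(id) f(tbl[[id]]))
}

meaning_to_record <- function(m) {
  drop_null(list(
    id = m$id, label = m$label,
    members = as.list(sort(as.character(m$members))),
    magnitude = m$magnitude, unit = m$unit
  ))
}

range_to_record <- function(r) {
  drop_null(list(lower = r$lower, upper = r$upper, unit = r$unit,
                 inclusive = as.list(r$inclusive)))
}

acquisition_to_record <- function(a) {
  rec <- drop_null(list(type = a$type, start = a$start, end = a$end))
  if (!is.null(a$participants) && nrow(a$participants)) {
    p <- a$participants[order(a$participants$role, a$participants$entity),
                        , drop = FALSE]
    rec$participants <- lapply(seq_len(nrow(p)), function(i)
      list(role = p$role[i], entity = p$entity[i]))
  }
  rec
}

registry_to_document <- function(registry) {
  g <- registry$graph
  list(
    schema_version = registry$schema_version,
    seed = registry$seed,
    relations_extra = as.list(sort(setdiff(g$relations,
                                           BASE_BINARY_RELATIONS))),
    entities = lapply(sort(names(g$entities)), function(id)
      entity_to_record(g$entities[[id]])),
    edges = edges_to_records(g$edges),
    ternary_edges = ternary_to_records(g$ternary_edges),
    decs = sorted_records(registry$decs, function(d) drop_null(list(
      id = d$id, label = d$label, object_class = d$object_class,
      property = list(category = d$property$category,
                      bearer_class = d$property$bearer_class,
                      connecting_relation = d$property$connecting_relation),
      conceptual_domain = d$conceptual_domain))),
    conceptual_domains = sorted_records(registry$conceptual_domains,
      function(cd) drop_null(list(
        id = cd$id, label = cd$label, description = cd$description,
        meanings = lapply(sort(names(cd$meanings)), function(mid)
          meaning_to_record(cd$meanings[[mid]]))))),
    value_domains = sorted_records(registry$value_domains, function(vd)
      list(id = vd$id, label = vd$label, represents = vd$represents,
           permissible_values = lapply(vd$permissible_values, function(pv)
             list(relator = pv$relator, meaning = pv$meaning,
                  token = pv$token, lexical = pv$lexical)))),
    data_elements = sorted_records(registry$data_elements, function(de)
      list(id = de$id, label = de$label, dec = de$dec,
           value_domain = de$value_domain)),
    facts = sorted_records(registry$facts, function(f)
      list(id = f$id, label = f$label,
           object_individual = f$object_individual,
           attributive = f$attributive, value_meaning = f$value_meaning,
           of_dec = f$of_dec)),
    representations = sorted_records(registry$representations, function(r)
      list(id = r$id, fact = r$fact, token = r$token, lexical = r$lexical,
           of_data_element = r$of_data_element)),
    items = sorted_records(registry$items, function(it) {
      rec <- drop_null(list(
        id = it$id, label = it$label, data_element = it$data_element,
        default = it$default,
        range = if (!is.null(it$range)) range_to_record(it$range),
        acquisition = if (!is.null(it$acquisition))
          acquisition_to_record(it$acquisition),
        parent = it$parent, facet = it$facet))
      rec
    }),
    groups = sorted_records(registry$groups, function(grp)
      list(id = grp$id, label = grp$label,
           members = as.list(grp$members))),
    complex_concepts = sorted_records(registry$complex_concepts, function(cc)
      list(id = cc$id, label = cc$label, base = cc$base,
           components = lapply(cc$components, function(cmp)
             list(relation = cmp$relation, target = cmp$target)))),
    nexus = lapply(registry$nexus, function(nx)
      list(property = nx$property, bearer_category = nx$bearer_category,
           relation = nx$relation, phenotypic = isTRUE(nx$phenotypic))),
    extensions = sorted_records(registry$extensions, function(ex)
      list(kind = ex$kind, added = ex$added))
  )
}

registry_to_json <- function(registry) {
  doc <- registry_to_document(registry)
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                                digits = NA, pretty = 2))
}

#' Save a registry to its canonical JSON document
#'
#' The document is UTF-8 with a fixed key order and id-sorted tables, so
#' saving, loading and saving again is byte-identical.
#'
#' @param registry An `mdr_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  stopifnot_registry(registry)
  txt <- registry_to_json(registry)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeBin(charToRaw(paste0(txt, "\n")), con)
  invisible(path)
}

chr_or_null <- function(x) if (is.null(x)) NULL else as.character(x)

record_to_entity <- function(rec) {
  ent <- list(id = rec$id, label = rec$label, type = rec$type)
  if (!is.null(rec$kind)) ent$kind <- rec$kind
  if (!is.null(rec$concrete_kind)) ent$concrete_kind <- rec$concrete_kind
  if (!is.null(rec$declared_order))
    ent$declared_order <- as.integer(rec$declared_order)
  if (!is.null(rec$level)) ent$level <- rec$level
  if (!is.null(rec$descriptive_role))
    ent$descriptive_role <- rec$descriptive_role
  if (!is.null(rec$lexical)) ent$lexical <- rec$lexical
  if (!is.null(rec$relation)) ent$relation <- rec$relation
  if (!is.null(rec$roles)) {
    ent$roles <- lapply(rec$roles, function(r)
      list(role = r$role, player = r$player))
  }
  ent
}

records_to_edges <- function(recs) {
  if (length(recs) == 0L) return(empty_edges())
  data.frame(
    relation = vapply(recs, `[[`, character(1), "relation"),
    source = vapply(recs, `[[`, character(1), "source"),
    target = vapply(recs, `[[`, character(1), "target"),
    stringsAsFactors = FALSE
  )
}

records_to_ternary <- function(recs) {
  if (length(recs) == 0L) return(empty_ternary())
  data.frame(
    relation = vapply(recs, `[[`, character(1), "relation"),
    x = vapply(recs, `[[`, character(1), "x"),
    y = vapply(recs, `[[`, character(1), "y"),
    z = vapply(recs, `[[`, character(1), "z"),
    stringsAsFactors = FALSE
  )
}

keyed <- function(recs, key = "id") {
  out <- list()
  for (r in recs) out[[r[[key]]]] <- r
  out
}

document_to_registry <- function(doc) {
  g <- ontology_graph()
  g$relations <- c(BASE_BINARY_RELATIONS,
                   vapply(doc$relations_extra, as.character, character(1)))
  for (rec in doc$entities) {
    g$entities[[rec$id]] <- record_to_entity(rec)
  }
  g$edges <- records_to_edges(doc$edges)
  g$ternary_edges <- records_to_ternary(doc$ternary_edges)

  reg <- structure(
    list(
      schema_version = doc$schema_version,
      seed = if (is.null(doc$seed)) NULL else as.integer(doc$seed),
      graph = g,
      decs = keyed(lapply(doc$decs, function(d) list(
        id = d$id, label = d$label, object_class = d$object_class,
        property = list(
          category = d$property$category,
          bearer_class = d$property$bearer_class,
          connecting_relation = d$property$connecting_relation),
        conceptual_domain = d$conceptual_domain))),
      conceptual_domains = keyed(lapply(doc$conceptual_domains, function(cd)
        list(id = cd$id, label = cd$label, description = cd$description,
             meanings = keyed(lapply(cd$meanings, function(m) list(
               id = m$id, label = m$label,
               members = vapply(m$members, as.character, character(1)),
               magnitude = m$magnitude, unit = m$unit)))))),
      value_domains = keyed(lapply(doc$value_domains, function(vd)
        list(id = vd$id, label = vd$label, represents = vd$represents,
             permissible_values = lapply(vd$permissible_values, function(pv)
               list(relator = pv$relator, meaning = pv$meaning,
                    token = pv$token, lexical = pv$lexical))))),
      data_elements = keyed(lapply(doc$data_elements, function(de)
        list(id = de$id, label = de$label, dec = de$dec,
             value_domain = de$value_domain))),
      facts = keyed(lapply(doc$facts, function(f)
        list(id = f$id, label = f$label,
             object_individual = f$object_individual,
             attributive = f$attributive, value_meaning = f$value_meaning,
             of_dec = f$of_dec))),
      representations = keyed(lapply(doc$representations, function(r)
        list(id = r$id, fact = r$fact, token = r$token,
             lexical = r$lexical, of_data_element = r$of_data_element))),
      items = keyed(lapply(doc$items, function(it) list(
        id = it$id, label = it$label, data_element = it$data_element,
        default = it$default,
        range = if (!is.null(it$range)) list(
          lower = it$range$lower, upper = it$range$upper,
          unit = it$range$unit,
          inclusive = vapply(it$range$inclusive, isTRUE, logical(1))),
        acquisition = if (!is.null(it$acquisition)) list(
          type = it$acquisition$type, start = it$acquisition$start,
          end = it$acquisition$end,
          participants = if (!is.null(it$acquisition$participants) &&
                             length(it$acquisition$participants))
            data.frame(
              role = vapply(it$acquisition$participants, `[[`,
                            character(1), "role"),
              entity = vapply(it$acquisition$participants, `[[`,
                              character(1), "entity"),
              stringsAsFactors = FALSE)),
        parent = it$parent, facet = it$facet))),
      groups = keyed(lapply(doc$groups, function(grp)
        list(id = grp$id, label = grp$label,
             members = vapply(grp$members, as.character, character(1))))),
      complex_concepts = keyed(lapply(doc$complex_concepts, function(cc)
        list(id = cc$id, label = cc$label, base = cc$base,
             components = lapply(cc$components, function(cmp)
               list(relation = cmp$relation, target = cmp$target))))),
      nexus = lapply(doc$nexus, function(nx)
        list(property = nx$property, bearer_category = nx$bearer_category,
             relation = nx$relation, phenotypic = isTRUE(nx$phenotypic))),
      extensions = keyed(lapply(doc$extensions, function(ex)
        list(kind = ex$kind, added = ex$added)), key = "added")
    ),
    class = "mdr_registry"
  )
  reg
}

#' Load a registry from its JSON document
#'
#' @param path Path to a registry document written by [save_registry()].
#' @return An `mdr_registry`.
#' @export
load_registry <- function(path) {
  txt <- tryCatch(
    readChar(path, file.size(path), useBytes = TRUE),
    error = function(e) mdr_abort("ParseError", conditionMessage(e))
  )
  doc <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) mdr_abort(
      "ParseError", sprintf("cannot parse '%s': %s", path,
                            conditionMessage(e)))
  )
  if (!is.list(doc) || is.null(doc$schema_version)) {
    mdr_abort("ParseError",
              sprintf("'%s' is not a registry document", path))
  }
  if (!identical(doc$schema_version, MDR_SCHEMA_VERSION)) {
    mdr_abort("SchemaVersionMismatch", sprintf(
      "document schema version '%s' != supported '%s'",
      doc$schema_version, MDR_SCHEMA_VERSION))
  }
  document_to_registry(doc)
}

dot_escape <- function(x) gsub('"', '\\\\"', gsub("\\\\", "\\\\\\\\", x))

#' Export a registry graph as DOT
#'
#' Produces one node per entity (boxes for categories, ellipses for
#' individuals) and one labelled edge per relation edge. Ternary
#' function-realization edges are rendered through an intermediate
#' diamond node with edges labelled function, process and realizer.
#'
#' @inheritParams add_category
#' @param format Only `"dot"` is supported.
#' @return A single string of DOT source.
#' @export
export_graph <- function(x, format = "dot") {
  format <- match.arg(format, "dot")
  graph <- as_ontology_graph(x)
  lines <- c("digraph registry {", "  rankdir=LR;")
  for (id in sort(names(graph$entities))) {
    ent <- graph$entities[[id]]
    shape <- if (identical(ent$type, "category")) "box" else "ellipse"
    lines <- c(lines, sprintf('  "%s" [label="%s", shape=%s];',
                              dot_escape(id), dot_escape(ent$label), shape))
  }
  e <- graph$edges
  if (nrow(e)) {
    ord <- order(e$relation, e$source, e$target)
    for (i in ord) {
      lines <- c(lines, sprintf('  "%s" -> "%s" [label="%s"];',
                                dot_escape(e$source[i]),
                                dot_escape(e$target[i]), e$relation[i]))
    }
  }
  te <- graph$ternary_edges
  if (nrow(te)) {
    for (i in seq_len(nrow(te))) {
      hub <- sprintf("__ternary_%d", i)
      lines <- c(
        lines,
        sprintf('  "%s" [label="%s", shape=diamond];', hub, te$relation[i]),
        sprintf('  "%s" -> "%s" [label="function"];', dot_escape(te$x[i]), hub),
        sprintf('  "%s" -> "%s" [label="process"];', hub, dot_escape(te$y[i])),
        sprintf('  "%s" -> "%s" [label="realizer"];', hub, dot_escape(te$z[i]))
      )
    }
  }
  paste(c(lines, "}"), collapse = "\n")
}
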