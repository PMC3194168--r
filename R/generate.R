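# Seeded fixture generation and violation injection. Both are pure
# functions of (spec, seed): the RNG is scoped with withr so global state
# is untouched, and identical inputs produce identical registries.

#' Specify a synthetic registry fixture
#'
#' The generator emulates a small clinical metadata registry: object
#' classes with one individual bearer each, properties connected by
#' inherence, data element concepts bound to enumerated conceptual
#' domains of integer-kilogram value meanings, value domains with one
#' token per meaning, one fact and fact-representation per data element,
#' and items with a default, a wide plausible range and a measuring
#' acquisition. Property nexus triples are emitted for every property,
#' with `depends_on` edges accompanying every inherence edge.
#'
#' @param n_object_classes,n_properties,n_data_elements,n_items
#'   Non-negative counts. Properties need at least one object class;
#'   data elements need at least one property; items need at least one
#'   data element.
#' @param max_order Maximum category order in the graph, >= 2. Orders
#'   above 2 add a chain of metaclasses-of-metaclasses.
#' @param meanings_per_domain Number of value meanings per conceptual
#'   domain, >= 1.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return A list of class `mdr_fixture_spec`.
#' @export
fixture_spec <- function(n_object_classes = 2L, n_properties = 2L,
                         n_data_elements = 2L, n_items = 2L,
                         max_order = 2L, meanings_per_domain = 3L,
                         seed = 1L) {
  counts <- c(n_object_classes, n_properties, n_data_elements, n_items)
  if (any(counts < 0L)) {
    mdr_abort("InvalidSpec", "all counts must be >= 0")
  }
  if (max_order < 2L) mdr_abort("InvalidSpec", "max_order must be >= 2")
  if (meanings_per_domain < 1L) {
    mdr_abort("InvalidSpec", "meanings_per_domain must be >= 1")
  }
  if (n_properties > 0L && n_object_classes == 0L) {
    mdr_abort("InvalidSpec", "properties require at least one object class")
  }
  if (n_data_elements > 0L && n_properties == 0L) {
    mdr_abort("InvalidSpec", "data elements require at least one property")
  }
  if (n_items > 0L && n_data_elements == 0L) {
    mdr_abort("InvalidSpec", "items require at least one data element")
  }
  structure(
    list(n_object_classes = as.integer(n_object_classes),
         n_properties = as.integer(n_properties),
         n_data_elements = as.integer(n_data_elements),
         n_items = as.integer(n_items),
         max_order = as.integer(max_order),
         meanings_per_domain = as.integer(meanings_per_domain),
         seed = as.integer(seed)),
    class = "mdr_fixture_spec"
  )
}

#' Generate a synthetic registry from a fixture spec
#'
#' @param spec An [fixture_spec()].
#' @return An `mdr_registry` that passes [validate_registry()] with zero
#'   findings. Identical specs (including seed) produce identical
#'   registries.
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "mdr_fixture_spec")) {
    mdr_abort("InvalidSpec", "spec must be built with fixture_spec()")
  }
  withr::with_seed(spec$seed, build_fixture(spec))
}

build_fixture <- function(spec) {
  reg <- mdr_registry()
  reg$seed <- spec$seed

  # metaclass chain above order 2 (bounded-order hierarchy)
  anchor <- META_DEC
  if (spec$max_order > 2L) {
    for (k in 3L:spec$max_order) {
      mc <- sprintf("META:order%d", k)
      reg <- add_category(reg, mc, kind = "concept",
                          declared_order = k,
                          label = sprintf("metaclass of order %d", k))
      reg <- add_edge(reg, "instance_of", anchor, mc)
      anchor <- mc
    }
  }

  ocs <- character(spec$n_object_classes)
  bearers <- character(spec$n_object_classes)
  for (i in seq_len(spec$n_object_classes)) {
    ocs[i] <- sprintf("OC:class_%02d", i)
    bearers[i] <- sprintf("IND:obj_%02d", i)
    reg <- add_category(reg, ocs[i], kind = "universal",
                        declared_order = 1L,
                        label = sprintf("object class %d", i))
    reg <- add_individual(reg, bearers[i], concrete_kind = "continuant",
                          label = sprintf("individual %d", i))
    reg <- add_edge(reg, "instance_of", bearers[i], ocs[i])
  }

  props <- character(spec$n_properties)
  prop_bearer <- integer(spec$n_properties)
  for (j in seq_len(spec$n_properties)) {
    props[j] <- sprintf("PROP:prop_%02d", j)
    prop_bearer[j] <- ((j - 1L) %% spec$n_object_classes) + 1L
    reg <- add_category(reg, props[j], kind = "universal",
                        declared_order = 1L,
                        label = sprintf("property %d", j))
    reg$nexus[[length(reg$nexus) + 1L]] <- list(
      property = props[j], bearer_category = ocs[prop_bearer[j]],
      relation = "inheres_in", phenotypic = TRUE)
  }

  for (k in seq_len(spec$n_data_elements)) {
    j <- ((k - 1L) %% spec$n_properties) + 1L
    i <- prop_bearer[j]
    attr_id <- sprintf("ATTR:attr_%02d", k)
    reg <- add_individual(reg, attr_id, concrete_kind = "attributive",
                          label = sprintf("attributive %d", k))
    reg <- add_edge(reg, "instance_of", attr_id, props[j])
    reg <- add_edge(reg, "inheres_in", attr_id, bearers[i])
    reg <- add_edge(reg, "depends_on", attr_id, bearers[i])

    mags <- sort(sample(40:200, spec$meanings_per_domain))
    meanings <- lapply(seq_along(mags), function(q) value_meaning(
      sprintf("VM:dom%02d_%03d", k, mags[q]),
      label = sprintf("%d kg", mags[q]),
      members = if (q == 1L) attr_id else character(),
      magnitude = mags[q], unit = "kg"))
    cd_id <- sprintf("CD:dom_%02d", k)
    reg <- make_conceptual_domain(reg, cd_id, meanings = meanings,
                                  label = sprintf("domain %d", k))
    vd_id <- sprintf("VD:dom_%02d", k)
    reg <- make_value_domain(reg, vd_id, cd_id,
                             lapply(meanings, function(m) list(
                               meaning = m$id,
                               lexical = as.character(m$magnitude))),
                             label = sprintf("values %d", k))
    dec_id <- sprintf("DEC:dec_%02d", k)
    reg <- make_dec(reg, dec_id, ocs[i], property_spec(props[j], ocs[i]),
                    label = sprintf("concept %d", k))
    reg <- bind_conceptual_domain(reg, dec_id, cd_id)
    de_id <- sprintf("DE:de_%02d", k)
    reg <- make_data_element(reg, de_id, dec_id, vd_id,
                             label = sprintf("data element %d", k))
    fact_id <- sprintf("FACT:fact_%02d", k)
    reg <- make_fact(reg, fact_id, bearers[i], attr_id, meanings[[1L]]$id,
                     dec_id, label = sprintf("fact %d", k))
    made <- represent_fact(reg, fact_id, de_id)
    reg <- made$registry
  }

  item_ids <- character(spec$n_items)
  for (t in seq_len(spec$n_items)) {
    k <- ((t - 1L) %% spec$n_data_elements) + 1L
    de_id <- sprintf("DE:de_%02d", k)
    vd <- get_value_domain(reg, get_data_element(reg, de_id)$value_domain)
    item_ids[t] <- sprintf("ITEM:item_%02d", t)
    reg <- make_item(
      reg, item_ids[t], de_id,
      default = vd$permissible_values[[1L]]$lexical,
      range = range_constraint(0, 300, unit = "kg"),
      acquisition = data_acquisition(
        "measuring", "2001-01-01T08:00:00", "2001-01-01T08:10:00",
        participants = data.frame(
          role = c("subject", "result_fact"),
          entity = c(get_fact(reg, sprintf("FACT:fact_%02d", k))$object_individual,
                     sprintf("FACT:fact_%02d", k)),
          stringsAsFactors = FALSE)),
      label = sprintf("item %d", t))
  }
  if (spec$n_items > 0L) {
    reg <- make_item_group(reg, "GRP:all", item_ids, label = "all items")
  }
  reg
}

MUTATION_CODES <- c(
  "MISSING_CD", "VD_CD_MISMATCH", "NONFUNCTIONAL_TOKEN_MAP",
  "OVERLAPPING_MEANINGS", "ORPHAN_CONSTITUENT", "BEARER_MISMATCH",
  "CYCLIC_INSTANTIATION", "MIXED_ORDER", "UNDETERMINED_ORDER",
  "DANGLING_EDGE", "RANGE_VIOLATION", "DEFAULT_NOT_IN_VD"
)

#' Finding codes supported by [mutate_fixture()]
#'
#' @return A character vector of injectable validator codes.
#' @export
mutation_codes <- function() MUTATION_CODES

pick_site <- function(sites, code) {
  if (length(sites) == 0L) {
    mdr_abort("NoInjectionSite",
              sprintf("registry has no site where %s can be injected", code))
  }
  sites[[sample.int(length(sites), 1L)]]
}

raw_edge <- function(registry, relation, source, target) {
  registry$graph$edges <- rbind(
    registry$graph$edges,
    data.frame(relation = relation, source = source, target = target,
               stringsAsFactors = FALSE))
  registry
}

#' Inject exactly one validation violation into a registry
#'
#' Deterministically (given the seed) picks an injection site and breaks
#' the corresponding invariant so that [validate_registry()] reports a
#' finding with exactly the requested code and no others. Raises
#' `NoInjectionSite` when the registry has no place where the violation
#' can be expressed (e.g. overlapping meanings in a one-meaning domain).
#'
#' @param registry An `mdr_registry` (typically from
#'   [generate_fixture()]).
#' @param code One of [mutation_codes()].
#' @param seed Integer seed for site selection.
#' @return The mutated registry.
#' @export
mutate_fixture <- function(registry, code, seed = 1L) {
  stopifnot_registry(registry)
  if (!code %in% MUTATION_CODES) {
    mdr_abort("UnknownViolationCode",
              sprintf("'%s' is not an injectable code", code))
  }
  withr::with_seed(as.integer(seed), inject_violation(registry, code, seed))
}

inject_violation <- function(registry, code, seed) {
  g <- registry$graph
  switch(code,
    MISSING_CD = {
      sites <- names(Filter(function(d) !is.null(d$conceptual_domain),
                            registry$decs))
      dec <- pick_site(as.list(sites), code)
      registry$decs[[dec]]$conceptual_domain <- NULL
      registry
    },
    VD_CD_MISMATCH = {
      sites <- Filter(function(de) {
        dec <- registry$decs[[de$dec]]
        !is.null(dec) && !is.null(dec$conceptual_domain)
      }, registry$data_elements)
      de <- pick_site(unname(sites), code)
      dec_id <- de$dec
      old_cd <- registry$decs[[dec_id]]$conceptual_domain
      new_cd <- paste0(old_cd, "__alt")
      clone <- registry$conceptual_domains[[old_cd]]
      clone$id <- new_cd
      registry$conceptual_domains[[new_cd]] <- clone
      registry <- add_individual(registry, new_cd,
                                 concrete_kind = "abstract",
                                 label = paste(clone$label, "(alt)"))
      registry$decs[[dec_id]]$conceptual_domain <- new_cd
      registry
    },
    NONFUNCTIONAL_TOKEN_MAP = {
      sites <- Filter(function(vd) {
        pvs <- vd$permissible_values
        length(pvs) >= 2L &&
          !identical(pvs[[1L]]$meaning, pvs[[2L]]$meaning) &&
          !identical(pvs[[1L]]$lexical, pvs[[2L]]$lexical)
      }, registry$value_domains)
      vd <- pick_site(unname(sites), code)
      pv1 <- vd$permissible_values[[1L]]
      pv2 <- vd$permissible_values[[2L]]
      tok <- paste0(vd$id, "__tok_dup")
      registry <- add_individual(registry, tok, concrete_kind = "token",
                                 label = pv1$lexical, lexical = pv1$lexical)
      registry <- add_edge(registry, "instance_of", tok, SYM_STRING)
      made <- make_relator(registry, REL_MV,
                           list(c("meaning", pv2$meaning), c("value", tok)),
                           id = paste0(vd$id, "__pv_dup"))
      registry <- made$graph
      registry$value_domains[[vd$id]]$permissible_values <- c(
        vd$permissible_values,
        list(list(relator = made$id, meaning = pv2$meaning, token = tok,
                  lexical = pv1$lexical)))
      registry
    },
    OVERLAPPING_MEANINGS = {
      sites <- list()
      for (cd in registry$conceptual_domains) {
        ms <- cd$meanings
        if (length(ms) < 2L) next
        donors <- Filter(function(m) length(m$members) > 0L, ms)
        if (length(donors) == 0L) next
        donor <- donors[[1L]]
        recipient <- setdiff(names(ms), donor$id)[1L]
        sites[[length(sites) + 1L]] <- list(cd = cd$id, donor = donor$id,
                                            recipient = recipient,
                                            member = donor$members[[1L]])
      }
      s <- pick_site(sites, code)
      old <- registry$conceptual_domains[[s$cd]]$meanings[[s$recipient]]$members
      registry$conceptual_domains[[s$cd]]$meanings[[s$recipient]]$members <-
        c(old, s$member)
      registry
    },
    ORPHAN_CONSTITUENT = {
      sites <- unname(registry$data_elements)
      de <- pick_site(sites, code)
      e <- registry$graph$edges
      hit <- which(e$relation == "constituent_part" & e$source == de$id &
                     e$target == de$value_domain)[1L]
      if (is.na(hit)) mdr_abort("NoInjectionSite", "no constituent edge found")
      registry$graph$edges <- e[-hit, , drop = FALSE]
      registry
    },
    BEARER_MISMATCH = {
      all_ocs <- unique(vapply(registry$decs, `[[`, character(1),
                               "object_class"))
      sites <- Filter(function(d) length(setdiff(all_ocs, d$object_class)) > 0L,
                      registry$decs)
      dec <- pick_site(unname(sites), code)
      other <- setdiff(all_ocs, dec$object_class)[1L]
      registry$decs[[dec$id]]$property$bearer_class <- other
      registry
    },
    CYCLIC_INSTANTIATION = {
      e <- g$edges
      inst <- e[e$relation == "instance_of", , drop = FALSE]
      # reversing an edge out of an item category would also corrupt the
      # extensional-subcategory invariant; keep the injection single-fault
      cat_src <- vapply(seq_len(nrow(inst)), function(i)
        is_category_id(g, inst$source[i]) &&
          !inst$source[i] %in% names(registry$items), logical(1))
      inst <- inst[cat_src, , drop = FALSE]
      if (nrow(inst) == 0L) mdr_abort("NoInjectionSite", "no category instantiation")
      i <- sample.int(nrow(inst), 1L)
      raw_edge(registry, "instance_of", inst$target[i], inst$source[i])
    },
    MIXED_ORDER = {
      cats <- Filter(function(ent) identical(ent$type, "category"),
                     g$entities)
      sites <- list()
      for (ent in cats) {
        n_inst <- length(edge_sources(g, "instance_of", ent$id))
        if (n_inst == 0L) next
        ord <- tryCatch(order_of(g, ent$id), mdr_error = function(e) NA)
        if (!is.na(ord) && ord >= 2L) sites[[length(sites) + 1L]] <- ent$id
      }
      target <- pick_site(sites, code)
      ind <- sprintf("IND:mixed_%d", seed)
      registry <- add_individual(registry, ind, concrete_kind = "abstract")
      raw_edge(registry, "instance_of", ind, target)
    },
    UNDETERMINED_ORDER = {
      add_category(registry, sprintf("CAT:undetermined_%d", seed),
                   kind = "concept")
    },
    DANGLING_EDGE = {
      ids <- names(g$entities)
      if (length(ids) == 0L) mdr_abort("NoInjectionSite", "empty graph")
      src <- ids[[sample.int(length(ids), 1L)]]
      raw_edge(registry, "part_of", src, sprintf("MISSING:%d", seed))
    },
    RANGE_VIOLATION = {
      sites <- list()
      for (item in registry$items) {
        if (is.null(item$range)) next
        de <- registry$data_elements[[item$data_element]]
        if (is.null(de)) next
        for (rep in registry$representations) {
          if (!identical(rep$of_data_element, de$id)) next
          fact <- registry$facts[[rep$fact]]
          dec <- registry$decs[[de$dec]]
          cd <- registry$conceptual_domains[[dec$conceptual_domain]]
          vm <- cd$meanings[[fact$value_meaning]]
          if (!is.null(vm$magnitude)) {
            sites[[length(sites) + 1L]] <- list(item = item$id,
                                                mag = vm$magnitude,
                                                unit = vm$unit)
          }
        }
      }
      s <- pick_site(sites, code)
      registry$items[[s$item]]$range$lower <- s$mag + 1
      registry$items[[s$item]]$range$upper <- s$mag + 2
      registry$items[[s$item]]$range$unit <- s$unit
      registry
    },
    DEFAULT_NOT_IN_VD = {
      sites <- names(Filter(function(it) !is.null(it$default),
                            registry$items))
      item <- pick_site(as.list(sites), code)
      registry$items[[item]]$default <- "__not_a_value__"
      registry
    }
  )
}

#' Query items by metadata filters
#'
#' Filters are conjunctive; unnamed or unknown filters raise
#' `UnknownFilterField`. The result is stably ordered by item id.
#'
#' @param registry An `mdr_registry`.
#' @param object_class Keep items whose DEC has this object class.
#' @param property Keep items whose DEC has this property category.
#' @param connecting_relation Keep items whose property uses this
#'   connecting relation.
#' @param acquisition_type Keep items with this acquisition type.
#' @param label Keep items whose label matches this pattern
#'   (case-insensitive regular expression).
#' @param ... Reserved; any argument here raises `UnknownFilterField`.
#' @return A named list of item records, ordered by id.
#' @export
query_items <- function(registry, object_class = NULL, property = NULL,
                        connecting_relation = NULL, acquisition_type = NULL,
                        label = NULL, ...) {
  stopifnot_registry(registry)
  extra <- list(...)
  if (length(extra)) {
    mdr_abort("UnknownFilterField", sprintf(
      "unknown filter field(s): %s",
      paste(names(extra), collapse = ", ")))
  }
  keep <- list()
  for (id in sort(names(registry$items))) {
    item <- registry$items[[id]]
    de <- registry$data_elements[[item$data_element]]
    dec <- if (!is.null(de)) registry$decs[[de$dec]]
    if (!is.null(object_class) &&
        (is.null(dec) || !identical(dec$object_class, object_class))) next
    if (!is.null(property) &&
        (is.null(dec) || !identical(dec$property$category, property))) next
    if (!is.null(connecting_relation) &&
        (is.null(dec) ||
         !identical(dec$property$connecting_relation, connecting_relation)))
      next
    if (!is.null(acquisition_type) &&
        (is.null(item$acquisition) ||
         !identical(item$acquisition$type, acquisition_type))) next
    if (!is.null(label) && !grepl(label, item$label, ignore.case = TRUE)) next
    keep[[id]] <- item
  }
  keep
}
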