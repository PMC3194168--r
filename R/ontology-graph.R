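# The finite ontology graph: categories, individuals, typed relation edges,
# relators. All quantified definitions (order typing, lifted relations) are
# evaluated closed-world over this carrier.

CATEGORY_KINDS <- c("universal", "concept", "symbol_structure", "unspecified")

INDIVIDUAL_KINDS <- c("continuant", "presential", "process", "attributive",
                      "relator", "role", "token", "fact", "situation",
                      "situoid", "abstract")

BASE_BINARY_RELATIONS <- c(
  "instance_of", "part_of", "constituent_part", "has_attr", "inheres_in",
  "depends_on", "participates_in", "plays", "role_part_of", "specifies",
  "models", "categorial_part", "has_facet", "has_function"
)

BASE_TERNARY_RELATIONS <- c("function_realizes")

empty_edges <- function() {
  data.frame(relation = character(), source = character(),
             target = character(), stringsAsFactors = FALSE)
}

empty_ternary <- function() {
  data.frame(relation = character(), x = character(), y = character(),
             z = character(), stringsAsFactors = FALSE)
}

#' Create an empty ontology graph
#'
#' An ontology graph is the finite substrate on which all checks are run: a
#' set of entities (categories and individuals, identified by case-sensitive
#' string ids) together with typed binary relation edges and ternary
#' `function_realizes` edges. Quantifiers in the lifted relation definitions
#' range over asserted entities and edges only (closed world).
#'
#' @return An object of class `ontology_graph`.
#' @seealso [add_category()], [add_individual()], [add_edge()], [order_of()]
#' @export
#' @examples
#' g <- ontology_graph()
#' g <- add_category(g, "dog", kind = "universal")
#' g <- add_individual(g, "fido")
#' g <- add_edge(g, "instance_of", "fido", "dog")
#' order_of(g, "dog")
ontology_graph <- function() {
  structure(
    list(
      entities = list(),
      edges = empty_edges(),
      ternary_edges = empty_ternary(),
      relations = BASE_BINARY_RELATIONS,
      ternary_relations = BASE_TERNARY_RELATIONS
    ),
    class = "ontology_graph"
  )
}

#' Coerce to an ontology graph
#'
#' Registries embed an ontology graph; graph-level operations accept either.
#'
#' @param x An `ontology_graph` or `mdr_registry`.
#' @return The underlying `ontology_graph`.
#' @export
as_ontology_graph <- function(x) {
  if (inherits(x, "mdr_registry")) return(x$graph)
  if (inherits(x, "ontology_graph")) return(x)
  mdr_abort("NotAGraph", "expected an ontology_graph or mdr_registry")
}

# Apply a graph-modifying function uniformly to a graph or a registry.
with_graph <- function(x, f) {
  if (inherits(x, "mdr_registry")) {
    x$graph <- f(x$graph)
    x
  } else {
    f(x)
  }
}

graph_has <- function(graph, id) id %in% names(graph$entities)

entity_of <- function(graph, id) {
  if (!graph_has(graph, id)) {
    mdr_abort("UnknownEntity", sprintf("entity '%s' is not in the graph", id))
  }
  graph$entities[[id]]
}

is_category_id <- function(graph, id) {
  graph_has(graph, id) && identical(graph$entities[[id]]$type, "category")
}

check_id <- function(id) {
  if (!is.character(id) || length(id) != 1L || is.na(id) || !nzchar(id)) {
    mdr_abort("InvalidId", "entity ids must be non-empty strings")
  }
  invisible(id)
}

#' Add a category to an ontology graph
#'
#' Categories are instantiable entities. Three kinds are distinguished:
#' universals (invariants of the real world), concepts (meanings in minds)
#' and symbol structures (instantiated by tokens); `"unspecified"` leaves
#' the kind open. A category with no asserted instances has no computable
#' order, so `declared_order` may fix one; when instances exist the declared
#' order must agree with the computed order or [well_typed()] reports a
#' `DECLARED_ORDER_MISMATCH` finding.
#'
#' @param x An `ontology_graph` or `mdr_registry`.
#' @param id Entity id (non-empty string, unique within the graph).
#' @param kind One of `"universal"`, `"concept"`, `"symbol_structure"`,
#'   `"unspecified"`.
#' @param declared_order Optional natural number >= 1.
#' @param label Display label (identity is by id; labels are display-only).
#' @param level Optional level tag: `"description"`, `"model"` or
#'   `"real_world"`.
#' @param descriptive_role Optional descriptive role, only meaningful when
#'   `level = "description"`: one of `"metadata_type"`, `"metadata_item"`,
#'   `"application_level_data_type"`, `"application_level_data_item"`.
#' @return The updated graph (or registry).
#' @export
add_category <- function(x, id, kind = "concept", declared_order = NULL,
                         label = id, level = NULL, descriptive_role = NULL) {
  check_id(id)
  kind <- match.arg(kind, CATEGORY_KINDS)
  if (!is.null(declared_order)) {
    declared_order <- as.integer(declared_order)
    if (is.na(declared_order) || declared_order < 1L) {
      mdr_abort("InvalidOrder", "declared_order must be a natural number >= 1")
    }
  }
  if (!is.null(descriptive_role) && !identical(level, "description")) {
    mdr_abort("InvalidLevelTag",
              "descriptive_role is only allowed when level = 'description'")
  }
  with_graph(x, function(graph) {
    if (graph_has(graph, id)) {
      mdr_abort("DuplicateId", sprintf("entity '%s' already exists", id))
    }
    ent <- list(id = id, label = label, type = "category", kind = kind)
    if (!is.null(declared_order)) ent$declared_order <- declared_order
    if (!is.null(level)) ent$level <- level
    if (!is.null(descriptive_role)) ent$descriptive_role <- descriptive_role
    graph$entities[[id]] <- ent
    graph
  })
}

#' Add an individual to an ontology graph
#'
#' Individuals are non-instantiable entities of order 0. The concrete kind
#' records the individual's relation to space and time (continuant,
#' presential, process, ...) or marks it as a dependent entity (attributive,
#' relator, role), a symbolic token, a fact, or an abstract individual.
#'
#' @inheritParams add_category
#' @param concrete_kind One of `r paste0('"', INDIVIDUAL_KINDS, '"', collapse = ", ")`.
#' @param lexical For tokens: the lexical form (the written value).
#' @return The updated graph (or registry).
#' @export
add_individual <- function(x, id, concrete_kind = "continuant", label = id,
                           level = NULL, lexical = NULL) {
  check_id(id)
  concrete_kind <- match.arg(concrete_kind, INDIVIDUAL_KINDS)
  with_graph(x, function(graph) {
    if (graph_has(graph, id)) {
      mdr_abort("DuplicateId", sprintf("entity '%s' already exists", id))
    }
    ent <- list(id = id, label = label, type = "individual",
                concrete_kind = concrete_kind)
    if (!is.null(level)) ent$level <- level
    if (!is.null(lexical)) ent$lexical <- lexical
    graph$entities[[id]] <- ent
    graph
  })
}

#' Add a typed relation edge
#'
#' Both endpoints must already exist in the graph. The relation name must be
#' one of the base relations or a relation added by a vertical metamodel
#' extension (see [register_extension()]).
#'
#' @inheritParams add_category
#' @param relation Relation name.
#' @param source,target Entity ids.
#' @return The updated graph (or registry).
#' @export
add_edge <- function(x, relation, source, target) {
  with_graph(x, function(graph) {
    if (!relation %in% graph$relations) {
      mdr_abort("UnknownRelation",
                sprintf("'%s' is not a registered binary relation", relation))
    }
    for (id in c(source, target)) {
      if (!graph_has(graph, id)) {
        mdr_abort("UnknownEntity",
                  sprintf("edge endpoint '%s' is not in the graph", id))
      }
    }
    graph$edges <- rbind(
      graph$edges,
      data.frame(relation = relation, source = source, target = target,
                 stringsAsFactors = FALSE)
    )
    graph
  })
}

has_edge <- function(graph, relation, source, target) {
  e <- graph$edges
  any(e$relation == relation & e$source == source & e$target == target)
}

edge_targets <- function(graph, relation, source) {
  e <- graph$edges
  unique(e$target[e$relation == relation & e$source == source])
}

edge_sources <- function(graph, relation, target) {
  e <- graph$edges
  unique(e$source[e$relation == relation & e$target == target])
}

#' Direct instances of a category
#'
#' Returns exactly the sources of `instance_of` edges targeting the
#' category. Instantiation is not closed under specialization: subcategory
#' traversal, where wanted, is an explicit operation at the call site.
#'
#' @inheritParams add_category
#' @param category A category id.
#' @return A character vector of entity ids (possibly empty), sorted.
#' @export
instances_of <- function(x, category) {
  graph <- as_ontology_graph(x)
  ent <- entity_of(graph, category)
  if (!identical(ent$type, "category")) {
    mdr_abort("NotACategory", sprintf("'%s' is not a category", category))
  }
  sort(edge_sources(graph, "instance_of", category))
}

# Inductive order computation with memoisation. Status is one of:
#   ok           - order computed (value in $order)
#   mixed        - instances of differing orders
#   undetermined - no instances and no declared order
#   cycle        - instantiation cycle through this entity
#   blocked      - depends on an entity whose order failed (root cause
#                  reported elsewhere)
order_status <- function(graph, id, memo, stack = character()) {
  if (!is.null(memo[[id]])) return(memo[[id]])
  if (id %in% stack) {
    res <- list(status = "cycle", order = NA_integer_)
    memo[[id]] <- res
    return(res)
  }
  ent <- graph$entities[[id]]
  if (identical(ent$type, "individual")) {
    res <- list(status = "ok", order = 0L)
    memo[[id]] <- res
    return(res)
  }
  inst <- edge_sources(graph, "instance_of", id)
  inst <- inst[inst %in% names(graph$entities)]
  if (length(inst) == 0L) {
    res <- if (!is.null(ent$declared_order)) {
      list(status = "ok", order = as.integer(ent$declared_order))
    } else {
      list(status = "undetermined", order = NA_integer_)
    }
    memo[[id]] <- res
    return(res)
  }
  sub <- lapply(inst, order_status, graph = graph, memo = memo,
                stack = c(stack, id))
  st <- vapply(sub, `[[`, character(1), "status")
  if (any(st == "cycle")) {
    res <- list(status = "cycle", order = NA_integer_)
  } else if (any(st != "ok")) {
    res <- list(status = "blocked", order = NA_integer_)
  } else {
    orders <- vapply(sub, `[[`, integer(1), "order")
    if (length(unique(orders)) > 1L) {
      res <- list(status = "mixed", order = NA_integer_)
    } else {
      res <- list(status = "ok", order = orders[[1L]] + 1L)
    }
  }
  memo[[id]] <- res
  res
}

#' Inductive order of an entity
#'
#' Every individual has order 0. A category all of whose instances have
#' order n has order n + 1; a category with no asserted instances takes its
#' `declared_order` when present. A category whose instances have differing
#' orders has no order under this induction and raises
#' `MixedOrderCategory`; an empty category without a declared order raises
#' `UndeterminedOrder`.
#'
#' @inheritParams add_category
#' @param entity An entity id.
#' @return A non-negative integer.
#' @export
#' @examples
#' g <- ontology_graph()
#' g <- add_individual(g, "fido")
#' g <- add_individual(g, "bella")
#' g <- add_category(g, "dog", kind = "universal")
#' g <- add_category(g, "species", kind = "concept")
#' g <- add_edge(g, "instance_of", "fido", "dog")
#' g <- add_edge(g, "instance_of", "bella", "dog")
#' g <- add_edge(g, "instance_of", "dog", "species")
#' order_of(g, "fido")    # 0
#' order_of(g, "dog")     # 1
#' order_of(g, "species") # 2
order_of <- function(x, entity) {
  graph <- as_ontology_graph(x)
  entity_of(graph, entity)
  memo <- new.env(parent = emptyenv())
  res <- order_status(graph, entity, memo)
  switch(res$status,
    ok = res$order,
    mixed = mdr_abort("MixedOrderCategory",
      sprintf("category '%s' has instances of differing orders", entity)),
    undetermined = mdr_abort("UndeterminedOrder",
      sprintf("category '%s' has no instances and no declared order", entity)),
    cycle = mdr_abort("CyclicInstantiation",
      sprintf("entity '%s' lies on an instantiation cycle", entity)),
    blocked = mdr_abort("UndeterminedOrder",
      sprintf("order of '%s' is blocked by an instance without a computable order",
              entity))
  )
}

#' Lift a base relation from individuals to categories
#'
#' A relation asserted between individuals is lifted to categories X and Y
#' by the universal-existential condition: every instance x of X has some
#' instance y of Y with a `base_relation` edge from x to y. An empty X
#' satisfies the condition vacuously. Evaluation is closed-world over the
#' asserted edges.
#'
#' @inheritParams add_category
#' @param base_relation Name of the individual-level relation.
#' @param X,Y Category ids.
#' @return `TRUE` or `FALSE`.
#' @export
lift_relation <- function(x, base_relation, X, Y) {
  graph <- as_ontology_graph(x)
  if (!base_relation %in% graph$relations) {
    mdr_abort("UnknownRelation",
              sprintf("'%s' is not a registered binary relation", base_relation))
  }
  xs <- instances_of(graph, X)
  ys <- instances_of(graph, Y)
  for (a in xs) {
    tg <- edge_targets(graph, base_relation, a)
    if (!any(tg %in% ys)) return(FALSE)
  }
  TRUE
}

fresh_id <- function(graph, prefix) {
  n <- length(graph$entities) + 1L
  repeat {
    id <- sprintf("%s_%d", prefix, n)
    if (!graph_has(graph, id)) return(id)
    n <- n + 1L
  }
}

#' Create a relator instance of a relation
#'
#' A relation is a category whose instances are relators: individuals that
#' connect players through roles that are parts of the relator. This
#' constructor creates the relator individual, one role individual per
#' (role, player) pair, `role_part_of` edges from each role to the relator,
#' `plays` edges from each player to its role, and an `instance_of` edge
#' from the relator to the relation category.
#'
#' @inheritParams add_category
#' @param relation Id of the relation category.
#' @param role_player_pairs A list of `c(role_label, player_id)` pairs;
#'   at least 2 pairs are required.
#' @param id Optional relator id; generated when `NULL`.
#' @return A list with elements `graph` (the updated graph or registry) and
#'   `id` (the relator's id).
#' @export
make_relator <- function(x, relation, role_player_pairs, id = NULL) {
  graph <- as_ontology_graph(x)
  ent <- entity_of(graph, relation)
  if (!identical(ent$type, "category")) {
    mdr_abort("NotACategory",
              sprintf("relation '%s' must be a category", relation))
  }
  if (length(role_player_pairs) < 2L) {
    mdr_abort("ArityError", "a relator needs at least 2 (role, player) pairs")
  }
  for (p in role_player_pairs) {
    if (length(p) != 2L) {
      mdr_abort("ArityError", "each pair must be (role_label, player_id)")
    }
    entity_of(graph, p[[2L]])
  }
  if (is.null(id)) id <- fresh_id(graph, paste0(relation, "_relator"))
  roles <- list()
  g2 <- add_individual(graph, id, concrete_kind = "relator")
  for (i in seq_along(role_player_pairs)) {
    p <- role_player_pairs[[i]]
    role_id <- sprintf("%s__role%d_%s", id, i, p[[1L]])
    g2 <- add_individual(g2, role_id, concrete_kind = "role",
                         label = p[[1L]])
    g2 <- add_edge(g2, "role_part_of", role_id, id)
    g2 <- add_edge(g2, "plays", p[[2L]], role_id)
    roles[[i]] <- list(role = role_id, player = p[[2L]])
  }
  g2 <- add_edge(g2, "instance_of", id, relation)
  g2$entities[[id]]$relation <- relation
  g2$entities[[id]]$roles <- roles
  out <- with_graph(x, function(...) g2)
  list(graph = out, id = id)
}

#' Record a ternary function realization
#'
#' Asserts the ternary relation `function_realizes(function, process,
#' realizer)`: the function is realized by the process with the given
#' realizer. The second argument must be an individual of concrete kind
#' `"process"`.
#'
#' @inheritParams add_category
#' @param fn,process,realizer Entity ids.
#' @return The updated graph (or registry).
#' @export
assert_function_realization <- function(x, fn, process, realizer) {
  graph <- as_ontology_graph(x)
  for (id in c(fn, process, realizer)) entity_of(graph, id)
  pent <- graph$entities[[process]]
  if (!identical(pent$type, "individual") ||
      !identical(pent$concrete_kind, "process")) {
    mdr_abort("NotAProcess",
              sprintf("'%s' must be an individual of kind 'process'", process))
  }
  with_graph(x, function(graph) {
    graph$ternary_edges <- rbind(
      graph$ternary_edges,
      data.frame(relation = "function_realizes", x = fn, y = process,
                 z = realizer, stringsAsFactors = FALSE)
    )
    graph
  })
}

#' Ternary edges touching an entity
#'
#' @inheritParams add_category
#' @param entity An entity id; rows are returned when it occurs in any of
#'   the three argument positions.
#' @return A data frame with columns `relation`, `x`, `y`, `z`.
#' @export
ternary_edges_of <- function(x, entity) {
  graph <- as_ontology_graph(x)
  te <- graph$ternary_edges
  te[te$x == entity | te$y == entity | te$z == entity, , drop = FALSE]
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf("<ontology_graph: %d entities, %d edges, %d ternary edges>\n",
              length(x$entities), nrow(x$edges), nrow(x$ternary_edges)))
  invisible(x)
}
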