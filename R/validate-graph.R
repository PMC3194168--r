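# Graph-level well-formedness. Findings are data, never errors: the report
# lists every violated invariant with a stable code. Checks are guarded so
# that a single defect produces a single root-cause finding (e.g. when an
# instantiation cycle exists, order-dependent checks are skipped).

EXPECTED_ROLE_ORDERS <- c(
  metadata_type = 2L,
  metadata_item = 1L,
  application_level_data_type = 2L,
  application_level_data_item = 1L
)

# Entities involved in instance_of cycles, grouped per cycle.
instantiation_cycles <- function(graph) {
  e <- graph$edges
  inst <- e[e$relation == "instance_of", , drop = FALSE]
  ids <- names(graph$entities)
  inst <- inst[inst$source %in% ids & inst$target %in% ids, , drop = FALSE]
  if (nrow(inst) == 0L) return(list())
  g <- igraph::graph_from_data_frame(
    inst[, c("source", "target")], directed = TRUE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g, mode = "strong")
  cycles <- list()
  big <- which(comp$csize > 1L)
  for (k in big) {
    cycles[[length(cycles) + 1L]] <- sort(names(comp$membership)[comp$membership == k])
  }
  loops <- unique(inst$source[inst$source == inst$target])
  for (id in loops) cycles[[length(cycles) + 1L]] <- id
  cycles
}

#' Validate the well-formedness of an ontology graph
#'
#' Checks, in dependency order: every edge endpoint exists
#' (`DANGLING_EDGE`), relation names are registered (`UNKNOWN_RELATION`),
#' no `instance_of` edge targets an individual
#' (`INSTANCE_OF_INDIVIDUAL`), instantiation is acyclic
#' (`CYCLIC_INSTANTIATION`), every category has a computable order
#' (`MIXED_ORDER`, `UNDETERMINED_ORDER`), declared orders agree with
#' computed ones (`DECLARED_ORDER_MISMATCH`), descriptive-role entities
#' carry their expected orders (`LEVEL_ROLE_ORDER`), and relator/role
#' structure is closed (`UNCLOSED_RELATOR`). When a cycle is present,
#' order-dependent checks are suppressed so the report names the root
#' cause only.
#'
#' @inheritParams add_category
#' @return An `mdr_validation_report`; zero rows means well-typed.
#' @export
well_typed <- function(x) {
  graph <- as_ontology_graph(x)
  findings <- list()
  note <- function(code, entity, message) {
    findings[[length(findings) + 1L]] <<- list(code = code, entity = entity,
                                               message = message)
  }
  ids <- names(graph$entities)
  e <- graph$edges

  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      if (!e$relation[i] %in% graph$relations) {
        note("UNKNOWN_RELATION", e$source[i],
             sprintf("edge uses unregistered relation '%s'", e$relation[i]))
      }
      missing <- setdiff(c(e$source[i], e$target[i]), ids)
      for (m in missing) {
        note("DANGLING_EDGE", m,
             sprintf("%s edge (%s -> %s) references missing entity '%s'",
                     e$relation[i], e$source[i], e$target[i], m))
      }
    }
  }
  te <- graph$ternary_edges
  if (nrow(te)) {
    for (i in seq_len(nrow(te))) {
      missing <- setdiff(c(te$x[i], te$y[i], te$z[i]), ids)
      for (m in missing) {
        note("DANGLING_EDGE", m,
             sprintf("ternary %s edge references missing entity '%s'",
                     te$relation[i], m))
      }
    }
  }

  inst <- e[e$relation == "instance_of" & e$source %in% ids & e$target %in% ids,
            , drop = FALSE]
  if (nrow(inst)) {
    for (i in seq_len(nrow(inst))) {
      tgt <- graph$entities[[inst$target[i]]]
      if (identical(tgt$type, "individual")) {
        note("INSTANCE_OF_INDIVIDUAL", inst$target[i],
             sprintf("individual '%s' cannot be instantiated (by '%s')",
                     inst$target[i], inst$source[i]))
      }
    }
  }

  cycles <- instantiation_cycles(graph)
  if (length(cycles)) {
    for (cyc in cycles) {
      note("CYCLIC_INSTANTIATION", cyc[[1L]],
           sprintf("instantiation cycle through: %s", paste(cyc, collapse = ", ")))
    }
  } else {
    memo <- new.env(parent = emptyenv())
    for (id in ids) {
      ent <- graph$entities[[id]]
      if (!identical(ent$type, "category")) next
      res <- order_status(graph, id, memo)
      if (res$status == "mixed") {
        note("MIXED_ORDER", id,
             sprintf("category '%s' has instances of differing orders", id))
      } else if (res$status == "undetermined") {
        note("UNDETERMINED_ORDER", id,
             sprintf("category '%s' has no instances and no declared order", id))
      } else if (res$status == "ok") {
        if (!is.null(ent$declared_order) &&
            as.integer(ent$declared_order) != res$order) {
          note("DECLARED_ORDER_MISMATCH", id,
               sprintf("category '%s' declared order %d but computed order %d",
                       id, as.integer(ent$declared_order), res$order))
        } else if (!is.null(ent$descriptive_role)) {
          expected <- EXPECTED_ROLE_ORDERS[[ent$descriptive_role]]
          if (!is.null(expected) && expected != res$order) {
            note("LEVEL_ROLE_ORDER", id,
                 sprintf("descriptive role '%s' expects order %d, computed %d",
                         ent$descriptive_role, expected, res$order))
          }
        }
      }
      # "blocked": root cause reported at the failing instance
    }
  }

  for (id in ids) {
    ent <- graph$entities[[id]]
    if (!identical(ent$type, "individual") ||
        !identical(ent$concrete_kind, "relator")) next
    ok <- TRUE
    if (is.null(ent$roles) || length(ent$roles) < 2L) ok <- FALSE
    if (ok) {
      for (r in ent$roles) {
        if (!graph_has(graph, r$role) || !graph_has(graph, r$player) ||
            !has_edge(graph, "role_part_of", r$role, id) ||
            !has_edge(graph, "plays", r$player, r$role)) {
          ok <- FALSE
          break
        }
      }
    }
    if (ok && !is.null(ent$relation) &&
        !has_edge(graph, "instance_of", id, ent$relation)) {
      ok <- FALSE
    }
    if (!ok) {
      note("UNCLOSED_RELATOR", id,
           sprintf("relator '%s' has incomplete role/player structure", id))
    }
  }

  new_validation_report(findings)
}
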