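dog_species_graph <- function() {
  g <- ontology_graph()
  g <- add_individual(g, "fido")
  g <- add_individual(g, "bella")
  g <- add_category(g, "dog", kind = "universal")
  g <- add_category(g, "species", kind = "concept")
  g <- add_edge(g, "instance_of", "fido", "dog")
  g <- add_edge(g, "instance_of", "bella", "dog")
  g <- add_edge(g, "instance_of", "dog", "species")
  g
}

test_that("graph construction enforces ids, endpoints and relations", {
  g <- ontology_graph()
  g <- add_category(g, "dog", kind = "universal")
  expect_error(add_category(g, "dog"), class = "mdr_error_DuplicateId")
  expect_error(add_individual(g, "dog"), class = "mdr_error_DuplicateId")
  expect_error(add_category(g, ""), class = "mdr_error_InvalidId")
  expect_error(add_edge(g, "instance_of", "fido", "dog"),
               class = "mdr_error_UnknownEntity")
  g <- add_individual(g, "fido")
  expect_error(add_edge(g, "barks_at", "fido", "dog"),
               class = "mdr_error_UnknownRelation")
  # ids are case-sensitive
  g <- add_category(g, "Dog", kind = "universal")
  expect_length(names(g$entities), 3L)
})

test_that("order typing follows the inductive definition", {
  g <- dog_species_graph()
  expect_identical(order_of(g, "fido"), 0L)
  expect_identical(order_of(g, "dog"), 1L)
  expect_identical(order_of(g, "species"), 2L)

  # empty category: declared order or no order at all
  g <- add_category(g, "genus", declared_order = 3L)
  expect_identical(order_of(g, "genus"), 3L)
  g <- add_category(g, "empty_cat")
  expect_error(order_of(g, "empty_cat"),
               class = "mdr_error_UndeterminedOrder")

  # mixed instance orders are rejected, not maxed
  g <- add_edge(g, "instance_of", "fido", "species")
  expect_error(order_of(g, "species"),
               class = "mdr_error_MixedOrderCategory")
})

test_that("a declared order contradicted by a later instance is flagged", {
  g <- ontology_graph()
  g <- add_category(g, "claims_first_order", declared_order = 1L)
  expect_identical(order_of(g, "claims_first_order"), 1L)
  g <- add_category(g, "sub", declared_order = 1L)
  g <- add_individual(g, "x")
  g <- add_edge(g, "instance_of", "x", "sub")
  g <- add_edge(g, "instance_of", "sub", "claims_first_order")
  rep <- well_typed(g)
  expect_true("DECLARED_ORDER_MISMATCH" %in% rep$code)
})

test_that("instances_of is direct and non-transitive", {
  g <- dog_species_graph()
  expect_identical(instances_of(g, "dog"), c("bella", "fido"))
  expect_identical(instances_of(g, "species"), "dog")  # not fido/bella
  g <- add_category(g, "breed")
  expect_identical(instances_of(g, "breed"), character())
  expect_error(instances_of(g, "fido"), class = "mdr_error_NotACategory")
  expect_error(instances_of(g, "nope"), class = "mdr_error_UnknownEntity")
})

test_that("lift_relation is the universal-existential condition", {
  ex <- phenotype_examples()
  g <- ex$graph
  expect_true(lift_relation(g, "inheres_in", "Red", "RedOb"))
  # an empty property lifts vacuously
  g2 <- add_category(g, "EmptyProp", declared_order = 1L)
  expect_true(lift_relation(g2, "inheres_in", "EmptyProp", "RedOb"))
  # severing the individual-level edge falsifies the lift
  g3 <- g
  keep <- !(g3$edges$relation == "inheres_in" & g3$edges$source == "red_1")
  g3$edges <- g3$edges[keep, , drop = FALSE]
  expect_false(lift_relation(g3, "inheres_in", "Red", "RedOb"))
  expect_error(lift_relation(g, "no_such_rel", "Red", "RedOb"),
               class = "mdr_error_UnknownRelation")
})

test_that("lift_relation agrees with the nested-loop oracle", {
  for (seed in 1:60) {
    rg <- random_lifting_graph(seed)
    for (X in rg$c1) {
      for (Y in rg$c1) {
        expect_identical(
          lift_relation(rg$graph, "inheres_in", X, Y),
          oracle_lift(rg$graph, "inheres_in", X, Y),
          info = sprintf("seed %d, %s/%s", seed, X, Y))
      }
    }
  }
})

test_that("make_relator builds the full role structure", {
  g <- ontology_graph()
  g <- add_category(g, "VR", label = "father relation", declared_order = 1L)
  g <- add_individual(g, "John")
  g <- add_individual(g, "Mary")
  made <- make_relator(g, "VR", list(c("father", "John"), c("child", "Mary")))
  g <- made$graph
  rel <- g$entities[[made$id]]
  expect_length(rel$roles, 2L)
  expect_identical(rel$concrete_kind, "relator")
  expect_true(made$id %in% instances_of(g, "VR"))
  expect_identical(nrow(well_typed(g)), 0L)
  expect_error(make_relator(g, "VR", list(c("father", "John"))),
               class = "mdr_error_ArityError")
  expect_error(make_relator(g, "John", list(c("a", "Mary"), c("b", "Mary"))),
               class = "mdr_error_NotACategory")

  # breaking the role structure is caught
  g$edges <- g$edges[g$edges$relation != "plays", , drop = FALSE]
  expect_true("UNCLOSED_RELATOR" %in% well_typed(g)$code)
})

test_that("well_typed reports cycles, mixed orders and dangling edges", {
  g <- dog_species_graph()
  expect_identical(nrow(well_typed(g)), 0L)

  g_cycle <- g
  g_cycle$edges <- rbind(
    g_cycle$edges,
    data.frame(relation = "instance_of", source = "species", target = "dog",
               stringsAsFactors = FALSE))
  rep <- well_typed(g_cycle)
  expect_identical(rep$code, "CYCLIC_INSTANTIATION")
  expect_error(order_of(g_cycle, "dog"),
               class = "mdr_error_CyclicInstantiation")

  g_mixed <- add_edge(g, "instance_of", "fido", "species")
  expect_true("MIXED_ORDER" %in% well_typed(g_mixed)$code)

  g_dangling <- g
  g_dangling$edges <- rbind(
    g_dangling$edges,
    data.frame(relation = "part_of", source = "fido", target = "ghost",
               stringsAsFactors = FALSE))
  expect_true("DANGLING_EDGE" %in% well_typed(g_dangling)$code)

  g_ind <- add_edge(g, "instance_of", "bella", "fido")
  expect_true("INSTANCE_OF_INDIVIDUAL" %in% well_typed(g_ind)$code)
})

test_that("order soundness holds on graphs with zero findings", {
  for (seed in c(1, 2, 3)) {
    reg <- generate_fixture(fixture_spec(seed = seed, max_order = 3L))
    g <- reg$graph
    expect_identical(nrow(well_typed(g)), 0L)
    inst <- g$edges[g$edges$relation == "instance_of", , drop = FALSE]
    for (i in seq_len(nrow(inst))) {
      expect_identical(order_of(g, inst$target[i]),
                       order_of(g, inst$source[i]) + 1L)
    }
  }
})

test_that("edge removal never introduces a cycle finding", {
  for (seed in 1:10) {
    rg <- random_lifting_graph(seed)
    g <- rg$graph
    before <- sum(well_typed(g)$code == "CYCLIC_INSTANTIATION")
    for (k in seq_len(min(nrow(g$edges), 5L))) {
      g2 <- g
      g2$edges <- g2$edges[-k, , drop = FALSE]
      expect_lte(sum(well_typed(g2)$code == "CYCLIC_INSTANTIATION"), before)
    }
  }
})

test_that("adding an unrelated entity leaves existing orders unchanged", {
  g <- dog_species_graph()
  before <- vapply(c("fido", "dog", "species"), order_of, integer(1), x = g)
  g <- add_category(g, "unrelated", declared_order = 2L)
  g <- add_individual(g, "stranger")
  after <- vapply(c("fido", "dog", "species"), order_of, integer(1), x = g)
  expect_identical(before, after)
})

test_that("ternary function realization is typed and queryable", {
  g <- ontology_graph()
  g <- add_individual(g, "fn", concrete_kind = "attributive")
  g <- add_individual(g, "proc", concrete_kind = "process")
  g <- add_individual(g, "device")
  g <- assert_function_realization(g, "fn", "proc", "device")
  for (endpoint in c("fn", "proc", "device")) {
    expect_identical(nrow(ternary_edges_of(g, endpoint)), 1L)
  }
  expect_error(assert_function_realization(g, "fn", "device", "proc"),
               class = "mdr_error_NotAProcess")
})
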