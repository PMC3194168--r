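test_that("a data element concept pairs an object class with its property", {
  reg <- subject_weight_example()
  expect_length(constituents(reg, "DEC:subjects_weight"), 2L)
  expect_setequal(constituents(reg, "DEC:subjects_weight"),
                  c("OC:subject", "PROP:weight"))
  # the DEC is an order-1 category; its fact instance has order 0
  expect_identical(order_of(reg, "DEC:subjects_weight"), 1L)
  expect_identical(order_of(reg, "FACT:johns_weight_70"), 0L)
  expect_true("FACT:johns_weight_70" %in%
                instances_of(reg, "DEC:subjects_weight"))

  r2 <- mdr_registry()
  r2 <- add_category(r2, "OC:a", declared_order = 1L)
  r2 <- add_category(r2, "OC:b", declared_order = 1L)
  r2 <- add_category(r2, "PROP:p", declared_order = 1L)
  expect_error(
    make_dec(r2, "DEC:x", "OC:a", property_spec("PROP:p", "OC:b")),
    class = "mdr_error_BearerMismatch")
})

test_that("a DEC binds exactly one conceptual domain", {
  reg <- mdr_registry()
  reg <- add_category(reg, "OC:s", declared_order = 1L)
  reg <- add_category(reg, "PROP:p", declared_order = 1L)
  reg <- make_dec(reg, "DEC:d", "OC:s", property_spec("PROP:p", "OC:s"))
  reg <- make_conceptual_domain(reg, "CD:1",
                                meanings = list(value_meaning("VM:a")))
  reg <- make_conceptual_domain(reg, "CD:2", description = "described only")
  # an unbound DEC is a validation finding
  expect_true("MISSING_CD" %in% validate_registry(reg)$code)
  reg <- bind_conceptual_domain(reg, "DEC:d", "CD:1")
  expect_error(bind_conceptual_domain(reg, "DEC:d", "CD:2"),
               class = "mdr_error_AlreadyBound")
  expect_error(make_conceptual_domain(reg, "CD:3"),
               class = "mdr_error_InvalidDomain")
})

test_that("measurement partitions are disjoint, covering and half-even", {
  out <- partition_property(
    data.frame(attributive = c("w1", "w2", "w3"),
               magnitude = c(70.2, 69.8, 70.4), unit = "kg",
               stringsAsFactors = FALSE))
  expect_length(out, 1L)
  expect_identical(out[[1L]]$label, "70 kg")
  expect_setequal(out[[1L]]$members, c("w1", "w2", "w3"))
  expect_identical(out[[1L]]$magnitude, 70)

  expect_identical(partition_property(NULL), list())
  expect_identical(
    partition_property(data.frame(attributive = character(),
                                  magnitude = numeric(),
                                  unit = character())),
    list())

  # unit conversion happens before binning
  out_g <- partition_property(
    data.frame(attributive = "w1", magnitude = 70200, unit = "g",
               stringsAsFactors = FALSE), unit = "kg")
  expect_identical(out_g[[1L]]$label, "70 kg")
  expect_error(
    partition_property(data.frame(attributive = "w1", magnitude = 1,
                                  unit = "mmHg", stringsAsFactors = FALSE),
                       unit = "kg"),
    class = "mdr_error_UnitMismatch")

  # property: disjoint and covering on random magnitude sets
  for (seed in 1:50) {
    withr::with_seed(seed, {
      n <- sample(1:12, 1)
      df <- data.frame(attributive = sprintf("a%d", seq_len(n)),
                       magnitude = runif(n, 0, 50), unit = "kg",
                       stringsAsFactors = FALSE)
    })
    classes <- partition_property(df)
    members <- unlist(lapply(classes, `[[`, "members"))
    expect_identical(sort(members), sort(df$attributive))
    expect_identical(anyDuplicated(members), 0L)
  }
})

test_that("make_fact enforces the DEC typing invariants", {
  reg <- subject_weight_example()
  expect_error(
    make_fact(reg, "FACT:bad1", "ATTR:johns_weight", "ATTR:johns_weight",
              "VM:weight_70_kg", "DEC:subjects_weight"),
    class = "mdr_error_NotInstanceOfObjectClass")
  expect_error(
    make_fact(reg, "FACT:bad2", "IND:john", "IND:john",
              "VM:weight_70_kg", "DEC:subjects_weight"),
    class = "mdr_error_NotInstanceOfProperty")
  # attributive in the wrong meaning's equivalence class
  expect_error(
    make_fact(reg, "FACT:bad3", "IND:john", "ATTR:johns_weight",
              "VM:weight_71_kg", "DEC:subjects_weight"),
    class = "mdr_error_MeaningMismatch")
  # an attributive not connected by the property's relation
  reg2 <- add_individual(reg, "ATTR:floating", concrete_kind = "attributive")
  reg2 <- add_edge(reg2, "instance_of", "ATTR:floating", "PROP:weight")
  expect_error(
    make_fact(reg2, "FACT:bad4", "IND:john", "ATTR:floating",
              "VM:weight_70_kg", "DEC:subjects_weight"),
    class = "mdr_error_AttributiveNotConnected")
})

test_that("fact representation and decoding are mutually inverse", {
  reg <- subject_weight_example()
  rep <- get_representation(reg, "DE:subjects_weight_kg__rep_FACT:johns_weight_70")
  expect_identical(rep$lexical, "70")
  expect_identical(decode_value(reg, rep$lexical, "VD:weight_kg"),
                   "VM:weight_70_kg")
  expect_error(decode_value(reg, "999", "VD:weight_kg"),
               class = "mdr_error_UnknownToken")
  # a value domain that omits the fact's meaning cannot represent it
  reg2 <- make_fact(reg, "FACT:second", "IND:john",
                    "ATTR:johns_weight", "VM:weight_70_kg",
                    "DEC:subjects_weight")
  reg2 <- make_value_domain(reg2, "VD:partial", "CD:weight_kg",
                            list(list(meaning = "VM:weight_71_kg",
                                      lexical = "71")))
  reg2 <- make_data_element(reg2, "DE:partial", "DEC:subjects_weight",
                            "VD:partial")
  expect_error(represent_fact(reg2, "FACT:second", "DE:partial"),
               class = "mdr_error_NoPermissibleValue")

  # two tokens for one meaning both decode to it (many-to-one direction)
  reg3 <- mdr_registry()
  reg3 <- make_conceptual_domain(
    reg3, "CD:m", meanings = list(value_meaning("VM:seventy"),
                                  value_meaning("VM:eighty")))
  reg3 <- make_value_domain(reg3, "VD:m", "CD:m",
                            list(list(meaning = "VM:seventy", lexical = "70"),
                                 list(meaning = "VM:seventy",
                                      lexical = "70.0")))
  expect_identical(decode_value(reg3, "70", "VD:m"), "VM:seventy")
  expect_identical(decode_value(reg3, "70.0", "VD:m"), "VM:seventy")
  # the functional direction is enforced at construction
  expect_error(
    make_value_domain(reg3, "VD:bad", "CD:m",
                      list(list(meaning = "VM:seventy", lexical = "70"),
                           list(meaning = "VM:eighty", lexical = "70"))),
    class = "mdr_error_NonfunctionalTokenMap")
})

test_that("represent/decode round-trips on randomly partitioned registries", {
  rw <- random_weight_registry(40, seed = 11)
  reg <- rw$registry
  for (i in seq_along(rw$attrs)) {
    a <- rw$attrs[[i]]
    vm <- rw$meaning_of[[a]]
    fid <- sprintf("FACT:%03d", i)
    reg <- make_fact(reg, fid, "IND:bearer", a, vm, "DEC:w")
    made <- represent_fact(reg, fid, "DE:w")
    reg <- made$registry
    expect_identical(decode_value(reg, made$lexical, "CD:w_vd"), vm)
  }
  expect_identical(nrow(validate_registry(reg)), 0L)
})

test_that("validate_registry catches metamodel corruption", {
  reg <- subject_weight_example()
  expect_identical(nrow(validate_registry(reg)), 0L)
  # layering: a clean registry is also well-typed
  expect_identical(nrow(well_typed(reg)), 0L)

  # token mapped to two meanings
  r1 <- reg
  pvs <- r1$value_domains[["VD:weight_kg"]]$permissible_values
  pvs[[2L]]$lexical <- pvs[[1L]]$lexical
  r1$value_domains[["VD:weight_kg"]]$permissible_values <- pvs
  expect_true("NONFUNCTIONAL_TOKEN_MAP" %in% validate_registry(r1)$code)

  # overlapping meaning member sets
  r2 <- reg
  r2$conceptual_domains[["CD:weight_kg"]]$meanings[["VM:weight_71_kg"]]$members <-
    "ATTR:johns_weight"
  expect_true("OVERLAPPING_MEANINGS" %in% validate_registry(r2)$code)

  # missing constituent edge
  r3 <- reg
  e <- r3$graph$edges
  drop <- which(e$relation == "constituent_part" &
                  e$source == "DE:subjects_weight_kg" &
                  e$target == "VD:weight_kg")[1L]
  r3$graph$edges <- e[-drop, , drop = FALSE]
  expect_true("ORPHAN_CONSTITUENT" %in% validate_registry(r3)$code)
})
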