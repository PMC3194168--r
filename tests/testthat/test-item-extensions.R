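test_that("items extend data elements with defaults and acquisition", {
  reg <- blood_pressure_example()
  item <- get_item(reg, "ITEM:blood_pressure")
  expect_identical(item$acquisition$type, "measuring")
  expect_identical(item$default, "120")
  # the item category sits at the same order as its data-element category
  expect_identical(order_of(reg, "ITEM:blood_pressure"),
                   order_of(reg, "DE:subject_bp"))
  expect_error(
    make_item(reg, "ITEM:bad", "DE:subject_bp", default = "999"),
    class = "mdr_error_DefaultNotInValueDomain")
  expect_identical(nrow(validate_registry(reg)), 0L)
})

test_that("acquisition specifications are validated", {
  expect_error(data_acquisition("measuring", "2001-01-02", "2001-01-01"),
               class = "mdr_error_InvalidTemporalExtension")
  expect_error(data_acquisition("measuring", "2001-01-01", "2001-01-01"),
               class = "mdr_error_InvalidTemporalExtension")
  expect_error(
    data_acquisition("measuring", "2001-01-01", "2001-01-02",
                     participants = data.frame(
                       role = c("result_fact", "result_fact"),
                       entity = c("f1", "f2"))),
    class = "mdr_error_InvalidParticipants")
  expect_error(
    data_acquisition("measuring", "2001-01-01", "2001-01-02",
                     participants = data.frame(role = "bystander",
                                               entity = "x")),
    class = "mdr_error_InvalidParticipants")
  a <- data_acquisition("observation", "2001-01-01t08:00:00",
                        " 2001-01-01T09:00:00 ")
  expect_identical(a$start, "2001-01-01T08:00:00")
  expect_identical(a$end, "2001-01-01T09:00:00")
})

test_that("range checks respect bounds, inclusivity and units", {
  r <- range_constraint(0, 300, unit = "kg")
  expect_true(check_range(70, "kg", r))
  expect_true(check_range(0, "kg", r))
  expect_false(check_range(301, "kg", r))
  r_excl <- range_constraint(0, 300, unit = "kg", inclusive = c(FALSE, TRUE))
  expect_false(check_range(0, "kg", r_excl))
  expect_true(check_range(70000, "g", r))
  expect_error(check_range(70, "mmHg", r), class = "mdr_error_UnitMismatch")
  expect_error(range_constraint(10, 5, unit = "kg"),
               class = "mdr_error_InvalidRange")
  # one-sided ranges
  expect_true(check_range(1e6, "kg", range_constraint(lower = 0, unit = "kg")))

  # random magnitudes agree with direct comparison
  withr::with_seed(99, {
    for (i in 1:200) {
      lo <- runif(1, 0, 50); hi <- lo + runif(1, 0, 50)
      m <- runif(1, -10, 110)
      inc <- sample(c(TRUE, FALSE), 2, replace = TRUE)
      r <- range_constraint(lo, hi, unit = "kg", inclusive = inc)
      direct <- (if (inc[1]) m >= lo else m > lo) &&
        (if (inc[2]) m <= hi else m < hi)
      expect_identical(check_range(m, "kg", r), direct)
    }
  })
})

test_that("complex concepts enumerate their components faithfully", {
  reg <- blood_pressure_example()
  counts <- component_counts(reg, "CC:Subject_Blood_Pressure")
  expect_identical(counts[["categorial_part"]], 2L)
  expect_identical(counts[["has_facet"]], 2L)
  # counts agree with the asserted edges
  e <- reg$graph$edges
  expect_identical(
    sum(e$relation == "categorial_part" &
          e$source == "DEC:Subject_Blood_Pressure"), 2L)
  expect_identical(
    sum(e$relation == "has_facet" &
          e$source == "DEC:Subject_Blood_Pressure"), 2L)
  cc <- get_complex_concept(reg, "CC:Subject_Blood_Pressure")
  got <- vapply(cc$components, `[[`, character(1), "target")
  expect_true(all(c("DEC:Subject_Systolic_BP", "DEC:Subject_Diastolic_BP")
                  %in% got))

  expect_error(
    compose_complex(reg, "CC:dup", "DEC:Subject_Blood_Pressure",
                    list(list(relation = "has_facet",
                              target = "FACET:systolic"),
                         list(relation = "has_facet",
                              target = "FACET:systolic"))),
    class = "mdr_error_DuplicateComponent")
  expect_error(
    compose_complex(reg, "CC:bad", "DEC:Subject_Blood_Pressure",
                    list(list(relation = "categorial_part",
                              target = "DEC:nope"))),
    class = "mdr_error_UnknownComponent")
})

test_that("item variants inherit and never mutate their parent", {
  reg <- blood_pressure_example()
  parent_before <- get_item(reg, "ITEM:blood_pressure")
  variant <- get_item(reg, "ITEM:systolic_bp")
  expect_identical(variant$range, parent_before$range)
  expect_identical(variant$default, parent_before$default)
  expect_identical(variant$data_element, parent_before$data_element)
  expect_identical(variant$parent, "ITEM:blood_pressure")
  expect_true(any(reg$graph$edges$relation == "has_facet" &
                    reg$graph$edges$source == "ITEM:systolic_bp" &
                    reg$graph$edges$target == "FACET:systolic"))
  # overriding the range leaves the parent untouched
  reg2 <- derive_variant(reg, "ITEM:blood_pressure", "FACET:resting_state",
                         "ITEM:resting_bp",
                         range = range_constraint(0, 200, unit = "mmHg"))
  expect_identical(get_item(reg2, "ITEM:blood_pressure"), parent_before)
  expect_identical(get_item(reg2, "ITEM:resting_bp")$range$upper, 200)
  expect_error(derive_variant(reg, "ITEM:blood_pressure", "FACET:nope",
                              "ITEM:x"),
               class = "mdr_error_UnknownFacet")
})

test_that("metamodel extensions add metaclasses and relations", {
  reg <- mdr_registry()
  reg <- register_extension(reg, "horizontal", "ISO:Collections")
  expect_identical(order_of(reg, "ISO:Collections"), 2L)
  expect_error(register_extension(reg, "horizontal", "ISO:Range",
                                  declared_order = 1L),
               class = "mdr_error_WrongOrder")
  expect_error(register_extension(reg, "horizontal", "ISO:Collections"),
               class = "mdr_error_DuplicateId")

  reg <- register_extension(reg, "vertical", "derives_from")
  expect_true("derives_from" %in% reg$graph$relations)
  expect_error(register_extension(reg, "vertical", "derives_from"),
               class = "mdr_error_DuplicateId")
  # the new relation is usable both lifted and in composition
  reg <- add_category(reg, "X", declared_order = 1L)
  reg <- add_category(reg, "Y", declared_order = 1L)
  expect_true(lift_relation(reg, "derives_from", "X", "Y"))
  reg <- compose_complex(reg, "CC:xy", "X",
                         list(list(relation = "derives_from", target = "Y")))
  expect_identical(component_counts(reg, "CC:xy")[["derives_from"]], 1L)
})

test_that("item groups keep distinct, ordered, registered members", {
  reg <- blood_pressure_example()
  reg <- make_item_group(reg, "GRP:bp",
                         c("ITEM:blood_pressure", "ITEM:systolic_bp"))
  expect_identical(reg$groups[["GRP:bp"]]$members,
                   c("ITEM:blood_pressure", "ITEM:systolic_bp"))
  expect_error(make_item_group(reg, "GRP:empty", character()),
               class = "mdr_error_EmptyGroup")
  expect_error(
    make_item_group(reg, "GRP:dup",
                    c("ITEM:blood_pressure", "ITEM:blood_pressure")),
    class = "mdr_error_DuplicateId")
  expect_error(make_item_group(reg, "GRP:ghost", "ITEM:nope"),
               class = "mdr_error_UnknownEntity")
})
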