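test_that("save and load round-trip byte-identically", {
  reg <- subject_weight_example()
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_registry(reg, p1)
  reg2 <- load_registry(p1)
  save_registry(reg2, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  expect_identical(nrow(validate_registry(reg2)), 0L)
  # semantics survive the round trip
  expect_identical(decode_value(reg2, "70", "VD:weight_kg"),
                   "VM:weight_70_kg")
  expect_identical(order_of(reg2, "DEC:subjects_weight"), 1L)
})

test_that("malformed documents are rejected with parse context", {
  p <- withr::local_tempfile(fileext = ".json")
  writeLines('{"schema_version": "1.0", "entities": [', p)
  expect_error(load_registry(p), class = "mdr_error_ParseError")
  writeLines('{"schema_version": "99.0", "entities": []}', p)
  expect_error(load_registry(p), class = "mdr_error_SchemaVersionMismatch")
  writeLines('[1, 2, 3]', p)
  expect_error(load_registry(p), class = "mdr_error_ParseError")
})

test_that("fixture generation is deterministic and honours the spec", {
  spec <- fixture_spec(n_object_classes = 3, n_properties = 2,
                       n_data_elements = 4, n_items = 5, max_order = 3,
                       meanings_per_domain = 4, seed = 42)
  a <- generate_fixture(spec)
  b <- generate_fixture(spec)
  p1 <- withr::local_tempfile(fileext = ".json")
  p2 <- withr::local_tempfile(fileext = ".json")
  save_registry(a, p1)
  save_registry(b, p2)
  expect_identical(readLines(p1), readLines(p2))

  expect_length(a$data_elements, 4L)
  expect_length(a$items, 5L)
  expect_length(a$decs, 4L)
  expect_length(a$conceptual_domains[[1L]]$meanings, 4L)
  expect_identical(a$seed, 42L)
  expect_identical(order_of(a, "META:order3"), 3L)
  expect_identical(nrow(validate_registry(a)), 0L)

  # all-zero spec: an empty but valid registry
  empty <- generate_fixture(fixture_spec(0, 0, 0, 0, seed = 1))
  expect_identical(nrow(validate_registry(empty)), 0L)
  expect_length(empty$data_elements, 0L)

  expect_error(fixture_spec(n_object_classes = 0, n_properties = 1),
               class = "mdr_error_InvalidSpec")
  expect_error(fixture_spec(max_order = 1), class = "mdr_error_InvalidSpec")
})

test_that("generated registries validate cleanly across seeds", {
  for (seed in 1:25) {
    reg <- generate_fixture(fixture_spec(seed = seed))
    expect_identical(nrow(validate_registry(reg)), 0L)
  }
})

test_that("mutation requires an injection site", {
  reg1 <- generate_fixture(fixture_spec(meanings_per_domain = 1, seed = 3))
  expect_error(mutate_fixture(reg1, "OVERLAPPING_MEANINGS", 1),
               class = "mdr_error_NoInjectionSite")
  expect_error(mutate_fixture(reg1, "NONFUNCTIONAL_TOKEN_MAP", 1),
               class = "mdr_error_NoInjectionSite")
  empty <- generate_fixture(fixture_spec(0, 0, 0, 0, seed = 1))
  expect_error(mutate_fixture(empty, "MISSING_CD", 1),
               class = "mdr_error_NoInjectionSite")
  expect_error(mutate_fixture(reg1, "NOT_A_CODE", 1),
               class = "mdr_error_UnknownViolationCode")
})

test_that("item queries filter conjunctively with stable order", {
  reg <- blood_pressure_example()
  hits <- query_items(reg, acquisition_type = "measuring")
  expect_true("ITEM:blood_pressure" %in% names(hits))
  all_items <- query_items(reg)
  expect_identical(names(all_items), sort(names(reg$items)))
  expect_length(
    query_items(reg, object_class = "OC:subject",
                acquisition_type = "questioning"), 0L)
  expect_length(query_items(reg, label = "systolic"), 1L)
  expect_length(query_items(reg, property = "PROP:blood_pressure",
                            connecting_relation = "inheres_in"), 2L)
  expect_error(query_items(reg, unit = "kg"),
               class = "mdr_error_UnknownFilterField")
})

test_that("DOT export covers every entity and routes ternary edges", {
  reg <- blood_pressure_example()
  dot <- export_graph(reg)
  lines <- strsplit(dot, "\n", fixed = TRUE)[[1L]]
  node_lines <- grep("^  \"[^\"]+\" \\[label=", lines, value = TRUE)
  n_entities <- length(reg$graph$entities)
  n_ternary <- nrow(reg$graph$ternary_edges)
  expect_length(node_lines, n_entities + n_ternary)
  expect_true(any(grepl("shape=diamond", lines)))
  expect_true(any(grepl('label="realizer"', lines, fixed = TRUE)))
  expect_identical(lines[[1L]], "digraph registry {")
  expect_identical(lines[[length(lines)]], "}")

  empty_dot <- export_graph(ontology_graph())
  expect_match(empty_dot, "digraph registry \\{")
  expect_match(empty_dot, "\\}$")
})

test_that("the CLI validates, queries and generates from the shell surface", {
  dir <- withr::local_tempdir()
  clean <- file.path(dir, "clean.json")
  save_registry(generate_fixture(fixture_spec(seed = 5)), clean)

  out <- capture.output(status <- mdr_cli(c("validate", clean)),
                        type = "output")
  expect_identical(status, 0L)
  expect_length(out[nzchar(out)], 0L)

  broken <- file.path(dir, "broken.json")
  save_registry(mutate_fixture(generate_fixture(fixture_spec(seed = 5)),
                               "MISSING_CD", 2), broken)
  out <- capture.output(status <- mdr_cli(c("validate", broken)),
                        type = "output")
  expect_identical(status, 1L)
  expect_match(out[[1L]], "MISSING_CD")

  out <- capture.output(
    status <- mdr_cli(c("query", clean, "--acquisition-type", "measuring")),
    type = "output")
  expect_identical(status, 0L)
  expect_true(any(grepl("ITEM:item_01", out)))

  spec_path <- file.path(dir, "spec.json")
  writeLines('{"n_data_elements": 1, "n_items": 1, "seed": 9}', spec_path)
  gen_path <- file.path(dir, "gen.json")
  status <- mdr_cli(c("fixture", "--spec", spec_path, "--out", gen_path))
  expect_identical(status, 0L)
  expect_identical(nrow(validate_registry(load_registry(gen_path))), 0L)

  out <- capture.output(status <- mdr_cli(c("demo", "metadata")),
                        type = "output")
  expect_identical(status, 0L)
  expect_match(out[[1L]], '"metadata_type":2')

  out <- capture.output(status <- mdr_cli(c("export", clean)),
                        type = "output")
  expect_identical(status, 0L)
  expect_match(out[[1L]], "digraph")

  expect_identical(mdr_cli(c("unknown-subcommand")), 2L)
})
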