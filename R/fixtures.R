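# Prebuilt worked examples: the subject-weight data element and the
# blood-pressure complex concept with an item and variants. Both are
# constructed entirely through the public constructors, so they double as
# end-to-end smoke fixtures.

#' Worked example: the subject's-weight data element
#'
#' Builds a complete registry around one data element: the object class
#' subject with the individual John, the property weight (connected by
#' inherence) with John's individual weight, a conceptual domain whose
#' value meanings are integer-kilogram equivalence classes ("70 kg",
#' "71 kg"), a value domain mapping the meanings to the tokens "70" and
#' "71", the data element pairing concept and representation, the fact
#' "John's weight being 70 kg", its fact-representation, and a weight
#' item with default, range and a measuring acquisition.
#'
#' @return An `mdr_registry` that passes [validate_registry()] with zero
#'   findings.
#' @export
subject_weight_example <- function() {
  reg <- mdr_registry()
  reg <- add_category(reg, "OC:subject", kind = "universal",
                      declared_order = 1L, label = "subject")
  reg <- add_individual(reg, "IND:john", concrete_kind = "continuant",
                        label = "John")
  reg <- add_edge(reg, "instance_of", "IND:john", "OC:subject")
  reg <- add_category(reg, "PROP:weight", kind = "universal",
                      declared_order = 1L, label = "weight")
  reg <- add_individual(reg, "ATTR:johns_weight",
                        concrete_kind = "attributive",
                        label = "John's weight")
  reg <- add_edge(reg, "instance_of", "ATTR:johns_weight", "PROP:weight")
  reg <- add_edge(reg, "inheres_in", "ATTR:johns_weight", "IND:john")
  reg <- add_edge(reg, "depends_on", "ATTR:johns_weight", "IND:john")

  # the measurement partition puts John's 70.2 kg weight into the
  # integer-kg class "70 kg"
  meanings <- partition_property(
    data.frame(attributive = "ATTR:johns_weight", magnitude = 70.2,
               unit = "kg", stringsAsFactors = FALSE),
    unit = "kg", id_prefix = "VM:weight")
  meanings <- c(meanings, list(
    value_meaning("VM:weight_71_kg", label = "71 kg", magnitude = 71,
                  unit = "kg")))
  reg <- make_conceptual_domain(reg, "CD:weight_kg", meanings = meanings,
                                description = "body weight in whole kilograms",
                                label = "weights in kg")
  reg <- make_value_domain(reg, "VD:weight_kg", "CD:weight_kg",
                           list(list(meaning = meanings[[1L]]$id,
                                     lexical = "70"),
                                list(meaning = "VM:weight_71_kg",
                                     lexical = "71")),
                           label = "weights in kg (integer tokens)")
  reg <- make_dec(reg, "DEC:subjects_weight", "OC:subject",
                  property_spec("PROP:weight", "OC:subject"),
                  label = "subject's weight")
  reg <- bind_conceptual_domain(reg, "DEC:subjects_weight", "CD:weight_kg")
  reg <- make_data_element(reg, "DE:subjects_weight_kg",
                           "DEC:subjects_weight", "VD:weight_kg",
                           label = "subject's weight in kg")
  reg <- make_fact(reg, "FACT:johns_weight_70", "IND:john",
                   "ATTR:johns_weight", meanings[[1L]]$id,
                   "DEC:subjects_weight",
                   label = "John's weight being 70 kg")
  made <- represent_fact(reg, "FACT:johns_weight_70", "DE:subjects_weight_kg")
  reg <- made$registry
  reg <- make_item(
    reg, "ITEM:weight", "DE:subjects_weight_kg", default = "70",
    range = range_constraint(0, 300, unit = "kg"),
    acquisition = data_acquisition(
      "measuring", "2001-01-01T08:00:00", "2001-01-01T08:05:00",
      participants = data.frame(
        role = c("subject", "result_fact"),
        entity = c("IND:john", "FACT:johns_weight_70"),
        stringsAsFactors = FALSE)),
    label = "subject weight item")
  reg
}

#' Worked example: the blood-pressure complex concept
#'
#' Builds three data element concepts (blood pressure, systolic and
#' diastolic) over the object class subject, binds them to an mmHg
#' conceptual domain, composes the blood-pressure concept into a complex
#' concept with two categorial parts (the systolic and diastolic
#' concepts) and two facets, creates a blood-pressure item with a
#' measuring acquisition, derives a systolic variant through a facet, and
#' records a function realization (the measuring function realized by the
#' measurement process with the sphygmomanometer as realizer). The
#' diastolic categorial part and the facet names are fixture conventions
#' of this package.
#'
#' @return An `mdr_registry` that passes [validate_registry()] with zero
#'   findings.
#' @export
blood_pressure_example <- function() {
  reg <- mdr_registry()
  reg <- add_category(reg, "OC:subject", kind = "universal",
                      declared_order = 1L, label = "subject")
  reg <- add_individual(reg, "IND:john", concrete_kind = "continuant",
                        label = "John")
  reg <- add_edge(reg, "instance_of", "IND:john", "OC:subject")
  for (p in c("PROP:blood_pressure", "PROP:systolic_bp",
              "PROP:diastolic_bp")) {
    reg <- add_category(reg, p, kind = "universal", declared_order = 1L)
  }
  meanings <- list(
    value_meaning("VM:bp_080", label = "80 mmHg", magnitude = 80,
                  unit = "mmHg"),
    value_meaning("VM:bp_120", label = "120 mmHg", magnitude = 120,
                  unit = "mmHg"))
  reg <- make_conceptual_domain(reg, "CD:bp_mmHg", meanings = meanings,
                                label = "blood pressure in mmHg")
  reg <- make_value_domain(reg, "VD:bp_mmHg", "CD:bp_mmHg",
                           list(list(meaning = "VM:bp_080", lexical = "80"),
                                list(meaning = "VM:bp_120", lexical = "120")),
                           label = "blood pressure values")
  decs <- c("DEC:Subject_Blood_Pressure", "DEC:Subject_Systolic_BP",
            "DEC:Subject_Diastolic_BP")
  props <- c("PROP:blood_pressure", "PROP:systolic_bp", "PROP:diastolic_bp")
  for (i in seq_along(decs)) {
    reg <- make_dec(reg, decs[i], "OC:subject",
                    property_spec(props[i], "OC:subject"))
    reg <- bind_conceptual_domain(reg, decs[i], "CD:bp_mmHg")
  }
  reg <- make_data_element(reg, "DE:subject_bp",
                           "DEC:Subject_Blood_Pressure", "VD:bp_mmHg",
                           label = "subject blood pressure")
  # facet concepts (elementary level)
  for (f in c("FACET:resting_state", "FACET:measurement_site",
              "FACET:systolic")) {
    reg <- add_category(reg, f, kind = "concept", declared_order = 1L)
  }
  reg <- compose_complex(
    reg, "CC:Subject_Blood_Pressure", "DEC:Subject_Blood_Pressure",
    list(list(relation = "categorial_part",
              target = "DEC:Subject_Systolic_BP"),
         list(relation = "categorial_part",
              target = "DEC:Subject_Diastolic_BP"),
         list(relation = "has_facet", target = "FACET:resting_state"),
         list(relation = "has_facet", target = "FACET:measurement_site")),
    label = "subject blood pressure (complex)")
  reg <- add_individual(reg, "IND:sphygmomanometer",
                        concrete_kind = "continuant",
                        label = "sphygmomanometer")
  reg <- make_item(
    reg, "ITEM:blood_pressure", "DE:subject_bp", default = "120",
    range = range_constraint(0, 350, unit = "mmHg"),
    acquisition = data_acquisition(
      "measuring", "2001-01-01T08:00:00", "2001-01-01T08:05:00",
      participants = data.frame(
        role = c("subject", "instrument"),
        entity = c("IND:john", "IND:sphygmomanometer"),
        stringsAsFactors = FALSE)),
    label = "blood pressure item")
  reg <- derive_variant(reg, "ITEM:blood_pressure", "FACET:systolic",
                        "ITEM:systolic_bp", label = "systolic bp item")
  reg <- add_individual(reg, "ATTR:pumping_function",
                        concrete_kind = "attributive",
                        label = "cuff pumping function")
  reg <- add_individual(reg, "PROC:bp_measurement",
                        concrete_kind = "process",
                        label = "blood pressure measurement process")
  reg <- assert_function_realization(reg, "ATTR:pumping_function",
                                     "PROC:bp_measurement",
                                     "IND:sphygmomanometer")
  reg
}
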