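# Independent brute-force oracles and a random-graph generator. The
# oracles work directly on the raw edge table with nested loops; they
# deliberately share no code with the package's quantifier evaluators.

oracle_instances <- function(g, cat) {
  e <- g$edges
  unique(e$source[e$relation == "instance_of" & e$target == cat])
}

oracle_has_edge <- function(g, rel, a, b) {
  e <- g$edges
  any(e$relation == rel & e$source == a & e$target == b)
}

# forall a in X exists b in Y: rel(a, b)
oracle_lift <- function(g, rel, X, Y) {
  xs <- oracle_instances(g, X)
  ys <- oracle_instances(g, Y)
  for (a in xs) {
    found <- FALSE
    for (b in ys) {
      if (oracle_has_edge(g, rel, a, b)) { found <- TRUE; break }
    }
    if (!found) return(FALSE)
  }
  TRUE
}

# forall a in X exists b in Y: instance_of(a, b)
oracle_categorial_instance <- function(g, X, Y) {
  oracle_lift(g, "instance_of", X, Y)
}

oracle_categorial_specifies <- function(g, X, Y) {
  oracle_lift(g, "specifies", X, Y)
}

# A random two-tier graph: individuals, first-order categories over them,
# second-order categories over those, and random individual-level edges
# for the liftable relations. At most 30 entities.
random_lifting_graph <- function(seed) {
  withr::with_seed(seed, {
    n_ind <- sample(3:12, 1)
    n_c1 <- sample(2:4, 1)
    n_c2 <- sample(1:3, 1)
    g <- ontology_graph()
    inds <- sprintf("i%02d", seq_len(n_ind))
    c1 <- sprintf("A%d", seq_len(n_c1))
    c2 <- sprintf("B%d", seq_len(n_c2))
    for (id in inds) g <- add_individual(g, id)
    for (id in c1) g <- add_category(g, id, declared_order = 1L)
    for (id in c2) g <- add_category(g, id, declared_order = 2L)
    for (id in inds) {
      for (cat in c1) {
        if (runif(1) < 0.4) g <- add_edge(g, "instance_of", id, cat)
      }
    }
    for (cat in c1) {
      for (meta in c2) {
        if (runif(1) < 0.4) g <- add_edge(g, "instance_of", cat, meta)
      }
    }
    for (rel in c("inheres_in", "depends_on", "specifies", "part_of",
                  "participates_in")) {
      for (a in inds) {
        for (b in inds) {
          if (a != b && runif(1) < 0.15) g <- add_edge(g, rel, a, b)
        }
      }
    }
    list(graph = g, individuals = inds, c1 = c1, c2 = c2)
  })
}

# A graph where every bearer-connecting edge is accompanied by a
# depends_on edge (dependency species emit their genus), for the
# relation-weakening property.
random_dependency_graph <- function(seed) {
  withr::with_seed(seed, {
    g <- ontology_graph()
    n_attr <- sample(2:6, 1)
    n_bear <- sample(2:5, 1)
    rel <- sample(c("inheres_in", "part_of", "participates_in"), 1)
    g <- add_category(g, "P", declared_order = 1L)
    g <- add_category(g, "Q", declared_order = 1L)
    attrs <- sprintf("a%d", seq_len(n_attr))
    bears <- sprintf("b%d", seq_len(n_bear))
    for (a in attrs) {
      g <- add_individual(g, a, concrete_kind = "attributive")
      g <- add_edge(g, "instance_of", a, "P")
    }
    kind <- if (rel == "participates_in") "process" else "continuant"
    for (b in bears) {
      g <- add_individual(g, b, concrete_kind = kind)
      g <- add_edge(g, "instance_of", b, "Q")
    }
    for (a in attrs) {
      if (runif(1) < 0.8) {
        b <- sample(bears, 1)
        g <- add_edge(g, rel, a, b)
        g <- add_edge(g, "depends_on", a, b)
      }
    }
    list(graph = g, relation = rel)
  })
}

# Registry with one data element whose conceptual domain is a measurement
# partition of n random attributive magnitudes; used for represent/decode
# round trips at scale.
random_weight_registry <- function(n, seed) {
  withr::with_seed(seed, {
    reg <- mdr_registry()
    reg <- add_category(reg, "OC:subject", kind = "universal",
                        declared_order = 1L)
    reg <- add_individual(reg, "IND:bearer", concrete_kind = "continuant")
    reg <- add_edge(reg, "instance_of", "IND:bearer", "OC:subject")
    reg <- add_category(reg, "PROP:weight", kind = "universal",
                        declared_order = 1L)
    attrs <- sprintf("ATTR:w%03d", seq_len(n))
    mags <- round(runif(n, 40, 120), 1)
    for (a in attrs) {
      reg <- add_individual(reg, a, concrete_kind = "attributive")
      reg <- add_edge(reg, "instance_of", a, "PROP:weight")
      reg <- add_edge(reg, "inheres_in", a, "IND:bearer")
      reg <- add_edge(reg, "depends_on", a, "IND:bearer")
    }
    meanings <- partition_property(
      data.frame(attributive = attrs, magnitude = mags, unit = "kg",
                 stringsAsFactors = FALSE),
      unit = "kg", id_prefix = "VM:w")
    reg <- make_conceptual_domain(reg, "CD:w", meanings = meanings)
    reg <- make_value_domain(reg, "CD:w_vd", "CD:w",
                             lapply(meanings, function(m) list(
                               meaning = m$id,
                               lexical = as.character(m$magnitude))))
    reg <- make_dec(reg, "DEC:w", "OC:subject",
                    property_spec("PROP:weight", "OC:subject"))
    reg <- bind_conceptual_domain(reg, "DEC:w", "CD:w")
    reg <- make_data_element(reg, "DE:w", "DEC:w", "CD:w_vd")
    meaning_of <- list()
    for (m in meanings) for (a in m$members) meaning_of[[a]] <- m$id
    list(registry = reg, attrs = attrs, meaning_of = meaning_of)
  })
}
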