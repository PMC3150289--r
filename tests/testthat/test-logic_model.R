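# Domain types, model file format, and IFF compilation.

test_that("model files round-trip through the writer and parser", {
  nets <- list(loop_net(), load_model("IL2R_validated"),
               generate_network(generator_config(9, 10, p_negated = 0.4,
                                                 p_late = 0.3, n_inputs = 2,
                                                 seed = 11)))
  for (net in nets) {
    back <- read_net(text = write_net(net))
    expect_identical(component_names(back), component_names(net))
    expect_identical(vapply(back$implications, implication_id, ""),
                     vapply(net$implications, implication_id, ""))
    expect_identical(lapply(back$implications, `[[`, "provenance"),
                     lapply(net$implications, `[[`, "provenance"))
    expect_identical(lapply(back$components, `[[`, "role"),
                     lapply(net$components, `[[`, "role"))
    # writer output is canonical: a second round trip is byte-identical
    expect_identical(write_net(back), write_net(net))
  }
})

test_that("validation reports undeclared, contradictory and role problems", {
  ok <- net_from("node TCRB input", "CSK = PAG", "LCKP1 = !CSK",
                 "FYN = LCKP1", "PAG = FYN & !TCRB @early")
  expect_identical(nrow(validate_network(ok)), 0L)

  bad <- logical_network(c("A", "B"),
                         list(implication("B", c("A", "X"))))
  d <- validate_network(bad)
  expect_true(any(grepl("undeclared component: X", d$message)))

  contra <- logical_network(c("A", "B"),
                            list(implication("B", c("A", "!A"))))
  d <- validate_network(contra)
  expect_true(any(grepl("contradictory antecedent", d$message)))
  expect_error(implication("B", character(0)), "empty antecedent")

  selfref <- logical_network(c("A", "B"),
                             list(implication("B", c("A", "B"))))
  expect_true(any(grepl("own antecedent", validate_network(selfref)$message)))

  miswired <- logical_network(list(component("A", role = "input"),
                                   component("B")),
                              list(implication("A", "B")))
  # constructor reconciles roles, so build the inconsistency by hand
  miswired$components$A$role <- "input"
  miswired$implications <- list(implication("A", "B"))
  d <- validate_network(miswired)
  expect_true(any(grepl("role 'input'", d$message)))
})

test_that("duplicate implications collapse with provenance union", {
  net <- logical_network(c("A", "B"), list(
    implication("B", "A", provenance = "M1"),
    implication("B", "A", provenance = "M2")))
  expect_identical(n_clauses(net), 1L)
  expect_identical(net$implications[[1]]$provenance, c("M1", "M2"))
})

test_that("input components are exactly the unregulated components", {
  expect_identical(input_components(loop_net()), "TCRB")
  chain <- net_from("B = A", "C = B")
  expect_identical(input_components(chain), "A")
  bare <- logical_network(c("X", "Y"), list())
  expect_setequal(input_components(bare), c("X", "Y"))
})

test_that("compile_iff collects same-consequent statements into one clause", {
  single <- net_from("ERK = MEK")
  sys <- compile_iff(single, "early")
  expect_identical(names(sys$clauses), "ERK")
  expect_identical(sys$clauses$ERK$dnf, list("MEK"))
  expect_identical(sys$free, "MEK")

  collect <- net_from("C = A", "C = B")
  sys <- compile_iff(collect, "early")
  expect_identical(sys$clauses$C$dnf, list("A", "B"))

  sys <- compile_iff(loop_net(), "early")
  expect_setequal(names(sys$clauses), c("PAG", "CSK", "LCKP1", "FYN"))
  expect_identical(sys$clauses$PAG$dnf, list(c("FYN", "!TCRB")))
  expect_identical(sys$clauses$CSK$dnf, list("PAG"))
  expect_identical(sys$clauses$LCKP1$dnf, list("!CSK"))
  expect_identical(sys$clauses$FYN$dnf, list("LCKP1"))
  expect_identical(sys$free, "TCRB")
})

test_that("components with only out-of-phase implications become free", {
  net <- net_from("B = A @late", "C = A @early", "D = A")
  early <- compile_iff(net, "early")
  expect_true("B" %in% early$free)
  expect_setequal(names(early$clauses), c("C", "D"))
  late <- compile_iff(net, "late")
  expect_true("C" %in% late$free)
  expect_setequal(names(late$clauses), c("B", "D"))
})

test_that("clause DNFs hold exactly the in-phase antecedents (property)", {
  for (seed in 1:20) {
    net <- generate_network(generator_config(10, 12, p_negated = 0.3,
                                             p_late = 0.3, n_inputs = 2,
                                             seed = seed))
    for (phase in c("early", "late")) {
      sys <- compile_iff(net, phase)
      expect_true(all(input_components(net) %in% sys$free))
      in_phase <- Filter(function(i) i$horizon %in% c("permanent", phase),
                         net$implications)
      for (cl in sys$clauses) {
        mine <- Filter(function(i) i$consequent == cl$consequent, in_phase)
        expect_setequal(
          vapply(cl$dnf, paste, "", collapse = "&"),
          vapply(mine, function(i) paste(i$antecedent, collapse = "&"), ""))
      }
      # idempotence through serialization
      sys2 <- compile_iff(read_net(text = write_net(net)), phase)
      expect_identical(sys2$clauses, sys$clauses)
      expect_identical(sys2$free, sys$free)
    }
  }
})

test_that("DOT export marks inhibitory edges and AND junctions", {
  dot <- export_dot(loop_net())
  expect_true(any(grepl("\"CSK\" -> \"LCKP1\" \\[style=dotted\\]", dot)))
  expect_true(any(grepl("shape=point", dot)))       # FYN & !TCRB junction
  expect_true(any(grepl("\"PAG\" -> \"CSK\" \\[style=solid\\]", dot)))
})
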