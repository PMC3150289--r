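# Standardization, conflict classification, merging, recovery, projection
# support functions.

test_that("standardize renames injectively and preserves structure", {
  net <- net_from("STAT5 = LCK", "PI3K = LCK & !CAMP")
  out <- standardize(net, c(LCK = "LCKP1"))
  expect_true("LCKP1" %in% component_names(out))
  expect_false("LCK" %in% component_names(out))
  expect_identical(out$implications[[1]]$antecedent, c("!CAMP", "LCKP1"))
  expect_identical(standardize(net, character(0)), net)
  both <- net_from("X = A", "Y = B")
  expect_error(standardize(both, c(A = "B")), "collide")
  expect_error(standardize(net, c(NOPE = "Z")), "unknown")
})

test_that("conflict kinds A-D are assigned by the classification rules", {
  # A: overlapping but non-identical left-hand sides (SHP2 example)
  a1 <- read_net(text = c("model P1", "SHP2 = GAB2"))
  a2 <- read_net(text = c("model P2", "SHP2 = GAB2 & !ERK"))
  cf <- classify_conflicts(a1, a2)
  expect_length(cf, 1L)
  expect_identical(cf[[1]]$kind, "A_overlapping_lhs")
  expect_identical(cf[[1]]$consequent, "SHP2")

  # B versus C: disjoint antecedents; C when the direct statement is a
  # simplification of the other parent's multi-step pathway (SFK -> JNK)
  tcrish <- read_net(text = c("model P1", "ZAP70 = SFK", "LAT = ZAP70",
                              "MKK = LAT", "JNK = MKK"))
  il2ish <- read_net(text = c("model P2", "node SFK input", "JNK = SFK"))
  cf <- classify_conflicts(tcrish, il2ish)
  kinds <- vapply(cf, `[[`, "", "kind")
  expect_setequal(kinds, c("B_disjoint_lhs", "C_refinement"))

  # pure B: no path between the mediators
  b1 <- read_net(text = c("model P1", "X = A"))
  b2 <- read_net(text = c("model P2", "X = B"))
  kinds <- vapply(classify_conflicts(b1, b2), `[[`, "", "kind")
  expect_identical(kinds, "B_disjoint_lhs")

  # D: antecedents related through the isoform hierarchy
  d1 <- read_net(text = c("model P1", "X = PKCTHETA & M"))
  d2 <- read_net(text = c("model P2", "X = NPKC & M"))
  hier <- isoform_hierarchy(c(PKCTHETA = "NPKC"))
  kinds <- vapply(classify_conflicts(d1, d2, hier), `[[`, "", "kind")
  expect_true("D_isoform" %in% kinds)
  # without the hierarchy no D is raised (no name-substring guessing)
  kinds0 <- vapply(classify_conflicts(d1, d2), `[[`, "", "kind")
  expect_false("D_isoform" %in% kinds0)

  # identical clause sets raise no conflict
  expect_length(classify_conflicts(a1, a1), 0L)
})

test_that("merge is an identity on one parent and a disjoint union otherwise", {
  net <- load_model("loop")
  m <- merge_networks(net, net)
  expect_identical(component_names(m$network), component_names(net))
  expect_identical(vapply(m$network$implications, implication_id, ""),
                   vapply(net$implications, implication_id, ""))
  expect_length(m$report$conflicts, 0L)

  a <- read_net(text = c("model A", "X = S1"))
  b <- read_net(text = c("model B", "Y = S2"))
  m2 <- merge_networks(a, b)
  expect_identical(length(m2$network$components), 4L)
  expect_identical(n_clauses(m2$network), 2L)
  expect_length(m2$report$conflicts, 0L)
  # provenance labels annotate each statement's origin
  expect_identical(lapply(m2$network$implications, `[[`, "provenance"),
                   list("A", "B"))
})

test_that("merge is commutative up to provenance labels", {
  a <- load_model("TCR")
  b <- load_model("IL2R_validated")
  hier <- bundled_isoforms()
  dec <- bundled_decisions()
  ab <- merge_networks(a, b, hier, dec)$network
  ba <- merge_networks(b, a, hier, dec)$network
  expect_identical(component_names(ab), component_names(ba))
  expect_identical(vapply(ab$implications, implication_id, ""),
                   vapply(ba$implications, implication_id, ""))
})

test_that("decisions steer conflict resolution and are checked", {
  a <- read_net(text = c("model A", "X = S1"))
  b <- read_net(text = c("model B", "node S1 input", "X = S1 & !N"))
  # default: union of both activating routes
  m <- merge_networks(a, b)
  expect_identical(length(compile_iff(m$network, "early")$clauses$X$dnf), 2L)
  expect_identical(m$report$decisions[[1]]$source, "default")
  # keep_A
  mA <- merge_networks(a, b, decisions = list(merge_decision("X", "keep_A")))
  expect_identical(compile_iff(mA$network, "early")$clauses$X$dnf, list("S1"))
  # replace_with
  mR <- merge_networks(a, b, decisions = list(
    merge_decision("X", "replace_with",
                   replacement = list(implication("X", c("S1", "!N"))))))
  expect_identical(compile_iff(mR$network, "early")$clauses$X$dnf,
                   list(c("!N", "S1")))
  # a decision for a non-conflict is an error
  expect_error(merge_networks(a, b, decisions = list(merge_decision("Z"))),
               "no known conflict")
})

test_that("every differing shared consequent yields at least one conflict", {
  a <- load_model("TCR")
  b <- load_model("IL2R_validated")
  cf <- classify_conflicts(a, b, bundled_isoforms())
  conflicted <- unique(vapply(cf, `[[`, "", "consequent"))
  key <- function(net, comp) sort(vapply(
    Filter(function(i) i$consequent == comp, net$implications),
    implication_id, ""))
  for (comp in intersect(component_names(a), component_names(b))) {
    ka <- key(a, comp); kb <- key(b, comp)
    if (length(ka) && length(kb) && !identical(ka, kb))
      expect_true(comp %in% conflicted, label = paste("conflict for", comp))
  }
})

test_that("common components and shared negative regulators are found", {
  a <- read_net(text = c("model A", "X = S1"))
  b <- read_net(text = c("model B", "Y = S2"))
  cc <- common_components(a, b)
  expect_length(cc$shared, 0L)
  expect_length(cc$negative_regulators, 0L)

  p1 <- net_from("ERK = MEK", "OUT1 = PI3K & !ERK")
  p2 <- net_from("ERK = JAK", "OUT2 = PI3K & !ERK")
  cc2 <- common_components(p1, p2)
  expect_true(all(c("ERK", "PI3K") %in% cc2$shared))
  expect_identical(cc2$negative_regulators, "ERK")

  cc3 <- common_components(load_model("TCR"), load_model("IL2R_validated"))
  expect_true(all(c("LCKP1", "FYN", "PI3K", "ERK", "JNK", "P38") %in%
                    cc3$shared))
  expect_true("SHP1" %in% cc3$negative_regulators)
})

test_that("recovery checks detect patterns broken by merged inhibitors", {
  # identity merge recovers any feasible parent scenario
  loop <- load_model("loop")
  child <- merge_networks(loop, loop)$network
  rep1 <- verify_merge(child, list(list(
    name = "tcrb_on", fix = c(TCRB = 1, PAG = 0, CSK = 0, LCKP1 = 1, FYN = 1))))
  expect_true(all(rep1$recovered))

  # a parent-B inhibitor unioned into a parent-A clause breaks recovery of
  # the parent-A pattern with the inhibitor ON, and the unique singleton
  # intervention is the offending clause
  pa <- read_net(text = c("model A", "node S input", "node X input", "B = S"))
  pb <- read_net(text = c("model B", "node S input", "node X input",
                          "B = S & !X"))
  child2 <- merge_networks(pa, pb, decisions = list(
    merge_decision("B", "replace_with",
                   replacement = list(implication("B", c("S", "!X")))))
  )$network
  rep2 <- verify_merge(child2,
                       list(list(name = "a_with_x", fix = c(S = 1, X = 1, B = 1))))
  expect_false(rep2$recovered[1])
  expect_match(rep2$interventions[1], "B = S & !X @permanent", fixed = TRUE)

  # disjoint-union merge recovers both parents' scenarios
  da <- read_net(text = c("model A", "P = S1"))
  db <- read_net(text = c("model B", "Q = S2"))
  child3 <- merge_networks(da, db)$network
  rep3 <- verify_merge(child3, list(
    list(name = "a", fix = c(S1 = 1, P = 1)),
    list(name = "b", fix = c(S2 = 1, Q = 1))))
  expect_true(all(rep3$recovered))
})

test_that("disjoint-parent children have product state spaces (property)", {
  for (seed in 1:8) {
    a <- generate_network(generator_config(6, 6, p_negated = 0.3,
                                           p_late = 0.2, n_inputs = 2,
                                           seed = seed))
    b0 <- generate_network(generator_config(7, 7, p_negated = 0.3,
                                            p_late = 0.2, n_inputs = 2,
                                            seed = 100 + seed))
    # make the second parent's names disjoint (and sorting after parent A's,
    # so child state keys factor as key(A) followed by key(B))
    map <- stats::setNames(paste0("Z", component_names(b0)),
                           component_names(b0))
    b <- standardize(b0, map)
    child <- merge_networks(a, b)$network
    for (phase in c("early", "late")) {
      sa <- state_keys(oracle_states(compile_iff(a, phase)))
      sb <- state_keys(oracle_states(compile_iff(b, phase)))
      sc <- state_keys(enumerate_states(compile_iff(child, phase),
                                        cap = 100000))
      expect_identical(length(sc), length(sa) * length(sb))
      want <- sort(as.vector(outer(sa, sb, paste0)))
      expect_identical(sc, want)
    }
  }
})

test_that("merge reports serialize to stable YAML", {
  m <- merge_networks(load_model("TCR"), load_model("IL2R_validated"),
                      bundled_isoforms(), bundled_decisions())
  txt <- write_merge_report(m$report)
  y <- yaml::yaml.load(txt)
  expect_identical(y$child, m$report$child)
  expect_length(y$conflicts, length(m$report$conflicts))
  expect_identical(txt, write_merge_report(m$report))
})
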