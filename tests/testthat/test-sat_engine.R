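# Feasibility, enumeration, prediction, interventions and infeasible cores.

test_that("the compensated feedback loop has the documented unique state", {
  loop <- loop_net()
  res <- is_feasible(loop, c(TCRB = 1))
  expect_true(res$feasible)
  expect_identical(res$state[c("TCRB", "PAG", "CSK", "LCKP1", "FYN")],
                   c(TCRB = 1L, PAG = 0L, CSK = 0L, LCKP1 = 1L, FYN = 1L))
  st <- enumerate_states(loop, c(TCRB = 1))
  expect_identical(nrow(st), 1L)

  # without the compensating input the early system is infeasible
  res0 <- is_feasible(loop, c(TCRB = 0))
  expect_false(res0$feasible)
  expect_setequal(res0$core$clauses, c("PAG", "CSK", "LCKP1", "FYN"))
  expect_identical(res0$core$fixations, fixation(c(TCRB = 0)))

  # the whole network admits exactly one state (the TCRB = 1 branch)
  expect_identical(nrow(enumerate_states(loop)), 1L)
})

test_that("empty systems and empty fixations are trivially feasible", {
  empty <- logical_network(character(0), list())
  res <- is_feasible(compile_iff(empty, "early"), NULL)
  expect_true(res$feasible)
  expect_length(res$state, 0L)
  one_free <- logical_network("A", list())
  expect_identical(nrow(enumerate_states(one_free, phase = "early")), 2L)
})

test_that("fixations are validated and unknown components are named", {
  expect_error(is_feasible(loop_net(), c(NOPE = 1)), "NOPE")
  expect_error(fixation("A=2"), "0 or 1")
  expect_error(fixation(c(A = 1, A = 0)), "twice")
})

test_that("enumeration is lexicographic and flags truncation", {
  net <- logical_network(c("A", "B", "C"), list())  # 3 free components
  st <- enumerate_states(net, phase = "early")
  expect_identical(nrow(st), 8L)
  expect_identical(st$A, rep(0:1, each = 4L))
  expect_false(attr(st, "truncated"))
  st2 <- enumerate_states(compile_iff(net, "early"), cap = 3)
  expect_identical(nrow(st2), 3L)
  expect_true(attr(st2, "truncated"))
})

test_that("solver enumeration equals brute force on random networks", {
  for (seed in 1:25) {
    net <- generate_network(generator_config(10 + seed %% 5, 12 + seed %% 5,
                                             p_negated = 0.35, p_late = 0.25,
                                             n_inputs = 2, seed = seed))
    for (phase in c("early", "late")) {
      sys <- compile_iff(net, phase)
      got <- enumerate_states(sys, cap = 100000)
      expect_false(attr(got, "truncated"))
      expect_identical(state_keys(got), state_keys(oracle_states(sys)))
    }
  }
})

test_that("predict propagates stimuli and defaults unnamed inputs to OFF", {
  chain <- net_from("B = A", "C = B")
  on <- predict(chain, c(A = 1))
  expect_identical(nrow(on), 1L)
  expect_identical(on$C, 1L)
  off <- predict(chain, NULL)
  expect_identical(unname(unlist(off[1, ])), c(0L, 0L, 0L))
  expect_error(predict(chain, c(B = 1)), "input")
})

test_that("with all inputs OFF a positive-antecedent network is all-OFF", {
  # p_late = 0 so every component is constrained in both phases; a component
  # regulated only in the other phase would be free, not forced OFF
  for (seed in 1:15) {
    net <- generate_network(generator_config(9, 11, p_negated = 0,
                                             p_late = 0, n_inputs = 2,
                                             seed = seed))
    for (phase in c("early", "late")) {
      st <- predict(net, NULL, phase = phase)
      expect_identical(nrow(st), 1L)
      expect_true(all(as.matrix(st) == 0L))
    }
  }
})

test_that("predict_summary reports forced readouts without enumeration", {
  chain <- net_from("B = A", "C = B")
  s <- predict_summary(chain, c(A = 1), readouts = c("B", "C"))
  expect_identical(s$state, c("ON", "ON"))
  free <- net_from("node A input", "node X input", "B = A")
  s2 <- predict_summary(free, c(A = 1), readouts = c("B", "X"))
  expect_identical(s2$state, c("ON", "OFF"))  # X is an unstimulated input
})

test_that("minimal interventions are exactly the oracle's relaxation sets", {
  loop <- loop_net()
  iv <- minimal_interventions(loop, "early", c(TCRB = 0), max_size = 2)
  expect_length(iv, 4L)
  expect_true(all(vapply(iv, `[[`, 0L, "size") == 1L))
  expect_setequal(unlist(lapply(iv, `[[`, "relaxed")),
                  vapply(loop$implications, implication_id, ""))

  # already feasible: empty result with a notice
  ok <- minimal_interventions(loop, "early", c(TCRB = 1))
  expect_length(ok, 0L)
  expect_match(attr(ok, "note"), "already feasible")

  chain <- net_from("B = A")
  iv2 <- minimal_interventions(chain, "early", c(A = 1, B = 0))
  expect_length(iv2, 1L)
  expect_identical(iv2[[1]]$relaxed, "B = A @permanent")

  # property: implementation == exhaustive oracle on seeded infeasible cases
  checked <- 0L
  seed <- 0L
  while (checked < 8L && seed < 120L) {
    seed <- seed + 1L
    net <- generate_network(generator_config(8, 10, p_negated = 0.4,
                                             p_late = 0.3, n_inputs = 2,
                                             seed = 1000L + seed))
    inputs <- input_components(net)
    target <- max(setdiff(component_names(net), inputs))
    fix <- fixation(stats::setNames(c(rep(0L, length(inputs)), 1L),
                                    c(inputs, target)))
    if (is_feasible(net, fix)$feasible) next
    checked <- checked + 1L
    got <- lapply(minimal_interventions(net, "early", fix, max_size = 2),
                  `[[`, "relaxed")
    want <- oracle_interventions(net, "early", fix, max_size = 2)
    expect_identical(sort(vapply(got, function(s) paste(sort(s), collapse = "|"), "")),
                     sort(vapply(want, function(s) paste(sort(s), collapse = "|"), "")))
    # every returned set restores feasibility, and is subset-minimal
    for (s in got) {
      keep <- Filter(function(i) !(implication_id(i) %in% s),
                     net$implications)
      sys <- compile_iff(net, "early", implications = keep)
      expect_true(is_feasible(sys, fix[names(fix) %in% sys$components])$feasible)
    }
  }
  expect_gte(checked, 3L)
})

test_that("infeasible cores are minimal and disjoint conflicts yield two cores", {
  chain <- net_from("B = A")
  cores <- infeasible_cores(chain, "early", c(A = 1, B = 0))
  expect_length(cores, 1L)
  expect_identical(cores[[1]]$clauses, "B")
  expect_identical(sort(names(cores[[1]]$fixations)), c("A", "B"))

  # two disjoint copies of the conflict give two disjoint cores
  double <- net_from("B = A", "D = C")
  cores2 <- infeasible_cores(double, "early", c(A = 1, B = 0, C = 1, D = 0))
  expect_length(cores2, 2L)
  expect_setequal(vapply(cores2, function(x) x$clauses, ""), c("B", "D"))

  # feasible input: no cores
  expect_length(infeasible_cores(chain, "early", c(A = 1, B = 1)), 0L)

  # each core is minimal: dropping any clause or fixation makes it satisfiable
  loop <- loop_net()
  core <- infeasible_cores(loop, "early", c(TCRB = 0))[[1]]
  expect_setequal(core$clauses, c("PAG", "CSK", "LCKP1", "FYN"))
  expect_identical(core$cycle[order(core$cycle)],
                   sort(c("PAG", "CSK", "LCKP1", "FYN")))
  expect_true(core$negative)
})

test_that("late-phase prediction can inherit forced early values", {
  net <- net_from("B = A", "C = B @early", "D = C @late")
  # without inheritance C is free late, so D follows C freely
  st <- predict(net, c(A = 1), phase = "late")
  expect_identical(nrow(st), 2L)
  sti <- predict(net, c(A = 1), phase = "late", inherit_early = TRUE)
  expect_identical(nrow(sti), 1L)
  expect_identical(sti$D, 1L)
})
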