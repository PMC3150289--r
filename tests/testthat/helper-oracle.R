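# Independent brute-force oracle: exhaustive truth-table search over all 2^n
# assignments, with its own clause evaluation. Used to cross-check the DPLL
# solver, the intervention search and the projection machinery on small
# networks.

oracle_assignments <- function(comps) {
  n <- length(comps)
  m <- if (n == 0L) matrix(logical(0), nrow = 1L, ncol = 0L) else
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n), KEEP.OUT.ATTRS = FALSE))
  colnames(m) <- comps
  m
}

oracle_clause_ok <- function(cl, m) {
  rhs <- rep(FALSE, nrow(m))
  for (d in cl$dnf) {
    if (length(d) == 0L) { rhs <- rep(TRUE, nrow(m)); next }
    v <- rep(TRUE, nrow(m))
    for (l in d) {
      neg <- startsWith(l, "!")
      nm <- sub("^!", "", l)
      v <- v & (if (neg) !m[, nm] else m[, nm])
    }
    rhs <- rhs | v
  }
  m[, cl$consequent] == rhs
}

oracle_keep <- function(system, m, fix = NULL) {
  ok <- rep(TRUE, nrow(m))
  for (cl in system$clauses) ok <- ok & oracle_clause_ok(cl, m)
  if (length(fix))
    for (nm in names(fix)) ok <- ok & (m[, nm] == (fix[[nm]] == 1L))
  ok
}

oracle_states <- function(system, fix = NULL) {
  m <- oracle_assignments(sort(system$components))
  m[oracle_keep(system, m, fix), , drop = FALSE]
}

state_keys <- function(states) {
  m <- as.matrix(states)
  mode(m) <- "integer"
  m <- m[, sort(colnames(m)), drop = FALSE]
  if (nrow(m) == 0L) return(character(0))
  sort(apply(m, 1L, paste, collapse = ""))
}

# Exhaustive subset-minimal intervention search (cardinality <= max_size),
# feasibility decided by truth table.
oracle_interventions <- function(network, phase, fix, max_size = 3L) {
  imps <- network$implications
  in_phase <- Filter(function(i) i$horizon %in% c("permanent", phase), imps)
  ids <- sort(vapply(in_phase, implication_id, ""))
  feasible_without <- function(drop) {
    sel <- Filter(function(i) !(implication_id(i) %in% drop), imps)
    sys <- compile_iff(network, phase, implications = sel)
    any(oracle_keep(sys, oracle_assignments(sort(sys$components)), fix))
  }
  found <- list()
  for (k in seq_len(max_size)) {
    if (length(ids) < k) break
    for (s in utils::combn(ids, k, simplify = FALSE)) {
      if (any(vapply(found, function(f) all(f %in% s), TRUE))) next
      if (feasible_without(s)) found[[length(found) + 1L]] <- s
    }
  }
  found
}

net_from <- function(...) read_net(text = c("model t", ...))

loop_net <- function() load_model("loop")
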