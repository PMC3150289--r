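# Compilation of implication formulas into per-horizon IFF systems.
#
# For a queried phase (early or late) all implications with horizon `permanent`
# or equal to the phase are selected. Statements with the same consequent are
# collected into A_1 OR ... OR A_n -> B and transformed into the IFF clause
# (A_1 OR ... OR A_n) <-> B: a regulated component is ON exactly when at least
# one of its in-phase activating conditions holds. Components without any
# in-phase implication are unconstrained ("free") in that phase; this includes
# all network inputs.

#' Compile a network into an IFF clause system
#'
#' @param network a valid `logical_network`.
#' @param phase `"early"` or `"late"`; permanent implications participate in
#'   both phases.
#' @param implications optional explicit implication subset to compile instead
#'   of the network's full list (used by sequential-stimulation prediction and
#'   by intervention search).
#' @param phase_filter if `FALSE`, the supplied implications are compiled
#'   as-is without the horizon selection (the caller has already chosen the
#'   horizon set per implication).
#' @return an object of class `iff_system` with elements `clauses` (named list;
#'   per regulated component a DNF stored as a list of literal vectors),
#'   `free` (components unconstrained in this phase), `components`, `phase`
#'   and `label`.
#' @export
#' @examples
#' loop <- read_net(text = c(
#'   "model loop",
#'   "node TCRB input",
#'   "CSK = PAG", "LCKP1 = !CSK", "FYN = LCKP1",
#'   "PAG = FYN & !TCRB @early"))
#' sys <- compile_iff(loop, "early")
#' names(sys$clauses)
#' sys$free
compile_iff <- function(network, phase = c("early", "late"),
                        implications = NULL, phase_filter = TRUE) {
  phase <- match.arg(phase)
  stopifnot_valid(network)
  imps <- if (is.null(implications)) network$implications else implications
  if (phase_filter) {
    keep <- vapply(imps, function(i) i$horizon %in% c("permanent", phase), TRUE)
    imps <- imps[keep]
  }

  comps <- component_names(network)
  clauses <- list()
  for (imp in imps) {
    cl <- clauses[[imp$consequent]]
    if (is.null(cl))
      cl <- list(consequent = imp$consequent, dnf = list(),
                 impl_ids = character(0), provenance = character(0),
                 horizon_set = phase)
    dj <- if (!is.na(imp$const)) {
      if (imp$const) character(0) else NULL  # constant TRUE / FALSE
    } else imp$antecedent
    if (!is.null(dj)) cl$dnf <- c(cl$dnf, list(dj))
    cl$impl_ids <- c(cl$impl_ids, implication_id(imp))
    cl$provenance <- sort(unique(c(cl$provenance, imp$provenance)))
    clauses[[imp$consequent]] <- cl
  }
  # canonicalize: unique disjuncts, sorted lexicographically by their string form
  clauses <- lapply(clauses, function(cl) {
    key <- vapply(cl$dnf, paste, "", collapse = " & ")
    keep <- !duplicated(key)
    cl$dnf <- cl$dnf[keep][order(key[keep])]
    cl$impl_ids <- sort(unique(cl$impl_ids))
    cl
  })
  if (length(clauses)) clauses <- clauses[order(names(clauses))]

  structure(list(label = network$label, phase = phase,
                 components = comps,
                 clauses = clauses,
                 free = setdiff(comps, names(clauses))),
            class = "iff_system")
}

#' @export
print.iff_system <- function(x, ...) {
  cat(sprintf("IFF system '%s' (%s phase): %d clauses, %d free components\n",
              x$label, x$phase, length(x$clauses), length(x$free)))
  for (cl in x$clauses) {
    rhs <- if (length(cl$dnf) == 0L) {
      "0"
    } else {
      paste(vapply(cl$dnf, function(d)
        if (length(d) == 0L) "1" else paste(d, collapse = " & "), ""),
        collapse = " | ")
    }
    cat(sprintf("  %s <-> %s\n", rhs, cl$consequent))
  }
  if (length(x$free)) cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

# Evaluate the DNF of a clause on a logical matrix of assignments
# (rows = assignments, columns named by component). Returns a logical vector.
eval_dnf <- function(dnf, m) {
  if (length(dnf) == 0L) return(rep(FALSE, nrow(m)))
  val <- rep(FALSE, nrow(m))
  for (d in dnf) {
    if (length(d) == 0L) return(rep(TRUE, nrow(m)))  # constant-true disjunct
    dv <- rep(TRUE, nrow(m))
    for (l in d) {
      v <- m[, lit_component(l)]
      dv <- dv & (if (lit_negated(l)) !v else v)
    }
    val <- val | dv
  }
  val
}

# Which rows of assignment matrix m satisfy every clause of the system
# (and an optional fixation)? The workhorse of the brute-force reference path
# used by project_network() and the size guard checks.
satisfies_system <- function(system, m, fixation = NULL) {
  ok <- rep(TRUE, nrow(m))
  for (cl in system$clauses)
    ok <- ok & (m[, cl$consequent] == eval_dnf(cl$dnf, m))
  if (!is.null(fixation) && length(fixation))
    for (nm in names(fixation))
      ok <- ok & (m[, nm] == (fixation[[nm]] == 1L))
  ok
}

#' Exhaustively enumerate satisfying states of a small IFF system
#'
#' Reference implementation: evaluates every clause on all 2^n total
#' assignments. Independent of the DPLL search path, so it serves as the
#' ground truth when validating solver results on small networks.
#'
#' @param system an `iff_system`.
#' @param fixation optional named 0/1 vector restricting the states.
#' @return a `state_table` of all satisfying assignments.
#' @export
brute_force_states <- function(system, fixation = NULL) {
  comps <- system$components
  n <- length(comps)
  if (n > 20L)
    stop("exhaustive enumeration is limited to 20 components (got ", n, ")")
  m <- if (n == 0L) {
    matrix(logical(0), nrow = 1L, ncol = 0L)
  } else {
    as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n),
                          KEEP.OUT.ATTRS = FALSE))
  }
  colnames(m) <- comps
  m <- m[satisfies_system(system, m, fixation), , drop = FALSE]
  state_table(m, comps)
}

# Order states lexicographically over sorted component columns (OFF < ON) and
# return the canonical integer data.frame used throughout the package.
state_table <- function(m, comps) {
  m <- matrix(as.integer(m), nrow = nrow(m), ncol = ncol(m),
              dimnames = list(NULL, colnames(m)))
  m <- m[, sort(comps), drop = FALSE]
  if (nrow(m) > 1L) {
    key <- do.call(order, as.data.frame(m))
    m <- m[key, , drop = FALSE]
  }
  df <- as.data.frame(m)
  rownames(df) <- NULL
  class(df) <- c("state_table", "data.frame")
  df
}
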