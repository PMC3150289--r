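# SAT machinery for IFF systems.
#
# Each IFF clause B <-> (D_1 OR ... OR D_k) is translated to CNF with one
# auxiliary variable per disjunct (Tseitin style): a_j <-> D_j, plus
# (B -> a_1 v ... v a_k) and (a_j -> B). Fixations become unit clauses.
# Auxiliary variables are functionally determined by the component variables,
# so enumerating CNF models projected to the components enumerates network
# states without duplicates. The solver is a plain DPLL with unit propagation;
# branching follows the sorted component order with OFF tried before ON, which
# makes enumeration deterministic and lexicographically ordered.

# ---- fixation patterns -------------------------------------------------------

#' Build a fixation pattern
#'
#' A fixation pattern is a partial ON/OFF assignment, typically encoding the
#' stimuli and readouts of an experiment.
#'
#' @param x either a named vector of 0/1 values (`c(TCRB = 1)`), a character
#'   vector of `"NAME=0|1"` strings (`"TCRB=1,PAG=0"` also works), or `NULL`
#'   for the empty pattern.
#' @return a named integer vector of 0/1 values, class `sg_fixation`.
#' @export
#' @examples
#' fixation(c(TCRB = 1))
#' fixation("TCRB=1,PAG=0")
fixation <- function(x = NULL) {
  if (is.null(x) || length(x) == 0L)
    return(structure(integer(0), class = "sg_fixation"))
  if (is.character(x) && is.null(names(x))) {
    parts <- trimws(unlist(strsplit(x, ",", fixed = TRUE)))
    parts <- parts[parts != ""]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("cannot parse fixation: ", paste(parts[bad], collapse = ", "))
    vals <- vapply(kv, function(p) trimws(p[2]), "")
    if (!all(vals %in% c("0", "1")))
      stop("fixation values must be 0 or 1")
    out <- as.integer(vals)
    names(out) <- norm_name(vapply(kv, `[[`, "", 1))
  } else {
    out <- as.integer(x)
    if (is.null(names(x)) || any(names(x) == ""))
      stop("fixation values must be named by component")
    if (!all(out %in% c(0L, 1L))) stop("fixation values must be 0 or 1")
    names(out) <- norm_name(names(x))
  }
  if (anyDuplicated(names(out)))
    stop("component fixed twice: ",
         paste(unique(names(out)[duplicated(names(out))]), collapse = ", "))
  structure(out[order(names(out))], class = "sg_fixation")
}

check_fixation <- function(system, fix) {
  unknown <- setdiff(names(fix), system$components)
  if (length(unknown))
    stop("fixation references unknown component(s): ",
         paste(unknown, collapse = ", "))
  invisible(fix)
}

# ---- CNF encoding ------------------------------------------------------------

# Returns list(nvars, n_primary, vars (component -> index), clauses,
# groups): `groups` maps soft-item labels ("clause:<comp>" / "fix:<comp>") to
# CNF clause indices, for MUS extraction.
encode_cnf <- function(system, fix = fixation()) {
  comps <- sort(system$components)
  vidx <- seq_along(comps)
  names(vidx) <- comps
  nv <- length(comps)
  clauses <- list()
  groups <- list()

  lit2int <- function(l) {
    v <- vidx[[lit_component(l)]]
    if (lit_negated(l)) -v else v
  }

  for (cl in system$clauses) {
    b <- vidx[[cl$consequent]]
    start <- length(clauses)
    if (length(cl$dnf) == 0L) {
      clauses[[length(clauses) + 1L]] <- -b
    } else if (any(lengths(cl$dnf) == 0L)) {
      clauses[[length(clauses) + 1L]] <- b  # constant-true activator
    } else {
      aux <- integer(length(cl$dnf))
      for (j in seq_along(cl$dnf)) {
        nv <- nv + 1L
        aux[j] <- nv
        ints <- vapply(cl$dnf[[j]], lit2int, 0L)
        for (li in ints)
          clauses[[length(clauses) + 1L]] <- c(-aux[j], li)
        clauses[[length(clauses) + 1L]] <- c(aux[j], -ints)
        clauses[[length(clauses) + 1L]] <- c(-aux[j], b)
      }
      clauses[[length(clauses) + 1L]] <- c(-b, aux)
    }
    groups[[paste0("clause:", cl$consequent)]] <-
      seq(start + 1L, length(clauses))
  }
  for (nm in names(fix)) {
    v <- vidx[[nm]]
    clauses[[length(clauses) + 1L]] <- if (fix[[nm]] == 1L) v else -v
    groups[[paste0("fix:", nm)]] <- length(clauses)
  }
  list(nvars = nv, n_primary = length(comps), vars = vidx,
       comps = comps, clauses = clauses, groups = groups)
}

# ---- DPLL --------------------------------------------------------------------

# Unit propagation. val: integer vector, NA = unassigned, 0/1 assigned.
# Returns list(ok, val).
propagate <- function(clauses, val) {
  repeat {
    changed <- FALSE
    for (cl in clauses) {
      vs <- abs(cl)
      sgn <- cl > 0L
      a <- val[vs]
      sat <- !is.na(a) & (a == 1L) == sgn
      if (any(sat)) next
      un <- is.na(a)
      k <- sum(un)
      if (k == 0L) return(list(ok = FALSE, val = val))
      if (k == 1L) {
        i <- which(un)
        val[vs[i]] <- if (sgn[i]) 1L else 0L
        changed <- TRUE
      }
    }
    if (!changed) return(list(ok = TRUE, val = val))
  }
}

# DPLL search. Branches over primary variables 1..n_primary in order, OFF
# first. Collects up to `cap` models (projected to primary vars) in `acc`.
# `assume`: integer vector of forced literals.
dpll_enumerate <- function(enc, cap = 1L, assume = integer(0)) {
  acc <- new.env(parent = emptyenv())
  acc$models <- vector("list", 0L)
  acc$truncated <- FALSE

  val0 <- rep(NA_integer_, enc$nvars)
  for (l in assume) {
    v <- abs(l); want <- as.integer(l > 0L)
    if (!is.na(val0[v]) && val0[v] != want) return(list(models = list(), truncated = FALSE))
    val0[v] <- want
  }
  p <- propagate(enc$clauses, val0)
  if (!p$ok) return(list(models = list(), truncated = FALSE))

  recurse <- function(val) {
    if (length(acc$models) >= cap) { acc$truncated <- TRUE; return(invisible()) }
    i <- which(is.na(val[seq_len(enc$n_primary)]))
    if (length(i) == 0L) {
      # complete over components; in a full encoding the auxiliaries are now
      # forced by propagation, but clause subsets (MUS extraction) may leave
      # orphaned auxiliaries - branch over them as well (cap = 1 there, so
      # duplicate projections cannot arise)
      i <- which(is.na(val))
      if (length(i) == 0L) {
        acc$models[[length(acc$models) + 1L]] <- val[seq_len(enc$n_primary)]
        return(invisible())
      }
    }
    v <- i[[1L]]
    for (b in c(0L, 1L)) {
      if (length(acc$models) >= cap) return(invisible())
      val2 <- val
      val2[v] <- b
      p <- propagate(enc$clauses, val2)
      if (p$ok) recurse(p$val)
    }
    invisible()
  }
  recurse(p$val)
  list(models = acc$models, truncated = acc$truncated && length(acc$models) >= cap)
}

sat_check <- function(enc) {
  length(dpll_enumerate(enc, cap = 1L)$models) > 0L
}

# ---- feasibility -------------------------------------------------------------

#' Check feasibility of a fixation pattern
#'
#' Solves the satisfiability problem for the conjunction of all IFF clauses of
#' the system together with the fixation. A feasible answer carries one
#' witness state; an infeasible one carries a minimal infeasible core (a
#' subset-minimal set of IFF clauses and fixations that is jointly
#' unsatisfiable), which typically pinpoints either a modeling error or a
#' negative feedback loop acting on a later time scale.
#'
#' @param system an `iff_system` from [compile_iff()], or a `logical_network`
#'   (compiled at `phase`).
#' @param fix a [fixation()] (or anything `fixation()` accepts).
#' @param phase phase used when `system` is a network.
#' @return a list of class `sg_feasibility` with elements `feasible`, and
#'   either `state` (named 0/1 vector) or `core` (an `infeasible_core`).
#' @export
#' @examples
#' loop <- read_net(text = c("model loop", "node TCRB input",
#'   "CSK = PAG", "LCKP1 = !CSK", "FYN = LCKP1",
#'   "PAG = FYN & !TCRB @early"))
#' is_feasible(loop, c(TCRB = 1))$state
#' is_feasible(loop, c(TCRB = 0))$feasible
is_feasible <- function(system, fix = NULL, phase = "early") {
  if (inherits(system, "logical_network")) system <- compile_iff(system, phase)
  fix <- check_fixation(system, fixation(fix))
  enc <- encode_cnf(system, fix)
  res <- dpll_enumerate(enc, cap = 1L)
  if (length(res$models)) {
    st <- res$models[[1L]]
    names(st) <- enc$comps
    return(structure(list(feasible = TRUE, state = st), class = "sg_feasibility"))
  }
  core <- extract_mus(system, fix)
  structure(list(feasible = FALSE, core = core), class = "sg_feasibility")
}

#' @export
print.sg_feasibility <- function(x, ...) {
  if (x$feasible) {
    cat("feasible\n")
    on <- names(x$state)[x$state == 1L]
    cat("  ON :", if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  } else {
    cat("infeasible\n")
    print(x$core)
  }
  invisible(x)
}

#' Enumerate all feasible states
#'
#' All total assignments satisfying every IFF clause and extending the
#' fixation, in lexicographic component order (OFF before ON), up to `cap`.
#'
#' @inheritParams is_feasible
#' @param cap maximum number of states to return (`attr(x, "truncated")` is
#'   set if the cap was hit).
#' @return a `state_table` data.frame, one row per state, one 0/1 column per
#'   component.
#' @export
enumerate_states <- function(system, fix = NULL, cap = 1024L, phase = "early") {
  if (inherits(system, "logical_network")) system <- compile_iff(system, phase)
  stopifnot(cap >= 1L)
  fix <- check_fixation(system, fixation(fix))
  enc <- encode_cnf(system, fix)
  # ask for one extra model so truncation at exactly `cap` is detectable
  res <- dpll_enumerate(enc, cap = cap + 1L)
  truncated <- length(res$models) > cap
  models <- res$models[seq_len(min(cap, length(res$models)))]
  m <- if (length(models)) {
    do.call(rbind, models)
  } else {
    matrix(integer(0), ncol = enc$n_primary)
  }
  colnames(m) <- enc$comps
  out <- state_table(m == 1L, enc$comps)
  attr(out, "truncated") <- truncated
  out
}

# ---- minimal unsatisfiable cores --------------------------------------------

# Deletion-based MUS extraction over soft items (IFF clauses + fixations).
# `keep_items`: optional starting item subset (labels). Deterministic item
# order => reproducible cores.
extract_mus <- function(system, fix, keep_items = NULL) {
  enc <- encode_cnf(system, fix)
  items <- names(enc$groups)
  if (!is.null(keep_items)) items <- intersect(items, keep_items)

  sat_subset <- function(its) {
    idx <- unlist(enc$groups[its], use.names = FALSE)
    sub <- list(nvars = enc$nvars, n_primary = enc$n_primary,
                comps = enc$comps, clauses = enc$clauses[idx])
    sat_check(sub)
  }
  if (sat_subset(items))
    stop("extract_mus called on a satisfiable item set")
  current <- items
  for (it in items) {
    trial <- setdiff(current, it)
    if (!sat_subset(trial)) current <- trial
  }
  cls <- sub("^clause:", "", grep("^clause:", current, value = TRUE))
  fx <- sub("^fix:", "", grep("^fix:", current, value = TRUE))
  core_fix <- fixation(unclass(fix)[names(fix) %in% fx])
  new_infeasible_core(system, cls, core_fix)
}

new_infeasible_core <- function(system, clause_comps, core_fix) {
  cyc <- core_cycle(system, clause_comps)
  structure(list(clauses = sort(clause_comps),
                 fixations = core_fix,
                 cycle = cyc$cycle, negative = cyc$negative),
            class = "infeasible_core")
}

#' @export
print.infeasible_core <- function(x, ...) {
  cat(sprintf("infeasible core: %d clause(s) [%s]",
              length(x$clauses), paste(x$clauses, collapse = ", ")))
  if (length(x$fixations))
    cat(sprintf(" + fixation {%s}",
                paste(sprintf("%s=%d", names(x$fixations), x$fixations),
                      collapse = ", ")))
  cat("\n")
  if (!is.null(x$cycle))
    cat(sprintf("  cycle: %s (%s feedback)%s\n",
                paste(c(x$cycle, x$cycle[1]), collapse = " -> "),
                if (isTRUE(x$negative)) "negative" else "positive",
                if (isTRUE(x$negative))
                  " - candidate for reclassification as late implication" else ""))
  invisible(x)
}

# Detect a directed cycle among the consequents of the core clauses, using
# only interactions contributed by those clauses. Returns the cycle vertex
# sequence (rotation-canonical: starts at the alphabetically first vertex)
# and whether it carries an odd number of inhibitions (negative feedback).
core_cycle <- function(system, clause_comps) {
  edges <- character(0)
  signs <- integer(0)
  for (nm in clause_comps) {
    cl <- system$clauses[[nm]]
    for (d in cl$dnf) for (l in d) {
      src <- lit_component(l)
      if (src %in% clause_comps) {
        edges <- c(edges, src, nm)
        signs <- c(signs, if (lit_negated(l)) -1L else 1L)
      }
    }
  }
  if (length(edges) == 0L) return(list(cycle = NULL, negative = NA))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(sort(clause_comps))
  g <- igraph::add_edges(g, edges)
  igraph::E(g)$sign <- signs
  scc <- igraph::components(g, mode = "strong")
  big <- which(scc$csize > 1L)
  if (length(big) == 0L) return(list(cycle = NULL, negative = NA))
  members <- sort(names(scc$membership)[scc$membership == big[[1L]]])
  sg <- igraph::induced_subgraph(g, members)
  start <- members[[1L]]
  # shortest closed walk through `start`
  outs <- igraph::neighbors(sg, start, mode = "out")$name
  best <- NULL
  for (u in sort(outs)) {
    if (u == start) { best <- start; break }
    sp <- suppressWarnings(igraph::shortest_paths(sg, from = u, to = start,
                                                  mode = "out"))$vpath[[1L]]
    if (length(sp) == 0L) next
    cand <- c(start, sp$name[-length(sp)])
    if (is.null(best) || length(cand) < length(best)) best <- cand
  }
  if (is.null(best)) return(list(cycle = NULL, negative = NA))
  cyc <- best
  # sign of the cycle: product over consecutive edges (first matching edge)
  neg <- 0L
  for (i in seq_along(cyc)) {
    from <- cyc[[i]]
    to <- cyc[[if (i == length(cyc)) 1L else i + 1L]]
    eid <- igraph::get_edge_ids(sg, c(from, to))
    if (eid == 0L) next
    if (igraph::E(sg)$sign[[eid]] < 0L) neg <- neg + 1L
  }
  list(cycle = cyc, negative = (neg %% 2L) == 1L)
}

#' All minimal infeasible cores of a fixation pattern
#'
#' Iterates deletion-based extraction of minimal unsatisfiable subsystems:
#' after a core is found, its items are removed from the candidate pool and
#' extraction repeats while the remainder is still infeasible (capped). Every
#' returned core is subset-minimal; jointly they cover one cause per
#' independent conflict. Cores whose clauses form a directed cycle in the
#' interaction graph are annotated with the cycle and its sign - a negative
#' feedback loop detected this way is the canonical candidate for
#' reclassifying its implications as late.
#'
#' @param network a `logical_network`.
#' @param phase `"early"` or `"late"`.
#' @param fix a [fixation()].
#' @param max_cores cap on the number of cores extracted.
#' @return list of `infeasible_core` objects (empty if feasible).
#' @export
infeasible_cores <- function(network, phase = "early", fix = NULL,
                             max_cores = 20L) {
  system <- compile_iff(network, phase)
  fix <- check_fixation(system, fixation(fix))
  enc <- encode_cnf(system, fix)
  if (sat_check(enc)) return(list())
  pool <- names(enc$groups)
  cores <- list()
  repeat {
    if (length(cores) >= max_cores) break
    idx <- unlist(enc$groups[pool], use.names = FALSE)
    sub <- list(nvars = enc$nvars, n_primary = enc$n_primary,
                comps = enc$comps, clauses = enc$clauses[idx])
    if (sat_check(sub)) break
    core <- extract_mus(system, fix, keep_items = pool)
    cores[[length(cores) + 1L]] <- core
    used <- c(paste0("clause:", core$clauses),
              paste0("fix:", names(core$fixations)))
    pool <- setdiff(pool, used)
  }
  cores
}

# ---- minimal interventions ---------------------------------------------------

#' Minimal intervention sets restoring feasibility
#'
#' Breadth-first search over sets of implication formulas whose removal (with
#' recompilation of the IFF system; a consequent losing all of its in-phase
#' activators becomes free) makes the fixation pattern feasible. Only
#' subset-minimal sets are returned, sorted by cardinality and then
#' lexicographically; search is exhaustive up to `max_size`.
#'
#' @param network a `logical_network`.
#' @param phase `"early"` or `"late"`.
#' @param fix a [fixation()] that is infeasible for the compiled system.
#' @param max_size largest cardinality searched.
#' @param cap maximum number of intervention sets returned.
#' @return list of `intervention_set` objects (`relaxed`: implication ids;
#'   `size`). If the input is already feasible an empty list is returned with
#'   attribute `note`.
#' @export
#' @examples
#' loop <- read_net(text = c("model loop", "node TCRB input",
#'   "CSK = PAG", "LCKP1 = !CSK", "FYN = LCKP1",
#'   "PAG = FYN & !TCRB @early"))
#' length(minimal_interventions(loop, "early", c(TCRB = 0)))
minimal_interventions <- function(network, phase = "early", fix = NULL,
                                  max_size = 3L, cap = 100L) {
  stopifnot(max_size >= 1L)
  system <- compile_iff(network, phase)
  fix <- check_fixation(system, fixation(fix))
  if (is_feasible_quick(network, phase, fix, integer(0))) {
    out <- list()
    attr(out, "note") <- "fixation already feasible; no intervention required"
    return(out)
  }
  imps <- network$implications
  in_phase <- which(vapply(imps, function(i)
    i$horizon %in% c("permanent", phase), TRUE))
  ids <- vapply(imps[in_phase], implication_id, "")
  ord <- order(ids)
  in_phase <- in_phase[ord]
  ids <- ids[ord]

  found <- list()
  for (k in seq_len(max_size)) {
    if (length(found) >= cap) break
    if (length(in_phase) < k) break
    sets <- utils::combn(seq_along(in_phase), k, simplify = FALSE)
    for (s in sets) {
      if (length(found) >= cap) break
      if (any(vapply(found, function(f) all(f$idx %in% s), TRUE))) next
      if (is_feasible_quick(network, phase, fix, in_phase[s])) {
        found[[length(found) + 1L]] <-
          list(idx = s,
               set = structure(list(relaxed = ids[s], size = k),
                               class = "intervention_set"))
      }
    }
  }
  out <- lapply(found, `[[`, "set")
  attr(out, "truncated") <- length(found) >= cap
  out
}

is_feasible_quick <- function(network, phase, fix, drop_idx) {
  imps <- network$implications
  if (length(drop_idx)) imps <- imps[-drop_idx]
  system <- compile_iff(network, phase, implications = imps)
  fix <- fix[names(fix) %in% system$components]
  enc <- encode_cnf(system, fix)
  sat_check(enc)
}

#' @export
print.intervention_set <- function(x, ...) {
  cat(sprintf("relax %d implication(s): %s\n", x$size,
              paste(x$relaxed, collapse = "; ")))
  invisible(x)
}
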