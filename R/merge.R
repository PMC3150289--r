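# Semi-automated merging of two parent networks into a child network.
#
# Prerequisite: standardization - components with identical names refer to
# identical molecules with a consistent interpretation of the ON state. The
# automatic part takes unions of components and clauses with provenance
# labels; wherever the two parents regulate a shared component differently, a
# conflict is raised and classified so that an expert decision (recorded in a
# decisions file) can resolve it. Without a decision the conservative fallback
# is the union of both parents' activating routes, which degenerates to an
# annotated disjoint union when the parents do not overlap.

# ---- name standardization ----------------------------------------------------

#' Rename components according to a standardization map
#'
#' @param network a `logical_network`.
#' @param map named character vector `c(OLD = "NEW", ...)`; must be injective
#'   and must not collide with unmapped names.
#' @return the renamed network (provenance and clause structure unchanged).
#' @export
#' @examples
#' net <- read_net(text = c("model il2r", "STAT5 = LCK"))
#' standardize(net, c(LCK = "LCKP1"))
standardize <- function(network, map) {
  if (length(map) == 0L) return(network)
  map <- stats::setNames(norm_name(map), norm_name(names(map)))
  if (anyDuplicated(map))
    stop("standardization map is not injective: ",
         paste(unique(map[duplicated(map)]), collapse = ", "))
  old <- component_names(network)
  missing_old <- setdiff(names(map), old)
  if (length(missing_old))
    stop("map renames unknown component(s): ",
         paste(missing_old, collapse = ", "))
  new_names <- ifelse(old %in% names(map), map[old], old)
  if (anyDuplicated(new_names))
    stop("standardization would collide names: ",
         paste(unique(new_names[duplicated(new_names)]), collapse = ", "))
  rename <- function(x) ifelse(x %in% names(map), map[x], x)
  comps <- lapply(network$components, function(cmp) {
    cmp$name <- unname(rename(cmp$name))
    cmp
  })
  imps <- lapply(network$implications, function(imp) {
    imp$consequent <- unname(rename(imp$consequent))
    imp$antecedent <- unname(lit(rename(lit_component(imp$antecedent)),
                                lit_negated(imp$antecedent)))
    imp
  })
  logical_network(comps, imps, label = network$label)
}

#' Read a name-standardization map from YAML
#'
#' The file maps old names to standardized names, e.g. `LCK: LCKP1`.
#'
#' @param path YAML file.
#' @return named character vector usable with [standardize()].
#' @export
read_name_map <- function(path) {
  y <- yaml::read_yaml(path)
  if (length(y) == 0L) return(character(0))
  stats::setNames(norm_name(unlist(y)), norm_name(names(y)))
}

# ---- isoform hierarchy -------------------------------------------------------

#' Read an isoform hierarchy from YAML
#'
#' A partial order mapping specific isoforms to their general protein class,
#' e.g. `PKCTHETA: NPKC` (PKC-theta is one of the novel PKCs). Used to detect
#' conflicts in which two parents describe the same regulation at different
#' isoform resolution.
#'
#' @param path YAML file mapping isoform name to class name.
#' @return data.frame with columns `isoform` and `class`.
#' @export
read_isoforms <- function(path) {
  y <- yaml::read_yaml(path)
  h <- isoform_hierarchy(stats::setNames(norm_name(unlist(y)),
                                         norm_name(names(y))))
  h
}

#' Build an isoform hierarchy
#'
#' @param map named character vector `c(ISOFORM = "CLASS", ...)`.
#' @return data.frame with columns `isoform` and `class`; acyclicity is
#'   enforced.
#' @export
isoform_hierarchy <- function(map = character(0)) {
  df <- data.frame(isoform = norm_name(names(map)),
                   class = norm_name(unname(map)))
  if (nrow(df)) {
    g <- igraph::graph_from_data_frame(df, directed = TRUE)
    if (!igraph::is_dag(g))
      stop("isoform hierarchy contains a cycle")
  }
  df
}

# TRUE if a and b are related through the hierarchy (either direction,
# transitively).
isoform_related <- function(a, b, hierarchy) {
  if (nrow(hierarchy) == 0L || a == b) return(FALSE)
  up <- function(x) {
    seen <- character(0)
    frontier <- x
    while (length(frontier)) {
      nxt <- hierarchy$class[hierarchy$isoform %in% frontier]
      nxt <- setdiff(nxt, seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    seen
  }
  b %in% up(a) || a %in% up(b)
}

# ---- conflict classification -------------------------------------------------

#' Classify clause conflicts between two standardized parents
#'
#' For every component regulated by both parents with non-identical clause
#' sets, one or more conflicts are raised:
#' \describe{
#'   \item{A (overlapping left-hand sides)}{the parents' antecedent component
#'     sets overlap but the clauses differ - is the extra condition universal
#'     or receptor-specific?}
#'   \item{B (disjoint left-hand sides)}{the antecedent component sets are
#'     disjoint - receptor-specific mediators, or does each receptor also use
#'     the other's route?}
#'   \item{C (refinement)}{disjoint, but a direct antecedent in one parent
#'     reaches the consequent through a multi-step pathway of the other
#'     parent - one description may simply omit intermediate steps.}
#'   \item{D (isoform)}{the clauses differ in components related through the
#'     isoform hierarchy (e.g. a specific PKC isoform versus the novel-PKC
#'     class).}
#' }
#'
#' @param parentA,parentB standardized `logical_network`s.
#' @param hierarchy an [isoform_hierarchy()] data.frame.
#' @param path_cap maximum refinement-path length for kind C.
#' @return list of `sg_conflict` objects (fields `kind`, `consequent`,
#'   `clauses_a`, `clauses_b`, `note`).
#' @export
classify_conflicts <- function(parentA, parentB,
                               hierarchy = isoform_hierarchy(),
                               path_cap = 10L) {
  conflicts <- list()
  shared <- intersect(component_names(parentA), component_names(parentB))
  ga <- interaction_graph(parentA, positive_only = TRUE)
  gb <- interaction_graph(parentB, positive_only = TRUE)

  imps_for <- function(net, comp)
    Filter(function(i) i$consequent == comp, net$implications)
  clause_key <- function(imps)
    sort(vapply(imps, function(i)
      paste0(paste(i$antecedent, collapse = " & "), "@", i$horizon), ""))

  add <- function(kind, comp, ia, ib, note) {
    conflicts[[length(conflicts) + 1L]] <<- structure(
      list(kind = kind, consequent = comp,
           clauses_a = vapply(ia, implication_id, ""),
           clauses_b = vapply(ib, implication_id, ""),
           note = note),
      class = "sg_conflict")
  }

  for (comp in sort(shared)) {
    ia <- imps_for(parentA, comp)
    ib <- imps_for(parentB, comp)
    if (length(ia) == 0L || length(ib) == 0L) next  # regulated by one parent only
    if (identical(clause_key(ia), clause_key(ib))) next

    comps_a <- unique(lit_component(unlist(lapply(ia, `[[`, "antecedent"))))
    comps_b <- unique(lit_component(unlist(lapply(ib, `[[`, "antecedent"))))
    overlap <- intersect(comps_a, comps_b)

    if (length(overlap)) {
      add("A_overlapping_lhs", comp, ia, ib, sprintf(
        "Both parents regulate %s through %s but with non-identical clauses. Is the additional condition universal or receptor-specific?",
        comp, paste(overlap, collapse = "/")))
    } else {
      add("B_disjoint_lhs", comp, ia, ib, sprintf(
        "The parents activate %s through disjoint mediators (%s: %s | %s: %s). Are these receptor-specific, or does each receptor also engage the other's route?",
        comp, parentA$label, paste(comps_a, collapse = ","),
        parentB$label, paste(comps_b, collapse = ",")))
      refine <- function(from_comps, graph, glabel, other) {
        hits <- character(0)
        vn <- igraph::V(graph)$name
        for (a in from_comps) {
          if (!(a %in% vn) || !(comp %in% vn)) next
          d <- igraph::distances(graph, v = a, to = comp, mode = "out")[1, 1]
          if (is.finite(d) && d >= 2 && d <= path_cap) hits <- c(hits, a)
        }
        if (length(hits))
          add("C_refinement", comp, ia, ib, sprintf(
            "%s of the %s clause reaches %s through a multi-step pathway of %s; the direct statement may omit intermediate steps.",
            paste(hits, collapse = "/"), other, comp, glabel))
      }
      refine(comps_b, ga, parentA$label, parentB$label)
      refine(comps_a, gb, parentB$label, parentA$label)
    }
    if (nrow(hierarchy)) {
      iso <- character(0)
      for (a in comps_a) for (b in comps_b)
        if (isoform_related(a, b, hierarchy))
          iso <- c(iso, paste0(a, "~", b))
      if (length(iso))
        add("D_isoform", comp, ia, ib, sprintf(
          "The clauses for %s depend on isoform-related components (%s): activation of the specific isoform may affect every interaction of the general class and vice versa.",
          comp, paste(unique(iso), collapse = ", ")))
    }
  }
  conflicts
}

#' @export
print.sg_conflict <- function(x, ...) {
  cat(sprintf("[%s] %s\n  %s\n", x$kind, x$consequent, x$note))
  invisible(x)
}

# ---- merging -----------------------------------------------------------------

#' Record an expert decision for a merge conflict
#'
#' @param consequent the conflicted component.
#' @param resolution `"union"` (keep both parents' activating routes),
#'   `"keep_A"`, `"keep_B"`, or `"replace_with"` (explicit implications in
#'   `replacement`).
#' @param justification free text recorded in the merge report.
#' @param replacement list of [implication()]s when
#'   `resolution = "replace_with"`.
#' @return a list of class `sg_decision`.
#' @export
merge_decision <- function(consequent,
                           resolution = c("union", "keep_A", "keep_B",
                                          "replace_with"),
                           justification = "", replacement = NULL) {
  resolution <- match.arg(resolution)
  if (resolution == "replace_with" && is.null(replacement))
    stop("replace_with requires a replacement implication list")
  structure(list(consequent = norm_name(consequent), resolution = resolution,
                 justification = justification, replacement = replacement),
            class = "sg_decision")
}

#' Read merge decisions from YAML
#'
#' Format: a list of entries with fields `consequent`, `resolution`,
#' optionally `justification` and (for `replace_with`) `replacement` - a list
#' of implication lines in the model text format, e.g.
#' `"ERK = MEK & NPKC @permanent"`.
#'
#' @param path YAML file.
#' @return list of [merge_decision()]s.
#' @export
read_decisions <- function(path) {
  y <- yaml::read_yaml(path)
  lapply(y, function(e) {
    repl <- NULL
    if (!is.null(e$replacement))
      repl <- unlist(lapply(seq_along(e$replacement), function(i)
        parse_implication_line(e$replacement[[i]], i)), recursive = FALSE)
    merge_decision(e$consequent, e$resolution,
                   justification = if (is.null(e$justification)) "" else e$justification,
                   replacement = repl)
  })
}

#' Merge two parent networks into a child
#'
#' Components are unioned with provenance labels; implications are unioned
#' with identical statements deduplicated (provenance union). Shared
#' components with differing clause sets raise classified conflicts; each is
#' resolved by the matching expert decision, or by the conservative default -
#' the union of both parents' activating routes - when no decision is given.
#' The child is validated before it is returned.
#'
#' @param parentA,parentB standardized, individually valid `logical_network`s.
#' @param hierarchy an [isoform_hierarchy()].
#' @param decisions list of [merge_decision()]s.
#' @param label child model label.
#' @return list with elements `network` (the child) and `report` (an
#'   `sg_merge_report`: conflicts, applied decisions, common components,
#'   common negative regulators, potential-quality clauses carried through).
#' @export
#' @examples
#' a <- read_net(text = c("model A", "X = S1"))
#' b <- read_net(text = c("model B", "X = S2"))
#' m <- merge_networks(a, b)
#' component_names(m$network)
merge_networks <- function(parentA, parentB,
                           hierarchy = isoform_hierarchy(),
                           decisions = list(),
                           label = paste0(parentA$label, "+", parentB$label)) {
  stopifnot_valid(parentA)
  stopifnot_valid(parentB)

  conflicts <- classify_conflicts(parentA, parentB, hierarchy)
  conflicted <- unique(vapply(conflicts, `[[`, "", "consequent"))
  dec_for <- stats::setNames(decisions,
                             vapply(decisions, `[[`, "", "consequent"))
  unknown_dec <- setdiff(names(dec_for), conflicted)
  if (length(unknown_dec))
    stop("decision(s) reference no known conflict: ",
         paste(unknown_dec, collapse = ", "))

  # components: union with provenance labels
  tag <- function(net) lapply(net$components, function(cmp) {
    if (length(cmp$provenance) == 0L) cmp$provenance <- net$label
    cmp
  })
  comps <- tag(parentA)
  for (cmp in tag(parentB)) {
    if (is.null(comps[[cmp$name]])) {
      comps[[cmp$name]] <- cmp
    } else {
      comps[[cmp$name]]$provenance <-
        sort(unique(c(comps[[cmp$name]]$provenance, cmp$provenance)))
      if (cmp$quality == "validated") comps[[cmp$name]]$quality <- "validated"
      if (!nzchar(comps[[cmp$name]]$interpretation))
        comps[[cmp$name]]$interpretation <- cmp$interpretation
    }
  }

  tag_imps <- function(net) lapply(net$implications, function(imp) {
    if (length(imp$provenance) == 0L) imp$provenance <- net$label
    imp
  })
  imps_a <- tag_imps(parentA)
  imps_b <- tag_imps(parentB)
  applied <- list()
  pick <- function(comp) {
    ia <- Filter(function(i) i$consequent == comp, imps_a)
    ib <- Filter(function(i) i$consequent == comp, imps_b)
    if (!(comp %in% conflicted)) return(c(ia, ib))  # dedup handled downstream
    dec <- dec_for[[comp]]
    res <- if (is.null(dec)) "union" else dec$resolution
    applied[[comp]] <<- list(
      consequent = comp, resolution = res,
      source = if (is.null(dec)) "default" else "decision",
      justification = if (is.null(dec)) "" else dec$justification)
    switch(res,
           union = c(ia, ib),
           keep_A = ia,
           keep_B = ib,
           replace_with = lapply(dec$replacement, function(imp) {
             if (norm_name(imp$consequent) != comp)
               stop("replacement for ", comp, " rewrites ", imp$consequent)
             if (length(imp$provenance) == 0L)
               imp$provenance <- c(parentA$label, parentB$label)
             imp
           }))
  }
  all_cons <- unique(c(vapply(imps_a, `[[`, "", "consequent"),
                       vapply(imps_b, `[[`, "", "consequent")))
  imps <- unlist(lapply(sort(all_cons), pick), recursive = FALSE)

  child <- logical_network(comps, imps, label = label)
  stopifnot_valid(child)

  common <- common_components(parentA, parentB)
  potential <- vapply(Filter(function(i) i$quality == "potential",
                             child$implications), implication_id, "")
  report <- structure(list(
    parents = c(parentA$label, parentB$label),
    child = label,
    conflicts = conflicts,
    decisions = unname(applied),
    common_components = common$shared,
    common_negative_regulators = common$negative_regulators,
    potential_quality = potential,
    recovery = NULL), class = "sg_merge_report")
  list(network = child, report = report)
}

#' @rdname merge_networks
#' @param x,y parent networks (S3 method for [merge()]).
#' @param ... passed on to `merge_networks()`.
#' @export
merge.logical_network <- function(x, y, ...) merge_networks(x, y, ...)

#' @export
print.sg_merge_report <- function(x, ...) {
  cat(sprintf("Merge %s + %s -> %s\n", x$parents[1], x$parents[2], x$child))
  cat(sprintf("  %d conflict(s), %d decision(s) applied (%d defaulted to union)\n",
              length(x$conflicts), length(x$decisions),
              sum(vapply(x$decisions, function(d) d$source == "default", TRUE))))
  cat("  common components:", length(x$common_components),
      "| common negative regulators:",
      paste(x$common_negative_regulators, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a merge report to YAML
#'
#' Keys are emitted in a stable order so successive reports diff cleanly,
#' mirroring version control of the curation history.
#'
#' @param report an `sg_merge_report`.
#' @param path optional output file.
#' @return the YAML text, invisibly when written to a file.
#' @export
write_merge_report <- function(report, path = NULL) {
  as_plain <- list(
    parents = as.list(report$parents),
    child = report$child,
    conflicts = lapply(report$conflicts, function(cf) list(
      kind = cf$kind, consequent = cf$consequent,
      clauses_a = as.list(cf$clauses_a), clauses_b = as.list(cf$clauses_b),
      note = cf$note)),
    decisions = lapply(report$decisions, function(d) list(
      consequent = d$consequent, resolution = d$resolution,
      source = d$source, justification = d$justification)),
    common_components = as.list(report$common_components),
    common_negative_regulators = as.list(report$common_negative_regulators),
    potential_quality = as.list(report$potential_quality),
    recovery = report$recovery)
  txt <- yaml::as.yaml(as_plain)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Components common to both parents, and shared negative regulators
#'
#' Cross-talk between two receptors is mediated by molecules common to both
#' pathways; shared components that appear as a negated literal in at least
#' one clause of each parent are candidate cross-inhibitors.
#'
#' @param parentA,parentB standardized `logical_network`s.
#' @return list with `shared` and `negative_regulators` (both sorted character
#'   vectors).
#' @export
common_components <- function(parentA, parentB) {
  shared <- sort(intersect(component_names(parentA),
                           component_names(parentB)))
  negated_in <- function(net) {
    lits <- unlist(lapply(net$implications, `[[`, "antecedent"))
    unique(lit_component(lits[lit_negated(lits)]))
  }
  list(shared = shared,
       negative_regulators = sort(intersect(shared,
                                            intersect(negated_in(parentA),
                                                      negated_in(parentB)))))
}

#' Verify that parent activation patterns are recovered in the child
#'
#' For each scenario, the expected activation pattern (a state restricted to
#' one parent's components) is checked as a fixation in the child: merging two
#' pathways must not make the known single-receptor behaviors infeasible. For
#' scenarios that are not recovered, minimal interventions correcting the
#' inconsistency are proposed.
#'
#' @param child the merged `logical_network`.
#' @param scenarios list of scenarios, each a list with elements `name`,
#'   `fix` (a [fixation()]: stimulus plus expected pattern) and optionally
#'   `phase` (default `"early"`).
#' @param max_size intervention search cap for failed scenarios.
#' @return data.frame with columns `scenario`, `phase`, `recovered`,
#'   `interventions` (semicolon-separated singleton proposals, `""` if
#'   recovered).
#' @export
verify_merge <- function(child, scenarios, max_size = 1L) {
  rows <- lapply(scenarios, function(sc) {
    phase <- if (is.null(sc$phase)) "early" else sc$phase
    fix <- fixation(sc$fix)
    ok <- is_feasible(child, fix, phase = phase)$feasible
    props <- ""
    if (!ok) {
      iv <- minimal_interventions(child, phase, fix, max_size = max_size)
      props <- paste(vapply(iv, function(s)
        paste(s$relaxed, collapse = " + "), ""), collapse = "; ")
    }
    data.frame(scenario = sc$name, phase = phase, recovered = ok,
               interventions = props)
  })
  do.call(rbind, rows)
}
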