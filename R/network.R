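#' @keywords internal
"_PACKAGE"

# ---- literals ----------------------------------------------------------------

#' Work with signed literals
#'
#' Literals are stored as strings: `"A"` for a positive occurrence of component
#' `A`, `"!A"` for a negated one.
#'
#' @param x character vector of literals.
#' @return `lit_component()` returns the component names, `lit_negated()` a
#'   logical vector, `lit()` builds literals from parts.
#' @keywords internal
#' @noRd
lit_component <- function(x) sub("^!", "", x)

#' @noRd
lit_negated <- function(x) startsWith(x, "!")

#' @noRd
lit <- function(component, negated = FALSE) {
  paste0(ifelse(negated, "!", ""), component)
}

norm_name <- function(x) toupper(trimws(x))

# Canonical form of an antecedent: unique literals sorted by (component, sign).
canon_antecedent <- function(lits) {
  lits <- unique(lits)
  lits[order(lit_component(lits), lit_negated(lits))]
}

# ---- components and implications --------------------------------------------

#' Create a network component
#'
#' A component is one logical variable of the model: a receptor chain, kinase,
#' adaptor, second messenger or transcription factor. Its ON state has a fixed
#' biological interpretation (e.g. "phosphorylated on Y394", "recruited to the
#' membrane") recorded in `interpretation`.
#'
#' @param name component identifier; normalized to uppercase.
#' @param role one of `"input"`, `"internal"`, `"output"`. Inputs are exactly
#'   the components that are the consequent of no implication.
#' @param interpretation free-text meaning of the ON state.
#' @param provenance character vector of parent-model labels.
#' @param quality `"validated"` (meets the curation standard) or `"potential"`
#'   (below-quality-standard evidence).
#' @return a list of class `sg_component`.
#' @export
#' @examples
#' component("ERK", "output", "ERK1/2 phosphorylated on T202/Y204")
component <- function(name, role = c("internal", "input", "output"),
                      interpretation = "", provenance = character(0),
                      quality = c("validated", "potential")) {
  role <- match.arg(role)
  quality <- match.arg(quality)
  structure(list(name = norm_name(name), role = role,
                 interpretation = interpretation,
                 provenance = sort(unique(as.character(provenance))),
                 quality = quality),
            class = "sg_component")
}

#' Create an implication formula
#'
#' One activating statement: the conjunction of the antecedent literals implies
#' activation of the consequent. The time horizon states when the implication
#' holds: `"early"` (ascending flank of a transient signal), `"late"`
#' (dominance of negative regulators) or `"permanent"` (both).
#'
#' @param consequent component name that is activated.
#' @param antecedent character vector of literals, e.g. `c("FYN", "!TCRB")`.
#'   The special antecedents `"1"` and `"0"` denote the constant activator
#'   (component forced ON) and the empty activator (component forced OFF);
#'   they are used by [project_network()] to pin projected components.
#' @param horizon `"early"`, `"late"` or `"permanent"`.
#' @param provenance character vector of parent-model labels.
#' @param quality `"validated"` or `"potential"`.
#' @return a list of class `sg_implication`.
#' @export
#' @examples
#' implication("PAG", c("FYN", "!TCRB"), horizon = "early")
implication <- function(consequent, antecedent,
                        horizon = c("permanent", "early", "late"),
                        provenance = character(0),
                        quality = c("validated", "potential")) {
  horizon <- match.arg(horizon)
  quality <- match.arg(quality)
  consequent <- norm_name(consequent)
  const <- NA
  if (length(antecedent) == 1L && antecedent %in% c("0", "1")) {
    const <- antecedent == "1"
    antecedent <- character(0)
  } else {
    antecedent <- canon_antecedent(toupper(trimws(antecedent)))
    if (length(antecedent) == 0L)
      stop("implication for ", consequent, " has an empty antecedent")
  }
  structure(list(consequent = consequent, antecedent = antecedent,
                 const = const, horizon = horizon,
                 provenance = sort(unique(as.character(provenance))),
                 quality = quality),
            class = "sg_implication")
}

#' Stable identifier of an implication
#'
#' Used to name implications in intervention sets and merge reports.
#'
#' @param imp an `sg_implication`.
#' @return a character scalar such as `"PAG = FYN & !TCRB @early"`.
#' @export
implication_id <- function(imp) {
  rhs <- if (!is.na(imp$const)) {
    if (imp$const) "1" else "0"
  } else {
    paste(imp$antecedent, collapse = " & ")
  }
  paste0(imp$consequent, " = ", rhs, " @", imp$horizon)
}

# ---- network -----------------------------------------------------------------

#' Assemble a logical network
#'
#' Collects components and implication formulas into a network. Components are
#' sorted by name; implications are sorted by (consequent, antecedent,
#' horizon); duplicate implications (identical antecedent, consequent and
#' horizon) are collapsed, taking the union of their provenance labels.
#' Component roles are reconciled with the implications: a component is an
#' input if and only if it is the consequent of no implication (declared
#' outputs keep the `"output"` role).
#'
#' @param components list of [component()] objects (bare names are promoted to
#'   internal components).
#' @param implications list of [implication()] objects.
#' @param label model name.
#' @return an object of class `logical_network`.
#' @export
#' @examples
#' net <- logical_network(
#'   c("MEK", "ERK"),
#'   list(implication("ERK", "MEK")),
#'   label = "demo")
#' input_components(net)
logical_network <- function(components, implications = list(), label = "model") {
  components <- lapply(components, function(x) {
    if (is.character(x)) component(x) else x
  })
  names(components) <- vapply(components, `[[`, "", "name")
  components <- components[order(names(components))]

  # collapse duplicates with provenance union
  ids <- vapply(implications, implication_id, "")
  if (anyDuplicated(ids)) {
    implications <- lapply(split(implications, ids), function(grp) {
      imp <- grp[[1L]]
      imp$provenance <- sort(unique(unlist(lapply(grp, `[[`, "provenance"))))
      if (any(vapply(grp, `[[`, "", "quality") == "validated"))
        imp$quality <- "validated"
      imp
    })
    names(implications) <- NULL
  }
  ord <- order(vapply(implications, `[[`, "", "consequent"),
               vapply(implications, implication_id, ""))
  implications <- implications[ord]

  regulated <- unique(vapply(implications, `[[`, "", "consequent"))
  for (nm in names(components)) {
    if (nm %in% regulated) {
      if (components[[nm]]$role == "input") components[[nm]]$role <- "internal"
    } else if (components[[nm]]$role == "internal") {
      components[[nm]]$role <- "input"
    }
  }

  structure(list(label = label, components = components,
                 implications = implications),
            class = "logical_network")
}

#' @export
print.logical_network <- function(x, ...) {
  cat(sprintf("Logical network '%s': %d components, %d implications\n",
              x$label, length(x$components), length(x$implications)))
  tab <- table(vapply(x$implications, `[[`, "", "horizon"))
  if (length(tab))
    cat("  horizons:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        "\n")
  cat("  inputs:", paste(input_components(x), collapse = ", "), "\n")
  invisible(x)
}

#' Component names of a network
#' @param network a `logical_network`.
#' @return character vector of component names (sorted).
#' @export
component_names <- function(network) names(network$components)

#' Input components of a network
#'
#' The inputs are exactly the components that appear as the consequent of no
#' implication, i.e. have no predecessor in the network.
#'
#' @param network a `logical_network`.
#' @return character vector of input component names.
#' @export
input_components <- function(network) {
  regulated <- vapply(network$implications, `[[`, "", "consequent")
  setdiff(component_names(network), regulated)
}

#' Validate a logical network
#'
#' Checks all structural invariants and returns diagnostics rather than
#' raising errors: undeclared components referenced by implications,
#' contradictory antecedents (a component and its negation in one
#' conjunction), consequents appearing in their own antecedent, duplicate or
#' empty component names, and role flags inconsistent with the implication
#' list.
#'
#' @param network a `logical_network`.
#' @return a data.frame with columns `where` and `message`; zero rows if the
#'   network is well formed.
#' @export
#' @examples
#' net <- logical_network("A", list(), label = "ok")
#' validate_network(net)
validate_network <- function(network) {
  msgs <- list()
  note <- function(where, message)
    msgs[[length(msgs) + 1L]] <<- data.frame(where = where, message = message)

  nms <- vapply(network$components, `[[`, "", "name")
  if (any(nms == "")) note("components", "empty component name")
  if (anyDuplicated(nms))
    note("components", paste("duplicate component name:",
                             paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  bad <- nms[nms != toupper(nms) | grepl("[^A-Z0-9_]", nms)]
  if (length(bad))
    note("components", paste("non-canonical name (uppercase A-Z0-9_ expected):",
                             paste(bad, collapse = ", ")))

  regulated <- vapply(network$implications, `[[`, "", "consequent")
  for (i in seq_along(network$implications)) {
    imp <- network$implications[[i]]
    id <- implication_id(imp)
    comps <- lit_component(imp$antecedent)
    undeclared <- setdiff(c(comps, imp$consequent), nms)
    if (length(undeclared))
      note(id, paste("undeclared component:", paste(undeclared, collapse = ", ")))
    dup <- comps[duplicated(comps)]
    if (length(dup))
      note(id, paste("contradictory antecedent (A and NOT A):",
                     paste(unique(dup), collapse = ", ")))
    if (imp$consequent %in% comps)
      note(id, "consequent appears in its own antecedent")
  }
  for (nm in nms) {
    cmp <- network$components[[nm]]
    is_input <- !(nm %in% regulated)
    if (is_input && cmp$role != "input")
      note(nm, sprintf("component has no implication but role '%s'", cmp$role))
    if (!is_input && cmp$role == "input")
      note(nm, "component is regulated but has role 'input'")
  }
  ids <- vapply(network$implications, implication_id, "")
  if (anyDuplicated(ids))
    note("implications", paste("duplicate implication:",
                               paste(unique(ids[duplicated(ids)]), collapse = "; ")))
  if (length(msgs) == 0L)
    return(data.frame(where = character(0), message = character(0)))
  do.call(rbind, msgs)
}

# Convenience used widely in tests and internally.
stopifnot_valid <- function(network) {
  d <- validate_network(network)
  if (nrow(d) > 0L)
    stop("invalid network '", network$label, "': ",
         paste(sprintf("[%s] %s", d$where, d$message), collapse = "; "))
  invisible(network)
}

#' Signed interaction graph of a network
#'
#' One edge per (antecedent literal, consequent) pair, with a sign attribute
#' (`+1` activating, `-1` inhibitory). Used for reachability during conflict
#' classification and for feedback-loop annotation.
#'
#' @param network a `logical_network`.
#' @param phase optional phase filter (`"early"`/`"late"`): restricts to
#'   implications valid in that phase (permanent ones always included).
#' @param positive_only drop inhibitory edges.
#' @return an [igraph::graph] object with vertex name attributes.
#' @export
interaction_graph <- function(network, phase = NULL, positive_only = FALSE) {
  imps <- network$implications
  if (!is.null(phase)) {
    keep <- vapply(imps, function(i) i$horizon %in% c("permanent", phase), TRUE)
    imps <- imps[keep]
  }
  edges <- list()
  sign <- integer(0)
  for (imp in imps) {
    for (l in imp$antecedent) {
      edges[[length(edges) + 1L]] <- c(lit_component(l), imp$consequent)
      sign <- c(sign, if (lit_negated(l)) -1L else 1L)
    }
  }
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(component_names(network))
  if (length(edges)) {
    em <- do.call(rbind, edges)
    keep <- if (positive_only) sign > 0L else rep(TRUE, nrow(em))
    em <- em[keep, , drop = FALSE]
    g <- igraph::add_edges(g, t(em))
    igraph::E(g)$sign <- sign[keep]
  }
  g
}
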