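# Plain-text model format.
#
#   model TCR
#   node TCRB input "TCR beta chain engaged by ligand"
#   node PAG internal
#   PAG = FYN & !TCRB @early #provenance=TCR;quality=validated
#   CSK = PAG @permanent #provenance=TCR
#
# One implication per line; `A | B` on the right-hand side expands to one
# implication per disjunct. `@horizon` defaults to permanent. Trailing
# annotations after `#` are key=value pairs separated by `;` (provenance is a
# comma-separated set). Full-line comments start with `#`.

#' Read a logical network from its text format
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param text optional character vector of lines (overrides `path`).
#' @return a `logical_network`.
#' @export
#' @examples
#' net <- read_net(text = c(
#'   "model demo",
#'   "node MEK input",
#'   "ERK = MEK"))
read_net <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  label <- "model"
  comps <- list()
  imps <- list()
  declared <- character(0)

  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^model\\s+", ln)) {
      label <- trimws(sub("^model\\s+", "", ln))
      next
    }
    if (grepl("^node\\s+", ln)) {
      m <- regmatches(ln, regexec(
        "^node\\s+(\\S+)(?:\\s+(input|internal|output))?(?:\\s+\"([^\"]*)\")?(?:\\s*#(.*))?$",
        ln))[[1]]
      if (length(m) == 0L)
        stop(sprintf("line %d: cannot parse node declaration: %s", i, ln))
      ann <- parse_annotations(m[5], i)
      cmp <- component(m[2],
                       role = if (m[3] == "") "internal" else m[3],
                       interpretation = m[4],
                       provenance = ann$provenance,
                       quality = if (is.null(ann$quality)) "validated" else ann$quality)
      comps[[cmp$name]] <- cmp
      declared <- c(declared, cmp$name)
      next
    }
    if (grepl("=", ln, fixed = TRUE)) {
      imps <- c(imps, parse_implication_line(ln, i))
      next
    }
    stop(sprintf("line %d: cannot parse: %s", i, ln))
  }

  # any component referenced but not declared gets a bare declaration
  referenced <- unique(unlist(lapply(imps, function(x)
    c(x$consequent, lit_component(x$antecedent)))))
  for (nm in setdiff(referenced, names(comps))) comps[[nm]] <- component(nm)

  net <- logical_network(comps, imps, label = label)
  d <- validate_network(net)
  d <- d[!grepl("^undeclared", d$message), , drop = FALSE] # declared above
  if (nrow(d) > 0L)
    stop("invalid model file: ",
         paste(sprintf("[%s] %s", d$where, d$message), collapse = "; "))
  net
}

parse_annotations <- function(ann, lineno) {
  out <- list(provenance = character(0), quality = NULL, horizon = NULL)
  if (is.na(ann) || ann == "") return(out)
  for (kv in strsplit(trimws(ann), ";", fixed = TRUE)[[1]]) {
    kv <- trimws(kv)
    if (kv == "") next
    parts <- strsplit(kv, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L)
      stop(sprintf("line %d: bad annotation '%s'", lineno, kv))
    key <- trimws(parts[1]); val <- trimws(parts[2])
    if (key == "provenance") {
      out$provenance <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
    } else if (key == "quality") {
      out$quality <- val
    } else {
      stop(sprintf("line %d: unknown annotation key '%s'", lineno, key))
    }
  }
  out
}

parse_implication_line <- function(ln, lineno) {
  body <- ln
  ann <- ""
  hash <- regexpr("#", body, fixed = TRUE)
  if (hash > 0) {
    ann <- substr(body, hash + 1L, nchar(body))
    body <- substr(body, 1L, hash - 1L)
  }
  horizon <- "permanent"
  at <- regexpr("@\\S+", body)
  if (at > 0) {
    horizon <- sub("^@", "", regmatches(body, at))
    body <- sub("@\\S+", "", body)
  }
  if (!horizon %in% c("early", "late", "permanent"))
    stop(sprintf("line %d: unknown horizon '@%s'", lineno, horizon))
  parts <- strsplit(body, "=", fixed = TRUE)[[1]]
  if (length(parts) != 2L)
    stop(sprintf("line %d: expected 'CONSEQUENT = antecedent': %s", lineno, ln))
  consequent <- trimws(parts[1])
  a <- parse_annotations(ann, lineno)
  quality <- if (is.null(a$quality)) "validated" else a$quality
  lapply(strsplit(trimws(parts[2]), "|", fixed = TRUE)[[1]], function(dj) {
    litstr <- trimws(strsplit(trimws(dj), "&", fixed = TRUE)[[1]])
    if (any(litstr == ""))
      stop(sprintf("line %d: empty literal in '%s'", lineno, dj))
    implication(consequent, litstr, horizon = horizon,
                provenance = a$provenance, quality = quality)
  })
}

#' Serialize a logical network to its text format
#'
#' The writer emits canonical order (components sorted by name, implications
#' by consequent/antecedent/horizon, one implication per line), so
#' serialization followed by parsing reproduces the identical network and
#' files diff cleanly under version control.
#'
#' @param network a `logical_network`.
#' @param path optional output file; if `NULL` the lines are returned.
#' @return invisibly (or visibly when `path` is `NULL`), the character vector
#'   of lines.
#' @export
write_net <- function(network, path = NULL) {
  lines <- c(paste("model", network$label))
  for (cmp in network$components) {
    ln <- paste("node", cmp$name, cmp$role)
    if (nzchar(cmp$interpretation))
      ln <- paste0(ln, " \"", cmp$interpretation, "\"")
    ann <- character(0)
    if (length(cmp$provenance))
      ann <- c(ann, paste0("provenance=", paste(cmp$provenance, collapse = ",")))
    if (cmp$quality != "validated") ann <- c(ann, paste0("quality=", cmp$quality))
    if (length(ann)) ln <- paste0(ln, " #", paste(ann, collapse = ";"))
    lines <- c(lines, ln)
  }
  for (imp in network$implications) {
    rhs <- if (!is.na(imp$const)) {
      if (imp$const) "1" else "0"
    } else paste(imp$antecedent, collapse = " & ")
    ln <- paste0(imp$consequent, " = ", rhs, " @", imp$horizon)
    ann <- character(0)
    if (length(imp$provenance))
      ann <- c(ann, paste0("provenance=", paste(imp$provenance, collapse = ",")))
    if (imp$quality != "validated") ann <- c(ann, paste0("quality=", imp$quality))
    if (length(ann)) ln <- paste0(ln, " #", paste(ann, collapse = ";"))
    lines <- c(lines, ln)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Export a network as a Graphviz DOT graph
#'
#' Activating edges are solid, inhibitory edges dotted; AND-connections
#' (multi-literal antecedents) are drawn through small point-shaped junction
#' nodes, following the usual graphical convention for logical interaction
#' hypergraphs.
#'
#' @param network a `logical_network`.
#' @param path optional output file.
#' @return invisibly (or visibly when `path` is `NULL`), the DOT lines.
#' @export
export_dot <- function(network, path = NULL) {
  q <- function(x) paste0("\"", x, "\"")
  lines <- c(sprintf("digraph %s {", q(network$label)),
             "  rankdir=TB;")
  for (cmp in network$components) {
    shape <- switch(cmp$role, input = "invhouse", output = "house", "box")
    lines <- c(lines, sprintf("  %s [shape=%s];", q(cmp$name), shape))
  }
  for (i in seq_along(network$implications)) {
    imp <- network$implications[[i]]
    if (!is.na(imp$const)) next
    if (length(imp$antecedent) == 1L) {
      l <- imp$antecedent
      style <- if (lit_negated(l)) "dotted" else "solid"
      lines <- c(lines, sprintf("  %s -> %s [style=%s];",
                                q(lit_component(l)), q(imp$consequent), style))
    } else {
      junction <- sprintf("and_%d", i)
      lines <- c(lines,
                 sprintf("  %s [shape=point, width=0.08];", q(junction)))
      for (l in imp$antecedent) {
        style <- if (lit_negated(l)) "dotted" else "solid"
        lines <- c(lines, sprintf("  %s -> %s [style=%s, arrowhead=none];",
                                  q(lit_component(l)), q(junction), style))
      }
      lines <- c(lines, sprintf("  %s -> %s;", q(junction), q(imp$consequent)))
    }
  }
  lines <- c(lines, "}")
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
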