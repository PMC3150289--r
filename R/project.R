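# Logical projection: restrict a network's feasible-state set to a component
# subset and re-express it as a smaller logical network. Exact by
# construction: the projected network is synthesized from the brute-forced
# state set and verified against it; projection is refused (with an explicit
# error, never a silent approximation) when the network is too large to
# enumerate or when the projected relation cannot be expressed as a system of
# one IFF clause per component.

#' Project a network onto a subset of its components
#'
#' The feasible states of the input network are enumerated, restricted to the
#' kept components, and a minimal network over those components is
#' synthesized. Every kept component whose value is a function of the other
#' kept values (on the observed states) gets one IFF clause; components that
#' can take both values under the same context become inputs. Assignments of
#' the other components that never occur are don't-cares: they default to
#' OFF and are re-pinned deterministically until the synthesized system has
#' exactly the projected solution set. Clause right-hand sides are minimal
#' DNFs (prime implicants with essential-first exact cover, lexicographic
#' tie-break), and clauses that do not constrain the solution set are dropped
#' (original inputs first), so e.g. a chain A -> B -> C projected onto
#' \{A, C\} yields the single clause `C = A`.
#'
#' @param network a `logical_network` with at most `guard` components.
#' @param phase `"early"` or `"late"`.
#' @param keep character vector of component names to keep.
#' @param guard enumeration size guard (components).
#' @return a `logical_network` over `keep` whose feasible-state set equals
#'   the restriction of the input network's feasible states to `keep`.
#' @export
#' @examples
#' chain <- read_net(text = c("model chain", "B = A", "C = B"))
#' write_net(project_network(chain, "early", c("A", "C")))
project_network <- function(network, phase = c("early", "late"), keep,
                            guard = 20L) {
  phase <- match.arg(phase)
  stopifnot_valid(network)
  keep <- sort(unique(norm_name(keep)))
  unknown <- setdiff(keep, component_names(network))
  if (length(unknown))
    stop("keep set references unknown component(s): ",
         paste(unknown, collapse = ", "))
  n <- length(component_names(network))
  if (n > guard)
    stop("exact projection infeasible at this size: ", n,
         " components exceeds the enumeration guard of ", guard)

  system <- compile_iff(network, phase)
  states <- brute_force_states(system)
  if (nrow(states) == 0L)
    stop("the network has no feasible state in the ", phase,
         " phase; the empty solution set has no network representation")
  target <- unique(as.matrix(states)[, keep, drop = FALSE])
  target_key <- apply(target, 1L, paste, collapse = "")

  # all assignments over the keep set, and per-component context keys
  grid <- as.matrix(expand.grid(rep(list(0:1), length(keep)),
                                KEEP.OUT.ATTRS = FALSE))
  colnames(grid) <- keep
  grid_key <- apply(grid, 1L, paste, collapse = "")
  ctx <- list()  # per component: context string of every grid row / target row
  for (comp in keep) {
    others <- setdiff(keep, comp)
    rowkeys <- function(m) {
      if (length(others) == 0L) return(rep("", nrow(m)))
      apply(m[, others, drop = FALSE], 1L, paste, collapse = "")
    }
    ctx[[comp]] <- list(others = others, grid = rowkeys(grid),
                        target = rowkeys(target))
  }

  # functional components: pinned value per observed context (conflict = free)
  tables <- list()
  for (comp in keep) {
    vals <- split(target[, comp], ctx[[comp]]$target)
    if (any(vapply(vals, function(v) length(unique(v)) > 1L, TRUE))) next
    tables[[comp]] <- vapply(vals, `[[`, 0L, 1L)
  }
  # Refinement on plain function tables (unpinned contexts default OFF):
  # batch-pin don't-cares against spurious solutions until exact.
  grid_solutions <- function(tabs) {
    ok <- rep(TRUE, nrow(grid))
    for (comp in names(tabs)) {
      f <- tabs[[comp]][ctx[[comp]]$grid]
      f[is.na(f)] <- 0L
      ok <- ok & (grid[, comp] == f)
    }
    ok
  }
  for (round in seq_len(64L)) {
    sol <- grid_solutions(tables)
    spurious <- which(sol & !(grid_key %in% target_key))
    if (length(spurious) == 0L) break
    progress <- FALSE
    for (i in spurious) {
      for (comp in names(tables)) {
        key <- ctx[[comp]]$grid[[i]]
        if (!key %in% names(tables[[comp]])) {
          tables[[comp]][key] <- 1L - grid[i, comp]
          progress <- TRUE
          break
        }
      }
    }
    if (!progress)
      stop("exact projection onto {", paste(keep, collapse = ", "),
           "} is not representable as an IFF clause system over the kept ",
           "components (a hidden component mediates a non-functional ",
           "dependency); choose a larger keep set")
  }
  sol <- grid_solutions(tables)
  if (!setequal(grid_key[sol], target_key))
    stop("exact projection onto {", paste(keep, collapse = ", "),
         "} is not representable as an IFF clause system over the kept ",
         "components (don't-care refinement did not converge)")

  # drop clauses that do not constrain the solution set: original inputs
  # first, then alphabetically
  orig_inputs <- intersect(keep, input_components(network))
  ord <- c(sort(intersect(names(tables), orig_inputs)),
           sort(setdiff(names(tables), orig_inputs)))
  for (comp in ord) {
    trial <- tables
    trial[[comp]] <- NULL
    if (setequal(grid_key[grid_solutions(trial)], target_key)) tables <- trial
  }

  # synthesize minimal DNFs from the completed functions (unpinned = OFF)
  imps <- list()
  for (comp in names(tables)) {
    f <- tables[[comp]]
    onset <- names(f)[f == 1L]
    dnf <- minimal_dnf(onset, character(0), setdiff(keep, comp))
    if (length(dnf) == 0L) {
      imps[[length(imps) + 1L]] <- implication(comp, "0",
                                               provenance = network$label)
    } else for (d in dnf) {
      imps[[length(imps) + 1L]] <-
        implication(comp, if (length(d) == 0L) "1" else d,
                    provenance = network$label)
    }
  }
  out <- logical_network(keep, imps,
                         label = paste0(network$label, "|",
                                        paste(keep, collapse = ",")))
  # final independent verification through the compiled system
  got <- brute_force_states(compile_iff(out, phase))
  if (!setequal(apply(as.matrix(got), 1L, paste, collapse = ""), target_key))
    stop("internal error: synthesized projection does not match its target")
  out
}

# ---- minimal DNF (Quine-McCluskey + essential-first exact cover) ------------
#
# Minterms are strings of 0/1 over `vars` (in order). Cubes are strings over
# {0,1,-}. Returns a list of literal vectors (empty vector = constant TRUE),
# or an empty list for constant FALSE.

minimal_dnf <- function(onset, dontcare, vars) {
  if (length(onset) == 0L) return(list())            # constant FALSE
  if (length(vars) == 0L) return(list(character(0))) # constant TRUE
  primes <- sort(prime_implicants(c(onset, dontcare)))
  cov <- lapply(primes, function(p) onset[cube_covers(p, onset)])
  names(cov) <- primes

  chosen <- character(0)
  remaining <- onset
  repeat {
    if (length(remaining) == 0L) break
    pool <- setdiff(primes, chosen)
    hits <- lapply(pool, function(p) intersect(cov[[p]], remaining))
    names(hits) <- pool
    counts <- table(unlist(hits))
    singles <- names(counts)[counts == 1L]
    if (length(singles) == 0L) break
    ess <- pool[vapply(pool, function(p) any(hits[[p]] %in% singles), TRUE)]
    chosen <- c(chosen, ess)
    remaining <- setdiff(remaining, unlist(cov[ess]))
  }
  if (length(remaining)) {
    pool <- setdiff(primes, chosen)
    pool <- pool[vapply(pool, function(p) any(cov[[p]] %in% remaining), TRUE)]
    if (length(pool) <= 14L) {
      best <- NULL
      k <- 1L
      while (is.null(best) && k <= length(pool)) {
        for (s in utils::combn(pool, k, simplify = FALSE)) {
          if (all(remaining %in% unlist(cov[s]))) { best <- s; break }
        }
        k <- k + 1L
      }
      chosen <- c(chosen, best)
    } else {
      while (length(remaining)) {  # greedy, deterministic tie-break
        gain <- vapply(pool, function(p) sum(cov[[p]] %in% remaining), 0L)
        pick <- pool[order(-gain, pool)][[1L]]
        chosen <- c(chosen, pick)
        remaining <- setdiff(remaining, cov[[pick]])
      }
    }
  }
  lapply(sort(chosen), cube_to_literals, vars = vars)
}

prime_implicants <- function(minterms) {
  cubes <- unique(minterms)
  primes <- character(0)
  while (length(cubes)) {
    combined <- character(0)
    used <- rep(FALSE, length(cubes))
    split_cubes <- strsplit(cubes, "")
    if (length(cubes) > 1L) {
      for (i in seq_len(length(cubes) - 1L)) {
        ci <- split_cubes[[i]]
        for (j in seq(i + 1L, length(cubes))) {
          cj <- split_cubes[[j]]
          diff <- which(ci != cj)
          if (length(diff) != 1L) next
          if (ci[diff] == "-" || cj[diff] == "-") next
          m <- ci
          m[diff] <- "-"
          combined <- c(combined, paste(m, collapse = ""))
          used[i] <- used[j] <- TRUE
        }
      }
    }
    primes <- c(primes, cubes[!used])
    cubes <- unique(combined)
  }
  unique(primes)
}

cube_covers <- function(cube, minterms) {
  cc <- strsplit(cube, "")[[1]]
  fixed <- cc != "-"
  vapply(minterms, function(m) {
    mm <- strsplit(m, "")[[1]]
    all(mm[fixed] == cc[fixed])
  }, TRUE, USE.NAMES = FALSE)
}

cube_to_literals <- function(cube, vars) {
  cc <- strsplit(cube, "")[[1]]
  out <- character(0)
  for (i in seq_along(cc)) {
    if (cc[i] == "1") out <- c(out, vars[i])
    if (cc[i] == "0") out <- c(out, lit(vars[i], TRUE))
  }
  out
}
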