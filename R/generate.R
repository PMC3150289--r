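# Seeded random-network generator. Implications are wired over a random
# topological order (guaranteeing an acyclic permanent-horizon core), while
# late-horizon implications may point backwards, creating the feedback loops
# that make some fixation patterns infeasible - the situation the
# intervention and core machinery is for.

#' Configuration for the random-network generator
#'
#' @param n_components number of components.
#' @param n_implications number of implication formulas.
#' @param max_antecedent_size largest antecedent conjunction (default 3).
#' @param p_negated probability that an antecedent literal is negated.
#' @param p_late probability that an implication is a late (feedback-capable)
#'   implication; the remainder are permanent.
#' @param n_inputs number of input components (at least 1).
#' @param seed integer seed; identical config and seed give a byte-identical
#'   network.
#' @return a list of class `sg_generator_config`.
#' @export
generator_config <- function(n_components, n_implications,
                             max_antecedent_size = 3L, p_negated = 0,
                             p_late = 0, n_inputs = 1L, seed = 1L) {
  stopifnot(n_inputs >= 1L, n_components > n_inputs,
            p_negated >= 0, p_negated <= 1, p_late >= 0, p_late <= 1,
            max_antecedent_size >= 1L, n_implications >= 0L)
  structure(list(n_components = as.integer(n_components),
                 n_implications = as.integer(n_implications),
                 max_antecedent_size = as.integer(max_antecedent_size),
                 p_negated = p_negated, p_late = p_late,
                 n_inputs = as.integer(n_inputs), seed = as.integer(seed)),
            class = "sg_generator_config")
}

#' Generate a random logical network
#'
#' @param config a [generator_config()].
#' @return a valid `logical_network` with exactly the requested numbers of
#'   components and implications; consequents are drawn only from non-input
#'   components.
#' @export
#' @examples
#' net <- generate_network(generator_config(6, 5, seed = 42))
#' nrow(validate_network(net))
generate_network <- function(config) {
  stopifnot(inherits(config, "sg_generator_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(config$seed)

  n <- config$n_components
  width <- max(2L, nchar(as.character(n)))
  names_all <- sprintf(paste0("N%0", width, "d"), seq_len(n))
  topo <- sample(names_all)            # random topological order
  inputs <- topo[seq_len(config$n_inputs)]
  internal <- topo[-seq_len(config$n_inputs)]

  imps <- list()
  ids <- character(0)
  tries <- 0L
  while (length(imps) < config$n_implications) {
    tries <- tries + 1L
    if (tries > 200L * config$n_implications + 200L)
      stop("infeasible generator config: cannot place ",
           config$n_implications, " distinct implications")
    horizon <- if (stats::runif(1) < config$p_late) "late" else "permanent"
    consequent <- sample(internal, 1L)
    pos <- match(consequent, topo)
    pool <- if (horizon == "late") setdiff(names_all, consequent)
            else topo[seq_len(pos - 1L)]
    if (length(pool) == 0L) next
    k <- sample(seq_len(min(config$max_antecedent_size, length(pool))), 1L)
    ante <- sample(pool, k)
    neg <- stats::runif(k) < config$p_negated
    imp <- implication(consequent, lit(ante, neg), horizon = horizon)
    id <- implication_id(imp)
    if (id %in% ids) next
    imps[[length(imps) + 1L]] <- imp
    ids <- c(ids, id)
  }
  net <- logical_network(names_all, imps,
                         label = sprintf("random-n%d-m%d-seed%d", n,
                                         config$n_implications, config$seed))
  # inputs that accidentally received no implication stay inputs; declared
  # inputs are exactly the unregulated components by construction
  stopifnot_valid(net)
  net
}
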