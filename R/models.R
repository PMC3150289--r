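# Bundled models: transcriptions of curated T-cell signaling networks.
#
# The bundled TCR/CD4/CD28 network, the initial and experimentally validated
# IL-2R networks and their merged child are reconstructions assembled from
# the published figure legends and narrative of the underlying study; see
# inst/extdata/models/TRANSCRIPTION_NOTES.md for what is faithful (component
# inventory, pathway topology, the published component/clause totals, the
# worked negative-feedback example) and what is necessarily approximate
# (clause-level details of interactions whose supplementary listings are not
# publicly machine-readable).

MODEL_FILES <- c(
  TCR = "tcr.net",
  IL2R_initial = "il2r_initial.net",
  IL2R_validated = "il2r_validated.net",
  MERGED = "merged_tcr_il2r.net",
  loop = "loop.net")

#' Path to a bundled model or merge-support file
#'
#' @param file file name under the package's `extdata/models` directory; with
#'   no argument, the directory itself.
#' @return absolute path.
#' @export
model_path <- function(file = "") {
  p <- system.file("extdata", "models", file, package = "signalogic",
                   mustWork = TRUE)
  p
}

#' Load a bundled network model
#'
#' Available models:
#' \describe{
#'   \item{TCR}{the TCR/CD4/CD28 signaling network (early + late horizons,
#'     including the PAG/CSK/LCKP1/FYN negative feedback loop).}
#'   \item{IL2R_initial}{the literature-derived IL-2R network: 68 components,
#'     69 implication clauses.}
#'   \item{IL2R_validated}{the IL-2R network revised after the validation
#'     experiments in human T-cell blasts (SFK-STAT links removed; PI3K
#'     placed downstream of SFKs and JAKs; ERK requiring JAKs, PI3K and
#'     novel PKCs; JNK requiring JAKs and PI3K; LAT phosphorylation added):
#'     68 components, 73 clauses.}
#'   \item{MERGED}{the merged TCR + IL-2R child network: 150 components,
#'     167 clauses. Reproducible from the parents with
#'     [merge_networks()] and the bundled decisions file.}
#'   \item{loop}{the four-clause PAG/CSK/LCKP1/FYN feedback-loop example.}
#' }
#'
#' @param name one of `"TCR"`, `"IL2R_initial"`, `"IL2R_validated"`,
#'   `"MERGED"`, `"loop"`.
#' @return a validated `logical_network`.
#' @export
#' @examples
#' loop <- load_model("loop")
#' is_feasible(loop, c(TCRB = 1))$feasible
load_model <- function(name) {
  if (!name %in% names(MODEL_FILES))
    stop("unknown model '", name, "'; available: ",
         paste(names(MODEL_FILES), collapse = ", "))
  net <- read_net(model_path(MODEL_FILES[[name]]))
  stopifnot_valid(net)
  net
}

#' Bundled expert decisions for the TCR + IL-2R merge
#'
#' @return list of [merge_decision()]s resolving the conflicts raised when
#'   merging the bundled `TCR` and `IL2R_validated` models.
#' @export
bundled_decisions <- function() {
  read_decisions(model_path("decisions_tcr_il2r.yaml"))
}

#' Bundled isoform hierarchy (PKC isoforms)
#'
#' @return an [isoform_hierarchy()] data.frame.
#' @export
bundled_isoforms <- function() {
  read_isoforms(model_path("isoforms.yaml"))
}

#' Number of implication clauses of a network
#'
#' @param network a `logical_network`.
#' @return integer count of implication formulas.
#' @export
n_clauses <- function(network) length(network$implications)
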