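# Stimulus-response prediction.
#
# A stimulus scenario fixes input components only: stimulated inputs are ON,
# all unnamed inputs are OFF (the biological resting state). Internal
# components that are free in the queried phase remain unconstrained, so a
# prediction is in general a set of states; readouts that take the same value
# in every feasible state are the model's firm predictions.

#' Predict the response to a stimulus
#'
#' @param object a `logical_network`.
#' @param stimulus a [fixation()] naming input components only. Inputs not
#'   named are fixed OFF.
#' @param phase `"early"` or `"late"`.
#' @param cap maximum number of states enumerated.
#' @param inherit_early for `phase = "late"`: additionally fix every component
#'   whose value is forced (identical across all feasible states) in the early
#'   phase under the same stimulus. Off by default; the two-time-scale
#'   formalism leaves this choice open and both modes are exposed.
#' @param ... unused.
#' @return a `state_table` (one row per feasible state), with attribute
#'   `truncated`.
#' @export
#' @examples
#' chain <- read_net(text = c("model chain", "B = A", "C = B"))
#' predict(chain, c(A = 1))
predict.logical_network <- function(object, stimulus = NULL,
                                    phase = c("early", "late"),
                                    cap = 1024L, inherit_early = FALSE, ...) {
  phase <- match.arg(phase)
  fix <- stimulus_fixation(object, stimulus)
  if (inherit_early && phase == "late") {
    early <- enumerate_states(compile_iff(object, "early"), fix, cap = cap)
    forced <- forced_components(early)
    forced <- forced[setdiff(names(forced), names(fix))]
    fix <- fixation(c(unclass(fix), forced))
  }
  enumerate_states(compile_iff(object, phase), fix, cap = cap)
}

stimulus_fixation <- function(network, stimulus) {
  stim <- fixation(stimulus)
  inputs <- input_components(network)
  non_input <- setdiff(names(stim), inputs)
  if (length(non_input))
    stop("stimulus may only fix input components; not inputs: ",
         paste(non_input, collapse = ", "),
         " (use is_feasible() for general fixation patterns)")
  rest <- setdiff(inputs, names(stim))
  fixation(c(unclass(stim), stats::setNames(rep(0L, length(rest)), rest)))
}

# Components taking the same value in every row of a state table.
forced_components <- function(states) {
  if (nrow(states) == 0L) return(integer(0))
  m <- as.matrix(states)
  keep <- apply(m, 2L, function(col) all(col == col[1L]))
  stats::setNames(as.integer(m[1L, keep]), colnames(m)[keep])
}

#' Summarize which readouts are forced ON or OFF under a stimulus
#'
#' Answers, per component, whether the model forces it ON, forces it OFF, or
#' admits both values across the feasible states. Decided by two
#' satisfiability calls per component rather than enumeration, so it scales to
#' networks whose state set is large.
#'
#' @param network a `logical_network` (or a precompiled `iff_system`).
#' @param stimulus a [fixation()] over inputs (for a network) or a general
#'   fixation (for a system).
#' @param phase `"early"` or `"late"`.
#' @param readouts components to report (default: all).
#' @return data.frame with columns `component` and `state`
#'   (`"ON"`/`"OFF"`/`"either"`; `"infeasible"` for all if no state exists).
#' @export
predict_summary <- function(network, stimulus = NULL, phase = "early",
                            readouts = NULL) {
  if (inherits(network, "logical_network")) {
    system <- compile_iff(network, phase)
    fix <- stimulus_fixation(network, stimulus)
  } else {
    system <- network
    fix <- check_fixation(system, fixation(stimulus))
  }
  summarize_system(system, fix, readouts)
}

summarize_system <- function(system, fix, readouts = NULL) {
  if (is.null(readouts)) readouts <- sort(system$components)
  readouts <- norm_name(readouts)
  unknown <- setdiff(readouts, system$components)
  if (length(unknown))
    stop("unknown readout(s): ", paste(unknown, collapse = ", "))
  enc <- encode_cnf(system, fix)
  if (!sat_check(enc))
    return(data.frame(component = readouts,
                      state = rep("infeasible", length(readouts))))
  state <- vapply(readouts, function(nm) {
    v <- enc$vars[[nm]]
    can_on <- length(dpll_enumerate(enc, cap = 1L, assume = v)$models) > 0L
    can_off <- length(dpll_enumerate(enc, cap = 1L, assume = -v)$models) > 0L
    if (can_on && can_off) "either" else if (can_on) "ON" else "OFF"
  }, "")
  data.frame(component = readouts, state = unname(state))
}

#' Predict the response to sequential stimulation of two receptors
#'
#' Models the scenario in which a second receptor is engaged while the first
#' receptor's signaling is already in its late phase. Implications whose
#' provenance includes the first (pre-stimulated) parent model are taken in
#' their late horizon set (permanent + late); implications exclusive to other
#' parents are taken in their early set (permanent + early); an implication
#' carrying both provenances follows the late set. The combined selection is
#' compiled into a single IFF system and solved under the joint stimulus.
#'
#' @param network the merged `logical_network` (implications must carry
#'   provenance labels).
#' @param stimulus joint stimulus over inputs: both the first receptor's
#'   ligand (still present) and the second receptor's.
#' @param first provenance label of the pre-stimulated parent model.
#' @param cap maximum number of states enumerated.
#' @param readouts if non-NULL, return the forced-value summary (see
#'   [predict_summary()]) for these components instead of the state table.
#' @return a `state_table`, or a summary data.frame when `readouts` is given.
#' @export
predict_sequential <- function(network, stimulus, first, cap = 1024L,
                               readouts = NULL) {
  labels <- unique(unlist(lapply(network$implications, `[[`, "provenance")))
  if (!first %in% labels)
    stop("no implication carries provenance label '", first, "' (known: ",
         paste(labels, collapse = ", "), ")")
  sel <- Filter(function(imp) {
    if (first %in% imp$provenance) imp$horizon %in% c("permanent", "late")
    else imp$horizon %in% c("permanent", "early")
  }, network$implications)
  system <- compile_iff(network, phase = "late", implications = sel,
                        phase_filter = FALSE)
  fix <- stimulus_fixation(network, stimulus)
  if (!is.null(readouts)) return(summarize_system(system, fix, readouts))
  enumerate_states(system, fix, cap = cap)
}
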