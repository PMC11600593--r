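# Model state space: five rhythm states, three of which carry a re-ablation
# substate index k = 0..3 (number of repeat procedures received). Death is
# absorbing and always last.

STATE_GROUPS <- c("nsr", "st", "lt", "permanent", "dead")

#' Markov state space
#'
#' The cohort model distinguishes normal sinus rhythm (NSR), short-term
#' episodic AF, long-term persistent AF, permanent AF and death. NSR,
#' ST-episodic and LT-persistent each carry four substates (k = 0..3)
#' recording the number of repeat ablations received, because the relative
#' risk of symptom recurrence and resolution depends on the number of
#' procedures. 14 states in total; death is last and absorbing.
#'
#' @return A tibble with one row per state: `state` (label), `group`
#'   (rhythm state), `k` (re-ablation substate, `NA` for permanent/dead)
#'   and `index` (position used by the transition matrices).
#' @examples
#' state_space()
#' @export
state_space <- function() {
  tibble::tibble(
    state = af_states(),
    group = c(rep("nsr", 4), rep("st", 4), rep("lt", 4), "permanent", "dead"),
    k = c(0:3, 0:3, 0:3, NA_integer_, NA_integer_),
    index = seq_len(14L)
  )
}

#' @rdname state_space
#' @export
af_states <- function() {
  c(paste0("nsr_", 0:3), paste0("st_", 0:3), paste0("lt_", 0:3),
    "permanent", "dead")
}

# Fixed index helpers (positions in the 14-vector).
IDX_NSR <- 1:4
IDX_ST <- 5:8
IDX_LT <- 9:12
IDX_PERM <- 13L
IDX_DEAD <- 14L
IDX_LIVING <- 1:13

state_group_of <- function() {
  c(rep("nsr", 4), rep("st", 4), rep("lt", 4), "permanent", "dead")
}

state_k_of <- function() {
  c(0:3, 0:3, 0:3, NA_integer_, NA_integer_)
}
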