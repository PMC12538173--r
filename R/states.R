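#' Health states and treatment arms
#'
#' The model distinguishes a stable out-of-episode state, two in-episode
#' states (episodes with only outpatient care vs. episodes that include
#' inpatient care), and an absorbing death state. An *episode* is a period
#' of increased specialised mental-healthcare use; *relapse* is the
#' transition out-of-episode -> in-episode and *remission* the reverse.
#'
#' @return `health_states()` returns the four state labels; `alive_states()`
#'   the three non-absorbing ones; `episode_states()` the two in-episode
#'   ones; `arms()` the two treatment-arm labels (`"tau"` = treatment as
#'   usual, `"tau_cbtp"` = TAU plus one-time CBTp).
#' @examples
#' health_states()
#' @export
health_states <- function() {
  c("out_of_episode", "episode_outpatient", "episode_inpatient", "dead")
}

#' @rdname health_states
#' @export
alive_states <- function() {
  c("out_of_episode", "episode_outpatient", "episode_inpatient")
}

#' @rdname health_states
#' @export
episode_states <- function() {
  c("episode_outpatient", "episode_inpatient")
}

#' @rdname health_states
#' @export
arms <- function() {
  c("tau", "tau_cbtp")
}

# internal label for a relapse destination that is resolved by the
# episode-type sub-model at relapse time
IN_EPISODE <- "in_episode"

assert_state <- function(x, allowed = health_states(), what = "state") {
  bad <- setdiff(unique(x), allowed)
  if (length(bad)) {
    stop(sprintf("unknown %s label(s): %s", what, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}
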