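# Counters for the documented numerical fallbacks (epsilon denominators,
# zero-variance genes, bootstrap redraws).  The CLI copies the counts into
# its run log; bsm_select() attaches them to its result.

.event_env <- new.env(parent = emptyenv())

.log_event <- function(name, n = 1L) {
  cur <- get0(name, envir = .event_env, ifnotfound = 0L)
  assign(name, cur + n, envir = .event_env)
  invisible(NULL)
}

#' Counts of numerical fallback events
#'
#' The package keeps a tally of every degenerate-input rule it applies
#' (epsilon-protected denominators, zero-variance genes treated as
#' uncorrelated, rejected bootstrap draws).  `bsm_event_log()` returns the
#' tally since the last [bsm_reset_events()].
#'
#' @return Named integer vector of event counts (possibly empty).
#' @export
bsm_event_log <- function() {
  nms <- ls(.event_env)
  stats::setNames(vapply(nms, get, integer(1), envir = .event_env), nms)
}

#' @rdname bsm_event_log
#' @export
bsm_reset_events <- function() {
  rm(list = ls(.event_env), envir = .event_env)
  invisible(NULL)
}
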