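#' Define a reinforcement schedule
#'
#' A schedule specification holds the family (fixed ratio FR, variable
#' ratio VR, or progressive ratio PR) and the parameters that govern a
#' session: the lick requirement, the post-reward timeout during which
#' licks are logged but do not count, the cue-light duration, and the
#' session-termination rule. FR/VR sessions run for a fixed `session_s`
#' (default one hour); a PR session ends `pr_idle_stop_s` (default 10 min)
#' after the last lick on the active spout.
#'
#' @param family `"FR"`, `"VR"` or `"PR"`.
#' @param ratio Positive integer: the FR requirement, the VR mean, or the
#'   PR base requirement. Default 10.
#' @param pr_step Positive integer increment of the PR requirement after
#'   each reward (requirement for reward k is `ratio + (k-1) * pr_step`).
#' @param timeout_s Non-negative post-reward timeout, seconds. Default 20.
#' @param cue_s Cue-light duration at each reward, seconds. Default 5.
#' @param session_s Fixed FR/VR session length, seconds. Default 3600.
#' @param pr_idle_stop_s PR stop window after the last active lick,
#'   seconds. Default 600.
#' @param vr_draws Optional integer vector: an explicit VR requirement
#'   sequence, consumed cyclically instead of random draws. Each entry must
#'   be a positive integer. Useful for exact replays.
#' @return An object of class `schedule_spec`.
#' @examples
#' schedule_spec("FR", ratio = 10)
#' schedule_spec("PR", ratio = 10, pr_step = 5)
#' @export
schedule_spec <- function(family = c("VR", "FR", "PR"), ratio = 10L,
                          pr_step = 5L, timeout_s = 20, cue_s = 5,
                          session_s = 3600, pr_idle_stop_s = 600,
                          vr_draws = NULL) {
  family <- match.arg(toupper(family), c("VR", "FR", "PR"))
  ratio <- as.integer(ratio)
  pr_step <- as.integer(pr_step)
  stopifnot(
    length(ratio) == 1L, !is.na(ratio), ratio >= 1L,
    length(pr_step) == 1L, !is.na(pr_step), pr_step >= 1L,
    length(timeout_s) == 1L, timeout_s >= 0,
    length(cue_s) == 1L, cue_s >= 0,
    length(session_s) == 1L, session_s > 0,
    length(pr_idle_stop_s) == 1L, pr_idle_stop_s > 0
  )
  if (!is.null(vr_draws)) {
    vr_draws <- as.integer(vr_draws)
    stopifnot(length(vr_draws) >= 1L, all(!is.na(vr_draws)), all(vr_draws >= 1L))
  }
  structure(
    list(family = family, ratio = ratio, pr_step = pr_step,
         timeout_s = as.numeric(timeout_s), cue_s = as.numeric(cue_s),
         session_s = as.numeric(session_s),
         pr_idle_stop_s = as.numeric(pr_idle_stop_s),
         vr_draws = vr_draws),
    class = "schedule_spec"
  )
}

#' @export
format.schedule_spec <- function(x, compact = FALSE, ...) {
  if (compact) return(sprintf("%s%d", x$family, x$ratio))
  sprintf("%s%d (timeout %gs, cue %gs, %s)",
          x$family, x$ratio, x$timeout_s, x$cue_s,
          if (x$family == "PR")
            sprintf("step %d, stops %gs after last lick", x$pr_step, x$pr_idle_stop_s)
          else sprintf("session %gs", x$session_s))
}

#' @export
print.schedule_spec <- function(x, ...) {
  cat("<schedule_spec>", format(x), "\n")
  invisible(x)
}

#' Named schedule presets
#'
#' The three schedules used in the original study: `"fr10"` (fixed ratio
#' 10), `"vr10"` (variable ratio with mean 10) and `"pr"` (progressive
#' ratio, base 10, step 5). All use a 20 s timeout and a 5 s cue.
#'
#' @param name Preset name, case-insensitive.
#' @return A [schedule_spec()].
#' @export
schedule_preset <- function(name) {
  switch(tolower(name),
    fr10 = schedule_spec("FR", 10L),
    vr10 = schedule_spec("VR", 10L),
    pr   = schedule_spec("PR", 10L, pr_step = 5L),
    stop(sprintf("unknown schedule preset '%s' (use fr10, vr10 or pr)", name),
         call. = FALSE)
  )
}

#' Read a schedule specification from a YAML config file
#'
#' The config mirrors the `schedule_spec` field names, e.g.
#' \preformatted{family: FR
#' ratio: 10
#' timeout_s: 20
#' cue_s: 5
#' session_s: 3600}
#' Omitted fields take their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [schedule_spec()].
#' @export
read_schedule_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("family", "ratio", "pr_step", "timeout_s", "cue_s",
             "session_s", "pr_idle_stop_s", "vr_draws")
  unknown <- setdiff(names(cfg), c(known, "seed"))
  if (length(unknown)) {
    stop("unknown schedule config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(schedule_spec, cfg[intersect(names(cfg), known)])
}

#' Map RFID tags to reinforcement schedules
#'
#' The acquisition system selects the schedule by the RFID tag that starts
#' the session: particular tags are bound to particular schedules and any
#' unmapped tag falls through to the default (variable ratio 10). Several
#' tags may map to the same schedule.
#'
#' @param entries Named list: names are 12-hex RFID tags, values are
#'   [schedule_spec()] objects.
#' @param default Schedule used for unmapped tags. Default VR10.
#' @return An object of class `rfid_schedule_map`.
#' @export
rfid_schedule_map <- function(entries = list(), default = schedule_spec("VR", 10L)) {
  stopifnot(is.list(entries), inherits(default, "schedule_spec"))
  if (length(entries)) {
    ok <- validate_tag(names(entries))
    if (!all(ok)) {
      stop("invalid RFID tag in schedule map: ", names(entries)[!ok][1],
           call. = FALSE)
    }
    if (!all(vapply(entries, inherits, TRUE, "schedule_spec"))) {
      stop("every schedule map entry must be a schedule_spec", call. = FALSE)
    }
    names(entries) <- toupper(names(entries))
  }
  structure(list(entries = entries, default = default),
            class = "rfid_schedule_map")
}

#' Resolve the schedule for an RFID tag
#'
#' @param tag 12-character hexadecimal RFID tag.
#' @param map An [rfid_schedule_map()].
#' @return The mapped [schedule_spec()], or the map's default when the tag
#'   is not bound to a schedule.
#' @export
resolve_schedule <- function(tag, map) {
  stopifnot(inherits(map, "rfid_schedule_map"))
  if (!isTRUE(validate_tag(tag))) {
    stop("tag must be a 12-character hexadecimal string", call. = FALSE)
  }
  map$entries[[toupper(tag)]] %||% map$default
}
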