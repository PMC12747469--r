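## Remote-representation event detection.
##
## Every time the posterior updates, the most recent dt_event of decoded
## activity is averaged and renormalised; an event fires when, jointly,
## (1) more than target_frac of the averaged distribution lies in the target
## region, (2) less than offtarget_frac lies in the off-target region, (3) the
## animal is within center_radius_cm of the central box, and (4) at least
## min_active_groups electrode groups showed spatially specific spiking in the
## window. Comparisons are strict as stated (greater than 40%, less than 20%).

#' Event-detection configuration
#'
#' @param target_bins,offtarget_bins Disjoint 0-based bin index sets.
#' @param dt_event_ms Trailing window of decoded activity in ms (default 36).
#' @param dt_ms Decoder time-bin size in ms (default 6); `dt_event_ms/dt_ms`
#'   posteriors are averaged.
#' @param target_frac Minimum target-region mass, strict (default 0.40).
#' @param offtarget_frac Maximum off-target mass, strict (default 0.20).
#' @param center_radius_cm Maximum distance of the animal from the central box
#'   (default 17).
#' @param min_active_groups Minimum electrode groups with spatially specific
#'   activity in the window (default 2).
#' @param refractory_s Suppression period after a trigger (default 3).
#' @param specificity_frac A group's spike is spatially specific when more
#'   than this fraction of its JMI mass lies in target plus off-target bins
#'   (default 0.5).
#' @return An `event_config`.
#' @export
event_config <- function(target_bins, offtarget_bins, dt_event_ms = 36,
                         dt_ms = 6, target_frac = 0.40, offtarget_frac = 0.20,
                         center_radius_cm = 17, min_active_groups = 2,
                         refractory_s = 3, specificity_frac = 0.5) {
  target_bins <- as.integer(target_bins); offtarget_bins <- as.integer(offtarget_bins)
  if (length(intersect(target_bins, offtarget_bins)))
    stop("configuration error: target and off-target bin sets overlap")
  if (!(target_frac > 0 && target_frac <= 1)) stop("target_frac must be in (0, 1]")
  if (dt_event_ms < dt_ms) stop("dt_event_ms must be >= dt_ms")
  structure(list(target_bins = target_bins, offtarget_bins = offtarget_bins,
                 dt_event_ms = dt_event_ms, dt_ms = dt_ms,
                 n_window = as.integer(round(dt_event_ms / dt_ms)),
                 target_frac = target_frac, offtarget_frac = offtarget_frac,
                 center_radius_cm = center_radius_cm,
                 min_active_groups = as.integer(min_active_groups),
                 refractory_s = refractory_s,
                 specificity_frac = specificity_frac),
            class = "event_config")
}

#' Average the most recent window of posteriors
#'
#' @param recent_posteriors Matrix with one posterior per row (oldest first)
#'   or list of vectors; only the last `dt_event_ms/dt_ms` rows are used.
#' @param config An [event_config()].
#' @return Averaged distribution renormalised to sum to 1, or `NULL` when
#'   fewer than `dt_event_ms/dt_ms` posteriors are available.
#' @export
window_average <- function(recent_posteriors, config) {
  if (is.list(recent_posteriors))
    recent_posteriors <- do.call(rbind, recent_posteriors)
  k <- config$n_window
  if (nrow(recent_posteriors) < k) return(NULL)
  m <- colMeans(recent_posteriors[(nrow(recent_posteriors) - k + 1):nrow(recent_posteriors), ,
                                  drop = FALSE])
  m / sum(m)
}

#' Posterior mass in the target and off-target regions
#'
#' @param distribution Normalised distribution over bins.
#' @param config An [event_config()].
#' @return `c(target_fraction, offtarget_fraction)`.
#' @export
region_fractions <- function(distribution, config) {
  c(target_fraction = sum(distribution[config$target_bins + 1L]),
    offtarget_fraction = sum(distribution[config$offtarget_bins + 1L]))
}

#' Evaluate the remote-representation rule for one update
#'
#' All four gates must pass: `target_fraction > target_frac`,
#' `offtarget_fraction < offtarget_frac`, `animal_distance_cm <=
#' center_radius_cm`, and `n_active_groups >= min_active_groups`.
#'
#' @param averaged Averaged distribution from [window_average()].
#' @param animal_distance_cm Distance of the animal from the central box, cm.
#' @param n_active_groups Electrode groups with spatially specific activity in
#'   the window.
#' @param config An [event_config()].
#' @param trigger_timestamp Tick timestamp recorded on the event.
#' @return A `representation_event` list, or `NULL` when any gate fails.
#' @export
evaluate_event <- function(averaged, animal_distance_cm, n_active_groups,
                           config, trigger_timestamp = NA_real_) {
  fr <- region_fractions(averaged, config)
  if (!(fr[["target_fraction"]] > config$target_frac)) return(NULL)
  if (!(fr[["offtarget_fraction"]] < config$offtarget_frac)) return(NULL)
  if (!(animal_distance_cm <= config$center_radius_cm)) return(NULL)
  if (!(n_active_groups >= config$min_active_groups)) return(NULL)
  structure(list(trigger_timestamp = trigger_timestamp,
                 target_fraction = fr[["target_fraction"]],
                 offtarget_fraction = fr[["offtarget_fraction"]],
                 animal_distance_cm = animal_distance_cm,
                 n_active_groups = n_active_groups),
            class = "representation_event")
}

#' Is a spike's JMI spatially specific to the task arms?
#'
#' @param jmi JMI vector over bins for one spike.
#' @param config An [event_config()].
#' @return `TRUE` when more than `specificity_frac` of the JMI mass lies in
#'   target plus off-target bins.
#' @export
jmi_is_specific <- function(jmi, config) {
  tot <- sum(jmi)
  if (tot <= 0) return(FALSE)
  sum(jmi[c(config$target_bins, config$offtarget_bins) + 1L]) / tot >
    config$specificity_frac
}

#' Stateful event gate with refractory suppression
#'
#' Wraps [evaluate_event()] so that after a trigger, further triggers are
#' suppressed for `refractory_s`.
#'
#' @param config An [event_config()].
#' @return An `event_gate`; call [gate_evaluate()] on it per update.
#' @export
event_gate <- function(config) {
  g <- new.env(parent = emptyenv())
  g$config <- config
  g$last_trigger_s <- -Inf
  class(g) <- "event_gate"
  g
}

#' @rdname event_gate
#' @param gate An [event_gate()].
#' @param t_s Current time in seconds.
#' @inheritParams evaluate_event
#' @export
gate_evaluate <- function(gate, averaged, animal_distance_cm, n_active_groups,
                          t_s, trigger_timestamp = NA_real_) {
  if (t_s - gate$last_trigger_s < gate$config$refractory_s) return(NULL)
  ev <- evaluate_event(averaged, animal_distance_cm, n_active_groups,
                       gate$config, trigger_timestamp)
  if (!is.null(ev)) gate$last_trigger_s <- t_s
  ev
}
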