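# The twelve per-cycle joint-angle parameters and their aggregation.

PARAMETER_NAMES <- c(
  "ankle_peak_dorsiflexion", "ankle_peak_plantarflexion", "ankle_excursion",
  "knee_stance_peak_flexion", "knee_stance_peak_extension",
  "knee_stance_excursion",
  "knee_swing_peak_flexion", "knee_swing_peak_extension",
  "knee_swing_excursion",
  "hip_peak_flexion", "hip_peak_extension", "hip_excursion"
)

#' Extract the twelve joint-angle parameters from one normalized cycle
#'
#' Given the three 101-point cycle-normalized waveforms (signed degrees,
#' flexion/dorsiflexion positive) and the stance-phase share of the cycle:
#' ankle and hip peaks/excursions are taken over the whole cycle, knee
#' parameters separately over the stance slice (0% up to and including
#' toe-off) and the swing slice (after toe-off to 100%). Peaks in the
#' extension/plantarflexion direction are reported as positive magnitudes
#' of the most-extended (minimum) value; excursions are max minus min
#' within the phase, hence always nonnegative.
#'
#' @param normalized Named list with 101-point numeric vectors `hip`,
#'   `knee`, `ankle`.
#' @param stance_pct Stance duration as percent of the cycle, in (0, 100).
#' @return Named numeric vector of the 12 parameters, degrees.
#' @examples
#' w <- sin(2 * pi * seq(0, 1, length.out = 101))
#' extract_parameters(list(hip = w, knee = w * 0, ankle = 10 * w), 60)
#' @export
extract_parameters <- function(normalized, stance_pct) {
  stopifnot(all(c("hip", "knee", "ankle") %in% names(normalized)))
  lens <- vapply(normalized[c("hip", "knee", "ankle")], length, 1L)
  if (any(lens != 101L)) stop("normalized waveforms must have 101 points")
  if (!is.finite(stance_pct) || stance_pct <= 0 || stance_pct >= 100) {
    stop("stance_pct must lie in (0, 100)")
  }
  grid <- 0:100
  stance <- grid <= stance_pct + 1e-9  # guard the boundary grid point
  if (!any(stance) || all(stance)) stop("empty phase slice")
  hip <- normalized$hip
  knee <- normalized$knee
  ankle <- normalized$ankle
  if (anyNA(hip) || anyNA(knee) || anyNA(ankle)) {
    stop("normalized waveforms must be complete")
  }
  ks <- knee[stance]
  kw <- knee[!stance]
  c(
    ankle_peak_dorsiflexion = max(ankle),
    ankle_peak_plantarflexion = abs(min(ankle)),
    ankle_excursion = max(ankle) - min(ankle),
    knee_stance_peak_flexion = max(ks),
    knee_stance_peak_extension = abs(min(ks)),
    knee_stance_excursion = max(ks) - min(ks),
    knee_swing_peak_flexion = max(kw),
    knee_swing_peak_extension = abs(min(kw)),
    knee_swing_excursion = max(kw) - min(kw),
    hip_peak_flexion = max(hip),
    hip_peak_extension = abs(min(hip)),
    hip_excursion = max(hip) - min(hip)
  )
}

#' Aggregate a parameter table to per-participant means
#'
#' Averages trial values within each participant x side x source x
#' parameter cell (a participant's trials enter with equal weight) and
#' records how many trials contributed, so partially excluded participants
#' stay identifiable.
#'
#' @param table data.frame with columns `participant`, `trial`, `side`,
#'   `source`, `parameter`, `value`.
#' @return data.frame with columns `participant`, `side`, `source`,
#'   `parameter`, `value` (mean) and `n_trials`.
#' @export
aggregate_parameters <- function(table) {
  need <- c("participant", "trial", "side", "source", "parameter", "value")
  missing <- setdiff(need, names(table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  agg <- stats::aggregate(
    value ~ participant + side + source + parameter, data = table,
    FUN = mean)
  cnt <- stats::aggregate(
    trial ~ participant + side + source + parameter, data = table,
    FUN = function(z) length(unique(z)))
  names(cnt)[names(cnt) == "trial"] <- "n_trials"
  merge(agg, cnt,
        by = c("participant", "side", "source", "parameter"))
}
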