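#' Protocol specification for a simulated in-laboratory experiment
#'
#' Describes either a 40-hour extended-wake (constant-routine) experiment with
#' bi-hourly sampling, or a 3-day matched-control protocol with a nightly
#' 8-hour sleep interval and pre/post-sleep sampling blocks.
#'
#' @param protocol_kind `"sleep_deprivation"` or `"matched_control"`.
#' @param n_participants number of participants (>= 1).
#' @param sample_times_tsw scheduled sampling times in hours since wake for the
#'   extended-wake protocol; default bi-hourly 2..38 h (19 time points).
#' @param control_days which protocol days the matched control samples
#'   (default days 2 and 3, the constant-posture days).
#' @param control_day_times within-day sampling hours since wake for the
#'   matched control; default covers the 2--6 h and 12--16 h blocks used by
#'   the recovery analysis.
#' @param missing_sample_rate fraction of scheduled samples not collected
#'   (dropped completely at random as a fixed count); in `[0, 1)`.
#' @param seed integer seed controlling the experiment draw.
#' @return a `protocol_spec` list.
#' @export
protocol_spec <- function(protocol_kind = c("sleep_deprivation", "matched_control"),
                          n_participants,
                          sample_times_tsw = seq(2, 38, by = 2),
                          control_days = 2:3,
                          control_day_times = c(2, 4, 6, 12, 14, 16),
                          missing_sample_rate = 0,
                          seed = 1L) {
  protocol_kind <- match.arg(protocol_kind)
  if (n_participants < 1) stop("n_participants must be >= 1")
  if (any(diff(sample_times_tsw) <= 0)) {
    stop("sample_times_tsw must be strictly increasing")
  }
  if (any(sample_times_tsw < 0) || any(control_day_times < 0)) {
    stop("sampling times must be >= 0")
  }
  if (missing_sample_rate < 0 || missing_sample_rate >= 1) {
    stop("missing_sample_rate must be in [0, 1)")
  }
  structure(
    list(protocol_kind = protocol_kind, n_participants = as.integer(n_participants),
         sample_times_tsw = sample_times_tsw, control_days = control_days,
         control_day_times = control_day_times,
         missing_sample_rate = missing_sample_rate, seed = as.integer(seed)),
    class = "protocol_spec"
  )
}

#' Generative specification of a single LC-MS feature's temporal profile
#'
#' Features belong to one of four classes mirroring the trend taxonomy used in
#' characterization: `linear` (homeostatic drift with time awake), `circadian`
#' (24-h cosinor cycling in clock time), `mixed` (both), or `null` (baseline
#' noise only).
#'
#' @param feature_class one of `"linear"`, `"circadian"`, `"mixed"`, `"null"`.
#' @param slope_per_hour signed homeostatic slope, intensity units per hour.
#' @param amplitude cosinor amplitude (>= 0), intensity units.
#' @param acrophase_h cosinor peak time in hours, `[0, 24)`.
#' @param baseline_log_mean,baseline_log_sd natural-log location/scale of the
#'   feature's relative-peak-area baseline.
#' @param noise_sd residual (technical + unmodeled biological) sd, >= 0.
#' @param lod_quantile left-censoring quantile in `[0, 1)`: the fraction of
#'   this feature's generated intensities reported as zero (below detection).
#' @return a `feature_profile_spec` list.
#' @export
feature_profile_spec <- function(feature_class = c("linear", "circadian", "mixed", "null"),
                                 slope_per_hour = 0, amplitude = 0, acrophase_h = 0,
                                 baseline_log_mean = 10, baseline_log_sd = 0.5,
                                 noise_sd = 1, lod_quantile = 0) {
  feature_class <- match.arg(feature_class)
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (lod_quantile < 0 || lod_quantile >= 1) stop("lod_quantile must be in [0, 1)")
  if (feature_class == "null" && (slope_per_hour != 0 || amplitude != 0)) {
    stop("null-class features must have zero slope and amplitude")
  }
  if (feature_class == "linear") amplitude <- 0
  if (feature_class == "circadian") slope_per_hour <- 0
  structure(
    list(feature_class = feature_class, slope_per_hour = slope_per_hour,
         amplitude = amplitude, acrophase_h = acrophase_h %% 24,
         baseline_log_mean = baseline_log_mean, baseline_log_sd = baseline_log_sd,
         noise_sd = noise_sd, lod_quantile = lod_quantile),
    class = "feature_profile_spec"
  )
}

#' Simulate one feature's intensity series
#'
#' Intensity at each sample is
#' `baseline * exp(participant_offset) + slope * tsw + A * cos(2*pi*(clock - acrophase)/24) + noise`,
#' floored at zero. The homeostatic term runs on time since wake (`tsw`,
#' resetting after sleep), the circadian term on clock time, which coincide
#' during uninterrupted extended wake.
#'
#' @param spec a [feature_profile_spec()].
#' @param times sampling times in hours; used for both `tsw` and `clock`
#'   unless overridden.
#' @param participant_offset participant-level log-scale baseline offset.
#' @param tsw,clock optional explicit time-since-wake and clock-time vectors.
#' @return numeric intensity vector (uses the current RNG state for noise).
#' @export
simulate_feature_profile <- function(spec, times, participant_offset = 0,
                                     tsw = times, clock = times) {
  stopifnot(inherits(spec, "feature_profile_spec"))
  if (length(times) == 0) stop("times must be nonempty")
  base <- exp(spec$baseline_log_mean + participant_offset)
  y <- rep(base, length(times))
  if (spec$feature_class %in% c("linear", "mixed")) {
    y <- y + spec$slope_per_hour * tsw
  }
  if (spec$feature_class %in% c("circadian", "mixed")) {
    y <- y + spec$amplitude * cos(2 * pi * (clock - spec$acrophase_h) / 24)
  }
  if (spec$noise_sd > 0) y <- y + stats::rnorm(length(times), 0, spec$noise_sd)
  pmax(y, 0)
}

#' Default effect-size configuration for the feature panel
#'
#' Relative effect sizes (fractions of each feature's baseline) used when
#' drawing a synthetic panel: homeostatic slopes of 1--3% of baseline per
#' hour, circadian amplitudes of 10--30% of baseline, residual noise of 5% of
#' baseline, participant baseline offsets with log-sd 0.3. Censoring is light
#' (quantile 0--0.12) for most features, heavy (0.22--0.40) for
#' `heavy_censor_frac` of them, so that a realistic minority of features
#' exceeds a 20% zero-fraction cleanup threshold.
#'
#' @param rel_slope_range,rel_amp_range,rel_noise_sd,participant_log_sd,
#'   light_censor_range,heavy_censor_range,heavy_censor_frac numeric knobs.
#' @return a list of effect parameters.
#' @export
panel_effect_defaults <- function(rel_slope_range = c(0.01, 0.03),
                                  rel_amp_range = c(0.10, 0.30),
                                  rel_noise_sd = 0.05,
                                  participant_log_sd = 0.3,
                                  light_censor_range = c(0, 0.12),
                                  heavy_censor_range = c(0.22, 0.40),
                                  heavy_censor_frac = 0.10) {
  list(rel_slope_range = rel_slope_range, rel_amp_range = rel_amp_range,
       rel_noise_sd = rel_noise_sd, participant_log_sd = participant_log_sd,
       light_censor_range = light_censor_range,
       heavy_censor_range = heavy_censor_range,
       heavy_censor_frac = heavy_censor_frac)
}

#' Draw a reusable panel of feature generative parameters
#'
#' The panel fixes each feature's class and effect sizes so that several
#' experiments (training, testing, matched control) share the same underlying
#' biology while differing in participants, noise, and missingness.
#'
#' @param class_counts named counts for classes `linear`, `circadian`,
#'   `mixed`, `null`; defaults follow 2% / 25% / 5% / 68% of 1000 features.
#' @param effects see [panel_effect_defaults()].
#' @param baseline_log_mean,baseline_log_sd baseline log-normal parameters.
#' @param seed integer seed for the panel draw.
#' @return data.frame, one row per feature: id, class, baseline, slope,
#'   amplitude, acrophase, noise sd, censoring quantile.
#' @export
make_feature_panel <- function(class_counts = c(linear = 20, circadian = 250,
                                                mixed = 50, null = 680),
                               effects = panel_effect_defaults(),
                               baseline_log_mean = 10, baseline_log_sd = 0.5,
                               seed = 1L) {
  if (sum(class_counts) < 1) stop("class_counts must total >= 1")
  bad <- setdiff(names(class_counts), c("linear", "circadian", "mixed", "null"))
  if (length(bad)) stop("unknown feature class(es): ", paste(bad, collapse = ", "))
  set.seed(seed)
  classes <- rep(names(class_counts), class_counts)
  p <- length(classes)
  baseline <- exp(stats::rnorm(p, baseline_log_mean, baseline_log_sd))
  has_lin <- classes %in% c("linear", "mixed")
  has_cyc <- classes %in% c("circadian", "mixed")
  slope <- ifelse(has_lin,
                  sample(c(-1, 1), p, replace = TRUE) *
                    stats::runif(p, effects$rel_slope_range[1], effects$rel_slope_range[2]) *
                    baseline,
                  0)
  amplitude <- ifelse(has_cyc,
                      stats::runif(p, effects$rel_amp_range[1], effects$rel_amp_range[2]) *
                        baseline,
                      0)
  acrophase <- stats::runif(p, 0, 24)
  noise_sd <- effects$rel_noise_sd * baseline
  heavy <- stats::runif(p) < effects$heavy_censor_frac
  lod_q <- ifelse(heavy,
                  stats::runif(p, effects$heavy_censor_range[1], effects$heavy_censor_range[2]),
                  stats::runif(p, effects$light_censor_range[1], effects$light_censor_range[2]))
  data.frame(
    feature_id = sprintf("F%04d", seq_len(p)),
    true_class = classes,
    baseline = baseline,
    slope = slope,
    amplitude = amplitude,
    acrophase_h = acrophase,
    noise_sd = noise_sd,
    lod_quantile = lod_q,
    participant_log_sd = effects$participant_log_sd,
    stringsAsFactors = FALSE
  )
}

# Core sample-level generator shared by both protocols. `grid` holds one row
# per scheduled sample with participant index, tsw and clock time.
simulate_from_grid <- function(panel, grid, experiment_id, protocol_kind,
                               missing_rate, seed, scale_factor = 1) {
  set.seed(seed)
  n_part <- length(unique(grid$participant))
  offsets <- stats::rnorm(n_part, 0, panel$participant_log_sd[1])
  n <- nrow(grid)
  p <- nrow(panel)
  Y <- matrix(0, n, p)
  part_idx <- match(grid$participant, sort(unique(grid$participant)))
  base_part <- exp(outer(offsets[part_idx], log(panel$baseline), `+`))
  lin <- outer(grid$tsw, panel$slope)
  phase <- outer(panel$acrophase_h, grid$clock, function(a, t) t - a) # p x n
  cyc <- t(panel$amplitude * cos(2 * pi * phase / 24))                # n x p
  noise <- matrix(stats::rnorm(n * p), n, p) * rep(panel$noise_sd, each = n)
  Y <- pmax(base_part + lin + cyc + noise, 0) * scale_factor
  # left-censoring at a per-feature empirical quantile
  for (j in seq_len(p)) {
    q <- panel$lod_quantile[j]
    if (q > 0) {
      lod <- stats::quantile(Y[, j], q, names = FALSE)
      Y[Y[, j] < lod, j] <- 0
    }
  }
  # fixed-count completely-at-random dropout of scheduled samples
  keep <- seq_len(n)
  n_drop <- round(missing_rate * n)
  if (n_drop > 0) keep <- sort(sample(seq_len(n), n - n_drop))
  Y <- Y[keep, , drop = FALSE]
  grid <- grid[keep, , drop = FALSE]
  sm <- data.frame(
    sample_id = sprintf("%s_%s_t%05.1f_d%d", experiment_id, grid$participant,
                        grid$tsw, grid$day),
    participant_id = grid$participant,
    experiment_id = experiment_id,
    tsw_hours = grid$tsw,
    day_index = grid$day,
    protocol_kind = protocol_kind,
    clock_h = grid$clock,
    stringsAsFactors = FALSE
  )
  feature_table(Y, sm, panel)
}

#' Generate a synthetic 40-hour sleep-deprivation experiment
#'
#' One scheduled sample per (participant, time-since-wake) pair at the
#' protocol's bi-hourly grid, minus completely-at-random dropouts. During
#' uninterrupted extended wake, clock time equals time since wake (wake times
#' are aligned under the constant routine), so homeostatic and circadian
#' terms share the time axis.
#'
#' @param panel feature panel from [make_feature_panel()].
#' @param protocol a [protocol_spec()] with kind `"sleep_deprivation"`.
#' @param experiment_id label written into the sample metadata.
#' @param scale_factor scalar per-experiment intensity scale (technical batch
#'   difference between independently run LC-MS experiments).
#' @return a [feature_table()] with generative truth in `feature_meta`.
#' @export
generate_sleep_dep_experiment <- function(panel, protocol,
                                          experiment_id = "exp1",
                                          scale_factor = 1) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (protocol$protocol_kind != "sleep_deprivation") {
    stop("protocol_kind must be sleep_deprivation")
  }
  participants <- sprintf("P%02d", seq_len(protocol$n_participants))
  grid <- expand.grid(tsw = protocol$sample_times_tsw, participant = participants,
                      stringsAsFactors = FALSE)
  grid$clock <- grid$tsw
  grid$day <- 1L + as.integer(grid$tsw >= 24)
  simulate_from_grid(panel, grid, experiment_id, "sleep_deprivation",
                     protocol$missing_sample_rate, protocol$seed, scale_factor)
}

#' Generate a synthetic matched-control (constant-posture) experiment
#'
#' Participants keep an 8 h : 16 h sleep/wake schedule; on each sampled day
#' the homeostatic (linear) term restarts from zero at wake while circadian
#' features continue uninterrupted in clock time. Sampling covers the
#' pre/post-sleep blocks (2--6 h and 12--16 h since wake each day) used by the
#' recovery analysis.
#'
#' @inheritParams generate_sleep_dep_experiment
#' @param protocol a [protocol_spec()] with kind `"matched_control"`.
#' @return a [feature_table()].
#' @export
generate_matched_control <- function(panel, protocol, experiment_id = "ctrl",
                                     scale_factor = 1) {
  stopifnot(inherits(protocol, "protocol_spec"))
  if (protocol$protocol_kind != "matched_control") {
    stop("protocol_kind must be matched_control")
  }
  participants <- sprintf("C%02d", seq_len(protocol$n_participants))
  grid <- expand.grid(tsw = protocol$control_day_times,
                      day = as.integer(protocol$control_days),
                      participant = participants, stringsAsFactors = FALSE)
  grid$clock <- (grid$day - 1) * 24 + grid$tsw
  simulate_from_grid(panel, grid, experiment_id, "matched_control",
                     protocol$missing_sample_rate, protocol$seed, scale_factor)
}
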