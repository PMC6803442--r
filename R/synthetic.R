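# Seeded two-group rest + auditory-oddball EEG simulator. Each subject's
# signal is a sum of narrow-band oscillators whose instantaneous frequency
# performs a mean-reverting (Ornstein-Uhlenbeck) drift inside the band,
# plus 1/f^beta background noise; the task adds per-trial post-onset
# modulations of trial-noise SD (variability quench/enhancement),
# oscillator frequency (frequency sliding) and power (power sliding), a
# common damped-oscillation evoked response, and deviant reaction times
# coupled to the variability modulation.

canonical_bands <- list(theta = c(4, 8), alpha = c(7, 13))

#' Oscillator specification
#'
#' Generative counterpart of the resting-state measures: `mean_pf` is the
#' target mean peak frequency, `pf_wander_sd` the stationary SD of the
#' mean-reverting instantaneous-frequency drift (drives the CV), and
#' `amplitude` the oscillation amplitude (drives band power).
#'
#' @param band_name `"theta"` (4-8 Hz) or `"alpha"` (7-13 Hz).
#' @param mean_pf Mean peak frequency in Hz; must lie inside the band.
#' @param pf_wander_sd Stationary SD of the frequency drift in Hz (>= 0).
#' @param reversion_rate Drift mean-reversion rate in 1/s.
#' @param amplitude Oscillation amplitude in microvolts (>= 0).
#' @return A list of class `oscillator_spec`.
#' @export
oscillator_spec <- function(band_name, mean_pf, pf_wander_sd,
                            reversion_rate = 2, amplitude = 5) {
  band_name <- match.arg(band_name, names(canonical_bands))
  band <- canonical_bands[[band_name]]
  if (mean_pf <= band[1L] || mean_pf >= band[2L]) {
    stop("`mean_pf` must lie inside the ", band_name, " band (",
         band[1L], "-", band[2L], " Hz)", call. = FALSE)
  }
  if (pf_wander_sd < 0) stop("`pf_wander_sd` must be >= 0", call. = FALSE)
  if (amplitude < 0) stop("`amplitude` must be >= 0", call. = FALSE)
  if (reversion_rate <= 0) stop("`reversion_rate` must be > 0", call. = FALSE)
  structure(list(band_name = band_name, band = band, mean_pf = mean_pf,
                 pf_wander_sd = pf_wander_sd,
                 reversion_rate = reversion_rate, amplitude = amplitude),
            class = "oscillator_spec")
}

#' Subject-level generative configuration
#'
#' @param group Group label, `"MDD"` or `"CON"`.
#' @param theta,alpha [oscillator_spec()] objects for the two bands.
#' @param noise_amplitude SD of the 1/f^beta background noise in
#'   microvolts.
#' @param noise_exponent Spectral slope beta of the background noise.
#' @param quench Named vector (standard/deviant/novel) of fractional
#'   post-onset change of the trial-noise SD; values must be > -1.
#'   Negative values quench variability, positive values enhance it.
#' @param fs_shift Named list per band of named vectors per condition:
#'   fractional post-onset peak-frequency shift, peaking inside that
#'   band's FS AUC window.
#' @param ps_shift As `fs_shift` but a fractional post-onset power shift,
#'   peaking inside the band's PS AUC window.
#' @param evoked_amplitude Amplitude (uV) of the common damped-oscillation
#'   evoked response added to every trial.
#' @param rt_base Baseline reaction time in ms (> 0).
#' @param rt_coupling Reaction-time gain in ms per unit of
#'   `|quench["deviant"]|`; larger variability modulation speeds responses.
#' @param rt_noise_sd Trial-level reaction-time noise SD in ms.
#' @return A list of class `subject_config`.
#' @export
subject_config <- function(group = c("CON", "MDD"),
                           theta = oscillator_spec("theta", 5.7, 0.50,
                                                   amplitude = 6),
                           alpha = oscillator_spec("alpha", 10.4, 0.30,
                                                   amplitude = 6),
                           noise_amplitude = 4.5,
                           noise_exponent = 1,
                           quench = c(standard = 0.2, deviant = 0.7,
                                      novel = 0.2),
                           fs_shift = list(
                             theta = c(standard = 0.02, deviant = 0.02,
                                       novel = 0.02),
                             alpha = c(standard = 0.02, deviant = 0.02,
                                       novel = 0.02)),
                           ps_shift = list(
                             theta = c(standard = 0.30, deviant = 0.20,
                                       novel = 0.20),
                             alpha = c(standard = 0.15, deviant = 0.20,
                                       novel = 0.20)),
                           evoked_amplitude = 1.5,
                           rt_base = 500, rt_coupling = 300,
                           rt_noise_sd = 50) {
  group <- match.arg(group)
  stopifnot(inherits(theta, "oscillator_spec"),
            inherits(alpha, "oscillator_spec"))
  if (any(quench <= -1)) {
    stop("`quench` values must be > -1 (SD cannot go negative)",
         call. = FALSE)
  }
  if (!all(c("standard", "deviant", "novel") %in% names(quench))) {
    stop("`quench` needs standard, deviant and novel entries", call. = FALSE)
  }
  if (rt_base <= 0) stop("`rt_base` must be > 0", call. = FALSE)
  if (noise_amplitude < 0) stop("`noise_amplitude` must be >= 0",
                                call. = FALSE)
  structure(list(group = group, theta = theta, alpha = alpha,
                 noise_amplitude = noise_amplitude,
                 noise_exponent = noise_exponent,
                 quench = quench, fs_shift = fs_shift, ps_shift = ps_shift,
                 evoked_amplitude = evoked_amplitude,
                 rt_base = rt_base, rt_coupling = rt_coupling,
                 rt_noise_sd = rt_noise_sd),
            class = "subject_config")
}

#' Cohort / session configuration
#'
#' Defaults reproduce the recording session the analysis assumes: 500 Hz
#' sampling, 3-min eyes-closed rest, 800 tones at 80/10/10
#' standard/deviant/novel proportions, 336-ms tones separated by a 1-s
#' fixation interval.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param fs Sampling rate, Hz.
#' @param rest_duration Rest length in seconds.
#' @param n_trials Number of task tones.
#' @param proportions Named fractions (standard, deviant, novel) summing
#'   to 1; each times `n_trials` must be a whole number.
#' @param tone_duration Tone length, ms.
#' @param iti Inter-stimulus interval, ms.
#' @param seed Integer master seed for the cohort.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 25L, fs = 500, rest_duration = 180,
                          n_trials = 800L,
                          proportions = c(standard = 0.8, deviant = 0.1,
                                          novel = 0.1),
                          tone_duration = 336, iti = 1000, seed = 1L) {
  if (n_per_group < 2L) {
    stop("`n_per_group` must be >= 2 (group SDs undefined otherwise)",
         call. = FALSE)
  }
  if (fs <= 0 || rest_duration <= 0) {
    stop("`fs` and `rest_duration` must be positive", call. = FALSE)
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("`proportions` must sum to 1", call. = FALSE)
  }
  counts <- proportions * n_trials
  if (any(abs(counts - round(counts)) > 1e-9)) {
    stop("each proportion times `n_trials` must be an integer",
         call. = FALSE)
  }
  structure(list(n_per_group = as.integer(n_per_group), fs = fs,
                 rest_duration = rest_duration,
                 n_trials = as.integer(n_trials),
                 proportions = proportions, tone_duration = tone_duration,
                 iti = iti, seed = as.integer(seed)),
            class = "cohort_config")
}

# --- signal building blocks -------------------------------------------------

# Exact AR(1) discretization of an OU process with stationary SD `sd`,
# reversion rate lambda (1/s), mean mu; clipped to `band`.
ou_frequency_series <- function(n, fs, spec) {
  a <- exp(-spec$reversion_rate / fs)
  f <- numeric(n)
  if (spec$pf_wander_sd == 0) {
    f[] <- spec$mean_pf
    return(f)
  }
  eps_sd <- spec$pf_wander_sd * sqrt(1 - a^2)
  dev0 <- stats::rnorm(1L, 0, spec$pf_wander_sd)
  innov <- stats::rnorm(n, 0, eps_sd)
  dev <- stats::filter(innov, a, method = "recursive", init = dev0)
  f <- spec$mean_pf + c(dev0, dev[-n])
  pmin(pmax(f, spec$band[1L]), spec$band[2L])
}

# 1/f^beta noise via spectral shaping of white noise, standardized to `sd`.
pink_noise <- function(n, fs, beta, sd) {
  if (sd == 0) return(numeric(n))
  w <- stats::rnorm(n)
  sp <- stats::fft(w)
  freq <- c(1, seq_len(n - 1L)) * fs / n          # guard DC
  freq <- pmin(freq, fs - freq + fs / n)          # mirror for neg freqs
  sp <- sp * freq^(-beta / 2)
  sp[1L] <- 0
  x <- Re(stats::fft(sp, inverse = TRUE)) / n
  x / stats::sd(x) * sd
}

# Damped evoked oscillation: latency `lat` s, decay constant `tau` s,
# carrier 10 Hz; returns a waveform over `n` post-onset samples.
evoked_waveform <- function(n, fs, amplitude, lat = 0.1, tau = 0.2) {
  t <- (seq_len(n) - 1L) / fs
  out <- numeric(n)
  on <- t >= lat
  out[on] <- amplitude * exp(-(t[on] - lat) / tau) *
    cos(2 * pi * 10 * (t[on] - lat))
  out
}

# Linear ramp 0-100 ms, sustained to 500 ms, released 500-600 ms.
quench_ramp <- function(n, fs) {
  t <- (seq_len(n) - 1L) / fs * 1000
  up <- pmin(1, t / 100)
  down <- pmax(0, pmin(1, (600 - t) / 100))
  ifelse(t <= 500, up, down)
}

# Gaussian bump (unit peak) centered at `center_ms` with SD `sd_ms`.
gaussian_bump <- function(n, fs, center_ms, sd_ms = 50) {
  t <- (seq_len(n) - 1L) / fs * 1000
  exp(-0.5 * ((t - center_ms) / sd_ms)^2)
}

# Post-onset modulation centers: midpoints of the fixed FS/PS AUC windows.
shift_centers <- list(
  theta = c(fs = 450, ps = 216),
  alpha = c(fs = 426, ps = 200)
)

# Fixed scalp projection of the two oscillators onto the two channels.
channel_weights <- matrix(c(1.0, 0.3,   # theta -> Fz, Pz
                            0.3, 1.0),  # alpha -> Fz, Pz
                          nrow = 2L, byrow = TRUE,
                          dimnames = list(c("theta", "alpha"), c("Fz", "Pz")))

# --- generators -------------------------------------------------------------

#' Simulate a resting-state recording for one subject
#'
#' Sum of the subject's theta and alpha oscillators (phase integrated from
#' the drifting instantaneous frequency) and 1/f^beta noise, projected on
#' channels Fz and Pz. Bit-identical output for identical `(subject,
#' duration, fs, seed)`.
#'
#' @param subject A [subject_config()].
#' @param duration Length in seconds.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed.
#' @return An [eeg_recording] with channels Fz and Pz.
#' @export
simulate_resting <- function(subject, duration, fs, seed) {
  stopifnot(inherits(subject, "subject_config"))
  if (duration <= 0 || fs <= 0) {
    stop("`duration` and `fs` must be positive", call. = FALSE)
  }
  n <- round(duration * fs)
  withr::with_seed(as.integer(seed), {
    osc <- lapply(c(theta = "theta", alpha = "alpha"), function(b) {
      spec <- subject[[b]]
      f <- ou_frequency_series(n, fs, spec)
      phase0 <- stats::runif(1L, 0, 2 * pi)
      spec$amplitude * cos(phase0 + 2 * pi * cumsum(f) / fs)
    })
    noise <- list(Fz = pink_noise(n, fs, subject$noise_exponent,
                                  subject$noise_amplitude),
                  Pz = pink_noise(n, fs, subject$noise_exponent,
                                  subject$noise_amplitude))
    data <- rbind(
      Fz = channel_weights["theta", "Fz"] * osc$theta +
        channel_weights["alpha", "Fz"] * osc$alpha + noise$Fz,
      Pz = channel_weights["theta", "Pz"] * osc$theta +
        channel_weights["alpha", "Pz"] * osc$alpha + noise$Pz
    )
    eeg_recording(data, fs, c("Fz", "Pz"))
  })
}

#' Simulate an oddball-task recording for one subject
#'
#' A continuous recording containing `n_trials` tones whose condition
#' labels honor the configured proportions in a seeded shuffled order.
#' After each onset: trial-noise SD is scaled by `1 + quench[condition]`
#' over a 0-100 ms ramp sustained to 500 ms; oscillator instantaneous
#' frequency and power are scaled by the band/condition `fs_shift` /
#' `ps_shift` with Gaussian time courses peaking inside the fixed AUC
#' windows; and a common damped-oscillation evoked response is added
#' (novel trials get a per-trial randomized evoked latency). Reaction
#' times are generated for deviant trials only:
#' `rt = rt_base - rt_coupling * |quench["deviant"]| + noise`.
#'
#' @param subject A [subject_config()].
#' @param cohort A [cohort_config()].
#' @param seed Integer seed.
#' @return List with `recording` ([eeg_recording]), `events` (tibble:
#'   `onset_sample`, `label`, `rt_ms`), and `reaction_times` (deviant
#'   RTs, ms).
#' @export
simulate_task <- function(subject, cohort, seed) {
  stopifnot(inherits(subject, "subject_config"),
            inherits(cohort, "cohort_config"))
  fs <- cohort$fs
  n_trials <- cohort$n_trials
  period <- round((cohort$tone_duration + cohort$iti) * fs / 1000)
  lead <- round(fs)                       # 1 s margin before first tone
  tail <- round(fs)
  n <- lead + n_trials * period + tail
  mod_len <- min(period, round(0.7 * fs)) # post-onset modulation support

  withr::with_seed(as.integer(seed), {
    counts <- round(cohort$proportions * n_trials)
    labels <- sample(rep(names(counts), counts))
    onsets <- lead + (seq_len(n_trials) - 1L) * period + 1L

    ramp <- quench_ramp(mod_len, fs)
    bumps <- lapply(shift_centers, function(cc) list(
      fs = gaussian_bump(mod_len, fs, cc[["fs"]]),
      ps = gaussian_bump(mod_len, fs, cc[["ps"]])
    ))

    # per-sample modulation tracks
    noise_gain <- rep(1, n)
    freq_gain <- list(theta = rep(1, n), alpha = rep(1, n))
    amp_gain <- list(theta = rep(1, n), alpha = rep(1, n))
    evoked <- numeric(n)
    base_evoked <- evoked_waveform(mod_len, fs, subject$evoked_amplitude)
    for (i in seq_len(n_trials)) {
      idx <- onsets[i]:(onsets[i] + mod_len - 1L)
      cond <- labels[i]
      noise_gain[idx] <- noise_gain[idx] + subject$quench[[cond]] * ramp
      for (b in c("theta", "alpha")) {
        freq_gain[[b]][idx] <- freq_gain[[b]][idx] +
          subject$fs_shift[[b]][[cond]] * bumps[[b]]$fs
        pgain <- 1 + subject$ps_shift[[b]][[cond]] * bumps[[b]]$ps
        amp_gain[[b]][idx] <- amp_gain[[b]][idx] * sqrt(pmax(0, pgain))
      }
      if (cond == "novel") {
        lat <- stats::runif(1L, 0.05, 0.15)
        evoked[idx] <- evoked[idx] +
          evoked_waveform(mod_len, fs, subject$evoked_amplitude, lat = lat)
      } else {
        evoked[idx] <- evoked[idx] + base_evoked
      }
    }

    osc <- lapply(c(theta = "theta", alpha = "alpha"), function(b) {
      spec <- subject[[b]]
      f <- ou_frequency_series(n, fs, spec) * freq_gain[[b]]
      phase0 <- stats::runif(1L, 0, 2 * pi)
      spec$amplitude * amp_gain[[b]] * cos(phase0 + 2 * pi * cumsum(f) / fs)
    })
    noise <- list(
      Fz = pink_noise(n, fs, subject$noise_exponent,
                      subject$noise_amplitude) * noise_gain,
      Pz = pink_noise(n, fs, subject$noise_exponent,
                      subject$noise_amplitude) * noise_gain
    )
    data <- rbind(
      Fz = channel_weights["theta", "Fz"] * osc$theta +
        channel_weights["alpha", "Fz"] * osc$alpha + noise$Fz + evoked,
      Pz = channel_weights["theta", "Pz"] * osc$theta +
        channel_weights["alpha", "Pz"] * osc$alpha + noise$Pz + evoked
    )

    is_dev <- labels == "deviant"
    rt <- rep(NA_real_, n_trials)
    rt[is_dev] <- pmax(
      100,
      subject$rt_base -
        subject$rt_coupling * abs(subject$quench[["deviant"]]) +
        stats::rnorm(sum(is_dev), 0, subject$rt_noise_sd)
    )
    list(
      recording = eeg_recording(data, fs, c("Fz", "Pz")),
      events = tibble::tibble(onset_sample = onsets, label = labels,
                              rt_ms = rt),
      reaction_times = rt[is_dev]
    )
  })
}

# Multiplicative 5% jitter helper; `z` optional shared latent factor.
jitter_value <- function(x, rel_sd = 0.05, z = NULL) {
  z <- if (is.null(z)) stats::rnorm(length(x)) else z
  x * (1 + rel_sd * z)
}

# Draw one subject's config from a template with seeded between-subject
# jitter (5% relative SD on all continuous parameters). When
# `coupling` > 0, a shared latent factor links theta-band frequency wander
# (the resting CV) to the deviant variability modulation.
jitter_subject <- function(template, seed, rel_sd = 0.05, coupling = 0) {
  withr::with_seed(as.integer(seed), {
    z_shared <- stats::rnorm(1L)
    mix <- function(z) coupling * z_shared + sqrt(1 - coupling^2) * z
    osc <- function(spec, wander_z = NULL) {
      oscillator_spec(
        spec$band_name,
        mean_pf = min(spec$band[2L] - 1e-6,
                      max(spec$band[1L] + 1e-6, jitter_value(spec$mean_pf, rel_sd))),
        pf_wander_sd = abs(jitter_value(
          spec$pf_wander_sd, rel_sd,
          z = if (is.null(wander_z)) stats::rnorm(1L) else wander_z)),
        reversion_rate = spec$reversion_rate,
        amplitude = abs(jitter_value(spec$amplitude, rel_sd))
      )
    }
    q <- template$quench
    q[["deviant"]] <- sign(q[["deviant"]]) *
      abs(jitter_value(abs(q[["deviant"]]), rel_sd, z = mix(stats::rnorm(1L))))
    q[c("standard", "novel")] <- sign(q[c("standard", "novel")]) *
      abs(jitter_value(abs(q[c("standard", "novel")]), rel_sd))
    subject_config(
      group = template$group,
      theta = osc(template$theta, wander_z = mix(stats::rnorm(1L))),
      alpha = osc(template$alpha),
      noise_amplitude = abs(jitter_value(template$noise_amplitude, rel_sd)),
      noise_exponent = template$noise_exponent,
      quench = q,
      fs_shift = template$fs_shift,
      ps_shift = template$ps_shift,
      evoked_amplitude = template$evoked_amplitude,
      rt_base = abs(jitter_value(template$rt_base, rel_sd)),
      rt_coupling = template$rt_coupling,
      rt_noise_sd = template$rt_noise_sd
    )
  })
}

#' Default group templates
#'
#' `template_con()` is the reference healthy-control generative setting.
#' `template_mdd()` encodes the depression-group effect directions the
#' analysis is designed to detect: higher theta peak frequency with lower
#' wander (CV) and lower amplitude; lower alpha peak frequency with higher
#' wander and lower amplitude; a smaller deviant-specific variability
#' modulation; and larger relative alpha-band sliding responses. Effect
#' magnitudes are simulator choices (directions, not sizes, are the
#' constrained quantities). `template_null()` equals the control template
#' (used for false-positive-rate checks).
#'
#' @return A [subject_config()].
#' @export
template_con <- function() {
  subject_config(
    group = "CON",
    theta = oscillator_spec("theta", 5.7, 0.50, amplitude = 6),
    alpha = oscillator_spec("alpha", 10.4, 0.30, amplitude = 6),
    quench = c(standard = 0.2, deviant = 0.7, novel = 0.2),
    fs_shift = list(theta = c(standard = 0.02, deviant = 0.02, novel = 0.02),
                    alpha = c(standard = 0.02, deviant = 0.02, novel = 0.02)),
    ps_shift = list(theta = c(standard = 0.30, deviant = 0.20, novel = 0.20),
                    alpha = c(standard = 0.15, deviant = 0.20, novel = 0.20))
  )
}

#' @rdname template_con
#' @export
template_mdd <- function() {
  subject_config(
    group = "MDD",
    theta = oscillator_spec("theta", 6.3, 0.20, amplitude = 5),
    alpha = oscillator_spec("alpha", 9.6, 0.50, amplitude = 5),
    quench = c(standard = 0.2, deviant = 0.1, novel = 0.2),
    fs_shift = list(theta = c(standard = 0.02, deviant = 0.02, novel = 0.02),
                    alpha = c(standard = 0.02, deviant = 0.05, novel = 0.02)),
    ps_shift = list(theta = c(standard = 0.10, deviant = 0.60, novel = 0.20),
                    alpha = c(standard = 0.40, deviant = 0.50, novel = 0.20))
  )
}

#' @rdname template_con
#' @export
template_null <- function() {
  t <- template_con()
  t$group <- "MDD"
  t
}

#' Simulate a two-group cohort
#'
#' Draws `n_per_group` subjects per group from the two templates with
#' seeded 5% between-subject parameter jitter, and generates rest and
#' task data for each. Fully deterministic given `(config, templates)`.
#'
#' @param config A [cohort_config()]; its `seed` drives everything.
#' @param mdd_template,con_template [subject_config()] templates; group
#'   labels are taken as MDD and CON respectively.
#' @param rest_task_coupling In \[0, 1\]: strength of a shared
#'   between-subject latent factor linking theta frequency wander (rest
#'   CV) and the deviant variability modulation (0 = independent).
#' @param jitter_sd Relative SD of the between-subject parameter jitter
#'   (default 0.05).
#' @return An `eeg_cohort` object: per-subject list entries (`id`,
#'   `group`, `config`, `rest`, `task`, `events`, `reaction_times`) and a
#'   `manifest` sufficient to regenerate the cohort bit-identically.
#' @export
simulate_cohort <- function(config,
                            mdd_template = template_mdd(),
                            con_template = template_con(),
                            rest_task_coupling = 0,
                            jitter_sd = 0.05) {
  stopifnot(inherits(config, "cohort_config"))
  templates <- list(MDD = mdd_template, CON = con_template)
  templates$MDD$group <- "MDD"
  templates$CON$group <- "CON"
  subjects <- list()
  for (gi in seq_along(templates)) {
    g <- names(templates)[gi]
    for (i in seq_len(config$n_per_group)) {
      sub_seed <- derive_seed(config$seed, gi, i)
      cfg <- jitter_subject(templates[[g]], sub_seed, rel_sd = jitter_sd,
                            coupling = rest_task_coupling)
      rest <- simulate_resting(cfg, config$rest_duration, config$fs,
                               derive_seed(sub_seed, 1L))
      task <- simulate_task(cfg, config, derive_seed(sub_seed, 2L))
      subjects[[length(subjects) + 1L]] <- list(
        id = sprintf("%s_%02d", g, i), group = g, config = cfg,
        rest = rest, task = task$recording, events = task$events,
        reaction_times = task$reaction_times
      )
    }
  }
  structure(
    list(subjects = subjects, config = config,
         manifest = cohort_manifest(config, templates$MDD, templates$CON,
                                    rest_task_coupling, jitter_sd)),
    class = "eeg_cohort"
  )
}

#' @export
print.eeg_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, `[[`, character(1L), "group"))
  cat("<eeg_cohort>", paste(sprintf("%s: %d", names(groups), groups),
                            collapse = ", "), "\n")
  cat(sprintf("rest %.0f s, %d trials @ %g Hz, seed %d\n",
              x$config$rest_duration, x$config$n_trials, x$config$fs,
              x$config$seed))
  invisible(x)
}

# Serializable description of how the cohort was generated. Named atomic
# vectors become named lists so JSON keeps their names.
cohort_manifest <- function(config, mdd_template, con_template, coupling,
                            jitter_sd) {
  strip <- function(x) {
    x <- unclass(x)
    x$theta <- unclass(x$theta)
    x$alpha <- unclass(x$alpha)
    x$quench <- as.list(x$quench)
    x$fs_shift <- lapply(x$fs_shift, as.list)
    x$ps_shift <- lapply(x$ps_shift, as.list)
    x
  }
  cc <- unclass(config)
  cc$proportions <- as.list(cc$proportions)
  list(
    generator = "eegdyn::simulate_cohort",
    cohort_config = cc,
    mdd_template = strip(mdd_template),
    con_template = strip(con_template),
    rest_task_coupling = coupling,
    jitter_sd = jitter_sd
  )
}

# Rebuild a cohort from its manifest (used for byte-identical replay).
cohort_from_manifest <- function(manifest) {
  cc <- manifest$cohort_config
  props <- unlist(cc$proportions)
  config <- cohort_config(cc$n_per_group, cc$fs, cc$rest_duration,
                          cc$n_trials, props, cc$tone_duration, cc$iti,
                          cc$seed)
  rebuild <- function(tpl) {
    mk_osc <- function(o) oscillator_spec(o$band_name, o$mean_pf,
                                          o$pf_wander_sd, o$reversion_rate,
                                          o$amplitude)
    subject_config(
      group = tpl$group,
      theta = mk_osc(tpl$theta), alpha = mk_osc(tpl$alpha),
      noise_amplitude = tpl$noise_amplitude,
      noise_exponent = tpl$noise_exponent,
      quench = unlist(tpl$quench),
      fs_shift = lapply(tpl$fs_shift, unlist),
      ps_shift = lapply(tpl$ps_shift, unlist),
      evoked_amplitude = tpl$evoked_amplitude,
      rt_base = tpl$rt_base, rt_coupling = tpl$rt_coupling,
      rt_noise_sd = tpl$rt_noise_sd
    )
  }
  simulate_cohort(config,
                  mdd_template = rebuild(manifest$mdd_template),
                  con_template = rebuild(manifest$con_template),
                  rest_task_coupling = manifest$rest_task_coupling,
                  jitter_sd = manifest$jitter_sd %||% 0.05)
}
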