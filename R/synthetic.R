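# Coupled-oscillator surrogate cohorts. Each channel carries one narrowband
# oscillation per band realized as a phase random walk around the band's
# center frequency (pure sinusoids would make every phase statistic
# degenerate); hubs inject their oscillation into target channels at a fixed
# nonzero lag (delay-and-add, giving direct control of the planted lag); a
# zero-lag common source mimics volume conduction; 1/f noise is the
# background. All randomness flows through one R RNG substream per subject,
# derived deterministically from (cohort seed, group, subject index), so
# cohorts are reproducible and unchanged subjects keep their data when the
# cohort grows.

#' Specify a planted hub
#'
#' @param electrode hub channel name (must be in the montage, and not among
#'   its own targets).
#' @param band band name (one of [band_specs()]).
#' @param targets channels receiving the hub's lagged oscillation.
#' @param coupling strength in \[0, 1]: the target's band component becomes
#'   `sqrt(1 - c^2) * own + c * lagged hub copy` (variance-preserving).
#' @param lag phase offset in radians. Must not be 0 or pi (mod 2*pi) when
#'   coupling > 0: such coupling is invisible to the PLI by construction,
#'   which the generator can plant deliberately only via the common source.
#' @return A `hub_spec` list.
#' @export
hub_spec <- function(electrode, band, targets, coupling, lag = pi / 4) {
  if (electrode %in% targets) stop("hub electrode cannot be its own target")
  if (coupling < 0 || coupling > 1) stop("coupling must lie in [0, 1]")
  lr <- lag %% (2 * pi)
  if (coupling > 0 && (min(lr, 2 * pi - lr) < 1e-9 || abs(lr - pi) < 1e-9)) {
    stop("lag of 0 or pi is invisible to PLI; choose a nonzero-lag offset")
  }
  structure(list(electrode = electrode, band = band,
                 targets = as.character(targets),
                 coupling = coupling, lag = lag), class = "hub_spec")
}

#' Default planted hub contrasts
#'
#' Both groups share hubs at (Fz, beta), (Pz, gamma) and (O1, gamma);
#' patients get weaker frontal-beta and parietal-gamma coupling and stronger
#' occipital-gamma coupling. This is the default recovery scenario: a BC
#' decrease at Fz in beta, a decrease at Pz in gamma, and an increase at O1
#' in gamma.
#'
#' @param strength overall coupling scale in (0, 1]; 1 is the calibrated
#'   strong-coupling default.
#' @return Named list of `hub_spec` lists, one per group.
#' @export
default_hub_contrasts <- function(strength = 1) {
  fz_t <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4")
  pz_t <- c("C3", "C4", "P3", "P4", "T5", "T6")
  o1_t <- c("O2", "P3", "T5")
  mk <- function(c_fz, c_pz, c_o1) {
    list(hub_spec("Fz", "beta", fz_t, strength * c_fz),
         hub_spec("Pz", "gamma", pz_t, strength * c_pz),
         hub_spec("O1", "gamma", o1_t, strength * c_o1))
  }
  list(control = mk(0.80, 0.80, 0.15),
       patient = mk(0.35, 0.35, 0.60))
}

#' Cohort simulation settings
#'
#' Defaults mirror the emulated study: 16-channel 10-20 montage, 200 Hz,
#' 600-s records, 31 controls and 21 patients, and BPRS scores with mean
#' 52.6 and SD 13.2 for patients. `bprs_model$rho` sets the target
#' correlation between the score and each subject's latent coupling
#' strength (0 by default: the study found no significant BC-symptom
#' correlation).
#'
#' @param n_per_group named integer vector `c(control = , patient = )`.
#' @param duration_s record length in seconds (>= 10, i.e. two 5-s epochs).
#' @param fs sampling rate in Hz.
#' @param hubs_by_group named list of `hub_spec` lists per group.
#' @param common_source_gain amplitude multiplier of the zero-lag common
#'   source added identically to all channels (volume-conduction surrogate).
#' @param noise_gain standard deviation, in microvolts, of the 1/f
#'   background noise per channel.
#' @param bprs_model list with `mean`, `sd`, `rho`.
#' @param coupling_sd between-subject SD of planted coupling strengths.
#' @param band_amplitude named vector of oscillation amplitudes in
#'   microvolts (alpha-dominant resting profile).
#' @param linewidth_frac phase-diffusion linewidth as a fraction of each
#'   band's width; controls epoch-to-epoch variability.
#' @param seed integer cohort seed (< 2^31).
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_per_group = c(control = 31, patient = 21),
                          duration_s = 600, fs = 200,
                          hubs_by_group = default_hub_contrasts(),
                          common_source_gain = 1, noise_gain = 5,
                          bprs_model = list(mean = 52.6, sd = 13.2, rho = 0),
                          coupling_sd = 0.05,
                          band_amplitude = c(delta = 10, theta = 8,
                                             alpha = 15, beta = 6,
                                             gamma = 3),
                          linewidth_frac = 0.25, seed = 1) {
  if (duration_s < 10) stop("duration_s must be >= 10 (two 5-s epochs)")
  if (common_source_gain < 0 || noise_gain < 0 || coupling_sd < 0) {
    stop("gains must be nonnegative")
  }
  if (is.null(names(n_per_group))) names(n_per_group) <- c("control", "patient")
  stopifnot(all(names(n_per_group) %in% c("control", "patient")))
  stopifnot(all(names(hubs_by_group) %in% c("control", "patient")))
  # coerce plain lists (e.g. from YAML configs) into validated hub_specs
  hubs_by_group <- lapply(hubs_by_group, function(hl) {
    lapply(hl, function(h) {
      if (inherits(h, "hub_spec")) h
      else hub_spec(h$electrode, h$band, h$targets, h$coupling,
                    if (is.null(h$lag)) pi / 4 else h$lag)
    })
  })
  structure(list(n_per_group = n_per_group, duration_s = duration_s,
                 fs = fs, hubs_by_group = hubs_by_group,
                 common_source_gain = common_source_gain,
                 noise_gain = noise_gain, bprs_model = bprs_model,
                 coupling_sd = coupling_sd, band_amplitude = band_amplitude,
                 linewidth_frac = linewidth_frac, seed = as.integer(seed)),
            class = "cohort_config")
}

# deterministic per-subject seed; independent of cohort size
subject_seed <- function(seed, group, index, session = "pre") {
  g <- switch(group, control = 11L, patient = 23L)
  s <- switch(session, pre = 0L, post = 1L, none = 0L)
  as.integer((as.double(seed) * 7919 + g * 104729 + s * 15485863 +
                index * 130363) %% 2147483647)
}

band_sigma <- function(band, linewidth_frac, fs) {
  sqrt(2 * pi * linewidth_frac * (band$high_hz - band$low_hz) / fs)
}

#' Generate one surrogate subject
#'
#' The recording is the sum of (a) per-band phase-random-walk oscillations
#' with independent phase noise per channel, (b) hub injections for this
#' group's `hub_spec`s at their specified lag and coupling, (c) a zero-lag
#' common source scaled by `common_source_gain`, and (d) 1/f noise scaled by
#' `noise_gain`. Deterministic given `(config$seed, group, index, session)`.
#'
#' @param config a [cohort_config()].
#' @param group "control" or "patient".
#' @param index subject index within the group (drives the RNG substream).
#' @param session "pre" or "post" (distinct substreams for paired designs).
#' @param coupling_scale multiplier applied to all planted couplings (used
#'   to inject treatment effects in paired designs).
#' @return List with `recording` (an [eeg_recording()]), `z` (the subject's
#'   latent coupling score), and `couplings` (realized strengths per hub).
#' @export
generate_subject <- function(config, group = "control", index = 1,
                             session = "pre", coupling_scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  mont <- default_montage()
  labs <- as.character(mont)
  n <- round(config$duration_s * config$fs)
  C <- length(mont)
  bands <- band_specs()
  hubs <- config$hubs_by_group[[group]]
  if (is.null(hubs)) hubs <- list()
  for (h in hubs) {
    if (!h$electrode %in% labs) {
      stop("hub electrode not in montage: ", h$electrode)
    }
    if (!all(h$targets %in% labs)) stop("hub target not in montage")
    if (!h$band %in% names(bands)) stop("unknown band: ", h$band)
  }
  seed_i <- subject_seed(config$seed, group, index, session)
  old <- globalenv()$.Random.seed
  set.seed(seed_i)
  z <- rnorm(1)                      # latent coupling strength
  bprs_noise <- rnorm(1)
  age <- round(runif(1, 20, 55))
  couplings <- vapply(hubs, function(h) {
    min(max(coupling_scale * h$coupling + config$coupling_sd * z, 0), 0.98)
  }, 0)
  # phase-diffusion steps are drawn per 5-sample block (25 ms), which leaves
  # the Lorentzian linewidth unchanged when the step SD is divided by
  # sqrt(block)
  block <- 5L
  nb <- ceiling(n / block)
  X <- matrix(0, n, C)
  for (b in names(bands)) {
    bh <- hubs[vapply(hubs, function(h) h$band == b, TRUE)]
    hub_idx <- vapply(bh, function(h) match(h$electrode, labs) - 1L, 1L)
    tgt <- lapply(bh, function(h) as.integer(match(h$targets, labs) - 1L))
    cpl <- couplings[vapply(hubs, function(h) h$band == b, TRUE)]
    lag <- vapply(bh, function(h) h$lag, 0)
    incr <- matrix(rnorm(nb * C), nb, C)
    theta0 <- runif(C, -pi, pi)
    sig <- band_sigma(bands[[b]], config$linewidth_frac, config$fs) /
      sqrt(block)
    Xb <- cpp_synth_band(incr, sig,
                         (bands[[b]]$low_hz + bands[[b]]$high_hz) / 2,
                         config$fs, theta0,
                         as.integer(hub_idx), as.numeric(cpl),
                         as.numeric(lag), tgt, as.integer(n), block)
    X <- X + config$band_amplitude[[b]] * Xb
  }
  if (config$common_source_gain > 0) {
    s <- numeric(n)
    for (b in names(bands)) {
      sig <- band_sigma(bands[[b]], config$linewidth_frac, config$fs) /
        sqrt(block)
      sb <- cpp_synth_band(matrix(rnorm(nb), nb, 1), sig,
                           (bands[[b]]$low_hz + bands[[b]]$high_hz) / 2,
                           config$fs, runif(1, -pi, pi),
                           integer(0), numeric(0), numeric(0), list(),
                           as.integer(n), block)
      s <- s + 0.5 * config$band_amplitude[[b]] * sb[, 1]
    }
    X <- X + config$common_source_gain * s  # recycled down all columns
  }
  if (config$noise_gain > 0) {
    X <- X + config$noise_gain * cpp_pink_noise(matrix(rnorm(n * C), n, C),
                                                config$fs, 1)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  id <- sprintf("%s%03d%s", switch(group, control = "hc", patient = "sz"),
                index, if (session == "post") "b" else "")
  list(recording = eeg_recording(t(X), fs = config$fs, montage = mont,
                                 subject_id = id),
       z = z, bprs_noise = bprs_noise, age = age, couplings = couplings)
}

#' Generate a full two-group cohort
#'
#' `n_per_group` subjects per group; patients receive BPRS scores drawn as
#' `mean + sd * (rho * z + sqrt(1 - rho^2) * e)` with `z` the subject's
#' latent coupling score, so `cor(BPRS, coupling)` approaches
#' `bprs_model$rho`. Fully reproducible from `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return List with `recordings` (list of [eeg_recording()]) and `meta`
#'   (a [subject_meta()] data.frame, plus hidden column `z`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  recs <- list(); rows <- list()
  for (g in names(config$n_per_group)) {
    ng <- config$n_per_group[[g]]
    for (i in seq_len(ng)) {
      s <- generate_subject(config, group = g, index = i)
      recs[[s$recording$subject_id]] <- s$recording
      bm <- config$bprs_model
      bprs <- if (g == "patient") {
        max(0, bm$mean + bm$sd * (bm$rho * s$z +
                                    sqrt(max(0, 1 - bm$rho^2)) * s$bprs_noise))
      } else NA_real_
      rows[[s$recording$subject_id]] <-
        data.frame(subject_id = s$recording$subject_id, group = g,
                   session = if (g == "patient") "pre" else "none",
                   bprs = bprs, age = s$age, z = s$z)
    }
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  z <- meta$z
  meta <- subject_meta(meta)
  meta$z <- z
  list(recordings = recs, meta = meta)
}

#' Generate a paired pre/post-treatment patient cohort
#'
#' Patients are generated twice from session-specific RNG substreams that
#' share the subject's latent coupling score; post-treatment couplings are
#' scaled by `post_coupling_scale` (1 = no treatment effect on connectivity,
#' the study's reported outcome). Post BPRS drops by a N(13, 16.3^2)
#' improvement, matching the reported completer means (56.2 pre, 43.2 post,
#' paired t with 13 df).
#'
#' @param config a [cohort_config()]; only the patient group is used.
#' @param n number of completers (default 14).
#' @param post_coupling_scale multiplier on planted couplings post
#'   treatment.
#' @return List with `pre`, `post` (lists of recordings) and `meta`.
#' @export
generate_prepost_cohort <- function(config, n = 14,
                                    post_coupling_scale = 1) {
  stopifnot(inherits(config, "cohort_config"))
  pre <- list(); post <- list(); rows <- list()
  for (i in seq_len(n)) {
    sp <- generate_subject(config, "patient", i, session = "pre")
    sq <- generate_subject(config, "patient", i, session = "post",
                           coupling_scale = post_coupling_scale)
    pre[[sp$recording$subject_id]] <- sp$recording
    post[[sp$recording$subject_id]] <- sq$recording
    set.seed(subject_seed(config$seed, "patient", i, "post") + 1L)
    bprs_pre <- max(0, 56.2 + 13.2 * sp$bprs_noise)
    bprs_post <- max(0, bprs_pre - rnorm(1, 13.0, 16.3))
    rows[[i]] <- data.frame(subject_id = sp$recording$subject_id,
                            group = "patient", session = "pre",
                            bprs = bprs_pre, age = sp$age)
    rows[[n + i]] <- data.frame(subject_id = sp$recording$subject_id,
                                group = "patient", session = "post",
                                bprs = bprs_post, age = sp$age)
  }
  meta <- subject_meta(do.call(rbind, rows))
  list(pre = pre, post = post, meta = meta)
}
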