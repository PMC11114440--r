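test_that("hub specifications reject degenerate coupling geometry", {
  expect_error(hub_spec("Fz", "beta", c("Fz", "F3"), 0.5), "own target")
  expect_error(hub_spec("Fz", "beta", "F3", 1.2), "0, 1")
  expect_error(hub_spec("Fz", "beta", "F3", 0.5, lag = 0), "invisible")
  expect_error(hub_spec("Fz", "beta", "F3", 0.5, lag = pi), "invisible")
  expect_error(hub_spec("Fz", "beta", "F3", 0.5, lag = 2 * pi), "invisible")
  expect_silent(hub_spec("Fz", "beta", "F3", 0, lag = 0))  # inert hub
  expect_error(cohort_config(duration_s = 5), "two 5-s epochs")
  expect_error(cohort_config(noise_gain = -1), "nonnegative")
  bad <- cohort_config(hubs_by_group = list(
    control = list(hub_spec("Zz9", "beta", "F3", 0.5))), duration_s = 20)
  expect_error(generate_subject(bad, "control", 1), "not in montage")
})

test_that("cohorts are bit-identical under a fixed seed", {
  cfg <- tiny_config(seed = 21)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1$meta, c2$meta)
  for (id in names(c1$recordings)) {
    expect_identical(c1$recordings[[id]]$data, c2$recordings[[id]]$data)
  }
  # a different seed gives different data
  c3 <- generate_cohort(tiny_config(seed = 22))
  expect_gt(max(abs(c3$recordings[[1]]$data - c1$recordings[[1]]$data)), 1)
})

test_that("default cohort matches the emulated study layout", {
  cfg <- cohort_config()
  expect_identical(unname(cfg$n_per_group), c(31, 21))
  expect_equal(cfg$duration_s, 600)
  expect_equal(cfg$fs, 200)
  # count subjects without synthesizing 600-s signals
  cfg2 <- tiny_config()
  cfg2$n_per_group <- c(control = 4, patient = 3)
  co <- generate_cohort(cfg2)
  expect_length(co$recordings, 7)
  expect_equal(sum(co$meta$group == "control"), 4)
  expect_equal(sum(co$meta$group == "patient"), 3)
  expect_true(all(is.na(co$meta$bprs[co$meta$group == "control"])))
  expect_true(all(co$meta$bprs[co$meta$group == "patient"] >= 0))
})

test_that("full-strength fixed-lag coupling yields PLI near 1 at targets", {
  # single beta hub, all 15 targets, coupling 1, lag pi/4, no noise and
  # negligible other-band activity: each target carries an exact
  # quarter-pi-lagged copy of the hub oscillation
  targets <- setdiff(as.character(default_montage()), "Fz")
  cfg <- cohort_config(
    n_per_group = c(control = 1, patient = 1), duration_s = 30,
    hubs_by_group = list(control = list(
      hub_spec("Fz", "beta", targets, coupling = 1, lag = pi / 4))),
    common_source_gain = 0, noise_gain = 0, coupling_sd = 0,
    band_amplitude = c(delta = 0.05, theta = 0.05, alpha = 0.05,
                       beta = 10, gamma = 0.05),
    seed = 23)
  s <- generate_subject(cfg, "control", 1)
  sh <- subject_hub_profiles(s$recording)
  expect_gt(min(sh$conn$beta["Fz", targets]), 0.97)
  # with realistic multi-band amplitudes, leakage from neighboring bands
  # lowers the estimate but the coupled pairs still dominate clearly
  cfg$band_amplitude <- cohort_config(duration_s = 30)$band_amplitude
  s2 <- generate_subject(cfg, "control", 1)
  sh2 <- subject_hub_profiles(s2$recording)
  expect_gt(min(sh2$conn$beta["Fz", targets]), 0.4)
})

# single-epoch PLI of independent channels shrinks toward 0 with record
# length (the per-epoch |mean sign| over short 5-s epochs instead retains a
# positive floor, which is why the emulated protocol balances epoch length)
test_that("independent channels decorrelate: long-epoch PLI tends to zero", {
  one_epoch_pli <- function(dur, seed) {
    cfg <- cohort_config(n_per_group = c(control = 1, patient = 1),
                         duration_s = dur,
                         hubs_by_group = list(control = list()),
                         common_source_gain = 0, seed = seed)
    s <- generate_subject(cfg, "control", 1)
    filt <- apply_filter(s$recording,
                         design_bandpass(band_specs()$alpha, 200, 4000))
    pe <- instantaneous_phase(segment_epochs(filt, epoch_len_s = dur,
                                             drop_edges = FALSE))
    m <- subject_connectivity(pe)
    max(m[upper.tri(m)])
  }
  p60 <- one_epoch_pli(60, 24)
  p600 <- one_epoch_pli(600, 24)
  expect_lt(p600, 0.08)
  expect_lt(p600, p60)
})

test_that("a strong zero-lag common source does not create PLI", {
  mk <- function(gain, seed) {
    cfg <- cohort_config(n_per_group = c(control = 1, patient = 1),
                         duration_s = 60,
                         hubs_by_group = list(control = list()),
                         common_source_gain = gain, noise_gain = 1,
                         seed = seed)
    generate_subject(cfg, "control", 1)$recording
  }
  rec0 <- mk(0, 25); rec8 <- mk(8, 25)
  # gain 8: channels become strongly amplitude-correlated ...
  cors <- cor(t(rec8$data))
  expect_gt(mean(cors[upper.tri(cors)]), 0.8)
  sh0 <- subject_hub_profiles(rec0)
  sh8 <- subject_hub_profiles(rec8)
  for (b in names(sh8$conn)) {
    # ... yet the PLI distribution is no higher than without the source
    expect_lt(mean(sh8$conn[[b]][upper.tri(sh8$conn[[b]])]),
              mean(sh0$conn[[b]][upper.tri(sh0$conn[[b]])]) + 0.05)
  }
  # high-frequency bands, whose phases mix fast, sit well below the
  # volume-conduction-free reporting threshold
  expect_lt(max(sh8$conn$gamma[upper.tri(sh8$conn$gamma)]), 0.15)
})

test_that("BPRS correlation with latent coupling follows the model", {
  cfg <- tiny_config(seed = 29)
  cfg$n_per_group <- c(control = 0, patient = 21)
  co <- generate_cohort(cfg)
  pat <- co$meta$group == "patient"
  r0 <- cor(co$meta$bprs[pat], co$meta$z[pat])
  expect_lt(abs(r0), 0.3)              # rho = 0: within sampling error at n=21
  cfg2 <- cohort_config(n_per_group = c(control = 0, patient = 60),
                        duration_s = 20, seed = 27,
                        bprs_model = list(mean = 52.6, sd = 13.2, rho = 0.7))
  co2 <- generate_cohort(cfg2)
  r1 <- cor(co2$meta$bprs, co2$meta$z)
  expect_gt(r1, 0.45)
})

test_that("pre/post cohorts share subjects and report BPRS improvement", {
  cfg <- tiny_config(seed = 28)
  pp <- generate_prepost_cohort(cfg, n = 14)
  expect_identical(names(pp$pre), names(pp$post))
  expect_length(pp$pre, 14)
  # same subject latent, different session noise
  expect_gt(max(abs(pp$pre[[1]]$data - pp$post[[1]]$data)), 1)
  pre <- pp$meta$bprs[pp$meta$session == "pre"]
  post <- pp$meta$bprs[pp$meta$session == "post"]
  expect_equal(length(pre), 14)
  expect_gt(mean(pre) - mean(post), 0)  # scores improve on average
})
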