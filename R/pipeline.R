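# End-to-end orchestration: simulate/load -> filter -> epoch -> phase ->
# PLI -> betweenness -> group statistics, with every intermediate artifact
# persisted as delimited text so any stage can be re-run in isolation.

#' Analysis settings
#'
#' @param filter_order FIR order per band (default 4000).
#' @param epoch_len_s epoch length in seconds (default 5).
#' @param drop_edge_epochs exclude the first and last epoch (default TRUE).
#' @param notch apply a 58-62 Hz band-stop before band filtering (default
#'   FALSE; synthetic data carries no mains interference).
#' @param bc_per_epoch compute BC per epoch and average the BC values,
#'   instead of the default epoch-averaged PLI matrix -> one BC (the
#'   conventional reading).
#' @param alpha ANOVA significance level.
#' @param q_threshold FDR level for post hoc families.
#' @param gate_interaction_fdr gate post hoc tests on the interaction
#'   p-values BH-corrected across the five bands (the group main effect is
#'   gated at its raw level).
#' @param top_fraction edge fraction for [top_edges()] reporting.
#' @return named list of settings.
#' @export
analysis_options <- function(filter_order = 4000, epoch_len_s = 5,
                             drop_edge_epochs = TRUE, notch = FALSE,
                             bc_per_epoch = FALSE, alpha = 0.05,
                             q_threshold = 0.05,
                             gate_interaction_fdr = TRUE,
                             top_fraction = 0.2) {
  list(filter_order = filter_order, epoch_len_s = epoch_len_s,
       drop_edge_epochs = drop_edge_epochs, notch = notch,
       bc_per_epoch = bc_per_epoch, alpha = alpha,
       q_threshold = q_threshold,
       gate_interaction_fdr = gate_interaction_fdr,
       top_fraction = top_fraction)
}

#' Per-band connectivity and hub profile of one subject
#'
#' Runs the per-subject chain: (optional notch), per-band FIR filtering
#' with a shared forward transform, 5-s epoching with edge-epoch exclusion,
#' per-epoch Hilbert phases, PLI averaging, inverse-PLI graph, normalized
#' betweenness.
#'
#' @param rec an [eeg_recording()].
#' @param bands named list of [band_spec()]s.
#' @param opts an [analysis_options()] list.
#' @return list with `conn` (named list of [connectivity_matrix()]), `bc`
#'   (bands x electrodes matrix), `n_epochs`.
#' @export
subject_hub_profiles <- function(rec, bands = band_specs(),
                                 opts = analysis_options()) {
  # sample-major fast path, numerically identical to the public chain
  # apply_filter_bank -> segment_epochs -> instantaneous_phase ->
  # subject_connectivity -> betweenness_profile (asserted in the tests)
  labs <- as.character(rec$montage)
  Xs <- t(rec$data)
  n <- nrow(Xs)
  L <- opts$filter_order + 1
  if (n <= L) {
    stop("record (", n, " samples) must be longer than the filter (",
         L, " taps)")
  }
  delay <- opts$filter_order %/% 2
  pad <- choose_fft_pad(n, delay)
  if (isTRUE(opts$notch)) {
    hn <- design_bandstop(fs = rec$fs, order = opts$filter_order)
    Hn <- filter_bank_responses(list(as.numeric(hn)), n + 2 * pad)
    Xs <- cpp_filter_bank(Xs, Hn, pad, delay)[[1]]
  }
  filters <- lapply(bands, design_bandpass, fs = rec$fs,
                    order = opts$filter_order)
  H <- filter_bank_responses(lapply(filters, as.numeric), n + 2 * pad)
  Ys <- cpp_filter_bank(Xs, H, pad, delay)
  S <- round(opts$epoch_len_s * rec$fs)
  n_tot <- n %/% S
  need <- if (opts$drop_edge_epochs) 3L else 1L
  if (n_tot < need) {
    stop("record too short: ", n_tot, " whole epoch(s), need >= ", need)
  }
  keep <- if (opts$drop_edge_epochs) seq.int(2L, n_tot - 1L) else
    seq_len(n_tot)
  offsets <- as.integer((keep - 1L) * S)
  conn <- list()
  bc <- matrix(NA_real_, length(bands), length(labs),
               dimnames = list(names(bands), labs))
  for (i in seq_along(bands)) {
    b <- names(bands)[i]
    Y <- Ys[[i]]
    # all-zero epoch check (phase undefined)
    ep_id <- integer(n)
    ep_id[rep(offsets, each = S) + seq_len(S)] <- rep(seq_along(offsets),
                                                      each = S)
    en <- rowsum(abs(Y), ep_id)
    if (any(en[rownames(en) != "0", ] == 0)) {
      stop("all-zero epoch in band ", b, " (phase undefined)")
    }
    cube <- cpp_epoch_pli(Y, S, offsets)
    m <- matrix(rowMeans(matrix(cube, ncol = dim(cube)[3])),
                length(labs), length(labs))
    conn[[b]] <- connectivity_matrix(m, labels = labs,
                                     subject_id = rec$subject_id, band = b)
    if (isTRUE(opts$bc_per_epoch)) {
      per <- vapply(seq_len(dim(cube)[3]), function(e) {
        as.numeric(betweenness_profile(connectivity_matrix(
          cube[, , e], labels = labs,
          subject_id = rec$subject_id, band = b)))
      }, numeric(length(labs)))
      bc[b, ] <- rowMeans(per)
    } else {
      bc[b, ] <- as.numeric(betweenness_profile(conn[[b]]))
    }
  }
  list(conn = conn, bc = bc, n_epochs = length(offsets))
}

#' Cohort-level analysis
#'
#' Computes per-subject, per-band PLI matrices and BC profiles, then the
#' statistical layer: per-band mixed RM-ANOVA (group x node), gated post
#' hoc electrode t-tests under BH-FDR, Pearson correlations of flagged BC
#' values against BPRS and age, and per-group top-fraction edge lists.
#'
#' Gating rule: a band enters post hoc testing when its group main effect
#' is significant (Greenhouse-Geisser p < alpha) or its group x node
#' interaction survives BH correction across the five bands
#' (q <= q_threshold); the ANOVA table reports both raw and across-band
#' corrected interaction p-values.
#'
#' @param recordings named list of [eeg_recording()] (pretreatment
#'   sessions).
#' @param meta a [subject_meta()] table covering all recordings.
#' @param bands named list of [band_spec()]s.
#' @param opts an [analysis_options()] list.
#' @param quiet suppress progress messages.
#' @return list with `conn`, `bc` (per-band subjects x electrodes
#'   matrices), `bc_table` (tidy data.frame), `anova`, `posthoc`,
#'   `correlations`, `top_edges`, `gated_bands`, `n_epochs`,
#'   `disconnected` (count of zero-PLI edges seen).
#' @export
analyze_cohort <- function(recordings, meta, bands = band_specs(),
                           opts = analysis_options(), quiet = TRUE) {
  meta <- subject_meta(meta)
  ids <- names(recordings)
  if (is.null(ids)) {
    ids <- vapply(recordings, function(r) r$subject_id, "")
    names(recordings) <- ids
  }
  if (!all(ids %in% meta$subject_id)) {
    stop("metadata missing for subject(s): ",
         paste(setdiff(ids, meta$subject_id), collapse = ", "))
  }
  meta <- meta[match(ids, meta$subject_id), ]
  labs <- as.character(recordings[[1]]$montage)
  conn <- list()
  bc <- lapply(setNames(names(bands), names(bands)), function(b) {
    matrix(NA_real_, length(ids), length(labs),
           dimnames = list(ids, labs))
  })
  n_ep <- NA_integer_; disconnected <- 0L
  for (id in ids) {
    sh <- tryCatch(
      subject_hub_profiles(recordings[[id]], bands, opts),
      error = function(e) {
        stop("stage connectivity/BC failed for subject ", id, ": ",
             conditionMessage(e))
      })
    conn[[id]] <- sh$conn
    n_ep <- sh$n_epochs
    for (b in names(bands)) bc[[b]][id, ] <- sh$bc[b, ]
    disconnected <- disconnected +
      sum(vapply(sh$conn, function(m) sum(m[upper.tri(m)] == 0), 0L))
    if (!quiet) message("  subject ", id, ": ", sh$n_epochs,
                        " epochs/band")
  }
  groups <- meta$group
  gs <- gated_group_stats(bc, groups, opts)
  anova <- gs$anova; posthoc <- gs$posthoc; gated <- gs$gated
  correlations <- cohort_correlations(bc, meta, posthoc)
  tops <- do.call(rbind, lapply(names(bands), function(b) {
    do.call(rbind, lapply(levels(groups), function(g) {
      gm <- Reduce(`+`, lapply(ids[groups == g],
                               function(id) unclass(conn[[id]][[b]])))
      gm <- gm / sum(groups == g)
      te <- top_edges(connectivity_matrix(gm, labels = labs,
                                          subject_id = paste0("mean_", g),
                                          band = b), opts$top_fraction)
      cbind(group = g, band = b, te)
    }))
  }))
  list(conn = conn, bc = bc,
       bc_table = bc_long_table(bc, meta),
       anova = anova, posthoc = posthoc, correlations = correlations,
       top_edges = tops, gated_bands = names(bands)[gated],
       n_epochs = n_ep, disconnected = disconnected)
}

#' Gated statistical layer on per-band BC tables
#'
#' Runs the per-band mixed RM-ANOVA, applies the post hoc gating rule (see
#' [analyze_cohort()]), and returns the post hoc electrode tests for the
#' gated bands.
#'
#' @param bc named list (per band) of subjects x electrodes BC matrices.
#' @param groups factor aligned with the matrix rows.
#' @param opts an [analysis_options()] list.
#' @return list with `anova` (with `q_bands` column: interaction p-values
#'   BH-corrected across bands), `gated` (logical per band), `posthoc`.
#' @export
gated_group_stats <- function(bc, groups, opts = analysis_options()) {
  bands <- names(bc)
  anova <- do.call(rbind, lapply(bands, function(b) {
    rm_anova_mixed(bc[[b]], groups, band = b, alpha = opts$alpha)
  }))
  ia <- anova$effect == "group:node"
  anova$q_bands <- NA_real_
  anova$q_bands[ia] <- bh_fdr(anova$p_gg[ia], opts$q_threshold)$q
  gated <- vapply(bands, function(b) {
    rows <- anova[anova$band == b, ]
    grp_sig <- rows$p_gg[rows$effect == "group"] < opts$alpha
    ia_sig <- if (isTRUE(opts$gate_interaction_fdr)) {
      rows$q_bands[rows$effect == "group:node"] <= opts$q_threshold
    } else {
      rows$p_gg[rows$effect == "group:node"] < opts$alpha
    }
    isTRUE(grp_sig) || isTRUE(ia_sig)
  }, TRUE)
  posthoc <- do.call(rbind, lapply(bands[gated], function(b) {
    posthoc_ttests(bc[[b]], groups = groups, gate = TRUE, band = b,
                   q_threshold = opts$q_threshold)
  }))
  if (is.null(posthoc)) {
    posthoc <- data.frame(band = character(), electrode = character(),
                          t = numeric(), df = numeric(), p_raw = numeric(),
                          q_bh = numeric(), significant = logical(),
                          direction = numeric())
  }
  list(anova = anova, gated = gated, posthoc = posthoc)
}

#' Simulate a cohort and compute its per-band BC tables
#'
#' Streaming helper for calibration and power studies: generates each
#' subject, reduces it to its per-band betweenness profile, and discards
#' the raw signal.
#'
#' @param config a [cohort_config()].
#' @param opts an [analysis_options()] list.
#' @return list with `bc` (named list of subjects x electrodes matrices per
#'   band) and `meta`.
#' @export
cohort_bc <- function(config, opts = analysis_options()) {
  labs <- as.character(default_montage())
  bands <- band_specs()
  ids <- character(0); rows <- list()
  bc <- lapply(setNames(names(bands), names(bands)), function(b) {
    matrix(NA_real_, 0, length(labs))
  })
  for (g in names(config$n_per_group)) {
    for (i in seq_len(config$n_per_group[[g]])) {
      s <- generate_subject(config, group = g, index = i)
      sh <- subject_hub_profiles(s$recording, bands, opts)
      ids <- c(ids, s$recording$subject_id)
      for (b in names(bands)) bc[[b]] <- rbind(bc[[b]], sh$bc[b, ])
      bm <- config$bprs_model
      rows[[s$recording$subject_id]] <- data.frame(
        subject_id = s$recording$subject_id, group = g,
        session = if (g == "patient") "pre" else "none",
        bprs = if (g == "patient") {
          max(0, bm$mean + bm$sd * (bm$rho * s$z +
                                      sqrt(max(0, 1 - bm$rho^2)) *
                                        s$bprs_noise))
        } else NA_real_,
        age = s$age, z = s$z)
    }
  }
  for (b in names(bands)) {
    rownames(bc[[b]]) <- ids
    colnames(bc[[b]]) <- labs
  }
  meta <- do.call(rbind, rows)
  rownames(meta) <- NULL
  z <- meta$z
  meta <- subject_meta(meta)
  meta$z <- z
  list(bc = bc, meta = meta)
}

bc_long_table <- function(bc, meta) {
  do.call(rbind, lapply(names(bc), function(b) {
    m <- bc[[b]]
    data.frame(subject_id = rep(rownames(m), times = ncol(m)),
               group = rep(as.character(meta$group), times = ncol(m)),
               band = b,
               electrode = rep(colnames(m), each = nrow(m)),
               bc = as.vector(m))
  }))
}

cohort_correlations <- function(bc, meta, posthoc) {
  sig <- posthoc[posthoc$significant, , drop = FALSE]
  rows <- list()
  pat <- meta$group == "patient" & !is.na(meta$bprs)
  for (i in seq_len(nrow(sig))) {
    b <- sig$band[i]; e <- sig$electrode[i]
    v <- bc[[b]][, e]
    if (sum(pat) >= 3 && sd(v[pat]) > 0 && sd(meta$bprs[pat]) > 0) {
      rows[[length(rows) + 1]] <-
        pearson_corr(v[pat], meta$bprs[pat],
                     label = sprintf("BC@%s-%s vs BPRS", e, b))
    }
    ok_age <- !is.na(meta$age)
    if (sum(ok_age) >= 3 && sd(v[ok_age]) > 0 && sd(meta$age[ok_age]) > 0) {
      rows[[length(rows) + 1]] <-
        pearson_corr(v[ok_age], meta$age[ok_age],
                     label = sprintf("BC@%s-%s vs age", e, b))
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pair = character(), n = integer(), r = numeric(),
                      p = numeric(), significant = logical()))
  }
  do.call(rbind, rows)
}

#' Run the full pipeline from a configuration
#'
#' Stages: simulate (or load EDFs), band filtering, epoching, PLI,
#' betweenness, group statistics. All intermediate artifacts are written
#' under `out_dir` as delimited text keyed by subject, band and electrode,
#' plus a deterministic JSON manifest (config echo, seed, package version,
#' epoch counts); identical config and seed give byte-identical outputs.
#'
#' @param config a run configuration: a list (or YAML/JSON file path) with
#'   elements `seed`, exactly one of `simulate` (fields of
#'   [cohort_config()]) or `input` (list with `dir` containing EDF files
#'   and `meta` CSV path), optional `analysis` ([analysis_options()]
#'   fields), and optional `write_recordings` (persist simulated EDFs).
#' @param out_dir output directory (created if needed).
#' @param quiet suppress progress messages.
#' @return The [analyze_cohort()] result, invisibly, with `out_dir`
#'   attached.
#' @export
run_pipeline <- function(config, out_dir, quiet = TRUE) {
  cfg <- load_run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- cfg$seed
    cc <- do.call(cohort_config, sim_args)
    if (!quiet) message("simulating cohort (seed ", cfg$seed, ")")
    cohort <- tryCatch(generate_cohort(cc), error = function(e) {
      stop("stage simulate failed: ", conditionMessage(e))
    })
    recordings <- cohort$recordings
    meta <- cohort$meta
    if (isTRUE(cfg$write_recordings)) {
      rec_dir <- file.path(out_dir, "recordings")
      dir.create(rec_dir, showWarnings = FALSE)
      for (r in recordings) {
        write_edf(r, file.path(rec_dir, paste0(r$subject_id, ".edf")))
      }
      write_subject_meta(meta, file.path(rec_dir, "metadata.csv"))
    }
  } else if (!is.null(cfg$input)) {
    meta <- read_subject_meta(cfg$input$meta)
    files <- list.files(cfg$input$dir, pattern = "\\.(edf|tsv)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0) stop("no recordings found in ", cfg$input$dir)
    recordings <- list()
    for (f in files) {
      id <- tools::file_path_sans_ext(basename(f))
      recordings[[id]] <- read_recording(f, subject_id = id)
    }
  } else {
    stop("config needs exactly one input source: 'simulate' or 'input'")
  }
  opts <- do.call(analysis_options,
                  if (is.null(cfg$analysis)) list() else cfg$analysis)
  res <- analyze_cohort(recordings, meta, opts = opts, quiet = quiet)
  write_results(res, meta, out_dir, cfg)
  invisible(c(res, list(out_dir = out_dir)))
}

write_results <- function(res, meta, out_dir, cfg) {
  for (d in c("connectivity", "bc", "stats")) {
    dir.create(file.path(out_dir, d), showWarnings = FALSE)
  }
  for (id in names(res$conn)) {
    for (b in names(res$conn[[id]])) {
      m <- res$conn[[id]][[b]]
      write_matrix_tsv(unclass(m), rownames(m), colnames(m),
                       file.path(out_dir, "connectivity",
                                 paste0(id, "_", b, ".tsv")))
    }
  }
  wcsv <- function(df, path) {
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(x) fmt_full(x))
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  wcsv(res$bc_table, file.path(out_dir, "bc", "bc_values.csv"))
  write_subject_meta(meta, file.path(out_dir, "bc", "metadata.csv"))
  wcsv(res$anova, file.path(out_dir, "stats", "anova.csv"))
  wcsv(res$posthoc, file.path(out_dir, "stats", "posthoc.csv"))
  wcsv(res$correlations, file.path(out_dir, "stats", "correlations.csv"))
  wcsv(res$top_edges, file.path(out_dir, "stats", "top_edges.csv"))
  manifest <- list(
    package = "plihub",
    version = as.character(packageVersion("plihub")),
    seed = cfg$seed,
    config = cfg[setdiff(names(cfg), "seed")],
    n_subjects = length(res$conn),
    n_epochs_per_band = res$n_epochs,
    gated_bands = res$gated_bands,
    disconnected_edges = res$disconnected)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

#' Group statistics from persisted BC tables
#'
#' Re-runs the statistical stage from a previous run's `bc/bc_values.csv`
#' and `bc/metadata.csv`, producing the same tables as the monolithic run.
#'
#' @param bc_dir directory holding `bc_values.csv` and `metadata.csv`.
#' @param opts an [analysis_options()] list.
#' @return list with `anova`, `posthoc`, `correlations`, `gated_bands`.
#' @export
stats_from_bc <- function(bc_dir, opts = analysis_options()) {
  tab <- read.csv(file.path(bc_dir, "bc_values.csv"))
  meta <- read_subject_meta(file.path(bc_dir, "metadata.csv"))
  bands <- unique(tab$band)
  ids <- unique(tab$subject_id)
  meta <- meta[match(ids, meta$subject_id), ]
  bc <- lapply(setNames(bands, bands), function(b) {
    sub <- tab[tab$band == b, ]
    m <- matrix(NA_real_, length(ids), length(unique(sub$electrode)),
                dimnames = list(ids, unique(sub$electrode)))
    m[cbind(match(sub$subject_id, ids),
            match(sub$electrode, colnames(m)))] <- sub$bc
    m
  })
  gs <- gated_group_stats(bc, meta$group, opts)
  list(anova = gs$anova, posthoc = gs$posthoc,
       correlations = cohort_correlations(bc, meta, gs$posthoc),
       gated_bands = bands[gs$gated])
}

load_run_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::fromJSON(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON path")
  if (is.null(config$seed)) config$seed <- 1L
  if (!is.null(config$simulate) && !is.null(config$input)) {
    stop("config needs exactly one input source, got both")
  }
  if (!is.null(config$simulate) && !is.null(config$simulate$n_per_group)) {
    config$simulate$n_per_group <- unlist(config$simulate$n_per_group)
  }
  config
}
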