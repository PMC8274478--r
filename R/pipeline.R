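# End-to-end orchestration: read a study directory tree, preprocess every
# stream, build the per-bar table, fit the models, and write reports.

read_study_manifest <- function(dir) {
  path <- file.path(dir, "config.yaml")
  if (!file.exists(path)) stop("no config.yaml in ", dir)
  m <- yaml::read_yaml(path)
  m$segment_map <- unlist(m$segment_map)
  m
}

log_line <- function(log, ...) {
  msg <- paste0(...)
  log$lines <- c(log$lines, msg)
  log
}

# per-bar pupil means for one subject x piece
bar_pupil_for <- function(dir, subject, piece, timeline, params) {
  trace <- read_pupil_csv(file.path(dir, "pupil",
                                    paste0(subject, "_", piece, ".csv")),
                          subject = subject, trial = piece)
  bl_path <- file.path(dir, "baseline", paste0(subject, "_", piece, ".csv"))
  bl <- baseline_stats(read_pupil_csv(bl_path, subject = subject,
                                      trial = piece))
  clean <- preprocess_trace(trace, bl, order = params$sg_order,
                            window = params$sg_window)
  per_bar_aggregate(clean$diameter, clean$time, timeline, stat = "mean")
}

#' Analysis parameters
#'
#' The preprocessing settings used throughout: 2 SD gates, Savitzky-Golay
#' (3, 11) for pupil and (3, 41) for motion, RMS frames of 2048 samples with
#' 50% overlap smoothed by a 50-sample Hamming window, and the 0.008
#' Bonferroni level for the six between-piece contrasts.
#'
#' @param sg_order,sg_window pupil smoothing parameters.
#' @param sg_order_motion,sg_window_motion motion differentiation parameters.
#' @param rms_frame,rms_overlap,rms_hamming sound-level parameters.
#' @param alpha_contrasts contrast significance level.
#' @export
analysis_params <- function(sg_order = 3L, sg_window = 11L,
                            sg_order_motion = 3L, sg_window_motion = 41L,
                            rms_frame = 2048L, rms_overlap = 0.5,
                            rms_hamming = 50L, alpha_contrasts = 0.008) {
  if (sg_window %% 2L == 0L || sg_window_motion %% 2L == 0L) {
    stop("smoothing windows must be odd")
  }
  list(sg_order = sg_order, sg_window = sg_window,
       sg_order_motion = sg_order_motion,
       sg_window_motion = sg_window_motion, rms_frame = rms_frame,
       rms_overlap = rms_overlap, rms_hamming = rms_hamming,
       alpha_contrasts = alpha_contrasts)
}

# shared feature extraction: timelines, cloud, sound, qom, ratings
extract_study_features <- function(dir, manifest, params, log) {
  timelines <- list()
  cloud <- list()
  sound <- list()
  for (pc in manifest$pieces) {
    tl <- read_timeline_csv(file.path(dir, "timelines", paste0(pc, ".csv")),
                            piece = pc)
    timelines[[pc]] <- tl
    notes <- read_musicxml(file.path(dir, "score", paste0(pc, ".musicxml")))
    cloud[[pc]] <- cloud_diameter_per_bar(notes, tl$n_bars)
    clip <- read_wav(file.path(dir, "audio", paste0(pc, ".wav")))
    env <- smooth_envelope(rms_frames(clip, frame = params$rms_frame,
                                      overlap = params$rms_overlap),
                           window = params$rms_hamming)
    sound[[pc]] <- sound_level_per_bar(env, tl)
  }
  qom_head <- list()
  qom_arms <- list()
  for (pf in manifest$performers) {
    for (pc in manifest$pieces) {
      key <- paste0(pf, "_", pc)
      path <- file.path(dir, "mocap", paste0(key, ".tsv"))
      if (!file.exists(path)) {
        log <- log_line(log, "mocap missing for ", key,
                         "; performer excluded from motion predictors ",
                         "for this piece")
        next
      }
      tracks <- read_mocap_tsv(path, manifest$segment_map, performer = pf)
      tl <- timelines[[pc]]
      for (seg in c("head", "arms")) {
        q <- tryCatch(
          qom(segment_speed(tracks, seg, order = params$sg_order_motion,
                            window = params$sg_window_motion), tl),
          error = function(e) NULL)
        if (is.null(q)) {
          log <- log_line(log, "no ", seg, " markers for ", key,
                          "; excluded from the ", seg, " motion predictor")
        } else if (seg == "head") {
          qom_head[[key]] <- q
        } else {
          qom_arms[[key]] <- q
        }
      }
    }
  }
  ratings <- do.call(rbind, lapply(manifest$performers, function(pf) {
    read_ratings_csv(file.path(dir, "ratings", paste0(pf, ".csv")))
  }))
  list(timelines = timelines, cloud = cloud, sound = sound,
       qom_head = qom_head, qom_arms = qom_arms, ratings = ratings,
       log = log)
}

model1_fixed <- c("cloud", "harmonic", "qom_head", "sound", "technical",
                  "expressive")
model2_fixed <- c("cloud", "harmonic", "qom_arms", "sound", "technical",
                  "expressive")

#' Build the performer per-bar analysis table
#'
#' Preprocesses every performer's pupil trace against its per-trial baseline
#' and joins the per-bar pupil means with cloud diameter, ratings, quantity
#' of motion, and sound level on the shared bar grid.
#'
#' @param dir study directory.
#' @param params an [analysis_params()].
#' @return list with `table` (a [bar_table()]), `manifest`, and `log`
#'   (character lines describing exclusions).
#' @export
performer_bar_table <- function(dir, params = analysis_params()) {
  manifest <- read_study_manifest(dir)
  log <- list(lines = character(0))
  feats <- extract_study_features(dir, manifest, params, log)
  log <- feats$log
  rows <- list()
  for (pf in manifest$performers) {
    rat <- feats$ratings[feats$ratings$performer == pf, ]
    for (pc in manifest$pieces) {
      tl <- feats$timelines[[pc]]
      pup <- bar_pupil_for(dir, pf, pc, tl, params)
      key <- paste0(pf, "_", pc)
      rp <- rat[rat$piece == pc, ]
      get_rating <- function(m) {
        v <- rp[rp$measure == m, ]
        v$value[match(seq_len(tl$n_bars), v$bar)]
      }
      rows[[key]] <- data.frame(
        subject = pf, piece = pc, bar = seq_len(tl$n_bars), pupil = pup,
        cloud = feats$cloud[[pc]],
        harmonic = get_rating("harmonic"),
        technical = get_rating("technical"),
        expressive = get_rating("expressive"),
        qom_head = if (is.null(feats$qom_head[[key]])) NA_real_
                   else feats$qom_head[[key]],
        qom_arms = if (is.null(feats$qom_arms[[key]])) NA_real_
                   else feats$qom_arms[[key]],
        sound = feats$sound[[pc]])
    }
  }
  tab <- bar_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  list(table = tab, manifest = manifest, log = log$lines)
}

fit_and_compare <- function(tab, fixed, alpha = 0.05) {
  spec <- model_spec(fixed)
  fit <- fit_lmm(tab, spec)
  co <- fit$coefficients
  co <- co[co$term != "(Intercept)" & is.finite(co$p), ]
  sig <- co[co$p < alpha, ]
  ordered <- sig$term[order(-abs(sig$estimate))]
  cmp <- if (length(ordered)) {
    hierarchical_compare(tab, spec, ordered)
  } else {
    hierarchical_compare(tab, spec, character(0))
  }
  list(fit = fit, comparison = cmp, ordered = ordered)
}

#' Run the performer analysis end to end
#'
#' Preprocesses every performer's pupil trace against its baseline, extracts
#' quantity of motion, sound level, cloud diameter and ratings on the shared
#' bar grid, joins them into the per-bar table, fits Model 1 (head motion)
#' and Model 2 (arm motion, typically on fewer rows because arm markers drop
#' out more), runs the hierarchical predictor addition for each model's
#' significant predictors, the per-performer between-piece contrasts, and
#' the rehearsal-vs-concert baseline comparison. All intermediate and final
#' tables are written under `out_dir`.
#'
#' @param dir study directory (layout as written by [gen_full_study()]).
#' @param out_dir report directory (default `<dir>/reports_performer`).
#' @param params an [analysis_params()].
#' @return invisibly, a list with the bar table, both fits and comparisons,
#'   contrasts, the baseline Wilcoxon result, and the run log.
#' @export
run_performer_analysis <- function(dir,
                                   out_dir = file.path(dir,
                                                       "reports_performer"),
                                   params = analysis_params()) {
  manifest <- read_study_manifest(dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  bt <- performer_bar_table(dir, params)
  tab <- bt$table
  manifest <- bt$manifest
  log <- list(lines = bt$log)
  total_bars <- length(manifest$performers) * length(manifest$pieces) *
    manifest$n_bars
  utils::write.csv(tab, file.path(out_dir, "bar_table.csv"),
                   row.names = FALSE)

  m1 <- fit_and_compare(tab, model1_fixed)
  m2 <- fit_and_compare(tab, model2_fixed)
  log <- log_line(log, "model 1 rows excluded: ", m1$fit$n_excluded,
                  " of ", total_bars)
  log <- log_line(log, "model 2 rows excluded: ", m2$fit$n_excluded,
                  " of ", total_bars)

  contrasts <- do.call(rbind, lapply(manifest$performers, function(pf) {
    piece_contrasts(tab[tab$subject == pf, ],
                    alpha = params$alpha_contrasts)
  }))

  occ_mean <- function(occ) {
    vapply(manifest$performers, function(pf) {
      p <- file.path(dir, "baseline", paste0(pf, "_", occ, ".csv"))
      if (!file.exists(p)) return(NA_real_)
      baseline_stats(read_pupil_csv(p, subject = pf,
                                    trial = occ))$mean_diameter
    }, 0)
  }
  reh <- occ_mean("first_rehearsal")
  con <- occ_mean("pre_concert")
  wil <- if (all(is.finite(reh)) && all(is.finite(con)) &&
             any(reh != con)) {
    wilcoxon_signed_rank(reh, con)
  } else NULL

  # per-performer mean pupil summaries (boxplot-style data)
  summaries <- stats::aggregate(pupil ~ subject + piece,
                                data = as.data.frame(tab), FUN = mean)

  write_fit <- function(m, name) {
    utils::write.csv(m$fit$coefficients,
                     file.path(out_dir, paste0(name, "_coefficients.csv")),
                     row.names = FALSE)
    utils::write.csv(m$comparison,
                     file.path(out_dir, paste0(name, "_hierarchical.csv")),
                     row.names = FALSE)
  }
  write_fit(m1, "model1")
  write_fit(m2, "model2")
  utils::write.csv(contrasts, file.path(out_dir, "piece_contrasts.csv"),
                   row.names = FALSE)
  utils::write.csv(summaries, file.path(out_dir, "pupil_summaries.csv"),
                   row.names = FALSE)
  summary_json <- list(
    n_rows = nrow(tab),
    model1 = list(logLik = m1$fit$logLik, BIC = m1$fit$BIC,
                  n = m1$fit$n, rho = m1$fit$varcomp$rho),
    model2 = list(logLik = m2$fit$logLik, BIC = m2$fit$BIC,
                  n = m2$fit$n, rho = m2$fit$varcomp$rho),
    baseline_wilcoxon = if (is.null(wil)) NULL
                        else list(W = wil$W, p = wil$p))
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  writeLines(log$lines, file.path(out_dir, "run_log.txt"))
  invisible(list(bar_table = tab, model1 = m1, model2 = m2,
                 contrasts = contrasts, baseline_wilcoxon = wil,
                 summaries = summaries, log = log$lines))
}

#' Run the listener analysis end to end
#'
#' Same modelling procedure as the performer analysis, with listeners'
#' pupil traces preprocessed against their own pre-trial baselines and the
#' predictors collapsed across performers: ratings and quantity of motion
#' are averaged over performers at each bar; cloud diameter and sound level
#' are piece-level already.
#'
#' @inheritParams run_performer_analysis
#' @return invisibly, a list with the listener bar table, both fits and
#'   comparisons, and the run log.
#' @export
run_listener_analysis <- function(dir,
                                  out_dir = file.path(dir,
                                                      "reports_listener"),
                                  params = analysis_params()) {
  manifest <- read_study_manifest(dir)
  if (length(manifest$listeners) == 0L) stop("study has no listeners")
  if (length(manifest$listeners) == 1L) {
    warning("single listener: listener random-intercept variance is ",
            "unidentified")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list(lines = character(0))
  feats <- extract_study_features(dir, manifest, params, log)
  log <- feats$log

  avg_pred <- list()
  for (pc in manifest$pieces) {
    tl <- feats$timelines[[pc]]
    avg_rating <- function(m) {
      rr <- feats$ratings[feats$ratings$piece == pc &
                            feats$ratings$measure == m, ]
      average_ratings(rr, measure = m)
    }
    avg_qom <- function(tabs) {
      keys <- paste0(manifest$performers, "_", pc)
      have <- keys[keys %in% names(tabs)]
      if (!length(have)) return(rep(NA_real_, tl$n_bars))
      rowMeans(do.call(cbind, tabs[have]), na.rm = FALSE)
    }
    avg_pred[[pc]] <- data.frame(
      bar = seq_len(tl$n_bars), cloud = feats$cloud[[pc]],
      harmonic = avg_rating("harmonic"),
      technical = avg_rating("technical"),
      expressive = avg_rating("expressive"),
      qom_head = avg_qom(feats$qom_head),
      qom_arms = avg_qom(feats$qom_arms),
      sound = feats$sound[[pc]])
  }

  rows <- list()
  for (ls in manifest$listeners) {
    for (pc in manifest$pieces) {
      tl <- feats$timelines[[pc]]
      pup <- bar_pupil_for(dir, ls, pc, tl, params)
      d <- avg_pred[[pc]]
      d$subject <- ls
      d$piece <- pc
      d$pupil <- pup
      rows[[paste0(ls, "_", pc)]] <- d
    }
  }
  tab <- bar_table(do.call(rbind, c(rows, list(make.row.names = FALSE))))
  utils::write.csv(tab, file.path(out_dir, "bar_table.csv"),
                   row.names = FALSE)

  m1 <- fit_and_compare(tab, model1_fixed)
  m2 <- fit_and_compare(tab, model2_fixed)
  log <- log_line(log, "model 1 rows excluded: ", m1$fit$n_excluded)
  log <- log_line(log, "model 2 rows excluded: ", m2$fit$n_excluded)

  utils::write.csv(m1$fit$coefficients,
                   file.path(out_dir, "model1_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(m2$fit$coefficients,
                   file.path(out_dir, "model2_coefficients.csv"),
                   row.names = FALSE)
  utils::write.csv(m1$comparison,
                   file.path(out_dir, "model1_hierarchical.csv"),
                   row.names = FALSE)
  utils::write.csv(m2$comparison,
                   file.path(out_dir, "model2_hierarchical.csv"),
                   row.names = FALSE)
  writeLines(log$lines, file.path(out_dir, "run_log.txt"))
  invisible(list(bar_table = tab, model1 = m1, model2 = m2,
                 log = log$lines))
}
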