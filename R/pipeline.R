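#' Classify behavioral response to stimulation
#'
#' A subject is a responder (`R+`) when the CRS-R total strictly increases
#' after stimulation; stable or decreasing scores are non-responders (`R-`).
#'
#' @param crsr_pre,crsr_post Integer CRS-R totals (0-23), vectorized.
#' @return Character vector of `"R+"` / `"R-"`.
#' @export
classify_response <- function(crsr_pre, crsr_post) {
  if (any(crsr_pre < 0 | crsr_pre > 23 | crsr_post < 0 | crsr_post > 23,
          na.rm = TRUE) || anyNA(crsr_pre) || anyNA(crsr_post)) {
    stop("CRS-R scores must lie in [0, 23]", call. = FALSE)
  }
  ifelse(crsr_post > crsr_pre, "R+", "R-")
}

#' Marker analysis of one resting subject/session
#'
#' Preprocesses a resting recording and computes the seventeen-marker
#' topographies, the wSMI pair matrix and the 68-feature summary.
#'
#' @param rec A resting `eeg_recording`.
#' @param seed Epoching seed.
#' @param n_iterations Resting segmentation iterations.
#' @param tau_ms Ordinal-pattern lag.
#' @return A list: `passed`, `topography` (channels x 17 matrix), `wsmi`
#'   (channels x channels), `features` (length-68), `report`.
#' @export
rest_session_analysis <- function(rec, seed = 1L, n_iterations = 2,
                                  tau_ms = 32) {
  pp <- preprocess_recording(rec, seed = seed, n_iterations = n_iterations)
  if (!pp$passed) {
    return(list(passed = FALSE, topography = NULL, wsmi = NULL,
                features = NULL, report = pp$report))
  }
  mk <- compute_markers(pp$epoch_sets, tau_ms = tau_ms)
  topo <- matrix(mk$value, ncol = length(marker_ids),
                 dimnames = list(NULL, unique(mk$marker)))
  list(passed = TRUE, topography = topo, wsmi = attr(mk, "wsmi"),
       features = build_features(mk), report = pp$report)
}

#' Run the complete study workflow on a cohort
#'
#' Orchestrates the end-to-end analysis of a responder/non-responder cohort:
#' responder labeling from CRS-R totals; per-subject resting preprocessing,
#' marker topographies, wSMI pairs and 68-feature vectors; the four
#' cluster-permutation contrast families on the post-minus-pre changes
#' (`R+` vs `R-`): marker topographies (Welch t over channels), wSMI pairs
#' (Welch t over electrode pairs), oddball ERP double difference (Welch t
#' over channel x time), and temporal-generalization decoding (Mann-Whitney
#' z over the AUC matrix); the MVPA prediction change with an
#' aligned-rank-transform interaction test; and, when field maps are
#' supplied, the electric-field correlation test. Subjects failing the
#' quality gate in a modality are excluded from that modality only, with a
#' log entry.
#'
#' @param cohort Tibble from [simulate_cohort()] (or same shape with real
#'   data): behavioral columns plus `rest_pre`/`rest_post` and/or
#'   `task_pre`/`task_post` recording list-columns.
#' @param clf A trained [train_mcs_classifier()] model, or `NULL` to skip
#'   the MVPA family.
#' @param field_maps Optional `field_map_set` whose subjects match the
#'   cohort rows with MVPA predictions.
#' @param n_iterations Resting epoching iterations per recording.
#' @param n_perm Permutations for every cluster test.
#' @param tau_ms Ordinal-pattern lag (ms).
#' @param erp_decim,decode_decim Temporal decimation for the ERP space-time
#'   and decoding-matrix families.
#' @param decode_iter CV repetitions inside [tg_decode()].
#' @param markers_to_test Marker ids contrasted topographically.
#' @param seed Master seed for epoching, decoding and permutations.
#' @return A list of class `study_report`.
#' @export
run_study <- function(cohort, clf = NULL, field_maps = NULL,
                      n_iterations = 2, n_perm = 500, tau_ms = 32,
                      erp_decim = 8, decode_decim = 16, decode_iter = 2,
                      markers_to_test = marker_ids, seed = 1L) {
  seed <- as.integer(seed)
  n <- nrow(cohort)
  behavioral <- tibble::tibble(
    subject_id = cohort$subject_id,
    diagnosis = cohort$diagnosis,
    crsr_pre = cohort$crsr_pre, crsr_post = cohort$crsr_post,
    crsr_delta = cohort$crsr_post - cohort$crsr_pre,
    response = classify_response(cohort$crsr_pre, cohort$crsr_post)
  )
  grp <- behavioral$response
  exclusions <- tibble::tibble(subject_id = character(), modality = character(),
                               reason = character())
  report <- list(behavioral = behavioral)

  has_rest <- all(c("rest_pre", "rest_post") %in% names(cohort))
  has_task <- all(c("task_pre", "task_post") %in% names(cohort))

  if (has_rest) {
    rest <- vector("list", n)
    for (i in seq_len(n)) {
      pre <- rest_session_analysis(cohort$rest_pre[[i]], seed = seed + 7 * i,
                                   n_iterations = n_iterations, tau_ms = tau_ms)
      post <- rest_session_analysis(cohort$rest_post[[i]], seed = seed + 7 * i + 3,
                                    n_iterations = n_iterations, tau_ms = tau_ms)
      if (!pre$passed || !post$passed) {
        exclusions <- dplyr::add_row(exclusions,
          subject_id = cohort$subject_id[i], modality = "rest",
          reason = "failed preprocessing quality gate")
        next
      }
      rest[[i]] <- list(pre = pre, post = post)
    }
    ok <- !vapply(rest, is.null, logical(1))
    layout <- cohort$rest_pre[[1]]$layout

    # marker topography contrasts
    marker_clusters <- list()
    if (sum(ok & grp == "R+") >= 2 && sum(ok & grp == "R-") >= 2) {
      chadj <- channel_adjacency(layout)
      for (mk in markers_to_test) {
        diffs <- t(vapply(which(ok), function(i) {
          rest[[i]]$post$topography[, mk] - rest[[i]]$pre$topography[, mk]
        }, numeric(nrow(layout$adjacency))))
        marker_clusters[[mk]] <- cluster_perm(
          diffs[grp[ok] == "R+", , drop = FALSE],
          diffs[grp[ok] == "R-", , drop = FALSE],
          chadj, "welch_t", n_perm = n_perm, seed = seed + 101)
      }

      # wSMI pair contrast
      padj <- pair_adjacency(layout)
      pr <- attr(padj, "pairs")
      pair_diffs <- t(vapply(which(ok), function(i) {
        (rest[[i]]$post$wsmi - rest[[i]]$pre$wsmi)[pr]
      }, numeric(nrow(pr))))
      report$wsmi_clusters <- cluster_perm(
        pair_diffs[grp[ok] == "R+", , drop = FALSE],
        pair_diffs[grp[ok] == "R-", , drop = FALSE],
        padj, "welch_t", n_perm = n_perm, seed = seed + 103)
    }
    report$marker_clusters <- marker_clusters

    # MVPA prediction change + ART interaction
    if (!is.null(clf)) {
      pred <- tibble::tibble(
        subject_id = cohort$subject_id[ok],
        group = grp[ok],
        p_pre = vapply(which(ok), function(i) predict_mcs(clf, rest[[i]]$pre$features), 0),
        p_post = vapply(which(ok), function(i) predict_mcs(clf, rest[[i]]$post$features), 0)
      )
      pred$delta <- pred$p_post - pred$p_pre
      report$mvpa_predictions <- pred
      long <- tidyr::pivot_longer(pred, c("p_pre", "p_post"),
                                  names_to = "session", values_to = "value")
      long$session <- sub("^p_", "", long$session)
      long$subject <- long$subject_id
      report$mvpa_art <- art_anova(long[, c("subject", "group", "session", "value")])
    }
  }

  if (has_task) {
    erps <- vector("list", n)
    tgs <- vector("list", n)
    for (i in seq_len(n)) {
      sess <- list()
      tg_sess <- list()
      bad <- FALSE
      for (s in c("pre", "post")) {
        rec <- cohort[[paste0("task_", s)]][[i]]
        pp <- preprocess_recording(rec, seed = seed + 13 * i)
        ep <- pp$epoch_sets[[1]]
        if (ep$failed) { bad <- TRUE; break }
        sess[[s]] <- list(standard = erp_average(ep, "standard"),
                          deviant = erp_average(ep, "deviant"))
        tg_sess[[s]] <- tg_decode(ep, seed = seed + 13 * i + 5,
                                  n_iter = decode_iter, decim = decode_decim)
        if (tg_sess[[s]]$flagged) bad <- TRUE
      }
      if (bad) {
        exclusions <- dplyr::add_row(exclusions,
          subject_id = cohort$subject_id[i], modality = "task",
          reason = "failed preprocessing quality gate or too few trials")
        next
      }
      erps[[i]] <- sess
      tgs[[i]] <- tg_sess
    }
    ok_t <- !vapply(erps, is.null, logical(1))
    if (sum(ok_t & grp == "R+") >= 2 && sum(ok_t & grp == "R-") >= 2) {
      layout <- cohort$task_pre[[1]]$layout
      nc <- nrow(layout$adjacency)
      # ERP double difference, decimated in time
      first_ok <- which(ok_t)[1]
      nt_full <- ncol(erps[[first_ok]]$pre$standard$data)
      tsel <- seq(1, nt_full, by = erp_decim)
      dd <- t(vapply(which(ok_t), function(i) {
        m <- (erps[[i]]$post$deviant$data - erps[[i]]$post$standard$data) -
          (erps[[i]]$pre$deviant$data - erps[[i]]$pre$standard$data)
        as.numeric(m[, tsel])
      }, numeric(nc * length(tsel))))
      report$erp_clusters <- cluster_perm(
        dd[grp[ok_t] == "R+", , drop = FALSE],
        dd[grp[ok_t] == "R-", , drop = FALSE],
        spacetime_adjacency(layout, length(tsel)), "welch_t",
        n_perm = n_perm, seed = seed + 107)
      report$erp_time_ms <- erps[[first_ok]]$pre$standard$time_ms[tsel]

      # decoding-matrix contrast (after minus before mean AUC)
      ntt <- nrow(tgs[[which(ok_t)[1]]]$pre$auc)
      am <- t(vapply(which(ok_t), function(i) {
        as.numeric(tgs[[i]]$post$auc - tgs[[i]]$pre$auc)
      }, numeric(ntt * ntt)))
      report$decode_clusters <- cluster_perm(
        am[grp[ok_t] == "R+", , drop = FALSE],
        am[grp[ok_t] == "R-", , drop = FALSE],
        matrix_adjacency(ntt), "mann_whitney_z",
        n_perm = n_perm, seed = seed + 109)
      report$decode_time_ms <- tgs[[which(ok_t)[1]]]$pre$time_ms
    }
  }

  if (!is.null(field_maps) && !is.null(report$mvpa_predictions)) {
    outcomes <- report$mvpa_predictions$delta
    nm <- length(if (inherits(field_maps, "field_map_set")) field_maps$maps else field_maps)
    if (nm == length(outcomes)) {
      report$field_corr <- mean_corr_test(field_maps, outcomes,
                                          n_perm = n_perm, seed = seed + 113)
    }
  }

  report$exclusions <- exclusions
  report$params <- list(n_iterations = n_iterations, n_perm = n_perm,
                        tau_ms = tau_ms, erp_decim = erp_decim,
                        decode_decim = decode_decim,
                        decode_iter = decode_iter, seed = seed)
  class(report) <- "study_report"
  report
}

#' Desk-scale study configuration
#'
#' The reduced-scale cohort specification used for calibration and
#' planted-effect recovery analyses: 6 responders and 6 non-responders, 12
#' channels, 20-s resting recordings, 80 oddball trials, 6-uV pink noise.
#' At `effect_scale = 1` responders' post sessions receive +3 uV theta and
#' alpha amplitude, +7 uV theta-alpha coupling and +8 uV P3 amplitude —
#' strong planted effects; `effect_scale = 0` is the matching null
#' configuration.
#'
#' @param effect_scale Multiplier on every planted post-stimulation effect.
#' @param seed Integer seed.
#' @return A [cohort_spec()].
#' @export
desk_study_spec <- function(effect_scale = 1, seed = 1L) {
  cohort_spec(n_rplus = 6, n_rminus = 6, n_channels = 12,
              rest_duration = 20, n_trials = 80,
              noise_sd = 6, sensor_noise_sd = 2,
              coupling_amplitude = 0,
              effect_theta = 3 * effect_scale,
              effect_alpha = 3 * effect_scale,
              effect_coupling = 7 * effect_scale,
              p3_amplitude = 1, effect_p3 = 8 * effect_scale,
              seed = seed)
}

#' Train the desk-scale reference classifier
#'
#' Builds a synthetic VS-vs-MCS reference database matched to the
#' desk-scale geometry and trains the MCS predictor on it.
#'
#' @param n_per_class Recordings per class.
#' @param separation Class-separation scale of the reference database.
#' @param seed Integer seed.
#' @return An `mcs_classifier`.
#' @export
desk_reference_classifier <- function(n_per_class = 12, separation = 0.6,
                                      seed = 99L) {
  base <- cohort_spec(n_channels = 12, rest_duration = 20, noise_sd = 6,
                      seed = seed)
  ref <- simulate_reference_database(n_per_class, n_per_class,
                                     separation = separation, seed = seed,
                                     spec = base)
  feats <- t(vapply(ref$recording, function(r) {
    rest_session_analysis(r, seed = seed, n_iterations = 1)$features
  }, numeric(68)))
  train_mcs_classifier(feats, ref$label, seed = seed)
}

#' Run the desk-scale study
#'
#' [run_study()] with the desk-scale analysis settings: one resting
#' epoching iteration, 200 permutations, time decimation 10 (ERP) and 20
#' (decoding), three decoding CV repetitions, and topographic contrasts on
#' the normalized theta and alpha powers.
#'
#' @param seed Integer seed (drives the cohort and all analyses).
#' @param effect_scale Planted-effect multiplier (0 for null cohorts).
#' @param clf Optional `mcs_classifier` (from
#'   [desk_reference_classifier()]).
#' @return A `study_report`.
#' @export
run_desk_study <- function(seed, effect_scale = 1, clf = NULL) {
  coh <- simulate_cohort(desk_study_spec(effect_scale, seed))
  run_study(coh, clf = clf, n_iterations = 1, n_perm = 200,
            erp_decim = 10, decode_decim = 20, decode_iter = 3,
            markers_to_test = c("theta_norm", "alpha_norm"), seed = seed)
}

#' Did a study report recover the canonical response signature?
#'
#' Conjunction checks on a `study_report`, one per effect family: a
#' significant positive theta-power cluster together with a significant
#' positive wSMI-pair cluster; a positive mean MVPA prediction change in
#' responders together with a significant ART interaction; a significant
#' positive decoding cluster overlapping the late (250-650 ms) square; and
#' a significant positive ERP cluster.
#'
#' @param report A `study_report`.
#' @param alpha Cluster significance level.
#' @return A tibble `family`, `recovered`.
#' @export
summarize_recovery <- function(report, alpha = 0.05) {
  sig_pos <- function(cl) {
    !is.null(cl) && nrow(cl) > 0 && any(cl$p_value < alpha & cl$sign > 0)
  }
  rest_ok <- sig_pos(report$marker_clusters$theta_norm) &&
    sig_pos(report$wsmi_clusters)
  mvpa_ok <- FALSE
  if (!is.null(report$mvpa_predictions)) {
    dplus <- report$mvpa_predictions$delta[report$mvpa_predictions$group == "R+"]
    intp <- report$mvpa_art$p_value[report$mvpa_art$effect == "group:session"]
    mvpa_ok <- mean(dplus) > 0 && is.finite(intp) && intp < alpha
  }
  decode_ok <- FALSE
  if (!is.null(report$decode_clusters) && nrow(report$decode_clusters) > 0) {
    tm <- report$decode_time_ms
    late <- which(outer(tm >= 250 & tm <= 650, tm >= 250 & tm <= 650, "&"))
    for (ci in seq_len(nrow(report$decode_clusters))) {
      cl <- report$decode_clusters[ci, ]
      if (cl$sign > 0 && cl$p_value < alpha &&
          length(intersect(cl$members[[1]], late)) > 0) decode_ok <- TRUE
    }
  }
  erp_ok <- sig_pos(report$erp_clusters)
  tibble::tibble(
    family = c("theta_power_and_wsmi", "mvpa_delta_and_interaction",
               "decode_late_square", "erp_positive_cluster"),
    recovered = c(rest_ok, mvpa_ok, decode_ok, erp_ok)
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  cat(sprintf("  subjects: %d (%d R+)\n", nrow(x$behavioral),
              sum(x$behavioral$response == "R+")))
  if (!is.null(x$marker_clusters)) {
    sig <- vapply(x$marker_clusters,
                  function(cl) any(cl$p_value < 0.05), logical(1))
    cat(sprintf("  marker families with significant clusters: %s\n",
                if (any(sig)) paste(names(sig)[sig], collapse = ", ") else "none"))
  }
  if (!is.null(x$mvpa_art)) {
    i <- x$mvpa_art[x$mvpa_art$effect == "group:session", ]
    cat(sprintf("  MVPA ART interaction: F(%d, %d) = %.2f, p = %.3f\n",
                i$df1, i$df2, i$F, i$p_value))
  }
  cat(sprintf("  exclusions: %d\n", nrow(x$exclusions)))
  invisible(x)
}
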