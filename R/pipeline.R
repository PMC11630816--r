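# End-to-end orchestration: simulate/ingest -> classify -> subtypes ->
# sequences -> clustering -> behavior, with one master seed and a summary
# holding every headline quantity.

#' Pipeline configuration
#'
#' @param seed master seed; per-stage seeds are derived as
#'   `seed * 7919 + stage_index` (mod 2^31), so one flag reproduces a run.
#' @param synthetic a [synthetic_config()], or `NULL` to ingest files.
#' @param input_dir directory of native-dialect session files (used when
#'   `synthetic` is `NULL`; files as written by [write_cohort()]).
#' @param rules a [class_rules()].
#' @param subtype_params a [subtype_params()].
#' @param max_gap bout gap threshold, seconds.
#' @param min_pts,eps DBSCAN parameters; `eps = NULL` takes the k-distance
#'   knee from [estimate_eps()].
#' @param max_k,n_init contour k-means parameters.
#' @param freeze a [freeze_params()].
#' @param stages character vector of stage toggles; subset of
#'   `c("classify", "subtypes", "sequences", "clustering", "behavior")`.
#' @param kmeans_sample at most this many contoured calls enter the contour
#'   k-means (subsampled reproducibly) to bound runtime.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, synthetic = synthetic_config(seed = seed),
                            input_dir = NULL,
                            rules = class_rules(),
                            subtype_params = usv44::subtype_params(),
                            max_gap = 0.320, min_pts = 150, eps = NULL,
                            max_k = 4, n_init = 10,
                            freeze = freeze_params(),
                            stages = c("classify", "subtypes", "sequences",
                                       "clustering", "behavior"),
                            kmeans_sample = 2000) {
  structure(list(seed = seed, synthetic = synthetic, input_dir = input_dir,
                 rules = rules, subtype_params = subtype_params,
                 max_gap = max_gap, min_pts = min_pts, eps = eps,
                 max_k = max_k, n_init = n_init, freeze = freeze,
                 stages = stages, kmeans_sample = kmeans_sample),
            class = "pipeline_config")
}

load_sessions <- function(config) {
  if (!is.null(config$synthetic)) {
    return(generate_cohort(config$synthetic, config$seed)$sessions)
  }
  if (is.null(config$input_dir)) {
    stop_usv("pipeline needs either a synthetic config or an input_dir",
             class = "usv44_validation_error")
  }
  metas <- list.files(config$input_dir, pattern = "_session\\.cfg$",
                      full.names = TRUE)
  lapply(metas, function(mf) {
    base <- sub("_session\\.cfg$", "", mf)
    meta <- read_session_meta(mf)
    list(meta = meta,
         calls = read_call_table(paste0(base, "_calls.csv")),
         contours = if (file.exists(paste0(base, "_contours.csv")))
           read_contours(paste0(base, "_contours.csv")) else list(),
         motion = if (file.exists(paste0(base, "_motion.csv")))
           read_motion_series(paste0(base, "_motion.csv"), meta$frame_rate)
         else NULL)
  })
}

#' Run the full analysis pipeline
#'
#' Deterministic given the configuration (and its seed). The summary gathers
#' every headline quantity: per-type counts, overall 44-kHz share, pooled
#' per-ITI profile, subtype shares, transition probabilities (all pairs and
#' within-bout), DBSCAN cluster statistics with silhouette, contour k-means
#' k, and mean freezing by bin category.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with `sessions` (typed tables),
#'   per-stage result blocks, and `summary` (plain named list, JSON-ready).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  sessions <- load_sessions(config)
  result <- list(config = config)
  summary <- list(seed = config$seed, n_sessions = length(sessions))
  wrap_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop_usv("stage '%s' failed: %s", stage, conditionMessage(e),
               class = "usv44_stage_error")
    })
  }

  if ("classify" %in% config$stages) {
    sessions <- wrap_stage("classify", lapply(sessions, function(s) {
      cl <- classify_table(s$calls, config$rules, s$contours)
      s$calls <- cl$records
      s$counts <- cl$counts
      s
    }))
    counts <- Reduce(`+`, lapply(sessions, `[[`, "counts"))
    profiles <- lapply(sessions, function(s) iti_profile(s$calls, s$meta))
    pooled <- pool_iti_profiles(profiles)
    summary$counts <- as.list(counts)
    summary$share_fortyfour <- unname(counts["fortyfour"] / sum(counts))
    summary$iti_profile <- pooled
  }

  if ("subtypes" %in% config$stages) {
    sessions <- wrap_stage("subtypes", lapply(sessions, function(s) {
      if (length(s$contours)) {
        s$calls <- subtype_table(s$calls, s$contours, config$subtype_params)
      }
      s
    }))
    sub <- unlist(lapply(sessions, function(s)
      s$calls$subtype[s$calls$call_type == "fortyfour"]))
    sub <- sub[!is.na(sub)]
    summary$subtype_shares <- if (length(sub))
      as.list(prop.table(table(factor(sub, levels = SUBTYPES)))) else NULL
    ratios <- unlist(lapply(sessions, function(s) {
      ids <- s$calls$call_id[s$calls$call_type == "fortyfour" &
                               s$calls$subtype %in% c("step_up", "step_down")]
      vapply(ids, function(id) {
        el <- trim_affixes(segment_elements(s$contours[[id]],
                                            config$subtype_params),
                           config$subtype_params)
        if (nrow(el) == 2) element_ratio(el) else NA_real_
      }, numeric(1))
    }))
    summary$step_ratio_mean <- if (length(ratios)) mean(ratios, na.rm = TRUE)
      else NA_real_
  }

  all_calls <- do.call(rbind, lapply(sessions, function(s) as.data.frame(s$calls)))

  if ("sequences" %in% config$stages) {
    result$transitions_all <- wrap_stage("sequences",
      transition_matrix(all_calls, "all", config$max_gap))
    result$transitions_bout <- transition_matrix(all_calls, "within_bout",
                                                 config$max_gap)
    result$bouts <- lapply(sessions, function(s)
      segment_bouts(s$calls, config$max_gap))
    summary$transition_all <- result$transitions_all$probabilities
    summary$transition_within_bout <- result$transitions_bout$probabilities
    summary$n_bouts <- sum(vapply(result$bouts, nrow, integer(1)))
  }

  if ("clustering" %in% config$stages) {
    result$dbscan <- wrap_stage("clustering", {
      feats <- standardize_features(all_calls)
      eps <- config$eps %||% estimate_eps(feats, k = config$min_pts)$eps
      dbscan_cluster(feats, eps, config$min_pts,
                     raw_features = cbind(all_calls$peak_frequency,
                                          all_calls$duration))
    })
    summary$dbscan <- list(eps = result$dbscan$eps,
                           n_clusters = nrow(result$dbscan$cluster_stats),
                           n_noise = result$dbscan$n_noise,
                           silhouette = result$dbscan$silhouette,
                           cluster_stats = result$dbscan$cluster_stats)
    contours <- do.call(c, lapply(sessions, `[[`, "contours"))
    contours <- contours[all_calls$call_id]
    have <- !vapply(contours, is.null, logical(1))
    idx <- which(have)
    if (length(idx) > config$kmeans_sample) {
      set.seed(derive_seed(config$seed, 2L))
      idx <- sort(sample(idx, config$kmeans_sample))
    }
    if (length(idx) >= config$max_k) {
      result$kmeans <- contour_kmeans(contours[idx], all_calls$duration[idx],
                                      all_calls$peak_frequency[idx],
                                      max_k = config$max_k,
                                      n_init = config$n_init,
                                      seed = derive_seed(config$seed, 3L))
      summary$kmeans <- list(k = result$kmeans$k,
                             inertia = result$kmeans$inertia)
    }
  }

  if ("behavior" %in% config$stages) {
    reports <- wrap_stage("behavior", lapply(sessions, function(s) {
      if (is.null(s$motion)) return(NULL)
      mask <- score_freezing(s$motion, config$freeze)
      bin_linkage(s$calls, mask, s$meta)
    }))
    reports <- Filter(Negate(is.null), reports)
    if (length(reports)) {
      result$bin_reports <- reports
      summary$freezing <- bin_summary(do.call(rbind, reports))
    }
  }

  result$sessions <- sessions
  result$summary <- summary
  class(result) <- "pipeline_result"
  result
}

#' Write a pipeline summary as JSON
#'
#' @param result a [run_pipeline()] result.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(result, path) {
  jsonlite::write_json(summary_to_json(result$summary), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

summary_to_json <- function(s) {
  rapply(s, function(x) {
    if (is.matrix(x)) as.data.frame(x) else x
  }, how = "replace")
}
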