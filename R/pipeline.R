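# End-to-end orchestration on synthetic paired sessions. The exported
# functions and this driver are the package's interface; each stage can be
# toggled and every numeric default is the printed analysis value.

#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Unknown keys are
#' rejected by the function signature itself. Stage toggles select which
#' analyses run; thresholds default to the analysis constants (0.25 cm/s,
#' 0.33 s, 3 cm/s, 99.5th percentile, 5.33 s, 20% safe zone, 14 cm, 1.11,
#' 0.9 likelihood, 60/10 s interleaving, 100 permutations, 1000 random
#' projections).
#'
#' @param seed master seed; every stage derives its RNG stream from it.
#' @param sim a [simulation_config()] for the synthetic sessions.
#' @param stages character vector of stages to run.
#' @param include_toy also simulate a toy-rat control session.
#' @param k_range candidate cluster counts for the states stage.
#' @param n_perm permutations (decoder and cluster nulls).
#' @param n_proj random projections (CoCA significance).
#' @param coca_restarts,coca_max_iter CoCA optimizer control.
#' @param out_dir optional directory for result JSON/CSV files.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            sim = simulation_config(seed = seed),
                            stages = c("behavior", "ensembles", "decoding",
                                       "glm", "coca", "states"),
                            include_toy = FALSE,
                            k_range = 1:10, n_perm = 100, n_proj = 1000,
                            coca_restarts = 5, coca_max_iter = 10000,
                            out_dir = NULL) {
  known <- c("behavior", "ensembles", "decoding", "glm", "coca", "states")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "))
  structure(list(seed = as.integer(seed), sim = sim, stages = stages,
                 include_toy = include_toy, k_range = k_range,
                 n_perm = n_perm, n_proj = n_proj,
                 coca_restarts = coca_restarts,
                 coca_max_iter = coca_max_iter, out_dir = out_dir),
            class = "pipeline_config")
}

#' @noRd
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config[setdiff(names(config), "out_dir")], tmp,
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Behavior processing shared by the pipeline stages: kinematics, events,
# zones and scores on the behavioral clock, then aligned to the neural one.
#' @noRd
process_session_behavior <- function(session) {
  pose <- session$pose
  geom <- session$geometry
  kin <- compute_kinematics(pose)
  zones <- assign_zones(pose, geom)
  events <- if (geom$assay_kind == "EPM") {
    combine_intervals(detect_freeze(kin), detect_head_dips(pose, zones))
  } else {
    combine_intervals(detect_freeze(kin), detect_approach_escape(kin),
                      detect_rat_movements(kin))
  }
  scores <- avoidance_approach_score(pose, events, geom)
  beh <- data.frame(zone = zones, score = scores$score,
                    dist_safety = scores$dist_safety,
                    speed = kin$speed)
  if (geom$assay_kind == "EPM") {
    beh$location_index <- scores$location_index
    beh$abs_x <- scores$abs_x
    beh$abs_y <- scores$abs_y
    beh$head_dip <- interval_indicator(events, pose$n_frames, pose$fps, "head_dip")
  } else {
    beh$dist_rat <- kin$dist_rat
    beh$rat_speed <- kin$rat_speed
    beh$angle_to_rat <- kin$angle_to_rat
    beh$approach <- interval_indicator(events, pose$n_frames, pose$fps, "approach")
    beh$escape <- interval_indicator(events, pose$n_frames, pose$fps, "escape")
    beh$rat_movement <- interval_indicator(events, pose$n_frames, pose$fps,
                                           "rat_movement")
  }
  beh$freeze <- interval_indicator(events, pose$n_frames, pose$fps, "freeze")
  aligned <- align_timebases(zscore_traces(variance_filter(session$traces)),
                             beh, fps = pose$fps)
  list(kin = kin, zones = zones, events = events, scores = scores,
       traces = aligned$traces, behavior = aligned$behavior)
}

# CoCA behavioral matrix for one aligned session (variables x timepoints).
#' @noRd
coca_behavior_matrix <- function(behavior, assay) {
  if (assay == "EPM") {
    Y <- rbind(abs_x = behavior$abs_x, abs_y = behavior$abs_y,
               speed = behavior$speed,
               head_dip = as.numeric(behavior$head_dip),
               freeze = as.numeric(behavior$freeze),
               location_index = behavior$location_index)
    normalize_behavior_matrix(Y, minmax = c("abs_x", "abs_y"))
  } else {
    Y <- rbind(dist_rat = behavior$dist_rat, speed = behavior$speed,
               rat_speed = behavior$rat_speed,
               angle_to_rat = behavior$angle_to_rat,
               approach = as.numeric(behavior$approach),
               escape = as.numeric(behavior$escape),
               freeze = as.numeric(behavior$freeze),
               rat_movement = as.numeric(behavior$rat_movement),
               dist_safety = behavior$dist_safety)
    normalize_behavior_matrix(Y)
  }
}

#' Run the full pipeline on synthetic paired sessions
#'
#' Simulates an EPM and a rat-exposure session (and optionally a toy-rat
#' control) with shared cell identities, conditions the traces, classifies
#' behavior, and runs the requested analysis stages. Deterministic under
#' the configuration seed; the summary carries the configuration hash.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_result` with per-stage results and a
#'   `summary` list (written as JSON to `out_dir` when set).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  sim <- config$sim
  sim_rat <- sim; sim_rat$seed <- sim$seed + 1L
  sessions <- list(EPM = simulate_session(assay_geometry("EPM"), sim),
                   RAT = simulate_session(assay_geometry("RAT"), sim_rat))
  if (config$include_toy) {
    sim_toy <- sim; sim_toy$seed <- sim$seed + 2L
    sessions$TOY <- simulate_session(assay_geometry("TOY"), sim_toy)
  }
  coreg <- synthetic_coregistration(sim)
  res <- list(config_hash = hash, sessions = sessions, coreg = coreg)
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  proc <- run_stage("behavior", lapply(sessions, process_session_behavior))
  res$behavior <- proc
  summary <- list(config_hash = hash, seed = config$seed,
                  n_cells = sim$n_cells,
                  n_events = lapply(proc, function(p) table(p$events$label)))

  if ("ensembles" %in% config$stages) {
    ep <- proc$EPM
    labels <- categorize_arm_cells(ep$traces, ep$behavior$zone)
    scores <- arm_scores(ep$traces, ep$behavior$zone)
    res$ensembles <- list(labels = labels, scores = scores)
    summary$ensembles <- list(
      n_open = sum(labels$category == "open"),
      n_closed = sum(labels$category == "closed"),
      n_neither = sum(labels$category == "neither"),
      mean_abs_preference = mean(abs(scores$preference_score)))
  }
  if ("decoding" %in% config$stages) {
    ep <- proc$EPM
    split <- make_interleaved_split(ncol(ep$traces$values), ep$traces$fs)
    dec <- decode_arm_type(ep$traces, ep$behavior$zone, split,
                           n_perm = config$n_perm, seed = config$seed)
    reg <- predict_location_index(ep$traces, ep$behavior$location_index, split)
    res$decoding <- list(svm = dec, regression = reg, split = split)
    summary$decoding <- list(mcc = dec$mcc, p_perm = dec$p_perm,
                             r_location = reg$r_test)
  }
  if ("glm" %in% config$stages) {
    rp <- proc$RAT
    n_t <- ncol(rp$traces$values)
    ev_neural <- rp$events
    kin_n <- rp$behavior[, c("dist_rat", "speed", "rat_speed", "angle_to_rat")]
    X <- build_design_matrix(ev_neural, kin_n, n_t, fs = rp$traces$fs)
    split <- make_interleaved_split(n_t, rp$traces$fs)
    fit <- fit_glm_encoding(rp$traces, X, split)
    res$glm <- fit
    summary$glm <- list(mean_r2_train = mean(fit$r2_train),
                        mean_r2_test = mean(fit$r2_test))
  }
  if ("coca" %in% config$stages) {
    ids <- coreg$cell_id_assay1
    mk <- function(p) {
      idx <- match(ids, p$traces$cell_ids)
      keep <- !is.na(idx)
      list(X = p$traces$values[idx[keep], , drop = FALSE],
           keep = keep)
    }
    sess <- list()
    for (a in c("EPM", "RAT")) {
      p <- proc[[a]]
      m <- mk(p)
      sess[[a]] <- list(mouse = "m1", assay = a, X = m$X,
                        Y = coca_behavior_matrix(p$behavior, a),
                        split = make_interleaved_split(ncol(m$X), p$traces$fs))
    }
    ds <- coca_dataset(sess)
    fit <- fit_coca(ds, restarts = config$coca_restarts,
                    max_iter = config$coca_max_iter, seed = config$seed)
    sig <- coca_significance(fit, ds, n_proj = config$n_proj,
                             seed = config$seed)
    res$coca <- list(fit = fit, significance = sig)
    summary$coca <- list(r_test = sig$r_test, p = sig$p)
  }
  if ("states" %in% config$stages) {
    rp <- proc$RAT
    ids <- coreg$cell_id_assay1
    idx <- match(ids, rp$traces$cell_ids)
    idx <- idx[!is.na(idx)]
    sub <- trace_matrix(rp$traces$values[idx, , drop = FALSE],
                        fs = rp$traces$fs,
                        cell_ids = rp$traces$cell_ids[idx],
                        is_zscored = TRUE)
    km <- fit_kmeans_with_aic(sub, k_range = config$k_range,
                              seed = config$seed)
    km <- label_state_clusters(km, rp$behavior$score)
    nul <- cluster_permutation_null(km, rp$behavior$score,
                                    n_perm = config$n_perm,
                                    seed = config$seed)
    res$states <- list(model = km, null = nul)
    summary$states <- list(K = km$K,
                           approach_mean = km$cluster_score_means[km$approach_cluster],
                           avoidance_mean = km$cluster_score_means[km$avoidance_cluster],
                           approach_significant = nul$approach_significant,
                           avoidance_significant = nul$avoidance_significant)
    # cross-assay transfer onto the EPM session (shared planted coding)
    epm_ids <- intersect(coreg$cell_id_assay2, proc$EPM$traces$cell_ids)
    cmap <- coregistration_map(epm_ids, epm_ids)
    idx2 <- match(cmap$cell_id_assay1, sub$cell_ids)
    if (!anyNA(idx2) && length(idx2)) {
      km2 <- km
      km2$centroids <- km$centroids[, idx2, drop = FALSE]
      tran <- transfer_clusters_across_assays(km2, proc$EPM$traces, cmap,
                                              proc$EPM$behavior$score)
      res$states$transfer <- tran
      summary$states$transfer_p <- tran$p_ranksum
    }
  }
  res$summary <- summary
  if (!is.null(config$out_dir)) {
    if (!dir.exists(config$out_dir))
      dir.create(config$out_dir, recursive = TRUE)
    jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, force = TRUE, digits = NA)
  }
  class(res) <- "pipeline_result"
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result> stages:",
      paste(intersect(names(x), c("ensembles", "decoding", "glm", "coca",
                                  "states")), collapse = ", "), "\n")
  cat("  config hash:", x$config_hash, "\n")
  invisible(x)
}
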