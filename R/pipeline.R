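#' Pipeline configuration
#'
#' Nested configuration for the end-to-end synthetic run. Accepts a YAML
#' file or a named list; unknown keys are rejected. Every run writes the
#' resolved configuration beside its outputs.
#'
#' @param config path to a YAML file, or a named list with any of the
#'   sections `simulate` (arguments of [sim_config()] plus `groups`,
#'   `n_lexicon_words`, `feature_subset`), `decode` ([decode_config()]
#'   arguments), `stats` ([test_config()] arguments), `metrics`
#'   (`train_window`, `ci_level`), and `run` (`per_sensor`, `subsets`,
#'   `write_arrays`).
#' @param seed master seed overriding the one in the file (optional).
#' @return resolved configuration list of class `pd_pipeline_config`.
#' @export
pipeline_config <- function(config = list(), seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "decode", "stats", "metrics", "run")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  sim_extra <- c("groups", "n_lexicon_words", "lexicon_zipf", "feature_subset")
  sim_args <- config$simulate %||% list()
  bad <- setdiff(names(sim_args), c(names(formals(sim_config)), sim_extra))
  if (length(bad)) stop("unknown simulate key(s): ", paste(bad, collapse = ", "))
  check <- function(args, fn, what) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) stop("unknown ", what, " key(s): ", paste(bad, collapse = ", "))
    args
  }
  dec_args <- check(config$decode %||% list(), decode_config, "decode")
  st_args <- check(config$stats %||% list(), test_config, "stats")
  met <- config$metrics %||% list()
  bad <- setdiff(names(met), c("train_window", "ci_level"))
  if (length(bad)) stop("unknown metrics key(s): ", paste(bad, collapse = ", "))
  run <- config$run %||% list()
  bad <- setdiff(names(run), c("per_sensor", "subsets", "write_arrays"))
  if (length(bad)) stop("unknown run key(s): ", paste(bad, collapse = ", "))
  if (!is.null(seed)) sim_args$seed <- seed
  extras <- sim_args[intersect(names(sim_args), sim_extra)]
  sim_args <- sim_args[setdiff(names(sim_args), sim_extra)]
  cfg <- list(
    simulate = do.call(sim_config, sim_args),
    sim_extras = extras,
    decode = do.call(decode_config, dec_args),
    stats = do.call(test_config, st_args),
    metrics = list(train_window = met$train_window %||% c(0, 0.35),
                   ci_level = met$ci_level %||% 0.95),
    run = list(per_sensor = isTRUE(run$per_sensor %||% TRUE),
               subsets = isTRUE(run$subsets %||% TRUE),
               write_arrays = isTRUE(run$write_arrays %||% FALSE)))
  class(cfg) <- "pd_pipeline_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Decode all features once, collecting the feature-average TG matrix and
# (optionally) per-subset-level feature averages in the same pass.
decode_stage <- function(epochs, table, subset_labels, cfg) {
  lv <- character(0)
  sub <- integer(dim(epochs$data)[1])
  if (!is.null(subset_labels)) {
    f <- factor(subset_labels)
    lv <- levels(f)
    sub <- as.integer(f)
    sub[is.na(sub)] <- 0L
  }
  acc <- NULL; acc_lv <- NULL; per_feature <- list(); nf <- 0L
  for (fname in table$feature_names) {
    y <- table$matrix[, fname]
    res <- tryCatch({
      fold <- make_folds(y, cfg$n_folds, cfg$seed)
      cpp_tg_decode(epochs$data, as.double(y), as.integer(fold), sub,
                    length(lv), cfg$lambda, cfg$max_iter, cfg$tol)
    }, error = function(e) {
      warning("feature ", fname, " dropped: ", conditionMessage(e)); NULL
    })
    if (is.null(res)) next
    nf <- nf + 1L
    per_feature[[fname]] <- res$overall
    acc <- if (is.null(acc)) res$overall else acc + res$overall
    if (length(lv)) {
      if (is.null(acc_lv)) acc_lv <- res$levels
      else for (i in seq_along(lv)) acc_lv[[i]] <- acc_lv[[i]] + res$levels[[i]]
    }
  }
  if (nf == 0L) stop("no feature could be decoded")
  out <- list(average = acc / nf, per_feature = per_feature)
  if (length(lv))
    out$subset_average <- setNames(lapply(acc_lv, function(m) m / nf), lv)
  out
}

#' Run the full synthetic pipeline
#'
#' Simulates a multi-group dataset, runs the conditioning chain and
#' epoching, decodes every retained phonetic feature with temporal
#' generalization (plus entropy-tertile test subsets and per-sensor
#' topographies), derives diagonals, generalization profiles and widths,
#' and performs the group statistics. Writes a deterministic output tree
#' `epochs/`, `tg/`, `metrics/`, `stats/`, `report/` under `out_dir`,
#' with machine-readable JSON summaries in `report/summary.json`.
#'
#' @param config a [pipeline_config()] (or anything it accepts).
#' @param out_dir output directory.
#' @param seed optional master-seed override.
#' @return the summary list, invisibly; also written as JSON.
#' @export
run_pipeline <- function(config = list(), out_dir, seed = NULL) {
  cfg <- if (inherits(config, "pd_pipeline_config")) config else
    pipeline_config(config, seed = seed)
  if (!is.null(seed)) cfg$simulate$seed <- seed
  for (d in c("", "epochs", "tg", "metrics", "stats", "report"))
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass_deep(cfg), file.path(out_dir, "config_resolved.yaml"))

  scfg <- cfg$simulate
  groups <- cfg$sim_extras$groups %||% names(scfg$group_gain_profile)
  subjects <- simulate_dataset(
    scfg, groups = groups,
    n_lexicon_words = cfg$sim_extras$n_lexicon_words %||% 250L,
    lexicon_zipf = cfg$sim_extras$lexicon_zipf %||% 1,
    feature_subset = cfg$sim_extras$feature_subset)

  tw <- cfg$metrics$train_window
  per_subject <- list()
  for (rec in subjects) {
    ep <- preprocess_chain(rec$eeg, rec$events)
    keep <- match(rownames(ep$events), rownames(rec$events))
    ft <- new_feature_table(rec$features$matrix[keep, , drop = FALSE])
    sub_lab <- if (cfg$run$subsets) ep$events$entropy_tertile else NULL
    dec <- decode_stage(ep, ft, sub_lab, cfg$decode)
    topo <- if (cfg$run$per_sensor) decode_per_sensor(ep, ft, cfg$decode) else NULL
    tg <- new_tg_matrix(dec$average, ep$times_s, feature = "average",
                        subject = rec$subject)
    prof <- tg_reorient(tg, train_window = tw)
    wid <- generalization_width(prof, ci_level = cfg$metrics$ci_level)
    if (cfg$run$write_arrays)
      write_eeg(continuous_eeg(dec$average, ep$sfreq),
                file.path(out_dir, "tg", sprintf("sub%02d_tg", rec$subject)))
    jsonlite::write_json(
      list(subject = rec$subject, group = rec$group,
           n_events = dim(ep$data)[1],
           n_dropped = nrow(rec$events) - dim(ep$data)[1],
           features = ft$feature_names),
      file.path(out_dir, "epochs", sprintf("sub%02d.json", rec$subject)),
      auto_unbox = TRUE)
    per_subject[[rec$subject]] <- list(
      subject = rec$subject, group = rec$group, tg = tg,
      per_feature = dec$per_feature,
      subset = dec$subset_average, topo = topo,
      diagonal = diag(dec$average), width_s = wid$width_s,
      times_s = ep$times_s)
  }
  times <- per_subject[[1]]$times_s
  grp <- vapply(per_subject, `[[`, character(1), "group")
  diags <- t(vapply(per_subject, `[[`, numeric(length(times)), "diagonal"))
  widths <- vapply(per_subject, `[[`, numeric(1), "width_s")
  g1 <- groups[1]; g2 <- if (length(groups) > 1) groups[2] else NULL

  stats_cfg <- cfg$stats
  summary <- list(groups = groups,
                  n_subjects = as.integer(table(grp)[groups]),
                  times_s = times)

  # per-feature above-chance windows (first group), Table-2-style layout
  featnames <- names(per_subject[[1]]$per_feature)
  ia <- which(grp == g1)
  feat_windows <- list()
  for (f in featnames) {
    dm <- t(vapply(per_subject[ia], function(s) diag(s$per_feature[[f]]),
                   numeric(length(times))))
    de <- diagonal_extent(dm, times, cfg = stats_cfg)
    feat_windows[[f]] <- list(
      windows = de$windows,
      mean_auc = mean(dm),
      extent_s = de$extent_s)
  }
  summary$feature_windows <- feat_windows
  de_avg <- diagonal_extent(diags[ia, , drop = FALSE], times, cfg = stats_cfg)
  summary$average_diagonal <- list(extent_s = de_avg$extent_s,
                                   windows = de_avg$windows)

  # dynamic-vs-static delta within first group
  dd <- dynamic_delta(lapply(per_subject[ia], `[[`, "tg"), train_window = tw)
  delta_res <- one_sample_cluster_perm(
    dd$delta[, dd$domain, drop = FALSE], cfg = stats_cfg,
    adjacency = adjacency_1d(length(dd$domain)))
  neg <- which(delta_res$p <= stats_cfg$alpha & delta_res$masses < 0)
  summary$dynamic_delta <- list(
    n_negative_clusters = length(neg),
    domain_s = range(times[dd$domain]),
    cluster_p = delta_res$p, cluster_masses = delta_res$masses)

  summary$widths <- data.frame(subject = vapply(per_subject, `[[`,
                                                integer(1), "subject"),
                               group = grp, width_s = widths)

  if (!is.null(g2)) {
    ib <- which(grp == g2)
    gc <- two_sample_cluster_perm(diags[ia, , drop = FALSE],
                                  diags[ib, , drop = FALSE], cfg = stats_cfg)
    sig <- which(gc$p <= stats_cfg$alpha)
    wins <- lapply(sig, function(c) range(times[gc$clusters[[c]]]))
    summary$group_clusters <- list(
      p = gc$p, masses = gc$masses,
      windows = if (length(wins)) do.call(rbind, wins) else NULL)
    summary$width_test <- perm_ttest_scalar(widths[ia], widths[ib],
                                            stats_cfg$n_permutations,
                                            stats_cfg$seed)
    if (cfg$run$per_sensor) {
      topoA <- t(vapply(per_subject[ia], `[[`,
                        numeric(length(per_subject[[1]]$topo)), "topo"))
      topoB <- t(vapply(per_subject[ib], `[[`,
                        numeric(length(per_subject[[1]]$topo)), "topo"))
      st <- max_t_sensor_test(topoA, topoB, stats_cfg)
      summary$sensor_test <- list(t = st$t, p_corrected = st$p_corrected,
                                  significant = st$significant)
    }
    if (cfg$run$subsets && !is.null(per_subject[[1]]$subset)) {
      getdiag <- function(ix, lev)
        t(vapply(per_subject[ix],
                 function(s) diag(s$subset[[lev]]), numeric(length(times))))
      ei <- entropy_interaction(getdiag(ia, "high"), getdiag(ia, "low"),
                                getdiag(ib, "high"), getdiag(ib, "low"),
                                times, alpha = stats_cfg$alpha)
      summary$entropy_interaction <- ei
    }
  }

  jsonlite::write_json(summary, file.path(out_dir, "report", "summary.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns",
                       force = TRUE)
  utils::write.csv(summary$widths, file.path(out_dir, "metrics", "widths.csv"),
                   row.names = FALSE)
  invisible(summary)
}

unclass_deep <- function(x) {
  x <- unclass(x)
  if (is.list(x)) lapply(x, unclass_deep) else x
}

#' Validate a phoneme event table
#'
#' Checks monotone onsets, positive durations, word-token contiguity and
#' phoneme inventory membership.
#'
#' @param path TSV path (columns as written by [write_events()]).
#' @param inventory allowed phoneme labels (default: shipped map).
#' @return character vector of error messages (empty if well-formed).
#' @export
validate_events <- function(path, inventory = phoneme_inventory()) {
  ev <- read_events(path)
  errs <- character(0)
  bad <- which(diff(ev$onset_s) < 0)
  if (length(bad))
    errs <- c(errs, paste0("onset regression at row ", bad[1] + 1))
  bad <- which(ev$duration_s <= 0)
  if (length(bad))
    errs <- c(errs, paste0("non-positive duration at row ", bad[1]))
  r <- rle(ev$word_index)
  if (anyDuplicated(r$values))
    errs <- c(errs, "word tokens are not contiguous (word_index repeats)")
  unknown <- setdiff(unique(ev$phoneme), inventory)
  if (length(unknown))
    errs <- c(errs, paste0("unknown phoneme label(s): ",
                           paste(unknown, collapse = ", ")))
  errs
}
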