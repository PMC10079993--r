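#' Pipeline configuration
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort to
#'   generate, or a path to an existing cohort container directory.
#' @param bands Character vector of band names to analyse.
#' @param density Proportional-threshold density for graph construction.
#' @param variants CNN variants to train: subset of `c("pli", "eeg")`
#'   (empty to skip classification).
#' @param epochs Training epochs for the CNN stage.
#' @param k Number of cross-validation folds.
#' @param test_fold Held-out fold for the reported evaluation.
#' @param out_dir Optional output directory for TSV/JSON artifacts.
#' @param seed Global pipeline seed; all stage seeds derive from it.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = default_cohort_spec(), bands = "theta",
                            density = 0.30, variants = "pli", epochs = 150L,
                            k = 10L, test_fold = 1L, out_dir = NULL,
                            seed = 1L) {
  known <- names(eeg_bands())
  abort_if(!all(bands %in% known),
           sprintf("unknown band(s): %s", paste(setdiff(bands, known), collapse = ", ")))
  abort_if(is.character(cohort) && !dir.exists(cohort),
           sprintf("cohort path '%s' does not exist", cohort))
  structure(list(cohort = cohort, bands = bands, density = density,
                 variants = variants, epochs = as.integer(epochs),
                 k = as.integer(k), test_fold = as.integer(test_fold),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

# Per-subject, per-band analysis products from a synthesized epoch set.
subject_band_products <- function(es, band, keep_epochs = FALSE) {
  ph <- band_phase_series(es, band)
  trials <- pli_trial_matrices(ph)
  vals <- apply(trials, c(2, 3), mean)
  dimnames(vals) <- list(ph$channel_names, ph$channel_names)
  list(subject_matrix = connectivity_matrix(vals, band = ph$band,
                                            level = "subject"),
       trial_matrices = trials,
       epochs = if (keep_epochs) band_epochs(es, band)$data else NULL)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, then per band: zero-phase band filtering
#' of each continuous record, target-locked epoching, Hilbert phase
#' extraction, per-trial PLI matrices and subject-level means,
#' proportional-threshold graphs with node/graph metrics, group-mean and
#' group-difference matrices, one-way ANOVA with Tukey post-hoc comparisons
#' on channel-mean connectivity, and (optionally) compact-CNN training and
#' evaluation under subject-exclusive cross-validation. Subjects are
#' processed one at a time so memory stays flat in cohort size.
#'
#' @param config A [pipeline_config()].
#' @param verbose Print stage progress.
#' @return A `pipeline_result` list, one entry per band, plus the fold
#'   assignment and a manifest of seeds. If `config$out_dir` is set, TSV and
#'   JSON artifacts are written there.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  from_disk <- is.character(config$cohort)
  if (from_disk) {
    cohort <- import_external(config$cohort)
    plan <- cbind(cohort$manifest, group_index = NA)
    spec <- NULL
  } else {
    spec <- config$cohort
    spec$seed <- derive_seed(config$seed, "cohort")
    plan <- cohort_plan(spec)
  }

  keep_epochs <- "eeg" %in% config$variants
  subjects <- plan$subject_id
  groups <- stats::setNames(plan$group, plan$subject_id)
  per_band <- stats::setNames(
    lapply(config$bands, function(b)
      list(subject_matrices = list(), trial_matrices = list(), epochs = list())),
    config$bands)

  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    es <- if (from_disk) cohort$subjects[[sid]] else
      synthesize_planned_subject(spec, plan[i, ])
    abort_if(from_disk && is.null(es$record) && is.null(es$data),
             sprintf("subject '%s' has no data", sid))
    for (b in config$bands) {
      pr <- if (is.null(es$record)) {
        # pre-epoched container: band-filter the epochs directly (no record)
        be <- es
        be$data <- aperm(apply(es$data, c(1, 2), bandpass,
                               band = b, sampling_rate = es$sampling_rate),
                         c(2, 3, 1))
        be$band <- b
        ph <- instantaneous_phase(be)
        list(subject_matrix = pli_matrix(ph),
             trial_matrices = pli_trial_matrices(ph),
             epochs = if (keep_epochs) be$data else NULL)
      } else subject_band_products(es, b, keep_epochs)
      per_band[[b]]$subject_matrices[[sid]] <- pr$subject_matrix
      per_band[[b]]$trial_matrices[[sid]] <- pr$trial_matrices
      if (keep_epochs) per_band[[b]]$epochs[[sid]] <- pr$epochs
    }
    say("processed subject %s (%d/%d)", sid, i, length(subjects))
  }

  folds <- if (length(config$variants))
    assign_folds(subjects, unname(groups), k = config$k,
                 seed = derive_seed(config$seed, "folds"))
  else NULL
  results <- list()
  for (b in config$bands) {
    say("band %s: graphs, statistics%s", b,
        if (length(config$variants)) ", classifier" else "")
    sm <- per_band[[b]]$subject_matrices
    grp <- groups[names(sm)]

    graphs <- lapply(sm, function(m)
      brain_graph(proportional_threshold(m, config$density)))
    metric_tables <- lapply(names(graphs), function(sid)
      cbind(subject = sid, node_metric_table(graphs[[sid]], band = b,
                                             group = grp[[sid]])))
    metrics <- do.call(rbind, metric_tables)
    eglob <- data.frame(subject = names(graphs), group = unname(grp),
                        band = b,
                        global_efficiency = vapply(graphs, global_efficiency, 0))

    group_levels <- unique(unname(grp))
    group_matrices <- lapply(group_levels, function(g)
      group_mean_matrix(sm[names(grp)[grp == g]]))
    names(group_matrices) <- group_levels
    diffs <- list()
    for (a in seq_along(group_levels)) for (bb in seq_along(group_levels)) {
      if (a >= bb) next
      key <- paste0(group_levels[a], "_vs_", group_levels[bb])
      diffs[[key]] <- difference_matrix(group_matrices[[group_levels[a]]],
                                        group_matrices[[group_levels[bb]]])
    }

    stats_res <- compare_groups(sm, unname(grp), names(sm), band = b)

    cnn <- list()
    for (variant in config$variants) {
      arch <- architecture_spec(variant)
      samples <- if (variant == "pli") per_band[[b]]$trial_matrices
                 else per_band[[b]]$epochs
      cfg <- train_config(epochs = config$epochs,
                          seed = derive_seed(config$seed, paste0("train_", b, "_", variant)))
      tr <- train_cnn(samples, groups, folds, arch, cfg,
                      test_fold = config$test_fold)
      ev <- evaluate_model(tr$model, samples, groups, tr$splits$test,
                           levels = tr$levels)
      cnn[[variant]] <- list(result = tr, evaluation = ev)
    }

    results[[b]] <- list(subject_matrices = sm, group_matrices = group_matrices,
                         difference_matrices = diffs, graphs = graphs,
                         metrics = metrics, global_efficiency = eglob,
                         stats = stats_res, cnn = cnn)
  }

  out <- structure(list(bands = results, folds = folds, groups = groups,
                        config = config,
                        manifest = plan[, c("group", "subject_id", "seed")]),
                   class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_results(out, config$out_dir)
  out
}

# Write the TSV/JSON artifact tree of a pipeline run.
write_pipeline_results <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in names(res$bands)) {
    rb <- res$bands[[b]]
    bd <- file.path(dir, b)
    dir.create(bd, showWarnings = FALSE)
    for (g in names(rb$group_matrices))
      write_connectivity_tsv(rb$group_matrices[[g]],
                             file.path(bd, sprintf("connectivity_group_%s.tsv", g)))
    for (k in names(rb$difference_matrices))
      write_connectivity_tsv(rb$difference_matrices[[k]],
                             file.path(bd, sprintf("difference_%s.tsv", k)))
    utils::write.table(rb$metrics, file.path(bd, "node_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rb$global_efficiency, file.path(bd, "global_efficiency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    an <- rb$stats$anova
    utils::write.table(
      data.frame(band = b, ss_between = an$ss_between, ms_between = an$ms_between,
                 F = an$F, p = an$p),
      file.path(bd, "anova.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cbind(band = b, rb$stats$tukey),
                       file.path(bd, "tukey.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (v in names(rb$cnn)) {
      utils::write.table(rb$cnn[[v]]$result$history,
                         file.path(bd, sprintf("cnn_%s_history.tsv", v)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      ev <- rb$cnn[[v]]$evaluation
      jsonlite::write_json(
        list(variant = v, band = b, accuracy = ev$accuracy,
             macro_f1 = ev$macro_f1, precision = ev$precision,
             recall = ev$recall, f1 = ev$f1,
             confusion = unclass(ev$confusion),
             best_epoch = rb$cnn[[v]]$result$best_epoch),
        file.path(bd, sprintf("cnn_%s_report.json", v)),
        auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(
    list(seed = res$config$seed, bands = res$config$bands,
         density = res$config$density, variants = res$config$variants,
         epochs = res$config$epochs,
         subjects = res$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Import an external dataset container
#'
#' Reads a cohort container directory and validates it against the expected
#' montage, naming any missing channels.
#'
#' @param path Container directory (see [write_cohort()]).
#' @param montage Expected channel names (default [default_montage()]).
#' @return A `cohort` list.
#' @export
import_external <- function(path, montage = default_montage()) {
  cohort <- read_cohort(path)
  got <- cohort$montage
  missing <- setdiff(montage, got)
  abort_if(length(missing) > 0, sprintf(
    "container montage lacks %d channel(s): %s",
    length(missing), paste(missing, collapse = ", ")))
  abort_if(length(got) != length(montage), sprintf(
    "container has %d channels; expected %d", length(got), length(montage)))
  cohort
}
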