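# End-to-end desk-scale experiment for one model instance, and a resumable
# multi-seed pipeline that writes all per-stage artifacts.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis for one model instance
#'
#' Trains an N-stream model on the synthetic dataset, then runs every
#' analysis stage: first-layer tuning metrics with between-stream tests,
#' between-stream RDM correlations per layer, the stream-deletion
#' experiment in both deletion modes, and (optionally) MES synthesis for a
#' deeper layer.
#'
#' @param train_seed seed for weight init and training (the instance id).
#' @param dataset a `shape_dataset` (shared across instances).
#' @param arch a [stream_arch()]; defaults to [desk_arch()] sized to the
#'   dataset.
#' @param tspec a [train_spec()]; defaults to [desk_train_spec()] with
#'   `train_seed`.
#' @param include_mes synthesize MES for `mes_layer` filters and summarize
#'   their colour index / preferred SF per stream.
#' @param mes_layer layer for MES synthesis (default `"conv2"`).
#' @param mes_filters filters per stream for MES (default all).
#' @param mes_steps ascent steps per MES.
#' @param n_permutations permutations for the deletion AUC test.
#' @param rdm_splits,rdm_seed split-half settings for the RDM diagonal.
#' @param alpha significance threshold for the between-stream tests
#'   (desk-scale default 0.05: per-stream filter counts are an order of
#'   magnitude below full scale).
#' @return list with `model`, `log`, `records` (per-filter table),
#'   `compare` (per-metric between-stream tests), `rdm` (cross-layer
#'   table), `between_stream_rdm`, `deletion` (from
#'   [compare_deletion_modes()]), `mes` (per-stream MES tables or NULL),
#'   and `summary` (one wide data.frame row).
#' @export
run_desk_experiment <- function(train_seed, dataset, arch = NULL,
                                tspec = NULL, include_mes = FALSE,
                                mes_layer = "conv2", mes_filters = NULL,
                                mes_steps = 128, n_permutations = 1000,
                                rdm_splits = 10, rdm_seed = 1, alpha = 0.05) {
  .assert(inherits(dataset, "shape_dataset"), "dataset must be a shape_dataset")
  arch <- arch %||% desk_arch(n_classes = dataset$spec$n_categories,
                              input_size = dataset$spec$image_size)
  tspec <- tspec %||% desk_train_spec(seed = train_seed)
  model <- build_model(arch, seed = train_seed)
  tr <- train(model, dataset, tspec)
  model <- tr$model

  records <- do.call(rbind, lapply(seq_len(arch$n_streams), function(s) {
    analyze_filter_bank(get_kernels(model, "conv1", s))
  }))
  cmp <- list(color_index = compare_streams(records, "color_index", alpha),
              orientation_index = compare_streams(records,
                                                  "orientation_index", alpha),
              preferred_sf = compare_streams(records, "preferred_sf", alpha))

  stim <- generate_rdm_stimulus_set(dataset, 1, seed = rdm_seed)
  cross <- cross_layer_matrix(model, stim, n_splits = rdm_splits,
                              seed = rdm_seed)
  bsr <- between_stream_rdm(cross)

  del <- compare_deletion_modes(model, dataset$eval$x, dataset$eval$y,
                                dataset$categories,
                                n_permutations = n_permutations,
                                seed = train_seed)

  mes_tabs <- NULL
  if (include_mes) {
    mes_tabs <- lapply(seq_len(arch$n_streams), function(s) {
      mes_summary(model, mes_layer, s, filter_indices = mes_filters,
                  n_steps = mes_steps, seed = train_seed)
    })
  }

  summary_row <- .instance_summary(train_seed, tr$log, records, cmp, bsr,
                                   del, mes_tabs, arch)
  list(model = model, log = tr$log, records = records, compare = cmp,
       rdm = cross, between_stream_rdm = bsr, deletion = del,
       mes = mes_tabs, summary = summary_row)
}

# Flatten one instance's results into a single wide data.frame row.
.instance_summary <- function(train_seed, log, records, cmp, bsr, del,
                              mes_tabs, arch) {
  last <- log[nrow(log), ]
  row <- data.frame(instance = train_seed, eval_top1 = last$eval_top1,
                    eval_top5 = last$eval_top5)
  for (metric in names(cmp)) {
    cm <- cmp[[metric]]
    short <- c(color_index = "color", orientation_index = "orient",
               preferred_sf = "sf")[[metric]]
    for (s in seq_along(cm$summaries)) {
      row[[paste0(short, "_s", s)]] <- unname(cm$summaries[s])
    }
    row[[paste0(short, "_abs_diff")]] <-
      if (length(cm$summaries) == 2)
        abs(cm$summaries[1] - cm$summaries[2]) else NA_real_
    row[[paste0(short, "_p")]] <- cm$p_value
  }
  for (i in seq_len(nrow(bsr))) {
    row[[paste0("rdm_between_", bsr$layer[i])]] <- bsr$r[i]
  }
  at <- del$auc_table
  for (i in seq_len(nrow(at))) {
    row[[paste0("auc_", at$mode[i], "_s", at$stream[i])]] <- at$auc[i]
    row[[paste0("auc_", at$mode[i], "_s", at$stream[i], "_p")]] <- at$p_value[i]
  }
  row$mode_rank_correlation <- del$mode_rank_correlation
  # the stream with higher median colour index, and its zero-mode AUC
  cs <- cmp$color_index$summaries
  hi <- which.max(cs)
  row$high_color_stream <- hi
  row$auc_high_color_zero <- at$auc[at$mode == "zero" & at$stream == hi]
  row$auc_high_color_zero_p <- at$p_value[at$mode == "zero" & at$stream == hi]
  if (!is.null(mes_tabs)) {
    for (s in seq_along(mes_tabs)) {
      mt <- mes_tabs[[s]][!mes_tabs[[s]]$dead_filter, , drop = FALSE]
      row[[paste0("mes_color_s", s)]] <- stats::median(mt$color_index,
                                                       na.rm = TRUE)
      row[[paste0("mes_sf_s", s)]] <- stats::median(mt$preferred_sf,
                                                    na.rm = TRUE)
    }
    if (length(mes_tabs) == 2) {
      row$mes_color_abs_diff <- abs(row$mes_color_s1 - row$mes_color_s2)
    }
  }
  rownames(row) <- NULL
  row
}

# Deterministic config fingerprint for cache safety.
.config_fingerprint <- function(config) {
  keep <- config[setdiff(names(config), "out_dir")]
  paste(deparse(lapply(keep, function(x) if (is.list(x)) unclass(x) else x)),
        collapse = "\n")
}

#' Run the multi-instance pipeline
#'
#' For each seed: (re)generate or reuse the dataset, train, analyse
#' (tuning metrics, RDM, deletion, optional MES), and write artifacts under
#' `out_dir`: the dataset (`dataset/`), per-instance checkpoints
#' (`ckpt_seed<k>.rds`), training logs and per-filter tables (CSV), and the
#' instance summary table (`summary.csv`). The run is resumable: completed
#' instances are skipped when their summary file exists, and a config
#' fingerprint refuses to mix artifacts from different configurations.
#'
#' @param config list with `dataset_spec` (a [dataset_spec()]), `seeds`
#'   (integer vector of instance seeds), `out_dir`, and optionally `arch`,
#'   `train` (a [train_spec()]), `include_mes`, `n_permutations`,
#'   `rdm_splits`, `alpha`.
#' @param verbose print stage progress.
#' @return data.frame of instance summaries (one row per seed), invisibly
#'   also written to `<out_dir>/summary.csv`.
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  .assert(is.list(config) && !is.null(config$dataset_spec) &&
            !is.null(config$seeds) && !is.null(config$out_dir),
          "config needs at least dataset_spec, seeds, out_dir")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- .config_fingerprint(config)
  fp_file <- file.path(out_dir, "config.txt")
  if (file.exists(fp_file)) {
    .assert(identical(paste(readLines(fp_file), collapse = "\n"), fp),
            paste("out_dir contains artifacts from a different configuration;",
                  "refusing to mix (use a fresh out_dir)"))
  } else {
    writeLines(fp, fp_file)
  }

  ds_dir <- file.path(out_dir, "dataset")
  if (file.exists(file.path(ds_dir, "categories.csv"))) {
    if (verbose) message("reusing cached dataset")
    dataset <- load_shape_dataset(ds_dir)
  } else {
    if (verbose) message("generating dataset")
    dataset <- generate_dataset(config$dataset_spec, out_dir = ds_dir)
  }

  summaries <- list()
  for (seed in config$seeds) {
    sfile <- file.path(out_dir, sprintf("summary_seed%d.csv", seed))
    if (file.exists(sfile)) {
      if (verbose) message(sprintf("seed %d: cached", seed))
      summaries[[length(summaries) + 1L]] <-
        utils::read.csv(sfile, stringsAsFactors = FALSE)
      next
    }
    if (verbose) message(sprintf("seed %d: training + analysis", seed))
    res <- run_desk_experiment(
      seed, dataset, arch = config$arch, tspec = config$train,
      include_mes = isTRUE(config$include_mes),
      n_permutations = config$n_permutations %||% 1000,
      rdm_splits = config$rdm_splits %||% 10,
      alpha = config$alpha %||% 0.05
    )
    save_checkpoint(res$model, file.path(out_dir,
                                         sprintf("ckpt_seed%d.rds", seed)))
    utils::write.csv(res$log,
                     file.path(out_dir, sprintf("trainlog_seed%d.csv", seed)),
                     row.names = FALSE)
    utils::write.csv(res$records,
                     file.path(out_dir, sprintf("filters_seed%d.csv", seed)),
                     row.names = FALSE)
    utils::write.csv(res$rdm,
                     file.path(out_dir, sprintf("rdm_seed%d.csv", seed)),
                     row.names = FALSE)
    utils::write.csv(res$deletion$auc_table,
                     file.path(out_dir, sprintf("auc_seed%d.csv", seed)),
                     row.names = FALSE)
    utils::write.csv(res$summary, sfile, row.names = FALSE)
    summaries[[length(summaries) + 1L]] <- res$summary
  }
  out <- do.call(rbind, summaries)
  utils::write.csv(out, file.path(out_dir, "summary.csv"), row.names = FALSE)
  writeLines(.pipeline_text_summary(out), file.path(out_dir, "summary.txt"))
  out
}

# One-paragraph plain-text digest of a multi-instance summary table.
.pipeline_text_summary <- function(out) {
  alpha <- 0.05
  lines <- c(sprintf("instances: %d", nrow(out)),
             sprintf("eval top-1: median %.3f (range %.3f-%.3f)",
                     stats::median(out$eval_top1), min(out$eval_top1),
                     max(out$eval_top1)),
             sprintf("conv1 colour-index |diff|: median %.3f; significant (p < %.2f) in %d/%d",
                     stats::median(out$color_abs_diff), alpha,
                     sum(out$color_p < alpha), nrow(out)),
             sprintf("deletion AUC of higher-colour stream (zero mode): median %.3f; > 0.5 in %d/%d",
                     stats::median(out$auc_high_color_zero),
                     sum(out$auc_high_color_zero > 0.5), nrow(out)))
  rdm_cols <- grep("^rdm_between_", names(out), value = TRUE)
  if (length(rdm_cols) >= 2) {
    first <- out[[rdm_cols[1]]]
    last <- out[[rdm_cols[length(rdm_cols)]]]
    lines <- c(lines,
               sprintf("between-stream RDM correlation: %s median %.3f, %s median %.3f; non-increasing in %d/%d",
                       sub("rdm_between_", "", rdm_cols[1]),
                       stats::median(first),
                       sub("rdm_between_", "", rdm_cols[length(rdm_cols)]),
                       stats::median(last), sum(last <= first), nrow(out)))
  }
  lines
}
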