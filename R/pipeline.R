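#' Study configuration for the end-to-end pipeline
#'
#' @param mode `"simulate"` (generate a phantom cohort) or `"files"` (load a
#'   cohort from a manifest CSV; see [load_cohort()]).
#' @param n_patients cohort size for simulate mode (default 10).
#' @param phantom a [phantom_config()] for simulate mode.
#' @param manifest manifest CSV path for files mode.
#' @param ratios a [subregion_ratios()].
#' @param v_thresholds_gy V-metric thresholds in Gy, positive and
#'   increasing (default 5, 10, 15, 20, 30, 40, 50).
#' @param d_percents D-metric percentiles (default 1, 50, 99).
#' @param posthoc `"lsd"` or `"bonferroni"` pairwise procedure.
#' @param out_dir directory for report CSVs and the run log, or `NULL` to
#'   skip writing.
#' @param seed integer seed driving the simulated cohort.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "files"),
                         n_patients = 10,
                         phantom = phantom_config(),
                         manifest = NULL,
                         ratios = subregion_ratios(),
                         v_thresholds_gy = c(5, 10, 15, 20, 30, 40, 50),
                         d_percents = c(1, 50, 99),
                         posthoc = c("lsd", "bonferroni"),
                         out_dir = NULL,
                         seed = 1) {
  mode <- match.arg(mode)
  posthoc <- match.arg(posthoc)
  if (mode == "files" && is.null(manifest)) {
    stop("files mode needs a manifest", call. = FALSE)
  }
  if (length(v_thresholds_gy) &&
      (any(v_thresholds_gy <= 0) || is.unsorted(v_thresholds_gy,
                                                strictly = TRUE))) {
    stop("v_thresholds_gy must be positive and strictly increasing",
         call. = FALSE)
  }
  structure(
    list(mode = mode, n_patients = n_patients, phantom = phantom,
         manifest = manifest, ratios = ratios,
         v_thresholds_gy = v_thresholds_gy, d_percents = d_percents,
         posthoc = posthoc, out_dir = out_dir, seed = seed),
    class = "study_config"
  )
}

# One long-format metric block for a structure on the dose grid.
.metric_rows <- function(patient, side, region, dose, mask, config) {
  mb <- metrics_bundle(dose, mask, config$v_thresholds_gy,
                       config$d_percents)
  data.frame(
    patient = patient, side = side, region = region,
    metric = c(names(mb$d), "Dmean", names(mb$v_at), "volume_cc"),
    value = c(unname(mb$d), mb$dmean, unname(mb$v_at), mb$volume_cc),
    stringsAsFactors = FALSE
  )
}

# Summarize one metric across patients for the three subregions of one
# side: mean/SD per region, overall ANOVA p, Fisher-LSD pairwise p, with
# the zero-mean skip rule — regions whose cohort mean is 0 take no part in
# any test and their cells are reported as NA (written as an em dash).
.subregion_stats <- function(df, posthoc) {
  regions <- c("head", "body", "tail")
  groups <- lapply(regions, function(r) df$value[df$region == r])
  names(groups) <- regions
  summ <- lapply(groups, summarize_values)
  nonzero <- vapply(groups, function(g) mean(g) != 0, logical(1))
  enough <- all(lengths(groups) >= 2)
  overall_p <- NA_real_
  if (enough && sum(nonzero) >= 2) {
    overall_p <- tryCatch(one_way_anova(groups[nonzero])$p,
                          error = function(e) NA_real_)
  }
  pw <- c("head-body" = NA_real_, "head-tail" = NA_real_,
          "body-tail" = NA_real_)
  if (enough && sum(nonzero) >= 2) {
    pt <- tryCatch(pairwise_tests(groups[nonzero], method = posthoc),
                   error = function(e) NULL)
    if (!is.null(pt)) {
      for (i in seq_len(nrow(pt))) {
        key <- paste(intersect(regions, c(pt$group1[i], pt$group2[i])),
                     collapse = "-")
        pw[key] <- pt$p[i]
      }
    }
  }
  data.frame(
    region = regions,
    mean = vapply(summ, `[[`, numeric(1), "mean"),
    sd = vapply(summ, `[[`, numeric(1), "sd"),
    n = vapply(summ, `[[`, numeric(1), "n"),
    overall_p = overall_p,
    p_head_body = pw[["head-body"]],
    p_head_tail = pw[["head-tail"]],
    p_body_tail = pw[["body-tail"]],
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full substructure dosimetry study
#'
#' For every patient and side: resample the structure onto the dose grid,
#' split it into head/body/tail by the configured layer ratios, and compute
#' the dose metrics for the whole structure and each subregion. Across
#' patients, per side and metric: mean +/- SD per subregion, overall one-way
#' ANOVA p and pairwise p values (head-body, head-tail, body-tail).
#' Patients whose structure spans fewer than 3 layers are skipped with a
#' logged warning. When every patient carries a pre/post score pair, a
#' paired t test is added.
#'
#' Output mirrors the conventional reporting layout: one table of
#' whole-structure D metrics per side, one of D metrics by subregion with
#' test columns, one of V metrics by subregion with test columns (cells
#' whose group mean is 0 are skipped and written as an em dash).
#'
#' @param config a [study_config()].
#' @return An object of class `cohort_table`: list with `per_patient`
#'   (long data frame), `table1_whole`, `table2_d_metrics`,
#'   `table3_v_metrics`, `scores` (or `NULL`), `skipped` (character), `log`
#'   (character lines), `files` (paths written, when `out_dir` is set).
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cohort <- if (config$mode == "simulate") {
    make_cohort(config$n_patients, config$phantom, config$seed)
  } else {
    load_cohort(config$manifest)
  }
  log <- character(0)
  say <- function(...) {
    log[[length(log) + 1L]] <<- paste0(...)
  }
  say("cohort: ", length(cohort), " patients, mode=", config$mode,
      ", seed=", config$seed)
  rows <- list()
  skipped <- character(0)
  for (p in cohort) {
    for (side in c("HC-L", "HC-R")) {
      mask <- if (side == "HC-L") p$left else p$right
      mask <- resample_mask(mask, p$dose$grid)
      vol <- mask_volume(mask)
      n_layers <- tryCatch(count_layers(mask), error = function(e) 0L)
      if (n_layers < 3) {
        say(p$id, " ", side, ": skipped (", n_layers,
            " layers, volume ", format(vol, digits = 4), " cc)")
        skipped <- c(skipped, paste(p$id, side))
        next
      }
      split <- split_structure(mask, config$ratios)
      say(p$id, " ", side, ": ", n_layers, " layers, volume ",
          format(vol, digits = 4), " cc, boundaries after layers ",
          paste(split$boundary_layers, collapse = "/"))
      rows[[length(rows) + 1L]] <-
        .metric_rows(p$id, side, "whole", p$dose, mask, config)
      for (r in c("head", "body", "tail")) {
        rows[[length(rows) + 1L]] <-
          .metric_rows(p$id, side, r, p$dose, split[[r]], config)
      }
    }
  }
  if (length(rows) == 0) {
    stop("all patients were skipped; nothing to analyze", call. = FALSE)
  }
  per_patient <- do.call(rbind, rows)
  d_names <- c(paste0("D", config$d_percents), "Dmean")
  v_names <- paste0("V", config$v_thresholds_gy)

  table1 <- do.call(rbind, lapply(c("HC-L", "HC-R"), function(side) {
    do.call(rbind, lapply(d_names, function(m) {
      v <- per_patient$value[per_patient$side == side &
                               per_patient$region == "whole" &
                               per_patient$metric == m]
      if (length(v) == 0) return(NULL)
      s <- summarize_values(v)
      data.frame(side = side, metric = m, mean = s$mean, sd = s$sd,
                 n = s$n, stringsAsFactors = FALSE)
    }))
  }))

  sub_table <- function(metric_names) {
    do.call(rbind, lapply(c("HC-L", "HC-R"), function(side) {
      do.call(rbind, lapply(metric_names, function(m) {
        df <- per_patient[per_patient$side == side &
                            per_patient$region != "whole" &
                            per_patient$metric == m, ]
        if (nrow(df) == 0) return(NULL)
        out <- .subregion_stats(df, config$posthoc)
        cbind(data.frame(side = side, metric = m,
                         stringsAsFactors = FALSE), out)
      }))
    }))
  }
  table2 <- sub_table(d_names)
  table3 <- sub_table(v_names)

  scores <- NULL
  have_scores <- vapply(cohort, function(p) !is.null(p$scores), logical(1))
  if (length(cohort) && all(have_scores)) {
    pre <- vapply(cohort, function(p) p$scores[["pre"]], numeric(1))
    post <- vapply(cohort, function(p) p$scores[["post"]], numeric(1))
    ts <- tryCatch(paired_t(pre, post), error = function(e) NULL)
    s_pre <- summarize_values(pre)
    s_post <- summarize_values(post)
    scores <- data.frame(
      n = length(pre), pre_mean = s_pre$mean, pre_sd = s_pre$sd,
      post_mean = s_post$mean, post_sd = s_post$sd,
      t = if (is.null(ts)) NA_real_ else ts$t,
      p = if (is.null(ts)) NA_real_ else ts$p,
      stringsAsFactors = FALSE
    )
    say("paired scores: n=", length(pre),
        if (is.null(ts)) ", test skipped" else
          paste0(", t=", format(ts$t, digits = 4),
                 ", p=", format(ts$p, digits = 4)))
  }

  result <- structure(
    list(per_patient = per_patient, table1_whole = table1,
         table2_d_metrics = table2, table3_v_metrics = table3,
         scores = scores, skipped = skipped, log = log, files = NULL),
    class = "cohort_table"
  )
  if (!is.null(config$out_dir)) {
    result$files <- .write_report(result, config$out_dir)
  }
  result
}

# Write report CSVs and the run log. NA cells (undefined SD, skipped tests)
# are written as an em dash, the conventional table marker. Deterministic:
# content depends only on the result object.
.write_report <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE, na = "—",
                     fileEncoding = "UTF-8")
    path
  }
  files <- c(
    w(result$per_patient, "per_patient_metrics.csv"),
    w(result$table1_whole, "table1_whole_hc.csv"),
    w(result$table2_d_metrics, "table2_d_metrics.csv"),
    w(result$table3_v_metrics, "table3_v_metrics.csv")
  )
  if (!is.null(result$scores)) {
    files <- c(files, w(result$scores, "scores.csv"))
  }
  log_path <- file.path(out_dir, "run_log.txt")
  writeLines(result$log, log_path, useBytes = TRUE)
  c(files, log_path)
}

#' @export
print.cohort_table <- function(x, ...) {
  np <- length(unique(x$per_patient$patient))
  cat("cohort_table:", np, "patients,",
      nrow(x$per_patient), "metric rows\n")
  if (length(x$skipped)) {
    cat("  skipped:", paste(x$skipped, collapse = ", "), "\n")
  }
  cat("\nWhole-structure dose (cGy), mean ± SD:\n")
  t1 <- x$table1_whole
  for (i in seq_len(nrow(t1))) {
    cat(sprintf("  %-5s %-6s %8.0f ± %.0f\n", t1$side[i],
                t1$metric[i], t1$mean[i], t1$sd[i]))
  }
  invisible(x)
}
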