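#' Voxel-level confusion counts between predicted and reference masks
#'
#' @param pred,truth Binary arrays (0/1) of identical dimensions.
#' @return A list of class `confusion_counts` with elements `TP`, `FP`,
#'   `FN` (true negatives are never needed by the three overlap metrics).
#' @export
confusion <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) {
    stop("pred and truth must have identical dimensions")
  }
  p <- as.logical(pred)
  y <- as.logical(truth)
  structure(list(TP = sum(p & y), FP = sum(p & !y), FN = sum(!p & y)),
            class = "confusion_counts")
}

#' Overlap metrics from confusion counts
#'
#' Computes the three standard voxel-overlap metrics:
#' `DSC = 2TP / (2TP + FP + FN)`, `SEN = TP / (TP + FN)`,
#' `PPV = TP / (TP + FP)`. DSC summarises overall segmentation quality,
#' SEN the fraction of true PVS voxels detected, PPV the fraction of
#' predicted voxels that are true PVS.
#'
#' Degenerate denominators (both masks empty, or an empty prediction or
#' reference) make the corresponding ratios 0/0; these are scored as 1
#' when both masks are empty (agreement on absence) and 0 otherwise, and
#' the record is flagged `degenerate` so aggregation can exclude it.
#'
#' @param counts A `confusion_counts` object or a list with `TP`, `FP`, `FN`.
#' @return Named numeric vector `c(DSC, SEN, PPV)` with attribute
#'   `degenerate` (logical).
#' @export
seg_metrics <- function(counts) {
  tp <- counts$TP; fp <- counts$FP; fn <- counts$FN
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  degenerate <- (tp + fp + fn) == 0 || (tp + fn) == 0 || (tp + fp) == 0
  if ((tp + fp + fn) == 0) {
    out <- c(DSC = 1, SEN = 1, PPV = 1)
  } else {
    out <- c(
      DSC = 2 * tp / (2 * tp + fp + fn),
      SEN = if (tp + fn > 0) tp / (tp + fn) else 0,
      PPV = if (tp + fp > 0) tp / (tp + fp) else 0
    )
  }
  attr(out, "degenerate") <- degenerate
  out
}

#' Per-subject metrics record
#'
#' Convenience wrapper producing one row of a metrics table from a
#' predicted and a reference mask.
#'
#' @param pred,truth Binary arrays of identical dimensions.
#' @param subject_id Subject identifier.
#' @param model_name Model identifier.
#' @return One-row `data.frame` with columns `subject_id`, `model`,
#'   `DSC`, `SEN`, `PPV`, `degenerate`.
#' @export
metrics_record <- function(pred, truth, subject_id, model_name = "model") {
  m <- seg_metrics(confusion(pred, truth))
  data.frame(subject_id = subject_id, model = model_name,
             DSC = m[["DSC"]], SEN = m[["SEN"]], PPV = m[["PPV"]],
             degenerate = attr(m, "degenerate"))
}

#' Aggregate per-subject metrics to Mean and Std rows
#'
#' Arithmetic mean and population standard deviation (divisor `N`, the
#' convention under which the bundled benchmark's printed Std row is
#' reproduced exactly) per model and metric.
#'
#' @param records `data.frame` with columns `model`, `DSC`, `SEN`, `PPV`.
#' @param exclude_degenerate Drop rows flagged degenerate (if the column is
#'   present) before aggregating.
#' @return `data.frame` with one `Mean` and one `Std` row per model.
#' @export
aggregate_metrics <- function(records, exclude_degenerate = FALSE) {
  stopifnot(nrow(records) >= 1L,
            all(c("model", "DSC", "SEN", "PPV") %in% names(records)))
  if (exclude_degenerate && "degenerate" %in% names(records)) {
    records <- records[!records$degenerate, , drop = FALSE]
  }
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  out <- do.call(rbind, lapply(split(records, records$model), function(d) {
    data.frame(
      model = d$model[1L], statistic = c("Mean", "Std"),
      DSC = c(mean(d$DSC), pop_sd(d$DSC)),
      SEN = c(mean(d$SEN), pop_sd(d$SEN)),
      PPV = c(mean(d$PPV), pop_sd(d$PPV))
    )
  }))
  rownames(out) <- NULL
  out
}

#' Model comparison table with best-score flags
#'
#' Assembles per-subject rows plus Mean/Std rows for several models and
#' flags, per subject and metric, every model attaining the maximum (ties
#' flag all tied models). On the Std row the minimum is flagged instead:
#' lower dispersion is the better score.
#'
#' @param records Long `data.frame` with columns `subject_id`, `model`,
#'   `DSC`, `SEN`, `PPV`.
#' @return `data.frame` in wide form: one row per (subject, metric) plus
#'   (Mean, metric) and (Std, metric) rows, one column per model, and a
#'   `best` column naming the flagged model(s), comma-separated.
#' @export
comparison_table <- function(records) {
  stopifnot(nrow(records) >= 1L)
  models <- unique(records$model)
  subjects <- unique(records$subject_id)
  agg <- aggregate_metrics(records)
  rows <- list()
  for (metric in c("DSC", "SEN", "PPV")) {
    for (s in subjects) {
      vals <- vapply(models, function(m) {
        records[records$subject_id == s & records$model == m, metric][1L]
      }, numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = as.character(s), metric = metric,
        as.list(setNames(vals, models)),
        best = paste(models[vals == max(vals)], collapse = ","),
        check.names = FALSE
      )
    }
    for (stat in c("Mean", "Std")) {
      vals <- vapply(models, function(m) {
        agg[agg$model == m & agg$statistic == stat, metric]
      }, numeric(1))
      pick <- if (stat == "Std") vals == min(vals) else vals == max(vals)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = stat, metric = metric,
        as.list(setNames(vals, models)),
        best = paste(models[pick], collapse = ","),
        check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published per-subject benchmark scores
#'
#' Loads the bundled per-subject DSC/SEN/PPV scores of five segmentation
#' models (IAANet, TriSegNet, U-Net, nnU-Net and the dense nested
#' multi-scale supervised model, MfNS_De) evaluated on a 20-subject
#' Parkinson's disease T2-weighted 3T cohort. Used as a fixture for the
#' aggregation and reporting code; the imaging data themselves are not
#' redistributable.
#'
#' @return Long `data.frame` with columns `subject_id`, `model`, `DSC`,
#'   `SEN`, `PPV`.
#' @export
benchmark_scores <- function() {
  path <- system.file("extdata", "benchmark_subject_scores.csv",
                      package = "perivox", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
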