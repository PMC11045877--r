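#' @include quantification.R simulate.R statistics.R
NULL

#' Simulate a dataset and write it to disk
#'
#' Thin orchestration over \code{\link{simulateExperiment}}: renders the
#' cells, writes per-cell TIFFs, the sample sheet and the ground-truth
#' table, plus a run manifest recording conditions, seeds and cell counts.
#'
#' @param configs Named list: condition to \linkS4class{SimulationConfig}.
#' @param n_cells Cells per condition.
#' @param dir Output directory.
#' @param replicates Replicate ids cycled over the cells.
#' @return The \code{\link{simulateExperiment}} result, invisibly.
#' @export
runSimulate <- function(configs, n_cells, dir, replicates = 3L) {
  sim <- simulateExperiment(configs, n_cells, dir = dir,
                            replicates = replicates)
  manifest <- data.frame(
    condition = names(configs),
    seed = vapply(configs, function(cfg) cfg@seed, 1L),
    n_cells = n_cells,
    n_loci = vapply(configs, function(cfg) cfg@nLoci, 1L),
    detector_efficiency = vapply(configs,
                                 function(cfg) cfg@detectorEfficiency, 1),
    dropout_probability = vapply(configs,
                                 function(cfg) cfg@dropoutProbability, 1),
    stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(sim)
}

.asCellImage <- function(x) {
  if (is(x, "SimulatedCell")) x@image else x
}

#' Quantify a batch of cells
#'
#' Runs nucleus segmentation, spot detection and relative-BiAD
#' quantification over a set of cell images, collecting per-cell rows,
#' per-spot rows and a QC report. Cells failing segmentation or
#' quantification are excluded with a reason code instead of aborting the
#' batch, so input cells always equal analyzed plus excluded cells.
#'
#' @param cells Named list of \linkS4class{CellImage} /
#'   \linkS4class{SimulatedCell} objects, or a sample-sheet data frame with
#'   \code{cell_id}, \code{path} and \code{channels}
#'   (semicolon-separated roles) columns, whose TIFFs are loaded with
#'   \code{\link{loadStack}} and projected.
#' @param sample_sheet Optional data frame with \code{cell_id},
#'   \code{condition}, \code{treatment}, \code{replicate} labels.
#' @param thresholds \code{NULL} for \code{\link{autoThresholds}} per cell,
#'   a single \linkS4class{ThresholdPair} for all cells, or a named list of
#'   per-cell pairs (manual mode).
#' @param max_spots,min_spot_area,allelic,stain_threshold,overlap_fraction_min,exclude_spots_from_background
#'   Passed to \code{\link{quantifyCell}}.
#' @param output_dir If given, per-cell and per-spot CSVs plus the QC
#'   report and the per-cell thresholds used are written there.
#' @return List: \code{cells} (experiment table), \code{spots} (long
#'   per-spot table), \code{qc} (cell_id, included, reason),
#'   \code{thresholds} (cell_id, nucleus, spot, method).
#' @export
runQuantify <- function(cells, sample_sheet = NULL, thresholds = NULL,
                        max_spots = 6L, min_spot_area = 4L, allelic = FALSE,
                        stain_threshold = NULL, overlap_fraction_min = 0.5,
                        exclude_spots_from_background = FALSE,
                        output_dir = NULL) {
  if (is.data.frame(cells)) {
    sheet <- cells
    stopifnot(all(c("cell_id", "path", "channels") %in% names(sheet)))
    missing <- sheet$cell_id[!file.exists(sheet$path)]
    if (length(missing))
      stop("sample sheet entries without readable images: ",
           paste(missing, collapse = ", "), call. = FALSE)
    if (is.null(sample_sheet)) sample_sheet <- sheet
    cells <- lapply(seq_len(nrow(sheet)), function(i) {
      stk <- loadStack(sheet$path[i],
                       strsplit(sheet$channels[i], ";", fixed = TRUE)[[1L]])
      maxIntensityProjection(stk, cell_id = sheet$cell_id[i])
    })
    names(cells) <- sheet$cell_id
  }
  stopifnot(is.list(cells), length(cells) >= 1L)
  if (is.null(names(cells)))
    names(cells) <- vapply(cells, function(x) cellId(.asCellImage(x)), "")

  labels <- function(id, col) {
    if (!is.null(sample_sheet) && col %in% names(sample_sheet)) {
      hit <- sample_sheet[[col]][match(id, sample_sheet$cell_id)]
      if (!is.na(hit)) return(hit)
    }
    NA_character_
  }
  thr_for <- function(id) {
    if (is.null(thresholds)) return(NULL)
    if (is(thresholds, "ThresholdPair")) return(thresholds)
    thresholds[[id]]
  }

  cell_rows <- list(); spot_rows <- list(); qc <- list(); thr_used <- list()
  for (id in names(cells)) {
    img <- .asCellImage(cells[[id]])
    res <- tryCatch(
      quantifyCell(img, thresholds = thr_for(id), max_spots = max_spots,
                   min_spot_area = min_spot_area, allelic = allelic,
                   stain_threshold = stain_threshold,
                   overlap_fraction_min = overlap_fraction_min,
                   exclude_spots_from_background =
                     exclude_spots_from_background,
                   condition = labels(id, "condition"),
                   treatment = labels(id, "treatment"),
                   replicate = labels(id, "replicate")),
      biad_segmentation_error = function(e) e,
      biad_qc_error = function(e) e)
    if (inherits(res, "condition")) {
      qc[[id]] <- data.frame(cell_id = id, included = FALSE,
                             reason = res$reason,
                             message = conditionMessage(res),
                             stringsAsFactors = FALSE)
    } else {
      qc[[id]] <- data.frame(cell_id = id, included = TRUE,
                             reason = "analyzed", message = "",
                             stringsAsFactors = FALSE)
      cell_rows[[id]] <- res$cell
      spot_rows[[id]] <- res$spots
      thr_used[[id]] <- data.frame(cell_id = id,
                                   nucleus = res$thresholds@nucleus,
                                   spot = res$thresholds@spot,
                                   method = res$thresholds@method,
                                   stringsAsFactors = FALSE)
    }
  }
  out <- list(
    cells = if (length(cell_rows)) {
      df <- do.call(rbind, cell_rows); rownames(df) <- NULL; df
    } else NULL,
    spots = if (length(spot_rows)) {
      df <- do.call(rbind, spot_rows); rownames(df) <- NULL; df
    } else NULL,
    qc = {
      df <- do.call(rbind, qc); rownames(df) <- NULL; df
    },
    thresholds = if (length(thr_used)) {
      df <- do.call(rbind, thr_used); rownames(df) <- NULL; df
    } else NULL)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    if (!is.null(out$cells))
      writeQuantTable(out$cells, file.path(output_dir, "per_cell.csv"),
                      spots = out$spots,
                      spots_path = file.path(output_dir, "per_spot.csv"))
    utils::write.csv(out$qc, file.path(output_dir, "qc_report.csv"),
                     row.names = FALSE)
    if (!is.null(out$thresholds))
      utils::write.csv(out$thresholds,
                       file.path(output_dir, "thresholds_used.csv"),
                       row.names = FALSE)
  }
  out
}

#' Compare groups of quantified cells
#'
#' Two groups are compared with a two-tailed unpaired t test, three or
#' more with one-way ANOVA plus Tukey's post test. The table may be an
#' experiment table (per-cell mode), a control-normalized table, or a
#' per-spot table with \code{xa_normalized} values grouped by allele
#' (allelic mode).
#'
#' @param table Data frame of quantified values.
#' @param value Column holding the values to compare.
#' @param group Grouping column.
#' @param groups Optional subset / ordering of group labels.
#' @param variant t-test variant for two groups.
#' @param output_dir If given, writes \code{comparison.csv} and a
#'   replicate-colored boxplot \code{comparison.png}.
#' @return List: \code{comparison} (\linkS4class{GroupComparison}),
#'   \code{plot} (ggplot), \code{summaries} (per-group boxplot summaries).
#' @export
runCompare <- function(table, value = "mean_relative_biad",
                       group = "condition", groups = NULL,
                       variant = c("welch", "student"), output_dir = NULL) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(table), all(c(value, group) %in% names(table)))
  keep <- !is.na(table[[value]]) & !is.na(table[[group]])
  table <- table[keep, , drop = FALSE]
  if (is.null(groups)) groups <- unique(table[[group]])
  absent <- setdiff(groups, table[[group]])
  if (length(absent))
    stop("empty group(s): ", paste(absent, collapse = ", "), call. = FALSE)
  vals <- lapply(groups, function(g) table[[value]][table[[group]] == g])
  names(vals) <- groups
  comparison <- if (length(vals) == 2L) {
    compareTwoGroups(vals[[1L]], vals[[2L]], variant = variant,
                     labels = names(vals))
  } else {
    compareMultiGroups(vals)
  }
  summaries <- lapply(groups, function(g) {
    sel <- table[[group]] == g
    reps <- if ("replicate" %in% names(table))
      table$replicate[sel] else NULL
    summarizeBoxplot(table[[value]][sel], reps)
  })
  names(summaries) <- groups
  plt <- plotGroupComparison(table, value = value, group = group)
  if (!is.null(output_dir)) {
    if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
    row <- data.frame(test = comparison@testName,
                      groups = paste(comparison@groupLabels, collapse = "|"),
                      means = paste(signif(comparison@groupMeans, 8),
                                    collapse = "|"),
                      statistic = comparison@statistic,
                      p_value = comparison@pValue,
                      stringsAsFactors = FALSE)
    utils::write.csv(row, file.path(output_dir, "comparison.csv"),
                     row.names = FALSE)
    if (!is.null(comparison@pairwise))
      utils::write.csv(comparison@pairwise,
                       file.path(output_dir, "tukey_pairwise.csv"),
                       row.names = FALSE)
    grDevices::png(file.path(output_dir, "comparison.png"), width = 900,
                   height = 700, res = 150)
    print(plt)
    grDevices::dev.off()
  }
  list(comparison = comparison, plot = plt, summaries = summaries)
}
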