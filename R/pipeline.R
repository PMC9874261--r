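#' Default pipeline configuration
#'
#' Run-wide settings for [runBurstPipeline()].  Reduced defaults
#' (\code{restarts = 10}, \code{gof_reps = 200}) keep routine runs fast;
#' \code{paperDefaults = TRUE} switches to the full protocol of 30
#' restarts per form and 1000 goodness-of-fit replicates.
#'
#' @param paperDefaults logical; use the full-fidelity settings?
#' @return A named list understood by [runBurstPipeline()].
#' @export
defaultConfig <- function(paperDefaults = FALSE) {
  list(lambda = 0.5,
       restarts = if (paperDefaults) 30 else 10,
       nodes = 200,
       gof_reps = if (paperDefaults) 1000 else 200,
       seed = 1,
       min_cells = 50, min_genes = 2000, min_mean = 2, tail_q = 0.05,
       out = "burst_out",
       cast_file = NULL, c57_file = NULL,
       counts_file = NULL, fit_file = NULL,
       theta_file = NULL, annotation_file = NULL,
       sim_cells = 500,
       robustness_cells = c(200, 500, 2000),
       robustness_dropout = 0,
       robustness_reps = 10)
}

# internal: error helpers carrying CLI exit-code semantics
.missing_input <- function(...) {
  stop(structure(class = c("bf_missing_input", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}
.config_error <- function(...) {
  stop(structure(class = c("bf_config_error", "error", "condition"),
                 list(message = paste0(...), call = NULL)))
}

# internal: validate a merged config
.validate_config <- function(config) {
  num <- c("lambda", "restarts", "nodes", "gof_reps", "seed", "min_cells",
           "min_genes", "min_mean", "tail_q", "sim_cells")
  for (f in num)
    if (!is.numeric(config[[f]]) || length(config[[f]]) != 1 ||
        !is.finite(config[[f]]))
      .config_error("config field '", f, "' must be a single number")
  if (config$lambda <= 0 || config$lambda > 1)
    .config_error("lambda must lie in (0, 1]")
  if (config$tail_q < 0 || config$tail_q >= 1)
    .config_error("tail_q must lie in [0, 1)")
  if (config$nodes < 20) .config_error("nodes must be >= 20")
  if (config$restarts < 1) .config_error("restarts must be >= 1")
  invisible(config)
}

.read_counts_matrix <- function(path) {
  if (is.null(path) || !file.exists(path %||% ""))
    .missing_input("counts file not found: ", path %||% "<unset>")
  SummarizedExperiment::assay(loadUmiCsv(path), "counts")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.read_theta_table <- function(path) {
  if (is.null(path) || !file.exists(path))
    .missing_input("theta file not found: ", path %||% "<unset>")
  tt <- data.table::fread(path, data.table = FALSE)
  need <- c("gene", "a", "b", "k", "h")
  if (!all(need %in% names(tt)))
    .config_error("theta file needs columns: ", paste(need, collapse = ", "))
  thetas <- lapply(seq_len(nrow(tt)), function(i)
    KineticParams(tt$a[i], tt$b[i],
                  k = if (tt$h[i] == 0) NA_real_ else tt$k[i], h = tt$h[i]))
  names(thetas) <- tt$gene
  thetas
}

.write_tsv <- function(d, path) {
  data.table::fwrite(d, path, sep = "\t")
  path
}

#' Run one pipeline stage
#'
#' Command-line style orchestration of the package: each command reads its
#' inputs from the paths in \code{config}, runs the corresponding package
#' functions, writes delimited result tables under \code{config$out} and
#' records a machine-readable JSON manifest of the run (config echo, seed,
#' package version, output files).  Every stochastic stage derives its
#' seeds deterministically from \code{config$seed}, so identical
#' configurations produce byte-identical tables.
#'
#' Commands: \describe{
#'   \item{qc}{assemble \code{cast_file}/\code{c57_file} via
#'     [qcPipeline()]; writes the merged counts, outlier mask and QC
#'     report.}
#'   \item{simulate}{draw synthetic genes from \code{theta_file} via
#'     [simulateExperiment()]; writes counts and the truth table.}
#'   \item{fit}{genome-wide fits of \code{counts_file} via
#'     [fitBurstKinetics()]; writes the per-gene results table.}
#'   \item{gof}{fit with the Monte-Carlo goodness-of-fit columns
#'     appended.}
#'   \item{stats}{burst statistics of \code{fit_file} (+ optional
#'     \code{annotation_file}) via [burstStatsTable()] and, when motif
#'     flags are present, [regressionTvalues()] for each response.}
#'   \item{robustness}{[robustnessSuite()] over \code{theta_file}.}
#' }
#'
#' @param command one of \code{"qc"}, \code{"simulate"}, \code{"fit"},
#'   \code{"gof"}, \code{"stats"}, \code{"robustness"}.
#' @param config a list as from [defaultConfig()]; partial lists are
#'   completed with the defaults.
#' @return Invisibly, a list of written file paths.
#' @export
runBurstPipeline <- function(command = c("qc", "simulate", "fit", "gof",
                                         "stats", "robustness"),
                             config = defaultConfig()) {
  command <- match.arg(command)
  config <- modifyList(defaultConfig(), config)
  .validate_config(config)
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out, name)
  written <- character()

  if (command == "qc") {
    for (f in c("cast_file", "c57_file"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        .missing_input("QC input not found: ", config[[f]] %||% f)
    se <- qcPipeline(loadUmiCsv(config$cast_file, allele = "cast"),
                     loadUmiCsv(config$c57_file, allele = "c57"),
                     minCells = config$min_cells,
                     minGenes = config$min_genes,
                     minMean = config$min_mean, tailQ = config$tail_q)
    written <- c(writeUmiCsv(se, outfile("qc_counts.csv")),
                 .write_tsv(as.data.frame(
                   SummarizedExperiment::assay(se, "keep"),
                   check.names = FALSE), outfile("qc_keep.tsv")),
                 .write_tsv(S4Vectors::metadata(se)$qc_report,
                            outfile("qc_report.tsv")))
  } else if (command == "simulate") {
    thetas <- .read_theta_table(config$theta_file)
    se <- simulateExperiment(thetas, nCells = config$sim_cells,
                             lambda = config$lambda, order = config$nodes,
                             seed = config$seed)
    truth <- as.data.frame(SummarizedExperiment::rowData(se))
    truth <- cbind(gene = rownames(truth), truth)
    written <- c(writeUmiCsv(se, outfile("sim_counts.csv")),
                 .write_tsv(truth, outfile("sim_truth.tsv")))
  } else if (command %in% c("fit", "gof")) {
    counts <- .read_counts_matrix(config$counts_file)
    fit <- fitBurstKinetics(counts, lambda = config$lambda,
                            restarts = config$restarts,
                            order = config$nodes,
                            gof = command == "gof",
                            gofReps = config$gof_reps,
                            seed = config$seed)
    written <- .write_tsv(fit, outfile(paste0(command, "_results.tsv")))
  } else if (command == "stats") {
    if (is.null(config$fit_file) || !file.exists(config$fit_file))
      .missing_input("fit results not found: ", config$fit_file %||% "<unset>")
    fit <- data.table::fread(config$fit_file, data.table = FALSE)
    ann <- NULL
    if (!is.null(config$annotation_file)) {
      if (!file.exists(config$annotation_file))
        .missing_input("annotation file not found: ", config$annotation_file)
      ann <- data.table::fread(config$annotation_file, data.table = FALSE)
    }
    stats <- burstStatsTable(fit, annotations = ann,
                             lambda = config$lambda, order = config$nodes,
                             gofOnly = "gof_pass" %in% names(fit))
    written <- .write_tsv(stats, outfile("burst_stats.tsv"))
    if (all(c("TATA", "Inr", "CCAAT", "GC") %in% names(stats))) {
      for (resp in c("rcv2", "log10_bf", "log10_bs")) {
        co <- regressionTvalues(stats, resp)
        written <- c(written,
                     .write_tsv(co, outfile(paste0("regression_", resp,
                                                   ".tsv"))))
      }
    }
  } else if (command == "robustness") {
    thetas <- .read_theta_table(config$theta_file)
    tab <- robustnessSuite(thetas, cellSizes = config$robustness_cells,
                           dropout = config$robustness_dropout,
                           reps = config$robustness_reps,
                           restarts = config$restarts,
                           lambda = config$lambda, order = config$nodes,
                           seed = config$seed)
    written <- .write_tsv(tab, outfile("robustness.tsv"))
  }

  manifest <- list(command = command, config = config,
                   package_version =
                     as.character(utils::packageVersion("burstfeedback")),
                   outputs = basename(written))
  jsonlite::write_json(manifest, outfile(paste0(command, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  invisible(c(written, outfile(paste0(command, "_manifest.json"))))
}
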