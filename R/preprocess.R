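#' Read a genes x cells UMI count matrix
#'
#' Parses a delimited text file with gene identifiers in the first column
#' and one column of nonnegative integer counts per cell (header row of
#' cell identifiers), the layout of allelic UMI exports such as
#' \code{SS3_cast_UMIs_concat.csv}.
#'
#' @param path file path.
#' @param allele optional allele tag recorded per cell in \code{colData}.
#' @param sep field separator (\code{"auto"} lets the reader detect it).
#' @return A \linkS4class{SummarizedExperiment} with integer assay
#'   \code{"counts"}, gene rownames and cell colnames.
#' @export
loadUmiCsv <- function(path, allele = NA_character_, sep = "auto") {
  if (!file.exists(path)) stop("input file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE,
                          data.table = FALSE)
  if (ncol(dt) < 2) stop("expected a gene-id column plus >= 1 cell column")
  genes <- as.character(dt[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene ids: ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(dt[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    badcol <- colnames(dt)[-1][!vapply(dt[-1], is.numeric, logical(1))][1]
    stop("non-numeric counts in cell column '", badcol, "'")
  }
  bad <- which(m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid count (negative or non-integer) for gene '",
         genes[bad[1, 1]], "', cell '", colnames(m)[bad[1, 2]],
         "' (file row ", bad[1, 1] + 1L, ")")
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    colData = S4Vectors::DataFrame(allele = rep(allele, ncol(m)),
                                   row.names = colnames(m)))
}

#' Write a genes x cells UMI count matrix
#'
#' Inverse of [loadUmiCsv()]: writes the \code{"counts"} assay as
#' delimited text with a \code{gene} id column.
#'
#' @param se a \code{SummarizedExperiment} (or plain matrix).
#' @param path output file path.
#' @param sep field separator.
#' @return \code{path}, invisibly.
#' @export
writeUmiCsv <- function(se, path, sep = ",") {
  m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se, "counts")
  dt <- data.frame(gene = rownames(m), m, check.names = FALSE)
  data.table::fwrite(dt, path, sep = sep)
  invisible(path)
}

# internal: one-allele QC filter returning the surviving matrix and a
# per-rule report
.qc_filter_once <- function(m, minCells, minGenes, minMean) {
  genes0 <- nrow(m); cells0 <- ncol(m)
  keep_gene1 <- rowSums(m > 0) >= minCells
  m <- m[keep_gene1, , drop = FALSE]
  keep_cell <- colSums(m > 0) >= minGenes
  m <- m[, keep_cell, drop = FALSE]
  keep_gene2 <- rowMeans(m) >= minMean
  m <- m[keep_gene2, , drop = FALSE]
  list(m = m,
       report = data.frame(
         rule = c("gene_min_cells", "cell_min_genes", "gene_min_mean"),
         dropped = c(sum(!keep_gene1), sum(!keep_cell), sum(!keep_gene2))))
}

#' Quality control of a single UMI matrix
#'
#' Applies, in order: drop genes expressed (count > 0) in fewer than
#' \code{minCells} cells; drop cells expressing fewer than \code{minGenes}
#' genes; drop genes with mean count below \code{minMean}.  One pass of
#' the three rules, in this order.
#'
#' @param se a \code{SummarizedExperiment} or counts matrix.
#' @param minCells,minGenes,minMean filter thresholds (defaults 50, 2000
#'   and 2, the values used for the allelic fibroblast matrices).
#' @return The filtered object of the same type, with the per-rule drop
#'   report in \code{metadata(se)$qc_report} (or attribute
#'   \code{"qc_report"} for matrices).
#' @seealso [qcPipeline()] for the full two-allele assembly.
#' @export
qcFilter <- function(se, minCells = 50, minGenes = 2000, minMean = 2) {
  m <- if (is.matrix(se)) se else SummarizedExperiment::assay(se, "counts")
  res <- .qc_filter_once(m, minCells, minGenes, minMean)
  if (nrow(res$m) == 0 || ncol(res$m) == 0)
    stop("no genes or cells survive quality control")
  if (is.matrix(se)) {
    out <- res$m
    attr(out, "qc_report") <- res$report
    return(out)
  }
  out <- se[rownames(res$m), colnames(res$m)]
  S4Vectors::metadata(out)$qc_report <- res$report
  out
}

# internal: per-gene upper-tail outlier mask on a counts matrix.
# The empirical quantile uses the inverse-ECDF convention (type 1) and
# values strictly above it are masked out of that gene's likelihood;
# tailQ = 0 disables masking.
.tail_mask <- function(m, tailQ) {
  keep <- matrix(TRUE, nrow(m), ncol(m), dimnames = dimnames(m))
  if (tailQ > 0) {
    thr <- apply(m, 1, quantile, probs = 1 - tailQ, type = 1, names = FALSE)
    keep <- m <= thr
  }
  keep
}

#' Assemble allelic UMI matrices into an inference-ready experiment
#'
#' Runs [qcFilter()] on each allelic matrix separately, keeps the genes
#' passing in both alleles, concatenates the surviving cells of the two
#' alleles per gene (allele recorded in \code{colData}, cell ids
#' suffixed), and marks per-gene upper-tail outliers: for each gene,
#' counts strictly above the empirical \code{1 - tailQ} quantile of its
#' merged cell vector are masked (assay \code{"keep"}) so they are
#' excluded from that gene's fit only — other genes keep the cell.
#'
#' @param cast,c57 the two allelic \code{SummarizedExperiment}s or count
#'   matrices (gene universes are intersected if they differ).
#' @param minCells,minGenes,minMean per-allele thresholds, see
#'   [qcFilter()].
#' @param tailQ per-gene upper-tail mass to mask (default 0.05; 0
#'   disables).
#' @return A \code{SummarizedExperiment} with assays \code{"counts"} and
#'   logical \code{"keep"}, \code{colData$allele}, and the combined QC
#'   report in \code{metadata()$qc_report}.
#' @export
qcPipeline <- function(cast, c57, minCells = 50, minGenes = 2000,
                       minMean = 2, tailQ = 0.05) {
  stopifnot(tailQ >= 0, tailQ < 1)
  as_mat <- function(x)
    if (is.matrix(x)) x else SummarizedExperiment::assay(x, "counts")
  mats <- list(cast = as_mat(cast), c57 = as_mat(c57))
  common <- intersect(rownames(mats$cast), rownames(mats$c57))
  if (length(common) == 0) stop("the two alleles share no genes")
  reports <- list()
  filtered <- lapply(names(mats), function(al) {
    res <- .qc_filter_once(mats[[al]][common, , drop = FALSE],
                           minCells, minGenes, minMean)
    res$report$allele <- al
    reports[[al]] <<- res$report
    res$m
  })
  names(filtered) <- names(mats)
  genes <- intersect(rownames(filtered$cast), rownames(filtered$c57))
  if (length(genes) == 0 || any(vapply(filtered, ncol, 0L) == 0))
    stop("no genes or cells survive quality control")
  merged <- cbind(filtered$cast[genes, , drop = FALSE],
                  filtered$c57[genes, , drop = FALSE])
  colnames(merged) <- c(paste0(colnames(filtered$cast), "_cast"),
                        paste0(colnames(filtered$c57), "_c57"))
  keep <- .tail_mask(merged, tailQ)
  allele <- rep(c("cast", "c57"),
                c(ncol(filtered$cast), ncol(filtered$c57)))
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = merged, keep = keep),
    colData = S4Vectors::DataFrame(allele = allele,
                                   row.names = colnames(merged)),
    metadata = list(qc_report = do.call(rbind, reports),
                    qc_params = list(minCells = minCells,
                                     minGenes = minGenes,
                                     minMean = minMean, tailQ = tailQ)))
}
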