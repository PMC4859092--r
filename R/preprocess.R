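#' Read a GEO Series Matrix text file
#'
#' Series Matrix files carry `!`-prefixed metadata lines and the expression
#' table between `!series_matrix_table_begin` and `!series_matrix_table_end`.
#' Only the table and a few sample-level metadata fields are retained.
#'
#' @param path Path to an (uncompressed) Series Matrix text file.
#' @return List with `values` (numeric probe x sample matrix, probe ids as
#'   rownames), `sample_ids`, and `metadata` (named list of the `!Sample_*`
#'   metadata lines, each a character vector over samples).
#' @export
read_series_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beg <- grep("^!series_matrix_table_begin", lines)
  end <- grep("^!series_matrix_table_end", lines)
  if (length(beg) != 1L || length(end) != 1L || end <= beg) {
    stop("not a Series Matrix file (missing table markers): ", path)
  }
  tab <- utils::read.delim(textConnection(lines[(beg + 1L):(end - 1L)]),
                           check.names = FALSE, stringsAsFactors = FALSE)
  probe_ids <- as.character(tab[[1L]])
  values <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- probe_ids
  colnames(values) <- gsub("\"", "", colnames(values))

  meta_lines <- grep("^!Sample_", lines, value = TRUE)
  metadata <- list()
  for (ml in meta_lines) {
    parts <- strsplit(ml, "\t")[[1]]
    key <- sub("^!", "", parts[1])
    metadata[[key]] <- gsub("\"", "", parts[-1])
  }
  list(values = values, sample_ids = colnames(values), metadata = metadata)
}

#' Read an expression matrix from TSV
#'
#' Genes (or probes) as rows with ids in the first column, one header row of
#' sample ids.
#'
#' @param path TSV file path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(tab[[1L]])
  m
}

#' Write an expression or PSF matrix as TSV
#'
#' @param m Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the row-identifier column.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id") {
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- data.frame(ids, m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sample sheet
#'
#' Expected columns: `sample_id`, `class_label`, `dataset_id`, `is_control`
#' (logical or 0/1). Every dataset must contain at least one control sample
#' and every sample id must be unique.
#'
#' @param path TSV file path, or a data frame with those columns.
#' @return Validated data frame.
#' @export
read_sample_sheet <- function(path) {
  sheet <- if (is.data.frame(path)) path else
    utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "class_label", "dataset_id", "is_control")
  miss <- setdiff(need, colnames(sheet))
  if (length(miss)) stop("sample sheet missing column(s): ",
                         paste(miss, collapse = ", "))
  sheet$is_control <- as.logical(sheet$is_control)
  if (anyDuplicated(sheet$sample_id)) {
    stop("duplicate sample_id in sample sheet: ",
         paste(unique(sheet$sample_id[duplicated(sheet$sample_id)]),
               collapse = ", "))
  }
  no_ctrl <- setdiff(unique(sheet$dataset_id),
                     unique(sheet$dataset_id[sheet$is_control]))
  if (length(no_ctrl)) {
    stop("dataset(s) without control samples: ",
         paste(no_ctrl, collapse = ", "))
  }
  sheet
}

#' Average probe rows into gene rows
#'
#' Probes mapping to the same gene are collapsed by the arithmetic mean of
#' their rows; probes absent from the map are discarded.
#'
#' @param probe_matrix Numeric probe x sample matrix with probe ids as
#'   rownames.
#' @param probe_to_gene_map Data frame with columns `probe_id`, `gene_id`, or
#'   a path to such a TSV.
#' @return Numeric gene x sample matrix, gene rows sorted by gene id.
#' @export
collapse_probes <- function(probe_matrix, probe_to_gene_map) {
  map <- if (is.data.frame(probe_to_gene_map)) probe_to_gene_map else
    utils::read.delim(probe_to_gene_map, stringsAsFactors = FALSE)
  stopifnot(all(c("probe_id", "gene_id") %in% colnames(map)))
  map <- map[map$probe_id %in% rownames(probe_matrix), , drop = FALSE]
  if (nrow(map) == 0L) {
    stop("no probe ids in common between matrix and probe map")
  }
  sub <- probe_matrix[map$probe_id, , drop = FALSE]
  gene <- factor(map$gene_id, levels = sort(unique(map$gene_id)))
  out <- apply(sub, 2, function(col) tapply(col, gene, mean))
  out <- matrix(out, nrow = nlevels(gene),
                dimnames = list(levels(gene), colnames(probe_matrix)))
  out
}

#' Detect the transformation of an expression matrix and bring it to linear
#' scale
#'
#' Applies a quantile heuristic in the spirit of the GEO2R log autocheck:
#' with `q` the quantiles at probabilities (0, 0.25, 0.5, 0.75, 0.99, 1),
#' the matrix is declared already linear when `q[0.99] > 100`, or when
#' `q[1] - q[0] > 50` and `q[0.25] > 0`; otherwise it is declared
#' log2-transformed and `2^x` is returned (`log10` only when forced via
#' `assume`). The decision is logged.
#'
#' @param m Numeric matrix.
#' @param assume One of `"auto"` (default), `"linear"`, `"log2"`, `"log10"`.
#' @return List with `values` (linear-scale matrix) and `scale_detected`
#'   (`"linear"`, `"log2"` or `"log10"`).
#' @export
detect_and_linearize <- function(m, assume = c("auto", "linear", "log2", "log10")) {
  assume <- match.arg(assume)
  stopifnot(is.numeric(m))
  if (assume == "auto") {
    q <- stats::quantile(m, c(0, 0.25, 0.5, 0.75, 0.99, 1), na.rm = TRUE,
                         names = FALSE)
    linear <- (q[5] > 100) || ((q[6] - q[1]) > 50 && q[2] > 0)
    scale_detected <- if (linear) "linear" else "log2"
  } else {
    scale_detected <- assume
  }
  if (scale_detected == "linear" && any(m < 0, na.rm = TRUE)) {
    stop("matrix declared linear but contains negative values ",
         "(impossible intensity)")
  }
  out <- switch(scale_detected, linear = m, log2 = 2^m, log10 = 10^m)
  psf_log("detect_and_linearize: matrix declared ", scale_detected)
  list(values = out, scale_detected = scale_detected)
}

#' Convert a linear-scale expression matrix to fold changes
#'
#' Each value is divided by the mean expression of the control samples of the
#' same dataset, so that for every gene the mean fold change over a dataset's
#' controls equals 1 by construction. Genes whose control mean is zero in any
#' dataset are dropped with a warning.
#'
#' @param m Linear-scale gene x sample matrix.
#' @param sheet Sample sheet (see [read_sample_sheet()]); only samples present
#'   in both the sheet and the matrix columns are used.
#' @return List with `values` (gene x sample fold-change matrix) and
#'   `dataset_id` (per-sample provenance, named by sample id).
#' @export
compute_fold_change <- function(m, sheet) {
  sheet <- read_sample_sheet(sheet)
  samples <- intersect(colnames(m), sheet$sample_id)
  if (length(samples) == 0L) stop("no samples shared by matrix and sheet")
  sheet <- sheet[match(samples, sheet$sample_id), , drop = FALSE]
  m <- m[, samples, drop = FALSE]
  if (any(m < 0)) stop("fold-change computation requires non-negative ",
                       "linear-scale expression values")
  fc <- m
  drop_genes <- logical(nrow(m))
  for (ds in unique(sheet$dataset_id)) {
    in_ds <- sheet$dataset_id == ds
    ctrl <- in_ds & sheet$is_control
    if (!any(ctrl)) stop("dataset without controls: ", ds)
    ctrl_mean <- rowMeans(m[, ctrl, drop = FALSE])
    drop_genes <- drop_genes | ctrl_mean == 0
    fc[, in_ds] <- m[, in_ds, drop = FALSE] / ctrl_mean
  }
  if (any(drop_genes)) {
    warning(sum(drop_genes), " gene(s) with zero control mean dropped")
    fc <- fc[!drop_genes, , drop = FALSE]
  }
  list(values = fc, dataset_id = setNames(sheet$dataset_id, sheet$sample_id))
}
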