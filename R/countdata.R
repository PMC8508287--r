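#' Construct a CountDataset
#'
#' Bundles a gene x sample matrix of raw integer counts with its sample sheet.
#' The sheet declares, for every column of the matrix, which sucrose-gradient
#' fraction the library came from (`cytoplasmic` or `polysomal`) and which
#' condition the cells were in (`NT` = non-treated, `T` = treated), plus a
#' replicate number.
#'
#' @param counts integer matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids). All cells must be
#'   non-negative integers.
#' @param samples data.frame with columns `sample_id`, `fraction`
#'   (`"cytoplasmic"`/`"polysomal"`), `condition` (`"NT"`/`"T"`) and
#'   `replicate` (positive integer). Must cover every column of `counts`
#'   and have at least one sample in each (fraction, condition) cell.
#' @return object of class `CountDataset`: a list with elements `counts`
#'   and `samples` (sheet reordered to match the column order of `counts`).
#' @export
count_dataset <- function(counts, samples) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene rownames and sample colnames")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate gene identifiers in counts")
  storage.mode(counts) <- "double"
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("count cell is not a non-negative integer: gene '%s', sample '%s'",
                 rownames(counts)[bad[1, 1]], colnames(counts)[bad[1, 2]]))
  samples <- validate_sample_sheet(samples)
  missing <- setdiff(colnames(counts), samples$sample_id)
  if (length(missing) > 0)
    stop(sprintf("sample sheet is missing count column(s): %s",
                 paste(missing, collapse = ", ")))
  samples <- samples[match(colnames(counts), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(counts = counts, samples = samples), class = "CountDataset")
}

#' Validate a sample sheet
#'
#' @param sheet data.frame; see [count_dataset()].
#' @return the sheet with `fraction`/`condition` as character, checked.
#' @export
validate_sample_sheet <- function(sheet) {
  req <- c("sample_id", "fraction", "condition", "replicate")
  if (!all(req %in% names(sheet)))
    stop("sample sheet must have columns: ", paste(req, collapse = ", "))
  sheet$sample_id <- as.character(sheet$sample_id)
  sheet$fraction  <- as.character(sheet$fraction)
  sheet$condition <- as.character(sheet$condition)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample_id in sample sheet")
  if (!all(sheet$fraction %in% c("cytoplasmic", "polysomal")))
    stop("fraction must be 'cytoplasmic' or 'polysomal'")
  if (!all(sheet$condition %in% c("NT", "T")))
    stop("condition must be 'NT' or 'T'")
  if (!all(is.finite(sheet$replicate) & sheet$replicate >= 1 &
           sheet$replicate == round(sheet$replicate)))
    stop("replicate must be a positive integer")
  cells <- table(sheet$fraction, sheet$condition)
  if (!all(dim(cells) == c(2, 2)) || any(cells == 0))
    stop("need at least one sample per (fraction, condition) group")
  sheet
}

#' @export
print.CountDataset <- function(x, ...) {
  cat(sprintf("CountDataset: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(fraction = x$samples$fraction, condition = x$samples$condition))
  invisible(x)
}

#' Column indices for one (fraction, condition) group
#'
#' @param ds CountDataset
#' @param fraction `"cytoplasmic"` or `"polysomal"`
#' @param condition `"NT"` or `"T"`
#' @return integer vector of column indices, ordered by replicate
#' @keywords internal
group_columns <- function(ds, fraction, condition) {
  idx <- which(ds$samples$fraction == fraction & ds$samples$condition == condition)
  idx[order(ds$samples$replicate[idx])]
}
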