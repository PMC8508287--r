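# Readers/writers for the plain-text formats the pipeline exchanges:
# tab-separated count matrices + sample sheets, 5'UTR FASTA, dose-response
# CSV matrices, and one-gene-per-line list files. Gene identifiers are opaque
# strings matched case-sensitively.

#' Read a count matrix and its sample sheet
#'
#' The counts file is a TSV with a header row of sample ids and gene
#' identifiers in the first column; the sheet is a TSV with columns
#' `sample_id`, `fraction`, `condition`, `replicate` covering every count
#' column.
#'
#' @param path counts TSV
#' @param sheet_path sample sheet TSV
#' @return [count_dataset()] object, genes in file order
#' @export
read_count_matrix <- function(path, sheet_path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("counts file needs a gene column plus >= 1 sample")
  genes <- as.character(tab[[1]])
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in counts file: ", path)
  rownames(m) <- genes
  sheet <- utils::read.delim(sheet_path, header = TRUE, sep = "\t", quote = "",
                             stringsAsFactors = FALSE)
  count_dataset(m, sheet)
}

#' Write a CountDataset to a counts TSV and a sample-sheet TSV
#'
#' @param ds CountDataset
#' @param path counts TSV destination
#' @param sheet_path sample sheet TSV destination
#' @return invisibly, `ds`
#' @export
write_count_matrix <- function(ds, path, sheet_path) {
  stopifnot(inherits(ds, "CountDataset"))
  tab <- data.frame(gene_id = rownames(ds$counts), ds$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$samples, sheet_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Read 5'UTR sequences from FASTA
#'
#' By contract the first base of each record is the +1 transcription start
#' site, i.e. the cap-adjacent nucleotide of the mRNA-sense sequence.
#' Sequences are upper-cased, whitespace is stripped, and RNA alphabet (U)
#' is mapped to DNA (T). The gene identifier is the first
#' whitespace-separated token of the header.
#'
#' @param path FASTA file
#' @return data.frame with columns `gene_id`, `sequence`
#' @export
read_fasta_utrs <- function(path) {
  x <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(x), "\\s+"), `[`, character(1), 1L)
  seqs <- gsub("\\s+", "", as.character(x))
  seqs <- chartr("u", "t", seqs)
  seqs <- toupper(seqs)
  seqs <- chartr("U", "T", seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for record: ", ids[which(!nzchar(seqs))[1]])
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("non-ACGTUN characters in record: ", ids[which(bad)[1]])
  data.frame(gene_id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write 5'UTR records to FASTA
#'
#' @param utrs data.frame with `gene_id`, `sequence`
#' @param path destination
#' @return invisibly, `utrs`
#' @export
write_fasta_utrs <- function(utrs, path) {
  set <- Biostrings::DNAStringSet(utrs$sequence)
  names(set) <- utrs$gene_id
  Biostrings::writeXStringSet(set, path)
  invisible(utrs)
}

#' Read a dose-response matrix from CSV
#'
#' Layout: first row holds the doses of drug B, first column the doses of
#' drug A (cell (1,1) is a label and is ignored); body cells are responses
#' normalized to the untreated control (= 1). Doses must be strictly
#' ascending; the zero-dose margins (monotherapy rows/columns) are expected
#' for Loewe scoring and their absence is flagged with a warning here.
#'
#' @param path CSV file
#' @return object of class `DoseMatrix`: list with `doses_a`, `doses_b`,
#'   `response` (|doses_a| x |doses_b| matrix)
#' @export
read_dose_matrix <- function(path) {
  tab <- utils::read.csv(path, header = FALSE, stringsAsFactors = FALSE)
  doses_b <- as.numeric(tab[1, -1])
  doses_a <- as.numeric(tab[-1, 1])
  resp <- as.matrix(tab[-1, -1, drop = FALSE])
  storage.mode(resp) <- "double"
  dose_matrix(doses_a, doses_b, resp)
}

#' Construct a DoseMatrix
#'
#' @param doses_a,doses_b strictly ascending non-negative dose vectors
#' @param response |doses_a| x |doses_b| numeric matrix, control = 1
#' @return `DoseMatrix` object
#' @export
dose_matrix <- function(doses_a, doses_b, response) {
  if (any(is.na(doses_a)) || any(is.na(doses_b)))
    stop("non-numeric dose labels")
  if (any(diff(doses_a) <= 0) || any(diff(doses_b) <= 0))
    stop("doses not ascending")
  if (any(doses_a < 0) || any(doses_b < 0)) stop("negative dose")
  response <- as.matrix(response)
  if (!all(dim(response) == c(length(doses_a), length(doses_b))))
    stop("response matrix shape does not match dose vectors")
  if (doses_a[1] != 0 || doses_b[1] != 0)
    warning("zero-dose margins absent; Loewe scoring will refuse this matrix")
  dimnames(response) <- list(format(doses_a, trim = TRUE),
                             format(doses_b, trim = TRUE))
  structure(list(doses_a = doses_a, doses_b = doses_b, response = response),
            class = "DoseMatrix")
}

#' Write a DoseMatrix to CSV (io dialect of [read_dose_matrix()])
#'
#' @param dm DoseMatrix
#' @param path destination CSV
#' @return invisibly, `dm`
#' @export
write_dose_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "DoseMatrix"))
  header <- c("dose", dm$doses_b)
  body <- cbind(dm$doses_a, dm$response)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  utils::write.table(body, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(dm)
}

#' @export
print.DoseMatrix <- function(x, ...) {
  cat(sprintf("DoseMatrix: %d x %d doses (drug A rows, drug B columns)\n",
              length(x$doses_a), length(x$doses_b)))
  print(x$response)
  invisible(x)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' @param path text file; blank lines and `#` comments ignored
#' @return character vector of unique identifiers, file order
#' @export
read_gene_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}
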