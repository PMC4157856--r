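#' Read reference gene sequences from FASTA
#'
#' @param path FASTA file.
#' @return data.frame \code{gene_id}, \code{sequence} (uppercase).
#' @export
read_gene_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  data.frame(gene_id = sub("\\s.*$", "", names(x)),
             sequence = toupper(as.character(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reference gene sequences to FASTA
#'
#' @param genes data.frame \code{gene_id}, \code{sequence}.
#' @param path Output file; sequences wrapped at 80 columns.
#' @export
write_gene_fasta <- function(genes, path) {
  x <- Biostrings::DNAStringSet(genes$sequence)
  names(x) <- genes$gene_id
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

# Strict TSV reader: tab-separated, header row, UTF-8, '.' decimal.
# Verifies the expected header and per-row field counts, citing the first
# offending line.
read_tsv_checked <- function(path, columns) {
  if (!file.exists(path)) stop_input("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) stop_input("%s: empty file", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (!all(columns %in% header))
    stop_input("%s: missing column(s) %s", path,
               paste(setdiff(columns, header), collapse = ", "))
  nf <- lengths(strsplit(lines, "\t", fixed = TRUE))
  bad <- which(nf != length(header))
  if (length(bad) > 0L)
    stop_input("%s: wrong column count at line %d", path, bad[1L])
  utils::read.delim(text = lines, stringsAsFactors = FALSE)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a tag count table from TSV
#'
#' Expects columns \code{tag}, \code{count}.
#'
#' @param path TSV file.
#' @param library_id,stage Metadata for the resulting table.
#' @return A \code{TagCountTable}.
#' @export
read_tag_table <- function(path, library_id = basename(path),
                           stage = "raw") {
  d <- read_tsv_checked(path, c("tag", "count"))
  tag_count_table(d$tag, d$count, library_id = library_id, stage = stage)
}

#' Write a tag count table to TSV
#' @param x A \code{TagCountTable}.
#' @param path Output file.
#' @export
write_tag_table <- function(x, path) write_tsv(x[, c("tag", "count")], path)

#' Read a gene annotation table from TSV
#'
#' Expects columns \code{gene_id}, \code{term}; optional \code{namespace}
#' and \code{label} are kept.
#'
#' @param path TSV file.
#' @return data.frame suitable for [enrich_terms()].
#' @export
read_annotations <- function(path) read_tsv_checked(path, c("gene_id", "term"))

#' Read a qPCR Ct table from TSV
#'
#' Expects columns \code{sample}, \code{group}, \code{gene}, \code{ct}.
#'
#' @param path TSV file.
#' @return data.frame suitable for [compare_groups()].
#' @export
read_ct_table <- function(path)
  read_tsv_checked(path, c("sample", "group", "gene", "ct"))
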