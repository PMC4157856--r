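#' Build the CATG-anchored reference tag index
#'
#' Scans each reference gene for the NlaIII recognition motif \code{CATG}
#' and derives, for every occurrence followed by at least 17 bases, one
#' 17 bp reference tag (the 17 bases immediately 3' of the motif, sense
#' strand only). A tag mapping to more than one distinct gene is flagged
#' ambiguous. The tag derived from the 3'-most qualifying site of a gene is
#' that gene's canonical tag, the one an NlaIII DGE library actually
#' sequences for the transcript.
#'
#' Sites within 17 bp of the 3' end yield no tag (the tag would be
#' truncated), and windows containing \code{N} are skipped because they
#' cannot be matched under the perfect/1-mismatch rule.
#'
#' @param genes A data.frame with columns \code{gene_id} and
#'   \code{sequence} (uppercase DNA), as produced by
#'   \code{\link{simulate_reference}} or \code{\link{read_gene_fasta}}.
#' @return An object of class \code{TagLibraryIndex}: a list with
#'   \describe{
#'     \item{tags}{data.table with one row per distinct reference tag:
#'       \code{tag}, \code{n_genes}, \code{gene_ids} (comma-separated),
#'       \code{gene_id} (the single gene when unambiguous, otherwise NA),
#'       \code{ambiguous}.}
#'     \item{canonical}{data.table \code{gene_id}, \code{tag}: each gene's
#'       canonical (3'-most) tag.}
#'     \item{summary}{named list of counts: \code{n_genes},
#'       \code{n_genes_catg}, \code{n_tags}, \code{n_unambiguous},
#'       \code{n_ambiguous}.}
#'   }
#' @examples
#' genes <- data.frame(gene_id = "g1",
#'                     sequence = "AAACATGTTTTTTTTTTTTTTTTA")
#' idx <- extract_reference_tags(genes)
#' idx$tags$tag  # "TTTTTTTTTTTTTTTTT"
#' @export
extract_reference_tags <- function(genes) {
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stop_input("'genes' must be a non-empty data.frame")
  if (!all(c("gene_id", "sequence") %in% names(genes)))
    stop_input("'genes' must have columns 'gene_id' and 'sequence'")
  if (anyDuplicated(genes$gene_id))
    stop_input("duplicate gene ids: %s",
               paste(unique(genes$gene_id[duplicated(genes$gene_id)]),
                     collapse = ", "))
  seqs <- as.character(genes$sequence)
  if (any(!grepl("^[ACGTN]*$", seqs)) || any(nchar(seqs) == 0L))
    stop_input("gene sequences must be non-empty and use alphabet A/C/G/T/N")

  hits <- gregexpr(ANCHOR_MOTIF, seqs, fixed = TRUE)
  n_sites <- vapply(hits, function(p) if (p[1L] == -1L) 0L else length(p),
                    integer(1))
  gene_i <- rep(seq_along(seqs), n_sites)
  start <- unlist(hits[n_sites > 0L], use.names = FALSE) + 4L
  keep <- (start + TAG_WIDTH - 1L) <= nchar(seqs)[gene_i]
  gene_i <- gene_i[keep]; start <- start[keep]
  tags <- substring(seqs[gene_i], start, start + TAG_WIDTH - 1L)
  ok <- !grepl("N", tags, fixed = TRUE)
  all_tags <- data.table::data.table(gene_id = genes$gene_id[gene_i[ok]],
                                     tag = tags[ok], pos = start[ok])
  # the 3'-most qualifying site of each gene yields its canonical tag
  if (nrow(all_tags) > 0L) {
    all_tags[, canonical := pos == max(pos), by = "gene_id"]
  } else {
    all_tags[, canonical := logical()]
  }

  if (nrow(all_tags) == 0L) {
    tags_dt <- data.table::data.table(tag = character(), n_genes = integer(),
                                      gene_ids = character(),
                                      gene_id = character(),
                                      ambiguous = logical())
    canonical <- data.table::data.table(gene_id = character(),
                                        tag = character())
  } else {
    uniq <- unique(all_tags[, c("gene_id", "tag")])
    tags_dt <- uniq[, list(n_genes = .N,
                           gene_ids = paste(sort(gene_id), collapse = ",")),
                    by = "tag"]
    tags_dt[, `:=`(ambiguous = n_genes > 1L,
                   gene_id = data.table::fifelse(n_genes == 1L, gene_ids,
                                                 NA_character_))]
    data.table::setkeyv(tags_dt, "tag")
    canonical <- all_tags[canonical == TRUE, c("gene_id", "tag")]
  }

  genes_catg <- length(unique(all_tags$gene_id))
  idx <- list(
    tags = tags_dt,
    canonical = canonical,
    summary = list(n_genes = nrow(genes),
                   n_genes_catg = genes_catg,
                   n_tags = nrow(tags_dt),
                   n_unambiguous = sum(!tags_dt$ambiguous),
                   n_ambiguous = sum(tags_dt$ambiguous))
  )
  class(idx) <- "TagLibraryIndex"
  idx
}

#' Summarise a reference tag index
#'
#' Produces the standard reference-accounting table: total reference genes,
#' genes with a qualifying CATG site, total distinct reference tags, and
#' their split into unambiguous (one gene) and ambiguous (several genes)
#' tags. Percentages use the gene total as denominator for the gene row and
#' the tag total for tag rows, rounded to 2 decimals; with an empty tag set
#' all tag percentages are reported as 0.
#'
#' Tags are taken on the sense strand only; the table's \code{policy}
#' attribute records this so summaries built under other strand policies
#' remain comparable.
#'
#' @param index A \code{TagLibraryIndex} from
#'   \code{\link{extract_reference_tags}}.
#' @return A data.frame with columns \code{item}, \code{count},
#'   \code{percentage} (NA where no percentage applies).
#' @export
reference_summary <- function(index) {
  if (!inherits(index, "TagLibraryIndex"))
    stop_input("'index' must be a TagLibraryIndex")
  s <- index$summary
  pct <- function(num, den) if (den > 0) round(num / den * 100, 2) else 0
  out <- data.frame(
    item = c("Reference genes", "Genes with CATG site",
             "Total reference tags", "Unambiguous tags", "Ambiguous tags"),
    count = c(s$n_genes, s$n_genes_catg, s$n_tags, s$n_unambiguous,
              s$n_ambiguous),
    percentage = c(NA, pct(s$n_genes_catg, s$n_genes), NA,
                   pct(s$n_unambiguous, s$n_tags),
                   pct(s$n_ambiguous, s$n_tags)),
    stringsAsFactors = FALSE
  )
  attr(out, "policy") <- "sense-strand 17 bp tags 3' of CATG"
  out
}

#' @export
print.TagLibraryIndex <- function(x, ...) {
  s <- x$summary
  cat("TagLibraryIndex:", s$n_genes, "genes,", s$n_genes_catg,
      "with CATG site,", s$n_tags, "reference tags (",
      s$n_unambiguous, "unambiguous /", s$n_ambiguous, "ambiguous )\n")
  invisible(x)
}
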