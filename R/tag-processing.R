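#' Construct a tag count table
#'
#' A tag count table is the unit of exchange of the pipeline: distinct tag
#' sequences with their copy counts, labelled with a library id and a
#' processing stage (\code{raw} -> \code{clean} -> \code{analysis}).
#'
#' @param tag Character vector of distinct tag sequences.
#' @param count Non-negative integer copy counts, same length.
#' @param library_id Library label.
#' @param stage One of \code{"raw"}, \code{"clean"}, \code{"analysis"}.
#' @return A data.frame of class \code{TagCountTable} with columns
#'   \code{tag}, \code{count} and attributes \code{library_id},
#'   \code{stage}.
#' @export
tag_count_table <- function(tag, count, library_id = "lib",
                            stage = c("raw", "clean", "analysis")) {
  stage <- match.arg(stage)
  if (anyDuplicated(tag)) stop_input("tags must be distinct within a table")
  assert_counts(count, "count")
  if (length(tag) != length(count))
    stop_input("'tag' and 'count' must have equal length")
  out <- data.frame(tag = as.character(tag), count = as.numeric(count),
                    stringsAsFactors = FALSE)
  attr(out, "library_id") <- library_id
  attr(out, "stage") <- stage
  class(out) <- c("TagCountTable", "data.frame")
  out
}

tag_stage <- function(x) attr(x, "stage") %||% "raw"

set_stage <- function(x, stage, ...) {
  extra <- list(...)
  attr(x, "stage") <- stage
  for (nm in names(extra)) attr(x, nm) <- extra[[nm]]
  x
}

#' Filter a raw tag table down to clean tags
#'
#' Removes low-quality tags (any non-A/C/G/T character, i.e. ambiguous
#' bases) and adaptor contamination (tags whose sequence starts with the
#' first \code{prefix_len} bases of the adaptor). The result is the
#' clean-tag table whose total is the library's clean-tag count, the
#' denominator of TPM normalisation.
#'
#' @param raw A \code{TagCountTable} at stage \code{raw}.
#' @param adaptor Adaptor sequence; defaults to [DGE_ADAPTOR].
#' @param prefix_len Length of the adaptor prefix compared against the tag
#'   start (default: the tag width, 17, so only tags that are pure adaptor
#'   sequence are removed).
#' @return A \code{TagCountTable} at stage \code{clean}, with attributes
#'   \code{raw_total}, \code{raw_distinct}, \code{clean_total},
#'   \code{clean_distinct}.
#' @export
clean_tags <- function(raw, adaptor = DGE_ADAPTOR, prefix_len = TAG_WIDTH) {
  if (!inherits(raw, "TagCountTable") || tag_stage(raw) != "raw")
    stop_input("'raw' must be a TagCountTable at stage 'raw'")
  if (!is.character(adaptor) || length(adaptor) != 1L || nchar(adaptor) < 1L)
    stop_input("'adaptor' must be a single DNA string")
  prefix_len <- min(prefix_len, nchar(adaptor))
  ok_alpha <- grepl("^[ACGT]+$", raw$tag)
  adaptor_prefix <- substr(adaptor, 1L, prefix_len)
  is_adaptor <- substr(raw$tag, 1L, prefix_len) == adaptor_prefix
  keep <- ok_alpha & !is_adaptor
  out <- raw[keep, , drop = FALSE]
  rownames(out) <- NULL
  set_stage(out, "clean",
            raw_total = sum(raw$count), raw_distinct = nrow(raw),
            clean_total = sum(out$count), clean_distinct = nrow(out))
}

#' Drop singleton tags
#'
#' Retains only tags seen more than once; single-copy tags are dominated
#' by sequencing error and are excluded from analysis. The clean-tag total
#' attribute is preserved for TPM normalisation downstream.
#'
#' @param clean A \code{TagCountTable} at stage \code{clean}.
#' @return A \code{TagCountTable} at stage \code{analysis}.
#' @export
drop_singletons <- function(clean) {
  if (!inherits(clean, "TagCountTable") || tag_stage(clean) != "clean")
    stop_input("'clean' must be a TagCountTable at stage 'clean'")
  out <- clean[clean$count > 1, , drop = FALSE]
  rownames(out) <- NULL
  set_stage(out, "analysis",
            clean_total = attr(clean, "clean_total") %||% sum(clean$count),
            clean_distinct = attr(clean, "clean_distinct") %||% nrow(clean))
}

# Resolve tags with no exact hit against the reference at Hamming distance
# 1, in chunks so the 3*width variant strings of large tag sets never live
# in memory at once. Returns a data.table (tag, genes, n): the union of
# gene ids over all distance-1 reference hits.
match_one_mismatch <- function(tags, ref, chunk = 20000L) {
  pieces <- lapply(split(tags, ceiling(seq_along(tags) / chunk)),
                   function(part) {
    vt <- hamming1_variants(part)
    vt[, ref_row := match(variant, ref$tag)]
    vt <- vt[!is.na(ref_row)]
    if (nrow(vt) == 0L) return(NULL)
    vt[, gene_ids := ref$gene_ids[ref_row]]
    vt[, list(genes = paste(sort(unique(unlist(
      strsplit(gene_ids, ",", fixed = TRUE)))), collapse = ",")),
      by = "tag"]
  })
  out <- data.table::rbindlist(pieces)
  if (nrow(out) > 0L)
    out[, n := lengths(strsplit(genes, ",", fixed = TRUE))]
  out
}

# All Hamming-distance-1 neighbours of each tag: 3 * width variants per tag.
# Returns a data.table (tag = original, variant). Vectorised across tags.
hamming1_variants <- function(tags) {
  width <- nchar(tags[1L])
  n <- length(tags)
  pieces <- vector("list", width * 3L)
  k <- 0L
  for (pos in seq_len(width)) {
    orig <- substr(tags, pos, pos)
    for (b in DNA_BASES4) {
      keep <- orig != b
      if (!any(keep)) next
      k <- k + 1L
      v <- tags[keep]
      substr(v, pos, pos) <- b
      pieces[[k]] <- data.table::data.table(tag = tags[keep], variant = v)
    }
  }
  data.table::rbindlist(pieces[seq_len(k)])
}

#' Map analysis tags to genes with the perfect/1-mismatch rule
#'
#' Each tag is looked up in the reference index: an exact hit takes
#' absolute precedence; otherwise all reference tags at Hamming distance 1
#' are collected (by enumerating the 3 x 17 single-base variants of the
#' query against the exact index). A tag is gene-assigned iff its hit set
#' resolves to exactly one gene (unambiguous); tags resolving to several
#' genes are ambiguous - counted among all tags mapping to genes but kept
#' out of the unambiguous, analysis-grade counts; tags with no hit are
#' unknown, unless they match an optional decoy tag set (then they fill
#' the genome bucket).
#'
#' @param analysis A \code{TagCountTable} at stage \code{analysis}.
#' @param index A \code{TagLibraryIndex}.
#' @param decoy_tags Optional character vector of genomic decoy tags; exact
#'   or 1-mismatch hits land in the genome bucket instead of unknown.
#' @return A list with
#'   \describe{
#'     \item{expression}{data.frame of class \code{ExpressionTable}:
#'       \code{gene_id}, \code{count} (unambiguous, the analysis-grade
#'       quantity), \code{all_count} (including ambiguous tags, used for
#'       gene-detection accounting); attributes \code{library_id},
#'       \code{clean_total}.}
#'     \item{report}{data.frame of class \code{MappingReport} mirroring
#'       the standard two-library accounting: total and distinct counts of
#'       clean analysis tags, all tags mapping to genes, unambiguous tag
#'       mappings, genome-bucket tags, unknown tags, plus all-mapped and
#'       unambiguously mapped gene counts.}
#'   }
#' @export
map_tags <- function(analysis, index, decoy_tags = NULL) {
  if (!inherits(analysis, "TagCountTable") || tag_stage(analysis) != "analysis")
    stop_input("'analysis' must be a TagCountTable at stage 'analysis'")
  if (!inherits(index, "TagLibraryIndex") || nrow(index$tags) == 0L)
    stop_input("'index' must be a non-empty TagLibraryIndex")
  if (nrow(analysis) > 0L && any(!grepl("^[ACGT]+$", analysis$tag)))
    stop_input("analysis tags contain characters outside A/C/G/T")

  ref <- index$tags
  tags <- analysis$tag
  counts <- analysis$count

  # pass 1: exact hits
  mx <- match(tags, ref$tag)
  exact <- !is.na(mx)
  gene_of <- rep(NA_character_, length(tags))
  n_genes_hit <- integer(length(tags))
  gene_sets <- rep(NA_character_, length(tags))  # comma-joined, for ambiguous
  gene_of[exact] <- ref$gene_id[mx[exact]]
  n_genes_hit[exact] <- ref$n_genes[mx[exact]]
  gene_sets[exact] <- ref$gene_ids[mx[exact]]

  # pass 2: 1-mismatch for the rest
  rest <- which(!exact)
  if (length(rest) > 0L) {
    hits <- match_one_mismatch(tags[rest], ref)
    if (nrow(hits) > 0L) {
      hm <- match(tags, hits$tag)
      got <- !is.na(hm)
      n_genes_hit[got] <- hits$n[hm[got]]
      gene_sets[got] <- hits$genes[hm[got]]
      one <- got & n_genes_hit == 1L
      gene_of[one] <- gene_sets[one]
    }
  }

  mapped <- n_genes_hit >= 1L
  unambig <- n_genes_hit == 1L
  nohit <- !mapped

  # optional genome decoy bucket for tags that hit no gene
  genome <- rep(FALSE, length(tags))
  if (!is.null(decoy_tags) && any(nohit)) {
    dmx <- !is.na(match(tags[nohit], decoy_tags))
    if (any(!dmx)) {
      vd <- hamming1_variants(tags[nohit][!dmx])
      hit1 <- vd[!is.na(match(variant, decoy_tags)), unique(tag)]
      dmx[!dmx] <- tags[nohit][!dmx] %in% hit1
    }
    genome[nohit] <- dmx
  }
  unknown <- nohit & !genome

  # per-gene expression: unambiguous counts (primary) and all-mapped counts
  dt <- data.table::data.table(gene = gene_of, count = counts,
                               unambig = unambig)
  expr_u <- dt[unambig == TRUE, list(count = sum(count)), by = "gene"]
  amb <- which(mapped & !unambig)
  if (length(amb) > 0L) {
    spl <- strsplit(gene_sets[amb], ",", fixed = TRUE)
    expr_a <- data.table::data.table(
      gene = unlist(spl), count = rep(counts[amb], lengths(spl)))
  } else {
    expr_a <- data.table::data.table(gene = character(), count = numeric())
  }
  all_dt <- data.table::rbindlist(list(expr_u[, c("gene", "count")], expr_a))
  expr_all <- all_dt[, list(all_count = sum(count)), by = "gene"]
  expr <- merge(expr_all, expr_u, by = "gene", all.x = TRUE)
  expr[is.na(count), count := 0]
  data.table::setorderv(expr, "gene")
  expression <- data.frame(gene_id = expr$gene, count = expr$count,
                           all_count = expr$all_count,
                           stringsAsFactors = FALSE)
  attr(expression, "library_id") <- attr(analysis, "library_id")
  attr(expression, "clean_total") <- attr(analysis, "clean_total") %||%
    sum(counts)
  class(expression) <- c("ExpressionTable", "data.frame")

  report <- data.frame(
    item = c("Clean analysis tags", "All tags mapping to genes",
             "Unambiguous tag mapping to genes", "All tag-mapped genes",
             "Unambiguous tag-mapped genes", "Mapping to genome",
             "Unknown tags"),
    total = c(sum(counts), sum(counts[mapped]), sum(counts[unambig]),
              nrow(expression), sum(expression$count > 0),
              sum(counts[genome]), sum(counts[unknown])),
    distinct = c(length(tags), sum(mapped), sum(unambig),
                 nrow(expression), sum(expression$count > 0),
                 sum(genome), sum(unknown)),
    stringsAsFactors = FALSE)
  class(report) <- c("MappingReport", "data.frame")

  list(expression = expression, report = report)
}

#' Normalise an expression table to TPM
#'
#' TPM here is tags per million clean tags: \code{count / N * 1e6} with
#' \code{N} the library's clean-tag total (not the mapped total), using the
#' unambiguous per-gene counts.
#'
#' @param expr An \code{ExpressionTable} from [map_tags()].
#' @param clean_total Clean-tag total \code{N}; defaults to the table's
#'   \code{clean_total} attribute.
#' @return The table with a \code{tpm} column added.
#' @export
compute_tpm <- function(expr, clean_total = attr(expr, "clean_total")) {
  if (!inherits(expr, "ExpressionTable"))
    stop_input("'expr' must be an ExpressionTable")
  if (is.null(clean_total) || !is.numeric(clean_total) || clean_total <= 0)
    stop_input("clean-tag total must be a positive number")
  expr$tpm <- expr$count / clean_total * 1e6
  expr
}

#' Sequencing saturation curve
#'
#' Estimates how gene detection grows with sequencing depth: the raw tag
#' stream is shuffled once (fixed seed) and nested prefixes of the sizes in
#' \code{grid} are cleaned, mapped, and the number of distinct detected
#' genes recorded. Nested prefixes make both detection columns monotone
#' non-decreasing by construction; a plateau indicates the library was
#' sequenced to saturation.
#'
#' @param stream Character vector of raw tags, one element per sequenced
#'   tag copy (see \code{simulate_tag_libraries(..., return_stream =
#'   TRUE)}).
#' @param index A \code{TagLibraryIndex}.
#' @param grid Increasing vector of subsample sizes; must not exceed
#'   \code{length(stream)}.
#' @param seed Integer seed for the shuffle.
#' @param adaptor Adaptor passed to [clean_tags()].
#' @return data.frame \code{tags_sampled}, \code{genes_detected_all},
#'   \code{genes_detected_unambiguous}.
#' @export
saturation_curve <- function(stream, index, grid, seed = 1L,
                             adaptor = DGE_ADAPTOR) {
  if (is.unsorted(grid, strictly = TRUE))
    stop_input("'grid' must be strictly increasing")
  if (any(grid < 0) || any(grid != floor(grid)))
    stop_input("'grid' must contain non-negative integers")
  if (max(grid) > length(stream))
    stop_input("grid point %d exceeds stream length %d", max(grid),
               length(stream))
  set.seed(seed)
  stream <- sample(stream)

  # every distinct tag maps identically at every depth, so resolve each
  # once and derive all grid points from first-occurrence positions
  first <- !duplicated(stream)
  utags <- stream[first]
  upos <- which(first)
  keep <- grepl("^[ACGT]+$", utags)
  prefix_len <- min(TAG_WIDTH, nchar(adaptor))
  keep <- keep &
    substr(utags, 1L, prefix_len) != substr(adaptor, 1L, prefix_len)
  ref <- index$tags

  genes_at <- rep(NA_character_, length(utags))   # comma-joined hit set
  n_hit <- integer(length(utags))
  mx <- match(utags, ref$tag)
  exact <- keep & !is.na(mx)
  genes_at[exact] <- ref$gene_ids[mx[exact]]
  n_hit[exact] <- ref$n_genes[mx[exact]]
  rest <- which(keep & !exact)
  if (length(rest) > 0L) {
    hits <- match_one_mismatch(utags[rest], ref)
    if (nrow(hits) > 0L) {
      hm <- match(utags[rest], hits$tag)
      got <- !is.na(hm)
      genes_at[rest[got]] <- hits$genes[hm[got]]
      n_hit[rest[got]] <- hits$n[hm[got]]
    }
  }

  # earliest stream position at which each gene becomes detected
  det_pos <- function(sel) {
    if (!any(sel)) return(integer())
    spl <- strsplit(genes_at[sel], ",", fixed = TRUE)
    d <- data.table::data.table(gene = unlist(spl),
                                pos = rep(upos[sel], lengths(spl)))
    d[, list(pos = min(pos)), by = "gene"]$pos
  }
  pos_all <- det_pos(n_hit >= 1L)
  pos_un <- det_pos(n_hit == 1L)

  data.frame(tags_sampled = grid,
             genes_detected_all = vapply(grid, function(g)
               sum(pos_all <= g), integer(1)),
             genes_detected_unambiguous = vapply(grid, function(g)
               sum(pos_un <= g), integer(1)))
}
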