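#' Configuration for the synthetic DGE study generator
#'
#' Bundles and validates every knob of the simulator. Defaults describe
#' the study conditions the package is benchmarked under: a reference of
#' 19,131 genes of which 92.28% carry a CATG site, two libraries of 2
#' million tags, 5% of expressed genes differentially expressed at
#' |log2 fold| = 2 (half up, half down) restricted to genes of at least
#' 50 TPM true abundance, a heavy-tailed log-normal abundance profile,
#' 0.1% per-base sequencing error, and raw-tag contamination (adaptor,
#' ambiguous bases, non-reference "unknown" tags) at rates that emulate
#' real two-library tag accounting, where roughly a quarter of clean tags
#' fail reference lookup.
#'
#' @param n_genes Number of reference genes.
#' @param frac_catg Probability that a gene carries >= 1 usable CATG site.
#' @param gene_length_range Integer pair, uniform gene length range (bp);
#'   minimum 21 (CATG + 17 bp tag).
#' @param n1,n2 Total raw tags per library.
#' @param frac_de Fraction of expressed genes made differentially
#'   expressed.
#' @param log2_effects Effect sizes; recycled over DE genes with
#'   alternating sign (half up, half down in library 1) when all positive.
#' @param de_min_tpm DE genes are drawn only from genes whose true
#'   baseline abundance is at least this many tags per million.
#' @param expression_model List \code{meanlog}, \code{sdlog} of the
#'   log-normal abundance distribution across expressed genes.
#' @param per_base_error Per-base substitution probability per sequenced
#'   tag copy.
#' @param frac_adaptor,frac_ambiguous_base,frac_unknown Fractions of raw
#'   tags replaced by adaptor sequence, given an 'N', or drawn from random
#'   non-reference sequence.
#' @param n_terms Number of annotation terms.
#' @param term_size_range Integer pair, members per term.
#' @param seed Root integer seed; all module streams derive from it.
#' @return A validated list of class \code{SimConfig}.
#' @export
sim_config <- function(n_genes = 19131L, frac_catg = 0.9228,
                       gene_length_range = c(300L, 4000L),
                       n1 = 2e6, n2 = 2e6,
                       frac_de = 0.05, log2_effects = 2, de_min_tpm = 50,
                       expression_model = list(meanlog = 0, sdlog = 2),
                       per_base_error = 0.001,
                       frac_adaptor = 0.015, frac_ambiguous_base = 0.012,
                       frac_unknown = 0.25,
                       n_terms = 50L, term_size_range = c(10L, 200L),
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), frac_catg = frac_catg,
              gene_length_range = as.integer(gene_length_range),
              n1 = n1, n2 = n2, frac_de = frac_de,
              log2_effects = log2_effects, de_min_tpm = de_min_tpm,
              expression_model = expression_model,
              per_base_error = per_base_error,
              frac_adaptor = frac_adaptor,
              frac_ambiguous_base = frac_ambiguous_base,
              frac_unknown = frac_unknown,
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              seed = as.integer(seed))
  if (cfg$n_genes < 1) stop_input("invalid config: n_genes must be >= 1")
  for (f in c("frac_catg", "frac_de", "per_base_error", "frac_adaptor",
              "frac_ambiguous_base", "frac_unknown")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop_input("invalid config: '%s' must be a fraction in [0, 1]", f)
  }
  if (cfg$frac_adaptor + cfg$frac_ambiguous_base + cfg$frac_unknown > 1)
    stop_input("invalid config: contamination fractions sum above 1")
  if (length(cfg$gene_length_range) != 2L ||
      cfg$gene_length_range[1L] > cfg$gene_length_range[2L] ||
      cfg$gene_length_range[1L] < 21L)
    stop_input("invalid config: gene_length_range must be increasing and >= 21 bp")
  if (cfg$n1 <= 0 || cfg$n2 <= 0)
    stop_input("invalid config: n1 and n2 must be positive")
  if (length(cfg$term_size_range) != 2L ||
      cfg$term_size_range[1L] > cfg$term_size_range[2L] ||
      cfg$term_size_range[1L] < 0L)
    stop_input("invalid config: term_size_range must be a non-negative increasing pair")
  if (cfg$term_size_range[2L] > cfg$n_genes)
    stop_input("invalid config: term_size_range exceeds n_genes")
  if (!is.list(cfg$expression_model) ||
      !all(c("meanlog", "sdlog") %in% names(cfg$expression_model)))
    stop_input("invalid config: expression_model needs meanlog and sdlog")
  class(cfg) <- "SimConfig"
  cfg
}

# sample() treats a scalar first argument as 1:x; this keeps degenerate
# ranges (lo == hi) literal.
sample_int_range <- function(lo, hi, n) {
  if (lo == hi) rep(lo, n) else sample(lo:hi, n, replace = TRUE)
}

# Deterministic sub-seeds per module stream, derived from the root seed and
# kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7L + offset * 1009L) %% 2147483647)
}

# Replace every CATG occurrence with CTTG; the replacement cannot create a
# new CATG across its boundaries, so one pass suffices.
strip_catg <- function(s) gsub("CATG", "CTTG", s, fixed = TRUE)

#' Simulate a reference transcriptome
#'
#' Draws \code{n_genes} random A/C/G/T sequences with uniform lengths in
#' \code{gene_length_range}. Each gene independently carries a usable CATG
#' site with probability \code{frac_catg}: carriers that lack one by
#' chance get a CATG planted at a position leaving room for a full 17 bp
#' tag; non-carriers have every CATG occurrence rewritten away.
#'
#' @param config A [sim_config()].
#' @return data.frame \code{gene_id}, \code{sequence}; attribute
#'   \code{has_catg} records the per-gene carrier flag (the realised
#'   fraction is binomial around \code{frac_catg}).
#' @export
simulate_reference <- function(config) {
  if (!inherits(config, "SimConfig")) stop_input("'config' must be a SimConfig")
  set.seed(derive_seed(config$seed, 1L))
  n <- config$n_genes
  lens <- sample_int_range(config$gene_length_range[1L],
                           config$gene_length_range[2L], n)
  pool <- paste(sample(DNA_BASES4, sum(lens), replace = TRUE),
                collapse = "")
  ends <- cumsum(lens)
  seqs <- substring(pool, ends - lens + 1L, ends)
  carrier <- stats::runif(n) < config$frac_catg
  # carriers need a site with >= 17 bases 3' of it
  has_usable <- vapply(seqs, function(s) {
    pos <- gregexpr(ANCHOR_MOTIF, s, fixed = TRUE)[[1L]]
    pos[1L] != -1L && any(pos + 20L <= nchar(s))
  }, logical(1), USE.NAMES = FALSE)
  plant <- carrier & !has_usable
  if (any(plant)) {
    at <- vapply(lens[plant], function(L) sample.int(L - 20L, 1L), integer(1))
    s <- seqs[plant]
    substr(s, at, at + 3L) <- ANCHOR_MOTIF
    seqs[plant] <- s
  }
  seqs[!carrier] <- strip_catg(seqs[!carrier])
  out <- data.frame(gene_id = sprintf("G%05d", seq_len(n)), sequence = seqs,
                    stringsAsFactors = FALSE)
  attr(out, "has_catg") <- carrier
  out
}

#' Simulate gene-to-term annotations
#'
#' Assigns \code{n_terms} annotation terms to random gene subsets with
#' sizes uniform in \code{term_size_range}. Terms alternate between a GO
#' and a KEGG namespace purely as labels; a gene may carry any number of
#' terms including none.
#'
#' @param genes Reference data.frame from [simulate_reference()].
#' @param config A [sim_config()].
#' @return data.frame \code{gene_id}, \code{term}, \code{namespace},
#'   \code{label}.
#' @export
simulate_annotations <- function(genes, config) {
  if (!is.data.frame(genes) || nrow(genes) == 0L)
    stop_input("'genes' must be non-empty")
  if (config$term_size_range[2L] > nrow(genes))
    stop_input("invalid config: term_size_range exceeds number of genes")
  set.seed(derive_seed(config$seed, 2L))
  if (config$n_terms == 0L)
    return(data.frame(gene_id = character(), term = character(),
                      namespace = character(), label = character(),
                      stringsAsFactors = FALSE))
  rows <- lapply(seq_len(config$n_terms), function(i) {
    size <- sample_int_range(config$term_size_range[1L],
                             config$term_size_range[2L], 1L)
    if (size == 0L) return(NULL)
    data.frame(gene_id = sample(genes$gene_id, size),
               term = sprintf("T%04d", i),
               namespace = if (i %% 2L == 1L) "GO" else "KEGG",
               label = sprintf("synthetic term %d", i),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ground-truth abundances and differential expression
#'
#' Draws a log-normal abundance profile over the expressed genes (those
#' with a usable canonical tag), selects DE genes among those at or above
#' \code{de_min_tpm} true baseline abundance, and applies the log2 effects
#' (alternating sign when all supplied effects are positive, i.e. half up
#' and half down). Effects are injected two-sidedly - up-regulated genes
#' are raised in library 1, down-regulated genes in library 2, giving the
#' same per-gene ratio 2^e - with signs alternating along the abundance
#' ranking of the selected genes, so up- and down-regulation add matching
#' tag mass and total-count normalisation stays unbiased for null genes.
#' Both libraries are renormalised to sum to 1.
#'
#' @param genes Reference from [simulate_reference()].
#' @param index \code{TagLibraryIndex} of the reference (built internally
#'   if omitted).
#' @param config A [sim_config()].
#' @return List of class \code{GroundTruth}: \code{abundance} (data.frame
#'   \code{gene_id}, \code{abundance1}, \code{abundance2},
#'   \code{log2_effect}), \code{de_gene_ids}.
#' @export
simulate_ground_truth <- function(genes, config,
                                  index = extract_reference_tags(genes)) {
  set.seed(derive_seed(config$seed, 3L))
  expressed <- index$canonical$gene_id
  if (length(expressed) == 0L) stop_input("no gene carries a usable CATG site")
  a <- stats::rlnorm(length(expressed),
                     meanlog = config$expression_model$meanlog,
                     sdlog = config$expression_model$sdlog)
  a <- a / sum(a)
  eligible <- expressed[a * 1e6 >= config$de_min_tpm]
  n_de <- min(round(config$frac_de * length(expressed)), length(eligible))
  de_ids <- if (n_de > 0) sample(eligible, n_de) else character()
  effects <- stats::setNames(rep(0, length(expressed)), expressed)
  if (n_de > 0) {
    # alternate up/down along the abundance ranking of the selected genes
    # so the tag mass added by up- and down-regulation balances and the
    # compositional shift of total-count normalisation stays negligible
    de_ids <- de_ids[order(-a[match(de_ids, expressed)])]
    eff <- rep_len(config$log2_effects, n_de)
    if (all(eff > 0)) eff <- eff * rep_len(c(1, -1), n_de)
    effects[de_ids] <- eff
  }
  # effects applied two-sidedly: up-regulation raises the gene in library
  # 1, down-regulation raises it in library 2; the pairwise ratio is 2^e
  # either way, and neither library's total mass is inflated relative to
  # the other
  a1 <- a * 2^pmax(effects, 0)
  a1 <- a1 / sum(a1)
  a <- a * 2^(-pmin(effects, 0))
  a <- a / sum(a)
  truth <- list(
    abundance = data.frame(gene_id = expressed, abundance1 = a1,
                           abundance2 = a, log2_effect = unname(effects),
                           stringsAsFactors = FALSE),
    de_gene_ids = sort(de_ids))
  class(truth) <- "GroundTruth"
  truth
}

# Mutate k tag copies of width w with per-base error e, conditioned on at
# least one substitution per copy.
mutate_tags <- function(tags, e) {
  w <- TAG_WIDTH
  n_mut <- sample(1:w, length(tags), replace = TRUE,
                  prob = stats::dbinom(1:w, w, e))
  for (m in sort(unique(n_mut))) {
    idx <- which(n_mut == m)
    for (j in seq_len(m)) {  # positions with replacement across rounds is
      pos <- sample.int(w, length(idx), replace = TRUE)  # fine at tiny e
      old <- substr(tags[idx], pos, pos)
      new <- vapply(old, function(b) sample(setdiff(DNA_BASES4, b), 1L),
                    character(1), USE.NAMES = FALSE)
      tg <- tags[idx]
      substr(tg, pos, pos) <- new
      tags[idx] <- tg
    }
  }
  tags
}

random_tags <- function(k) {
  if (k == 0L) return(character())
  pool <- paste(sample(DNA_BASES4, k * TAG_WIDTH, replace = TRUE),
                collapse = "")
  starts <- seq.int(1L, by = TAG_WIDTH, length.out = k)
  substring(pool, starts, starts + TAG_WIDTH - 1L)
}

#' Simulate a pair of raw tag libraries
#'
#' Samples \code{n1}/\code{n2} raw tag copies per library. Each copy is,
#' independently: adaptor sequence (rate \code{frac_adaptor}), a random
#' non-reference 17-mer ("unknown", rate \code{frac_unknown}), a gene tag
#' with one base replaced by 'N' (rate \code{frac_ambiguous_base}), or a
#' gene's canonical tag drawn proportional to its abundance in that
#' library. Gene-tag copies then suffer per-base substitution errors at
#' \code{per_base_error} — corruption is applied per sampled copy, as a
#' sequencer operates on reads, so error tags scale with depth. Copies are
#' aggregated into distinct-tag count tables whose totals equal
#' \code{n1}/\code{n2} exactly.
#'
#' @param genes Reference from [simulate_reference()].
#' @param truth A \code{GroundTruth}.
#' @param config A [sim_config()].
#' @param index Reference index (rebuilt if omitted).
#' @param return_stream If TRUE, also return the per-copy raw tag vectors
#'   (needed for saturation analysis).
#' @return List with \code{lib1}, \code{lib2} (raw \code{TagCountTable}s)
#'   and, if requested, \code{stream1}, \code{stream2}.
#' @export
simulate_tag_libraries <- function(genes, truth, config,
                                   index = extract_reference_tags(genes),
                                   return_stream = FALSE) {
  if (!inherits(truth, "GroundTruth")) stop_input("'truth' must be a GroundTruth")
  ab <- truth$abundance
  missing_catg <- setdiff(ab$gene_id[ab$abundance1 + ab$abundance2 > 0],
                          index$canonical$gene_id)
  if (length(missing_catg) > 0L)
    stop_input("expressed gene(s) without CATG site: %s",
               paste(utils::head(missing_catg, 5L), collapse = ", "))
  canon <- stats::setNames(index$canonical$tag, index$canonical$gene_id)
  adaptor17 <- substr(DGE_ADAPTOR, 1L, TAG_WIDTH)

  one_library <- function(n, abundance, sub_seed) {
    set.seed(sub_seed)
    n <- as.integer(n)
    kinds <- rmultinom_counts(n, c(adaptor = config$frac_adaptor,
                                   unknown = config$frac_unknown,
                                   nbase = config$frac_ambiguous_base))
    n_gene <- n - sum(kinds)
    gcounts <- as.vector(stats::rmultinom(1L, n_gene, abundance))
    gene_tags <- rep(canon[ab$gene_id], gcounts)
    e <- config$per_base_error
    if (e > 0 && length(gene_tags) > 0L) {
      hit <- which(stats::runif(length(gene_tags)) < 1 - (1 - e)^TAG_WIDTH)
      if (length(hit) > 0L)
        gene_tags[hit] <- mutate_tags(gene_tags[hit], e)
    }
    ntags <- character(kinds[["nbase"]])
    if (kinds[["nbase"]] > 0L) {
      base_idx <- sample.int(length(ab$gene_id), kinds[["nbase"]],
                             replace = TRUE, prob = abundance)
      ntags <- canon[ab$gene_id[base_idx]]
      pos <- sample.int(TAG_WIDTH, kinds[["nbase"]], replace = TRUE)
      substr(ntags, pos, pos) <- "N"
    }
    unk <- random_tags(kinds[["unknown"]])
    if (length(unk) > 0L) {  # keep unknowns genuinely absent from the index
      redo <- unk %in% index$tags$tag
      while (any(redo)) {
        unk[redo] <- random_tags(sum(redo))
        redo <- unk %in% index$tags$tag
      }
    }
    stream <- c(gene_tags, ntags, unk,
                rep(adaptor17, kinds[["adaptor"]]))
    stream <- sample(stream)  # shuffle copies
    counts <- data.table::data.table(tag = stream)[, list(count = .N),
                                                   by = "tag"]
    data.table::setorderv(counts, "tag")
    list(table = tag_count_table(counts$tag, counts$count, stage = "raw"),
         stream = stream)
  }

  l1 <- one_library(config$n1, ab$abundance1, derive_seed(config$seed, 4L))
  l2 <- one_library(config$n2, ab$abundance2, derive_seed(config$seed, 5L))
  l1$table <- set_stage(l1$table, "raw"); attr(l1$table, "library_id") <- "lib1"
  l2$table <- set_stage(l2$table, "raw"); attr(l2$table, "library_id") <- "lib2"
  out <- list(lib1 = l1$table, lib2 = l2$table)
  if (return_stream) { out$stream1 <- l1$stream; out$stream2 <- l2$stream }
  out
}

# Multinomial split of n copies into named contamination classes (remainder
# goes to gene tags).
rmultinom_counts <- function(n, probs) {
  p <- c(probs, gene = 1 - sum(probs))
  k <- as.vector(stats::rmultinom(1L, n, p))
  stats::setNames(k[seq_along(probs)], names(probs))
}

#' One-call synthetic study
#'
#' Convenience wrapper generating reference, annotations, ground truth and
#' the raw tag library pair from a single configuration.
#'
#' @param config A [sim_config()].
#' @param return_stream Passed to [simulate_tag_libraries()].
#' @return List \code{genes}, \code{index}, \code{annotations},
#'   \code{truth}, \code{libs}.
#' @export
simulate_study <- function(config = sim_config(), return_stream = FALSE) {
  genes <- simulate_reference(config)
  index <- extract_reference_tags(genes)
  annotations <- simulate_annotations(genes, config)
  truth <- simulate_ground_truth(genes, config, index = index)
  libs <- simulate_tag_libraries(genes, truth, config, index = index,
                                 return_stream = return_stream)
  list(genes = genes, index = index, annotations = annotations,
       truth = truth, libs = libs)
}
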