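#' Pipeline configuration
#'
#' Validates paths and thresholds for a full two-library run.
#'
#' @param fasta Reference gene FASTA path.
#' @param tags1,tags2 Raw tag table TSV paths (library 1 = test, library 2
#'   = control).
#' @param annotations Optional annotation TSV path.
#' @param outdir Output directory (created if absent).
#' @param adaptor Adaptor sequence for cleaning.
#' @param p_threshold,fdr_threshold,log2_threshold DE gates.
#' @param enrich_alpha Enrichment significance threshold.
#' @param seed Integer seed recorded in the report.
#' @return Validated list of class \code{PipelineConfig}.
#' @export
pipeline_config <- function(fasta, tags1, tags2, annotations = NULL,
                            outdir = "dgetag_run", adaptor = DGE_ADAPTOR,
                            p_threshold = 0.005, fdr_threshold = 0.001,
                            log2_threshold = 1, enrich_alpha = 0.05,
                            seed = 1L) {
  assert_scalar_number(p_threshold, "p_threshold", 0, 1)
  assert_scalar_number(fdr_threshold, "fdr_threshold", 0, 1)
  assert_scalar_number(log2_threshold, "log2_threshold", 0)
  assert_scalar_number(enrich_alpha, "enrich_alpha", 0, 1)
  cfg <- list(fasta = fasta, tags1 = tags1, tags2 = tags2,
              annotations = annotations, outdir = outdir, adaptor = adaptor,
              p_threshold = p_threshold, fdr_threshold = fdr_threshold,
              log2_threshold = log2_threshold, enrich_alpha = enrich_alpha,
              seed = as.integer(seed))
  class(cfg) <- "PipelineConfig"
  cfg
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full two-library DGE pipeline
#'
#' Executes, in order: reference index construction, cleaning, singleton
#' removal, perfect/1-mismatch mapping, TPM normalisation, the
#' Audic-Claverie differential expression test with BH FDR and fold-change
#' gates, and (when annotations are supplied) hypergeometric term
#' enrichment against the background of annotated genes detected in either
#' library. All stage outputs are written as TSV under \code{outdir}
#' together with a run report; the run is deterministic given the inputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list: \code{reference_summary},
#'   \code{mapping_report1}, \code{mapping_report2}, \code{de}
#'   (a \code{DEResult}), \code{fold_histogram}, \code{enrichment},
#'   \code{top_terms}, \code{files}.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "PipelineConfig"))
    stop_input("'config' must be a PipelineConfig")
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)

  genes <- pipeline_stage("build-ref", read_gene_fasta(config$fasta))
  index <- pipeline_stage("build-ref", extract_reference_tags(genes))
  ref_sum <- reference_summary(index)

  process <- function(path, lib) {
    raw <- pipeline_stage("clean", read_tag_table(path, library_id = lib))
    cl <- pipeline_stage("clean", clean_tags(raw, adaptor = config$adaptor))
    an <- pipeline_stage("clean", drop_singletons(cl))
    m <- pipeline_stage("map", map_tags(an, index))
    m$expression <- compute_tpm(m$expression)
    m
  }
  m1 <- process(config$tags1, "lib1")
  m2 <- process(config$tags2, "lib2")

  n1 <- attr(m1$expression, "clean_total")
  n2 <- attr(m2$expression, "clean_total")
  counts <- merge(m1$expression[, c("gene_id", "count")],
                  m2$expression[, c("gene_id", "count")],
                  by = "gene_id", all = TRUE)
  names(counts) <- c("gene_id", "x", "y")
  counts$x[is.na(counts$x)] <- 0
  counts$y[is.na(counts$y)] <- 0
  de <- pipeline_stage("test",
    call_degs(counts, n1, n2, p_threshold = config$p_threshold,
              fdr_threshold = config$fdr_threshold,
              log2_threshold = config$log2_threshold))
  fh <- fold_change_histogram(de)

  enr <- NULL; topk <- NULL
  if (!is.null(config$annotations)) {
    ann <- pipeline_stage("enrich", read_annotations(config$annotations))
    detected <- counts$gene_id
    degs <- de$table$gene_id[de$table$call != "ns"]
    enr <- pipeline_stage("enrich",
      enrich_terms(degs, ann, background_ids = detected,
                   alpha = config$enrich_alpha))
    topk <- top_k_report(enr)
  }

  files <- c(
    reference_summary = file.path(config$outdir, "reference_summary.tsv"),
    mapping_report1 = file.path(config$outdir, "mapping_report_lib1.tsv"),
    mapping_report2 = file.path(config$outdir, "mapping_report_lib2.tsv"),
    expression1 = file.path(config$outdir, "expression_lib1.tsv"),
    expression2 = file.path(config$outdir, "expression_lib2.tsv"),
    degs = file.path(config$outdir, "degs.tsv"),
    report = file.path(config$outdir, "run_report.txt"))
  write_tsv(ref_sum, files[["reference_summary"]])
  write_tsv(m1$report, files[["mapping_report1"]])
  write_tsv(m2$report, files[["mapping_report2"]])
  write_tsv(m1$expression, files[["expression1"]])
  write_tsv(m2$expression, files[["expression2"]])
  deg_out <- de$table
  deg_out$p_value <- signif(deg_out$p_value, 12)
  deg_out$fdr <- signif(deg_out$fdr, 12)
  write_tsv(deg_out, files[["degs"]])
  if (!is.null(enr)) {
    files[["enrichment"]] <- file.path(config$outdir, "enrichment.tsv")
    enr_out <- enr
    enr_out$p_value <- signif(enr_out$p_value, 12)
    write_tsv(enr_out, files[["enrichment"]])
  }

  s <- de$summary
  report_lines <- c(
    "dgetag run report",
    sprintf("seed: %d", config$seed),
    sprintf("thresholds: p<%g, FDR<%g, |log2 ratio|>=%g",
            config$p_threshold, config$fdr_threshold,
            config$log2_threshold),
    sprintf("input hashes: %s",
            paste(vapply(c(config$fasta, config$tags1, config$tags2),
                         function(f) substr(digest_file(f), 1, 12),
                         character(1)), collapse = " ")),
    "",
    "Reference:",
    sprintf("  %s: %s%s", ref_sum$item, format(ref_sum$count, big.mark = ","),
            ifelse(is.na(ref_sum$percentage), "",
                   sprintf(" (%.2f%%)", ref_sum$percentage))),
    "",
    sprintf("Clean tags: %s (lib1) / %s (lib2)",
            format(n1, big.mark = ","), format(n2, big.mark = ",")),
    sprintf("DEGs: %d identified, of which %d (%.1f%%) higher and %d (%.1f%%) lower in library 1",
            s$n_total, s$n_up, s$pct_up, s$n_down, s$pct_down),
    sprintf("Ratios within 5-fold: %.2f%%", fh$pct_within_5fold))
  if (!is.null(topk) && nrow(topk) > 0L)
    report_lines <- c(report_lines, "", "Top enriched terms:",
                      sprintf("  %s p=%.3g", topk$display, topk$p_value))
  writeLines(report_lines, files[["report"]])

  invisible(list(reference_summary = ref_sum, mapping_report1 = m1$report,
                 mapping_report2 = m2$report, expression1 = m1$expression,
                 expression2 = m2$expression, de = de, fold_histogram = fh,
                 enrichment = enr, top_terms = topk, files = files))
}

# Content checksum of an input file (vectorised polynomial hash; for
# provenance logging only, not cryptographic).
digest_file <- function(path) {
  b <- as.double(readBin(path, "raw", n = file.info(path)$size))
  w <- (seq_along(b) - 1) %% 9973 + 1
  h <- (sum((b + 1) * w) + length(b)) %% 2147483647
  sprintf("%08x-%d", as.integer(h), length(b))
}

#' Write a simulated study to disk
#'
#' Writes the reference FASTA, the two raw tag tables, the annotation
#' table, and the ground truth (gene, abundance1, abundance2,
#' log2_effect) under one directory, the on-disk interface between the
#' simulator and the pipeline.
#'
#' @param study Result of [simulate_study()].
#' @param outdir Output directory.
#' @return Named vector of file paths, invisibly.
#' @export
write_study <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(fasta = file.path(outdir, "reference.fasta"),
             tags1 = file.path(outdir, "tags_lib1.tsv"),
             tags2 = file.path(outdir, "tags_lib2.tsv"),
             annotations = file.path(outdir, "annotations.tsv"),
             truth = file.path(outdir, "truth.tsv"))
  write_gene_fasta(study$genes, files[["fasta"]])
  write_tag_table(study$libs$lib1, files[["tags1"]])
  write_tag_table(study$libs$lib2, files[["tags2"]])
  write_tsv(study$annotations, files[["annotations"]])
  write_tsv(study$truth$abundance, files[["truth"]])
  invisible(files)
}
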