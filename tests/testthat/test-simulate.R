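test_that("invalid configurations are rejected naming the field", {
  expect_error(sim_config(frac_catg = 1.2), "frac_catg")
  expect_error(sim_config(n1 = 0), "n1")
  expect_error(sim_config(gene_length_range = c(10, 50)), "gene_length_range")
  expect_error(sim_config(n_genes = 100, term_size_range = c(10, 200)),
               "term_size_range")
  expect_error(sim_config(frac_unknown = 0.9, frac_adaptor = 0.2),
               "contamination")
})

test_that("frac_catg = 1 forces a CATG site into every gene", {
  cfg <- sim_config(n_genes = 100L, frac_catg = 1, n1 = 10, n2 = 10,
                    gene_length_range = c(50L, 100L),
                    term_size_range = c(5L, 20L), seed = 7)
  genes <- simulate_reference(cfg)
  expect_equal(nrow(genes), 100L)
  expect_true(all(grepl("CATG", genes$sequence, fixed = TRUE)))
  expect_true(all(grepl("^[ACGT]+$", genes$sequence)))
})

test_that("realized CATG fraction falls in the binomial 99% interval", {
  cfg <- sim_config(n_genes = 200L, frac_catg = 0.92, n1 = 10, n2 = 10,
                    gene_length_range = c(60L, 120L), seed = 3)
  genes <- simulate_reference(cfg)
  n_catg <- sum(grepl("CATG", genes$sequence, fixed = TRUE))
  bounds <- qbinom(c(0.005, 0.995), 200, 0.92)
  expect_gte(n_catg, bounds[1])
  expect_lte(n_catg, bounds[2])
})

test_that("same seed gives byte-identical FASTA; seeds differ otherwise", {
  cfg <- small_config(seed = 9)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  write_gene_fasta(simulate_reference(cfg), f1)
  write_gene_fasta(simulate_reference(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  g3 <- simulate_reference(small_config(seed = 10))
  expect_false(identical(g3$sequence, read_gene_fasta(f1)$sequence))
})

test_that("annotation tables honour n_terms and term sizes, deterministically", {
  genes <- simulate_reference(small_config(seed = 2))
  expect_equal(nrow(simulate_annotations(
    genes, small_config(seed = 2, n_terms = 0L))), 0L)
  cfg10 <- small_config(seed = 2, n_terms = 5L,
                        term_size_range = c(10L, 10L))
  ann <- simulate_annotations(genes, cfg10)
  expect_equal(length(unique(ann$term)), 5L)
  expect_true(all(table(ann$term) == 10L))
  expect_identical(ann, simulate_annotations(genes, cfg10))
})

test_that("uncorrupted libraries contain only exact reference tags and conserve totals", {
  cfg <- small_config(seed = 4, per_base_error = 0, frac_adaptor = 0,
                      frac_ambiguous_base = 0, frac_unknown = 0)
  st <- simulate_study(cfg)
  expect_equal(sum(st$libs$lib1$count), cfg$n1)
  expect_equal(sum(st$libs$lib2$count), cfg$n2)
  expect_true(all(st$libs$lib1$tag %in% st$index$tags$tag))
  expect_true(all(st$libs$lib2$tag %in% st$index$tags$tag))
})

test_that("unknown-tag injection rate falls in its binomial 99% interval", {
  cfg <- sim_config(n_genes = 200L, gene_length_range = c(100L, 400L),
                    n1 = 10000, n2 = 100, frac_unknown = 0.25,
                    frac_adaptor = 0, frac_ambiguous_base = 0,
                    per_base_error = 0, seed = 12)
  st <- simulate_study(cfg)
  known <- st$libs$lib1$tag %in% st$index$tags$tag
  n_unknown <- sum(st$libs$lib1$count[!known])
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.25)
  expect_gte(n_unknown, bounds[1])
  expect_lte(n_unknown, bounds[2])
})

test_that("two-gene abundances 0.9/0.1 reproduce a 9:1 tag ratio", {
  genes <- data.frame(
    gene_id = c("hi", "lo"),
    sequence = c(paste0("CATG", "AAAAAAAACCCCCCCCC", "GG"),
                 paste0("CATG", "GGGGGGGGTTTTTTTTT", "GG")))
  idx <- extract_reference_tags(genes)
  truth <- list(abundance = data.frame(
    gene_id = c("hi", "lo"), abundance1 = c(0.9, 0.1),
    abundance2 = c(0.9, 0.1), log2_effect = 0), de_gene_ids = character())
  class(truth) <- "GroundTruth"
  cfg <- sim_config(n_genes = 2L, n1 = 1e5, n2 = 100, per_base_error = 0,
                    frac_adaptor = 0, frac_ambiguous_base = 0,
                    frac_unknown = 0, term_size_range = c(0L, 2L), seed = 8)
  libs <- simulate_tag_libraries(genes, truth, cfg, index = idx)
  hi_tag <- idx$canonical$tag[idx$canonical$gene_id == "hi"]
  n_hi <- libs$lib1$count[libs$lib1$tag == hi_tag]
  bounds <- qbinom(c(0.005, 0.995), 1e5, 0.9)
  expect_gte(n_hi, bounds[1])
  expect_lte(n_hi, bounds[2])
})

test_that("an expressed gene without a CATG site aborts generation with its id", {
  genes <- data.frame(gene_id = c("ok", "bad"),
                      sequence = c(paste0("CATG", strrep("A", 17)),
                                   strrep("T", 40)))
  idx <- extract_reference_tags(genes)
  truth <- list(abundance = data.frame(
    gene_id = c("ok", "bad"), abundance1 = c(0.5, 0.5),
    abundance2 = c(0.5, 0.5), log2_effect = 0), de_gene_ids = character())
  class(truth) <- "GroundTruth"
  cfg <- sim_config(n_genes = 2L, n1 = 100, n2 = 100,
                    term_size_range = c(0L, 2L))
  expect_error(simulate_tag_libraries(genes, truth, cfg, index = idx), "bad")
})

test_that("ground truth: non-DE effects are exactly 0, abundances sum to 1, DE set respects the TPM floor", {
  cfg <- small_config(seed = 6)
  genes <- simulate_reference(cfg)
  idx <- extract_reference_tags(genes)
  truth <- simulate_ground_truth(genes, cfg, index = idx)
  ab <- truth$abundance
  expect_equal(sum(ab$abundance1), 1)
  expect_equal(sum(ab$abundance2), 1)
  non_de <- !(ab$gene_id %in% truth$de_gene_ids)
  expect_true(all(ab$log2_effect[non_de] == 0))
  expect_true(all(abs(ab$log2_effect[!non_de]) == 2))
  # DE genes drawn only from genes at or above the true-TPM floor
  base <- ab$abundance2 / 2^(-pmin(ab$log2_effect, 0))
  base <- base / sum(base)
  expect_true(all(base[!non_de] * 1e6 >= cfg$de_min_tpm * 0.999))
  # up and down balanced to within one gene
  expect_lte(abs(sum(ab$log2_effect > 0) - sum(ab$log2_effect < 0)), 1)
})
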