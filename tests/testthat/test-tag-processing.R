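test_that("cleaning removes ambiguous-base and adaptor tags, nothing else", {
  adaptor17 <- substr(DGE_ADAPTOR, 1, 17)
  raw <- tag_count_table(
    c("ACGTNACGTACGTACGT", adaptor17, strrep("A", 17), strrep("C", 17)),
    c(5, 7, 3, 2), stage = "raw")
  cl <- clean_tags(raw)
  expect_setequal(cl$tag, c(strrep("A", 17), strrep("C", 17)))
  expect_equal(attr(cl, "raw_total"), 17)
  expect_equal(attr(cl, "clean_total"), 5)
  expect_equal(attr(cl, "stage"), "clean")

  # identity case: nothing to remove, table unchanged but relabelled
  ok <- tag_count_table(c(strrep("G", 17), strrep("T", 17)), c(4, 9),
                        stage = "raw")
  cl2 <- clean_tags(ok)
  expect_equal(cl2$tag, ok$tag)
  expect_equal(cl2$count, ok$count)
  expect_equal(attr(cl2, "stage"), "clean")
})

test_that("ambiguous-base removal rate falls in its binomial interval", {
  cfg <- sim_config(n_genes = 150L, gene_length_range = c(100L, 400L),
                    n1 = 10000, n2 = 100, frac_ambiguous_base = 0.1,
                    frac_adaptor = 0, frac_unknown = 0, per_base_error = 0,
                    term_size_range = c(5L, 20L), seed = 21)
  st <- simulate_study(cfg)
  cl <- clean_tags(st$libs$lib1)
  removed <- attr(cl, "raw_total") - attr(cl, "clean_total")
  bounds <- qbinom(c(0.005, 0.995), 10000, 0.1)
  expect_gte(removed, bounds[1])
  expect_lte(removed, bounds[2])
})

test_that("singleton filtering keeps exactly the counts above 1", {
  cl <- clean_tags(tag_count_table(
    c(strrep("A", 17), strrep("C", 17), strrep("G", 17)), c(1, 2, 3),
    stage = "raw"))
  an <- drop_singletons(cl)
  expect_equal(an$count, c(2, 3))
  expect_equal(attr(an, "stage"), "analysis")
  expect_equal(attr(an, "clean_total"), 6)  # TPM denominator is preserved

  all_single <- clean_tags(tag_count_table(strrep("T", 17), 1, stage = "raw"))
  expect_equal(nrow(drop_singletons(all_single)), 0L)

  none_single <- clean_tags(tag_count_table(
    c(strrep("A", 17), strrep("G", 17)), c(5, 2), stage = "raw"))
  expect_equal(drop_singletons(none_single)$count, c(5, 2))
})

make_analysis <- function(tags, counts) {
  raw <- tag_count_table(tags, counts, stage = "raw")
  drop_singletons(clean_tags(raw))
}

test_that("mapping follows the perfect/1-mismatch rule with exact precedence", {
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    sequence = c(paste0("CATG", "AAAAAAAAAAAAAAAAA", "GG"),
                 paste0("CATG", "CCCCCCCCCCCCCCCCC", "GG")))
  idx <- extract_reference_tags(genes)
  t_exact <- strrep("A", 17)
  t_mm1 <- paste0("T", strrep("A", 16))     # 1 mismatch from g1 only
  t_far <- paste0("TTTT", strrep("A", 13))  # distance 4 from everything
  an <- make_analysis(c(t_exact, t_mm1, t_far), c(10, 4, 6))
  m <- map_tags(an, idx)
  expect_equal(m$expression$count[m$expression$gene_id == "g1"], 14)
  rep <- m$report
  expect_equal(rep$total[rep$item == "Unknown tags"], 6)
  expect_equal(rep$distinct[rep$item == "Unknown tags"], 1)
  # conservation: mapped + genome + unknown = clean analysis total
  expect_equal(rep$total[rep$item == "All tags mapping to genes"] +
                 rep$total[rep$item == "Mapping to genome"] +
                 rep$total[rep$item == "Unknown tags"],
               rep$total[rep$item == "Clean analysis tags"])
})

test_that("a tag 1 mismatch from two different genes is ambiguous", {
  genes <- data.frame(
    gene_id = c("g1", "g2"),
    sequence = c(paste0("CATG", "AAAAAAAAAAAAAAAAA", "GG"),
                 paste0("CATG", "CAAAAAAAAAAAAAAAA", "GG")))
  idx <- extract_reference_tags(genes)
  query <- paste0("G", strrep("A", 16))  # distance 1 from both tags
  m <- map_tags(make_analysis(query, 8), idx)
  rep <- m$report
  expect_equal(rep$total[rep$item == "All tags mapping to genes"], 8)
  expect_equal(rep$total[rep$item == "Unambiguous tag mapping to genes"], 0)
  expect_equal(sum(m$expression$count), 0)
  expect_equal(m$expression$all_count, c(8, 8))
})

test_that("mapping agrees with a brute-force all-pairs Hamming oracle", {
  set.seed(17)
  cfg <- sim_config(n_genes = 30L, gene_length_range = c(60L, 200L),
                    n1 = 2000, n2 = 100, per_base_error = 0.02,
                    frac_unknown = 0.1, frac_adaptor = 0,
                    frac_ambiguous_base = 0, seed = 17,
                    term_size_range = c(0L, 10L))
  st <- simulate_study(cfg)
  an <- drop_singletons(clean_tags(st$libs$lib1))
  m <- map_tags(an, st$index)
  ref <- st$index$tags
  for (i in seq_len(nrow(an))) {
    d <- vapply(ref$tag, hamming, numeric(1), a = an$tag[i])
    hit <- if (any(d == 0)) which(d == 0) else which(d == 1)
    genes_hit <- unique(unlist(strsplit(ref$gene_ids[hit], ",")))
    row <- m$expression[m$expression$gene_id %in% genes_hit, , drop = FALSE]
    if (length(genes_hit) == 1L) {
      expect_gte(row$count, an$count[i])
    } else if (length(genes_hit) == 0L) {
      expect_equal(
        sum(m$expression$all_count[m$expression$gene_id %in% genes_hit]), 0)
    }
  }
  # totals agree with the oracle's partition
  oracle_class <- vapply(an$tag, function(tg) {
    d <- vapply(ref$tag, hamming, numeric(1), a = tg)
    hit <- if (any(d == 0)) which(d == 0) else which(d == 1)
    length(unique(unlist(strsplit(ref$gene_ids[hit], ","))))
  }, numeric(1))
  rep <- m$report
  expect_equal(rep$total[rep$item == "Unknown tags"],
               sum(an$count[oracle_class == 0]))
  expect_equal(rep$total[rep$item == "Unambiguous tag mapping to genes"],
               sum(an$count[oracle_class == 1]))
  expect_equal(rep$total[rep$item == "All tags mapping to genes"],
               sum(an$count[oracle_class >= 1]))
})

test_that("TPM is count per million clean tags and scale-equivariant", {
  genes <- data.frame(gene_id = "g1",
                      sequence = paste0("CATG", strrep("A", 17), "GG"))
  idx <- extract_reference_tags(genes)
  an <- make_analysis(strrep("A", 17), 100)
  attr(an, "clean_total") <- 1e6
  expr <- compute_tpm(map_tags(an, idx)$expression, clean_total = 1e6)
  expect_equal(expr$tpm, 100)
  # scale-equivariance: doubling counts and the denominator leaves TPM fixed
  expect_equal(compute_tpm(map_tags(make_analysis(strrep("A", 17), 200),
                                    idx)$expression,
                           clean_total = 2e6)$tpm,
               expr$tpm)
  expect_error(compute_tpm(map_tags(an, idx)$expression, clean_total = 0),
               "positive")
})

test_that("TPM sums to 1e6 when every clean tag maps unambiguously", {
  genes <- data.frame(
    gene_id = c("g1", "g2", "g3"),
    sequence = paste0("CATG", c(strrep("A", 17), strrep("C", 17),
                                strrep("G", 17)), "GG"))
  idx <- extract_reference_tags(genes)
  an <- make_analysis(c(strrep("A", 17), strrep("C", 17), strrep("G", 17)),
                      c(10, 20, 30))
  expr <- compute_tpm(map_tags(an, idx)$expression, clean_total = 60)
  expect_equal(sum(expr$tpm), 1e6)
})

test_that("saturation curves are monotone, anchored at 0 and full depth", {
  for (sd in 1:3) {
    cfg <- sim_config(n_genes = 120L, gene_length_range = c(80L, 300L),
                      n1 = 20000, n2 = 100, seed = sd,
                      term_size_range = c(0L, 10L))
    st <- simulate_study(cfg, return_stream = TRUE)
    grid <- c(0L, as.integer(seq(2000, 20000, length.out = 9)))
    sat <- saturation_curve(st$libs$stream1, st$index, grid, seed = sd)
    expect_equal(unlist(sat[1, ]), c(tags_sampled = 0,
                                     genes_detected_all = 0,
                                     genes_detected_unambiguous = 0))
    expect_true(all(diff(sat$genes_detected_all) >= 0))
    expect_true(all(diff(sat$genes_detected_unambiguous) >= 0))
    # at 100% depth the curve equals the full-data mapping result
    full <- map_tags(set_stage_for_test(clean_tags(st$libs$lib1)), st$index)
    expect_equal(sat$genes_detected_all[nrow(sat)],
                 sum(full$expression$all_count > 0))
    expect_equal(sat$genes_detected_unambiguous[nrow(sat)],
                 sum(full$expression$count > 0))
  }
  expect_error(saturation_curve(rep(strrep("A", 17), 10), NULL,
                                grid = c(5L, 20L)), "exceeds")
})
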