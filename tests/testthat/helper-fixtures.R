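# Shared fixtures: all synthetic, built in code.

# A small but non-trivial study configuration used by most pipeline tests.
small_config <- function(seed = 1L, ...) {
  defaults <- list(n_genes = 400L, gene_length_range = c(100L, 800L),
                   n1 = 40000, n2 = 40000, n_terms = 12L,
                   term_size_range = c(5L, 40L), seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Hand-rolled gene records with known CATG structure.
tiny_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    sequence = c(
      # one qualifying site, tag = the 17 bases 3' of CATG
      "AAACATGTTTTTTTTTTTTTTTTA",
      # two qualifying sites; 3'-most tag is canonical
      paste0("CATG", strrep("A", 17), "CATG", strrep("G", 17), "CC"),
      # CATG too close to the 3' end: no tag
      paste0(strrep("T", 10), "CATG", strrep("A", 10))),
    stringsAsFactors = FALSE)
}

# Naive reference-tag oracle: plain substring scan, no shared code with
# extract_reference_tags' bookkeeping.
oracle_reference_tags <- function(genes) {
  out <- list()
  for (i in seq_len(nrow(genes))) {
    s <- genes$sequence[i]
    for (p in seq_len(max(nchar(s) - 3L, 0L))) {
      if (substr(s, p, p + 3L) == "CATG" && p + 20L <= nchar(s)) {
        tag <- substr(s, p + 4L, p + 20L)
        if (!grepl("N", tag, fixed = TRUE))
          out[[length(out) + 1L]] <- c(genes$gene_id[i], tag)
      }
    }
  }
  if (length(out) == 0L)
    return(data.frame(gene_id = character(), tag = character()))
  d <- unique(as.data.frame(do.call(rbind, out), stringsAsFactors = FALSE))
  names(d) <- c("gene_id", "tag")
  d
}

# Relabel a clean table as analysis stage without singleton filtering
# (saturation analysis maps clean tags directly).
set_stage_for_test <- function(cl) {
  attr(cl, "stage") <- "analysis"
  cl
}

# Brute-force Hamming distance between two equal-length strings.
hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Two-sided Audic-Claverie oracle via the negative-binomial identity:
# y | x ~ NB(size = x + 1, prob = N1 / (N1 + N2)).
oracle_ac_pvalue <- function(x, y, n1, n2) {
  pr <- n1 / (n1 + n2)
  lo <- stats::pnbinom(y, size = x + 1, prob = pr)
  up <- stats::pnbinom(y - 1, size = x + 1, prob = pr, lower.tail = FALSE)
  min(1, 2 * min(lo, up))
}

# Exhaustive hypergeometric upper-tail oracle by direct summation of
# binomial-coefficient products (exact at the small N it is used for).
oracle_hyper_p <- function(N, n, M, m) {
  if (m == 0) return(1)
  i <- m:min(n, M)
  sum(choose(M, i) * choose(N - M, n - i)) / choose(N, n)
}
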