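# shared fixtures and independent oracles for the test suite

AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

# independent oracle: count every length-k substring by brute force,
# ignoring windows with characters outside the standard alphabet; returns a
# named frequency table (kmer -> relative frequency among valid windows)
naive_kmer_table <- function(sequence, k) {
  chars <- strsplit(sequence, "")[[1]]
  if (length(chars) < k) return(numeric(0))
  wins <- vapply(seq_len(length(chars) - k + 1L),
                 function(i) paste(chars[i:(i + k - 1L)], collapse = ""), "")
  valid <- wins[!grepl(paste0("[^", paste(AA, collapse = ""), "]"), wins)]
  if (length(valid) == 0L) return(numeric(0))
  tab <- table(valid)
  setNames(as.numeric(tab) / length(valid), names(tab))
}

# compare kmer_frequencies against the naive oracle on one sequence
expect_matches_naive_kmers <- function(sequence, vocab) {
  got <- kmer_frequencies(sequence, vocab)
  nz <- which(got > 0)
  got_tab <- setNames(got[nz], kmer_strings(vocab, nz))
  ora <- naive_kmer_table(sequence, vocab$k)
  expect_equal(got_tab[order(names(got_tab))], ora[order(names(ora))],
               tolerance = 1e-12)
  expect_equal(sum(got), if (length(ora)) 1 else 0)
}

# independent oracle: textbook one-way ANOVA per feature, residual form
textbook_anova_f <- function(X, groups) {
  groups <- factor(groups)
  g <- nlevels(groups)
  n <- nrow(X)
  apply(X, 2L, function(x) {
    mg <- tapply(x, groups, mean)
    ng <- tapply(x, groups, length)
    grand <- mean(x)
    ssb <- sum(ng * (mg - grand)^2)
    ssw <- sum((x - mg[groups])^2)
    msb <- ssb / (g - 1)
    msw <- ssw / (n - g)
    if (msw > 0) msb / msw else if (msb > 0) Inf else 0
  })
}

# independent oracle: exact two-sided Mann-Whitney p by full enumeration of
# the n1-subsets of pooled midranks
exact_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  ranks <- rank(c(a, b))
  U_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  combos <- utils::combn(n1 + n2, n1)
  u_all <- apply(combos, 2L, function(ix) sum(ranks[ix]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(U_obs - mu) - 1e-12)
}

# small labeled corpus with implanted motifs, cheap enough for unit tests
tiny_corpus <- function(n_families = 3L, sizes = c(24L, 16L, 12L),
                        n_background = 10L, seed = 11L) {
  generate_corpus(synthetic_config(
    n_families = n_families, family_sizes = sizes, motif_length = 8L,
    mutation_rate = 0, length_range = c(60L, 120L),
    n_background = n_background, seed = seed))
}

# reduced training schedule: unit tests exercise contracts, not accuracy
fast_config <- function() train_config(max_epochs = 120L, patience = 30L)

# a tiny trained ensemble, built once per test run and reused
tiny_ensemble <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      co <- tiny_corpus()
      cache <<- list(
        corpus = co,
        ensemble = train_ensemble(co, k = 2, n_features = 100, seed = 3L,
                                  config = fast_config())
      )
    }
    cache
  }
})

corpus_subset <- function(corpus, ids) {
  kmerTF:::new_corpus(corpus$records[corpus$records$id %in% ids, ,
                                     drop = FALSE])
}

write_tmp_fasta <- function(records, dir = tempdir()) {
  path <- tempfile("seqs", tmpdir = dir, fileext = ".fasta")
  write_fasta(records, path)
  path
}
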