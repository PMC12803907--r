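#' Configuration for the synthetic TF-family corpus generator
#'
#' The generator emulates the structure of a curated plant TF corpus: a
#' multi-family collection with a long-tail family-size distribution, where
#' each family is defined by a short conserved motif (standing in for the
#' family's DNA-binding domain) implanted in variable background sequence,
#' plus unlabeled non-TF background sequences carrying no motif.
#'
#' @param n_families number of TF families.
#' @param family_sizes integer vector of per-family member counts (length
#'   `n_families`). The default draws a geometric long tail between
#'   `size_range[2]` (largest) and `size_range[1]` (smallest).
#' @param size_range used only when `family_sizes` is NULL.
#' @param motif_length conserved motif length in residues (default 8, the
#'   scale of a short DBD signature).
#' @param motifs_per_family number of motifs per family (default 1).
#' @param mutation_rate per-residue probability that an implanted motif
#'   residue is substituted (default 0.05).
#' @param length_range background sequence length bounds (default 80-300).
#' @param background_composition residue probabilities (default uniform).
#' @param n_background number of unlabeled non-TF sequences.
#' @param family_names optional names; default `FAM01`, `FAM02`, ...
#' @param seed integer seed; the whole corpus is a deterministic function of
#'   the configuration.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_families = 6L, family_sizes = NULL,
                             size_range = c(20L, 200L), motif_length = 8L,
                             motifs_per_family = 1L, mutation_rate = 0.05,
                             length_range = c(80L, 300L),
                             background_composition = rep(1 / 20, 20),
                             n_background = 0L, family_names = NULL,
                             seed = 1L) {
  if (is.null(family_sizes)) {
    family_sizes <- round(exp(seq(log(size_range[2]), log(size_range[1]),
                                  length.out = n_families)))
  }
  stopifnot(length(family_sizes) == n_families,
            all(family_sizes >= 1),
            mutation_rate >= 0, mutation_rate <= 1,
            motif_length >= 2,
            length_range[1] <= length_range[2],
            length(background_composition) == 20,
            all(background_composition >= 0),
            n_background >= 0)
  if (motif_length >= length_range[1]) {
    stop("motif_length (", motif_length, ") must be shorter than the ",
         "minimum background length (", length_range[1], ")")
  }
  if (is.null(family_names)) {
    family_names <- sprintf("FAM%02d", seq_len(n_families))
  }
  stopifnot(length(family_names) == n_families, !anyDuplicated(family_names))
  structure(list(n_families = as.integer(n_families),
                 family_sizes = as.integer(family_sizes),
                 motif_length = as.integer(motif_length),
                 motifs_per_family = as.integer(motifs_per_family),
                 mutation_rate = mutation_rate,
                 length_range = as.integer(length_range),
                 background_composition = background_composition /
                   sum(background_composition),
                 n_background = as.integer(n_background),
                 family_names = family_names,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

random_aa <- function(n, prob) {
  paste(sample(AA_CHARS, n, replace = TRUE, prob = prob), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# draw pairwise-distinct motifs with minimum Hamming distance motif_length/2,
# so families stay distinguishable by their k-mer content
draw_motifs <- function(n, len, min_dist = ceiling(len / 2)) {
  motifs <- character(0)
  guard <- 0L
  while (length(motifs) < n) {
    cand <- random_aa(len, NULL)
    if (all(vapply(motifs, function(m) hamming(m, cand) >= min_dist,
                   logical(1)))) {
      motifs <- c(motifs, cand)
    }
    guard <- guard + 1L
    if (guard > 10000L) stop("could not draw ", n, " motifs at distance ",
                             min_dist, "; lower n or min_dist")
  }
  motifs
}

mutate_motif <- function(motif, rate) {
  if (rate <= 0) return(motif)
  chars <- strsplit(motif, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    chars[hit] <- vapply(chars[hit], function(ch) {
      sample(setdiff(AA_CHARS, ch), 1L)
    }, character(1))
  }
  paste(chars, collapse = "")
}

#' Generate a synthetic labeled TF corpus
#'
#' Per family, one (or more) conserved motifs are drawn uniformly over the
#' 20-letter alphabet with a minimum pairwise Hamming distance of half the
#' motif length. Each family member is an i.i.d. background sequence with a
#' (possibly mutated) copy of a family motif implanted at a random position.
#' Background (non-TF) records carry no label; any background sequence that
#' happens to contain a family motif verbatim is regenerated.
#'
#' @param config a [synthetic_config()].
#' @return a `tf_corpus` with attribute `"manifest"`: list with `motifs`
#'   (per family), `implants` (data.frame id/family/motif/position) and the
#'   `config`.
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  motifs <- draw_motifs(config$n_families * config$motifs_per_family,
                        config$motif_length)
  motifs <- split(motifs, rep(seq_len(config$n_families),
                              each = config$motifs_per_family))
  names(motifs) <- config$family_names

  ids <- character(0); seqs <- character(0); fams <- character(0)
  implants <- list()
  for (fi in seq_len(config$n_families)) {
    fam <- config$family_names[fi]
    for (m in seq_len(config$family_sizes[fi])) {
      id <- sprintf("%s_%04d", fam, m)
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      bg <- random_aa(L, config$background_composition)
      motif <- motifs[[fam]][sample.int(config$motifs_per_family, 1L)]
      imp <- mutate_motif(motif, config$mutation_rate)
      pos <- sample.int(L - config$motif_length + 1L, 1L)
      seq <- paste0(substr(bg, 1L, pos - 1L), imp,
                    substr(bg, pos + config$motif_length, L))
      ids <- c(ids, id); seqs <- c(seqs, seq); fams <- c(fams, fam)
      implants[[length(implants) + 1L]] <-
        data.frame(id = id, family = fam, motif = motif, position = pos,
                   stringsAsFactors = FALSE)
    }
  }
  all_motifs <- unlist(motifs, use.names = FALSE)
  for (b in seq_len(config$n_background)) {
    repeat {
      L <- sample(config$length_range[1]:config$length_range[2], 1L)
      bg <- random_aa(L, config$background_composition)
      if (!any(vapply(all_motifs, grepl, logical(1), x = bg, fixed = TRUE))) break
    }
    ids <- c(ids, sprintf("BG_%04d", b))
    seqs <- c(seqs, bg)
    fams <- c(fams, NA_character_)
  }
  corpus <- new_corpus(protein_records(ids, seqs, fams))
  attr(corpus, "manifest") <- list(motifs = motifs,
                                   implants = do.call(rbind, implants),
                                   config = config)
  corpus
}

#' The fixed benchmark corpus
#'
#' A published, fully reproducible configuration used by the package's own
#' benchmark: 8 families with long-tail sizes 400, 300, 200, 150, 100, 60,
#' 40, 20 (1270 labeled TFs), motif length 8, mutation rate 0.05, 500
#' unlabeled background sequences, seed 1337. Family names follow common
#' plant TF families purely as familiar labels; the sequences are synthetic.
#'
#' @return a `tf_corpus` of 1770 records (see [generate_corpus()]).
#' @export
make_acceptance_corpus <- function() {
  generate_corpus(synthetic_config(
    n_families = 8L,
    family_sizes = c(400L, 300L, 200L, 150L, 100L, 60L, 40L, 20L),
    motif_length = 8L,
    mutation_rate = 0.05,
    length_range = c(80L, 300L),
    n_background = 500L,
    family_names = c("bHLH", "MYB", "ERF", "NAC", "WRKY", "bZIP", "C2H2",
                     "GRAS"),
    seed = 1337L
  ))
}

#' Write a synthetic corpus to disk in pipeline formats
#'
#' Emits exactly what the main pipeline consumes: a FASTA of all sequences,
#' a TSV of id-to-family labels (labeled records only), and a JSON manifest
#' of the generator's ground truth.
#'
#' @param corpus a `tf_corpus` from [generate_corpus()].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written (fasta, labels, manifest).
#' @export
write_synthetic_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- file.path(dir, "sequences.fasta")
  labels <- file.path(dir, "labels.tsv")
  manifest <- file.path(dir, "manifest.json")
  write_fasta(corpus$records, fasta)
  write_labels(corpus, labels)
  man <- attr(corpus, "manifest")
  if (!is.null(man)) {
    jsonlite::write_json(
      list(motifs = man$motifs, implants = man$implants,
           config = unclass(man$config)),
      manifest, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(fasta = fasta, labels = labels, manifest = manifest))
}
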