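#' Read protein sequences from a FASTA file
#'
#' Returns one record per FASTA entry, in file order. The header token before
#' the first whitespace becomes the record id, sequences are upper-cased, and
#' a single terminal stop symbol `*` (a common proteome-export dialect) is
#' stripped. No residue validation happens here; see [validate_and_dedup()].
#'
#' @param path path to a FASTA file.
#' @return data.frame with columns `id`, `sequence`, `family` (all `NA` at
#'   this stage), one row per entry.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) {
    warning("empty FASTA file: ", path)
    return(protein_records(character(), character()))
  }
  first <- nonblank[1L]
  if (!startsWith(trimws(lines[first]), ">")) {
    stop("malformed FASTA: sequence data before any '>' header at line ",
         first, " of ", path)
  }
  # BStringSet: no alphabet restriction, so entries with stray characters
  # survive reading and are reported properly at validation time.
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[[:space:]]+"), `[[`, character(1), 1L)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  protein_records(ids, seqs)
}

protein_records <- function(id, sequence, family = NULL) {
  data.frame(
    id = as.character(id),
    sequence = as.character(sequence),
    family = if (is.null(family)) rep(NA_character_, length(id)) else as.character(family),
    stringsAsFactors = FALSE
  )
}

#' Write protein records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns (a corpus'
#'   `records`, or the output of [read_fasta()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Validate residues and remove exact duplicate sequences
#'
#' Records whose sequences contain characters outside the accepted alphabet
#' are dropped (reported with id and offending character); among identical
#' sequence strings only the first occurrence is kept. By default the
#' accepted alphabet is the 20 standard amino acids, so ambiguity codes
#' (B, J, O, U, X, Z) cause a drop; with `permissive = TRUE` such records are
#' retained and their non-standard residues simply never contribute a valid
#' k-mer window downstream.
#'
#' @param records data.frame of protein records (see [read_fasta()]).
#' @param permissive keep records with non-standard residues? Default `FALSE`.
#' @return a `tf_corpus`: list with `records` (validated, deduplicated,
#'   input order preserved) and `families` (unique non-missing labels in
#'   first-appearance order), plus counts `n_dropped` and `n_merged`.
#' @export
validate_and_dedup <- function(records, permissive = FALSE) {
  stopifnot(is.data.frame(records))
  if (is.null(records$family)) records$family <- NA_character_
  keep <- rep(TRUE, nrow(records))
  if (nrow(records) > 0) {
    bad_len <- !nzchar(records$sequence)
    # internal '*' is always invalid; terminal '*' was stripped at read time
    pat <- paste0("[^", AA_ALPHABET, "]")
    has_bad <- grepl(pat, records$sequence)
    # even permissively, non-letters (digits, internal '*', ...) are rejected
    if (permissive) has_bad <- grepl("[^A-Z]", records$sequence)
    drop <- bad_len | has_bad
    if (any(has_bad)) {
      use_pat <- if (permissive) "[^A-Z]" else pat
      first_bad <- regmatches(records$sequence[has_bad],
                              regexpr(use_pat, records$sequence[has_bad]))
      msg <- paste0(records$id[has_bad], " ('", first_bad, "')", collapse = ", ")
      message("dropped ", sum(has_bad), " record(s) with invalid residues: ", msg)
    }
    keep <- !drop
  }
  kept <- records[keep, , drop = FALSE]
  dup <- duplicated(kept$sequence)
  if (any(dup)) {
    # conflicting labels among duplicates: first wins, conflict is reported
    first_idx <- match(kept$sequence[dup], kept$sequence)
    conflict <- !is.na(kept$family[dup]) & !is.na(kept$family[first_idx]) &
      kept$family[dup] != kept$family[first_idx]
    if (any(conflict)) {
      message("label conflict among duplicate sequences; kept first label for: ",
              paste(kept$id[which(dup)[conflict]], collapse = ", "))
    }
    message("merged ", sum(dup), " exact duplicate sequence(s)")
  }
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no valid records remain after validation")
  new_corpus(out, n_dropped = sum(!keep), n_merged = sum(dup))
}

new_corpus <- function(records, n_dropped = 0L, n_merged = 0L) {
  fams <- unique(records$family[!is.na(records$family)])
  structure(
    list(records = records, families = fams,
         n_dropped = as.integer(n_dropped), n_merged = as.integer(n_merged)),
    class = "tf_corpus"
  )
}

#' @export
print.tf_corpus <- function(x, ...) {
  n_lab <- sum(!is.na(x$records$family))
  cat("tf_corpus: ", nrow(x$records), " records (", n_lab, " labeled, ",
      nrow(x$records) - n_lab, " unlabeled), ",
      length(x$families), " families\n", sep = "")
  if (length(x$families)) {
    cat("families:", paste(head(x$families, 10), collapse = ", "),
        if (length(x$families) > 10) "..." else "", "\n")
  }
  invisible(x)
}

#' Read a sequence id to family label table
#'
#' @param path 2-column TSV with header `id<TAB>family`.
#' @return data.frame with columns `id` and `family`.
#' @export
read_labels <- function(path) {
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = "character")
  if (!all(c("id", "family") %in% names(tab))) {
    stop("label table must have columns 'id' and 'family': ", path)
  }
  tab[, c("id", "family")]
}

#' Attach family labels to a corpus
#'
#' Records whose id appears in the table get their family set; others remain
#' unlabeled. Label-table ids absent from the corpus are reported as orphans.
#'
#' @param corpus a `tf_corpus`.
#' @param labels data.frame with columns `id`, `family` (ids unique).
#' @return the relabeled `tf_corpus`.
#' @export
attach_labels <- function(corpus, labels) {
  stopifnot(inherits(corpus, "tf_corpus"))
  if (anyDuplicated(labels$id)) {
    stop("duplicate id(s) in label table: ",
         paste(unique(labels$id[duplicated(labels$id)]), collapse = ", "))
  }
  hit <- match(corpus$records$id, labels$id)
  corpus$records$family <- ifelse(is.na(hit), corpus$records$family,
                                  labels$family[hit])
  orphans <- setdiff(labels$id, corpus$records$id)
  if (length(orphans)) {
    warning(length(orphans), " label id(s) not present in corpus: ",
            paste(head(orphans, 20), collapse = ", "))
  }
  new_corpus(corpus$records, corpus$n_dropped, corpus$n_merged)
}

#' Write the label table of a corpus as TSV
#'
#' @param corpus a `tf_corpus`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(corpus, path) {
  lab <- corpus$records[!is.na(corpus$records$family), c("id", "family")]
  write.table(lab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
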