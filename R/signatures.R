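# Oligonucleotide signatures: sliding-window word counts -> percentages.

BASES <- c("A", "C", "G", "T")

.check_k <- function(k) {
  if (length(k) != 1L || is.na(k) || k != as.integer(k) || k < 1 || k > 9)
    stop("word length k must be an integer between 1 and 9 (got ",
         paste(k, collapse = ","), ")")
  as.integer(k)
}

#' Lexicographic index of DNA words
#'
#' Maps words over {A,C,G,T} of a common length k to 0-based indices in
#' lexicographic order (A < C < G < T), the bin ordering used by all
#' signature vectors. [index_word()] is the inverse.
#'
#' @param words Character vector of equal-length DNA words.
#' @return Integer vector of 0-based indices in `0 .. 4^k - 1`.
#' @seealso [index_word()], [kmer_words()]
#' @export
word_index <- function(words) {
  words <- toupper(words)
  k <- unique(nchar(words))
  if (length(k) != 1L) stop("words must all have the same length")
  k <- .check_k(k)
  codes <- match(unlist(strsplit(words, "", fixed = TRUE)), BASES) - 1L
  if (anyNA(codes)) stop("words may only contain A, C, G or T")
  m <- matrix(codes, ncol = k, byrow = TRUE)
  as.integer(m %*% 4^((k - 1):0))
}

#' @rdname word_index
#' @param i Integer vector of 0-based word indices.
#' @param k Word length (1-9).
#' @export
index_word <- function(i, k) {
  k <- .check_k(k)
  if (any(i < 0 | i >= 4^k)) stop("index out of range for k = ", k)
  out <- matrix("", length(i), k)
  x <- as.integer(i)
  for (j in k:1) {
    out[, j] <- BASES[x %% 4L + 1L]
    x <- x %/% 4L
  }
  apply(out, 1, paste, collapse = "")
}

#' @rdname word_index
#' @export
kmer_words <- function(k) index_word(seq_len(4^.check_k(k)) - 1L, k)

#' Count oligonucleotide words with a sliding window
#'
#' Counts every overlapping window of length `k` along a sequence
#' (forward strand, offsets `0 .. L-k`). Windows containing any non-ACGT
#' character are skipped; matching is case-insensitive.
#'
#' @param seq A single DNA string (or anything coercible via
#'   `as.character`).
#' @param k Word length, 1-9.
#' @return An object of class `kmer_counts`: list with `k`, `counts`
#'   (integer vector of length `4^k`, lexicographic word order) and
#'   `n_windows` (total valid windows).
#' @export
count_words <- function(seq, k) {
  k <- .check_k(k)
  seq <- as.character(seq)
  if (length(seq) != 1L) stop("count_words expects a single sequence")
  counts <- count_words_cpp(seq, k)
  nw <- attr(counts, "n_windows")
  attr(counts, "n_windows") <- NULL
  structure(list(k = k, counts = counts, n_windows = nw),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("<kmer_counts> k =", x$k, "|", length(x$counts), "bins |",
      format(x$n_windows, big.mark = ","), "windows\n")
  invisible(x)
}

#' Oligonucleotide signature of a set of sequences
#'
#' Accumulates sliding-window word counts over one or more records
#' (windows never bridge record boundaries) and converts them to
#' percentages: `pct[i] = 100 * counts[i] / n_windows`.
#'
#' @param seqs Character vector of DNA strings (or a
#'   `Biostrings::DNAStringSet`).
#' @param k Word length, 1-9.
#' @param label Source identifier attached to the signature.
#' @return An object of class `oligo_signature`: list with `k`, `label`,
#'   `pct` (numeric, length `4^k`, percent units) and `n_windows`.
#' @export
signature_from_sequences <- function(seqs, k, label = "signature") {
  k <- .check_k(k)
  seqs <- as.character(seqs)
  if (length(seqs) < 1L) stop("at least one sequence record is required")
  total <- numeric(4^k)
  nw <- 0
  for (s in seqs) {
    cw <- count_words(s, k)
    total <- total + as.numeric(cw$counts)
    nw <- nw + cw$n_windows
  }
  if (nw == 0)
    stop("empty signature: no valid length-", k, " windows in the input")
  structure(list(k = k, label = label, pct = 100 * total / nw,
                 n_windows = nw),
            class = "oligo_signature")
}

# signature object from a precomputed percentage vector (no sequence);
# used for tests and large-N bookkeeping where sequences are not needed
#' Construct a signature from a percentage vector
#'
#' Low-level constructor for an `oligo_signature` from an existing
#' percentage vector (must have length `4^k` and sum to 100 when
#' `n_windows > 0`).
#'
#' @param pct Numeric vector of length `4^k`, percent units.
#' @param k Word length, 1-9.
#' @param label Source identifier.
#' @param n_windows Window count the percentages were derived from.
#' @return An `oligo_signature`.
#' @export
new_signature <- function(pct, k, label = "signature", n_windows = NA_real_) {
  k <- .check_k(k)
  if (length(pct) != 4^k) stop("pct must have length 4^k = ", 4^k)
  if (any(pct < 0)) stop("signature percentages must be non-negative")
  structure(list(k = k, label = label, pct = as.numeric(pct),
                 n_windows = n_windows),
            class = "oligo_signature")
}

#' @export
print.oligo_signature <- function(x, ...) {
  cat("<oligo_signature>", x$label, "| k =", x$k, "|",
      length(x$pct), "bins | n_windows =",
      format(x$n_windows, big.mark = ","), "\n")
  invisible(x)
}

#' Per-record signatures of a multi-FASTA
#'
#' @param seqs Named character vector of sequences (e.g. from
#'   [read_fasta()]).
#' @param k Word length, 1-9.
#' @return Named list of `oligo_signature`, one per record.
#' @export
signatures_per_record <- function(seqs, k) {
  seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("sequences must be named")
  out <- lapply(names(seqs), function(nm)
    signature_from_sequences(seqs[[nm]], k, label = nm))
  names(out) <- names(seqs)
  out
}

#' Read a (multi-)FASTA file as named DNA strings
#'
#' Wraps `Biostrings::readDNAStringSet`; record names are truncated to the
#' first whitespace-delimited token of the header.
#'
#' @param path FASTA file path.
#' @param drop_plasmids If `TRUE`, records whose full header contains the
#'   keyword "plasmid" (case-insensitive) are removed, so that only
#'   chromosomal records are analyzed.
#' @return Named character vector of uppercase DNA strings.
#' @export
read_fasta <- function(path, drop_plasmids = FALSE) {
  x <- Biostrings::readDNAStringSet(path)
  if (drop_plasmids) x <- x[!grepl("plasmid", names(x), ignore.case = TRUE)]
  if (length(x) == 0L) stop("no usable records in ", path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of DNA strings.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Write / read signature tables
#'
#' `write_signature_tsv` writes one signature as a two-column (word,
#' percent) table. `write_signatures_tsv` writes several signatures of a
#' common word length as a wide table (one row per signature, one column
#' per word, preceded by `label` and `n_windows`); `read_signatures_tsv`
#' reads that wide format back.
#'
#' @param sig An `oligo_signature`.
#' @param sigs List of `oligo_signature` of equal `k`.
#' @param path Output path.
#' @param header_lines Optional character vector of `#`-prefixed metadata
#'   lines written before the table.
#' @return The path (writers) or a list of signatures (reader), invisibly
#'   for writers.
#' @export
write_signature_tsv <- function(sig, path, header_lines = character()) {
  stopifnot(inherits(sig, "oligo_signature"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste("word", "percent", sep = "\t"), con)
  writeLines(paste(kmer_words(sig$k), sprintf("%.10g", sig$pct), sep = "\t"),
             con)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
write_signatures_tsv <- function(sigs, path, header_lines = character()) {
  ks <- unique(vapply(sigs, `[[`, integer(1), "k"))
  if (length(ks) != 1L) stop("all signatures must share the same k")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines(paste(c("label", "n_windows", kmer_words(ks)), collapse = "\t"),
             con)
  for (s in sigs)
    writeLines(paste(c(s$label, sprintf("%.10g", s$n_windows),
                       sprintf("%.10g", s$pct)), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_signature_tsv
#' @export
read_signatures_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  hdr <- fields[[1]]
  words <- hdr[-(1:2)]
  k <- unique(nchar(words))
  if (length(k) != 1L || hdr[1] != "label")
    stop("not a signature table: ", path)
  out <- lapply(fields[-1], function(f) {
    new_signature(as.numeric(f[-(1:2)]), k = k, label = f[1],
                  n_windows = as.numeric(f[2]))
  })
  names(out) <- vapply(out, `[[`, character(1), "label")
  out
}
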