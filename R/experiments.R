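# Evaluation experiments: leave-one-out histograms, fragment and chunk
# experiments, best-hit binning, identity/distance scatter data.

#' Leave-one-out distance histogram
#'
#' Bins the genus-normalized Euclidean distances of all distinct unordered
#' organism pairs into `n_bins` equal-width bins spanning `[0, max
#' observed distance]`, and tabulates the highest shared taxonomic level of
#' the pairs in each bin. The per-bin proportions estimate the probability
#' that a given distance implies a given shared rank.
#'
#' @param m A genus-normalized `oligo_distmat` (see [genus_normalize()]).
#' @param tax Taxonomy data frame covering all labels.
#' @param n_bins Number of equal-width bins (default 30).
#' @return An object of class `loo_histogram`: list with `breaks` (length
#'   `n_bins + 1`), `counts` (`n_bins` x 7 matrix by comparison level),
#'   `proportions` (row-normalized; `NA` rows for empty bins) and
#'   `n_pairs`.
#' @export
leave_one_out_histogram <- function(m, tax, n_bins = 30) {
  if (!isTRUE(attr(m, "normalized")))
    stop("leave_one_out_histogram expects a genus-normalized matrix")
  if (n_bins < 1) stop("n_bins must be >= 1")
  labels <- rownames(m)
  if (length(labels) < 2L) stop("need at least 2 organisms")
  iu <- which(upper.tri(m), arr.ind = TRUE)
  d <- unclass(m)[iu]
  lv <- shared_levels(tax, labels[iu[, 1]], labels[iu[, 2]])
  top <- max(d)
  breaks <- seq(0, if (top > 0) top else 1, length.out = n_bins + 1)
  bin <- findInterval(d, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- table(factor(bin, levels = seq_len(n_bins)), lv)
  counts <- matrix(as.integer(counts), nrow = n_bins,
                   dimnames = list(NULL, rank_levels()))
  rs <- rowSums(counts)
  proportions <- counts / ifelse(rs > 0, rs, NA_real_)
  structure(list(breaks = breaks, counts = counts,
                 proportions = proportions, n_pairs = length(d)),
            class = "loo_histogram")
}

#' @export
print.loo_histogram <- function(x, ...) {
  cat("<loo_histogram>", nrow(x$counts), "bins |", x$n_pairs,
      "distinct pairs | range [0,", signif(max(x$breaks), 4), "]\n")
  invisible(x)
}

#' Write a leave-one-out histogram as long TSV
#'
#' @param h A `loo_histogram`.
#' @param path File path.
#' @param header_lines Optional `#`-prefixed metadata lines.
#' @return The path, invisibly.
#' @export
write_loo_tsv <- function(h, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines("bin\tbin_low\tbin_high\tlevel\tcount\tproportion", con)
  for (b in seq_len(nrow(h$counts)))
    writeLines(paste(b, .fmt_num(h$breaks[b]), .fmt_num(h$breaks[b + 1]),
                     colnames(h$counts), h$counts[b, ],
                     .fmt_num(h$proportions[b, ]), sep = "\t"), con)
  invisible(path)
}

#' Sample one random contiguous fragment
#'
#' @param seq A DNA string.
#' @param length Fragment length (1 to `nchar(seq)`).
#' @param seed Optional RNG seed.
#' @return The fragment string; the 1-based start offset is attached as
#'   attribute `start`.
#' @export
sample_fragment <- function(seq, length, seed = NULL) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (length < 1) stop("fragment length must be >= 1")
  if (length > L)
    stop("fragment length ", length, " exceeds sequence length ", L)
  .with_seed(seed, {
    start <- sample.int(L - length + 1L, 1L)
    out <- substr(seq, start, start + length - 1L)
    attr(out, "start") <- start
    out
  })
}

#' Fragment nearest-neighbor experiment
#'
#' Replicates the fragment-length evaluation: for each fragment length, one
#' random fragment is drawn per genome, signatures are computed for each
#' requested word length, an all-vs-all matrix and NJ cladogram are built,
#' and the percentage of fragments whose nearest neighbor on the cladogram
#' shares the genus is recorded. Results are averaged over replicates.
#'
#' @param genomes Named character vector of genome sequences.
#' @param tax Taxonomy data frame covering the genome names.
#' @param lengths Fragment lengths in bp (default: the metagenomically
#'   relevant set 1,000-50,000).
#' @param ks Word lengths (default tetra- and heptanucleotide).
#' @param replicates Independent repeats per length (default 1).
#' @param seed Optional RNG seed for the whole experiment.
#' @return An object of class `fragment_experiment`: list with `results`
#'   (per replicate: `fragment_length`, `k`, `replicate`,
#'   `same_genus_pct`) and `summary` (replicate means).
#' @export
fragment_nn_experiment <- function(genomes, tax,
                                   lengths = c(1000, 2500, 5000, 10000,
                                               15000, 25000, 50000),
                                   ks = c(4, 7), replicates = 1,
                                   seed = NULL) {
  genomes <- setNames(as.character(genomes), names(genomes))
  rows <- list()
  .with_seed(seed, {
    for (rep in seq_len(replicates)) {
      for (l in lengths) {
        usable <- nchar(genomes) >= l
        if (sum(usable) < 2L)
          stop("fewer than 2 genomes of length >= ", l)
        if (any(!usable))
          warning(sum(!usable), " genome(s) shorter than ", l, " bp skipped")
        frags <- vapply(genomes[usable], sample_fragment, character(1),
                        length = l)
        for (k in ks) {
          sigs <- signatures_per_record(frags, k)
          tree <- neighbor_joining(all_pairs_matrix(sigs))
          ag <- taxonomic_agreement_profile(leaf_nearest_neighbors(tree), tax)
          rows[[length(rows) + 1L]] <- data.frame(
            fragment_length = l, k = k, replicate = rep,
            same_genus_pct = same_genus_pct(ag))
        }
      }
    }
  })
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(same_genus_pct ~ fragment_length + k,
                              data = results, FUN = mean)
  summary <- summary[order(summary$k, summary$fragment_length), ]
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary, lengths = lengths,
                 ks = ks, replicates = replicates, seed = seed),
            class = "fragment_experiment")
}

#' @export
print.fragment_experiment <- function(x, ...) {
  cat("<fragment_experiment>", x$replicates, "replicate(s)\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# break one sequence into non-overlapping chunks, trailing remainder dropped
.chunk_seq <- function(seq, len) {
  L <- nchar(seq)
  starts <- seq.int(1L, L - len + 1L, by = len)
  substring(seq, starts, starts + len - 1L)
}

#' Mean chunk-to-chunk distance profiles
#'
#' Breaks each genome into non-overlapping consecutive chunks of each
#' requested length (trailing remainder discarded) and reports, for every
#' organism pair including self-comparisons, the mean Euclidean distance
#' over all ordered chunk pairs. Self-comparison means include the zero
#' same-chunk diagonal, so a genome whose chunk is its whole sequence has
#' mean self-distance 0.
#'
#' @param genomes Named character vector of genome sequences.
#' @param chunk_lengths Chunk lengths in bp (default 500-50,000).
#' @param k Word length.
#' @param pairs `"all"` for every organism pair, `"self"` for
#'   self-comparisons only.
#' @return Data frame with `label_a`, `label_b`, `chunk_length`,
#'   `mean_distance`, `n_chunk_pairs`.
#' @export
chunk_distance_profile <- function(genomes,
                                   chunk_lengths = c(500, 1000, 2500, 5000,
                                                     10000, 15000, 20000,
                                                     50000),
                                   k = 4, pairs = c("all", "self")) {
  pairs <- match.arg(pairs)
  genomes <- setNames(as.character(genomes), names(genomes))
  nms <- names(genomes)
  rows <- list()
  for (len in chunk_lengths) {
    usable <- nchar(genomes) >= len
    if (any(!usable))
      warning(sum(!usable), " genome(s) shorter than ", len, " bp skipped")
    P <- lapply(genomes[usable], function(g) {
      sigs <- lapply(.chunk_seq(g, len), count_words, k = k)
      do.call(rbind, lapply(sigs, function(cw) {
        if (cw$n_windows == 0) stop("chunk with no valid windows")
        100 * as.numeric(cw$counts) / cw$n_windows
      }))
    })
    use_nms <- nms[usable]
    for (ai in seq_along(use_nms)) {
      bis <- if (pairs == "self") ai else seq.int(ai, length(use_nms))
      for (bi in bis) {
        if (ai == bi) {
          D <- as.matrix(dist(P[[ai]]))
          md <- mean(D)            # ordered pairs incl. zero diagonal
          np <- length(D)
        } else {
          na <- nrow(P[[ai]])
          D <- as.matrix(dist(rbind(P[[ai]], P[[bi]])))
          blk <- D[seq_len(na), -seq_len(na), drop = FALSE]
          md <- mean(blk)
          np <- length(blk)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          label_a = use_nms[ai], label_b = use_nms[bi], chunk_length = len,
          mean_distance = md, n_chunk_pairs = np, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Best-hit composition binning
#'
#' Assigns each query signature to the reference signature with the lowest
#' Euclidean distance (ties broken by lexicographically smaller reference
#' label) and, when truth labels are supplied, reports the percentage of
#' queries whose assigned reference label matches the truth.
#'
#' @param queries,refs Lists of `oligo_signature` of a common word length;
#'   `refs` must be non-empty with unique labels.
#' @param truth_labels Optional character vector of correct reference
#'   labels, one per query (or named by query label).
#' @return List with `assignments` (data frame: `query`, `assigned`,
#'   `distance`, plus `truth` and `correct` when truth is given) and
#'   `agreement_pct` (`NA` without truth).
#' @export
best_hit_binning <- function(queries, refs, truth_labels = NULL) {
  if (length(refs) == 0L) stop("reference signature set is empty")
  if (length(queries) == 0L) stop("query signature set is empty")
  ks <- unique(vapply(c(queries, refs), `[[`, integer(1), "k"))
  if (length(ks) != 1L) stop("queries and references must share one k")
  rlab <- vapply(refs, `[[`, character(1), "label")
  if (anyDuplicated(rlab)) stop("reference labels must be unique")
  ord <- order(rlab)                       # ties -> lexicographic label
  refs <- refs[ord]; rlab <- rlab[ord]
  R <- do.call(rbind, lapply(refs, `[[`, "pct"))
  qlab <- vapply(queries, `[[`, character(1), "label")
  assigned <- character(length(queries))
  dmin <- numeric(length(queries))
  for (i in seq_along(queries)) {
    dd <- sqrt(colSums((t(R) - queries[[i]]$pct)^2))
    j <- which.min(dd)
    assigned[i] <- rlab[j]
    dmin[i] <- dd[j]
  }
  assignments <- data.frame(query = qlab, assigned = assigned,
                            distance = dmin, stringsAsFactors = FALSE)
  agreement <- NA_real_
  if (!is.null(truth_labels)) {
    truth <- if (!is.null(names(truth_labels))) {
      unname(truth_labels[qlab])
    } else rep_len(truth_labels, length(qlab))
    assignments$truth <- truth
    assignments$correct <- assignments$assigned == truth
    agreement <- 100 * mean(assignments$correct)
  }
  list(assignments = assignments, agreement_pct = agreement)
}

#' Percent identity of two aligned sequences
#'
#' Column identity over an existing alignment: columns where either
#' sequence has a gap (`-` or `.`) are excluded; identity is
#' `100 * matches / comparable columns`, case-insensitive.
#'
#' @param a,b Aligned sequences of equal length (strings).
#' @return Percentage in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  a <- strsplit(toupper(as.character(a)), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(as.character(b)), "", fixed = TRUE)[[1]]
  if (length(a) != length(b))
    stop("aligned sequences must have equal length")
  gap <- c("-", ".")
  ok <- !(a %in% gap | b %in% gap)
  if (!any(ok)) stop("no comparable columns (all gapped)")
  100 * mean(a[ok] == b[ok])
}

#' Identity vs. signature distance scatter data
#'
#' For every unordered distinct pair of organisms present both in a
#' pre-aligned marker-gene alignment and a signature distance matrix,
#' emits `(label_a, label_b, identity_pct, distance, shared_level)` —
#' the data behind identity/distance scatter plots.
#'
#' @param alignment Named character vector of pre-aligned sequences
#'   (equal lengths, gaps as `-` or `.`).
#' @param m An `oligo_distmat` (typically genus-normalized).
#' @param tax Taxonomy data frame.
#' @return Data frame, one row per pair.
#' @export
identity_distance_scatter <- function(alignment, m, tax) {
  common <- intersect(names(alignment), rownames(m))
  if (length(common) < 2L)
    stop("need at least 2 organisms present in both alignment and matrix")
  pr <- utils::combn(common, 2)
  ident <- vapply(seq_len(ncol(pr)), function(j)
    percent_identity(alignment[[pr[1, j]]], alignment[[pr[2, j]]]),
    numeric(1))
  data.frame(label_a = pr[1, ], label_b = pr[2, ],
             identity_pct = ident,
             distance = unclass(m)[cbind(pr[1, ], pr[2, ])],
             shared_level = as.character(shared_levels(tax, pr[1, ], pr[2, ])),
             stringsAsFactors = FALSE)
}
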