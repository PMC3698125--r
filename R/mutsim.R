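# Random-mutation divergence experiment: how fast signatures drift away
# from an original sequence under iterative single-base substitution.

#' Generate a uniform random DNA sequence
#'
#' Bases drawn i.i.d. uniformly over {A,C,G,T}. The experiment's reference
#' scale is a one million base pair sequence.
#'
#' @param length Sequence length (>= 1); default 1e6.
#' @param seed Optional RNG seed.
#' @return A single DNA string.
#' @export
random_dna <- function(length = 1e6, seed = NULL) {
  if (length < 1) stop("length must be >= 1")
  .with_seed(seed, paste(sample(BASES, length, replace = TRUE),
                         collapse = ""))
}

#' Iterative point-mutation trajectory
#'
#' Applies `n_iter` single-base substitutions to a sequence: each
#' iteration picks a uniform position and replaces it with a base drawn
#' uniformly from all four (so one quarter of mutations are silent,
#' matching the literal "mutated to a randomly selected base";
#' `exclude_same = TRUE` restricts to the three differing bases). Word
#' counts are updated incrementally — only the at most `k` windows
#' overlapping the mutated position are adjusted per word length — and the
#' percent-scale Euclidean distance to the original signature is recorded
#' at iteration 0 and every `snapshot_every` iterations.
#'
#' @param seq Unambiguous DNA string (A/C/G/T only).
#' @param n_iter Number of mutation iterations; default 1e6.
#' @param snapshot_every Snapshot cadence in iterations; default 100.
#' @param ks Word lengths to track (subset of 1-9); default `c(4, 7)`.
#' @param seed Optional RNG seed.
#' @param exclude_same If `TRUE`, the replacement base always differs from
#'   the current one.
#' @param record_counts Keep a copy of the full count vectors at every
#'   snapshot (memory-guarded; intended for small validation runs).
#' @return An object of class `mutation_trajectory`: list with
#'   `iterations`, `distance` (snapshots x `length(ks)` matrix, columns
#'   `k<k>`), `ks`, `seq_length`, `snapshot_every`, `seed`,
#'   `final_sequence`, `final_counts` (list of `kmer_counts`) and
#'   optionally `counts_snapshots`.
#' @export
mutation_trajectory <- function(seq, n_iter = 1e6, snapshot_every = 100,
                                ks = c(4, 7), seed = NULL,
                                exclude_same = FALSE,
                                record_counts = FALSE) {
  seq <- as.character(seq)
  if (grepl("[^ACGTacgt]", seq))
    stop("sequence must contain only A, C, G, T")
  ks <- vapply(ks, .check_k, integer(1))
  if (anyDuplicated(ks)) stop("duplicate word lengths in ks")
  if (nchar(seq) < max(ks)) stop("sequence shorter than max(ks)")
  if (n_iter < 0) stop("n_iter must be >= 0")
  if (snapshot_every < 1) stop("snapshot_every must be >= 1")
  n_snap <- floor(n_iter / snapshot_every) + 1
  if (record_counts && n_snap * sum(4^ks) > 5e7)
    stop("record_counts = TRUE would store too much; use a smaller run")
  res <- .with_seed(seed, {
    if (exclude_same) {
      .mut_traj_r(seq, n_iter, snapshot_every, ks, record_counts)
    } else {
      mutation_trajectory_cpp(seq, n_iter, snapshot_every, ks, record_counts)
    }
  })
  dist <- res$distance
  colnames(dist) <- paste0("k", ks)
  fc <- lapply(seq_along(ks), function(t) {
    cv <- res$final_counts[[t]]
    nw <- attr(cv, "n_windows")
    attr(cv, "n_windows") <- NULL
    structure(list(k = ks[t], counts = cv, n_windows = nw),
              class = "kmer_counts")
  })
  names(fc) <- paste0("k", ks)
  out <- list(iterations = as.numeric(res$iterations), distance = dist,
              ks = ks, seq_length = nchar(seq),
              snapshot_every = snapshot_every, seed = seed,
              final_sequence = res$final_sequence, final_counts = fc)
  if (record_counts) out$counts_snapshots <- res$counts_snapshots
  structure(out, class = "mutation_trajectory")
}

# reference implementation used when the replacement base must differ from
# the current one; full recount per snapshot, so only suited to small runs
.mut_traj_r <- function(seq, n_iter, snapshot_every, ks, record_counts) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  orig <- lapply(ks, function(k) count_words(seq, k))
  n_snap <- floor(n_iter / snapshot_every) + 1
  dist <- matrix(0, n_snap, length(ks))
  iters <- numeric(n_snap)
  counts_snapshots <- if (record_counts) vector("list", n_snap) else NULL
  snap <- function(row, it) {
    cur <- paste(chars, collapse = "")
    cc <- lapply(ks, function(k) count_words(cur, k))
    iters[row] <<- it
    dist[row, ] <<- vapply(seq_along(ks), function(t)
      100 * sqrt(sum((cc[[t]]$counts - orig[[t]]$counts)^2)) /
        orig[[t]]$n_windows, numeric(1))
    if (record_counts)
      counts_snapshots[[row]] <<- lapply(cc, `[[`, "counts")
    cc
  }
  cc <- snap(1, 0)
  row <- 1
  if (n_iter >= 1) for (it in seq_len(n_iter)) {
    pos <- sample.int(length(chars), 1L)
    cc_new <- sample(setdiff(BASES, chars[pos]), 1L)
    chars[pos] <- cc_new
    if (it %% snapshot_every == 0) {
      row <- row + 1
      cc <- snap(row, it)
    }
  }
  final <- paste(chars, collapse = "")
  fc <- lapply(seq_along(ks), function(t) {
    cw <- count_words(final, ks[t])
    cv <- cw$counts
    attr(cv, "n_windows") <- cw$n_windows
    cv
  })
  list(iterations = iters, distance = dist, final_sequence = final,
       final_counts = fc, counts_snapshots = counts_snapshots)
}

#' @export
print.mutation_trajectory <- function(x, ...) {
  cat("<mutation_trajectory>", x$seq_length, "bp |",
      max(x$iterations), "iterations | snapshots every", x$snapshot_every,
      "| k =", paste(x$ks, collapse = ","), "\n")
  invisible(x)
}

#' Plateau (saturation) onset of a mutation trajectory
#'
#' Operationalizes "saturation": the first snapshot iteration after which
#' every later distance stays within a relative tolerance of the final
#' snapshot's distance.
#'
#' @param traj A `mutation_trajectory` with at least 2 snapshots.
#' @param k Word length to inspect (must be in `traj$ks`).
#' @param tol Relative tolerance band around the final distance
#'   (default 0.02).
#' @return The onset iteration number.
#' @export
plateau_onset <- function(traj, k, tol = 0.02) {
  stopifnot(inherits(traj, "mutation_trajectory"))
  t <- match(k, traj$ks)
  if (is.na(t)) stop("k = ", k, " not tracked in this trajectory")
  d <- traj$distance[, t]
  if (length(d) < 2L) stop("need at least 2 snapshots")
  final <- d[length(d)]
  ok <- abs(d - final) <= tol * abs(final)
  bad <- which(!ok)
  j <- if (length(bad)) max(bad) + 1L else 1L
  traj$iterations[j]
}

#' Write a mutation trajectory as long TSV
#'
#' @param traj A `mutation_trajectory`.
#' @param path File path.
#' @param header_lines Optional `#`-prefixed metadata lines.
#' @return The path, invisibly.
#' @export
write_trajectory_tsv <- function(traj, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines("iteration\tk\tdistance", con)
  for (t in seq_along(traj$ks))
    writeLines(paste(.fmt_num(traj$iterations), traj$ks[t],
                     .fmt_num(traj$distance[, t]), sep = "\t"), con)
  invisible(path)
}
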