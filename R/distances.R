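# Euclidean distances between signatures; matrices; genus normalization.

new_distmat <- function(d, k = NA_integer_, normalized = FALSE,
                        normalization_factor = NA_real_) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d))
  structure(d, k = k, normalized = normalized,
            normalization_factor = normalization_factor,
            class = c("oligo_distmat", class(matrix())))
}

#' @export
print.oligo_distmat <- function(x, ...) {
  cat("<oligo_distmat>", nrow(x), "x", ncol(x), "| k =", attr(x, "k"),
      if (isTRUE(attr(x, "normalized")))
        paste("| genus-normalized, factor =",
              signif(attr(x, "normalization_factor"), 6)) else "", "\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

#' Euclidean distance between two signatures
#'
#' The distance between signatures p and q is
#' `sqrt(sum_i (p_i - q_i)^2)` over all `4^k` percentage bins.
#'
#' @param p,q `oligo_signature` objects of equal word length.
#' @return Non-negative distance on the percent scale.
#' @export
euclidean_distance <- function(p, q) {
  stopifnot(inherits(p, "oligo_signature"), inherits(q, "oligo_signature"))
  if (p$k != q$k)
    stop("mismatched word length k: ", p$k, " vs ", q$k)
  sqrt(sum((p$pct - q$pct)^2))
}

#' All-vs-all Euclidean distance matrix
#'
#' Builds a symmetric distance matrix over a set of signatures sharing a
#' word length. The enumerated comparison stream used downstream for
#' scatter plots and histograms is all ordered pairs including
#' self-comparisons (`N^2` points); see [comparison_pairs()].
#'
#' @param sigs List of at least two `oligo_signature` objects with unique
#'   labels and a common `k`.
#' @return An `oligo_distmat`: square symmetric matrix with labels as
#'   dimnames, zero diagonal, and attributes `k`, `normalized`,
#'   `normalization_factor`.
#' @export
all_pairs_matrix <- function(sigs) {
  if (length(sigs) < 2L) stop("need at least 2 signatures")
  ks <- unique(vapply(sigs, `[[`, integer(1), "k"))
  if (length(ks) != 1L)
    stop("mixed word lengths in signature set: ", paste(ks, collapse = ", "))
  labels <- vapply(sigs, `[[`, character(1), "label")
  if (anyDuplicated(labels))
    stop("signature labels must be unique: ",
         labels[duplicated(labels)][1], " repeats")
  P <- do.call(rbind, lapply(sigs, `[[`, "pct"))
  d <- as.matrix(dist(P))
  dimnames(d) <- list(labels, labels)
  diag(d) <- 0
  new_distmat(d, k = ks)
}

#' Enumerate the pairwise comparison stream of a distance matrix
#'
#' @param m An `oligo_distmat`.
#' @param include_self Keep self-comparisons (default `TRUE`: `N^2` ordered
#'   pairs, the stream behind all-vs-all scatter data).
#' @return A data frame with columns `label_a`, `label_b`, `distance`.
#' @export
comparison_pairs <- function(m, include_self = TRUE) {
  labels <- rownames(m)
  n <- length(labels)
  out <- data.frame(label_a = rep(labels, times = n),
                    label_b = rep(labels, each = n),
                    distance = as.vector(unclass(m)),
                    stringsAsFactors = FALSE)
  if (!include_self) out <- out[out$label_a != out$label_b, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genus-normalize a distance matrix
#'
#' Divides every entry by the largest Euclidean distance observed between
#' two distinct organisms sharing a genus (same-species pairs count as
#' same-genus). The factor corrects for the shrinking of raw distances at
#' longer word lengths and is recorded in the result's
#' `normalization_factor` attribute; the maximal same-genus pair maps to
#' exactly 1.0.
#'
#' @param m An `oligo_distmat` whose labels appear in `tax`.
#' @param tax Taxonomy data frame (see [read_taxonomy()]).
#' @return A normalized `oligo_distmat`.
#' @export
genus_normalize <- function(m, tax) {
  labels <- rownames(m)
  iu <- which(upper.tri(m), arr.ind = TRUE)
  lv <- shared_levels(tax, labels[iu[, 1]], labels[iu[, 2]])
  same_genus <- lv %in% c("species", "genus")
  if (!any(same_genus))
    stop("genus normalization undefined: no pair of distinct organisms ",
         "shares a genus")
  f <- max(unclass(m)[iu[same_genus, , drop = FALSE]])
  if (f <= 0)
    stop("genus normalization undefined: all same-genus distances are zero")
  new_distmat(unclass(m) / f, k = attr(m, "k"), normalized = TRUE,
              normalization_factor = f)
}

.fmt_num <- function(x) sprintf("%.12g", x)

#' Write / read PHYLIP square distance matrices
#'
#' Writes the full (lower + upper) square matrix. Labels of at most 10
#' characters are space-padded to the classic fixed width of 10; longer
#' labels fall back to relaxed PHYLIP (label followed by two spaces). The
#' reader tokenizes on whitespace and accepts both layouts, which means
#' labels must not contain spaces.
#'
#' @param m An `oligo_distmat`.
#' @param path File path.
#' @return The path (writer, invisibly) or an `oligo_distmat` (reader).
#' @export
write_phylip_distmat <- function(m, path) {
  labels <- rownames(m)
  if (any(grepl("\\s", labels))) stop("PHYLIP labels must not contain spaces")
  strict <- all(nchar(labels) <= 10L)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(m)), con)
  for (i in seq_len(nrow(m))) {
    lab <- if (strict) formatC(labels[i], width = -10L)
           else paste0(labels[i], "  ")
    writeLines(paste0(lab, paste(.fmt_num(unclass(m)[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}

#' @rdname write_phylip_distmat
#' @export
read_phylip_distmat <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || length(lines) != n + 1L)
    stop("malformed PHYLIP distance matrix: ", path)
  labels <- character(n)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    toks <- strsplit(trimws(lines[i + 1L]), "\\s+")[[1]]
    if (length(toks) != n + 1L)
      stop("malformed PHYLIP row ", i, " in ", path)
    labels[i] <- toks[1]
    d[i, ] <- as.numeric(toks[-1])
  }
  dimnames(d) <- list(labels, labels)
  new_distmat(d)
}

#' Write a distance matrix as a long TSV
#'
#' One `(label_a, label_b, distance)` row per ordered pair.
#'
#' @param m An `oligo_distmat`.
#' @param path File path.
#' @param header_lines Optional `#`-prefixed metadata lines.
#' @param include_self Keep self-comparisons.
#' @return The path, invisibly.
#' @export
write_distmat_tsv <- function(m, path, header_lines = character(),
                              include_self = TRUE) {
  df <- comparison_pairs(m, include_self = include_self)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines("label_a\tlabel_b\tdistance", con)
  writeLines(paste(df$label_a, df$label_b, .fmt_num(df$distance), sep = "\t"),
             con)
  invisible(path)
}
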