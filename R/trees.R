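# Neighbor-joining cladograms and nearest-neighbor taxonomic agreement.

.nwk_label <- function(x) {
  bad <- grepl("[ ():,;'\\[\\]]", x)
  x[bad] <- paste0("'", gsub("'", "''", x[bad]), "'")
  x
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Saitou-Nei neighbor joining with Studier-Keppler Q-criterion
#' updates: iteratively join the active pair minimizing
#' `Q(i,j) = (r-2) d(i,j) - R_i - R_j`, compute the two branch lengths from
#' the three-point formulas, and reduce the matrix, finishing with an
#' unrooted trifurcation (or a single edge for two leaves, represented as a
#' degree-2 root with two half-length branches). Ties in Q are broken
#' deterministically by the first minimal pair in row-major order.
#' Negative branch lengths, which NJ can produce on non-additive input, are
#' kept in the tree; path-based operations clamp them to zero.
#'
#' @param m A symmetric `oligo_distmat` (or plain labeled matrix) with at
#'   least two labels.
#' @return An unrooted `ape::phylo` tree with branch lengths in the units
#'   of the input matrix.
#' @export
neighbor_joining <- function(m) {
  d <- unclass(m)
  storage.mode(d) <- "double"
  labels <- rownames(d)
  n <- nrow(d)
  if (is.null(labels) || n < 2L) stop("need a labeled matrix with >= 2 rows")
  if (max(abs(d - t(d))) > 1e-8 * max(1, max(abs(d))))
    stop("distance matrix must be symmetric")
  nwk <- .nwk_label(labels)
  if (n == 2L) {
    txt <- sprintf("(%s:%s,%s:%s);", nwk[1], .fmt_num(d[1, 2] / 2),
                   nwk[2], .fmt_num(d[1, 2] / 2))
    return(ape::read.tree(text = txt))
  }
  while (nrow(d) > 3L) {
    r <- nrow(d)
    Rsum <- rowSums(d)
    Q <- (r - 2) * d - outer(Rsum, Rsum, `+`)
    diag(Q) <- Inf
    cand <- which(Q == min(Q), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]
    bi <- d[i, j] / 2 + (Rsum[i] - Rsum[j]) / (2 * (r - 2))
    bj <- d[i, j] - bi
    newd <- (d[i, ] + d[j, ] - d[i, j]) / 2
    nwk[i] <- sprintf("(%s:%s,%s:%s)", nwk[i], .fmt_num(bi),
                      nwk[j], .fmt_num(bj))
    d[i, ] <- newd; d[, i] <- newd; d[i, i] <- 0
    d <- d[-j, -j, drop = FALSE]
    nwk <- nwk[-j]
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], .fmt_num(la),
                 nwk[2], .fmt_num(lb), nwk[3], .fmt_num(lc))
  ape::read.tree(text = txt)
}

#' Leaf-to-leaf path distances on a tree
#'
#' Sums branch lengths along the path between every pair of leaves.
#' Negative branch lengths (possible under NJ) are clamped to zero for
#' path purposes so that nearest neighbors stay well-defined.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return Symmetric matrix of path distances, leaf labels as dimnames.
#' @export
leaf_path_distances <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree$edge.length <- pmax(tree$edge.length, 0)
  stats::cophenetic(tree)
}

#' Nearest neighbor of every leaf
#'
#' For each leaf, the other leaf with minimal branch-length path distance;
#' exact ties are broken by the lexicographically smaller label.
#'
#' @param tree An `ape::phylo` tree with >= 2 leaves.
#' @return Named character vector: `nn[leaf]` is the nearest leaf label.
#' @export
leaf_nearest_neighbors <- function(tree) {
  pd <- leaf_path_distances(tree)
  if (nrow(pd) < 2L) stop("need at least 2 leaves")
  ord <- order(colnames(pd))
  pd <- pd[, ord, drop = FALSE]
  out <- character(nrow(pd))
  for (i in seq_len(nrow(pd))) {
    row <- pd[i, ]
    row[colnames(pd) == rownames(pd)[i]] <- Inf
    out[i] <- colnames(pd)[which.min(row)]   # columns sorted: ties -> smaller
  }
  names(out) <- rownames(pd)
  out
}

#' Taxonomic agreement profile of a nearest-neighbor map
#'
#' For each rank from species to domain, the percentage of leaves whose
#' nearest neighbor shares that rank or a more specific one (cumulative, so
#' the value at phylum means "phylum or better"). Also emits the four-way
#' cladogram coloring classes: `strong` (same species or genus), `good`
#' (family, order or phylum), `same_domain`, and `different_domain`.
#'
#' @param nn Named character vector from [leaf_nearest_neighbors()].
#' @param tax Taxonomy data frame covering every leaf.
#' @return A list of class `nn_agreement` with `profile` (data frame:
#'   `rank`, `percent`, `n`), `leaf_level` (factor per leaf) and
#'   `leaf_class` (character per leaf).
#' @export
taxonomic_agreement_profile <- function(nn, tax) {
  leaves <- names(nn)
  missing <- setdiff(unique(c(leaves, nn)), tax$organism_id)
  if (length(missing))
    stop("leaf missing from taxonomy: ", missing[1])
  lv <- shared_levels(tax, leaves, unname(nn))
  names(lv) <- leaves
  idx <- as.integer(lv)
  profile <- data.frame(
    rank = TAX_RANKS,
    percent = vapply(seq_along(TAX_RANKS),
                     function(j) 100 * mean(idx <= j), numeric(1)),
    n = vapply(seq_along(TAX_RANKS), function(j) sum(idx <= j), integer(1)),
    stringsAsFactors = FALSE)
  cls <- c(species = "strong", genus = "strong", family = "good",
           order = "good", phylum = "good", domain = "same_domain",
           different_domain = "different_domain")[as.character(lv)]
  names(cls) <- leaves
  structure(list(profile = profile, leaf_level = lv, leaf_class = cls),
            class = "nn_agreement")
}

#' @export
print.nn_agreement <- function(x, ...) {
  cat("<nn_agreement>", length(x$leaf_level), "leaves\n")
  print(x$profile, row.names = FALSE)
  invisible(x)
}

#' Same-genus nearest-neighbor percentage
#'
#' Convenience accessor: percentage of leaves whose nearest neighbor shares
#' the genus (or species) — the statistic tracked across word lengths and
#' fragment lengths.
#'
#' @param agreement An `nn_agreement` object.
#' @return A single percentage in `[0, 100]`.
#' @export
same_genus_pct <- function(agreement) {
  stopifnot(inherits(agreement, "nn_agreement"))
  agreement$profile$percent[agreement$profile$rank == "genus"]
}

#' Write an agreement profile as TSV
#'
#' @param agreement An `nn_agreement` object.
#' @param path File path.
#' @param header_lines Optional `#`-prefixed metadata lines.
#' @return The path, invisibly.
#' @export
write_agreement_tsv <- function(agreement, path, header_lines = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header_lines, con)
  writeLines("rank\tpercent\tn", con)
  p <- agreement$profile
  writeLines(paste(p$rank, .fmt_num(p$percent), p$n, sep = "\t"), con)
  invisible(path)
}
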