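# Six-rank taxonomy tables and shared-rank queries.

TAX_RANKS <- c("species", "genus", "family", "order", "phylum", "domain")

#' Ordered taxonomic comparison levels
#'
#' Levels at which two organisms can agree, from most specific
#' (`species`) to least (`domain`), plus `different_domain` for pairs whose
#' domains disagree.
#'
#' @return Character vector of the seven levels, most specific first.
#' @export
rank_levels <- function() c(TAX_RANKS, "different_domain")

#' Read a six-rank taxonomy table
#'
#' Parses a tab-delimited table with seven columns: organism id followed by
#' species, genus, family, order, phylum and domain. A header line is
#' detected by a literal `organism_id` first cell.
#'
#' @param path Path to a UTF-8 tab-delimited file.
#' @return A `data.frame` with columns `organism_id`, `species`, `genus`,
#'   `family`, `order`, `phylum`, `domain`, one row per organism.
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("taxonomy file is empty: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- if (trimws(fields[[1]][1]) == "organism_id") 2L else 1L
  rows <- vector("list", length(fields) - start + 1L)
  for (i in seq.int(start, length(fields))) {
    f <- fields[[i]]
    if (length(f) != 7L)
      stop("taxonomy parse error at line ", i, ": expected 7 tab-delimited ",
           "columns, found ", length(f))
    rows[[i - start + 1L]] <- trimws(f)
  }
  m <- do.call(rbind, rows)
  tax <- data.frame(m, stringsAsFactors = FALSE)
  names(tax) <- c("organism_id", TAX_RANKS)
  validate_taxonomy(tax)
}

#' Validate a taxonomy data frame
#'
#' Checks the seven required columns, non-empty rank strings and unique
#' organism ids.
#'
#' @param tax A data frame with columns `organism_id` plus the six ranks.
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_taxonomy <- function(tax) {
  need <- c("organism_id", TAX_RANKS)
  miss <- setdiff(need, names(tax))
  if (length(miss))
    stop("taxonomy table is missing column(s): ", paste(miss, collapse = ", "))
  dup <- tax$organism_id[duplicated(tax$organism_id)]
  if (length(dup))
    stop("duplicate organism_id in taxonomy table: ",
         paste(unique(dup), collapse = ", "))
  for (r in need) {
    bad <- which(!nzchar(trimws(tax[[r]])))
    if (length(bad))
      stop("empty '", r, "' value in taxonomy row ", bad[1])
  }
  tax[need]
}

.norm_rank <- function(x) tolower(trimws(x))

# core shared-level computation on two n x 6 rank matrices (species..domain)
.shared_level_core <- function(ra, rb) {
  eq <- matrix(.norm_rank(ra) == .norm_rank(rb), ncol = length(TAX_RANKS))
  # suffix conjunction: level j agrees only if ranks j..domain all agree
  for (j in rev(seq_len(ncol(eq) - 1L))) eq[, j] <- eq[, j] & eq[, j + 1L]
  lvl <- ifelse(eq[, ncol(eq)], max.col(eq, ties.method = "first"),
                length(TAX_RANKS) + 1L)
  factor(rank_levels()[lvl], levels = rank_levels())
}

#' Most specific shared taxonomic level of two records
#'
#' Returns the most specific rank at which all ranks from that level upward
#' agree (exact string equality after whitespace trimming and case
#' folding), or `different_domain` when the domains differ. Inconsistent
#' hierarchies (e.g. same genus under different families) are accepted
#' as-is and resolved by the all-ranks-upward rule.
#'
#' @param a,b Named character vectors (or one-row data frames) holding the
#'   six ranks `species` ... `domain`.
#' @return A length-1 factor over [rank_levels()].
#' @export
shared_level <- function(a, b) {
  a <- unlist(a); b <- unlist(b)
  ra <- matrix(a[TAX_RANKS], nrow = 1)
  rb <- matrix(b[TAX_RANKS], nrow = 1)
  if (anyNA(ra) || anyNA(rb))
    stop("records must contain all six ranks: ",
         paste(TAX_RANKS, collapse = ", "))
  .shared_level_core(ra, rb)
}

#' Shared taxonomic levels for vectors of organism pairs
#'
#' Vectorized form of [shared_level()] that looks organisms up by id in a
#' taxonomy table.
#'
#' @param tax Taxonomy data frame (see [read_taxonomy()]).
#' @param a,b Character vectors of organism ids, recycled to equal length.
#' @return A factor over [rank_levels()], one element per pair.
#' @export
shared_levels <- function(tax, a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  ia <- match(a, tax$organism_id); ib <- match(b, tax$organism_id)
  if (anyNA(ia)) stop("organism not in taxonomy: ", a[which(is.na(ia))[1]])
  if (anyNA(ib)) stop("organism not in taxonomy: ", b[which(is.na(ib))[1]])
  ra <- as.matrix(tax[ia, TAX_RANKS])
  rb <- as.matrix(tax[ib, TAX_RANKS])
  .shared_level_core(ra, rb)
}
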