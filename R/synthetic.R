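# Hierarchical synthetic communities: rank-structured perturbed Markov
# sequence models standing in for a real multi-genome dataset.

SIGMA_RANKS <- c("domain", "phylum", "order", "family", "genus", "species")

#' Describe a synthetic community
#'
#' A community is a balanced rank hierarchy (domains, phyla per domain,
#' ... species per genus) of order-`m` Markov sequence models. A root
#' model is drawn with logit jitter `root_jitter`; each child taxon's
#' model is its parent's with a logit-scale Gaussian perturbation whose
#' magnitude `sigma[rank]` decreases from domain to species, so signatures
#' are conserved within genera and increasingly distinct at higher ranks.
#' The defaults are the frozen reference community used by the package's
#' regression tests: 1 domain / 3 phyla / 6 genera / 12 species, Markov
#' order 5, 200 kb genomes.
#'
#' @param n_domains,phyla_per_domain,orders_per_phylum,families_per_order,genera_per_family,species_per_genus
#'   Counts per rank (all >= 1).
#' @param sigma Named numeric vector of per-rank logit perturbation
#'   magnitudes, non-increasing from `domain` to `species`.
#' @param markov_order Context length m of the sequence models (0-8).
#' @param genome_length Genome length in bp (> `markov_order`).
#' @param root_jitter Logit s.d. of the root model around uniform.
#' @param seed RNG seed for model construction.
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(n_domains = 1, phyla_per_domain = 3,
                           orders_per_phylum = 1, families_per_order = 1,
                           genera_per_family = 2, species_per_genus = 2,
                           sigma = c(domain = 0.50, phylum = 0.35,
                                     order = 0.25, family = 0.18,
                                     genus = 0.15, species = 0.02),
                           markov_order = 5, genome_length = 200000,
                           root_jitter = 0.50, seed = 101) {
  counts <- c(n_domains = n_domains, phyla_per_domain = phyla_per_domain,
              orders_per_phylum = orders_per_phylum,
              families_per_order = families_per_order,
              genera_per_family = genera_per_family,
              species_per_genus = species_per_genus)
  if (any(counts < 1)) stop("all rank counts must be >= 1")
  if (!all(SIGMA_RANKS %in% names(sigma)))
    stop("sigma must be named with: ", paste(SIGMA_RANKS, collapse = ", "))
  sigma <- sigma[SIGMA_RANKS]
  if (any(sigma < 0) || any(diff(sigma) > 1e-12))
    stop("sigma must satisfy domain >= phylum >= ... >= species >= 0")
  if (markov_order < 0 || markov_order > 8)
    stop("markov_order must be between 0 and 8")
  if (genome_length <= markov_order)
    stop("genome_length must exceed markov_order")
  structure(list(n_domains = n_domains,
                 phyla_per_domain = phyla_per_domain,
                 orders_per_phylum = orders_per_phylum,
                 families_per_order = families_per_order,
                 genera_per_family = genera_per_family,
                 species_per_genus = species_per_genus,
                 sigma = sigma, markov_order = markov_order,
                 genome_length = genome_length, root_jitter = root_jitter,
                 seed = seed),
            class = "community_spec")
}

#' The frozen reference community specification
#'
#' @return The default [community_spec()].
#' @export
reference_community_spec <- function() community_spec()

#' Write / read a community spec as JSON
#'
#' @param spec A `community_spec`.
#' @param path File path.
#' @return The path (writer, invisibly) or a `community_spec` (reader).
#' @export
write_community_spec <- function(spec, path) {
  stopifnot(inherits(spec, "community_spec"))
  x <- unclass(spec)
  x$sigma <- as.list(x$sigma)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_community_spec
#' @export
read_community_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$sigma <- unlist(x$sigma)
  do.call(community_spec, x)
}

#' @export
print.community_spec <- function(x, ...) {
  n_sp <- x$n_domains * x$phyla_per_domain * x$orders_per_phylum *
    x$families_per_order * x$genera_per_family * x$species_per_genus
  cat("<community_spec>", n_sp, "organisms | m =", x$markov_order,
      "|", x$genome_length, "bp | seed", x$seed, "\n")
  invisible(x)
}

.softmax_rows <- function(l) {
  e <- exp(l - apply(l, 1, max))
  e / rowSums(e)
}

#' Build a synthetic community
#'
#' Draws the full model hierarchy described by a spec: a root logit matrix
#' with Gaussian jitter, then per-rank Gaussian logit perturbations down
#' to species, renormalized to probabilities at the leaves. Organisms get
#' systematic six-rank names (e.g. `D1_P2_O1_F1_G2_S1`), so the emitted
#' taxonomy table parses without curation.
#'
#' @param spec A `community_spec`.
#' @return An object of class `synthetic_community`: list with `spec`,
#'   `taxonomy` (data frame, one row per organism) and `models` (named
#'   list of `taxon_model`: `m` plus a `4^m x 4` probability matrix).
#' @export
build_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  m <- spec$markov_order
  nctx <- 4^m
  perturb <- function(logits, s) logits + rnorm(length(logits), 0, s)
  tax_rows <- list()
  models <- list()
  .with_seed(spec$seed, {
    root <- matrix(rnorm(nctx * 4, 0, spec$root_jitter), nctx, 4)
    for (di in seq_len(spec$n_domains)) {
      d_name <- paste0("D", di)
      d_log <- perturb(root, spec$sigma[["domain"]])
      for (pi in seq_len(spec$phyla_per_domain)) {
        p_name <- paste0(d_name, "_P", pi)
        p_log <- perturb(d_log, spec$sigma[["phylum"]])
        for (oi in seq_len(spec$orders_per_phylum)) {
          o_name <- paste0(p_name, "_O", oi)
          o_log <- perturb(p_log, spec$sigma[["order"]])
          for (fi in seq_len(spec$families_per_order)) {
            f_name <- paste0(o_name, "_F", fi)
            f_log <- perturb(o_log, spec$sigma[["family"]])
            for (gi in seq_len(spec$genera_per_family)) {
              g_name <- paste0(f_name, "_G", gi)
              g_log <- perturb(f_log, spec$sigma[["genus"]])
              for (si in seq_len(spec$species_per_genus)) {
                s_name <- paste0(g_name, "_S", si)
                s_log <- perturb(g_log, spec$sigma[["species"]])
                tax_rows[[length(tax_rows) + 1L]] <- data.frame(
                  organism_id = s_name, species = s_name, genus = g_name,
                  family = f_name, order = o_name, phylum = p_name,
                  domain = d_name, stringsAsFactors = FALSE)
                models[[s_name]] <- structure(
                  list(m = m, probs = .softmax_rows(s_log)),
                  class = "taxon_model")
              }
            }
          }
        }
      }
    }
  })
  taxonomy <- validate_taxonomy(do.call(rbind, tax_rows))
  structure(list(spec = spec, taxonomy = taxonomy, models = models),
            class = "synthetic_community")
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat("<synthetic_community>", nrow(x$taxonomy), "organisms | m =",
      x$spec$markov_order, "| seed", x$spec$seed, "\n")
  invisible(x)
}

#' Sample a genome from a taxon's Markov model
#'
#' The first `m` bases are uniform; every later base is drawn from the
#' model row of its preceding length-`m` context.
#'
#' @param model A `taxon_model`.
#' @param length Genome length (> `m`).
#' @param seed Optional RNG seed.
#' @return A DNA string.
#' @export
sample_genome <- function(model, length, seed = NULL) {
  stopifnot(inherits(model, "taxon_model"))
  if (length <= model$m) stop("length must exceed the Markov order")
  .with_seed(seed, sample_markov_cpp(model$probs, model$m,
                                     as.integer(length)))
}

#' Sample one genome per community member
#'
#' @param community A `synthetic_community`.
#' @param seed Optional RNG seed for the whole draw.
#' @param genome_length Override of the spec's genome length.
#' @return Named character vector of genomes (names = organism ids).
#' @export
community_genomes <- function(community, seed = NULL, genome_length = NULL) {
  stopifnot(inherits(community, "synthetic_community"))
  len <- if (is.null(genome_length)) community$spec$genome_length
         else genome_length
  .with_seed(seed, vapply(community$models, sample_genome, character(1),
                          length = len))
}

#' Write a community's genomes and taxonomy to disk
#'
#' @param genomes Named character vector of genomes.
#' @param taxonomy Taxonomy data frame.
#' @param fasta_path Output multi-FASTA path.
#' @param tax_path Output tab-delimited taxonomy path (with header).
#' @return Invisibly, a list of the two paths.
#' @export
write_community <- function(genomes, taxonomy, fasta_path, tax_path) {
  write_fasta(genomes, fasta_path)
  con <- file(tax_path, "w")
  on.exit(close(con))
  writeLines(paste(c("organism_id", TAX_RANKS), collapse = "\t"), con)
  writeLines(do.call(paste, c(unname(taxonomy), list(sep = "\t"))), con)
  invisible(list(fasta = fasta_path, taxonomy = tax_path))
}
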