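# Shared fixtures: small taxonomies, signatures and communities built in code.

make_tax <- function(ids, species = ids, genus = "G1", family = "F1",
                     order = "O1", phylum = "P1", domain = "Bacteria") {
  data.frame(organism_id = ids, species = species,
             genus = rep_len(genus, length(ids)),
             family = rep_len(family, length(ids)),
             order = rep_len(order, length(ids)),
             phylum = rep_len(phylum, length(ids)),
             domain = rep_len(domain, length(ids)),
             stringsAsFactors = FALSE)
}

# random but valid signature: percentages from Poisson-ish random counts
rand_sig <- function(k, label = "s", seed = NULL) {
  gen <- function() {
    counts <- stats::rpois(4^k, 5) + 1
    new_signature(100 * counts / sum(counts), k, label = label,
                  n_windows = sum(counts))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

random_seq <- function(n, seed = NULL, alphabet = c("A", "C", "G", "T")) {
  gen <- function() paste(sample(alphabet, n, replace = TRUE), collapse = "")
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

# small, fast community for unit tests (not the frozen reference spec)
tiny_spec <- function(...) {
  community_spec(phyla_per_domain = 2, genera_per_family = 2,
                 species_per_genus = 2, markov_order = 2,
                 genome_length = 20000,
                 sigma = c(domain = 0.6, phylum = 0.4, order = 0.3,
                           family = 0.25, genus = 0.2, species = 0.02),
                 seed = 11, ...)
}

write_tax_file <- function(tax, path = tempfile(fileext = ".tsv"),
                           header = TRUE) {
  lines <- do.call(paste, c(unname(tax), list(sep = "\t")))
  if (header)
    lines <- c(paste(c("organism_id", "species", "genus", "family", "order",
                       "phylum", "domain"), collapse = "\t"), lines)
  writeLines(lines, path)
  path
}
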