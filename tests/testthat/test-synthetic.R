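test_that("community construction nests ranks and counts correctly", {
  spec <- community_spec(genera_per_family = 2, species_per_genus = 3,
                         markov_order = 1, genome_length = 1000,
                         phyla_per_domain = 1,
                         sigma = c(domain = 0.5, phylum = 0.4, order = 0.3,
                                   family = 0.25, genus = 0.2,
                                   species = 0.05), seed = 1)
  com <- build_community(spec)
  expect_identical(nrow(com$taxonomy), 6L)
  expect_length(com$models, 6)
  expect_identical(length(unique(com$taxonomy$genus)), 2L)
  # every organism's ranks nest: same genus implies same family etc.
  for (i in 1:6) for (j in 1:6) {
    a <- com$taxonomy[i, ]; b <- com$taxonomy[j, ]
    if (a$genus == b$genus) expect_identical(a$family, b$family)
    if (a$family == b$family) expect_identical(a$phylum, b$phylum)
  }
  expect_true(all(vapply(com$models, function(m)
    max(abs(rowSums(m$probs) - 1)) < 1e-12, logical(1))))
})

test_that("zero divergence collapses all leaf models to the root", {
  spec <- community_spec(markov_order = 1, genome_length = 1000,
                         sigma = c(domain = 0, phylum = 0, order = 0,
                                   family = 0, genus = 0, species = 0),
                         seed = 3)
  com <- build_community(spec)
  probs <- lapply(com$models, `[[`, "probs")
  for (p in probs[-1]) expect_equal(p, probs[[1]], tolerance = 1e-12)
})

test_that("sigma ordering and count preconditions are enforced", {
  expect_error(community_spec(sigma = c(domain = 0.1, phylum = 0.5,
                                        order = 0.3, family = 0.2,
                                        genus = 0.1, species = 0.01)),
               "domain >= phylum")
  expect_error(community_spec(species_per_genus = 0), ">= 1")
  expect_error(community_spec(genome_length = 3, markov_order = 5),
               "exceed")
})

test_that("genus divergence dominates species divergence in signatures", {
  # Monte Carlo over 20 seeded communities: with sigma_genus >> sigma_species
  # the mean inter-genus signature distance exceeds the intra-genus mean
  inter <- intra <- numeric(20)
  for (s in 1:20) {
    spec <- community_spec(phyla_per_domain = 1, genera_per_family = 2,
                           species_per_genus = 2, markov_order = 2,
                           genome_length = 20000,
                           sigma = c(domain = 0.5, phylum = 0.5, order = 0.5,
                                     family = 0.5, genus = 0.4,
                                     species = 0.02), seed = 1000 + s)
    com <- build_community(spec)
    g <- community_genomes(com, seed = 2000 + s)
    m <- all_pairs_matrix(signatures_per_record(g, 4))
    iu <- which(upper.tri(m), arr.ind = TRUE)
    lv <- shared_levels(com$taxonomy, rownames(m)[iu[, 1]],
                        rownames(m)[iu[, 2]])
    d <- unclass(m)[iu]
    intra[s] <- mean(d[lv %in% c("species", "genus")])
    inter[s] <- mean(d[!lv %in% c("species", "genus")])
  }
  expect_gt(mean(inter), mean(intra))
  expect_gt(mean(inter > intra), 0.9)
})

test_that("Markov genome sampling is seeded and honors the model", {
  uniform <- structure(list(m = 0, probs = matrix(0.25, 1, 4)),
                       class = "taxon_model")
  g <- sample_genome(uniform, 20000, seed = 5)
  expect_identical(g, sample_genome(uniform, 20000, seed = 5))
  counts <- count_words(g, 1)$counts
  sd4 <- 4 * sqrt(20000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 5000) < sd4))

  # deterministic cyclic model A->C->G->T->A produces a periodic sequence
  P <- matrix(0, 4, 4)
  P[cbind(1:4, c(2, 3, 4, 1))] <- 1
  cyc <- structure(list(m = 1, probs = P), class = "taxon_model")
  g2 <- sample_genome(cyc, 40, seed = 2)
  body <- substr(g2, 2, 40)
  expect_true(grepl("^(ACGT|CGTA|GTAC|TACG)+", paste0(body, body)))
  # consecutive bases always follow the cycle
  ch <- strsplit(g2, "")[[1]]
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  expect_true(all(ch[-1] == nxt[ch[-length(ch)]]))

  expect_error(sample_genome(cyc, 1), "exceed")
})

test_that("community specs round-trip through JSON with seeds intact", {
  spec <- tiny_spec()
  path <- tempfile(fileext = ".json")
  write_community_spec(spec, path)
  back <- read_community_spec(path)
  expect_equal(unclass(back), unclass(spec), tolerance = 1e-12)
  com1 <- build_community(spec)
  com2 <- build_community(back)
  expect_equal(com1$models[[1]]$probs, com2$models[[1]]$probs)
})

test_that("community FASTA + taxonomy files re-enter the pipeline", {
  com <- build_community(tiny_spec())
  g <- community_genomes(com, seed = 12, genome_length = 2000)
  fasta <- tempfile(fileext = ".fasta"); taxf <- tempfile(fileext = ".tsv")
  write_community(g, com$taxonomy, fasta, taxf)
  g2 <- read_fasta(fasta)
  expect_identical(g2, g)
  expect_equal(read_taxonomy(taxf), com$taxonomy)
})
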