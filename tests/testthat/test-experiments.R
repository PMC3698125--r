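test_that("leave-one-out histograms bin all distinct pairs exactly once", {
  sigs <- lapply(1:6, function(i) rand_sig(3, paste0("s", i), seed = 40 + i))
  tax <- make_tax(paste0("s", 1:6),
                  genus = rep(c("g1", "g2", "g3"), each = 2),
                  phylum = rep(c("p1", "p1", "p2"), each = 2))
  m <- genus_normalize(all_pairs_matrix(sigs), tax)
  h <- leave_one_out_histogram(m, tax, n_bins = 30)
  expect_length(h$breaks, 31)
  expect_equal(h$breaks[1], 0)
  expect_equal(max(h$breaks), max(unclass(m)))
  expect_equal(sum(h$counts), choose(6, 2))
  expect_equal(h$n_pairs, 15L)
  nonempty <- rowSums(h$counts) > 0
  expect_equal(rowSums(h$proportions)[nonempty],
               rep(1, sum(nonempty)), ignore_attr = TRUE)
  expect_true(all(is.na(h$proportions[!nonempty, ])))

  # unnormalized input is refused
  expect_error(leave_one_out_histogram(all_pairs_matrix(sigs), tax),
               "normalized")

  # two organisms of the same species: a single nonempty bin, all species
  sigs2 <- lapply(1:2, function(i) rand_sig(2, paste0("t", i), seed = i))
  tax2 <- make_tax(c("t1", "t2"), species = "same sp")
  m2 <- genus_normalize(all_pairs_matrix(sigs2), tax2)
  h2 <- leave_one_out_histogram(m2, tax2)
  expect_identical(sum(rowSums(h2$counts) > 0), 1L)
  expect_equal(h2$proportions[rowSums(h2$counts) > 0, "species"], 1,
               ignore_attr = TRUE)
})

test_that("fragments are uniform contiguous substrings at the stated offset", {
  seq <- random_seq(500, seed = 1)
  expect_identical(as.character(sample_fragment(seq, 500)), seq)
  f <- sample_fragment(seq, 40, seed = 3)
  expect_identical(as.character(f),
                   substr(seq, attr(f, "start"), attr(f, "start") + 39))
  expect_identical(as.character(sample_fragment(seq, 40, seed = 3)),
                   as.character(f))
  expect_error(sample_fragment(seq, 0), ">= 1")
  expect_error(sample_fragment(seq, 501), "exceeds")
})

test_that("full-length fragments reduce to the whole-genome experiment", {
  com <- build_community(tiny_spec())
  g <- community_genomes(com, seed = 21)
  sigs <- signatures_per_record(g, 3)
  tree <- neighbor_joining(all_pairs_matrix(sigs))
  whole <- same_genus_pct(
    taxonomic_agreement_profile(leaf_nearest_neighbors(tree), com$taxonomy))
  fx <- fragment_nn_experiment(g, com$taxonomy,
                               lengths = nchar(g[[1]]), ks = 3, seed = 5)
  expect_equal(fx$summary$same_genus_pct, whole)
  expect_identical(nrow(fx$results), 1L)
})

test_that("chunk profiles: whole-sequence self chunk has zero mean distance", {
  g <- c(org1 = random_seq(4000, seed = 2), org2 = random_seq(4000, seed = 3))
  pr <- chunk_distance_profile(g, chunk_lengths = 4000, k = 2)
  self <- pr[pr$label_a == pr$label_b, ]
  expect_equal(self$mean_distance, c(0, 0))
  expect_identical(self$n_chunk_pairs, c(1L, 1L))
  cross <- pr[pr$label_a != pr$label_b, ]
  expect_true(all(cross$mean_distance > 0))

  pr2 <- chunk_distance_profile(g, chunk_lengths = c(500, 2000), k = 2,
                                pairs = "self")
  agg <- tapply(pr2$mean_distance, pr2$chunk_length, mean)
  expect_lt(agg[["2000"]], agg[["500"]])  # longer chunks, smaller self noise
})

test_that("best-hit binning assigns minimal-distance references", {
  refs <- lapply(1:4, function(i) rand_sig(3, paste0("r", i), seed = 50 + i))
  queries <- lapply(refs, function(r)
    new_signature(r$pct, r$k, label = paste0("q_", r$label)))
  truth <- setNames(paste0("r", 1:4), paste0("q_r", 1:4))
  res <- best_hit_binning(queries, refs, truth_labels = truth)
  expect_equal(res$assignments$distance, rep(0, 4))
  expect_identical(res$assignments$assigned, paste0("r", 1:4))
  expect_equal(res$agreement_pct, 100)

  # agreement is invariant under a global relabeling bijection
  relabel <- function(x) paste0("Z", x)
  refs2 <- lapply(refs, function(r)
    new_signature(r$pct, r$k, label = relabel(r$label)))
  res2 <- best_hit_binning(queries, refs2,
                           truth_labels = setNames(relabel(truth),
                                                   names(truth)))
  expect_equal(res2$agreement_pct, res$agreement_pct)

  expect_error(best_hit_binning(queries, list()), "empty")
})

test_that("percent identity uses gap-free columns only", {
  expect_equal(percent_identity("ACGT", "ACGT"), 100)
  expect_equal(percent_identity("ACGT", "ACGA"), 75)
  expect_equal(percent_identity("AC-T", "ACGT"), 100)
  expect_equal(percent_identity("ac.t", "ACGT"), 100)
  expect_error(percent_identity("ACG", "ACGT"), "equal length")
  expect_error(percent_identity("----", "AAAA"), "no comparable")
})

test_that("identity/distance scatter rows carry the shared level", {
  sigs <- lapply(1:3, function(i) rand_sig(2, paste0("s", i), seed = 60 + i))
  tax <- make_tax(paste0("s", 1:3), genus = c("g1", "g1", "g2"))
  m <- genus_normalize(all_pairs_matrix(sigs), tax)
  aln <- c(s1 = "ACGTAC-T", s2 = "ACGTACGT", s3 = "TTTTACGT")
  sc <- identity_distance_scatter(aln, m, tax)
  expect_identical(nrow(sc), 3L)
  row12 <- sc[sc$label_a == "s1" & sc$label_b == "s2", ]
  expect_equal(row12$identity_pct, 100)
  expect_equal(row12$distance, unclass(m)["s1", "s2"])
  expect_identical(row12$shared_level, "genus")
})
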