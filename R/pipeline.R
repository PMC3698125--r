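# Stage orchestration: the package's pipeline stages as named subcommands
# with file inputs/outputs, #-prefixed metadata headers and explicit seeds.

.cfg <- function(config, key, default = NULL, required = FALSE) {
  if (!is.null(config[[key]])) return(config[[key]])
  if (required) stop("missing required config key '", key, "'")
  default
}

.meta_header <- function(stage, params = list()) {
  ver <- as.character(utils::packageVersion("oligosig"))
  p <- if (length(params))
    paste(names(params),
          vapply(params, function(v) paste(v, collapse = ","), character(1)),
          sep = "=", collapse = " ")
  else ""
  c(paste0("# oligosig ", ver), paste0("# stage: ", stage),
    paste0("# params: ", p))
}

.log_stage <- function(stage, params, t0) {
  message(sprintf("[oligosig] stage=%s %s elapsed=%.2fs", stage,
                  paste(names(params),
                        vapply(params, function(v)
                          paste(v, collapse = ","), character(1)),
                        sep = "=", collapse = " "),
                  as.numeric(proc.time()[3] - t0)))
}

#' Run a pipeline stage
#'
#' Dispatches one of the named subcommands with a configuration list.
#' Every stochastic stage takes an explicit `seed` (no silent clock
#' seeding); reruns with identical config produce byte-identical outputs.
#' Output tables begin with `#`-prefixed metadata lines (package version,
#' stage, parameters, seeds); structured progress lines go to standard
#' error.
#'
#' Stages and their main config keys:
#' \describe{
#'   \item{synth}{`out_fasta`, `out_taxonomy`; optional `spec_json`, `seed`,
#'     plus any [community_spec()] argument as an override.}
#'   \item{signature}{`fasta`, `k`, `out`; optional `drop_plasmids`.}
#'   \item{distmat}{`signatures`, `out_phylip`; optional `out_tsv`,
#'     `normalize` (needs `taxonomy`).}
#'   \item{tree}{`phylip`, `out_newick`.}
#'   \item{nn-eval}{`newick`, `taxonomy`, `out`.}
#'   \item{loo}{`signatures`, `taxonomy`, `out`; optional `n_bins`.}
#'   \item{fragments}{`fasta`, `taxonomy`, `out`; optional `lengths`, `ks`,
#'     `replicates`, `seed`.}
#'   \item{chunks}{`fasta`, `out`; optional `chunk_lengths`, `k`, `pairs`.}
#'   \item{mutsim}{`out`; optional `length`, `n_iter`, `snapshot_every`,
#'     `ks`, `seed`.}
#'   \item{bin}{`queries_fasta`, `refs_fasta`, `k`, `out`; optional
#'     `truth_tsv` (two columns: query, truth).}
#'   \item{identity-scatter}{`alignment_fasta`, `signatures`, `taxonomy`,
#'     `out`.}
#' }
#'
#' @param name Subcommand name (see Details).
#' @param config Named list of stage parameters.
#' @return Invisibly, a named list of output paths.
#' @export
run_subcommand <- function(name, config = list()) {
  stages <- list(`synth` = .stage_synth, `signature` = .stage_signature,
                 `distmat` = .stage_distmat, `tree` = .stage_tree,
                 `nn-eval` = .stage_nn_eval, `loo` = .stage_loo,
                 `fragments` = .stage_fragments, `chunks` = .stage_chunks,
                 `mutsim` = .stage_mutsim, `bin` = .stage_bin,
                 `identity-scatter` = .stage_identity_scatter)
  if (!name %in% names(stages))
    stop("unknown subcommand '", name, "'; available: ",
         paste(names(stages), collapse = ", "))
  t0 <- proc.time()[3]
  out <- stages[[name]](config)
  .log_stage(name, config[!vapply(config, is.null, logical(1))], t0)
  invisible(out)
}

.stage_synth <- function(config) {
  spec <- if (!is.null(config$spec_json)) {
    read_community_spec(config$spec_json)
  } else {
    args <- config[intersect(names(config), names(formals(community_spec)))]
    do.call(community_spec, args)
  }
  if (!is.null(config$seed)) spec$seed <- as.integer(config$seed)
  out_fasta <- .cfg(config, "out_fasta", required = TRUE)
  out_tax <- .cfg(config, "out_taxonomy", required = TRUE)
  com <- build_community(spec)
  genomes <- community_genomes(com, seed = spec$seed + 1L)
  write_community(genomes, com$taxonomy, out_fasta, out_tax)
  if (!is.null(config$out_spec)) write_community_spec(spec, config$out_spec)
  list(fasta = out_fasta, taxonomy = out_tax)
}

.stage_signature <- function(config) {
  fasta <- .cfg(config, "fasta", required = TRUE)
  k <- .check_k(.cfg(config, "k", required = TRUE))
  out <- .cfg(config, "out", required = TRUE)
  seqs <- read_fasta(fasta,
                     drop_plasmids = isTRUE(.cfg(config, "drop_plasmids",
                                                 FALSE)))
  sigs <- signatures_per_record(seqs, k)
  write_signatures_tsv(sigs, out,
                       .meta_header("signature",
                                    list(fasta = fasta, k = k)))
  list(signatures = out)
}

.stage_distmat <- function(config) {
  sigs <- read_signatures_tsv(.cfg(config, "signatures", required = TRUE))
  m <- all_pairs_matrix(sigs)
  factor <- NA_real_
  if (isTRUE(.cfg(config, "normalize", FALSE))) {
    tax <- read_taxonomy(.cfg(config, "taxonomy", required = TRUE))
    m <- genus_normalize(m, tax)
    factor <- attr(m, "normalization_factor")
  }
  out_phylip <- .cfg(config, "out_phylip", required = TRUE)
  write_phylip_distmat(m, out_phylip)
  outs <- list(phylip = out_phylip)
  if (!is.null(config$out_tsv)) {
    write_distmat_tsv(m, config$out_tsv,
                      .meta_header("distmat",
                                   list(k = attr(m, "k"),
                                        normalized = isTRUE(attr(m, "normalized")),
                                        factor = factor)))
    outs$tsv <- config$out_tsv
  }
  outs
}

.stage_tree <- function(config) {
  m <- read_phylip_distmat(.cfg(config, "phylip", required = TRUE))
  out <- .cfg(config, "out_newick", required = TRUE)
  ape::write.tree(neighbor_joining(m), file = out)
  list(newick = out)
}

.stage_nn_eval <- function(config) {
  tree <- ape::read.tree(.cfg(config, "newick", required = TRUE))
  tax <- read_taxonomy(.cfg(config, "taxonomy", required = TRUE))
  out <- .cfg(config, "out", required = TRUE)
  ag <- taxonomic_agreement_profile(leaf_nearest_neighbors(tree), tax)
  write_agreement_tsv(ag, out, .meta_header("nn-eval", list()))
  list(agreement = out)
}

.stage_loo <- function(config) {
  sigs <- read_signatures_tsv(.cfg(config, "signatures", required = TRUE))
  tax <- read_taxonomy(.cfg(config, "taxonomy", required = TRUE))
  n_bins <- .cfg(config, "n_bins", 30)
  out <- .cfg(config, "out", required = TRUE)
  m <- genus_normalize(all_pairs_matrix(sigs), tax)
  h <- leave_one_out_histogram(m, tax, n_bins = n_bins)
  write_loo_tsv(h, out, .meta_header("loo", list(n_bins = n_bins)))
  list(histogram = out)
}

.stage_fragments <- function(config) {
  genomes <- read_fasta(.cfg(config, "fasta", required = TRUE))
  tax <- read_taxonomy(.cfg(config, "taxonomy", required = TRUE))
  lengths <- as.numeric(.cfg(config, "lengths",
                             c(1000, 2500, 5000, 10000, 15000, 25000,
                               50000)))
  ks <- as.integer(.cfg(config, "ks", c(4, 7)))
  replicates <- as.integer(.cfg(config, "replicates", 1))
  seed <- .cfg(config, "seed", required = TRUE)
  out <- .cfg(config, "out", required = TRUE)
  fx <- fragment_nn_experiment(genomes, tax, lengths = lengths, ks = ks,
                               replicates = replicates, seed = seed)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(.meta_header("fragments",
                          list(lengths = lengths, ks = ks,
                               replicates = replicates, seed = seed)), con)
  writeLines("fragment_length\tk\treplicate\tsame_genus_pct", con)
  r <- fx$results
  writeLines(paste(r$fragment_length, r$k, r$replicate,
                   .fmt_num(r$same_genus_pct), sep = "\t"), con)
  list(fragments = out)
}

.stage_chunks <- function(config) {
  genomes <- read_fasta(.cfg(config, "fasta", required = TRUE))
  lengths <- as.numeric(.cfg(config, "chunk_lengths",
                             c(500, 1000, 2500, 5000, 10000, 15000, 20000,
                               50000)))
  k <- .check_k(.cfg(config, "k", 4))
  pairs <- .cfg(config, "pairs", "all")
  out <- .cfg(config, "out", required = TRUE)
  pr <- chunk_distance_profile(genomes, chunk_lengths = lengths, k = k,
                               pairs = pairs)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(.meta_header("chunks", list(chunk_lengths = lengths, k = k,
                                         pairs = pairs)), con)
  writeLines("label_a\tlabel_b\tchunk_length\tmean_distance\tn_chunk_pairs",
             con)
  writeLines(paste(pr$label_a, pr$label_b, pr$chunk_length,
                   .fmt_num(pr$mean_distance), pr$n_chunk_pairs, sep = "\t"),
             con)
  list(chunks = out)
}

.stage_mutsim <- function(config) {
  len <- as.numeric(.cfg(config, "length", 1e6))
  n_iter <- as.numeric(.cfg(config, "n_iter", 1e6))
  cadence <- as.numeric(.cfg(config, "snapshot_every", 100))
  ks <- as.integer(.cfg(config, "ks", c(4, 7)))
  seed <- as.integer(.cfg(config, "seed", required = TRUE))
  out <- .cfg(config, "out", required = TRUE)
  seq <- random_dna(len, seed = seed)
  traj <- mutation_trajectory(seq, n_iter = n_iter,
                              snapshot_every = cadence, ks = ks,
                              seed = seed + 1L)
  write_trajectory_tsv(traj, out,
                       .meta_header("mutsim",
                                    list(length = len, n_iter = n_iter,
                                         snapshot_every = cadence, ks = ks,
                                         seed = seed)))
  list(trajectory = out)
}

.stage_bin <- function(config) {
  k <- .check_k(.cfg(config, "k", required = TRUE))
  queries <- signatures_per_record(
    read_fasta(.cfg(config, "queries_fasta", required = TRUE)), k)
  refs <- signatures_per_record(
    read_fasta(.cfg(config, "refs_fasta", required = TRUE)), k)
  truth <- NULL
  if (!is.null(config$truth_tsv)) {
    tt <- utils::read.table(config$truth_tsv, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE, comment.char = "#")
    truth <- setNames(tt[[2]], tt[[1]])
  }
  out <- .cfg(config, "out", required = TRUE)
  res <- best_hit_binning(queries, refs, truth_labels = truth)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(.meta_header("bin", list(k = k,
                                      agreement_pct = res$agreement_pct)),
             con)
  a <- res$assignments
  writeLines(paste(names(a), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(a, function(col)
    if (is.numeric(col)) .fmt_num(col) else as.character(col)),
    list(sep = "\t"))), con)
  list(assignments = out)
}

.stage_identity_scatter <- function(config) {
  aln <- read_fasta(.cfg(config, "alignment_fasta", required = TRUE))
  sigs <- read_signatures_tsv(.cfg(config, "signatures", required = TRUE))
  tax <- read_taxonomy(.cfg(config, "taxonomy", required = TRUE))
  out <- .cfg(config, "out", required = TRUE)
  m <- genus_normalize(all_pairs_matrix(sigs), tax)
  sc <- identity_distance_scatter(aln, m, tax)
  con <- file(out, "w")
  on.exit(close(con))
  writeLines(.meta_header("identity-scatter", list()), con)
  writeLines("label_a\tlabel_b\tidentity_pct\tdistance\tshared_level", con)
  writeLines(paste(sc$label_a, sc$label_b, .fmt_num(sc$identity_pct),
                   .fmt_num(sc$distance), sc$shared_level, sep = "\t"), con)
  list(scatter = out)
}
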