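# shared fixtures, all built in code

library(dplyr)

# small in-memory genome from named character strings
toy_genome <- function(...) {
  Biostrings::DNAStringSet(c(...))
}

# coverage_profile object built directly from a depth vector, for
# scoring tests that need exact constructed profiles
make_profile <- function(depth, start = 1L, strand = "+", chrom = "c",
                         bin_size = 200L) {
  len <- length(depth)
  nb <- ceiling(len / bin_size)
  idx <- rep(seq_len(nb), each = bin_size, length.out = len)
  structure(list(chrom = chrom, start = start, end = start + len - 1L,
                 strand = strand, bin_size = bin_size,
                 depth = as.numeric(depth),
                 bins = as.numeric(tapply(depth, idx, mean))),
            class = "coverage_profile")
}

# minimal alignment tibble
aln_tbl <- function(pos, cigar, chrom = "c", strand = "+",
                    sample_id = "s", read_id = NULL) {
  n <- max(length(pos), length(cigar))
  tibble::tibble(
    sample_id = sample_id,
    read_id = read_id %||% sprintf("r%03d", seq_len(n)),
    flag = ifelse(rep_len(strand, n) == "-", 16L, 0L),
    chrom = chrom, pos = as.integer(pos), mapq = 255L,
    cigar = cigar, strand = strand
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# random CIGAR strings over all operation types, anchored to start and
# end on reference-consuming ops so they are realistic alignments
random_cigars <- function(n, seed = 1) {
  set.seed(seed)
  ops_mid <- c("M", "I", "D", "N", "=", "X")
  replicate(n, {
    k <- sample(1:6, 1)
    op <- c("M", sample(ops_mid, k, replace = TRUE), "M")
    len <- sample(1:200, length(op), replace = TRUE)
    paste0(len, op, collapse = "")
  })
}

# independent CIGAR-walk oracle for junction extraction, via
# GenomicAlignments reference-space ranges of the N operations
oracle_junctions <- function(pos, cigar) {
  rng <- GenomicAlignments::cigarRangesAlongReferenceSpace(
    cigar, pos = pos, ops = "N")
  purrr::map2_dfr(as.list(rng), seq_along(cigar), function(r, i) {
    tibble::tibble(aln = i,
                   donor_end = BiocGenerics::start(r) - 1L,
                   acceptor_start = BiocGenerics::end(r) + 1L)
  })
}

# brute-force enumeration of the RS candidate cascade used as the
# pipeline-order oracle: evaluates each filter independently
brute_force_candidates <- function(tbl, min_intron, min_count, min_fold) {
  ok <- logical(nrow(tbl))
  for (i in seq_len(nrow(tbl))) {
    ok[i] <- !is.na(tbl$intron_length[i]) &&
      tbl$intron_length[i] >= min_intron &&
      tbl$total_rpm[i] > min_fold * tbl$mrna_rpm[i] &&
      tbl$merged_count[i] >= min_count
  }
  tbl$site_id[ok]
}

# the default simulated study: 5 RS sites, 3 cryptic exons, 1 plain
# gene; 2 total-RNA replicates + mRNA control.  Built once per test
# run and cached.
.fixture_env <- new.env(parent = emptyenv())

sim_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  dir <- file.path(tempdir(), "recsplice-fixture")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- simulate_reference(sim_config(seed = 1))
  paths <- write_simulation(truth, dir)
  depths <- simulate_replicates(truth, dir, n_rep = 2, seed = 101)
  total <- setNames(depths$path[depths$role == "total_rna"],
                    depths$sample_id[depths$role == "total_rna"])
  mrna <- setNames(depths$path[depths$role == "mrna_control"],
                   depths$sample_id[depths$role == "mrna_control"])
  fx <- list(truth = truth, paths = paths, depths = depths,
             total = total, mrna = mrna, dir = dir)
  .fixture_env$fx <- fx
  fx
}

# RS pipeline result on the fixture, cached
fixture_rs_result <- function() {
  if (!is.null(.fixture_env$rs)) return(.fixture_env$rs)
  fx <- sim_fixture()
  .fixture_env$rs <- run_rs_pipeline(fx$paths$genome, fx$paths$gtf,
                                     fx$total, fx$mrna)
  .fixture_env$rs
}

# cryptic pipeline result on the fixture, cached
fixture_cryptic_result <- function() {
  if (!is.null(.fixture_env$cr)) return(.fixture_env$cr)
  fx <- sim_fixture()
  .fixture_env$cr <- run_cryptic_pipeline(fx$paths$genome, fx$paths$gtf,
                                          fx$total, fx$mrna)
  .fixture_env$cr
}

site_key <- function(d) paste(d$chrom, d$a_pos, d$strand)

# random donor/acceptor training sequences with the required cores
rand_donors <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste0(
    paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = ""), "GT",
    paste(sample(c("A", "C", "G", "T"), 4, TRUE), collapse = "")))
}
rand_acceptors <- function(n, seed) {
  set.seed(seed)
  replicate(n, paste0(
    paste(sample(c("A", "C", "G", "T"), 18, TRUE), collapse = ""), "AG",
    paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")))
}

# site/count/depth tables for the candidate cascade with dialled-in
# filter outcomes: two total replicates splitting total_count, one
# mRNA control carrying mrna_count
cascade_fixture <- function(tbl) {
  depths <- tibble::tibble(sample_id = c("t1", "t2", "m"),
                           depth = c(1e6, 1e6, 1e6),
                           role = c("total_rna", "total_rna",
                                    "mrna_control"))
  sites <- tibble::tibble(
    site_id = tbl$site_id, gene_id = tbl$site_id, chrom = "c",
    strand = "+", a_pos = seq_len(nrow(tbl)) * 1000L,
    acceptor_pos = seq_len(nrow(tbl)) * 1000L + 2L, motif = "AGGT",
    intron_ordinal = 1L, intron_length = tbl$intron_length)
  counts <- tidyr::expand_grid(site_id = tbl$site_id,
                               sample_id = depths$sample_id) %>%
    dplyr::left_join(tbl, by = "site_id") %>%
    dplyr::mutate(up_count = dplyr::case_when(
      sample_id == "t1" ~ as.integer(ceiling(total_count / 2)),
      sample_id == "t2" ~ as.integer(floor(total_count / 2)),
      TRUE ~ mrna_count),
      up_rpm = up_count) %>%
    dplyr::select(site_id, sample_id, up_count, up_rpm)
  list(sites = sites, counts = counts, depths = depths)
}
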