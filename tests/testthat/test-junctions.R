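test_that("junctions come from N operations with exact SAM arithmetic", {
  expect_equal(nrow(extract_junctions(aln_tbl(100L, "50M"))), 0L)
  j <- extract_junctions(aln_tbl(1001L, "20M100N30M"))
  expect_equal(j$donor_end, 1020L)
  expect_equal(j$acceptor_start, 1121L)
  # one record per gap
  j2 <- extract_junctions(aln_tbl(1L, "10M50N10M50N10M"))
  expect_equal(nrow(j2), 2L)
  expect_equal(j2$donor_end, c(10L, 70L))
  expect_equal(j2$acceptor_start, c(61L, 121L))
  # insertions and soft clips do not consume reference
  j3 <- extract_junctions(aln_tbl(1001L, "5S10M3I5M100N10M"))
  expect_equal(j3$donor_end, 1015L)
  expect_equal(j3$acceptor_start, 1116L)
  expect_true(all(j3$acceptor_start > j3$donor_end + 1L))
  expect_error(extract_junctions(aln_tbl(1L, "10M5Q", read_id = "bad1")),
               "bad1")
})

test_that("extraction matches an independent CIGAR-walk oracle", {
  skip_if_not_installed("GenomicAlignments")
  cigs <- random_cigars(300, seed = 21)
  pos <- as.integer(sample(1:1e6, length(cigs)))
  aln <- aln_tbl(pos, cigs)
  mine <- extract_junctions(aln) %>%
    dplyr::mutate(aln = match(read_id, aln$read_id)) %>%
    dplyr::arrange(aln, donor_end) %>%
    dplyr::select(aln, donor_end, acceptor_start)
  want <- oracle_junctions(pos, cigs) %>%
    dplyr::arrange(aln, donor_end)
  expect_equal(as.data.frame(mine), as.data.frame(want))
})

# one plus- and one minus-strand toy gene sharing the same geometry:
# exon1 [1001,1200], intron [1201,5200], exon2 [5201,5400]; an AGGT
# site with acceptor 300 nt into the intron
up_toy <- function(strand) {
  gm <- gene_models(tibble::tibble(gene_id = "g", chrom = "c",
                                   strand = strand,
                                   start = c(1001L, 5201L),
                                   end = c(1200L, 5400L)))
  a_pos <- if (strand == "+") 1498L else 4903L
  sites <- tibble::tibble(
    site_id = "s1", gene_id = "g", chrom = "c", strand = strand,
    a_pos = a_pos,
    acceptor_pos = if (strand == "+") a_pos + 2L else a_pos - 2L,
    motif = "AGGT", intron_ordinal = 1L, intron_length = 4000L)
  list(gm = gm, sites = sites)
}
depths1 <- tibble::tibble(sample_id = "s", depth = 1e6, role = "total_rna")

test_that("up-junctions need an exact acceptor and an annotated donor", {
  toy <- up_toy("+")
  acc <- toy$sites$acceptor_pos
  jn <- function(donor_end, acceptor_start) {
    tibble::tibble(sample_id = "s", read_id = paste0("r", acceptor_start),
                   chrom = "c", strand = "+",
                   donor_end = donor_end, acceptor_start = acceptor_start)
  }
  # exact acceptor + donor at the annotated exon end: counted
  ok <- count_up_junctions(jn(1200L, acc), toy$sites, toy$gm, depths1)
  expect_equal(ok$up_count, 1L)
  expect_equal(ok$up_rpm, 1.0)
  # acceptor off by one: not counted
  expect_equal(count_up_junctions(jn(1200L, acc + 1L), toy$sites, toy$gm,
                                  depths1)$up_count, 0L)
  # donor inside the exon but not at its 3' end: strict rule rejects,
  # diagnostic loose count keeps it
  loose <- count_up_junctions(jn(1150L, acc), toy$sites, toy$gm, depths1)
  expect_equal(loose$up_count, 0L)
  expect_equal(loose$up_count_anyexon, 1L)
  # wrong read strand under a forward-stranded library: not counted
  jm <- jn(1200L, acc) %>% dplyr::mutate(strand = "-")
  expect_equal(count_up_junctions(jm, toy$sites, toy$gm,
                                  depths1)$up_count, 0L)
  expect_equal(count_up_junctions(jm, toy$sites, toy$gm, depths1,
                                  strandedness = "unstranded")$up_count, 1L)
})

test_that("minus-strand junction boundaries map through sense space", {
  toy <- up_toy("-")
  acc <- toy$sites$acceptor_pos   # lower-coordinate gap edge
  # upstream exon for a minus gene is the higher-coordinate exon
  # [5201,5400]; its sense 3' end is reference 5201
  j <- tibble::tibble(sample_id = "s", read_id = "r1", chrom = "c",
                      strand = "-", donor_end = acc,
                      acceptor_start = 5201L)
  expect_equal(count_up_junctions(j, toy$sites, toy$gm,
                                  depths1)$up_count, 1L)
  # same junction on a plus-strand read: rejected (forward library)
  expect_equal(count_up_junctions(j %>% dplyr::mutate(strand = "+"),
                                  toy$sites, toy$gm, depths1)$up_count, 0L)
})

test_that("down-junctions respect the scan window and record the modal donor", {
  toy <- up_toy("+")
  acc <- toy$sites$acceptor_pos
  jn <- function(donor_end, n = 1L) {
    tibble::tibble(sample_id = "s",
                   read_id = sprintf("r%d_%d", donor_end, seq_len(n)),
                   chrom = "c", strand = "+", donor_end = donor_end,
                   acceptor_start = 1201L)   # NOT an exon start
  }
  # valid down-junction: donor inside (acc, acc+350], acceptor at the
  # downstream exon start
  good <- function(donor_end, n = 1L) {
    jn(donor_end, n) %>% dplyr::mutate(acceptor_start = 5201L)
  }
  d <- count_down_junctions(good(acc + 100L), toy$sites, toy$gm, depths1)
  expect_equal(d$counts$down_count, 1L)
  expect_equal(d$donors$down_donor_pos, acc + 100L)
  # boundary: 350 in, 351 out
  expect_equal(count_down_junctions(good(acc + 350L), toy$sites, toy$gm,
                                    depths1)$counts$down_count, 1L)
  expect_equal(count_down_junctions(good(acc + 351L), toy$sites, toy$gm,
                                    depths1)$counts$down_count, 0L)
  # acceptor not at an annotated exon start: rejected
  expect_equal(count_down_junctions(jn(acc + 100L), toy$sites, toy$gm,
                                    depths1)$counts$down_count, 0L)
  # modal donor: 5 reads at one position beat 3 at another
  d2 <- count_down_junctions(
    dplyr::bind_rows(good(acc + 120L, 5L), good(acc + 80L, 3L)),
    toy$sites, toy$gm, depths1)
  expect_equal(d2$counts$down_count, 8L)
  expect_equal(d2$donors$down_donor_pos, acc + 120L)
})

test_that("RPM normalization is exact and scale-invariant", {
  expect_equal(rpm(10, 5e6), 2)
  expect_equal(rpm(0, 5e6), 0)
  expect_equal(rpm(7 * 3, 2e6 * 3), rpm(7, 2e6))
  expect_error(rpm(1, 0), "positive")
})

test_that("replicate merging sums counts and pools RPM", {
  counts <- tibble::tibble(
    site_id = "s1", sample_id = c("a", "b", "c", "m"),
    up_count = c(3L, 4L, 5L, 2L))
  depths <- tibble::tibble(sample_id = c("a", "b", "c", "m"),
                           depth = c(1e6, 1e6, 1e6, 2e6),
                           role = c(rep("total_rna", 3), "mrna_control"))
  m <- merge_replicates(counts, depths)
  expect_equal(m$merged_up_count, 12L)
  expect_equal(m$total_rpm, 12 / 3)        # pooled over 3e6 reads
  expect_equal(m$mrna_count, 2L)
  expect_equal(m$mrna_rpm, 1)
  # equal-depth pooled RPM equals the mean of per-replicate RPMs
  per_rep <- rpm(c(3, 4, 5), 1e6)
  expect_equal(m$total_rpm, mean(per_rep))
  # single replicate: identity
  one <- merge_replicates(counts[1, ], depths[1, ])
  expect_equal(one$merged_up_count, 3L)
})

test_that("planted junction counts are recovered exactly from the fixture", {
  fx <- sim_fixture()
  truth <- fx$truth
  aln <- dplyr::bind_rows(lapply(seq_len(nrow(fx$depths)), function(i) {
    read_sam(fx$depths$path[i], fx$depths$sample_id[i])
  }))
  junc <- extract_junctions(aln)
  sites <- scan_motif_sites(truth$models, truth$genome) %>%
    filter_intronic_sites(1000)
  depths <- fx$depths %>% dplyr::select(sample_id, depth, role)
  ups <- count_up_junctions(junc, sites, truth$models, depths)
  merged <- merge_replicates(ups, depths)
  planted <- dplyr::bind_rows(truth$rs_sites, truth$cryptic_exons)
  got <- sites %>%
    dplyr::inner_join(planted %>% dplyr::select(chrom, a_pos, up_reads,
                                                down_reads),
                      by = c("chrom", "a_pos")) %>%
    dplyr::inner_join(merged, by = "site_id")
  expect_equal(got$merged_up_count, got$up_reads)
  expect_true(all(got$mrna_count == 0L))
  # down counts, at candidate sites
  down <- count_down_junctions(junc, sites %>%
                                 dplyr::semi_join(got, by = "site_id"),
                               truth$models, depths)
  dm <- down$counts %>%
    dplyr::inner_join(depths, by = "sample_id") %>%
    dplyr::filter(role == "total_rna") %>%
    dplyr::group_by(site_id) %>%
    dplyr::summarise(down = sum(down_count))
  got2 <- got %>% dplyr::left_join(dm, by = "site_id")
  expect_equal(got2$down, got2$down_reads)
  # sum of per-site up counts cannot exceed the junction record count
  expect_lte(sum(ups$up_count), nrow(junc))
})
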