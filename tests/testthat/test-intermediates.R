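# toy gene for sequence assembly: exon1 ends ...ACG at 130, the site
# AGGT is followed by AAGT deep in the intron, and a downstream donor
# AAG|GTAAGA sits 60 nt past the acceptor
toy_seq_gene <- function() {
  exon1 <- paste0(paste(rep("C", 27), collapse = ""), "ACG")   # 30 nt
  intron_pre <- strrep("T", 169)
  site <- "AGGTAAGT"
  mid <- strrep("C", 49)                      # up to the down donor
  down <- "AAGGTAAGA"
  intron_post <- strrep("T", 1000)
  exon2 <- strrep("G", 50)
  seq <- paste0(strrep("A", 100), exon1, intron_pre, site, mid, down,
                intron_post, exon2)
  g <- toy_genome(c1 = seq)
  e1s <- 101L; e1e <- 130L
  a_pos <- e1e + 169L + 1L                    # the A of AGGT
  e2s <- nchar(seq) - 49L
  gm <- gene_models(tibble::tibble(gene_id = "g", chrom = "c1",
                                   strand = "+",
                                   start = c(e1s, e2s),
                                   end = c(e1e, e2s + 49L)))
  sites <- tibble::tibble(site_id = "s", gene_id = "g", chrom = "c1",
                          strand = "+", a_pos = a_pos,
                          acceptor_pos = a_pos + 2L, motif = "AGGT",
                          intron_ordinal = 1L,
                          intron_length = e2s - e1e - 1L)
  list(genome = g, gm = gm, sites = sites, a_pos = a_pos)
}

test_that("r5'SS assembly follows the 30+GT+20 / 3+GT+4 recipe", {
  toy <- toy_seq_gene()
  ss <- build_splice_site_sequences(toy$sites, toy$gm, toy$genome)
  expect_equal(ss$r5ss_maxent, "ACGGTAAGT")
  expect_equal(nchar(ss$r5ss_logo), 52L)
  expect_equal(substr(ss$r5ss_logo, 31, 32), "GT")
  expect_equal(substr(ss$r5ss_logo, 28, 30), "ACG")
  # the 9-mer sits inside the 52-mer at the aligned offset
  expect_equal(substr(ss$r5ss_logo, 28, 36), ss$r5ss_maxent)
})

test_that("observed down donors give the Down 5'SS verbatim", {
  toy <- toy_seq_gene()
  # the planted donor boundary: ...AAG | GTAAGA, i.e. the G of AAG
  dd <- toy$a_pos + 8L + 49L + 3L - 1L
  ss <- build_splice_site_sequences(
    toy$sites, toy$gm, toy$genome,
    down_donors = tibble::tibble(site_id = "s", down_donor_pos = dd))
  expect_equal(ss$down_donor_source, "observed_junction")
  expect_equal(ss$down5ss_maxent, "AAGGTAAGA")
  expect_equal(substr(ss$down5ss_logo, 31, 32), "GT")
  expect_equal(substr(ss$down5ss_logo, 28, 36), ss$down5ss_maxent)
})

test_that("without an observed donor the best window GT is used", {
  toy <- toy_seq_gene()
  ss <- build_splice_site_sequences(toy$sites, toy$gm, toy$genome)
  expect_equal(ss$down_donor_source, "best_window_donor")
  # the only strong GT context in the 350-nt window is the planted
  # GTAAGA donor (the site's own GT at offset +2 is outside the window)
  expect_equal(substr(ss$down5ss_maxent, 4, 5), "GT")
  expect_equal(ss$down5ss_maxent, "AAGGTAAGA")
})

test_that("short upstream exons left-pad the logo with N", {
  toy <- toy_seq_gene()
  gm <- gene_models(tibble::tibble(gene_id = "g", chrom = "c1",
                                   strand = "+",
                                   start = c(121L, 2000L),
                                   end = c(130L, 2049L)))   # 10-nt exon
  ss <- build_splice_site_sequences(toy$sites, gm, toy$genome)
  expect_equal(substr(ss$r5ss_logo, 1, 20), strrep("N", 20))
  expect_equal(ss$r5ss_maxent, "ACGGTAAGT")   # 9-mer needs only 3 nt
})

test_that("cryptic-exon thresholds are enforced", {
  depths <- tibble::tibble(sample_id = c("t", "m"), depth = c(1e6, 1e6),
                           role = c("total_rna", "mrna_control"))
  base_sites <- tibble::tibble(
    site_id = paste0("s", 1:3), gene_id = "g", chrom = "c", strand = "+",
    a_pos = c(1000L, 2000L, 3000L),
    acceptor_pos = c(1002L, 2002L, 3002L), motif = "AGGT",
    intron_ordinal = 1L, intron_length = 60000L)
  mk_counts <- function(up, down) {
    list(
      up = tidyr::expand_grid(site_id = base_sites$site_id,
                              sample_id = c("t", "m")) %>%
        dplyr::mutate(up_count = ifelse(sample_id == "t",
                                        up[match(site_id,
                                                 base_sites$site_id)], 0L),
                      up_rpm = up_count),
      down = tidyr::expand_grid(site_id = base_sites$site_id,
                                sample_id = c("t", "m")) %>%
        dplyr::mutate(down_count = ifelse(sample_id == "t",
                                          down[match(site_id,
                                                     base_sites$site_id)],
                                          0L),
                      down_rpm = down_count))
  }
  ev <- tibble::tibble(site_id = base_sites$site_id,
                       sawtooth_score = 0.2, exon_score = 3,
                       trend_ok = FALSE, bg_coverage = 1)
  cnt <- mk_counts(up = c(12L, 12L, 9L), down = c(4L, 1L, 4L))
  calls <- call_cryptic_exons(cnt$up, cnt$down, base_sites, depths, ev)
  # 12 up / 4 down called; 12 up / 1 down fails min_down;
  # 9 up / 4 down fails min_up
  expect_equal(calls$cryptic_exon, c(TRUE, FALSE, FALSE))
  expect_false(calls$pass_down[2])
  expect_false(calls$pass_up[3])
  # a saw-tooth profile blocks a cryptic call even with the counts
  ev2 <- ev %>% dplyr::mutate(sawtooth_score = 2.5)
  calls2 <- call_cryptic_exons(cnt$up, cnt$down, base_sites, depths, ev2)
  expect_false(any(calls2$cryptic_exon))
})

test_that("up/down correlation uses the standard Pearson machinery", {
  calls <- tibble::tibble(merged_up_count = c(10, 20, 30, 40),
                          merged_down_count = c(3, 6, 9, 12))
  r <- up_down_correlation(calls)
  expect_equal(r$r, 1)
  anti <- tibble::tibble(merged_up_count = c(1, 2, 3),
                         merged_down_count = c(3, 2, 1))
  expect_equal(up_down_correlation(anti)$r, -1)
  # oracle: agrees with stats::cor.test on arbitrary data
  set.seed(3)
  x <- tibble::tibble(merged_up_count = rpois(10, 20),
                      merged_down_count = rpois(10, 6))
  ct <- cor.test(x$merged_up_count, x$merged_down_count)
  got <- up_down_correlation(x)
  expect_equal(got$r, unname(ct$estimate))
  expect_equal(got$p_value, ct$p.value)
  expect_error(up_down_correlation(calls[1:2, ]), "at least 3")
  expect_error(up_down_correlation(
    tibble::tibble(merged_up_count = c(1, 1, 1),
                   merged_down_count = c(1, 2, 3))), "variance")
})

test_that("cryptic calls and RS calls partition the planted sites", {
  fx <- sim_fixture()
  rs <- fixture_rs_result()
  cr <- fixture_cryptic_result()
  rs_called <- rs$calls %>% dplyr::filter(classification == "RS")
  cr_called <- cr$calls %>% dplyr::filter(cryptic_exon)
  expect_equal(length(intersect(site_key(rs_called),
                                site_key(cr_called))), 0L)
  # Down 5'SS of called cryptic exons carries the planted strong donor
  expect_true(all(cr_called$down5ss_maxent == "CAGGTAAGT"))
  # modal down donor equals the planted exon 3' end
  got <- cr_called %>%
    dplyr::inner_join(fx$truth$cryptic_exons %>%
                        dplyr::select(chrom, a_pos,
                                      planted = down_donor_pos),
                      by = c("chrom", "a_pos"))
  expect_equal(got$down_donor_pos, got$planted)
})
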