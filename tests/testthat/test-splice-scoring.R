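
test_that("WMM score of a single-sequence model matches hand arithmetic", {
  m <- splice_model_from_seqs("CAGGTAAGT", rand_acceptors(1, 1),
                              kind = "wmm")
  # uniform-mixture smoothing with weight 0.05 and n=1: an observed
  # base has frequency 0.95 + 0.05/4 = 0.9625, an unobserved one
  # 0.0125; uniform background 0.25
  hi <- log2(0.9625 / 0.25); lo <- log2(0.0125 / 0.25)
  expect_equal(score_donor(m, "CAGGTAAGT"), 9 * hi, tolerance = 1e-12)
  # TAGGTTTTT matches the training sequence at positions 2-5 and 9
  expect_equal(score_donor(m, "TAGGTTTTT"), 5 * hi + 4 * lo,
               tolerance = 1e-12)
})

test_that("input contracts are enforced", {
  m <- splice_model_from_seqs(rand_donors(20, 2), rand_acceptors(20, 3))
  expect_error(score_donor(m, "CAGGTAAG"), "length 9")
  expect_error(score_donor(m, "CAGCTAAGT"), "GT")
  expect_error(score_acceptor(m, "CAGGTAAGT"), "length 23")
  expect_error(score_acceptor(m, paste0(strrep("T", 18), "GGTTT")), "AG")
  expect_error(splice_model_from_seqs("CAGCTAAGT", rand_acceptors(1, 1)),
               "GT")
})

test_that("trained WMM consensus attains the maximum (hill climbing)", {
  donors <- rand_donors(200, 7)
  m <- splice_model_from_seqs(donors, rand_acceptors(5, 8), kind = "wmm")
  # consensus: per-position argmax over the weight matrix
  cons <- paste(rownames(m$donor$wmm)[apply(m$donor$wmm, 2, which.max)],
                collapse = "")
  expect_equal(substr(cons, 4, 5), "GT")
  best <- score_donor(m, cons)
  set.seed(99)
  bases <- c("A", "C", "G", "T")
  free <- c(1:3, 6:9)
  for (i in 1:1000) {
    x <- strsplit(rand_donors(1, 1000 + i), "")[[1]]
    moves <- expand.grid(p = free, b = bases, stringsAsFactors = FALSE)
    repeat {   # greedy hill climb over the free positions
      sc <- score_donor(m, paste(x, collapse = ""))
      ys <- vapply(seq_len(nrow(moves)), function(k) {
        y <- x; y[moves$p[k]] <- moves$b[k]
        paste(y, collapse = "")
      }, character(1))
      cand <- score_donor(m, ys)
      if (max(cand) <= sc + 1e-12) break
      x <- strsplit(ys[which.max(cand)], "")[[1]]
    }
    expect_lte(score_donor(m, paste(x, collapse = "")), best + 1e-9)
  }
})

test_that("scores are invariant to duplicating the training set", {
  donors <- rand_donors(30, 11)
  acceptors <- rand_acceptors(30, 12)
  panel_d <- rand_donors(25, 13)
  panel_a <- rand_acceptors(25, 14)
  for (kind in c("wmm", "markov1")) {
    m1 <- splice_model_from_seqs(donors, acceptors, kind = kind)
    m2 <- splice_model_from_seqs(rep(donors, 3), rep(acceptors, 3),
                                 kind = kind)
    expect_equal(score_donor(m1, panel_d), score_donor(m2, panel_d))
    expect_equal(score_acceptor(m1, panel_a), score_acceptor(m2, panel_a))
  }
})

test_that("scoring tables round-trip with identical scores", {
  panel_d <- rand_donors(100, 31)
  panel_a <- rand_acceptors(100, 32)
  for (kind in c("wmm", "markov1")) {
    m <- splice_model_from_seqs(rand_donors(50, 21), rand_acceptors(50, 22),
                                background = c(A = .3, C = .2, G = .2,
                                               T = .3),
                                kind = kind)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_scoring_tables(m, f)
    m2 <- load_scoring_tables(f)
    expect_equal(m2$trained_kind, "loaded_tables")
    expect_equal(score_donor(m2, panel_d), score_donor(m, panel_d),
                 tolerance = 1e-9)
    expect_equal(score_acceptor(m2, panel_a), score_acceptor(m, panel_a),
                 tolerance = 1e-9)
    # loaded and trained models rank a panel identically
    expect_gt(cor(score_donor(m2, panel_d), score_donor(m, panel_d),
                  method = "spearman"), 0.99)
  }
  # missing entries are rejected with the offending side named
  m <- splice_model_from_seqs(rand_donors(5, 41), rand_acceptors(5, 42))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scoring_tables(m, f)
  tab <- readr::read_tsv(f, show_col_types = FALSE)
  readr::write_tsv(tab[-(which(tab$record == "param" &
                                 tab$side == "donor")[1]), ], f)
  expect_error(load_scoring_tables(f), "donor")
})

test_that("acceptor models trained on pyrimidine tracts prefer them", {
  set.seed(51)
  py_acc <- replicate(40, paste0(
    paste(sample(c("T", "C"), 18, TRUE), collapse = ""), "AG",
    paste(sample(c("A", "C", "G", "T"), 3, TRUE), collapse = "")))
  m <- splice_model_from_seqs(rand_donors(5, 52), py_acc)
  hi <- score_acceptor(m, paste0(strrep("T", 18), "AG", "GTA"))
  lo <- score_acceptor(m, paste0(strrep("A", 18), "AG", "GTA"))
  expect_gt(hi, lo)
})

test_that("annotation-trained models recover the planted donor consensus", {
  fx <- sim_fixture()
  m <- train_splice_model(fx$truth$models, fx$truth$genome, kind = "wmm")
  # annotated donors were planted as exon|GTAAGT
  expect_gt(score_donor(m, "AAGGTAAGT"), score_donor(m, "AAGGTCCCT"))
  # scores depend only on the sequence (translation invariance):
  # scoring the same string twice from different call sites is equal
  expect_equal(score_donor(m, "CAGGTAAGT"), score_donor(m, "CAGGTAAGT"))
})

test_that("context statistics summarise composition and the U1 motif", {
  up <- "TCTCTCTCTCTCTCTCTCTC"   # 50% T, 50% C
  g <- toy_genome(c1 = paste0(strrep("G", 30), up, "AGGTAAGT",
                              strrep("G", 30)))
  sites <- tibble::tibble(site_id = "s", chrom = "c1", strand = "+",
                          a_pos = 51L, motif = "AGGT")
  cs <- context_stats(sites, g)
  expect_equal(cs$composition$pct_t, 50)
  expect_equal(cs$composition$pct_c, 50)
  expect_equal(cs$composition$pct_py, 100)
  expect_equal(cs$aggtaagt_rate, 1)
  expect_equal(colSums(cs$freq), rep(1, 64), ignore_attr = TRUE)
  # all-T upstream gives 100% T
  g2 <- toy_genome(c1 = paste0(strrep("G", 30), strrep("T", 20),
                               "AGGTCCCC", strrep("G", 30)))
  cs2 <- context_stats(sites, g2)
  expect_equal(cs2$composition$pct_t, 100)
  expect_equal(cs2$aggtaagt_rate, 0)
  # a site at the contig edge is skipped with a warning
  sites2 <- dplyr::bind_rows(sites, sites %>%
                               dplyr::mutate(site_id = "edge",
                                             a_pos = 5L))
  expect_warning(cs3 <- context_stats(sites2, g), "skipped")
  expect_equal(cs3$n_skipped, 1L)
  expect_equal(cs3$n_sites, 1L)
})
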