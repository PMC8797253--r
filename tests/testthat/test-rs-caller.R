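
# all eight pass/fail combinations of {intron >= 1 kb, fold > 2,
# count >= 10}
eight_cases <- tibble::tibble(
  site_id = sprintf("x%d", 1:8),
  intron_length = rep(c(5000L, 999L), each = 4),
  total_count = rep(c(12L, 12L, 6L, 6L), 2),
  mrna_count = rep(c(1L, 12L, 1L, 12L), 2)
)

test_that("the cascade reproduces brute-force filter enumeration", {
  fxt <- cascade_fixture(eight_cases)
  calls <- call_candidates(fxt$counts, fxt$sites, fxt$depths)
  # independent oracle: evaluate the three filters per site by hand
  merged <- eight_cases %>%
    dplyr::mutate(total_rpm = rpm(total_count, 2e6),
                  mrna_rpm = rpm(mrna_count, 1e6),
                  merged_count = total_count)
  want <- brute_force_candidates(merged, 1000, 10, 2)
  expect_setequal(calls$site_id[calls$candidate], want)
  expect_equal(sort(calls$site_id[calls$candidate]), "x1")
  # the filter trace follows pipeline order and is complete
  expect_equal(
    names(calls)[grep("^pass_", names(calls))],
    c("pass_intron", "pass_enrichment", "pass_count", "pass_pattern"))
  att <- attrition(calls)
  expect_equal(att$stage, c("sites", "intron_length", "enrichment",
                            "count", "pattern"))
  expect_true(all(diff(att$survivors) <= 0))
})

test_that("worked filter examples behave as specified", {
  mk <- function(total_count, mrna_count, intron_length = 5000L) {
    cascade_fixture(tibble::tibble(site_id = "s",
                                   intron_length = intron_length,
                                   total_count = total_count,
                                   mrna_count = mrna_count))
  }
  # 6+6 replicate reads, 2.4 rpm total vs 0.5 rpm mRNA: candidate
  f <- mk(12L, 1L)
  expect_true(call_candidates(f$counts, f$sites, f$depths)$candidate)
  # merged 12 but mRNA too high (fold <= 2): fails enrichment
  f2 <- mk(12L, 4L)   # total_rpm 6, mrna_rpm 4 -> 6 <= 8
  c2 <- call_candidates(f2$counts, f2$sites, f2$depths)
  expect_false(c2$candidate)
  expect_false(c2$pass_enrichment)
  expect_true(c2$pass_count)
  # zero mRNA with any total signal passes (fold effectively infinite)
  f3 <- mk(12L, 0L)
  c3 <- call_candidates(f3$counts, f3$sites, f3$depths)
  expect_true(c3$pass_enrichment)
  expect_true(is.finite(c3$fold_enrichment))   # pseudocounted display
  expect_error(call_candidates(f3$counts, f3$sites,
                               f3$depths %>%
                                 dplyr::filter(role == "total_rna")),
               "mRNA control")
})

test_that("candidate sets are monotone in min_count and min_fold", {
  set.seed(8)
  tbl <- tibble::tibble(
    site_id = sprintf("s%02d", 1:40),
    intron_length = sample(c(800L, 2000L, 60000L), 40, TRUE),
    total_count = as.integer(rpois(40, 9)),
    mrna_count = as.integer(rpois(40, 2)))
  fxt <- cascade_fixture(tbl)
  sets <- list()
  for (mc in c(5, 10)) for (mf in c(1, 2)) {
    calls <- call_candidates(fxt$counts, fxt$sites, fxt$depths,
                             min_count = mc, min_fold = mf)
    sets[[paste(mc, mf)]] <- calls$site_id[calls$candidate]
  }
  expect_true(all(sets[["10 2"]] %in% sets[["5 2"]]))
  expect_true(all(sets[["10 2"]] %in% sets[["10 1"]]))
  expect_true(all(sets[["10 1"]] %in% sets[["5 1"]]))
  expect_true(all(sets[["5 2"]] %in% sets[["5 1"]]))
})

test_that("the AGNN pattern filter removes canonical AGGT", {
  fxt <- cascade_fixture(eight_cases[1:2, ])
  fxt$sites$motif <- c("AGGT", "AGCA")
  calls <- call_candidates(fxt$counts, fxt$sites, fxt$depths,
                           exclude_nn = "GT")
  expect_false(calls$pass_pattern[calls$motif == "AGGT"])
  expect_true(calls$pass_pattern[calls$motif == "AGCA"])
})

test_that("classification follows the evidence hierarchy", {
  fxt <- cascade_fixture(eight_cases)
  calls <- call_candidates(fxt$counts, fxt$sites, fxt$depths,
                           min_count = 5, min_fold = 0.1)
  ev <- tibble::tibble(
    site_id = calls$site_id,
    sawtooth_score = c(2.5, 0.3, 0.2, 0.1, 2.5, 0, 0, 0),
    trend_ok = c(TRUE, FALSE, FALSE, FALSE, TRUE, rep(FALSE, 3)),
    exon_score = c(0.5, 3.2, 0.3, 0.2, 0.1, 0, 0, 0),
    bg_coverage = c(5, 5, 5, 0.001, 1, 0, 0, 0))
  cls <- classify_candidates(calls, ev)
  got <- setNames(cls$classification, cls$site_id)
  expect_equal(unname(got[c("x1", "x2", "x3", "x4")]),
               c("RS", "unannotated_exon", "nascent_transcript",
                 "unknown"))
  # sites that failed the cascade stay "fail" whatever the evidence
  expect_true(all(got[!cls$candidate] == "fail"))
  # a high saw-tooth score without declining trends is not RS
  ev2 <- ev %>% dplyr::mutate(trend_ok = FALSE)
  cls2 <- classify_candidates(calls, ev2)
  expect_false(any(cls2$classification == "RS"))
  expect_error(classify_candidates(calls, ev[-1, ]), "evidence")
})

test_that("site-set comparison partitions by genomic key", {
  a <- tibble::tibble(chrom = "c", a_pos = c(1L, 2L), strand = "+")
  expect_true(all(compare_site_sets(a, a)$set == "shared"))
  b <- tibble::tibble(chrom = "c", a_pos = c(2L, 3L), strand = "+")
  cmp <- compare_site_sets(a, b)
  expect_equal(cmp$set[cmp$a_pos == 1], "only_a")
  expect_equal(cmp$set[cmp$a_pos == 2], "shared")
  expect_equal(cmp$set[cmp$a_pos == 3], "only_b")
  # two simulated cell types sharing truth: shared set equals the truth
  fx <- sim_fixture()
  rs <- fixture_rs_result()
  called <- rs$calls %>% dplyr::filter(classification == "RS")
  cmp2 <- compare_site_sets(called, fx$truth$rs_sites)
  expect_true(all(cmp2$set == "shared"))
})
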