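#' Apply the RS candidate filtering cascade
#'
#' Evaluates every site against the pipeline filters, in pipeline
#' order: (1) host intron at least `min_intron` nt; (2) pooled
#' total-RNA junction RPM strictly greater than `min_fold` times the
#' pooled mRNA-control RPM (strict inequality, so an mRNA RPM of 0 with
#' any total signal passes — fold is effectively infinite); (3)
#' replicate-merged raw up-junction count at least `min_count`; (4)
#' motif-pattern filter (used by the AGNN pipeline to exclude NN ==
#' GT).  Every decision is recorded in `pass_*` columns, so the filter
#' trace of each site can be reproduced, and per-stage survivor counts
#' are attached as the `"attrition"` attribute (see [attrition()]).
#'
#' For display, `fold_enrichment` uses a 0.5-read pseudocount on the
#' mRNA side so it stays finite; the enrichment *filter* uses the raw
#' strict inequality.
#'
#' @param site_counts Tibble `site_id, sample_id, up_count` from
#'   [count_up_junctions()].
#' @param sites Site tibble from [scan_motif_sites()] (supplies intron
#'   annotation and motif).
#' @param depths Tibble `sample_id, depth, role`; must contain at least
#'   one `total_rna` and one `mrna_control` sample.
#' @param min_intron Minimum host-intron length in nt (default 1000).
#' @param min_count Minimum merged up-junction count (default 10).
#' @param min_fold Enrichment factor over mRNA (default 2).
#' @param exclude_nn Optional 2-mer: sites whose motif positions 3-4
#'   equal it fail the pattern filter (the AGNN pipeline uses
#'   `exclude_nn = "GT"` to remove canonical AGGT).
#' @return Tibble with one row per site: identification columns, merged
#'   counts and RPMs, `fold_enrichment`, the ordered `pass_intron,
#'   pass_enrichment, pass_count, pass_pattern` trace and the final
#'   `candidate` flag.
#' @export
call_candidates <- function(site_counts, sites, depths,
                            min_intron = 1000, min_count = 10,
                            min_fold = 2, exclude_nn = NULL) {
  check_cols(depths, c("sample_id", "depth", "role"), "depths")
  if (!any(depths$role == "mrna_control")) {
    abort("no mRNA control sample: the enrichment filter is undefined")
  }
  if (!any(depths$role == "total_rna")) {
    abort("no total RNA sample provided")
  }
  merged <- merge_replicates(site_counts, depths)
  mrna_depth <- sum(depths$depth[depths$role == "mrna_control"])
  out <- sites %>%
    inner_join(merged, by = "site_id") %>%
    mutate(
      fold_enrichment = .data$total_rpm /
        rpm(.data$mrna_count + 0.5, mrna_depth),
      pass_intron = !is.na(.data$intron_length) &
        .data$intron_length >= min_intron,
      pass_enrichment = .data$total_rpm > min_fold * .data$mrna_rpm,
      pass_count = .data$merged_up_count >= min_count,
      pass_pattern = if (is.null(exclude_nn)) TRUE else {
        substr(.data$motif, 3L, 4L) != toupper(exclude_nn)
      },
      candidate = .data$pass_intron & .data$pass_enrichment &
        .data$pass_count & .data$pass_pattern
    )
  att <- tibble(
    stage = c("sites", "intron_length", "enrichment", "count", "pattern"),
    survivors = c(
      nrow(out),
      sum(out$pass_intron),
      sum(out$pass_intron & out$pass_enrichment),
      sum(out$pass_intron & out$pass_enrichment & out$pass_count),
      sum(out$candidate)
    )
  )
  attr(out, "attrition") <- att
  out
}

#' Per-stage survivor counts of a filter cascade
#'
#' @param calls Result of [call_candidates()].
#' @return Tibble `stage, survivors` in pipeline order.
#' @export
attrition <- function(calls) {
  att <- attr(calls, "attrition")
  if (is.null(att)) abort("object carries no attrition record")
  att
}

#' Classify candidates from coverage evidence
#'
#' Automates the visual triage of candidates using the saw-tooth and
#' exon-likeness evidence: a candidate is classified `RS` when its
#' saw-tooth score reaches `tau_saw` (and, when `require_trend`, both
#' flanks decline); otherwise `unannotated_exon` when exon-likeness
#' reaches `tau_exon`; otherwise `nascent_transcript` when the host
#' intron carries background coverage of at least `tau_bg` reads per
#' base; otherwise `unknown`.  Sites that failed the cascade are
#' classified `fail`.
#'
#' @param calls Tibble from [call_candidates()].
#' @param evidence Tibble from [sawtooth_evidence()] (needs `site_id,
#'   sawtooth_score, trend_ok, exon_score, bg_coverage`).
#' @param tau_saw Saw-tooth score threshold in log2 units (default 1).
#' @param tau_exon Exon-likeness threshold in log2 units (default 2).
#' @param tau_bg Background-coverage threshold in reads/base (default
#'   0.05).
#' @param require_trend Require declining flank trends for an RS call
#'   (default TRUE).
#' @return `calls` with evidence columns and a `classification` column
#'   over {RS, unannotated_exon, nascent_transcript, unknown, fail}.
#' @export
classify_candidates <- function(calls, evidence, tau_saw = 1,
                                tau_exon = 2, tau_bg = 0.05,
                                require_trend = TRUE) {
  check_cols(evidence, c("site_id", "sawtooth_score", "trend_ok",
                         "exon_score", "bg_coverage"), "evidence")
  out <- calls %>%
    left_join(evidence %>%
                select("site_id", "sawtooth_score", "trend_ok",
                       "exon_score", "bg_coverage"),
              by = "site_id")
  need <- out$candidate & is.na(out$sawtooth_score)
  if (any(need)) {
    abort(paste0("missing coverage evidence for candidate site(s): ",
                 paste(head(out$site_id[need], 3L), collapse = ", ")))
  }
  saw_ok <- out$sawtooth_score >= tau_saw &
    (!require_trend | out$trend_ok)
  cls <- dplyr::case_when(
    !out$candidate ~ "fail",
    saw_ok ~ "RS",
    out$exon_score >= tau_exon ~ "unannotated_exon",
    out$bg_coverage >= tau_bg ~ "nascent_transcript",
    TRUE ~ "unknown"
  )
  out$classification <- cls
  attr(out, "attrition") <- attr(calls, "attrition")
  out
}

#' Compare two RS site sets
#'
#' Partitions the union of two call sets by genomic site key
#' `(chrom, a_pos, strand)` — e.g. calls from two cell types or sexes.
#'
#' @param calls_a,calls_b Tibbles carrying `chrom, a_pos, strand`
#'   (typically classified calls filtered to one class).
#' @return Tibble `chrom, a_pos, strand, set` with `set` in
#'   {`shared`, `only_a`, `only_b`}.
#' @export
compare_site_sets <- function(calls_a, calls_b) {
  key <- c("chrom", "a_pos", "strand")
  a <- calls_a %>% distinct(across(all_of(key)))
  b <- calls_b %>% distinct(across(all_of(key)))
  bind_rows(
    semi_join(a, b, by = key) %>% mutate(set = "shared"),
    anti_join(a, b, by = key) %>% mutate(set = "only_a"),
    anti_join(b, a, by = key) %>% mutate(set = "only_b")
  ) %>% arrange(.data$chrom, .data$a_pos)
}
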