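# matching splice junctions to motif-site acceptors (up-junctions) and
# to downstream annotated exons (down-junctions)
#
# All boundary arithmetic is done in gene-sense orientation.  For a
# minus-strand gene the acceptor side of a junction is the
# lower-coordinate gap edge on the reference: walking the reference a
# junction is (donor_end | gap | acceptor_start), but in transcription
# order the higher-coordinate block comes first, so the sense donor
# boundary is `acceptor_start` and the sense acceptor boundary is
# `donor_end`.

# collapsed-exon sense boundaries per gene: sense 3' end (a proper
# donor position) and sense 5' start (an acceptor position)
exon_sense_boundaries <- function(models) {
  models$exons %>%
    mutate(
      sense_end = if_else(.data$strand == "+", .data$end, .data$start),
      sense_start = if_else(.data$strand == "+", .data$start, .data$end)
    ) %>%
    select("gene_id", "strand", "start", "end", "sense_end", "sense_start")
}

# keep junctions whose read strand is compatible with the gene strand
match_junction_strand <- function(junctions, strandedness) {
  if (strandedness == "unstranded") return(junctions)
  junctions %>%
    filter(effective_strand(.data$strand, strandedness) == .data$gene_strand)
}

#' Count up-junction reads at motif sites
#'
#' An up-junction read is the footprint of the upstream RS splicing
#' intermediate: a junction whose gene-sense acceptor boundary equals
#' the site's `acceptor_pos` (the first base after AG, i.e. the G of
#' GT) and whose gene-sense donor boundary equals the 3' end of a
#' collapsed exon of the same gene upstream of the site.  Matching is
#' exact — aligners report junction boundaries exactly.
#'
#' Counts are reported for every sample in `depths` (zero-filled) with
#' RPM normalization.  The column `up_count_anyexon` additionally counts
#' junctions under the looser rule that the donor falls anywhere inside
#' an upstream exon; a difference flags donors at non-annotated exonic
#' positions.
#'
#' @param junctions Tibble from [extract_junctions()] (any number of
#'   samples, identified by `sample_id`).
#' @param sites Tibble from [scan_motif_sites()].
#' @param models A [gene_models()] object.
#' @param depths Tibble `sample_id, depth, role` with `depth` the
#'   uniquely mapped read count and `role` one of `"total_rna"`,
#'   `"mrna_control"`.
#' @param strandedness Library strandedness (see
#'   [count_exonic_reads()]).
#' @return Tibble `site_id, sample_id, up_count, up_rpm,
#'   up_count_anyexon`.
#' @export
count_up_junctions <- function(junctions, sites, models, depths,
                               strandedness = "forward") {
  stopifnot(inherits(models, "gene_models"))
  check_cols(depths, c("sample_id", "depth"), "depths")
  if (any(depths$depth <= 0)) abort("depth missing or non-positive")
  ex <- exon_sense_boundaries(models)

  s <- sites %>%
    select("site_id", "gene_id", "chrom", gene_strand = "strand",
           "a_pos", "acceptor_pos")
  # sense acceptor/donor boundary of each junction given the gene strand
  j <- junctions %>%
    inner_join(s %>% distinct(.data$chrom, .data$gene_strand),
               by = "chrom", relationship = "many-to-many")
  j <- match_junction_strand(j, strandedness) %>%
    mutate(
      sense_acc = if_else(.data$gene_strand == "+",
                          .data$acceptor_start, .data$donor_end),
      sense_don = if_else(.data$gene_strand == "+",
                          .data$donor_end, .data$acceptor_start)
    )
  hit <- j %>%
    inner_join(s, by = c("chrom", "gene_strand", "sense_acc" = "acceptor_pos"))
  # strict rule: donor equals an upstream collapsed-exon 3' end
  upstream_of <- function(don, a_pos, strand) {
    if_else(strand == "+", don < a_pos, don > a_pos)
  }
  strict <- hit %>%
    semi_join(ex, by = c("gene_id", "sense_don" = "sense_end")) %>%
    filter(upstream_of(.data$sense_don, .data$a_pos, .data$gene_strand))
  loose <- hit %>%
    inner_join(ex %>% select("gene_id", ex_start = "start", ex_end = "end"),
               by = dplyr::join_by("gene_id", "sense_don" >= "ex_start",
                                   "sense_don" <= "ex_end")) %>%
    filter(upstream_of(.data$sense_don, .data$a_pos, .data$gene_strand)) %>%
    distinct(.data$site_id, .data$sample_id, .data$read_id,
             .data$sense_acc)

  grid <- tidyr::expand_grid(site_id = sites$site_id,
                             sample_id = depths$sample_id)
  grid %>%
    left_join(strict %>% count(.data$site_id, .data$sample_id,
                               name = "up_count"),
              by = c("site_id", "sample_id")) %>%
    left_join(loose %>% count(.data$site_id, .data$sample_id,
                              name = "up_count_anyexon"),
              by = c("site_id", "sample_id")) %>%
    mutate(across(c("up_count", "up_count_anyexon"),
                  ~ dplyr::coalesce(.x, 0L))) %>%
    left_join(depths %>% select("sample_id", "depth"), by = "sample_id") %>%
    mutate(up_rpm = rpm(.data$up_count, .data$depth)) %>%
    select("site_id", "sample_id", "up_count", "up_rpm", "up_count_anyexon")
}

#' Count down-junction reads and locate the RS-exon 3' end
#'
#' A down-junction read is the footprint of the downstream splicing
#' intermediate: a junction whose gene-sense donor boundary lies within
#' `window` nt sense-downstream of the site's acceptor (boundary
#' exclusive at the acceptor, inclusive at `acceptor_pos + window`) and
#' whose gene-sense acceptor boundary coincides with the sense start of
#' an annotated collapsed exon of the same gene downstream of the site.
#' The modal donor position over total-RNA samples is recorded per site
#' as the putative RS-exon 3' end (`down_donor_pos`, reference
#' coordinate of the last exonic base).
#'
#' @inheritParams count_up_junctions
#' @param window Scan window in nt sense-downstream of the site
#'   (default 350).
#' @return List with `counts` (tibble `site_id, sample_id, down_count,
#'   down_rpm`) and `donors` (tibble `site_id, down_donor_pos,
#'   down_donor_reads`).
#' @export
count_down_junctions <- function(junctions, sites, models, depths,
                                 window = 350, strandedness = "forward") {
  stopifnot(inherits(models, "gene_models"))
  if (window <= 0) abort("window must be positive")
  ex <- exon_sense_boundaries(models)
  s <- sites %>%
    select("site_id", "gene_id", "chrom", gene_strand = "strand",
           "a_pos", "acceptor_pos")
  j <- junctions %>%
    inner_join(s %>% distinct(.data$chrom, .data$gene_strand),
               by = "chrom", relationship = "many-to-many")
  j <- match_junction_strand(j, strandedness) %>%
    mutate(
      sense_acc = if_else(.data$gene_strand == "+",
                          .data$acceptor_start, .data$donor_end),
      sense_don = if_else(.data$gene_strand == "+",
                          .data$donor_end, .data$acceptor_start)
    )
  # junction acceptor must be an annotated exon sense-start downstream
  j <- j %>%
    inner_join(ex %>% select("gene_id", "sense_start"),
               by = c("sense_acc" = "sense_start"),
               relationship = "many-to-many")
  hit <- j %>%
    inner_join(s, by = c("chrom", "gene_strand", "gene_id"),
               relationship = "many-to-many") %>%
    mutate(dist = if_else(.data$gene_strand == "+",
                          .data$sense_don - .data$acceptor_pos,
                          .data$acceptor_pos - .data$sense_don),
           acc_dist = if_else(.data$gene_strand == "+",
                              .data$sense_acc - .data$a_pos,
                              .data$a_pos - .data$sense_acc)) %>%
    filter(.data$dist >= 1, .data$dist <= window, .data$acc_dist > 0)

  grid <- tidyr::expand_grid(site_id = sites$site_id,
                             sample_id = depths$sample_id)
  counts <- grid %>%
    left_join(hit %>% count(.data$site_id, .data$sample_id,
                            name = "down_count"),
              by = c("site_id", "sample_id")) %>%
    mutate(down_count = dplyr::coalesce(.data$down_count, 0L)) %>%
    left_join(depths %>% select("sample_id", "depth"), by = "sample_id") %>%
    mutate(down_rpm = rpm(.data$down_count, .data$depth)) %>%
    select("site_id", "sample_id", "down_count", "down_rpm")

  total_ids <- if ("role" %in% names(depths)) {
    depths$sample_id[depths$role == "total_rna"]
  } else depths$sample_id
  donors <- hit %>%
    filter(.data$sample_id %in% total_ids) %>%
    group_by(.data$site_id) %>%
    summarise(down_donor_pos = as.integer(modal_value(.data$sense_don)),
              down_donor_reads = sum(.data$sense_don ==
                                       modal_value(.data$sense_don)),
              .groups = "drop")
  list(counts = counts, donors = donors)
}

#' Merge biological replicates of junction counts
#'
#' Counts of biological replicates are summed per site and role, and
#' the pooled RPM is `sum(counts) / sum(depths) * 1e6` over the
#' replicates of each role.
#'
#' @param site_counts Tibble `site_id, sample_id, up_count` from
#'   [count_up_junctions()] (a `down_count` column, if present, is
#'   merged the same way).
#' @param depths Tibble `sample_id, depth, role`.
#' @return Tibble `site_id, merged_up_count, total_rpm, mrna_count,
#'   mrna_rpm` (plus `merged_down_count` when down counts were given).
#'   Roles missing from `depths` yield an error downstream, not here.
#' @export
merge_replicates <- function(site_counts, depths) {
  check_cols(site_counts, c("site_id", "sample_id", "up_count"),
             "site_counts")
  check_cols(depths, c("sample_id", "depth", "role"), "depths")
  has_down <- "down_count" %in% names(site_counts)
  x <- site_counts %>%
    inner_join(depths %>% select("sample_id", "depth", "role"),
               by = "sample_id")
  role_depth <- depths %>%
    group_by(.data$role) %>%
    summarise(role_depth = sum(.data$depth), .groups = "drop")
  agg <- x %>%
    group_by(.data$site_id, .data$role) %>%
    summarise(up = sum(.data$up_count),
              down = if (has_down) sum(.data$down_count) else NA_integer_,
              .groups = "drop") %>%
    left_join(role_depth, by = "role") %>%
    mutate(rpm = rpm(.data$up, .data$role_depth))
  wide <- agg %>%
    select("site_id", "role", "up", "down", "rpm") %>%
    tidyr::pivot_wider(names_from = "role",
                       values_from = c("up", "down", "rpm"),
                       values_fill = list(up = 0L, down = 0L, rpm = 0))
  out <- tibble(site_id = wide$site_id)
  out$merged_up_count <- wide[["up_total_rna"]] %||% rep(0L, nrow(wide))
  out$total_rpm <- wide[["rpm_total_rna"]] %||% rep(0, nrow(wide))
  out$mrna_count <- wide[["up_mrna_control"]] %||% rep(0L, nrow(wide))
  out$mrna_rpm <- wide[["rpm_mrna_control"]] %||% rep(0, nrow(wide))
  if (has_down) {
    out$merged_down_count <- wide[["down_total_rna"]] %||%
      rep(0L, nrow(wide))
  }
  out
}
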