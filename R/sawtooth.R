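# saw-tooth coverage analytics: nascent-transcript coverage declines
# toward each splice point and steps UP immediately after an RS site
# (the next segment persists longer before being spliced), so the
# statistic is oriented downstream-over-upstream.

#' Per-base and binned coverage over an intron, sense-oriented
#'
#' Depth is computed from aligned reference blocks (`N` gaps contribute
#' nothing) and reported in sense orientation: position 1 is the intron
#' 5' end in the direction of transcription.
#'
#' @param alignments Tibble from [read_sam()] (pool replicates by
#'   row-binding before calling).
#' @param intron One-row data frame (or list) with `chrom, start, end,
#'   strand` — typically a row of `models$introns`.
#' @param bin_size Bin width in nt for the binned summary (default
#'   200).
#' @param strandedness Library strandedness; reads whose effective
#'   strand does not match the intron strand are ignored (unless
#'   `"unstranded"`).
#' @param chrom_length Optional contig length for a bounds check.
#' @return A `coverage_profile` object: list with the intron
#'   coordinates, `depth` (per-base, sense order) and `bins` (per-bin
#'   mean depth, `ceiling(length / bin_size)` bins).
#' @export
intron_coverage <- function(alignments, intron, bin_size = 200,
                            strandedness = "forward",
                            chrom_length = NULL) {
  if (bin_size < 1) abort("bin_size must be >= 1")
  intron <- as.list(intron)
  if (intron$start < 1 ||
      (!is.null(chrom_length) && intron$end > chrom_length)) {
    abort("intron outside reference bounds")
  }
  len <- intron$end - intron$start + 1L
  blocks <- if (isTRUE(attr(alignments, "ref_blocks"))) alignments else
    cigar_ref_blocks(alignments)
  blocks <- blocks %>% filter(.data$chrom == intron$chrom)
  if (strandedness != "unstranded") {
    blocks <- blocks %>%
      filter(effective_strand(.data$strand, strandedness) == intron$strand)
  }
  blocks <- blocks %>%
    filter(.data$end >= intron$start, .data$start <= intron$end)
  depth <- numeric(len)
  if (nrow(blocks) > 0L) {
    ir <- IRanges::IRanges(pmax(blocks$start, intron$start) - intron$start + 1L,
                           pmin(blocks$end, intron$end) - intron$start + 1L)
    depth <- as.numeric(IRanges::coverage(ir, width = len))
  }
  if (intron$strand == "-") depth <- rev(depth)
  nb <- ceiling(len / bin_size)
  idx <- rep(seq_len(nb), each = bin_size, length.out = len)
  bins <- as.numeric(tapply(depth, idx, mean))
  structure(list(chrom = intron$chrom, start = intron$start,
                 end = intron$end, strand = intron$strand,
                 bin_size = bin_size, depth = depth, bins = bins),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat("<coverage_profile> ", x$chrom, ":", x$start, "-", x$end, " (",
      x$strand, "), ", length(x$depth), " nt, mean depth ",
      signif(mean(x$depth), 3), "\n", sep = "")
  invisible(x)
}

#' @describeIn intron_coverage `tidy()` returns one row per bin with
#'   the sense bin index, the reference coordinate of the bin's
#'   sense-first base and the mean depth.
#' @param x A `coverage_profile`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.coverage_profile <- function(x, ...) {
  nb <- length(x$bins)
  sense_start <- (seq_len(nb) - 1L) * x$bin_size + 1L
  ref_start <- if (x$strand == "+") {
    x$start + sense_start - 1L
  } else {
    x$end - sense_start + 1L
  }
  tibble(bin = seq_len(nb), sense_start = sense_start,
         ref_pos = ref_start, depth = x$bins)
}

# sense offset of a reference position inside a profiled intron
sense_offset <- function(profile, ref_pos) {
  if (ref_pos < profile$start || ref_pos > profile$end) {
    abort("site is not inside the profiled intron")
  }
  if (profile$strand == "+") {
    ref_pos - profile$start + 1L
  } else {
    profile$end - ref_pos + 1L
  }
}

spearman_rho <- function(x) {
  if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
  suppressWarnings(cor(seq_along(x), x, method = "spearman"))
}

#' Saw-tooth step score at a candidate RS site
#'
#' `score = log2((mean depth over W nt sense-downstream of the site +
#' eps) / (mean depth over W nt sense-upstream + eps))` — positive when
#' coverage steps up just after the site, the saw-tooth signature.  The
#' upstream window ends at the base before the site's A; the downstream
#' window starts at the retained G of GT.  When a flank is shorter than
#' `W`, both windows shrink to the shorter flank and the result is
#' flagged.  Additionally each flank must decline along the sense
#' direction (Spearman rank correlation of binned depth against
#' position at most `rho_max`) for `trend_ok`.
#'
#' @param profile A `coverage_profile` of the host intron (from
#'   [intron_coverage()]).
#' @param a_pos Reference coordinate of the site's sense-strand A.
#' @param W Flank window in nt (default 5000).
#' @param eps Pseudo-depth guarding against division blow-ups in sparse
#'   introns (default 0.1 reads per base).
#' @param rho_max Maximum Spearman rho for a declining trend (default
#'   -0.3).
#' @param trend_bin Bin width for the trend test (default 200 nt).
#' @return One-row tibble `up_mean, down_mean, sawtooth_score,
#'   trend_up_rho, trend_down_rho, trend_ok, W_used, shrunk`.
#' @export
sawtooth_score <- function(profile, a_pos, W = 5000, eps = 0.1,
                           rho_max = -0.3, trend_bin = 200) {
  stopifnot(inherits(profile, "coverage_profile"))
  s0 <- sense_offset(profile, a_pos)
  len <- length(profile$depth)
  avail_up <- s0 - 1L
  avail_down <- len - s0 - 1L
  if (avail_up < 1L || avail_down < 1L) {
    abort("site has an empty flank inside the intron")
  }
  W_used <- min(W, avail_up, avail_down)
  up <- profile$depth[(s0 - W_used):(s0 - 1L)]
  down <- profile$depth[(s0 + 2L):(s0 + 1L + W_used)]
  bin_means <- function(v) {
    idx <- rep(seq_len(ceiling(length(v) / trend_bin)), each = trend_bin,
               length.out = length(v))
    as.numeric(tapply(v, idx, mean))
  }
  rho_up <- spearman_rho(bin_means(up))
  rho_down <- spearman_rho(bin_means(down))
  tibble(
    up_mean = mean(up), down_mean = mean(down),
    sawtooth_score = log2((mean(down) + eps) / (mean(up) + eps)),
    trend_up_rho = rho_up, trend_down_rho = rho_down,
    trend_ok = isTRUE(rho_up <= rho_max) && isTRUE(rho_down <= rho_max),
    W_used = W_used, shrunk = W_used < W
  )
}

#' Exon-likeness of local coverage at a site
#'
#' Contrasts mean depth inside the putative exon — from the site's
#' acceptor to `down_donor_pos`, or `window` nt when no donor was
#' observed — with the average of the two flanking windows:
#' `log2((inside + eps) / (mean of flank means + eps))`.  A planted
#' cryptic exon with k-fold local coverage scores about `log2(k)`; a
#' saw-tooth RS site scores low because its downstream flank is as high
#' as the exon region.
#'
#' @inheritParams sawtooth_score
#' @param down_donor_pos Reference coordinate of the observed down-
#'   junction donor (exon 3' end), or `NULL`.
#' @param window Fallback exon extent in nt when no donor is observed
#'   (default 350).
#' @param flank Flanking window in nt (default 5000).
#' @return One-row tibble `inside_mean, flank_mean, exon_score,
#'   exon_len_used`.
#' @export
exon_likeness <- function(profile, a_pos, down_donor_pos = NULL,
                          window = 350, flank = 5000, eps = 0.1) {
  stopifnot(inherits(profile, "coverage_profile"))
  s0 <- sense_offset(profile, a_pos)
  len <- length(profile$depth)
  e_end <- if (!is.null(down_donor_pos) && !is.na(down_donor_pos)) {
    sense_offset(profile, down_donor_pos)
  } else {
    min(s0 + 1L + window, len)
  }
  e_start <- min(s0 + 2L, len)
  if (e_end < e_start) e_end <- e_start
  inside <- profile$depth[e_start:e_end]
  up_ix <- max(1L, s0 - flank):max(1L, s0 - 1L)
  down_ix <- min(len, e_end + 1L):min(len, e_end + flank)
  flank_mean <- mean(c(mean(profile$depth[up_ix]),
                       mean(profile$depth[down_ix])))
  tibble(
    inside_mean = mean(inside), flank_mean = flank_mean,
    exon_score = log2((mean(inside) + eps) / (flank_mean + eps)),
    exon_len_used = e_end - e_start + 1L
  )
}

#' Coverage evidence for a set of candidate sites
#'
#' Computes, per site, the saw-tooth score, the flank trend
#' diagnostics, the exon-likeness score and the background intron
#' coverage, profiling each host intron once.  This is the automated
#' stand-in for visual inspection of saw-tooth patterns; every call
#' carries the underlying numbers so a human can re-inspect.
#'
#' @param alignments Pooled total-RNA alignments (tibble from
#'   [read_sam()], replicates row-bound).
#' @param sites Site tibble (must carry `site_id, gene_id, chrom,
#'   strand, a_pos`); sites outside introns are skipped.
#' @param models A [gene_models()] object.
#' @param down_donors Optional tibble `site_id, down_donor_pos` from
#'   [count_down_junctions()].
#' @param W,eps,rho_max,window,flank,bin_size,strandedness Tuning
#'   parameters passed through to [sawtooth_score()],
#'   [exon_likeness()] and [intron_coverage()].
#' @return Tibble `site_id, sawtooth_score, up_mean, down_mean,
#'   trend_up_rho, trend_down_rho, trend_ok, exon_score, bg_coverage,
#'   W_used, shrunk`.
#' @export
sawtooth_evidence <- function(alignments, sites, models,
                              down_donors = NULL, W = 5000, eps = 0.1,
                              rho_max = -0.3, window = 350, flank = 5000,
                              bin_size = 200, strandedness = "forward") {
  stopifnot(inherits(models, "gene_models"))
  sites <- sites %>% filter(!is.na(.data$intron_ordinal))
  if (nrow(sites) == 0L) {
    return(tibble(site_id = character(), sawtooth_score = numeric(),
                  up_mean = numeric(), down_mean = numeric(),
                  trend_up_rho = numeric(), trend_down_rho = numeric(),
                  trend_ok = logical(), exon_score = numeric(),
                  bg_coverage = numeric(), W_used = integer(),
                  shrunk = logical()))
  }
  with_introns <- sites %>%
    inner_join(models$introns %>%
                 select("gene_id", "ordinal", int_start = "start",
                        int_end = "end"),
               by = c("gene_id", "intron_ordinal" = "ordinal"))
  if (!is.null(down_donors)) {
    with_introns <- with_introns %>%
      left_join(down_donors %>% select("site_id", "down_donor_pos"),
                by = "site_id")
  } else {
    with_introns$down_donor_pos <- NA_integer_
  }
  blocks <- cigar_ref_blocks(alignments)   # parse CIGARs once
  attr(blocks, "ref_blocks") <- TRUE
  with_introns %>%
    group_by(.data$gene_id, .data$int_start, .data$int_end,
             .data$chrom, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      prof <- intron_coverage(
        blocks,
        list(chrom = key$chrom, start = key$int_start,
             end = key$int_end, strand = key$strand),
        bin_size = bin_size, strandedness = strandedness)
      bg <- mean(prof$depth)
      purrr::pmap(list(d$site_id, d$a_pos, d$down_donor_pos),
                  function(sid, ap, ddp) {
        st <- sawtooth_score(prof, ap, W = W, eps = eps,
                             rho_max = rho_max)
        ex <- exon_likeness(prof, ap,
                            down_donor_pos = if (is.na(ddp)) NULL else ddp,
                            window = window, flank = flank, eps = eps)
        dplyr::bind_cols(tibble(site_id = sid), st,
                         ex %>% select("exon_score"),
                         tibble(bg_coverage = bg))
      }) %>% bind_rows()
    }) %>%
    ungroup() %>%
    select("site_id", "sawtooth_score", "up_mean", "down_mean",
           "trend_up_rho", "trend_down_rho", "trend_ok", "exon_score",
           "bg_coverage", "W_used", "shrunk")
}
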