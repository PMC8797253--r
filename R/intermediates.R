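# splicing-intermediate sequence analyses: reconstituted 5'SS (r5'SS),
# downstream 5'SS, cryptic-exon calling, up/down correlation

# genomic sense sequence at [pos_lo..pos_hi] in *sense* coordinates
# relative to a site; N-padded where it runs off the contig
sense_slice <- function(genome, chrom, strand, sense_anchor, lo_off, hi_off) {
  w <- length(genome[[chrom]])
  if (strand == "+") {
    lo <- sense_anchor + lo_off; hi <- sense_anchor + hi_off
  } else {
    lo <- sense_anchor - hi_off; hi <- sense_anchor - lo_off
  }
  pad_l <- max(0L, 1L - lo); pad_r <- max(0L, hi - w)
  lo <- max(1L, lo); hi <- min(w, hi)
  if (hi < lo) return(strrep("N", hi_off - lo_off + 1L))
  core <- sense_seq(genome, chrom, lo, hi, strand)
  if (strand == "+") {
    paste0(strrep("N", pad_l), core, strrep("N", pad_r))
  } else {
    paste0(strrep("N", pad_r), core, strrep("N", pad_l))
  }
}

# similarity fallback when no donor model is supplied: matches to the
# U1-pairing consensus following the donor boundary
consensus_donor_score <- function(seqs) {
  ref <- strsplit("CAGGTAAGT", "")[[1L]]
  vapply(strsplit(seqs, ""), function(x) sum(x == ref), numeric(1))
}

#' Build r5'SS and Down 5'SS sequences for sites
#'
#' For each site, constructs the reconstituted 5' splice site — the
#' last 30 nt of the upstream collapsed exon, the GT of AGGT, and the
#' 20 nt following AGGT (52-mer "logo" flavour), plus the 9-mer
#' scoring flavour (3 exonic nt + GT + 4 nt) — and the downstream 5'SS
#' at the 3' end of the RS/cryptic exon.  The Down 5'SS donor is the
#' observed modal down-junction donor when available
#' (`down_donor_source = "observed_junction"`); otherwise the
#' best-scoring GT within `window` nt sense-downstream of the site
#' (`"best_window_donor"`, scored by `donor_model` or by similarity to
#' the CAGGTAAGT consensus); `"none"` when no GT exists in the window.
#'
#' An upstream exon shorter than 30 nt left-pads the logo sequence
#' with N; the 9-mer needs only 3 exonic nt.
#'
#' @param sites Site tibble (needs `site_id, gene_id, chrom, strand,
#'   a_pos, acceptor_pos`).
#' @param models A [gene_models()] object.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param down_donors Optional tibble `site_id, down_donor_pos`
#'   (reference coordinate of the donor boundary) from
#'   [count_down_junctions()].
#' @param window Donor search window in nt (default 350).
#' @param donor_model Optional `splice_model` used to pick the best
#'   window donor.
#' @return Tibble `site_id, r5ss_logo, r5ss_maxent, down5ss_logo,
#'   down5ss_maxent, down_donor_pos, down_donor_source`.  Logo
#'   sequences are 52-mers with GT at positions 31-32; scoring
#'   sequences are 9-mers with GT at positions 4-5.
#' @export
build_splice_site_sequences <- function(sites, models, genome,
                                        down_donors = NULL, window = 350,
                                        donor_model = NULL) {
  stopifnot(inherits(models, "gene_models"))
  ex <- exon_sense_boundaries(models)
  dd <- if (is.null(down_donors)) {
    tibble(site_id = character(), down_donor_pos = integer())
  } else {
    down_donors %>% select("site_id", "down_donor_pos")
  }
  s <- sites %>%
    left_join(dd, by = "site_id")
  purrr::pmap(s %>% select("site_id", "gene_id", "chrom", "strand",
                           "a_pos", "down_donor_pos"),
              function(site_id, gene_id, chrom, strand, a_pos,
                       down_donor_pos) {
    gx <- ex[ex$gene_id == gene_id, , drop = FALSE]
    up_ends <- if (strand == "+") {
      sort(gx$sense_end[gx$sense_end < a_pos], decreasing = TRUE)
    } else {
      sort(gx$sense_end[gx$sense_end > a_pos])
    }
    if (length(up_ends) == 0L) {
      return(tibble(site_id = site_id, r5ss_logo = NA_character_,
                    r5ss_maxent = NA_character_,
                    down5ss_logo = NA_character_,
                    down5ss_maxent = NA_character_,
                    down_donor_pos = NA_integer_,
                    down_donor_source = "none"))
    }
    up_end <- up_ends[1L]
    # exon length available upstream of its 3' end
    up_exon <- gx[gx$sense_end == up_end, ][1L, ]
    exon_len <- up_exon$end - up_exon$start + 1L
    take <- min(30L, exon_len)
    exon30 <- sense_slice(genome, chrom, strand, up_end, -(take - 1L), 0L)
    exon30 <- paste0(strrep("N", 30L - take), exon30)
    gt <- sense_slice(genome, chrom, strand, a_pos, 2L, 3L)
    after20 <- sense_slice(genome, chrom, strand, a_pos, 4L, 23L)
    r5ss_logo <- paste0(exon30, gt, substr(after20, 1L, 20L))
    r5ss_maxent <- paste0(substr(exon30, 28L, 30L), gt,
                          substr(after20, 1L, 4L))

    # downstream donor boundary, in sense offset from a_pos
    src <- "none"; don_off <- NA_integer_
    if (!is.na(down_donor_pos)) {
      don_off <- if (strand == "+") down_donor_pos - a_pos else
        a_pos - down_donor_pos
      gt2 <- sense_slice(genome, chrom, strand, a_pos, don_off + 1L,
                         don_off + 2L)
      if (identical(gt2, "GT")) {
        src <- "observed_junction"
      } else {
        don_off <- NA_integer_   # junction donor without GT: fall back
      }
    }
    if (is.na(don_off)) {
      win <- sense_slice(genome, chrom, strand, a_pos, 3L, 2L + window)
      gt_off <- which(vapply(seq_len(nchar(win) - 1L), function(i) {
        substr(win, i, i + 1L) == "GT"
      }, logical(1)))
      if (length(gt_off) > 0L) {
        cand_off <- gt_off + 1L       # donor boundary offset from a_pos
        cand9 <- vapply(cand_off, function(o) {
          sense_slice(genome, chrom, strand, a_pos, o - 2L, o + 6L)
        }, character(1))
        valid <- substr(cand9, 4L, 5L) == "GT" & !grepl("[^ACGT]", cand9)
        if (any(valid)) {
          cand_off <- cand_off[valid]; cand9 <- cand9[valid]
          sc <- if (!is.null(donor_model)) {
            score_donor(donor_model, cand9)
          } else {
            consensus_donor_score(cand9)
          }
          best <- which(sc == max(sc))
          best <- best[which.min(cand_off[best])]  # tie: smaller span
          don_off <- cand_off[best]
          src <- "best_window_donor"
        }
      }
    }
    if (is.na(don_off)) {
      down_logo <- NA_character_; down9 <- NA_character_
      ddp <- NA_integer_
    } else {
      down_logo <- paste0(
        sense_slice(genome, chrom, strand, a_pos, don_off - 29L, don_off),
        sense_slice(genome, chrom, strand, a_pos, don_off + 1L,
                    don_off + 22L) %>% substr(1L, 22L))
      down9 <- sense_slice(genome, chrom, strand, a_pos, don_off - 2L,
                           don_off + 6L)
      ddp <- if (strand == "+") a_pos + don_off else a_pos - don_off
    }
    tibble(site_id = site_id, r5ss_logo = r5ss_logo,
           r5ss_maxent = r5ss_maxent, down5ss_logo = down_logo,
           down5ss_maxent = down9,
           down_donor_pos = as.integer(ddp), down_donor_source = src)
  }) %>% bind_rows()
}

#' Call RS-like cryptic exons
#'
#' The cryptic-exon cascade over very long introns: host intron at
#' least `min_intron` nt (default 50 kb); pooled total-RNA up-junction
#' RPM strictly greater than `min_fold` times the mRNA RPM (default
#' fold 1 — *larger*, not two-fold as in the RS cascade);
#' replicate-merged up-junction count at least `min_up` (default 10)
#' and down-junction count at least `min_down` (default 2); and an
#' exon-like but not saw-tooth-like coverage profile
#' (`exon_score >= tau_exon` and `sawtooth_score < tau_saw`).
#'
#' @param up_counts Tibble from [count_up_junctions()].
#' @param down_counts Tibble (`counts` element) from
#'   [count_down_junctions()].
#' @param sites Site tibble.
#' @param depths Tibble `sample_id, depth, role`.
#' @param evidence Tibble from [sawtooth_evidence()].
#' @param down_donors Optional `donors` tibble from
#'   [count_down_junctions()]; adds the exon span to called rows.
#' @param min_intron,min_up,min_down,min_fold,tau_exon,tau_saw
#'   Thresholds (defaults 50000, 10, 2, 1, 2, 1).
#' @return Tibble with per-site counts, evidence, `pass_*` trace
#'   columns, exon span (`exon_start, exon_end`, reference
#'   coordinates) and the final `cryptic_exon` flag.
#' @export
call_cryptic_exons <- function(up_counts, down_counts, sites, depths,
                               evidence, down_donors = NULL,
                               min_intron = 50000, min_up = 10,
                               min_down = 2, min_fold = 1,
                               tau_exon = 2, tau_saw = 1) {
  joined <- up_counts %>%
    inner_join(down_counts, by = c("site_id", "sample_id"))
  merged <- merge_replicates(joined, depths)
  out <- sites %>%
    inner_join(merged, by = "site_id") %>%
    left_join(evidence %>%
                select("site_id", "sawtooth_score", "exon_score"),
              by = "site_id") %>%
    mutate(
      pass_intron = !is.na(.data$intron_length) &
        .data$intron_length >= min_intron,
      pass_enrichment = .data$total_rpm > min_fold * .data$mrna_rpm,
      pass_up = .data$merged_up_count >= min_up,
      pass_down = .data$merged_down_count >= min_down,
      pass_pattern = !is.na(.data$exon_score) &
        .data$exon_score >= tau_exon &
        (is.na(.data$sawtooth_score) | .data$sawtooth_score < tau_saw),
      cryptic_exon = .data$pass_intron & .data$pass_enrichment &
        .data$pass_up & .data$pass_down & .data$pass_pattern
    )
  if (!is.null(down_donors)) {
    out <- out %>%
      left_join(down_donors %>% select("site_id", "down_donor_pos"),
                by = "site_id") %>%
      mutate(
        exon_start = pmin(.data$acceptor_pos, .data$down_donor_pos),
        exon_end = pmax(.data$acceptor_pos, .data$down_donor_pos)
      )
  }
  att <- tibble(
    stage = c("sites", "intron_length", "enrichment", "up_count",
              "down_count", "pattern"),
    survivors = c(nrow(out), sum(out$pass_intron),
                  sum(out$pass_intron & out$pass_enrichment),
                  sum(out$pass_intron & out$pass_enrichment & out$pass_up),
                  sum(out$pass_intron & out$pass_enrichment &
                        out$pass_up & out$pass_down),
                  sum(out$cryptic_exon))
  )
  attr(out, "attrition") <- att
  out
}

#' Correlation between up- and down-junction read counts
#'
#' Pearson correlation over calls, via [stats::cor.test()].
#'
#' @param calls Tibble with the two count columns.
#' @param up_col,down_col Column names (defaults `merged_up_count`,
#'   `merged_down_count`).
#' @return One-row tibble `r, p_value, n`.
#' @export
up_down_correlation <- function(calls, up_col = "merged_up_count",
                                down_col = "merged_down_count") {
  check_cols(calls, c(up_col, down_col), "calls")
  up <- calls[[up_col]]; down <- calls[[down_col]]
  if (length(up) < 3L) abort("need at least 3 calls for a correlation")
  if (stats::sd(up) == 0 || stats::sd(down) == 0) {
    abort("zero variance in junction counts")
  }
  ct <- cor.test(up, down, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(up))
}
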