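#' Scan gene sense strands for AGGT / AGNN acceptor motifs
#'
#' Enumerates every occurrence of a 4-mer acceptor pattern on the sense
#' strand of each gene span (TSS to TES; intergenic sequence is never
#' scanned) and annotates each occurrence with its host intron, if any.
#' The pattern must begin `AG` — the acceptor convention: the AG acts as
#' a 3' splice site and the retained intermediate begins at the third
#' motif base (`acceptor_pos`), i.e. the G of GT for AGGT.
#'
#' `N` in the pattern matches any of A/C/G/T; ambiguity codes in the
#' genome (including N) never match, so hits containing non-ACGT letters
#' are dropped.  Sites of overlapping genes are reported once per gene
#' (distinct `gene_id` rows); deduplicate on `(chrom, a_pos, strand)`
#' for coordinate-unique counts.
#'
#' @param models A [gene_models()] object.
#' @param genome A named [Biostrings::DNAStringSet] (see
#'   [read_genome()]).
#' @param pattern 4-character pattern starting with `"AG"`; letters in
#'   A/C/G/T/N.
#' @return Tibble `site_id, gene_id, chrom, strand, a_pos, acceptor_pos,
#'   motif, intron_ordinal, intron_length` (1-based reference
#'   coordinates; `a_pos` is the position of the sense-strand A,
#'   `acceptor_pos` the first retained base after AG).  Intron columns
#'   are `NA` for exonic or boundary-overlapping sites.
#' @export
scan_motif_sites <- function(models, genome, pattern = "AGGT") {
  stopifnot(inherits(models, "gene_models"))
  pattern <- toupper(pattern)
  if (nchar(pattern) != 4L || !startsWith(pattern, "AG") ||
      grepl("[^ACGTN]", pattern)) {
    abort("pattern must be a 4-mer over A/C/G/T/N starting with 'AG'")
  }
  miss <- setdiff(unique(models$genes$chrom), names(genome))
  if (length(miss) > 0L) {
    abort(paste0("chromosome(s) not in genome: ", paste(miss, collapse = ", ")))
  }
  pat <- Biostrings::DNAString(pattern)

  per_gene <- purrr::pmap(models$genes, function(gene_id, chrom, strand,
                                                 start, end, ...) {
    sense <- Biostrings::DNAString(
      sense_seq(genome, chrom, start, end, strand))
    hits <- Biostrings::matchPattern(pat, sense, fixed = "subject")
    if (length(hits) == 0L) return(NULL)
    off <- BiocGenerics::start(hits)           # sense offset of the A
    motif <- as.character(hits)
    keep <- !grepl("[^ACGT]", motif)           # genome ambiguity: no match
    if (!any(keep)) return(NULL)
    off <- off[keep]; motif <- motif[keep]
    a_pos <- if (strand == "+") start + off - 1L else end - off + 1L
    acceptor_pos <- if (strand == "+") a_pos + 2L else a_pos - 2L
    tibble(gene_id = gene_id, chrom = chrom, strand = strand,
           a_pos = a_pos, acceptor_pos = acceptor_pos, motif = motif)
  })
  sites <- bind_rows(per_gene)
  if (nrow(sites) == 0L) {
    return(tibble(site_id = character(), gene_id = character(),
                  chrom = character(), strand = character(),
                  a_pos = integer(), acceptor_pos = integer(),
                  motif = character(), intron_ordinal = integer(),
                  intron_length = integer()))
  }

  # host intron: the whole 4-mer must lie strictly inside the intron
  sites <- sites %>%
    mutate(motif_lo = pmin(.data$a_pos, .data$a_pos +
                             if_else(.data$strand == "+", 3L, -3L)),
           motif_hi = pmax(.data$a_pos, .data$a_pos +
                             if_else(.data$strand == "+", 3L, -3L)))
  sites <- sites %>%
    left_join(
      models$introns %>%
        select("gene_id", int_start = "start", int_end = "end",
               intron_ordinal = "ordinal", intron_length = "length"),
      by = dplyr::join_by("gene_id", "motif_lo" >= "int_start",
                          "motif_hi" <= "int_end")
    ) %>%
    select(-"motif_lo", -"motif_hi", -"int_start", -"int_end")

  sites %>%
    mutate(site_id = paste(.data$gene_id, .data$chrom, .data$a_pos,
                           .data$strand, sep = ":")) %>%
    select("site_id", "gene_id", "chrom", "strand", "a_pos",
           "acceptor_pos", "motif", "intron_ordinal", "intron_length") %>%
    arrange(.data$chrom, .data$a_pos, .data$gene_id)
}

#' Restrict motif sites to long introns
#'
#' Keeps sites whose host intron is at least `min_intron_length` nt;
#' sites outside introns (`intron_ordinal` `NA`) are dropped.  The
#' default 1000 nt is the RS-pipeline threshold; the cryptic-exon
#' pipeline uses 50000 nt.
#'
#' @param sites Tibble from [scan_motif_sites()].
#' @param min_intron_length Minimum host-intron length in nt.
#' @return Filtered site tibble.
#' @export
filter_intronic_sites <- function(sites, min_intron_length = 1000) {
  check_cols(sites, c("intron_ordinal", "intron_length"), "sites")
  sites %>%
    filter(!is.na(.data$intron_ordinal),
           .data$intron_length >= min_intron_length)
}
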