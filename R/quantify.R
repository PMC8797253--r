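# expression-level summaries: FPKM over collapsed exons and the
# exonic/intronic/intergenic partition of uniquely mapped reads

# effective read strand used to match gene strand under a library
# strandedness protocol
effective_strand <- function(read_strand, strandedness) {
  switch(strandedness,
    forward = read_strand,
    reverse = if_else(read_strand == "+", "-", "+"),
    unstranded = read_strand,
    abort("strandedness must be 'forward', 'reverse' or 'unstranded'")
  )
}

blocks_granges <- function(blocks, strandedness) {
  GenomicRanges::GRanges(
    blocks$chrom,
    IRanges::IRanges(blocks$start, blocks$end),
    strand = effective_strand(blocks$strand, strandedness)
  )
}

#' Count reads overlapping collapsed exonic regions, per gene
#'
#' A read is counted for a gene when any of its aligned blocks overlaps
#' a collapsed exon of that gene on the matching strand (see
#' `strandedness`).  Each read contributes at most once per gene.
#'
#' @param alignments Tibble from [read_sam()].
#' @param models A [gene_models()] object.
#' @param strandedness `"forward"` (read strand equals gene strand),
#'   `"reverse"`, or `"unstranded"`.
#' @return Tibble `gene_id, count` covering every gene in `models`.
#' @export
count_exonic_reads <- function(alignments, models, strandedness = "forward") {
  stopifnot(inherits(models, "gene_models"))
  blocks <- cigar_ref_blocks(alignments)
  bg <- blocks_granges(blocks, strandedness)
  eg <- GenomicRanges::GRanges(models$exons$chrom,
                               IRanges::IRanges(models$exons$start,
                                                models$exons$end),
                               strand = models$exons$strand)
  hits <- GenomicRanges::findOverlaps(bg, eg,
    ignore.strand = strandedness == "unstranded")
  counted <- tibble(
    aln = blocks$aln[S4Vectors::queryHits(hits)],
    gene_id = models$exons$gene_id[S4Vectors::subjectHits(hits)]
  ) %>% distinct()
  models$genes %>%
    select("gene_id") %>%
    left_join(counted %>% count(.data$gene_id, name = "count"),
              by = "gene_id") %>%
    mutate(count = dplyr::coalesce(.data$count, 0L))
}

#' FPKM over collapsed exonic length
#'
#' `FPKM = count / (exonic_kb * depth_in_millions)`: reads per kilobase
#' of collapsed exonic region per million uniquely mapped reads.
#'
#' @param counts Tibble `gene_id, count` of reads overlapping collapsed
#'   exons (e.g. from [count_exonic_reads()]).
#' @param models A [gene_models()] object (supplies exonic lengths).
#' @param depth Uniquely mapped reads in the sample (positive scalar).
#' @return Tibble `gene_id, exonic_kb, count, fpkm`.
#' @export
gene_fpkm <- function(counts, models, depth) {
  stopifnot(inherits(models, "gene_models"))
  check_cols(counts, c("gene_id", "count"), "counts")
  if (depth <= 0) abort("sequencing depth must be positive")
  out <- counts %>%
    inner_join(models$genes %>% select("gene_id", "exonic_nt"),
               by = "gene_id") %>%
    mutate(exonic_kb = .data$exonic_nt / 1000)
  if (any(out$exonic_nt <= 0)) {
    abort(paste0("gene with zero exonic length: ",
                 out$gene_id[which(out$exonic_nt <= 0)[1L]]))
  }
  out %>%
    mutate(fpkm = .data$count / (.data$exonic_kb * (depth / 1e6))) %>%
    select("gene_id", "exonic_kb", "count", "fpkm")
}

#' Partition of uniquely mapped reads over exonic/intronic/intergenic
#'
#' Each read is assigned to exactly one category: exonic when any
#' aligned block overlaps a collapsed exon of a gene on the read's
#' assigned strand; otherwise intronic when the read falls inside any
#' gene span; otherwise intergenic.  Reads overlapping two genes count
#' once (priority exonic > intronic).
#'
#' @inheritParams count_exonic_reads
#' @return Tibble `category, reads, fraction`; fractions sum to 1.
#' @export
intronic_fraction <- function(alignments, models, strandedness = "forward") {
  stopifnot(inherits(models, "gene_models"))
  if (nrow(alignments) == 0L) abort("no alignments supplied")
  blocks <- cigar_ref_blocks(alignments)
  bg <- blocks_granges(blocks, strandedness)
  ignore <- strandedness == "unstranded"
  eg <- GenomicRanges::GRanges(models$exons$chrom,
                               IRanges::IRanges(models$exons$start,
                                                models$exons$end),
                               strand = models$exons$strand)
  sg <- GenomicRanges::GRanges(models$genes$chrom,
                               IRanges::IRanges(models$genes$start,
                                                models$genes$end),
                               strand = models$genes$strand)
  hit_exon <- IRanges::overlapsAny(bg, eg, ignore.strand = ignore)
  hit_gene <- IRanges::overlapsAny(bg, sg, ignore.strand = ignore)
  per_read <- tibble(aln = blocks$aln, exon = hit_exon, gene = hit_gene) %>%
    group_by(.data$aln) %>%
    summarise(exon = any(.data$exon), gene = any(.data$gene),
              .groups = "drop")
  cat_ <- if_else(per_read$exon, "exonic",
                  if_else(per_read$gene, "intronic", "intergenic"))
  tibble(category = factor(cat_, c("exonic", "intronic", "intergenic"))) %>%
    count(.data$category, name = "reads", .drop = FALSE) %>%
    mutate(category = as.character(.data$category),
           fraction = .data$reads / sum(.data$reads))
}
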