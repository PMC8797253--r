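#' Build collapsed gene models from an exon table
#'
#' Collapses exons across transcripts into a disjoint, sorted exon set per
#' gene (interval union), and derives introns as the gaps between
#' collapsed exons.  Intron ordinals are strand-aware: ordinal 1 is the
#' 5'-most intron in the direction of transcription.
#'
#' All coordinates are 1-based inclusive reference coordinates.
#'
#' @param exons A data frame with columns `gene_id`, `chrom`, `strand`
#'   (`"+"` or `"-"`), `start`, `end` — one row per (transcript) exon.
#' @return An object of class `gene_models`: a list with tibbles `genes`
#'   (`gene_id, chrom, strand, start, end, exonic_nt, n_introns`),
#'   `exons` (collapsed, sorted) and `introns` (with `ordinal`, `length`).
#' @examples
#' ex <- tibble::tibble(gene_id = "g1", chrom = "chr1", strand = "+",
#'                      start = c(101, 501), end = c(200, 600))
#' gene_models(ex)$introns
#' @export
gene_models <- function(exons) {
  exons <- as_tibble(exons)
  check_cols(exons, c("gene_id", "chrom", "strand", "start", "end"), "exons")
  if (!all(exons$strand %in% c("+", "-"))) {
    abort("exon strand must be '+' or '-'")
  }
  if (any(exons$end < exons$start)) abort("exon end < start")
  if (nrow(exons) == 0L) {
    empty_int <- tibble(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer())
    return(structure(list(
      genes = empty_int %>% mutate(exonic_nt = integer(),
                                   n_introns = integer()),
      exons = empty_int,
      introns = empty_int %>% mutate(ordinal = integer(),
                                     length = integer())
    ), class = "gene_models"))
  }

  collapsed <- exons %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
      tibble(start = IRanges::start(r), end = IRanges::end(r))
    }) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$start)

  genes <- collapsed %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    summarise(exonic_nt = sum(.data$end - .data$start + 1L),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop") %>%
    select("gene_id", "chrom", "strand", "start", "end", "exonic_nt")

  introns <- collapsed %>%
    group_by(.data$gene_id, .data$chrom, .data$strand) %>%
    dplyr::group_modify(function(d, key) {
      if (nrow(d) < 2L) {
        return(tibble(start = integer(), end = integer()))
      }
      tibble(start = d$end[-nrow(d)] + 1L, end = d$start[-1L] - 1L)
    }) %>%
    ungroup() %>%
    mutate(length = .data$end - .data$start + 1L) %>%
    group_by(.data$gene_id) %>%
    # ordinal 1 = 5'-most in transcription direction
    mutate(ordinal = as.integer(if_else(.data$strand == "+",
                                        rank(.data$start),
                                        rank(-.data$start)))) %>%
    ungroup() %>%
    arrange(.data$gene_id, .data$start) %>%
    select("gene_id", "chrom", "strand", "start", "end", "ordinal", "length")

  genes <- genes %>%
    left_join(introns %>% count(.data$gene_id, name = "n_introns"),
              by = "gene_id") %>%
    mutate(n_introns = dplyr::coalesce(.data$n_introns, 0L))

  structure(list(genes = genes, exons = collapsed, introns = introns),
            class = "gene_models")
}

#' Read gene models from a GTF annotation
#'
#' Imports an Ensembl-dialect GTF with [rtracklayer::import()], keeps
#' `exon` features, and collapses them per `gene_id` via [gene_models()].
#' When a genome is supplied, chromosome names are cross-checked.
#'
#' @param gtf_file Path to a GTF file with gene/transcript/exon features.
#' @param genome Optional [Biostrings::DNAStringSet]; an error names any
#'   annotated chromosome missing from it.
#' @return A `gene_models` object.
#' @export
read_gene_models <- function(gtf_file, genome = NULL) {
  gr <- tryCatch(
    rtracklayer::import(gtf_file, format = "gtf"),
    error = function(e) abort(paste0("malformed GTF '", gtf_file, "': ",
                                     conditionMessage(e)))
  )
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) abort("GTF contains no exon features")
  ex <- tibble(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr)
  )
  if (any(ex$strand == "*")) abort("GTF exon without strand")
  if (!is.null(genome)) {
    miss <- setdiff(unique(ex$chrom), names(genome))
    if (length(miss) > 0L) {
      abort(paste0("chromosome(s) in annotation but not genome: ",
                   paste(miss, collapse = ", ")))
    }
  }
  gene_models(ex)
}

#' @export
print.gene_models <- function(x, ...) {
  cat("<gene_models> ", nrow(x$genes), " genes, ",
      nrow(x$exons), " collapsed exons, ",
      nrow(x$introns), " introns\n", sep = "")
  invisible(x)
}

#' @describeIn gene_models `tidy()` returns the intron table (one row per
#'   intron, with strand-aware ordinal and length).
#' @param x A `gene_models` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.gene_models <- function(x, ...) x$introns
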