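# shared internal helpers

# reverse complement of a character vector of DNA strings (keeps N)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# extract sense-strand sequence for 1-based inclusive reference intervals;
# for minus-strand rows the reference slice is reverse-complemented
sense_seq <- function(genome, chrom, start, end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss) > 0L) {
    abort(paste0("chromosome(s) not in genome: ", paste(miss, collapse = ", ")))
  }
  widths <- setNames(Biostrings::width(genome), names(genome))
  if (any(start < 1L) || any(end > widths[chrom])) {
    abort("interval outside reference bounds")
  }
  out <- as.character(Biostrings::subseq(genome[chrom], start = start, end = end))
  neg <- strand == "-"
  if (any(neg)) out[neg] <- revcomp(out[neg])
  unname(out)
}

#' Read a reference genome from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that truncates
#' sequence names at the first whitespace so they match GTF/SAM
#' chromosome names.
#'
#' @param path Path to a (possibly gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

# stop unless `df` has the given columns
check_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss) > 0L) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(df)
}

# statistical mode with deterministic tie-break (smallest value)
modal_value <- function(x) {
  if (length(x) == 0L) return(NA_integer_)
  tab <- sort(table(x), decreasing = TRUE)
  winners <- names(tab)[tab == tab[1L]]
  v <- suppressWarnings(as.numeric(winners))
  if (!anyNA(v)) min(v) else sort(winners)[1L]
}
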