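#' Read uniquely-mapped alignments from a SAM file
#'
#' Parses the eleven mandatory SAM columns, drops unmapped records
#' (FLAG 0x4) and header lines, and derives the read strand from FLAG
#' 0x10.  Optional tags are ignored.
#'
#' @param path Path to a SAM file.
#' @param sample_id Optional sample label attached to every record
#'   (defaults to the file name without extension).
#' @return A tibble with columns `sample_id, read_id, flag, chrom, pos,
#'   mapq, cigar, strand` (`pos` is the 1-based leftmost reference
#'   position).
#' @export
read_sam <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("SAM file not found: ", path))
  sample_id <- sample_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (length(lines) == 0L) {
    return(tibble(sample_id = character(), read_id = character(),
                  flag = integer(), chrom = character(), pos = integer(),
                  mapq = integer(), cigar = character(), strand = character()))
  }
  f <- stringr::str_split_fixed(lines, "\t", 12L)
  flag <- as.integer(f[, 2L])
  out <- tibble(
    sample_id = sample_id,
    read_id = f[, 1L],
    flag = flag,
    chrom = f[, 3L],
    pos = as.integer(f[, 4L]),
    mapq = as.integer(f[, 5L]),
    cigar = f[, 6L],
    strand = if_else(bitwAnd(flag, 16L) > 0L, "-", "+")
  )
  out[bitwAnd(out$flag, 4L) == 0L, , drop = FALSE]
}

# validate CIGAR syntax; abort with the offending read id
check_cigars <- function(cigar, read_id) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad)) {
    abort(paste0("malformed CIGAR '", cigar[which(bad)[1L]],
                 "' for read ", read_id[which(bad)[1L]]))
  }
  invisible(NULL)
}

# parse CIGARs into a list of (length, op) matrices
cigar_ops <- function(cigar) {
  m <- stringr::str_match_all(cigar, "(\\d+)([MIDNSHP=X])")
  lapply(m, function(x) list(len = as.integer(x[, 2L]), op = x[, 3L]))
}

#' Extract splice junctions from alignments
#'
#' Walks each CIGAR per SAM semantics (`M`, `D`, `=`, `X` consume the
#' reference; `I`, `S`, `H`, `P` do not) and emits one junction record
#' per `N` operation: `donor_end` is the last aligned reference base
#' before the gap and `acceptor_start` the first aligned base after it
#' (1-based).  A read whose CIGAR holds several `N` operations yields
#' several records.
#'
#' @param alignments Tibble from [read_sam()].
#' @return A tibble `sample_id, read_id, chrom, strand, donor_end,
#'   acceptor_start`, satisfying `acceptor_start > donor_end + 1`.
#' @examples
#' aln <- tibble::tibble(sample_id = "s", read_id = "r", flag = 0L,
#'                       chrom = "chr1", pos = 1001L, mapq = 255L,
#'                       cigar = "20M100N30M", strand = "+")
#' extract_junctions(aln)  # donor_end 1020, acceptor_start 1121
#' @export
extract_junctions <- function(alignments) {
  check_cols(alignments, c("read_id", "chrom", "pos", "cigar", "strand"),
             "alignments")
  check_cigars(alignments$cigar, alignments$read_id)
  if (!"sample_id" %in% names(alignments)) alignments$sample_id <- "sample"
  has_n <- grepl("N", alignments$cigar, fixed = TRUE)
  empty <- tibble(sample_id = character(), read_id = character(),
                  chrom = character(), strand = character(),
                  donor_end = integer(), acceptor_start = integer())
  if (!any(has_n)) return(empty)
  sub <- alignments[has_n, , drop = FALSE]
  ops <- cigar_ops(sub$cigar)
  recs <- purrr::map2(ops, seq_len(nrow(sub)), function(o, i) {
    ref_consume <- o$op %in% c("M", "D", "N", "=", "X")
    # reference coordinate at which each op starts
    starts <- sub$pos[i] + cumsum(c(0L, (o$len * ref_consume)[-length(o$len)]))
    k <- which(o$op == "N")
    tibble(row = i, donor_end = starts[k] - 1L,
           acceptor_start = starts[k] + o$len[k])
  })
  recs <- bind_rows(recs)
  tibble(
    sample_id = sub$sample_id[recs$row],
    read_id = sub$read_id[recs$row],
    chrom = sub$chrom[recs$row],
    strand = sub$strand[recs$row],
    donor_end = recs$donor_end,
    acceptor_start = recs$acceptor_start
  )
}

# aligned reference blocks per alignment: maximal runs of reference-
# consuming ops between N gaps (M/D/=/X; soft clips and insertions are
# skipped).  Fast path for pure-match CIGARs like "100M".
cigar_ref_blocks <- function(alignments) {
  check_cols(alignments, c("read_id", "chrom", "pos", "cigar", "strand"),
             "alignments")
  check_cigars(alignments$cigar, alignments$read_id)
  empty <- tibble(aln = integer(), chrom = character(),
                  strand = character(), start = integer(),
                  end = integer())
  if (nrow(alignments) == 0L) return(empty)
  simple <- grepl("^[0-9]+M$", alignments$cigar)
  out <- list(empty)
  if (any(simple)) {
    s <- alignments[simple, , drop = FALSE]
    w <- as.integer(sub("M", "", s$cigar, fixed = TRUE))
    out[[1L]] <- tibble(aln = which(simple), chrom = s$chrom,
                        strand = s$strand, start = s$pos,
                        end = s$pos + w - 1L)
  }
  if (any(!simple)) {
    idx <- which(!simple)
    s <- alignments[idx, , drop = FALSE]
    ops <- cigar_ops(s$cigar)
    blk <- purrr::map2(ops, seq_along(idx), function(o, i) {
      ref_consume <- o$op %in% c("M", "D", "N", "=", "X")
      starts <- s$pos[i] + cumsum(c(0L, (o$len * ref_consume)[-length(o$len)]))
      ends <- starts + if_else(ref_consume, o$len, 0L) - 1L
      keep <- o$op %in% c("M", "D", "=", "X")
      # merge consecutive kept ops separated only by non-ref-consuming ops
      grp <- cumsum(o$op == "N")[keep]
      tibble(i = i, grp = grp, start = starts[keep], end = ends[keep]) %>%
        group_by(.data$i, .data$grp) %>%
        summarise(start = min(.data$start), end = max(.data$end),
                  .groups = "drop")
    })
    blk <- bind_rows(blk)
    out[[2L]] <- tibble(aln = idx[blk$i], chrom = s$chrom[blk$i],
                        strand = s$strand[blk$i],
                        start = blk$start, end = blk$end)
  }
  bind_rows(out) %>% arrange(.data$aln, .data$start)
}

#' Reads-per-million normalization
#'
#' @param count Raw read count(s).
#' @param depth Uniquely mapped reads in the sample; must be positive.
#' @return `count / depth * 1e6`.
#' @export
rpm <- function(count, depth) {
  if (any(depth <= 0)) abort("sequencing depth must be positive")
  count / depth * 1e6
}
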