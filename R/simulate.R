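# nascent RNA-seq simulator with planted recursive-splicing ground
# truth.  Each simulated gene occupies its own chromosome:
#
#   pad | exon1 | intron1 (long) | exon2 | intron2 | exon3 | pad
#
# RS sites and cryptic exons are planted inside intron1.  Intronic
# coverage follows the nascent-transcription logic: the chance that a
# nascent transcript still covers an intronic position is proportional
# to the distance from that position to its segment's sense-downstream
# splice point plus a splicing delay, which produces the linear
# decline within each segment and the step-up just after an RS site
# (the saw-tooth).  Junction reads are emitted in exact planted
# numbers.  The mRNA control carries exon and annotated-junction reads
# only.

#' Simulator configuration
#'
#' Defaults describe a desk-scale world about ten times smaller than a
#' mammalian brain transcriptome: RS host introns of 20-45 kb (real RS
#' introns exceed 51 kb), cryptic-exon hosts of 52-60 kb, 300-nt
#' exons.  Planted junction-read counts sit at or above the pipeline's
#' count thresholds (10 up-junction reads; 2 down-junction reads).
#'
#' @param n_rs_sites Planted RS sites, one per RS gene (default 5).
#' @param n_cryptic_exons Planted cryptic exons, one per host gene
#'   (default 3).
#' @param n_plain_genes Genes with flat intron coverage and no planted
#'   site (default 1).
#' @param rs_intron_range,cryptic_intron_range Intron-1 length ranges
#'   in nt.
#' @param exon_nt Annotated exon length (default 300).
#' @param intron2_nt Short second intron (default 2000).
#' @param site_frac Relative position of a planted site inside
#'   intron 1 (default 0.45).
#' @param rs_exon_nt RS-exon extent for sites with down-junctions
#'   (default 60 nt).
#' @param cryptic_exon_nt Cryptic-exon length (default 150 nt).
#' @param read_length Read length in nt (default 100).
#' @param delay Splicing delay of the nascent coverage model in nt
#'   (default 2000).
#' @param rs_coverage Fold coverage over RS introns (default 50).
#' @param bg_coverage Flat intron coverage for cryptic/plain genes
#'   (default 3).
#' @param cryptic_fold Local coverage multiple over background inside
#'   a cryptic exon (default 10).
#' @param up_reads,down_reads Planted up-/down-junction read counts
#'   for RS sites (recycled; default 15,12,20,14,11 and 6,0
#'   alternating — half the sites lack downstream intermediates).
#' @param cryptic_up_reads,cryptic_down_reads Planted counts for
#'   cryptic exons (recycled).
#' @param exonic_reads Mature-mRNA-style reads per gene in total-RNA
#'   samples (default 500).
#' @param mrna_reads Reads per gene in the mRNA control (default
#'   1500).
#' @param seed Seed for the reference generator (default 1).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_rs_sites = 5, n_cryptic_exons = 3,
                       n_plain_genes = 1,
                       rs_intron_range = c(20000, 45000),
                       cryptic_intron_range = c(52000, 60000),
                       exon_nt = 300, intron2_nt = 2000,
                       site_frac = 0.45, rs_exon_nt = 60,
                       cryptic_exon_nt = 150, read_length = 100,
                       delay = 2000, rs_coverage = 50, bg_coverage = 3,
                       cryptic_fold = 10,
                       up_reads = c(15L, 12L, 20L, 14L, 11L),
                       down_reads = c(6L, 0L),
                       cryptic_up_reads = c(15L, 12L, 18L),
                       cryptic_down_reads = c(4L, 3L, 6L),
                       exonic_reads = 500, mrna_reads = 1500,
                       seed = 1) {
  cfg <- as.list(environment())
  if (cfg$rs_intron_range[1L] < 2000) abort("intron lengths must be >= 2 kb")
  if (cfg$site_frac <= 0 || cfg$site_frac >= 1) {
    abort("site_frac must be in (0, 1)")
  }
  structure(cfg, class = "sim_config")
}

rand_dna <- function(n) {
  paste(sample(BASES, n, replace = TRUE), collapse = "")
}

rand_polypy <- function(n) {
  paste(sample(c("T", "C"), n, replace = TRUE, prob = c(.6, .4)),
        collapse = "")
}

# overwrite a planted motif at sense positions [at, at+nchar-1]
plant <- function(seq, at, motif) {
  substr(seq, at, at + nchar(motif) - 1L) <- motif
  seq
}

#' Generate a toy reference with planted RS sites and cryptic exons
#'
#' Builds the genome (FASTA-ready [Biostrings::DNAStringSet]), the
#' gene models and the ground-truth tables.  Every planted site reads
#' AGGT on its gene's sense strand; RS sites carry the AGGTAAGT
#' U1-pairing context and a 20-nt polypyrimidine tract, cryptic exons
#' carry a weak reconstituted donor context but a strong downstream
#' donor (CAG|GTAAGT) at their 3' end.  Annotated introns get
#' canonical GT..AG boundaries so splice-site models can be trained
#' from the annotation.  Gene strands alternate; identical seeds give
#' byte-identical output.
#'
#' @param config A [sim_config()].
#' @return A `sim_truth` object: list with `genome`, `models`
#'   ([gene_models()]), tibbles `genes`, `rs_sites`, `cryptic_exons`,
#'   and `config`.
#' @export
simulate_reference <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  n_genes <- cfg$n_rs_sites + cfg$n_cryptic_exons + cfg$n_plain_genes
  kinds <- c(rep("rs", cfg$n_rs_sites),
             rep("cryptic", cfg$n_cryptic_exons),
             rep("plain", cfg$n_plain_genes))
  up_reads <- rep_len(cfg$up_reads, cfg$n_rs_sites)
  down_reads <- rep_len(cfg$down_reads, cfg$n_rs_sites)
  cup <- rep_len(cfg$cryptic_up_reads, cfg$n_cryptic_exons)
  cdown <- rep_len(cfg$cryptic_down_reads, cfg$n_cryptic_exons)
  pad <- 500L; ex <- as.integer(cfg$exon_nt)
  i2 <- as.integer(cfg$intron2_nt)

  chroms <- list(); exon_rows <- list(); gene_rows <- list()
  rs_rows <- list(); cr_rows <- list()
  i_rs <- 0L; i_cr <- 0L
  for (g in seq_len(n_genes)) {
    kind <- kinds[g]
    L <- switch(kind,
      rs = sample(cfg$rs_intron_range[1L]:cfg$rs_intron_range[2L], 1L),
      cryptic = sample(cfg$cryptic_intron_range[1L]:
                         cfg$cryptic_intron_range[2L], 1L),
      plain = cfg$rs_intron_range[1L])
    strand <- if (g %% 2L == 1L) "+" else "-"
    gene_id <- sprintf("g%02d", g)
    chrom <- sprintf("chr%02d", g)
    # sense-space layout
    e1s <- pad + 1L; e1e <- e1s + ex - 1L
    i1s <- e1e + 1L; i1e <- i1s + L - 1L
    e2s <- i1e + 1L; e2e <- e2s + ex - 1L
    i2s <- e2e + 1L; i2e <- i2s + i2 - 1L
    e3s <- i2e + 1L; e3e <- e3s + ex - 1L
    clen <- e3e + pad
    seq <- rand_dna(clen)
    # canonical boundaries of the annotated introns
    for (b in list(c(i1s, i1e), c(i2s, i2e))) {
      seq <- plant(seq, b[1L], "GTAAGT")
      seq <- plant(seq, b[2L] - 19L, paste0(rand_polypy(18L), "AG"))
    }
    site <- NULL
    if (kind != "plain") {
      p <- i1s + as.integer(round(cfg$site_frac * L))
      seq <- plant(seq, p - 20L, rand_polypy(20L))
      seq <- plant(seq, p, "AGGT")
      if (kind == "rs") {
        i_rs <- i_rs + 1L
        seq <- plant(seq, p + 4L, "AAGT")
        dd <- NA_integer_
        if (down_reads[i_rs] > 0L) {
          dd <- p + 2L + as.integer(cfg$rs_exon_nt) - 1L
          seq <- plant(seq, dd - 2L, "CAGGTAAGT")
        }
        site <- list(kind = "rs", p = p, dd = dd,
                     up = up_reads[i_rs], down = down_reads[i_rs])
      } else {
        i_cr <- i_cr + 1L
        dd <- p + 2L + as.integer(cfg$cryptic_exon_nt) - 1L
        seq <- plant(seq, dd - 2L, "CAGGTAAGT")
        site <- list(kind = "cryptic", p = p, dd = dd,
                     up = cup[i_cr], down = cdown[i_cr])
      }
    }
    if (strand == "-") seq <- revcomp(seq)
    to_ref <- function(x) if (strand == "+") x else clen - x + 1L
    exon_rows[[g]] <- tibble(
      gene_id = gene_id, chrom = chrom, strand = strand,
      start = pmin(to_ref(c(e1s, e2s, e3s)), to_ref(c(e1e, e2e, e3e))),
      end = pmax(to_ref(c(e1s, e2s, e3s)), to_ref(c(e1e, e2e, e3e)))
    )
    gene_rows[[g]] <- tibble(
      gene_id = gene_id, chrom = chrom, strand = strand, kind = kind,
      coverage_model = if (kind == "rs") "sawtooth" else "flat",
      chrom_len = clen,
      i1_sense_start = i1s, i1_sense_end = i1e, intron_length = L,
      i1_ref_start = min(to_ref(i1s), to_ref(i1e)),
      i1_ref_end = max(to_ref(i1s), to_ref(i1e)),
      e1_sense_end = e1e, e2_sense_start = e2s
    )
    if (!is.null(site)) {
      row <- tibble(
        gene_id = gene_id, chrom = chrom, strand = strand,
        a_sense = site$p, a_pos = to_ref(site$p),
        acceptor_pos = to_ref(site$p + 2L),
        up_reads = site$up, down_reads = site$down,
        down_donor_sense = site$dd,
        down_donor_pos = if (is.na(site$dd)) NA_integer_ else
          to_ref(site$dd),
        site_sense_in_intron = site$p - i1s + 1L,
        seg1_len = site$p + 1L - i1s + 1L,
        seg2_len = i1e - (site$p + 2L) + 1L,
        intron_length = L
      )
      if (site$kind == "rs") rs_rows[[length(rs_rows) + 1L]] <- row
      else cr_rows[[length(cr_rows) + 1L]] <- row
    }
    chroms[[chrom]] <- seq
  }
  genome <- Biostrings::DNAStringSet(
    if (length(chroms)) unlist(chroms) else character())
  empty_exons <- tibble(gene_id = character(), chrom = character(),
                        strand = character(), start = integer(),
                        end = integer())
  models <- gene_models(bind_rows(c(list(empty_exons), exon_rows)))
  structure(list(
    genome = genome, models = models,
    genes = bind_rows(gene_rows),
    rs_sites = bind_rows(rs_rows),
    cryptic_exons = if (length(cr_rows)) bind_rows(cr_rows) else
      tibble(gene_id = character()),
    config = cfg
  ), class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$genes), " genes on ", length(x$genome),
      " chromosomes; ", nrow(x$rs_sites), " RS sites, ",
      nrow(x$cryptic_exons), " cryptic exons planted\n", sep = "")
  invisible(x)
}

#' Write the simulated reference and truth tables to disk
#'
#' Emits `genome.fa`, `annotation.gtf` (Ensembl-dialect: gene,
#' transcript and exon features with `gene_id`/`transcript_id`
#' attributes) and truth TSVs into `dir`.
#'
#' @param truth A `sim_truth` from [simulate_reference()].
#' @param dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
write_simulation <- function(truth, dir) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  Biostrings::writeXStringSet(truth$genome, fa)
  gtf <- file.path(dir, "annotation.gtf")
  lines <- purrr::pmap(truth$models$genes, function(gene_id, chrom,
                                                    strand, start, end,
                                                    ...) {
    attr_g <- sprintf('gene_id "%s";', gene_id)
    attr_t <- sprintf('gene_id "%s"; transcript_id "%s.t1";',
                      gene_id, gene_id)
    ex <- truth$models$exons %>% filter(.data$gene_id == .env$gene_id)
    c(paste(chrom, "recsplice_sim", "gene", start, end, ".", strand, ".",
            attr_g, sep = "\t"),
      paste(chrom, "recsplice_sim", "transcript", start, end, ".", strand,
            ".", attr_t, sep = "\t"),
      paste(ex$chrom, "recsplice_sim", "exon", ex$start, ex$end, ".",
            ex$strand, ".", attr_t, sep = "\t"))
  })
  readr::write_lines(unlist(lines), gtf)
  paths <- list(genome = fa, gtf = gtf)
  for (nm in c("genes", "rs_sites", "cryptic_exons")) {
    p <- file.path(dir, paste0("truth_", nm, ".tsv"))
    readr::write_tsv(truth[[nm]], p, progress = FALSE)
    paths[[nm]] <- p
  }
  invisible(paths)
}

# two-block spliced read in sense space -> one SAM record row
# blocks are sense intervals (lo1<hi1 upstream in sense, lo2<hi2)
spliced_row <- function(strand, clen, s1, e1, s2, e2) {
  to_ref <- function(x) if (strand == "+") x else clen - x + 1L
  r1 <- sort(c(to_ref(s1), to_ref(e1)))
  r2 <- sort(c(to_ref(s2), to_ref(e2)))
  if (r1[1L] > r2[1L]) { tmp <- r1; r1 <- r2; r2 <- tmp }
  list(pos = r1[1L],
       cigar = paste0(r1[2L] - r1[1L] + 1L, "M",
                      r2[1L] - r1[2L] - 1L, "N",
                      r2[2L] - r2[1L] + 1L, "M"))
}

#' Simulate an aligned RNA-seq sample over a simulated reference
#'
#' Emits a headered, coordinate-sorted single-end SAM file.  For
#' `role = "total_rna"`: intronic reads whose start density follows
#' the nascent model (distance to the segment's sense-downstream
#' splice point plus `delay`; flat for `coverage_model = "flat"`
#' genes), exon-confined extra coverage over cryptic exons,
#' mature-style exonic/junction reads, and exactly the planted numbers
#' of up- and down-junction reads per planted site (scaled by
#' `junction_frac`, see [simulate_replicates()]).  For
#' `role = "mrna_control"`: mature-style reads only — no intronic
#' coverage and no RS junction reads, so planted sites show infinite
#' fold enrichment.
#'
#' Reads are error-free, uniquely mapped (MAPQ 255), with CIGARs
#' constructed from truth; the library is forward-stranded (read
#' strand equals gene strand).
#'
#' @param truth A `sim_truth`.
#' @param path Output SAM path.
#' @param sample_id Sample label.
#' @param role `"total_rna"` or `"mrna_control"`.
#' @param seed RNG seed for this sample.
#' @param junction_frac Fraction of each planted junction count to
#'   emit (rounded half up; default 1).
#' @param coverage_frac Fraction of the configured intronic coverage
#'   to emit (default 1).
#' @return Tibble `sample_id, depth, role` (one row; depth = emitted
#'   reads), invisibly; the SAM file is written to `path`.
#' @export
simulate_reads <- function(truth, path, sample_id,
                           role = c("total_rna", "mrna_control"),
                           seed = 1, junction_frac = 1,
                           coverage_frac = 1) {
  stopifnot(inherits(truth, "sim_truth"))
  role <- match.arg(role)
  cfg <- truth$config
  rl <- as.integer(cfg$read_length)
  set.seed(seed)
  if (coverage_frac < 0 || junction_frac < 0) {
    abort("coverage_frac and junction_frac must be non-negative")
  }
  if (role == "mrna_control" && cfg$mrna_reads <= 0) {
    abort("mRNA control sample with zero depth requested")
  }
  rows <- list()
  planted <- bind_rows(
    if (nrow(truth$rs_sites)) truth$rs_sites else NULL,
    if (nrow(truth$cryptic_exons) &&
        "a_sense" %in% names(truth$cryptic_exons)) {
      truth$cryptic_exons
    } else NULL
  )
  for (g in seq_len(nrow(truth$genes))) {
    gene <- truth$genes[g, ]
    strand <- gene$strand; clen <- gene$chrom_len
    to_ref <- function(x) if (strand == "+") x else clen - x + 1L
    L <- gene$intron_length
    gsites <- if (nrow(planted)) {
      planted %>% filter(.data$gene_id == gene$gene_id)
    } else planted

    if (role == "total_rna") {
      # cryptic hosts get low flat background (so the exon contrast is
      # visible); RS and plain genes are covered at full depth
      cov <- if (gene$kind == "cryptic") cfg$bg_coverage else
        cfg$rs_coverage
      cov <- cov * coverage_frac
      n_int <- round(cov * L / rl)
      if (n_int > 0L) {
        xs_max <- L - rl + 1L
        w <- if (gene$coverage_model == "sawtooth" && nrow(gsites) == 1L) {
          srel <- gsites$site_sense_in_intron
          seg_end <- if_else(seq_len(xs_max) <= srel + 1L, srel + 1L, L)
          seg_end - seq_len(xs_max) + cfg$delay
        } else rep(1, xs_max)
        x <- sample.int(xs_max, n_int, replace = TRUE, prob = w)
        sense_start <- gene$i1_sense_start + x - 1L
        ref_start <- if (strand == "+") sense_start else
          clen - (sense_start + rl - 1L) + 1L
        rows[[length(rows) + 1L]] <- tibble(
          chrom = gene$chrom, strand = strand, pos = ref_start,
          cigar = paste0(rl, "M"))
      }
      # exon-confined extra coverage inside a cryptic exon
      if (gene$kind == "cryptic" && nrow(gsites) == 1L) {
        acc <- gsites$a_sense + 2L; dd <- gsites$down_donor_sense
        n_ex <- round((cfg$cryptic_fold - 1) * cfg$bg_coverage *
                        (dd - acc + 1L) / rl * coverage_frac)
        if (n_ex > 0L && dd - rl + 1L >= acc) {
          st <- acc + sample.int(dd - rl + 1L - acc + 1L, n_ex,
                                 replace = TRUE) - 1L
          ref_start <- if (strand == "+") st else clen - (st + rl - 1L) + 1L
          rows[[length(rows) + 1L]] <- tibble(
            chrom = gene$chrom, strand = strand, pos = ref_start,
            cigar = paste0(rl, "M"))
        }
      }
    }

    # mature-mRNA-style reads over the spliced transcript (reads span
    # at most two exons: exons are longer than the read length)
    n_mat <- if (role == "total_rna") cfg$exonic_reads else cfg$mrna_reads
    if (n_mat > 0L) {
      gexons <- truth$models$exons %>%
        filter(.data$gene_id == gene$gene_id) %>%
        arrange(.data$start)
      sense_ex <- if (strand == "+") gexons else
        gexons[rev(seq_len(nrow(gexons))), ]
      ex_len <- sense_ex$end - sense_ex$start + 1L
      stopifnot(all(ex_len >= rl))
      cum <- cumsum(c(0L, ex_len))
      mat_len <- sum(ex_len)
      m <- sample.int(mat_len - rl + 1L, n_mat, replace = TRUE)
      lo <- m; hi <- m + rl - 1L
      k1 <- findInterval(lo, cum + 1L); k2 <- findInterval(hi, cum + 1L)
      # sense offsets -> reference interval within exon k
      ref_iv <- function(k, s_off, e_off) {
        if (strand == "+") {
          cbind(sense_ex$start[k] + s_off - 1L, sense_ex$start[k] + e_off - 1L)
        } else {
          cbind(sense_ex$end[k] - e_off + 1L, sense_ex$end[k] - s_off + 1L)
        }
      }
      one <- k1 == k2
      if (any(one)) {
        iv <- ref_iv(k1[one], lo[one] - cum[k1[one]], hi[one] - cum[k1[one]])
        rows[[length(rows) + 1L]] <- tibble(
          chrom = gene$chrom, strand = strand, pos = iv[, 1L],
          cigar = paste0(rl, "M"))
      }
      if (any(!one)) {
        ka <- k1[!one]; kb <- k2[!one]
        iv_a <- ref_iv(ka, lo[!one] - cum[ka], ex_len[ka])
        iv_b <- ref_iv(kb, 1L, hi[!one] - cum[kb])
        first <- ifelse(iv_a[, 1L] <= iv_b[, 1L], 1L, 2L)
        f_s <- ifelse(first == 1L, iv_a[, 1L], iv_b[, 1L])
        f_e <- ifelse(first == 1L, iv_a[, 2L], iv_b[, 2L])
        s_s <- ifelse(first == 1L, iv_b[, 1L], iv_a[, 1L])
        s_e <- ifelse(first == 1L, iv_b[, 2L], iv_a[, 2L])
        rows[[length(rows) + 1L]] <- tibble(
          chrom = gene$chrom, strand = strand, pos = as.integer(f_s),
          cigar = paste0(f_e - f_s + 1L, "M", s_s - f_e - 1L, "N",
                         s_e - s_s + 1L, "M"))
      }
    }

    # planted junction reads (total RNA only)
    if (role == "total_rna" && nrow(gsites) == 1L) {
      half <- min(50L, rl %/% 2L)
      n_up <- as.integer(round(gsites$up_reads * junction_frac))
      n_down <- as.integer(round(gsites$down_reads * junction_frac))
      if (n_up > 0L) {
        r <- spliced_row(strand, clen,
                         gene$e1_sense_end - half + 1L, gene$e1_sense_end,
                         gsites$a_sense + 2L, gsites$a_sense + 1L + half)
        rows[[length(rows) + 1L]] <- tibble(
          chrom = gene$chrom, strand = strand,
          pos = rep(as.integer(r$pos), n_up), cigar = r$cigar)
      }
      if (n_down > 0L && !is.na(gsites$down_donor_sense)) {
        dd <- gsites$down_donor_sense
        r <- spliced_row(strand, clen, dd - half + 1L, dd,
                         gene$e2_sense_start, gene$e2_sense_start + half - 1L)
        rows[[length(rows) + 1L]] <- tibble(
          chrom = gene$chrom, strand = strand,
          pos = rep(as.integer(r$pos), n_down), cigar = r$cigar)
      }
    }
  }
  reads <- bind_rows(rows) %>%
    arrange(match(.data$chrom, names(truth$genome)), .data$pos,
            .data$cigar) %>%
    mutate(read_id = sprintf("%s_r%06d", sample_id, row_number()),
           flag = if_else(.data$strand == "-", 16L, 0L))
  seqs <- extract_read_seq(truth$genome, reads)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", names(truth$genome),
                      Biostrings::width(truth$genome)))
  body <- paste(reads$read_id, reads$flag, reads$chrom, reads$pos, 255L,
                reads$cigar, "*", 0L, 0L, seqs, "*", sep = "\t")
  readr::write_lines(c(header, body), path)
  invisible(tibble(sample_id = sample_id, depth = nrow(reads),
                   role = role))
}

# reference (plus-strand) sequence spanned by each read's M blocks
extract_read_seq <- function(genome, reads) {
  simple <- grepl("^[0-9]+M$", reads$cigar)
  out <- character(nrow(reads))
  for (ch in unique(reads$chrom)) {
    ix <- which(simple & reads$chrom == ch)
    if (length(ix)) {
      w <- as.integer(sub("M", "", reads$cigar[ix], fixed = TRUE))
      v <- Biostrings::Views(genome[[ch]], start = reads$pos[ix],
                             end = reads$pos[ix] + w - 1L)
      out[ix] <- as.character(v)
    }
  }
  rest <- which(!simple)
  if (length(rest)) {
    blocks <- cigar_ref_blocks(
      reads[rest, ] %>% mutate(read_id = .data$read_id))
    seqs <- sense_seq(genome, blocks$chrom, blocks$start, blocks$end,
                      rep("+", nrow(blocks)))
    agg <- tapply(seqs, blocks$aln, paste, collapse = "")
    out[rest[as.integer(names(agg))]] <- as.character(agg)
  }
  out
}

#' Simulate replicated total-RNA samples plus an mRNA control
#'
#' Splits each planted junction count across `n_rep` total-RNA
#' replicates so that the replicate-merged counts equal the planted
#' counts exactly, divides intronic coverage evenly, and writes one
#' SAM per sample plus the mRNA control.
#'
#' @param truth A `sim_truth`.
#' @param dir Output directory.
#' @param n_rep Number of total-RNA replicates (default 2).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @return Tibble `sample_id, depth, role, path`.
#' @export
simulate_replicates <- function(truth, dir, n_rep = 2, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- list()
  # per-replicate junction fractions: cumulative rounding sums to 1
  for (r in seq_len(n_rep)) {
    p <- file.path(dir, sprintf("total_rep%d.sam", r))
    d <- simulate_reads_split(truth, p, sprintf("total_rep%d", r),
                              seed = seed + r, rep_index = r,
                              n_rep = n_rep)
    out[[length(out) + 1L]] <- d %>% mutate(path = p)
  }
  p <- file.path(dir, "mrna.sam")
  d <- simulate_reads(truth, p, "mrna", role = "mrna_control",
                      seed = seed + n_rep + 1L)
  out[[length(out) + 1L]] <- d %>% mutate(path = p)
  bind_rows(out)
}

# emit replicate r of n_rep with junction counts split exactly
simulate_reads_split <- function(truth, path, sample_id, seed,
                                 rep_index, n_rep) {
  split_counts <- function(k, r) {
    lo <- round(k * (r - 1) / n_rep); hi <- round(k * r / n_rep)
    as.integer(hi - lo)
  }
  tr <- truth
  if (nrow(tr$rs_sites)) {
    tr$rs_sites$up_reads <- vapply(tr$rs_sites$up_reads, split_counts,
                                   integer(1), r = rep_index)
    tr$rs_sites$down_reads <- vapply(tr$rs_sites$down_reads, split_counts,
                                     integer(1), r = rep_index)
  }
  if (nrow(tr$cryptic_exons) && "up_reads" %in% names(tr$cryptic_exons)) {
    tr$cryptic_exons$up_reads <- vapply(tr$cryptic_exons$up_reads,
                                        split_counts, integer(1),
                                        r = rep_index)
    tr$cryptic_exons$down_reads <- vapply(tr$cryptic_exons$down_reads,
                                          split_counts, integer(1),
                                          r = rep_index)
  }
  simulate_reads(tr, path, sample_id, role = "total_rna", seed = seed,
                 coverage_frac = 1 / n_rep)
}
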