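# donor/acceptor strength models.  The published analyses used the
# external MaxEntScan score tables; absolute MaxEnt values are not
# reproduced here.  Instead the package (a) loads external parameter
# tables when available and (b) otherwise trains a weight-matrix (WMM)
# or position-specific first-order Markov model on the annotated GT
# donors / AG acceptors of the supplied annotation + genome.  All
# internal pipeline decisions use score comparisons only, so any
# monotone transform of a score model preserves classifications.
#
# Donor support: 9-mers, GT at positions 4-5 (3 exonic nt + GT + 4 nt).
# Acceptor support: 23-mers, AG at positions 19-20 (18 nt + AG + 3 nt;
# for an AGGT acceptor site this is 18 nt + AGGT + 1 nt).

DONOR_LEN <- 9L
ACCEPTOR_LEN <- 23L
BASES <- c("A", "C", "G", "T")

seq_matrix <- function(seqs, len) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)), ncol = len,
         byrow = TRUE)
}

# smoothing: fixed-weight shrinkage toward the uniform distribution.
# Unlike an additive pseudocount, this keeps scores exactly invariant
# under duplication of the training set while still bounding every
# frequency away from zero.
SMOOTH_LAMBDA <- 0.05

smooth_freq <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(rep(0.25, length(counts)))
  (1 - SMOOTH_LAMBDA) * counts / n + SMOOTH_LAMBDA * 0.25
}

# position-specific base frequencies
wmm_freq <- function(seqs, len) {
  m <- seq_matrix(seqs, len)
  f <- sapply(seq_len(len), function(j) {
    smooth_freq(table(factor(m[, j], levels = BASES)))
  })
  rownames(f) <- BASES
  f   # 4 x len
}

# position-specific first-order conditional frequencies
markov1_freq <- function(seqs, len) {
  m <- seq_matrix(seqs, len)
  p1 <- smooth_freq(table(factor(m[, 1L], levels = BASES)))
  cond <- array(NA_real_, dim = c(4, 4, len - 1L),
                dimnames = list(prev = BASES, base = BASES, NULL))
  for (j in 2:len) {
    tab <- table(factor(m[, j - 1L], levels = BASES),
                 factor(m[, j], levels = BASES))
    cond[, , j - 1L] <- t(apply(tab, 1, smooth_freq))
  }
  list(p1 = as.numeric(p1), cond = cond)
}

genome_background <- function(genome) {
  counts <- colSums(Biostrings::letterFrequency(genome, BASES))
  counts / sum(counts)
}

# extract annotated donor 9-mers / acceptor 23-mers from gene models
annotated_splice_seqs <- function(models, genome) {
  widths <- setNames(Biostrings::width(genome), names(genome))
  ir <- models$introns
  don <- ir %>%
    mutate(lo = if_else(.data$strand == "+", .data$start - 3L, .data$end - 5L),
           hi = if_else(.data$strand == "+", .data$start + 5L, .data$end + 3L)) %>%
    filter(.data$lo >= 1L, .data$hi <= widths[.data$chrom])
  acc <- ir %>%
    mutate(lo = if_else(.data$strand == "+", .data$end - 19L, .data$start - 3L),
           hi = if_else(.data$strand == "+", .data$end + 3L, .data$start + 19L)) %>%
    filter(.data$lo >= 1L, .data$hi <= widths[.data$chrom])
  donors <- if (nrow(don)) {
    sense_seq(genome, don$chrom, don$lo, don$hi, don$strand)
  } else character()
  acceptors <- if (nrow(acc)) {
    sense_seq(genome, acc$chrom, acc$lo, acc$hi, acc$strand)
  } else character()
  donors <- donors[substr(donors, 4L, 5L) == "GT" & !grepl("[^ACGT]", donors)]
  acceptors <- acceptors[substr(acceptors, 19L, 20L) == "AG" &
                           !grepl("[^ACGT]", acceptors)]
  list(donors = donors, acceptors = acceptors)
}

#' Train a splice-site strength model from the annotation
#'
#' Collects the annotated donor 9-mers (3 exonic nt + GT + 4 intronic
#' nt, GT required) and acceptor 23-mers (18 intronic nt + AG + 3
#' exonic nt, AG required) implied by the gene models, and fits either
#' a position weight matrix (`"wmm"`) or a position-specific
#' first-order Markov model (`"markov1"`), with frequencies shrunk
#' toward uniform by a fixed mixture weight.
#' Scores are log2 odds against the genome-wide mononucleotide
#' background, so higher means stronger and the score of a sequence is
#' invariant to duplicating every training sequence.
#'
#' @param models A [gene_models()] object.
#' @param genome A named [Biostrings::DNAStringSet].
#' @param kind `"wmm"` or `"markov1"`.
#' @return A `splice_model` object.
#' @export
train_splice_model <- function(models, genome, kind = c("wmm", "markov1")) {
  kind <- match.arg(kind)
  seqs <- annotated_splice_seqs(models, genome)
  if (length(seqs$donors) < 1L || length(seqs$acceptors) < 1L) {
    abort("annotation yields no GT donors or no AG acceptors to train on")
  }
  splice_model_from_seqs(seqs$donors, seqs$acceptors,
                         background = genome_background(genome),
                         kind = kind)
}

#' Build a splice-site model from explicit training sequences
#'
#' @param donors Character vector of 9-mers with GT at positions 4-5.
#' @param acceptors Character vector of 23-mers with AG at positions
#'   19-20.
#' @param background Named numeric of A/C/G/T background frequencies
#'   (default uniform).
#' @param kind `"wmm"` or `"markov1"`.
#' @return A `splice_model` object with elements `kind`, `donor`,
#'   `acceptor`, `background`.
#' @export
splice_model_from_seqs <- function(donors, acceptors,
                                   background = c(A = .25, C = .25,
                                                  G = .25, T = .25),
                                   kind = c("wmm", "markov1")) {
  kind <- match.arg(kind)
  donors <- toupper(donors); acceptors <- toupper(acceptors)
  if (any(nchar(donors) != DONOR_LEN) ||
      any(substr(donors, 4L, 5L) != "GT")) {
    abort("donor training sequences must be 9-mers with GT at 4-5")
  }
  if (any(nchar(acceptors) != ACCEPTOR_LEN) ||
      any(substr(acceptors, 19L, 20L) != "AG")) {
    abort("acceptor training sequences must be 23-mers with AG at 19-20")
  }
  background <- background[BASES] / sum(background[BASES])
  fit <- function(seqs, len) {
    if (kind == "wmm") list(wmm = wmm_freq(seqs, len), n = length(seqs))
    else c(markov1_freq(seqs, len), list(n = length(seqs)))
  }
  structure(list(kind = kind,
                 trained_kind = paste0("trained_", kind),
                 donor = fit(donors, DONOR_LEN),
                 acceptor = fit(acceptors, ACCEPTOR_LEN),
                 background = background),
            class = "splice_model")
}

#' @export
print.splice_model <- function(x, ...) {
  cat("<splice_model> kind: ", x$trained_kind %||% x$kind,
      "; donors n=", x$donor$n %||% NA,
      ", acceptors n=", x$acceptor$n %||% NA, "\n", sep = "")
  invisible(x)
}

score_seqs <- function(part, kind, seqs, len, background) {
  m <- seq_matrix(seqs, len)
  bg <- log2(background)
  if (kind == "wmm") {
    lw <- log2(part$wmm)
    rowSums(sapply(seq_len(len), function(j) {
      lw[m[, j], j] - bg[m[, j]]
    }) |> matrix(nrow = nrow(m)))
  } else {
    s <- log2(part$p1[match(m[, 1L], BASES)]) - bg[m[, 1L]]
    for (j in 2:len) {
      s <- s + log2(part$cond[cbind(match(m[, j - 1L], BASES),
                                    match(m[, j], BASES),
                                    j - 1L)]) - bg[m[, j]]
    }
    s
  }
}

#' Score 5' splice-site 9-mers
#'
#' Sequences are 3 nt of exon + GT + 4 nt (for a reconstituted RS
#' donor: 3 exonic nt + the GT of AGGT + the 4 nt following AGGT).
#' Higher scores mean stronger donors; units are log2 odds against the
#' model background.
#'
#' @param model A `splice_model` (trained or loaded).
#' @param seqs Character vector of 9-mers with GT at positions 4-5.
#' @return Numeric score per sequence.
#' @export
score_donor <- function(model, seqs) {
  stopifnot(inherits(model, "splice_model"))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) != DONOR_LEN)) abort("donor sequences must have length 9")
  if (any(substr(seqs, 4L, 5L) != "GT")) abort("donor core GT missing at 4-5")
  if (any(grepl("[^ACGT]", seqs))) abort("donor sequences must be A/C/G/T")
  unname(score_seqs(model$donor, model$kind, seqs, DONOR_LEN,
                    model$background))
}

#' Score 3' splice-site 23-mers
#'
#' Sequences are 18 nt upstream + AG + 3 nt (for an AGGT acceptor
#' site: 18 nt + AGGT + 1 nt).
#'
#' @param model A `splice_model`.
#' @param seqs Character vector of 23-mers with AG at positions 19-20.
#' @return Numeric score per sequence.
#' @export
score_acceptor <- function(model, seqs) {
  stopifnot(inherits(model, "splice_model"))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) != ACCEPTOR_LEN)) {
    abort("acceptor sequences must have length 23")
  }
  if (any(substr(seqs, 19L, 20L) != "AG")) {
    abort("acceptor core AG missing at 19-20")
  }
  if (any(grepl("[^ACGT]", seqs))) abort("acceptor sequences must be A/C/G/T")
  unname(score_seqs(model$acceptor, model$kind, seqs, ACCEPTOR_LEN,
                    model$background))
}

#' @describeIn splice_model_from_seqs `tidy()` returns the model
#'   parameters as a long tibble (`side, position, context, base,
#'   log_odds`).
#' @param x A `splice_model`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.splice_model <- function(x, ...) {
  part_rows <- function(part, side, len) {
    bg <- log2(x$background)
    if (x$kind == "wmm") {
      lw <- log2(part$wmm)
      tidyr::expand_grid(position = seq_len(len), base = BASES) %>%
        mutate(side = side, context = ".",
               log_odds = purrr::map2_dbl(.data$position, .data$base,
                                          ~ lw[.y, .x] - bg[.y]))
    } else {
      first <- tibble(position = 1L, context = ".", base = BASES,
                      log_odds = log2(part$p1) - bg, side = side)
      rest <- tidyr::expand_grid(position = 2:len, context = BASES,
                                 base = BASES) %>%
        mutate(side = side,
               log_odds = purrr::pmap_dbl(
                 list(.data$position, .data$context, .data$base),
                 function(p, ctx, b) {
                   log2(part$cond[ctx, b, p - 1L]) - bg[b]
                 }))
      bind_rows(first, rest)
    }
  }
  bind_rows(part_rows(x$donor, "donor", DONOR_LEN),
            part_rows(x$acceptor, "acceptor", ACCEPTOR_LEN)) %>%
    select("side", "position", "context", "base", "log_odds")
}

#' Export a splice-site model as a parameter table
#'
#' Writes a TSV with columns `record, side, position, context, base,
#' value`: one `meta` record holding the model kind, `background`
#' records, and one `param` record per log-odds entry.  The format
#' round-trips through [load_scoring_tables()] with identical scores.
#'
#' @param model A `splice_model`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_scoring_tables <- function(model, path) {
  stopifnot(inherits(model, "splice_model"))
  params <- tidy(model) %>%
    mutate(record = "param", value = as.character(.data$log_odds)) %>%
    select("record", "side", "position", "context", "base", "value")
  meta <- tibble(record = c("meta", rep("background", 4L)),
                 side = ".", position = NA_integer_,
                 context = ".",
                 base = c(".", BASES),
                 value = c(model$kind,
                           as.character(model$background)))
  readr::write_tsv(bind_rows(meta, params), path, progress = FALSE)
  invisible(path)
}

#' Load a splice-site scoring model from a parameter table
#'
#' Reads the TSV format written by [write_scoring_tables()] and
#' rebuilds a model whose scores match the exported model exactly.
#' The loaded model reports kind `"loaded_tables"`.
#'
#' @param path Path to a scoring-table TSV.
#' @return A `splice_model`.
#' @export
load_scoring_tables <- function(path) {
  tab <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(paste0("malformed scoring table: ",
                                     conditionMessage(e)))
  )
  need <- c("record", "side", "position", "context", "base", "value")
  check_cols(tab, need, "scoring table")
  kind <- tab$value[tab$record == "meta"][1L]
  if (is.na(kind) || !kind %in% c("wmm", "markov1")) {
    abort("scoring table lacks a valid 'meta' kind record")
  }
  bgrows <- tab[tab$record == "background", ]
  if (nrow(bgrows) != 4L) abort("scoring table lacks 4 background records")
  background <- setNames(as.numeric(bgrows$value), bgrows$base)[BASES]
  bg <- log2(background)
  params <- tab[tab$record == "param", ] %>%
    mutate(position = as.integer(.data$position),
           value = as.numeric(.data$value))
  build <- function(side, len) {
    p <- params[params$side == side, ]
    if (kind == "wmm") {
      if (nrow(p) != 4L * len) {
        abort(paste0("scoring table: expected ", 4L * len, " ", side,
                     " entries, found ", nrow(p)))
      }
      lw <- matrix(NA_real_, 4L, len, dimnames = list(BASES, NULL))
      lw[cbind(match(p$base, BASES), p$position)] <- p$value + bg[p$base]
      if (anyNA(lw)) abort(paste0("scoring table: missing ", side, " entry"))
      list(wmm = 2^lw, n = NA_integer_)
    } else {
      p1r <- p[p$position == 1L, ]
      if (nrow(p1r) != 4L) abort(paste0("scoring table: missing ", side,
                                        " position-1 entries"))
      p1 <- 2^(setNames(p1r$value, p1r$base)[BASES] + bg)
      cond <- array(NA_real_, c(4, 4, len - 1L),
                    dimnames = list(prev = BASES, base = BASES, NULL))
      rest <- p[p$position > 1L, ]
      if (nrow(rest) != 16L * (len - 1L)) {
        abort(paste0("scoring table: incomplete ", side, " conditionals"))
      }
      cond[cbind(match(rest$context, BASES), match(rest$base, BASES),
                 rest$position - 1L)] <- 2^(rest$value + bg[rest$base])
      if (anyNA(cond)) abort(paste0("scoring table: missing ", side, " entry"))
      list(p1 = unname(p1), cond = cond, n = NA_integer_)
    }
  }
  structure(list(kind = kind, trained_kind = "loaded_tables",
                 donor = build("donor", DONOR_LEN),
                 acceptor = build("acceptor", ACCEPTOR_LEN),
                 background = background),
            class = "splice_model")
}

#' Sequence context around motif sites
#'
#' Summarises the primary sequence context of a site set: a per-
#' position base-frequency matrix over a `window`-nt sense window
#' centred on the AGGT (30 nt + AGGT + 30 nt for the default 64), the
#' per-site T/C/pyrimidine percentages over the `upstream` nt
#' immediately 5' of the A (the polypyrimidine-tract region), and the
#' fraction of sites matching the U1-pairing consensus AGGTAAGT (site
#' 4-mer AGGT followed by AAGT).
#'
#' Sites too close to a contig edge are skipped with a warning and
#' counted in `n_skipped`.
#'
#' @param sites Site tibble (needs `chrom, strand, a_pos, motif`).
#' @param genome A named [Biostrings::DNAStringSet].
#' @param window Total context window in nt (default 64).
#' @param upstream Upstream composition window in nt (default 20).
#' @return A `context_stats` object: list with `freq` (4 x window
#'   matrix, columns sum to 1), `composition` (per-site tibble
#'   `site_id, pct_t, pct_c, pct_py`), `aggtaagt_rate`, `n_sites`,
#'   `n_skipped`.
#' @export
context_stats <- function(sites, genome, window = 64, upstream = 20) {
  check_cols(sites, c("chrom", "strand", "a_pos", "motif"), "sites")
  widths <- setNames(Biostrings::width(genome), names(genome))
  up_ctx <- (window - 4L) %/% 2L          # nt before the A
  down_ctx <- window - 4L - up_ctx        # nt after the T of AGGT
  lo <- if_else(sites$strand == "+",
                sites$a_pos - pmax(up_ctx, upstream),
                sites$a_pos - 3L - down_ctx - 4L)
  # conservative single bound: compute both window extents explicitly
  win_lo <- if_else(sites$strand == "+", sites$a_pos - up_ctx,
                    sites$a_pos - 3L - down_ctx)
  win_hi <- if_else(sites$strand == "+", sites$a_pos + 3L + down_ctx,
                    sites$a_pos + up_ctx)
  ups_lo <- if_else(sites$strand == "+", sites$a_pos - upstream,
                    sites$a_pos + 1L)
  ups_hi <- if_else(sites$strand == "+", sites$a_pos - 1L,
                    sites$a_pos + upstream)
  ok <- pmin(win_lo, ups_lo) >= 1L &
    pmax(win_hi, ups_hi) <= widths[sites$chrom]
  n_skipped <- sum(!ok)
  if (n_skipped > 0L) {
    warn(paste0(n_skipped, " site(s) too close to a contig edge; skipped"))
  }
  s <- sites[ok, , drop = FALSE]
  if (nrow(s) == 0L) abort("no site with sufficient flanking sequence")
  ctx <- sense_seq(genome, s$chrom,
                   if_else(s$strand == "+", s$a_pos - up_ctx,
                           s$a_pos - 3L - down_ctx),
                   if_else(s$strand == "+", s$a_pos + 3L + down_ctx,
                           s$a_pos + up_ctx),
                   s$strand)
  m <- seq_matrix(ctx, window)
  freq <- sapply(seq_len(window), function(j) {
    col <- m[, j][m[, j] %in% BASES]
    as.numeric(table(factor(col, levels = BASES))) / max(length(col), 1L)
  })
  rownames(freq) <- BASES
  ups <- sense_seq(genome, s$chrom, ups_lo[ok], ups_hi[ok], s$strand)
  comp_of <- function(x, base) {
    100 * stringr::str_count(x, base) / nchar(x)
  }
  composition <- tibble(
    site_id = s$site_id %||% paste0(s$chrom, ":", s$a_pos, ":", s$strand),
    pct_t = comp_of(ups, "T"),
    pct_c = comp_of(ups, "C")
  ) %>% mutate(pct_py = .data$pct_t + .data$pct_c)
  next4 <- substr(ctx, up_ctx + 5L, up_ctx + 8L)
  aggtaagt_rate <- mean(s$motif == "AGGT" & next4 == "AAGT")
  structure(list(freq = freq, composition = composition,
                 aggtaagt_rate = aggtaagt_rate,
                 n_sites = nrow(s), n_skipped = n_skipped),
            class = "context_stats")
}

#' @export
print.context_stats <- function(x, ...) {
  cat("<context_stats> ", x$n_sites, " sites (", x$n_skipped,
      " skipped); AGGTAAGT match rate ", signif(x$aggtaagt_rate, 3),
      "; mean upstream %py ", signif(mean(x$composition$pct_py), 3),
      "\n", sep = "")
  invisible(x)
}

#' @describeIn context_stats `tidy()` returns the frequency matrix in
#'   long form (`position, base, freq`).
#' @param x A `context_stats` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.context_stats <- function(x, ...) {
  tidyr::expand_grid(position = seq_len(ncol(x$freq)), base = BASES) %>%
    mutate(freq = purrr::map2_dbl(.data$position, .data$base,
                                  ~ x$freq[.y, .x]))
}
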