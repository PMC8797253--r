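#' Pipeline configuration
#'
#' Collects every tunable threshold of the RS and cryptic-exon
#' pipelines with the published defaults: 1 kb minimum intron and
#' two-fold mRNA enrichment with 10 merged up-junction reads for RS
#' candidates; 50 kb, greater-than-one-fold, 10 up and 2 down for
#' cryptic exons; a 350-nt down-junction scan window.  Saw-tooth
#' automation parameters (`W`, `eps`, `tau_saw`, `tau_exon`, `tau_bg`,
#' `rho_max`, `bin_size`, `flank`) replace the visual inspection step
#' and are calibrated on the simulator.  Nothing is hard-coded: a
#' scaled-down world can lower the length thresholds coherently.
#'
#' @param min_intron,min_count,min_fold RS cascade thresholds
#'   (defaults 1000 nt, 10 reads, 2-fold).
#' @param cryptic_min_intron,cryptic_min_up,cryptic_min_down,cryptic_min_fold
#'   Cryptic cascade thresholds (defaults 50000 nt, 10, 2, 1-fold).
#' @param window Down-junction scan window in nt (default 350).
#' @param W Saw-tooth flank window in nt (default 5000).
#' @param eps Coverage pseudo-depth (default 0.1 reads/base).
#' @param tau_saw,tau_exon,tau_bg Classification thresholds (defaults
#'   1, 2 log2 units; 0.05 reads/base).
#' @param rho_max Maximum Spearman rho for a declining flank (default
#'   -0.3).
#' @param bin_size,flank Coverage binning and exon-likeness flank
#'   (defaults 200, 5000 nt).
#' @param strandedness Library strandedness (default `"forward"`).
#' @param pattern Acceptor motif pattern (default `"AGGT"`).
#' @param exclude_nn Optional NN exclusion for the AGNN pipeline
#'   (e.g. `"GT"`).
#' @param seed Seed recorded in the run manifest (default 1).
#' @return A list of class `rs_config`.
#' @export
rs_config <- function(min_intron = 1000, min_count = 10, min_fold = 2,
                      cryptic_min_intron = 50000, cryptic_min_up = 10,
                      cryptic_min_down = 2, cryptic_min_fold = 1,
                      window = 350, W = 5000, eps = 0.1, tau_saw = 1,
                      tau_exon = 2, tau_bg = 0.05, rho_max = -0.3,
                      bin_size = 200, flank = 5000,
                      strandedness = c("forward", "reverse", "unstranded"),
                      pattern = "AGGT", exclude_nn = NULL, seed = 1) {
  strandedness <- match.arg(strandedness)
  cfg <- as.list(environment())
  num <- c("min_intron", "min_count", "min_fold", "cryptic_min_intron",
           "cryptic_min_up", "cryptic_min_down", "cryptic_min_fold",
           "window", "W", "bin_size", "flank")
  for (f in num) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("config field '", f, "' must be a positive number"))
    }
  }
  structure(cfg, class = "rs_config")
}

read_alignment_set <- function(paths) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  }
  purrr::imap(paths, ~ read_sam(.x, sample_id = .y)) %>% bind_rows()
}

load_reference <- function(genome, annotation) {
  if (is.character(genome)) genome <- read_genome(genome)
  models <- if (inherits(annotation, "gene_models")) annotation else
    read_gene_models(annotation, genome)
  list(genome = genome, models = models)
}

#' Run the RS-site detection pipeline
#'
#' Wires the full cascade: gene models, motif scan, long-intron
#' filter, junction extraction, up-junction counting, the candidate
#' filters, down-junction scan, saw-tooth/exon-likeness evidence and
#' classification.  With `out_dir`, writes the calls/evidence TSVs and
#' a JSON run manifest (config, input checksums, depths, per-stage
#' attrition) sufficient to reproduce the run.
#'
#' @param genome Path to a FASTA file or a
#'   [Biostrings::DNAStringSet].
#' @param annotation Path to a GTF file or a [gene_models()] object.
#' @param total_sams Named character vector of total-RNA SAM paths
#'   (names are sample ids).
#' @param mrna_sams Named character vector of mRNA-control SAM paths.
#' @param config An [rs_config()].
#' @param out_dir Optional output directory.
#' @return An `rs_result`: list with `calls` (classified site table),
#'   `sites`, `site_counts`, `down`, `evidence`, `depths`,
#'   `attrition`, `config`.
#' @export
run_rs_pipeline <- function(genome, annotation, total_sams, mrna_sams,
                            config = rs_config(), out_dir = NULL) {
  stopifnot(inherits(config, "rs_config"))
  if (length(mrna_sams) == 0L) {
    abort("no mRNA control provided: the enrichment filter is undefined")
  }
  ref <- load_reference(genome, annotation)
  aln_total <- read_alignment_set(total_sams)
  aln_mrna <- read_alignment_set(mrna_sams)
  depths <- bind_rows(
    aln_total %>% count(.data$sample_id, name = "depth") %>%
      mutate(role = "total_rna"),
    aln_mrna %>% count(.data$sample_id, name = "depth") %>%
      mutate(role = "mrna_control")
  )
  sites <- scan_motif_sites(ref$models, ref$genome, config$pattern) %>%
    filter_intronic_sites(config$min_intron)
  junc <- bind_rows(extract_junctions(aln_total),
                    extract_junctions(aln_mrna))
  ups <- count_up_junctions(junc, sites, ref$models, depths,
                            strandedness = config$strandedness)
  calls <- call_candidates(ups, sites, depths,
                           min_intron = config$min_intron,
                           min_count = config$min_count,
                           min_fold = config$min_fold,
                           exclude_nn = config$exclude_nn)
  cand_sites <- sites %>%
    semi_join(calls %>% filter(.data$candidate), by = "site_id")
  down <- count_down_junctions(junc, cand_sites, ref$models, depths,
                               window = config$window,
                               strandedness = config$strandedness)
  evidence <- sawtooth_evidence(
    aln_total, cand_sites, ref$models, down_donors = down$donors,
    W = config$W, eps = config$eps, rho_max = config$rho_max,
    window = config$window, flank = config$flank,
    bin_size = config$bin_size, strandedness = config$strandedness)
  classified <- classify_candidates(calls, evidence,
                                    tau_saw = config$tau_saw,
                                    tau_exon = config$tau_exon,
                                    tau_bg = config$tau_bg)
  res <- structure(list(
    calls = classified, sites = sites, site_counts = ups, down = down,
    evidence = evidence, depths = depths,
    attrition = attrition(calls), config = config
  ), class = "rs_result")
  if (!is.null(out_dir)) {
    write_rs_result(res, out_dir,
                    inputs = c(if (is.character(genome)) genome,
                               if (is.character(annotation)) annotation,
                               total_sams, mrna_sams))
  }
  res
}

#' Run the RS-like cryptic-exon pipeline
#'
#' The companion cascade over very long introns (>= 50 kb by
#' default): greater-than-one-fold mRNA enrichment, 10 or more merged
#' up-junction reads, 2 or more down-junction reads, and an exon-like
#' but not saw-tooth-like coverage profile.
#'
#' @inheritParams run_rs_pipeline
#' @return An `rs_result` whose `calls` carry a `cryptic_exon` flag
#'   plus sequence columns from [build_splice_site_sequences()].
#' @export
run_cryptic_pipeline <- function(genome, annotation, total_sams,
                                 mrna_sams, config = rs_config(),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "rs_config"))
  if (length(mrna_sams) == 0L) {
    abort("no mRNA control provided: the enrichment filter is undefined")
  }
  ref <- load_reference(genome, annotation)
  aln_total <- read_alignment_set(total_sams)
  aln_mrna <- read_alignment_set(mrna_sams)
  depths <- bind_rows(
    aln_total %>% count(.data$sample_id, name = "depth") %>%
      mutate(role = "total_rna"),
    aln_mrna %>% count(.data$sample_id, name = "depth") %>%
      mutate(role = "mrna_control")
  )
  sites <- scan_motif_sites(ref$models, ref$genome, config$pattern) %>%
    filter_intronic_sites(config$cryptic_min_intron)
  junc <- bind_rows(extract_junctions(aln_total),
                    extract_junctions(aln_mrna))
  ups <- count_up_junctions(junc, sites, ref$models, depths,
                            strandedness = config$strandedness)
  # restrict the expensive scans to sites with any up-junction signal
  active <- ups %>%
    group_by(.data$site_id) %>%
    summarise(n = sum(.data$up_count), .groups = "drop") %>%
    filter(.data$n > 0L)
  act_sites <- sites %>% semi_join(active, by = "site_id")
  down <- count_down_junctions(junc, act_sites, ref$models, depths,
                               window = config$window,
                               strandedness = config$strandedness)
  evidence <- sawtooth_evidence(
    aln_total, act_sites, ref$models, down_donors = down$donors,
    W = config$W, eps = config$eps, rho_max = config$rho_max,
    window = config$window, flank = config$flank,
    bin_size = config$bin_size, strandedness = config$strandedness)
  calls <- call_cryptic_exons(
    ups %>% semi_join(active, by = "site_id"),
    down$counts, act_sites, depths, evidence,
    down_donors = down$donors,
    min_intron = config$cryptic_min_intron,
    min_up = config$cryptic_min_up, min_down = config$cryptic_min_down,
    min_fold = config$cryptic_min_fold, tau_exon = config$tau_exon,
    tau_saw = config$tau_saw)
  seqs <- build_splice_site_sequences(
    act_sites %>% semi_join(calls %>% filter(.data$cryptic_exon),
                            by = "site_id"),
    ref$models, ref$genome, down_donors = down$donors,
    window = config$window)
  calls <- calls %>% left_join(seqs, by = "site_id",
                               suffix = c("", "_seq"))
  res <- structure(list(
    calls = calls, sites = sites, site_counts = ups, down = down,
    evidence = evidence, depths = depths,
    attrition = attrition(calls), config = config
  ), class = "rs_result")
  if (!is.null(out_dir)) {
    write_rs_result(res, out_dir,
                    inputs = c(if (is.character(genome)) genome,
                               if (is.character(annotation)) annotation,
                               total_sams, mrna_sams))
  }
  res
}

#' Write pipeline outputs and a reproducibility manifest
#'
#' Emits `calls.tsv`, `site_counts.tsv`, `evidence.tsv`,
#' `attrition.tsv` and `manifest.json` (package version, full config,
#' MD5 checksums of the inputs, per-sample depths, per-stage survivor
#' counts).  Outputs are deterministic for fixed inputs + config, so
#' repeated runs are byte-identical.
#'
#' @param res An `rs_result`.
#' @param out_dir Output directory (created if needed).
#' @param inputs Character vector of input paths to checksum.
#' @return Named list of written paths, invisibly.
#' @export
write_rs_result <- function(res, out_dir, inputs = character()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    calls = file.path(out_dir, "calls.tsv"),
    site_counts = file.path(out_dir, "site_counts.tsv"),
    evidence = file.path(out_dir, "evidence.tsv"),
    attrition = file.path(out_dir, "attrition.tsv"),
    manifest = file.path(out_dir, "manifest.json")
  )
  readr::write_tsv(res$calls, paths$calls, progress = FALSE)
  readr::write_tsv(res$site_counts, paths$site_counts, progress = FALSE)
  readr::write_tsv(res$evidence, paths$evidence, progress = FALSE)
  readr::write_tsv(res$attrition, paths$attrition, progress = FALSE)
  manifest <- list(
    package = "recsplice",
    version = as.character(utils::packageVersion("recsplice")),
    config = unclass(res$config),
    inputs = as.list(tools::md5sum(inputs)),
    depths = res$depths,
    attrition = res$attrition
  )
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' @export
print.rs_result <- function(x, ...) {
  cat("<rs_result> ", nrow(x$calls), " sites evaluated\n", sep = "")
  if ("classification" %in% names(x$calls)) {
    tab <- table(x$calls$classification)
    cat("  classes: ",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n",
        sep = "")
  }
  if ("cryptic_exon" %in% names(x$calls)) {
    cat("  cryptic exons called: ", sum(x$calls$cryptic_exon), "\n",
        sep = "")
  }
  print(x$attrition)
  invisible(x)
}

#' @describeIn run_rs_pipeline `tidy()` returns the per-site call
#'   table.
#' @param x An `rs_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rs_result <- function(x, ...) as_tibble(x$calls)

#' @describeIn run_rs_pipeline `glance()` returns a one-row summary
#'   (sites evaluated, candidates, RS calls or cryptic calls, samples,
#'   total depth).
#' @exportS3Method generics::glance
glance.rs_result <- function(x, ...) {
  tibble(
    n_sites = nrow(x$calls),
    n_candidates = if ("candidate" %in% names(x$calls)) {
      sum(x$calls$candidate)
    } else NA_integer_,
    n_rs = if ("classification" %in% names(x$calls)) {
      sum(x$calls$classification == "RS")
    } else NA_integer_,
    n_cryptic = if ("cryptic_exon" %in% names(x$calls)) {
      sum(x$calls$cryptic_exon)
    } else NA_integer_,
    n_samples = nrow(x$depths),
    total_depth = sum(x$depths$depth)
  )
}
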