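# End-to-end mini-barcode design: alignment statistics -> reference NJ tree
# -> sliding-window scan -> candidate selection -> best fragment -> barcode
# gap on the fragment -> primer design in its flanks -> in-silico PCR across
# all input sequences.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full mini-barcode design workflow
#'
#' Accepts either a species-labelled alignment or a simulation configuration
#' (which is simulated first with `seed`). All stages of the design are run
#' in order; artifacts are optionally written to `out_dir` together with a
#' machine-readable JSON summary. Every number in the report is recomputable
#' from the inputs, the configuration and the seed.
#'
#' @param input a `species_alignment` or a `simulation_config`.
#' @param lengths,step,per_length,min_sites_frac scan settings
#'   (see \code{\link{minibar_scan}}).
#' @param flank_width,len_range,clamp_len,max_degeneracy,freq_threshold
#'   primer-design settings (see \code{\link{design_primers}}).
#' @param max_mismatch,pcr_clamp_len,len_bounds in-silico PCR settings
#'   (see \code{\link{insilico_pcr}}).
#' @param bin_width barcode-gap histogram bin width.
#' @param seed seed used when `input` is a `simulation_config`.
#' @param out_dir optional output directory for artifacts (FASTA slices,
#'   TSV tables, Newick trees, JSON summary).
#' @return a `minibar_design` object: `scan` (a `minibar_scan`), `gap`
#'   (a `barcode_gap` for the winning fragment), `primers` (a
#'   `primer_pair`), `pcr` (an `insilico_pcr` table), `species_success`,
#'   `stats`, `truth` (when simulated), `config` (all settings), `summary`
#'   (plain list mirrored to JSON).
#' @export
run_full_design <- function(input,
                            lengths = seq(100L, 230L, by = 10L), step = 10L,
                            per_length = 2L, min_sites_frac = 0.5,
                            flank_width = 60L, len_range = c(18L, 25L),
                            clamp_len = 3L, max_degeneracy = 32L,
                            freq_threshold = 0.05,
                            max_mismatch = 2L, pcr_clamp_len = 2L,
                            len_bounds = c(50L, 2000L),
                            bin_width = 0.01, seed = 1L, out_dir = NULL) {
  truth <- NULL
  if (inherits(input, "simulation_config")) {
    sim <- .stage("simulate", simulate_dataset(input, seed))
    aln <- sim$alignment
    truth <- sim$truth
  } else if (inherits(input, "species_alignment")) {
    aln <- input
  } else stop("input must be a species_alignment or a simulation_config",
              call. = FALSE)

  scan <- .stage("scan", minibar_scan(aln, lengths, step, per_length,
                                      min_sites_frac))
  best <- scan$best
  frag <- .stage("slice", slice_alignment(aln, best$window$start, best$window$end))
  frag_m <- .stage("fragment_distances", k2p_matrix(frag, min_sites_frac))
  gap <- .stage("gap", barcode_gap(partition_distances(frag_m), bin_width))
  primers <- .stage("design", design_primers(aln, best$window, flank_width,
                                             len_range, clamp_len,
                                             max_degeneracy, freq_threshold))
  pcr <- .stage("ispcr", insilico_pcr(primers, aln, max_mismatch,
                                      pcr_clamp_len, len_bounds))
  sp_succ <- amplification_by_species(pcr)

  config <- list(lengths = lengths, step = step, per_length = per_length,
                 min_sites_frac = min_sites_frac, flank_width = flank_width,
                 len_range = len_range, clamp_len = clamp_len,
                 max_degeneracy = max_degeneracy,
                 freq_threshold = freq_threshold, max_mismatch = max_mismatch,
                 pcr_clamp_len = pcr_clamp_len, len_bounds = len_bounds,
                 bin_width = bin_width, seed = seed)
  summary <- list(
    config = config,
    n_sequences = length(aln$id),
    n_species = length(unique(aln$species)),
    n_columns = aln$n_columns,
    stats = list(V = scan$stats$V, Pi = scan$stats$Pi,
                 composition = as.list(scan$stats$composition)),
    n_windows = nrow(scan$scores),
    n_candidates = nrow(scan$candidates),
    best_fragment = best$window,
    best_k_score = best$comparison$k_score,
    best_rf = best$comparison$rf,
    gap = list(max_intra = gap$max_intra, min_inter = gap$min_inter,
               gap = gap$gap, gap_present = gap$gap_present,
               jm_sqrt = gap$jm_sqrt, jm_two = gap$jm_two),
    primers = list(forward = primers$forward, reverse = primers$reverse,
                   fwd_span = primers$fwd_span, rev_span = primers$rev_span,
                   degeneracy_f = primers$degeneracy_f,
                   degeneracy_r = primers$degeneracy_r),
    amplification = list(n_targets = nrow(pcr),
                         n_success = sum(pcr$success),
                         species_all_amplified = all(sp_succ$any_success)),
    warnings = list(missing_pairs = sum(is.na(scan$full_matrix$d[
      lower.tri(scan$full_matrix$d)])),
      saturated_pairs = scan$full_matrix$n_saturated,
      dropped_taxa = attr(scan$ref_tree, "dropped"))
  )

  res <- structure(
    list(scan = scan, gap = gap, primers = primers, pcr = pcr,
         species_success = sp_succ, stats = scan$stats, truth = truth,
         alignment = aln, config = config, summary = summary),
    class = "minibar_design"
  )
  if (!is.null(out_dir)) write_design_artifacts(res, out_dir)
  res
}

#' Write all design artifacts to a directory
#'
#' Emits `alignment_stats.tsv`, `window_scores.tsv`, `candidates.tsv`,
#' `reference_tree.nwk`, the winning fragment slice as FASTA, the gap
#' histogram TSV, `primers.fasta`, `amplification.tsv` and `summary.json`.
#'
#' @param design a `minibar_design`.
#' @param out_dir directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_design_artifacts <- function(design, out_dir) {
  stopifnot(inherits(design, "minibar_design"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(x) file.path(out_dir, x)
  write_stats_tsv(design$stats, fp("alignment_stats.tsv"))
  write_scores_tsv(design$scan$scores, fp("window_scores.tsv"))
  write_scores_tsv(design$scan$best$table, fp("candidates.tsv"))
  write_tree_newick(design$scan$ref_tree, fp("reference_tree.nwk"))
  w <- design$scan$best$window
  write_alignment(slice_alignment(design$alignment, w$start, w$end),
                  fp(paste0("fragment_", w$name, ".fasta")))
  write_gap_histogram_tsv(design$gap, fp("gap_histogram.tsv"))
  write_primers_fasta(design$primers, fp("primers.fasta"))
  utils::write.table(design$pcr[, setdiff(names(design$pcr), "predicted_amplicon")],
                     fp("amplification.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(design$summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.minibar_design <- function(x, ...) {
  cat("Mini-barcode design report\n")
  cat("  input: ", x$summary$n_sequences, " sequences, ",
      x$summary$n_species, " species, ", x$summary$n_columns, " columns\n",
      sep = "")
  print(x$scan$best)
  cat("  barcode gap: ", format(x$gap$gap, digits = 4L),
      if (x$gap$gap_present) " (present)" else " (absent)",
      "; J-M sqrt = ", format(x$gap$jm_sqrt, digits = 4L),
      ", two = ", format(x$gap$jm_two, digits = 4L), "\n", sep = "")
  cat("  primers: F 5'-", x$primers$forward, "-3' / R 5'-",
      x$primers$reverse, "-3'\n", sep = "")
  cat("  in-silico PCR: ", sum(x$pcr$success), "/", nrow(x$pcr),
      " targets, ", sum(x$species_success$any_success), "/",
      nrow(x$species_success), " species amplified\n", sep = "")
  invisible(x)
}

#' @export
summary.minibar_design <- function(object, ...) {
  print(object)
  cat("\n")
  summary(object$scan)
  cat("\n")
  print(object$gap)
  cat("\n")
  print(object$primers)
  invisible(object)
}

#' @export
plot.minibar_design <- function(x, which = c("scan", "gap"), ...) {
  which <- match.arg(which)
  if (which == "scan") plot(x$scan, ...) else plot(x$gap, ...)
  invisible(x)
}
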