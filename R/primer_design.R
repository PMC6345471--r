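# Degenerate primer design from the conserved flanks of a selected window,
# and in-silico PCR: a degenerate-aware site search with a mismatch budget
# and an exact 3'-clamp requirement, the computational analog of a
# cross-species amplification panel.

#' Threshold consensus of alignment columns as an IUPAC string
#'
#' Per column, the IUPAC code covering every unambiguous base whose frequency
#' (among unambiguous bases in that column; gaps and ambiguity codes excluded
#' from the denominator) reaches `freq_threshold`. A column with no
#' qualifying base (e.g. all-gap) becomes `N`, with a warning for all-gap
#' columns.
#'
#' @param aln a `species_alignment`.
#' @param region 1-based inclusive column range `c(start, end)`.
#' @param freq_threshold minimum base frequency to be covered (default 0.05).
#' @return IUPAC consensus string of length `diff(region) + 1`.
#' @export
consensus_iupac <- function(aln, region, freq_threshold = 0.05) {
  stopifnot(inherits(aln, "species_alignment"), length(region) == 2L)
  s <- as.integer(region[1L]); e <- as.integer(region[2L])
  if (s < 1L || e > aln$n_columns || s > e)
    stop("region [", s, ", ", e, "] outside alignment", call. = FALSE)
  m <- alignment_matrix(aln)[, s:e, drop = FALSE]
  bases <- c("A", "C", "G", "T")
  out <- character(ncol(m))
  for (k in seq_len(ncol(m))) {
    col <- m[, k]
    cnt <- table(factor(col[col %in% bases], levels = bases))
    tot <- sum(cnt)
    if (tot == 0L) {
      if (all(col == "-")) warning("all-gap column at position ", s + k - 1L,
                                   "; consensus N", call. = FALSE)
      out[k] <- "N"
      next
    }
    keep <- bases[cnt / tot >= freq_threshold]
    out[k] <- if (length(keep)) iupac_code(keep) else "N"
  }
  paste(out, collapse = "")
}

#' Wallace-rule melting-temperature range of a degenerate primer
#'
#' Tm = 2(A+T) + 4(G+C) evaluated over the two extreme degenerate expansions
#' (minimum-GC and maximum-GC).
#'
#' @param primer IUPAC string.
#' @return numeric `c(min, max)` in degrees C.
#' @export
tm_estimate <- function(primer) {
  ch <- strsplit(toupper(primer), "", fixed = TRUE)[[1]]
  sets <- lapply(ch, iupac_bases)
  lo <- sum(vapply(sets, function(s) if (any(s %in% c("A", "T"))) 2 else 4, 0))
  hi <- sum(vapply(sets, function(s) if (any(s %in% c("G", "C"))) 4 else 2, 0))
  c(min = lo, max = hi)
}

.count_nondeg_clamp <- function(primer_chars, clamp_idx) {
  sum(vapply(primer_chars[clamp_idx], function(c) length(iupac_bases(c)) == 1L, TRUE))
}

# search one flank for the best primer placement; `side` decides which end of
# the consensus is the 3' end (forward: right; reverse: left, since the
# reverse primer is the reverse complement of its sense-strand site)
.scan_flank <- function(aln, flank, len_range, clamp_len, max_degeneracy,
                        freq_threshold, side, window_edge) {
  cons_full <- strsplit(consensus_iupac(aln, flank, freq_threshold), "", fixed = TRUE)[[1]]
  best <- NULL
  width <- flank[2L] - flank[1L] + 1L
  for (L in seq(len_range[1L], min(len_range[2L], width))) {
    for (off in 0:(width - L)) {
      cols <- (flank[1L] + off):(flank[1L] + off + L - 1L)
      chars <- cons_full[(off + 1L):(off + L)]
      deg <- prod(vapply(chars, function(c) length(iupac_bases(c)), 1L))
      if (deg > max_degeneracy) next
      clamp_idx <- if (side == "forward") (L - clamp_len + 1L):L else seq_len(clamp_len)
      clamp_ok <- .count_nondeg_clamp(chars, clamp_idx)
      prox <- abs(window_edge - if (side == "forward") cols[L] else cols[1L])
      cand <- list(cols = cols, chars = chars, deg = deg,
                   clamp_ok = clamp_ok, prox = prox)
      if (is.null(best) ||
          deg < best$deg ||
          (deg == best$deg && clamp_ok > best$clamp_ok) ||
          (deg == best$deg && clamp_ok == best$clamp_ok && prox < best$prox))
        best <- cand
    }
  }
  best
}

#' Design a degenerate primer pair flanking a window
#'
#' Scans candidate placements of length `len_range` inside the upstream flank
#' (forward primer) and downstream flank (reverse primer, emitted as the
#' reverse complement of its sense-strand consensus). Placements exceeding
#' `max_degeneracy` are rejected; among the rest the scoring prefers lower
#' degeneracy, then more non-degenerate positions in the 3'-terminal
#' `clamp_len` bases, then proximity to the window.
#'
#' @param aln a `species_alignment` (the full-length alignment).
#' @param window list/row with `start` and `end` (the selected fragment).
#' @param flank_width columns searched on each side of the window (default 60).
#' @param len_range primer length range in bp (default `c(18, 25)`).
#' @param clamp_len 3'-clamp width used in scoring (default 3).
#' @param max_degeneracy maximum tolerated degeneracy (default 32).
#' @param freq_threshold consensus base-frequency threshold (default 0.05).
#' @return a `primer_pair` object: `forward`, `reverse` (IUPAC, 5'->3'),
#'   `fwd_span`, `rev_span` (alignment columns), `degeneracy_f`,
#'   `degeneracy_r`, `tm_range_f`, `tm_range_r`, `amplicon_span`,
#'   `amplicon_length`.
#' @export
design_primers <- function(aln, window, flank_width = 60L,
                           len_range = c(18L, 25L), clamp_len = 3L,
                           max_degeneracy = 32L, freq_threshold = 0.05) {
  stopifnot(inherits(aln, "species_alignment"))
  ws <- as.integer(window$start); we <- as.integer(window$end)
  if (ws - flank_width < 1L || we + flank_width > aln$n_columns)
    stop("design error: window lacks ", flank_width,
         " flanking columns on each side", call. = FALSE)
  up <- c(ws - flank_width, ws - 1L)
  down <- c(we + 1L, we + flank_width)
  fwd <- .scan_flank(aln, up, len_range, clamp_len, max_degeneracy,
                     freq_threshold, "forward", ws)
  if (is.null(fwd))
    stop("design error: no feasible forward placement in the upstream flank ",
         "(degeneracy cap ", max_degeneracy, " exceeded everywhere)", call. = FALSE)
  rev <- .scan_flank(aln, down, len_range, clamp_len, max_degeneracy,
                     freq_threshold, "reverse", we)
  if (is.null(rev))
    stop("design error: no feasible reverse placement in the downstream flank ",
         "(degeneracy cap ", max_degeneracy, " exceeded everywhere)", call. = FALSE)
  forward <- paste(fwd$chars, collapse = "")
  rev_sense <- paste(rev$chars, collapse = "")
  reverse <- revcomp_iupac(rev_sense)
  fwd_span <- range(fwd$cols)
  rev_span <- range(rev$cols)
  structure(
    list(forward = forward, reverse = reverse,
         fwd_span = fwd_span, rev_span = rev_span,
         degeneracy_f = primer_degeneracy(forward),
         degeneracy_r = primer_degeneracy(reverse),
         tm_range_f = tm_estimate(forward), tm_range_r = tm_estimate(reverse),
         amplicon_span = c(fwd_span[1L], rev_span[2L]),
         amplicon_length = rev_span[2L] - fwd_span[1L] + 1L),
    class = "primer_pair"
  )
}

#' @export
print.primer_pair <- function(x, ...) {
  cat("Degenerate primer pair\n")
  cat("  forward: 5'-", x$forward, "-3'  (cols ", x$fwd_span[1L], "-",
      x$fwd_span[2L], ", degeneracy ", x$degeneracy_f, ", Tm ",
      x$tm_range_f[1L], "-", x$tm_range_f[2L], " C)\n", sep = "")
  cat("  reverse: 5'-", x$reverse, "-3'  (cols ", x$rev_span[1L], "-",
      x$rev_span[2L], ", degeneracy ", x$degeneracy_r, ", Tm ",
      x$tm_range_r[1L], "-", x$tm_range_r[2L], " C)\n", sep = "")
  cat("  amplicon: cols ", x$amplicon_span[1L], "-", x$amplicon_span[2L],
      " (", x$amplicon_length, " bp in alignment coordinates)\n", sep = "")
  invisible(x)
}

# best degenerate-match site of a sense-strand motif in a target sequence;
# clamp_idx = motif positions that must match exactly. Returns the best site
# (fewest mismatches, then leftmost) honouring the clamp, plus whether a
# budget-passing site failed only the clamp.
.find_site <- function(motif_sets, target_chars, max_mismatch, clamp_idx) {
  L <- length(motif_sets)
  M <- length(target_chars)
  if (M < L) return(list(site = NULL, clamp_only = FALSE))
  match_pos <- matrix(FALSE, L, M)
  for (l in seq_len(L)) match_pos[l, ] <- target_chars %in% motif_sets[[l]]
  best <- NULL
  clamp_only <- FALSE
  for (o in seq_len(M - L + 1L)) {
    hits <- match_pos[cbind(seq_len(L), o:(o + L - 1L))]
    mm <- L - sum(hits)
    if (mm > max_mismatch) next
    if (!all(hits[clamp_idx])) { clamp_only <- TRUE; next }
    if (is.null(best) || mm < best$mm) best <- list(start = o, end = o + L - 1L, mm = mm)
  }
  list(site = best, clamp_only = clamp_only)
}

#' In-silico PCR of a primer pair against target sequences
#'
#' Degenerate-aware sliding match of the forward primer on the sense strand
#' and of the reverse primer on the antisense strand (i.e. its reverse
#' complement on the sense strand). A site is accepted when its mismatch
#' count is at most `max_mismatch` AND the 3'-terminal `clamp_len` positions
#' match exactly; the best (fewest mismatches, then leftmost) site per primer
#' is used. Amplification succeeds when the forward site lies upstream of the
#' reverse site and the product length falls within `len_bounds`. Failures
#' are results, not errors.
#'
#' @param pair a `primer_pair`.
#' @param targets data.frame with columns `id`, `species`, `sequence`
#'   (gap-free nucleotide strings), or a `species_alignment` (gaps are
#'   stripped).
#' @param max_mismatch mismatch budget per primer site (default 2).
#' @param clamp_len 3'-terminal positions that must match exactly (default 2).
#' @param len_bounds allowed product length `c(min, max)` in bp.
#' @return data.frame (class `insilico_pcr`) with one row per target:
#'   `target_id`, `species`, `success`, `fwd_mismatches`, `rev_mismatches`,
#'   `amplicon_length`, `failure_reason` (one of `no_fwd_site`,
#'   `no_rev_site`, `three_prime_mismatch`, `orientation`,
#'   `length_out_of_bounds`, or `""`), `predicted_amplicon`.
#' @export
insilico_pcr <- function(pair, targets, max_mismatch = 2L, clamp_len = 2L,
                         len_bounds = c(50L, 2000L)) {
  stopifnot(inherits(pair, "primer_pair"))
  if (inherits(targets, "species_alignment"))
    targets <- data.frame(id = targets$id, species = targets$species,
                          sequence = gsub("-", "", targets$seq, fixed = TRUE),
                          stringsAsFactors = FALSE)
  stopifnot(all(c("id", "species", "sequence") %in% names(targets)))
  fwd_sets <- lapply(strsplit(pair$forward, "", fixed = TRUE)[[1]], iupac_bases)
  rev_sense <- revcomp_iupac(pair$reverse)
  rev_sets <- lapply(strsplit(rev_sense, "", fixed = TRUE)[[1]], iupac_bases)
  Lf <- length(fwd_sets); Lr <- length(rev_sets)
  fwd_clamp <- (Lf - clamp_len + 1L):Lf      # 3' end of forward = right end
  rev_clamp <- seq_len(clamp_len)            # 3' end of reverse = left end on sense
  rows <- lapply(seq_len(nrow(targets)), function(i) {
    tch <- strsplit(toupper(targets$sequence[i]), "", fixed = TRUE)[[1]]
    f <- .find_site(fwd_sets, tch, max_mismatch, fwd_clamp)
    r <- .find_site(rev_sets, tch, max_mismatch, rev_clamp)
    reason <- ""
    amp_len <- NA_integer_
    amplicon <- NA_character_
    success <- FALSE
    if (is.null(f$site)) {
      reason <- if (f$clamp_only) "three_prime_mismatch" else "no_fwd_site"
    } else if (is.null(r$site)) {
      reason <- if (r$clamp_only) "three_prime_mismatch" else "no_rev_site"
    } else if (r$site$start <= f$site$start) {
      reason <- "orientation"
    } else {
      amp_len <- r$site$end - f$site$start + 1L
      if (amp_len < len_bounds[1L] || amp_len > len_bounds[2L]) {
        reason <- "length_out_of_bounds"
      } else {
        success <- TRUE
        amplicon <- paste(tch[f$site$start:r$site$end], collapse = "")
      }
    }
    data.frame(target_id = targets$id[i], species = targets$species[i],
               success = success,
               fwd_mismatches = if (is.null(f$site)) NA_integer_ else f$site$mm,
               rev_mismatches = if (is.null(r$site)) NA_integer_ else r$site$mm,
               amplicon_length = amp_len, failure_reason = reason,
               predicted_amplicon = amplicon, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("insilico_pcr", "data.frame")
  out
}

#' @export
print.insilico_pcr <- function(x, ...) {
  cat("In-silico PCR: ", sum(x$success), "/", nrow(x), " targets amplified; ",
      length(unique(x$species[x$success])), "/", length(unique(x$species)),
      " species\n", sep = "")
  print.data.frame(x[, c("target_id", "species", "success", "fwd_mismatches",
                         "rev_mismatches", "amplicon_length", "failure_reason")],
                   row.names = FALSE)
  invisible(x)
}

#' Per-species amplification summary
#'
#' @param results an `insilico_pcr` data.frame.
#' @return data.frame with `species`, `n_targets`, `n_success`,
#'   `any_success`, `all_success`.
#' @export
amplification_by_species <- function(results) {
  sp <- split(results$success, results$species)
  data.frame(species = names(sp),
             n_targets = vapply(sp, length, 1L),
             n_success = vapply(sp, sum, 1L),
             any_success = vapply(sp, any, TRUE),
             all_success = vapply(sp, all, TRUE),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write primers as FASTA
#' @param pair a `primer_pair`.
#' @param path output file.
#' @param name_prefix primer name prefix (default `"minibar"`).
#' @return `path`, invisibly.
#' @export
write_primers_fasta <- function(pair, path, name_prefix = "minibar") {
  stopifnot(inherits(pair, "primer_pair"))
  writeLines(c(paste0(">", name_prefix, "F"), pair$forward,
               paste0(">", name_prefix, "R"), pair$reverse), path)
  invisible(path)
}
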