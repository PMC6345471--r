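# Barcode-gap analysis: do the intraspecific and interspecific distance
# distributions separate? Reports the empirical gap (min interspecific minus
# max intraspecific), histogram bins for plotting, and the Jeffries-Matusita
# separability statistic computed from the Bhattacharyya distance between the
# two classes summarised as univariate normals.

.normal_summary <- function(x) {
  list(mean = mean(x), sd = if (length(x) > 1L) stats::sd(x) else 0, n = length(x))
}

#' Bhattacharyya distance between two univariate normal summaries
#'
#' \deqn{B = \frac{1}{8}(\mu_1-\mu_2)^2 \frac{2}{\sigma_1^2+\sigma_2^2}
#'       + \frac{1}{2}\ln\frac{\sigma_1^2+\sigma_2^2}{2\sigma_1\sigma_2}}
#'
#' Standard deviations are floored at `sigma_floor` to keep degenerate
#' (constant) classes finite; two degenerate classes with equal means give 0
#' by continuity.
#'
#' @param mean1,sd1,mean2,sd2 class summaries.
#' @param sigma_floor lower bound applied to each standard deviation.
#' @return the Bhattacharyya distance (nonnegative).
#' @export
bhattacharyya_normal <- function(mean1, sd1, mean2, sd2, sigma_floor = 1e-6) {
  if (sd1 <= 0 && sd2 <= 0 && mean1 == mean2) return(0)
  s1 <- max(sd1, sigma_floor)
  s2 <- max(sd2, sigma_floor)
  v <- s1^2 + s2^2
  (1 / 8) * (mean1 - mean2)^2 * (2 / v) + 0.5 * log(v / (2 * s1 * s2))
}

#' Jeffries-Matusita distance between two normal class summaries
#'
#' Bounded transform of the Bhattacharyya distance `B`. Two conventions are
#' in circulation and both are provided: the square-root form
#' \eqn{\sqrt{2(1-e^{-B})}}, asymptotic to \eqn{\sqrt 2 \approx 1.414} for
#' fully separable classes, and the two form \eqn{2(1-e^{-B})}, asymptotic
#' to 2.
#'
#' @inheritParams bhattacharyya_normal
#' @param form `"sqrt"` (default, saturates at 1.414...) or `"two"`
#'   (saturates at 2).
#' @return the J-M distance.
#' @examples
#' jm_distance(0, 1, 1000, 1)          # ~1.414: fully separable
#' jm_distance(0, 1, 1000, 1, form = "two")  # ~2 under the other convention
#' @export
jm_distance <- function(mean1, sd1, mean2, sd2, form = c("sqrt", "two"),
                        sigma_floor = 1e-6) {
  form <- match.arg(form)
  B <- bhattacharyya_normal(mean1, sd1, mean2, sd2, sigma_floor)
  base <- 2 * (1 - exp(-B))
  if (form == "sqrt") sqrt(base) else base
}

#' Barcode-gap analysis of a distance partition
#'
#' Computes the extremes of the intra- and interspecific distance multisets,
#' the barcode gap (minimum interspecific minus maximum intraspecific), a
#' shared histogram for plotting, and the Jeffries-Matusita separability of
#' the two classes (both conventions, from their normal summaries with
#' sample standard deviations).
#'
#' @param p a `distance_partition` (see \code{\link{partition_distances}}).
#' @param bin_width histogram bin width on the distance axis (default 0.01).
#' @param sigma_floor standard-deviation floor for the J-M computation.
#' @return a `barcode_gap` object: `max_intra`, `min_inter`, `gap`,
#'   `gap_present`, `B`, `jm_sqrt`, `jm_two`, `intra_summary`,
#'   `inter_summary`, `histogram` (data.frame `bin_lo`, `bin_hi`,
#'   `intra_count`, `inter_count`).
#' @export
barcode_gap <- function(p, bin_width = 0.01, sigma_floor = 1e-6) {
  stopifnot(inherits(p, "distance_partition"))
  if (length(p$intra) == 0L)
    stop("analysis error: intraspecific distance class is empty", call. = FALSE)
  if (length(p$inter) == 0L)
    stop("analysis error: interspecific distance class is empty", call. = FALSE)
  max_intra <- max(p$intra)
  min_inter <- min(p$inter)
  gap <- min_inter - max_intra
  si <- .normal_summary(p$intra)
  se <- .normal_summary(p$inter)
  B <- bhattacharyya_normal(si$mean, si$sd, se$mean, se$sd, sigma_floor)
  top <- max(p$intra, p$inter)
  breaks <- seq(0, (floor(top / bin_width) + 1L) * bin_width, by = bin_width)
  hi <- graphics::hist(p$intra, breaks = breaks, plot = FALSE)$counts
  he <- graphics::hist(p$inter, breaks = breaks, plot = FALSE)$counts
  structure(
    list(max_intra = max_intra, min_inter = min_inter, gap = gap,
         gap_present = gap > 0, B = B,
         jm_sqrt = sqrt(2 * (1 - exp(-B))), jm_two = 2 * (1 - exp(-B)),
         intra_summary = si, inter_summary = se,
         histogram = data.frame(bin_lo = utils::head(breaks, -1L),
                                bin_hi = breaks[-1L],
                                intra_count = hi, inter_count = he)),
    class = "barcode_gap"
  )
}

#' @export
print.barcode_gap <- function(x, ...) {
  cat("Barcode-gap analysis\n")
  cat("  intraspecific: n = ", x$intra_summary$n, ", range up to ",
      format(x$max_intra, digits = 4L), "\n", sep = "")
  cat("  interspecific: n = ", x$inter_summary$n, ", range from ",
      format(x$min_inter, digits = 4L), "\n", sep = "")
  cat("  gap = ", format(x$gap, digits = 4L),
      if (x$gap_present) " (barcode gap present)" else " (classes overlap)",
      "\n", sep = "")
  cat("  Jeffries-Matusita: ", format(x$jm_sqrt, digits = 4L),
      " (sqrt form, max 1.414) / ", format(x$jm_two, digits = 4L),
      " (two form, max 2)\n", sep = "")
  invisible(x)
}

#' @export
plot.barcode_gap <- function(x, ...) {
  h <- x$histogram
  mids <- (h$bin_lo + h$bin_hi) / 2
  m <- rbind(intra = h$intra_count, inter = h$inter_count)
  graphics::barplot(m, beside = TRUE, names.arg = format(mids, digits = 2L),
                    legend.text = c("intraspecific", "interspecific"),
                    xlab = "K2P distance", ylab = "pair count",
                    main = "Barcode gap", las = 2L, cex.names = 0.6, ...)
  invisible(x)
}

#' Write the barcode-gap histogram as TSV
#' @param gap a `barcode_gap` object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gap_histogram_tsv <- function(gap, path) {
  stopifnot(inherits(gap, "barcode_gap"))
  utils::write.table(gap$histogram, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
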