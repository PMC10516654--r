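#' Estimate the expected peak width of a coverage track
#'
#' Adaptive width estimation ahead of kernel construction: (i) find all
#' candidate summits, i.e. (plateau-aware) local maxima whose coverage exceeds
#' `threshold_mult` times the genome-wide mean; (ii) for each, measure the
#' distance between the nearest flanking positions at which coverage drops
#' below half the summit height; (iii) return the median of those widths.
#'
#' @param track A `coverage_track` tibble (a single replicate; if several are
#'   present the first is used).
#' @param threshold_mult Summit threshold as a multiple of mean coverage.
#' @return Expected peak width in bp (scalar).
#' @export
estimate_expected_width <- function(track, threshold_mult = 3) {
  values <- track_values(track)[[1]]
  if (length(values) == 0) abort("empty coverage track")
  thr <- threshold_mult * mean(values)
  summits <- plateau_local_maxima(values)
  summits <- summits[values[summits] > thr]
  if (length(summits) == 0) {
    abort(
      paste0("no candidate peak exceeds ", threshold_mult,
             "x mean coverage; supply `fixed_width` in peakcall_config()"),
      class = "mrpr_no_candidate_error"
    )
  }
  widths <- vapply(summits, function(s) half_height_width(values, s), double(1))
  median(widths)
}

# Leftmost indices of plateau-aware local maxima of a numeric vector.
plateau_local_maxima <- function(values) {
  r <- rle(values)
  k <- length(r$values)
  if (k == 1) return(integer())
  starts <- cumsum(c(1L, r$lengths[-k]))
  left_lower <- c(FALSE, r$values[-1] > r$values[-k])
  right_lower <- c(r$values[-k] > r$values[-1], FALSE)
  starts[left_lower & right_lower]
}

# Number of bases >= half the summit height between the nearest flanking
# positions where coverage drops below half of it.
half_height_width <- function(values, summit) {
  half <- values[summit] / 2
  below <- values < half
  left <- summit
  while (left >= 1 && !below[left]) left <- left - 1L
  right <- summit
  n <- length(values)
  while (right <= n && !below[right]) right <- right + 1L
  right - left - 1
}

#' Build a mean-subtracted Ricker kernel for peak detection
#'
#' The kernel is the negative second derivative of a Gaussian ("Mexican hat"),
#' `w(x) = (1 - x^2/sigma^2) * exp(-x^2 / (2 sigma^2))`, with
#' `sigma = expected_width / 2` so the distance between its positive-lobe zero
#' crossings matches the expected peak width (a matched filter for the bump
#' shape). Support is truncated at four sigmas and the weights are then
#' mean-subtracted so they sum exactly to zero: convolution with any constant
#' background is identically zero.
#'
#' @param expected_width Expected peak width in bp (>= 2), typically from
#'   [estimate_expected_width()].
#' @return An object of class `ricker_kernel`: list with `sigma`, `half_width`
#'   (= `ceiling(4 * sigma)`) and `weights` (length `2 * half_width + 1`).
#' @export
build_kernel <- function(expected_width) {
  if (!is.numeric(expected_width) || expected_width < 2) {
    abort("`expected_width` must be >= 2 bp")
  }
  sigma <- expected_width / 2
  half_width <- as.integer(ceiling(4 * sigma))
  x <- seq(-half_width, half_width)
  w <- (1 - x^2 / sigma^2) * exp(-x^2 / (2 * sigma^2))
  w <- w - mean(w)
  structure(list(sigma = sigma, half_width = half_width, weights = w),
            class = "ricker_kernel")
}

#' @export
print.ricker_kernel <- function(x, ...) {
  cat("<ricker_kernel> sigma =", x$sigma, "bp, support", 2 * x$half_width + 1,
      "bp, sum(weights) =", signif(sum(x$weights), 3), "\n")
  invisible(x)
}

#' Convolve a coverage track with a kernel
#'
#' `response[x] = sum_d weights[d] * coverage[x + d]`. Edges are handled by
#' reflect padding by default (appropriate for a linear representation of a
#' circular chromosome without inventing boundary peaks); `circular = TRUE`
#' wraps around instead.
#'
#' @param track A `coverage_track` (single replicate used).
#' @param kernel A [build_kernel()] result.
#' @param circular Wrap-around convolution instead of reflect padding.
#' @return Numeric response vector, one value per base.
#' @export
convolve_track <- function(track, kernel, circular = FALSE) {
  values <- track_values(track)[[1]]
  convolve_values(values, kernel, circular)
}

convolve_values <- function(values, kernel, circular = FALSE) {
  n <- length(values)
  hw <- kernel$half_width
  if (2 * hw + 1 > n) abort("kernel support exceeds track length")
  padded <- if (circular) {
    c(values[(n - hw + 1):n], values, values[1:hw])
  } else {
    c(values[(hw + 1):2], values, values[(n - 1):(n - hw)])
  }
  resp <- stats::filter(padded, kernel$weights, method = "convolution", sides = 2)
  as.numeric(resp[(hw + 1):(hw + n)])
}

#' Peak-calling configuration
#'
#' @param threshold_mult Retained peaks need raw summit coverage above
#'   `threshold_mult` times the genome-wide mean (default 3).
#' @param fixed_width Optional expected-width override in bp (skips
#'   [estimate_expected_width()]).
#' @param min_score Optional minimum convolution score.
#' @param circular Use wrap-around convolution.
#' @param normalization `"ratio"` (peak intensity divided by the background
#'   coefficient, scaled by 1e6) or `"literal"` (coefficient divided by
#'   intensity).
#' @return A `peakcall_config` list.
#' @export
peakcall_config <- function(threshold_mult = 3, fixed_width = NULL,
                            min_score = NULL, circular = FALSE,
                            normalization = c("ratio", "literal")) {
  if (threshold_mult <= 0) abort("`threshold_mult` must be > 0")
  structure(list(threshold_mult = threshold_mult, fixed_width = fixed_width,
                 min_score = min_score, circular = circular,
                 normalization = match.arg(normalization)),
            class = "peakcall_config")
}

#' Call peaks on one coverage track
#'
#' The convolution response is scanned for positions where its discrete first
#' derivative changes from positive to negative (the leftmost position of a
#' zero-derivative plateau is the summit). Each such region is a potential
#' peak whose convolution score is the response at the summit and whose
#' interval runs between the nearest response zero-crossings flanking the
#' summit. Retained peaks have raw summit coverage above
#' `threshold_mult * mean(coverage)`, positive convolution score, and (if set)
#' score above `min_score`.
#'
#' @param track A single-replicate `coverage_track`.
#' @param kernel A [build_kernel()] result.
#' @param cfg A [peakcall_config()].
#' @return A tibble of class `mrpr_peaks`: `contig`, `start`, `end` (0-based,
#'   half-open), `summit`, `conv_score`, `raw_intensity`, `replicate`.
#' @export
call_peaks <- function(track, kernel, cfg = peakcall_config()) {
  values <- track_values(track)[[1]]
  contig <- if ("contig" %in% names(track)) track$contig[1] else "contig"
  replicate <- if ("replicate" %in% names(track)) track$replicate[1] else 1L
  resp <- convolve_values(values, kernel, cfg$circular)

  d <- diff(resp)
  nz <- which(d != 0)
  summits <- integer()
  if (length(nz) > 1) {
    pos_to_neg <- which(d[nz[-length(nz)]] > 0 & d[nz[-1]] < 0)
    summits <- nz[pos_to_neg] + 1L   # leftmost position of the plateau
  }
  if (length(summits) == 0) return(empty_peaks())

  keep <- values[summits] > cfg$threshold_mult * mean(values) & resp[summits] > 0
  if (!is.null(cfg$min_score)) keep <- keep & resp[summits] > cfg$min_score
  summits <- summits[keep]
  if (length(summits) == 0) return(empty_peaks())

  pos_run <- resp > 0
  n <- length(values)
  bounds <- vapply(summits, function(s) {
    left <- s
    while (left > 1 && pos_run[left - 1]) left <- left - 1L
    right <- s
    while (right < n && pos_run[right + 1]) right <- right + 1L
    c(left, right)
  }, numeric(2))

  out <- tibble::tibble(
    contig = contig,
    start = as.integer(bounds[1, ] - 1L),          # 0-based inclusive start
    end = as.integer(bounds[2, ]),                 # 0-based exclusive end
    summit = as.integer(summits - 1L),
    conv_score = resp[summits],
    raw_intensity = vapply(seq_along(summits),
                           function(i) sum(values[bounds[1, i]:bounds[2, i]]),
                           double(1)),
    replicate = replicate
  )
  out <- dplyr::arrange(out, .data$start)
  class(out) <- c("mrpr_peaks", class(out))
  out
}

empty_peaks <- function() {
  out <- tibble::tibble(contig = character(), start = integer(), end = integer(),
                        summit = integer(), conv_score = double(),
                        raw_intensity = double(), replicate = integer())
  class(out) <- c("mrpr_peaks", class(out))
  out
}

#' Normalize peak intensities against non-peak background coverage
#'
#' Per replicate, the normalization coefficient is the total track coverage
#' minus the summed raw intensity of its peaks (i.e. the background coverage
#' left after removing all detected peaks). With `normalization = "ratio"`
#' (default) each peak reports `raw_intensity / coefficient * 1e6`; the
#' `"literal"` reading reports `coefficient / raw_intensity`.
#'
#' @param peaks An `mrpr_peaks` tibble (may span replicates).
#' @param tracks The matching `coverage_track` tibble.
#' @param normalization `"ratio"` or `"literal"`.
#' @return `peaks` with a `normalized_intensity` column.
#' @export
normalize_peaks <- function(peaks, tracks, normalization = c("ratio", "literal")) {
  normalization <- match.arg(normalization)
  totals <- dplyr::summarise(dplyr::group_by(tracks, .data$replicate),
                             total = sum(.data$coverage), .groups = "drop")
  sums <- dplyr::summarise(dplyr::group_by(peaks, .data$replicate),
                           peak_sum = sum(.data$raw_intensity), .groups = "drop")
  coefs <- dplyr::left_join(totals, sums, by = "replicate")
  coefs$peak_sum[is.na(coefs$peak_sum)] <- 0
  coefs$coef <- coefs$total - coefs$peak_sum
  if (any(coefs$coef <= 0)) {
    abort("degenerate background: peaks account for all coverage",
          class = "mrpr_degenerate_background_error")
  }
  out <- dplyr::left_join(peaks, coefs[, c("replicate", "coef")], by = "replicate")
  out$normalized_intensity <- if (normalization == "ratio") {
    out$raw_intensity / out$coef * 1e6
  } else {
    out$coef / out$raw_intensity
  }
  out$coef <- NULL
  class(out) <- unique(c("mrpr_peaks", class(out)))
  out
}

#' Merge peaks across replicates by summit proximity
#'
#' Peaks whose summits lie within `overlap_tol` of a cluster are merged; each
#' merged peak reports the number of distinct supporting replicates and the
#' mean of its members' scores and normalized intensities.
#'
#' @param peaks Normalized `mrpr_peaks` across replicates.
#' @param overlap_tol Maximum summit distance in bp for two replicate peaks to
#'   be considered the same binding site (default: half the expected width
#'   that built the kernel; pass explicitly here).
#' @return Merged `mrpr_peaks` with `n_replicates`.
#' @export
merge_replicate_peaks <- function(peaks, overlap_tol) {
  if (nrow(peaks) == 0) {
    out <- dplyr::mutate(peaks, n_replicates = integer())
    class(out) <- unique(c("mrpr_peaks", class(out)))
    return(out)
  }
  peaks <- dplyr::arrange(peaks, .data$contig, .data$summit)
  newc <- c(TRUE, diff(peaks$summit) > overlap_tol |
              peaks$contig[-1] != peaks$contig[-nrow(peaks)])
  peaks$cluster <- cumsum(newc)
  out <- dplyr::summarise(
    dplyr::group_by(peaks, .data$contig, .data$cluster),
    start = min(.data$start),
    end = max(.data$end),
    summit = as.integer(round(mean(.data$summit))),
    conv_score = mean(.data$conv_score),
    raw_intensity = mean(.data$raw_intensity),
    normalized_intensity = if ("normalized_intensity" %in% names(peaks))
      mean(.data$normalized_intensity) else NA_real_,
    n_replicates = dplyr::n_distinct(.data$replicate),
    .groups = "drop"
  )
  out$cluster <- NULL
  out <- dplyr::arrange(out, .data$contig, .data$start)
  class(out) <- c("mrpr_peaks", class(out))
  out
}

#' Normalize and merge replicate peak sets
#'
#' Convenience wrapper: [normalize_peaks()] then [merge_replicate_peaks()].
#'
#' @param peaks Peaks across replicates (e.g. `dplyr::bind_rows()` of
#'   per-replicate [call_peaks()] results).
#' @param tracks Matching coverage tracks.
#' @param overlap_tol Summit merge tolerance in bp.
#' @param normalization See [normalize_peaks()].
#' @return Merged, normalized `mrpr_peaks`.
#' @export
normalize_and_merge <- function(peaks, tracks, overlap_tol,
                                normalization = c("ratio", "literal")) {
  merge_replicate_peaks(normalize_peaks(peaks, tracks, normalization), overlap_tol)
}

#' Write peaks as BED6+ text
#'
#' Columns: chrom, start, end, name, score (convolution score rescaled to
#' 0-1000), strand (`.`), then raw_intensity, normalized_intensity, summit,
#' n_replicates.
#'
#' @param peaks An `mrpr_peaks` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if (nrow(peaks) > 0 && max(peaks$conv_score) > 0) {
    as.integer(round(1000 * peaks$conv_score / max(peaks$conv_score)))
  } else integer(nrow(peaks))
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%d\t.\t%g\t%g\t%d\t%d",
                   peaks$contig, peaks$start, peaks$end, seq_len(nrow(peaks)),
                   score, peaks$raw_intensity,
                   peaks$normalized_intensity %||% NA_real_,
                   peaks$summit,
                   if ("n_replicates" %in% names(peaks)) peaks$n_replicates else 1L)
  writeLines(lines, path)
  invisible(path)
}
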