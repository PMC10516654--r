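#' Coverage-simulation configuration
#'
#' Parameters of the read-coverage generator. The expected coverage at base
#' `x` is `mean_depth * (1 + sum_sites enrichment_s * exp(-(x - center_s)^2 /
#' (2 * peak_shape_sd^2)))`; observed coverage is Poisson-sampled around that
#' expectation (optionally negative-binomial for overdispersion, or exact
#' expectation with `noise = "none"`).
#'
#' @param mean_depth Background reads per base (> 0).
#' @param peak_shape_sd Gaussian peak shape standard deviation in bp.
#' @param noise One of `"poisson"`, `"nbinom"`, `"none"`.
#' @param nb_size Negative-binomial size (dispersion) used when
#'   `noise = "nbinom"`; larger means closer to Poisson.
#' @param n_replicates Number of replicate tracks; replicate `r` uses the
#'   deterministic sub-seed `seed + r - 1`.
#' @param seed Master integer seed.
#' @return A `coverage_config` list.
#' @export
coverage_config <- function(mean_depth = 50, peak_shape_sd = 75,
                            noise = c("poisson", "nbinom", "none"),
                            nb_size = 10, n_replicates = 3, seed = 1) {
  noise <- match.arg(noise)
  if (mean_depth <= 0) abort("`mean_depth` must be > 0")
  if (peak_shape_sd <= 0) abort("`peak_shape_sd` must be > 0")
  if (n_replicates < 1) abort("`n_replicates` must be >= 1")
  structure(list(mean_depth = mean_depth, peak_shape_sd = peak_shape_sd,
                 noise = noise, nb_size = nb_size,
                 n_replicates = as.integer(n_replicates), seed = seed),
            class = "coverage_config")
}

expected_coverage <- function(genome, cfg) {
  n <- nchar(genome$sequence)
  lambda <- rep(cfg$mean_depth, n)
  sites <- genome$planted_sites
  if (nrow(sites) > 0) {
    half <- ceiling(6 * cfg$peak_shape_sd)
    x <- seq_len(n) - 1L
    for (i in seq_len(nrow(sites))) {
      c0 <- sites$center[i]
      idx <- max(1L, c0 - half + 1L):min(n, c0 + half + 1L)
      lambda[idx] <- lambda[idx] + cfg$mean_depth * sites$enrichment[i] *
        exp(-(x[idx] - c0)^2 / (2 * cfg$peak_shape_sd^2))
    }
  }
  lambda
}

#' Simulate replicate coverage tracks for a synthetic genome
#'
#' @param genome A [gen_genome()] result, usually after [plant_sites()].
#' @param cfg A [coverage_config()].
#' @return A tibble of class `coverage_track` with columns `contig`, `pos`
#'   (0-based), `coverage`, `replicate`.
#' @examples
#' g <- gen_genome(5000, seed = 1)
#' cov <- simulate_coverage(g, coverage_config(mean_depth = 10, n_replicates = 1))
#' @export
simulate_coverage <- function(genome, cfg = coverage_config()) {
  stopifnot(inherits(genome, "synthetic_genome"), inherits(cfg, "coverage_config"))
  lambda <- expected_coverage(genome, cfg)
  n <- length(lambda)
  reps <- purrr::map(seq_len(cfg$n_replicates), function(r) {
    values <- switch(cfg$noise,
      none = lambda,
      poisson = with_seed(cfg$seed + r - 1, rpois(n, lambda)),
      nbinom = with_seed(cfg$seed + r - 1,
                         stats::rnbinom(n, size = cfg$nb_size, mu = lambda))
    )
    tibble::tibble(contig = genome$name, pos = seq_len(n) - 1L,
                   coverage = as.numeric(values), replicate = r)
  })
  out <- dplyr::bind_rows(reps)
  class(out) <- c("coverage_track", class(out))
  out
}

# Per-replicate coverage vectors (index 1 == position 0), validated.
track_values <- function(track) {
  stopifnot(is.data.frame(track), all(c("pos", "coverage") %in% names(track)))
  if (any(track$coverage < 0)) abort("coverage values must be non-negative")
  if (!"replicate" %in% names(track)) track$replicate <- 1L
  split(track$coverage, track$replicate)
}

#' Write coverage tracks as bedGraph (one file per replicate)
#'
#' @param track A `coverage_track` tibble.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Character vector of file paths, invisibly.
#' @export
write_coverage_bedgraph <- function(track, dir, prefix = "coverage") {
  stopifnot(dir.exists(dir))
  paths <- purrr::imap_chr(split(track, track$replicate), function(tr, r) {
    path <- file.path(dir, sprintf("%s_rep%s.bedgraph", prefix, r))
    df <- data.frame(chrom = tr$contig, start = tr$pos, end = tr$pos + 1L,
                     value = tr$coverage)
    # collapse runs of equal value for compactness
    run <- cumsum(c(TRUE, diff(df$value) != 0 | diff(df$start) != 1))
    df <- do.call(rbind, lapply(split(df, run), function(d) {
      data.frame(chrom = d$chrom[1], start = d$start[1],
                 end = d$end[nrow(d)], value = d$value[1])
    }))
    writeLines(c("track type=bedGraph",
                 sprintf("%s\t%d\t%d\t%g", df$chrom, df$start, df$end, df$value)),
               path)
    path
  })
  invisible(paths)
}

#' Read a bedGraph file into a per-base coverage track
#'
#' Uses `rtracklayer` for parsing (bedGraph and wiggle alike) and expands
#' intervals to per-base resolution.
#'
#' @param path bedGraph/wig file path.
#' @param replicate Replicate label to attach.
#' @return A `coverage_track` tibble.
#' @export
read_coverage_bedgraph <- function(path, replicate = 1L) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("reading coverage files requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path)
  starts <- GenomicRanges::start(gr) - 1L   # to 0-based
  ends <- GenomicRanges::end(gr)
  widths <- ends - starts
  out <- tibble::tibble(
    contig = rep(as.character(GenomicRanges::seqnames(gr)), widths),
    pos = unlist(purrr::map2(starts, ends - 1L, seq)),
    coverage = rep(gr$score, widths),
    replicate = replicate
  )
  out <- dplyr::arrange(out, .data$contig, .data$pos)
  class(out) <- c("coverage_track", class(out))
  out
}
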