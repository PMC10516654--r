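#' Default HDX peptide quality-filter criteria
#'
#' The six quality criteria applied to peptide-level measurements before
#' residue assignment: identification in at least 2 of 3 non-deuterated
#' samples, minimum intensity 10 000 counts, maximum length 30 residues,
#' minimum number of fragmentation products 2, maximum mass error 25 ppm and
#' retention-time tolerance 0.5 min.
#'
#' @param min_nondeut_ids,min_intensity,max_length,min_products,max_mass_error,max_rt_delta
#'   Thresholds; defaults as above.
#' @return An `hdx_filter_criteria` list.
#' @export
hdx_filter_criteria <- function(min_nondeut_ids = 2, min_intensity = 10000,
                                max_length = 30, min_products = 2,
                                max_mass_error = 25, max_rt_delta = 0.5) {
  vals <- c(min_nondeut_ids, min_intensity, max_length, min_products,
            max_mass_error, max_rt_delta)
  if (any(vals <= 0)) abort("all filter thresholds must be positive")
  structure(list(min_nondeut_ids = min_nondeut_ids,
                 min_intensity = min_intensity, max_length = max_length,
                 min_products = min_products, max_mass_error = max_mass_error,
                 max_rt_delta = max_rt_delta),
            class = "hdx_filter_criteria")
}

#' Simulate an HDX-MS peptide measurement table
#'
#' Peptides from two protease digestions tile the protein with the requested
#' mean length and overlap. Residue-level uptake at labeling time `t` follows
#' first-order exchange, `d2o_fraction * (1 - exp(-rate * t))`; a peptide's
#' deuterium uptake is the sum over its residues plus Gaussian measurement
#' noise. QC columns (intensity, products, mass error, retention-time delta,
#' non-deuterated identifications) are drawn so that a configurable fraction
#' of rows fails the standard filters, exercising the downstream filtering.
#'
#' @param protein_sequence Amino-acid string (one-letter codes).
#' @param rates Per-residue exchange rates (1/s), length `nchar(protein_sequence)`.
#' @param timepoints Labeling times in seconds.
#' @param d2o_fraction Deuterium fraction after dilution (default 0.9 for a
#'   10-fold dilution into heavy-water buffer).
#' @param peptide_mean_len,peptide_overlap Tiling geometry in residues.
#' @param n_replicates Replicate measurements per peptide and timepoint.
#' @param noise_sd Gaussian noise on peptide uptake (Da).
#' @param contaminant_rate Fraction of rows drawn to fail a random QC filter.
#' @param proteases Protease labels; each gets its own tiling.
#' @param seed Integer seed.
#' @return Tibble of class `hdx_peptides` with one row per
#'   peptide x timepoint x replicate; ground-truth rates in
#'   `attr(, "rates")`.
#' @export
simulate_hdx <- function(protein_sequence, rates,
                         timepoints = c(10, 30, 100, 1000, 10000),
                         d2o_fraction = 0.9, peptide_mean_len = 10,
                         peptide_overlap = 5, n_replicates = 3,
                         noise_sd = 0.05, contaminant_rate = 0,
                         proteases = c("pepsin", "fungal"), seed = 1) {
  nres <- nchar(protein_sequence)
  if (nres == 0) abort("`protein_sequence` must be non-empty")
  if (length(rates) != nres) abort("`rates` must have one entry per residue")
  if (any(rates < 0)) abort("exchange rates must be >= 0")
  if (d2o_fraction <= 0 || d2o_fraction > 1) abort("`d2o_fraction` must be in (0, 1]")

  with_seed(seed, {
    peptides <- purrr::imap(setNames(proteases, proteases), function(prot, nm) {
      tile_peptides(protein_sequence, peptide_mean_len, peptide_overlap)
    })
    peptides <- dplyr::bind_rows(peptides, .id = "protease")
    peptides$peptide_id <- sprintf("%s_%03d", substr(peptides$protease, 1, 3),
                                   seq_len(nrow(peptides)))

    grid <- tidyr::expand_grid(peptides,
                               timepoint = timepoints,
                               replicate = seq_len(n_replicates))
    res_uptake <- function(start, end, t) {
      sum(d2o_fraction * (1 - exp(-rates[start:end] * t)))
    }
    grid$uptake <- pmax(0, purrr::pmap_dbl(
      grid[, c("start", "end", "timepoint")],
      function(start, end, timepoint) res_uptake(start, end, timepoint)
    ) + rnorm(nrow(grid), 0, noise_sd))

    n <- nrow(grid)
    grid$intensity <- exp(rnorm(n, log(2e5), 0.6))
    grid$n_products <- 2L + stats::rpois(n, 3)
    grid$mass_error <- abs(rnorm(n, 0, 6))
    grid$rt_delta <- abs(rnorm(n, 0, 0.12))
    grid$n_nondeut_ids <- 3L

    if (contaminant_rate > 0) {
      bad <- runif(n) < contaminant_rate
      which_crit <- sample(5, sum(bad), replace = TRUE)
      idx <- which(bad)
      for (k in seq_along(idx)) {
        i <- idx[k]
        switch(which_crit[k],
               grid$intensity[i] <- runif(1, 100, 9000),
               grid$n_products[i] <- 1L,
               grid$mass_error[i] <- runif(1, 26, 80),
               grid$rt_delta[i] <- runif(1, 0.6, 2),
               grid$n_nondeut_ids[i] <- sample(0:1, 1))
      }
    }
    out <- grid[, c("peptide_id", "sequence", "start", "end", "protease",
                    "replicate", "timepoint", "uptake", "intensity",
                    "n_products", "mass_error", "rt_delta", "n_nondeut_ids")]
    attr(out, "rates") <- rates
    attr(out, "d2o_fraction") <- d2o_fraction
    class(out) <- c("hdx_peptides", class(out))
    out
  })
}

# Overlapping tiling of a protein; 1-based inclusive coordinates.
tile_peptides <- function(protein_sequence, mean_len, overlap) {
  nres <- nchar(protein_sequence)
  starts <- integer(); ends <- integer()
  s <- 1L
  repeat {
    len <- max(4L, min(30L, round(rnorm(1, mean_len, 2))))
    e <- min(nres, s + len - 1L)
    starts <- c(starts, s); ends <- c(ends, e)
    if (e >= nres) break
    s <- max(s + 1L, e - overlap + 1L)
  }
  tibble::tibble(
    sequence = substring(protein_sequence, starts, ends),
    start = starts, end = ends
  )
}

#' Filter HDX peptide measurements by quality criteria
#'
#' Removes rows failing any of the six criteria. Filtering is idempotent.
#'
#' @param table An `hdx_peptides` tibble (or any data frame with the QC
#'   columns).
#' @param criteria An [hdx_filter_criteria()].
#' @return The filtered tibble; a warning (not an error) is raised if nothing
#'   survives.
#' @export
filter_peptides <- function(table, criteria = hdx_filter_criteria()) {
  out <- dplyr::filter(
    table,
    .data$n_nondeut_ids >= criteria$min_nondeut_ids,
    .data$intensity >= criteria$min_intensity,
    nchar(.data$sequence) <= criteria$max_length,
    .data$n_products >= criteria$min_products,
    .data$mass_error <= criteria$max_mass_error,
    .data$rt_delta <= criteria$max_rt_delta
  )
  if (nrow(out) == 0) warn("no peptides pass the quality filters")
  out
}

#' Aggregate filtered peptides over replicates
#'
#' Concatenates surviving rows from both protease digestions and averages
#' uptake over replicates per peptide and timepoint, retaining the replicate
#' standard deviation.
#'
#' @param table A filtered peptide table.
#' @return Tibble with one row per peptide x timepoint: `peptide_id`,
#'   `sequence`, `start`, `end`, `protease`, `timepoint`, `uptake`,
#'   `uptake_sd`, `n_rep`.
#' @export
aggregate_peptides <- function(table) {
  dplyr::summarise(
    dplyr::group_by(table, .data$peptide_id, .data$sequence, .data$start,
                    .data$end, .data$protease, .data$timepoint),
    uptake_sd = stats::sd(.data$uptake),
    n_rep = dplyr::n(),
    uptake = mean(.data$uptake),
    .groups = "drop"
  )
}

#' Filter and merge dual-protease HDX tables
#'
#' Convenience wrapper: [filter_peptides()] then [aggregate_peptides()]. The
#' input may be one combined table or a list of per-protease tables sharing
#' the protein coordinate system.
#'
#' @param tables A peptide table or list of tables.
#' @param criteria An [hdx_filter_criteria()].
#' @return Aggregated peptide table.
#' @export
filter_and_merge <- function(tables, criteria = hdx_filter_criteria()) {
  if (!is.data.frame(tables)) tables <- dplyr::bind_rows(tables)
  aggregate_peptides(filter_peptides(tables, criteria))
}

#' Assign residue-level deuterium uptake from overlapping peptides
#'
#' For every residue covered by at least one peptide: if a single peptide
#' covers it, the residue value equals that peptide's uptake; with
#' overlapping peptides, the shortest covering peptide is used; among
#' equal-shortest peptides, the one whose C-terminus is closest to the
#' residue wins; remaining ties break to the lexicographically smallest
#' peptide id (deterministic). Uncovered residues are absent from the output.
#'
#' @param table An aggregated peptide table (see [aggregate_peptides()]).
#' @param timepoint Labeling time to extract, or `NULL` for all timepoints
#'   present.
#' @return Tibble of class `hdx_residues`: `residue` (1-based), `timepoint`,
#'   `uptake`, `uptake_sd`, `source_peptide_id`.
#' @export
residue_uptake <- function(table, timepoint = NULL) {
  if (!is.null(timepoint)) {
    if (!any(table$timepoint %in% timepoint)) {
      abort("requested timepoint absent from the table")
    }
    table <- dplyr::filter(table, .data$timepoint %in% !!timepoint)
  }
  if (!"uptake_sd" %in% names(table)) table$uptake_sd <- NA_real_
  expanded <- tidyr::unnest(
    dplyr::mutate(table,
                  residue = purrr::map2(.data$start, .data$end, seq),
                  pep_len = .data$end - .data$start + 1L),
    "residue"
  )
  expanded <- dplyr::mutate(expanded, cdist = .data$end - .data$residue)
  expanded <- dplyr::arrange(expanded, .data$timepoint, .data$residue,
                             .data$pep_len, .data$cdist, .data$peptide_id)
  out <- dplyr::distinct(expanded, .data$timepoint, .data$residue,
                         .keep_all = TRUE)
  out <- tibble::tibble(
    residue = out$residue, timepoint = out$timepoint, uptake = out$uptake,
    uptake_sd = out$uptake_sd, source_peptide_id = out$peptide_id
  )
  out <- dplyr::arrange(out, .data$timepoint, .data$residue)
  class(out) <- c("hdx_residues", class(out))
  out
}

#' Differential residue-level uptake between two profiles
#'
#' Computes `delta = uptake_b - uptake_a` for every residue and timepoint
#' defined in both profiles, and classifies each residue as `increased`,
#' `decreased` or `unchanged` according to whether `|delta|` exceeds the
#' threshold at any timepoint (sign taken from the largest-magnitude delta).
#'
#' @param profile_a,profile_b `hdx_residues` tibbles sharing residue
#'   numbering (e.g. wild type and a destabilized variant).
#' @param threshold Classification threshold in Da. The default, `NULL`,
#'   uses twice the pooled replicate standard deviation carried in the
#'   profiles' `uptake_sd`; supply a value if no replicate information is
#'   available.
#' @return Tibble of class `hdx_differential` with `residue`, `timepoint`,
#'   `uptake_a`, `uptake_b`, `delta`, `class`; the threshold used is stored
#'   in `attr(, "threshold")`.
#' @export
differential_uptake <- function(profile_a, profile_b, threshold = NULL) {
  joined <- dplyr::inner_join(
    dplyr::select(profile_a, "residue", "timepoint",
                  uptake_a = "uptake", sd_a = "uptake_sd"),
    dplyr::select(profile_b, "residue", "timepoint",
                  uptake_b = "uptake", sd_b = "uptake_sd"),
    by = c("residue", "timepoint")
  )
  if (nrow(joined) == 0) {
    warn("profiles share no residue/timepoint combinations")
    out <- tibble::tibble(residue = integer(), timepoint = double(),
                          uptake_a = double(), uptake_b = double(),
                          delta = double(), class = character())
    class(out) <- c("hdx_differential", class(out))
    return(out)
  }
  if (is.null(threshold)) {
    pooled <- sqrt(mean(c(joined$sd_a, joined$sd_b)^2, na.rm = TRUE))
    if (!is.finite(pooled)) {
      abort("no replicate SDs available; supply `threshold` explicitly")
    }
    threshold <- 2 * pooled
  }
  joined$delta <- joined$uptake_b - joined$uptake_a
  cls <- dplyr::summarise(
    dplyr::group_by(joined, .data$residue),
    class = {
      d <- .data$delta[which.max(abs(.data$delta))]
      if (abs(d) > threshold) (if (d > 0) "increased" else "decreased")
      else "unchanged"
    },
    .groups = "drop"
  )
  out <- dplyr::left_join(
    dplyr::select(joined, "residue", "timepoint", "uptake_a", "uptake_b", "delta"),
    cls, by = "residue"
  )
  attr(out, "threshold") <- threshold
  class(out) <- c("hdx_differential", class(out))
  out
}
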