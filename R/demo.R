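#' Default 15-bp operator consensus used by the demo pipeline
#'
#' A fixed synthetic 15-bp consensus standing in for the conserved operator
#' element recognized by the repressor; the true element's letters are not
#' reproduced here, only its width and information content regime.
#'
#' @return Character scalar.
#' @export
default_consensus <- function() "TGTTCACTAAAGGAC"

#' Run the synthetic ChAP-seq to motif pipeline end to end
#'
#' Generates a prophage-sized genome with planted operator sites, simulates
#' replicate coverage with binding-site enrichment, estimates the expected
#' peak width, calls peaks per replicate with the Ricker-kernel caller,
#' normalizes and merges them across replicates, extracts sequences under the
#' merged summits, discovers the motif by ZOOPS-EM with automatic width
#' selection, and scans the genome for motif occurrences. Fully deterministic
#' for a given seed.
#'
#' @param seed Master integer seed; every stage derives from it.
#' @param genome_length Genome size in bp.
#' @param gc GC fraction of the background genome.
#' @param n_sites Number of planted operator sites.
#' @param consensus Planted consensus (default [default_consensus()]).
#' @param mutation_rate Per-position mutation rate at planting.
#' @param enrichment Fold enrichment of coverage at each site.
#' @param mean_depth Background sequencing depth.
#' @param peak_shape_sd Gaussian peak-shape SD in bp.
#' @param n_replicates Coverage replicates.
#' @param flank Flank around merged summits for motif input.
#' @param width_range Candidate motif widths for EM.
#' @param restarts EM restarts per width.
#' @param scan_frac Scan threshold as a fraction of the maximal log-odds.
#' @param out_dir Optional directory; when given, FASTA/bedGraph/BED/MEME
#'   outputs and a plain-text report are written there.
#' @return A list of class `mrpr_demo`: `genome`, `tracks`, `peaks` (merged),
#'   `pwm`, `hits`, `recovery` (planted-vs-called table), `params`.
#' @examples
#' \donttest{
#' demo <- run_demo(seed = 1, genome_length = 20000, n_sites = 3,
#'                  width_range = c(8, 16), restarts = 3)
#' demo$recovery
#' }
#' @export
run_demo <- function(seed = 1, genome_length = 130000, gc = 0.44,
                     n_sites = 10, consensus = default_consensus(),
                     mutation_rate = 0.1, enrichment = 20, mean_depth = 50,
                     peak_shape_sd = 75, n_replicates = 3, flank = 50,
                     width_range = c(8, 20), restarts = 10, scan_frac = 0.8,
                     out_dir = NULL) {
  params <- as.list(environment())
  params$out_dir <- NULL

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("[", name, "] ", conditionMessage(e)), parent = e)
    })
  }

  genome <- stage("simulate-genome", {
    g <- gen_genome(genome_length, gc = gc, seed = seed)
    if (n_sites > 0) {
      pos <- spread_positions(genome_length, n_sites, width = nchar(consensus),
                              seed = seed + 1)
      g <- plant_sites(g, consensus, pos, mutation_rate = mutation_rate,
                       enrichment = enrichment, seed = seed + 2)
    }
    g
  })

  tracks <- stage("simulate-coverage", {
    simulate_coverage(genome, coverage_config(
      mean_depth = mean_depth, peak_shape_sd = peak_shape_sd,
      noise = "poisson", n_replicates = n_replicates, seed = seed + 3
    ))
  })

  track_list <- split(tracks, tracks$replicate)

  peaks <- stage("peak-calling", {
    width <- tryCatch(estimate_expected_width(track_list[[1]]),
                      mrpr_no_candidate_error = function(e) NA_real_)
    if (is.na(width)) {
      merged <- empty_peaks()
      merged$n_replicates <- integer()
      merged$normalized_intensity <- double()
      attr(merged, "expected_width") <- NA_real_
      merged
    } else {
      kernel <- build_kernel(width)
      per_rep <- dplyr::bind_rows(
        purrr::map(track_list, call_peaks, kernel = kernel)
      )
      merged <- normalize_and_merge(per_rep, tracks, overlap_tol = width / 2)
      attr(merged, "expected_width") <- width
      merged
    }
  })

  if (nrow(peaks) == 0) {
    pwm <- NULL
    hits <- NULL
    message("no peaks called; motif stage skipped")
  } else {
    pwm <- stage("motif-discovery", {
      seqs <- extract_peak_sequences(genome, peaks, flank = flank)
      discover_motif(seqs, width_range = width_range, restarts = restarts,
                     seed = seed + 4)
    })
    hits <- stage("motif-scan", {
      scan_genome(genome, pwm, threshold = scan_frac * max_logodds(pwm))
    })
  }

  recovery <- stage("recovery-table", {
    planted <- genome$planted_sites
    if (nrow(planted) == 0 || nrow(peaks) == 0) {
      tibble::tibble(motif_id = character(), center = integer(),
                     nearest_summit = integer(), distance = integer())
    } else {
      nearest <- vapply(planted$center, function(c0) {
        peaks$summit[which.min(abs(peaks$summit - c0))]
      }, double(1))
      tibble::tibble(
        motif_id = planted$motif_id,
        center = planted$center,
        nearest_summit = as.integer(nearest),
        distance = as.integer(abs(nearest - planted$center))
      )
    }
  })

  out <- structure(list(genome = genome, tracks = tracks, peaks = peaks,
                        pwm = pwm, hits = hits, recovery = recovery,
                        params = params),
                   class = "mrpr_demo")

  if (!is.null(out_dir)) {
    stage("write-outputs", {
      if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
      write_genome_fasta(genome, file.path(out_dir, "genome.fasta"))
      write_coverage_bedgraph(tracks, out_dir)
      write_peaks_bed(peaks, file.path(out_dir, "peaks.bed"))
      if (!is.null(pwm)) {
        write_meme(pwm, file.path(out_dir, "motif.meme"))
        write_hits_bed(hits, pwm, file.path(out_dir, "hits.bed"))
      }
      write_ground_truth(genome, file.path(out_dir, "planted_sites.bed"))
      writeLines(utils::capture.output(print(out)),
                 file.path(out_dir, "report.txt"))
    })
  }
  out
}

write_ground_truth <- function(genome, path) {
  s <- genome$planted_sites
  writeLines(sprintf("%s\t%d\t%d\t%s\t%g\t+", genome$name, s$position,
                     s$position + (s$center - s$position) * 2L + 1L,
                     s$motif_id, s$enrichment),
             path)
  invisible(path)
}

#' @export
print.mrpr_demo <- function(x, ...) {
  cat("== synthetic ChAP-seq demo ==\n")
  cat("seed:", x$params$seed, "\n")
  cat("genome:", nchar(x$genome$sequence), "bp,",
      nrow(x$genome$planted_sites), "planted sites\n")
  cat("expected peak width:", signif(attr(x$peaks, "expected_width") %||% NA, 4),
      "bp\n")
  cat("merged peaks:", nrow(x$peaks), "\n")
  if (!is.null(x$pwm)) {
    cat("motif: width", x$pwm$width, "bp, consensus", pwm_consensus(x$pwm), "\n")
    cat("genome hits at threshold:", nrow(x$hits), "\n")
  } else {
    cat("motif stage skipped (no peaks)\n")
  }
  if (nrow(x$recovery) > 0) {
    cat("summit recovery: max |distance| =", max(x$recovery$distance), "bp\n")
  }
  invisible(x)
}
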