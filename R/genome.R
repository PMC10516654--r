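#' Generate a random genome sequence
#'
#' Draws an i.i.d. base sequence with a prescribed GC content, sized by default
#' like a ~130 kb prophage region. The result carries an (initially empty)
#' table of planted operator sites that downstream generators and the peak
#' caller's ground-truth bookkeeping use.
#'
#' @param length Genome length in bp (>= 1).
#' @param gc Target GC fraction in `[0, 1]`. `P(G) + P(C) = gc`, split evenly.
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param name Contig name.
#' @return An object of class `synthetic_genome`: a list with `name`,
#'   `sequence` (single character string) and `planted_sites` (tibble with
#'   columns `position` (0-based start), `center`, `motif_id`, `enrichment`).
#' @examples
#' g <- gen_genome(1000, gc = 0.44, seed = 1)
#' nchar(g$sequence)
#' @export
gen_genome <- function(length, gc = 0.44, seed = 1, name = "synthetic") {
  if (!is.numeric(length) || length(length) != 1 || length < 1) {
    abort("`length` must be a positive number of base pairs")
  }
  if (gc < 0 || gc > 1) abort("`gc` must lie in [0, 1]")
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  bases <- with_seed(seed, sample(DNA_BASES, size = length, replace = TRUE, prob = probs))
  new_synthetic_genome(name, paste(bases, collapse = ""))
}

new_synthetic_genome <- function(name, sequence, planted_sites = NULL) {
  planted_sites <- planted_sites %||% tibble::tibble(
    position = integer(), center = integer(),
    motif_id = character(), enrichment = double()
  )
  structure(
    list(name = name, sequence = sequence, planted_sites = planted_sites),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome> ", x$name, ": ", nchar(x$sequence), " bp, ",
      nrow(x$planted_sites), " planted site(s)\n", sep = "")
  invisible(x)
}

#' Plant operator-site copies of a consensus into a genome
#'
#' Overwrites the genome sequence with `consensus` at each position, mutating
#' every written base independently with probability `mutation_rate` (a mutated
#' base is drawn uniformly from the three alternatives). Planted sites are
#' recorded with their enrichment so coverage simulation can place binding
#' peaks on them.
#'
#' @param genome A `synthetic_genome`.
#' @param consensus DNA string over `{A,C,G,T}`.
#' @param positions Integer vector of 0-based start positions; must be
#'   non-overlapping and fit inside the genome.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param enrichment Fold enrichment recorded per site (recycled).
#' @param seed Integer seed for the mutation draws.
#' @return The modified `synthetic_genome` with `planted_sites` filled in.
#' @export
plant_sites <- function(genome, consensus, positions, mutation_rate = 0,
                        enrichment = 20, seed = 1) {
  stopifnot(inherits(genome, "synthetic_genome"))
  w <- nchar(consensus)
  positions <- as.integer(positions)
  n <- nchar(genome$sequence)
  if (any(positions < 0) || any(positions + w > n)) {
    abort("planted positions must satisfy 0 <= position and position + width <= genome length")
  }
  if (length(positions) > 1) {
    p <- sort(positions)
    if (any(diff(p) < w)) abort("planted positions overlap")
  }
  if (mutation_rate < 0 || mutation_rate > 1) abort("`mutation_rate` must lie in [0, 1]")

  cons <- seq_to_int(consensus)
  seq_int <- seq_to_int(genome$sequence)
  enrichment <- rep_len(enrichment, length(positions))
  with_seed(seed, {
    for (i in seq_along(positions)) {
      site <- cons
      mut <- runif(w) < mutation_rate
      if (any(mut)) {
        site[mut] <- vapply(site[mut], function(b) sample(setdiff(1:4, b), 1L), integer(1))
      }
      seq_int[positions[i] + seq_len(w)] <- site
    }
  })
  sites <- tibble::tibble(
    position = positions,
    center = positions + w %/% 2L,
    motif_id = sprintf("site_%02d", seq_along(positions)),
    enrichment = enrichment
  )
  new_synthetic_genome(genome$name, int_to_seq(seq_int),
                       dplyr::bind_rows(genome$planted_sites, sites))
}

#' Non-overlapping site positions spread along a genome
#'
#' Convenience helper used by the demo pipeline: places `n_sites` start
#' positions roughly evenly, jittered, respecting a minimum spacing.
#'
#' @param genome_length,n_sites,width,min_gap,seed See description.
#' @return Sorted integer vector of 0-based positions.
#' @export
spread_positions <- function(genome_length, n_sites, width = 15, min_gap = 2000,
                             seed = 1) {
  if (n_sites < 1) return(integer())
  slot <- genome_length / n_sites
  if (slot < width + min_gap) abort("genome too short for the requested site spacing")
  with_seed(seed, {
    base <- (seq_len(n_sites) - 1) * slot + slot / 2
    jit <- runif(n_sites, -slot / 4, slot / 4)
    sort(as.integer(round(base + jit)))
  })
}

#' Write a synthetic genome to FASTA
#'
#' @param genome A `synthetic_genome`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::DNAStringSet(setNames(genome$sequence, genome$name))
    Biostrings::writeXStringSet(x, path)
  } else {
    lines <- c(paste0(">", genome$name),
               substring(genome$sequence,
                         seq(1, nchar(genome$sequence), 70),
                         pmin(seq(1, nchar(genome$sequence), 70) + 69,
                              nchar(genome$sequence))))
    writeLines(lines, path)
  }
  invisible(path)
}
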