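# Fixture builders shared across test files. Everything is generated in code;
# no data files.

# A coverage track from a raw value vector (positions 0-based).
track_from_values <- function(values, contig = "chr", replicate = 1L) {
  out <- tibble::tibble(contig = contig, pos = seq_along(values) - 1L,
                        coverage = as.numeric(values), replicate = replicate)
  class(out) <- c("coverage_track", class(out))
  out
}

# Constant background with rectangular bumps: bumps is a list of
# c(start, width, height) triplets (1-based start).
rect_track <- function(n = 1000, background = 2, bumps = list()) {
  v <- rep(background, n)
  for (b in bumps) v[b[1]:(b[1] + b[2] - 1)] <- b[3]
  track_from_values(v)
}

# Sequences with a consensus planted at the center of each, emulating
# extracted peak sequences.
planted_seqs <- function(n = 20, len = 60, consensus = "GATTACAGATTACAG",
                         mutation_rate = 0, seed = 1) {
  g <- gen_genome(n * len, gc = 0.5, seed = seed)
  pos <- (seq_len(n) - 1) * len + (len - nchar(consensus)) %/% 2
  g <- plant_sites(g, consensus, pos, mutation_rate = mutation_rate,
                   seed = seed + 500)
  vapply(seq_len(n), function(i) substr(g$sequence, (i - 1) * len + 1, i * len), "")
}

# Minimal peptide measurement row with QC fields that pass all filters.
peptide_row <- function(peptide_id = "p1", start = 1, end = 10,
                        sequence = strrep("A", end - start + 1),
                        protease = "pepsin", replicate = 1L, timepoint = 10,
                        uptake = 1, intensity = 2e5, n_products = 4L,
                        mass_error = 5, rt_delta = 0.1, n_nondeut_ids = 3L) {
  tibble::tibble(peptide_id, sequence, start = as.integer(start),
                 end = as.integer(end), protease, replicate, timepoint,
                 uptake, intensity, n_products, mass_error, rt_delta,
                 n_nondeut_ids)
}

# Independent brute-force oracle for residue-level assignment: enumerate all
# covering peptides, order by (length, end - residue, peptide_id), take the
# first. Used to cross-check residue_uptake().
residue_oracle <- function(table, timepoint) {
  tp <- table[table$timepoint == timepoint, ]
  residues <- sort(unique(unlist(mapply(seq, tp$start, tp$end, SIMPLIFY = FALSE))))
  do.call(rbind, lapply(residues, function(r) {
    cov <- tp[tp$start <= r & tp$end >= r, ]
    ord <- order(cov$end - cov$start + 1, cov$end - r, cov$peptide_id)
    data.frame(residue = r, uptake = cov$uptake[ord[1]],
               source_peptide_id = cov$peptide_id[ord[1]])
  }))
}

# Independent equilibrium oracle for the single-site isotherm: solve the
# mass-action equation for free titrant by root finding at each injection's
# concentrations instead of the closed-form quadratic.
isotherm_oracle_heats <- function(params, schedule) {
  conc <- mrpr:::itc_concentrations(schedule)
  B <- vapply(seq_along(conc$X), function(i) {
    X <- conc$X[i]; S <- params$n * conc$M[i]
    if (X == 0) return(0)
    f <- function(free) free + S * free / (params$kd + free) - X
    free <- stats::uniroot(f, c(0, X), tol = 1e-14)$root
    S * free / (params$kd + free)
  }, double(1))
  v0 <- schedule$cell_volume
  Q <- v0 * params$dh * B * 1e-3
  Qprev <- c(0, Q[-length(Q)])
  dv <- schedule$injection_volumes / v0
  Q - Qprev + dv * (Q + Qprev) / 2
}

# Brute-force per-position PWM scanner used as an oracle for scan_genome().
scan_oracle <- function(sequence, pwm, threshold) {
  score_at <- function(code, probs, bg) {
    sum(log2(probs[cbind(code, seq_len(ncol(probs)))] / bg[code]))
  }
  code <- mrpr:::seq_to_int(sequence)
  w <- pwm$width
  hits <- list()
  rc <- pwm$probs[4:1, rev(seq_len(w)), drop = FALSE]
  for (s in seq_len(length(code) - w + 1)) {
    sub <- code[s:(s + w - 1)]
    for (strand in c("+", "-")) {
      probs <- if (strand == "+") pwm$probs else rc
      sc <- score_at(sub, probs, pwm$background)
      if (sc >= threshold) {
        hits[[length(hits) + 1]] <- data.frame(start = s - 1L, strand = strand,
                                               log_odds = sc)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      log_odds = double()))
  }
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}
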