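#' Extract sequences under peak summits
#'
#' Returns the subsequence `[summit - flank, summit + flank + 1)` for each
#' peak, clipped at contig ends, uppercase, in peak order.
#'
#' @param genome A `synthetic_genome` (or named character vector of contig
#'   sequences).
#' @param peaks An `mrpr_peaks` tibble.
#' @param flank Flank in bp on each side of the summit.
#' @return Character vector of sequences (named by peak index).
#' @export
extract_peak_sequences <- function(genome, peaks, flank = 50) {
  seqs <- if (inherits(genome, "synthetic_genome")) {
    setNames(genome$sequence, genome$name)
  } else {
    genome
  }
  missing <- setdiff(unique(peaks$contig), names(seqs))
  if (length(missing) > 0) {
    abort(paste("peak contig(s) missing from genome:", paste(missing, collapse = ", ")))
  }
  out <- purrr::map2_chr(peaks$contig, peaks$summit, function(ctg, s) {
    len <- nchar(seqs[[ctg]])
    from <- max(0L, s - flank)              # 0-based inclusive
    to <- min(len, s + flank + 1L)          # 0-based exclusive
    toupper(substr(seqs[[ctg]], from + 1L, to))
  })
  setNames(out, sprintf("peak_%d", seq_len(nrow(peaks))))
}

new_pwm <- function(probs, background, pseudocount, n_sites, score = NA_real_,
                    ll = NA_real_, ll_trace = numeric(), gamma = NA_real_) {
  stopifnot(nrow(probs) == 4)
  rownames(probs) <- DNA_BASES
  structure(list(width = ncol(probs), probs = probs, background = background,
                 pseudocount = pseudocount, n_sites = n_sites, score = score,
                 ll = ll, ll_trace = ll_trace, gamma = gamma),
            class = "mrpr_pwm")
}

#' @export
print.mrpr_pwm <- function(x, ...) {
  cat("<mrpr_pwm> width", x$width, "bp, consensus", pwm_consensus(x),
      "\n  score", signif(x$score, 6), " n_sites", signif(x$n_sites, 4), "\n")
  invisible(x)
}

#' Consensus string of a PWM
#' @param pwm An `mrpr_pwm`.
#' @return Character scalar.
#' @export
pwm_consensus <- function(pwm) {
  paste(DNA_BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Tidy a PWM into a long tibble
#' @param x An `mrpr_pwm`.
#' @param ... Unused.
#' @return Tibble with `position`, `base`, `prob`.
#' @export
tidy.mrpr_pwm <- function(x, ...) {
  tibble::tibble(
    position = rep(seq_len(x$width), each = 4),
    base = rep(DNA_BASES, x$width),
    prob = as.vector(x$probs)
  )
}

# Strand-symmetric 0-order background from integer-encoded sequences.
estimate_background <- function(seq_ints, pseudo = 1) {
  counts <- tabulate(unlist(seq_ints), nbins = 4) + pseudo
  f <- counts / sum(counts)
  f <- (f + rev(f)) / 2          # symmetrize over complements (A<->T, C<->G)
  setNames(f, DNA_BASES)
}

# Log-likelihood-ratio of the motif model at every offset of one strand.
# mat: integer vector; returns vector over starts 1..(L - w + 1).
site_llr <- function(code, log_odds) {
  w <- ncol(log_odds)
  m <- length(code) - w + 1L
  if (m < 1) return(numeric())
  out <- numeric(m)
  idx <- seq_len(m)
  for (j in seq_len(w)) {
    out <- out + log_odds[code[idx + j - 1L], j]
  }
  out
}

#' Discover a motif by ZOOPS expectation-maximization
#'
#' A re-implementation of the MEME-style discovery step used downstream of
#' peak calling: a position weight matrix is fit under the zero-or-one
#' occurrence-per-sequence (ZOOPS) model by EM, searching both strands, from
#' several seeded random initializations per candidate width. The reported
#' motif is the one maximizing a length-penalized log-likelihood-ratio score
#' `2 * (LL_motif - LL_background) - 3 * width * penalty` across the width
#' range (a stand-in for an E-value ranking; the PWM has `3 * width` free
#' parameters). The default per-parameter penalty, `qchisq(0.995, 3) / 3`,
#' keeps a column only when its likelihood gain beats the upper tail of what
#' an uninformative background column achieves by chance: that chance gain
#' follows a chi-square with the column's 3 free parameters (inflated by the
#' registration search) and its scale does not grow with the number of
#' sequences, so the critical value is fixed rather than BIC-style.
#'
#' @param seqs Character vector of >= 2 DNA sequences, each at least
#'   `max(width_range)` long.
#' @param width_range Integer vector `c(min, max)` of candidate widths.
#' @param mode `"zoops"` (default) or `"oops"` (exactly one site per
#'   sequence).
#' @param restarts Random initializations per width.
#' @param penalty Width-selection penalty per free PWM parameter.
#' @param pseudocount Dirichlet pseudocount per base per PWM column.
#' @param seed Master seed; all restarts derive from it deterministically.
#' @param max_iter,tol EM stopping rule (objective change below `tol`).
#' @return The best `mrpr_pwm`. Its `ll_trace` holds the (penalized MAP)
#'   objective across iterations of the winning EM run, non-decreasing by
#'   construction; `ll` the final data log-likelihood; `score` the
#'   width-selection score.
#' @export
discover_motif <- function(seqs, width_range = c(8, 20),
                           mode = c("zoops", "oops"), restarts = 10,
                           penalty = stats::qchisq(0.995, df = 3) / 3,
                           pseudocount = 0.25, seed = 1,
                           max_iter = 200, tol = 1e-10) {
  mode <- match.arg(mode)
  if (length(seqs) < 2) abort("need at least 2 sequences")
  widths <- seq(min(width_range), max(width_range))
  if (any(nchar(seqs) < max(widths))) {
    abort("all sequences must be at least `max(width_range)` long")
  }
  fwd <- purrr::map(unname(seqs), seq_to_int)
  rev <- purrr::map(fwd, revcomp_int)
  bg <- estimate_background(fwd)
  n <- length(fwd)

  best <- NULL
  for (w in widths) {
    best_w <- NULL
    for (r in seq_len(restarts)) {
      fit <- with_seed(seed * 1000 + w * 100 + r,
                       zoops_em(fwd, rev, w, bg, mode, pseudocount, max_iter, tol))
      if (is.null(best_w) || fit$objective > best_w$objective) best_w <- fit
    }
    best_w <- shift_refine(best_w, fwd, rev, w, bg, mode, pseudocount,
                           max_iter, tol)
    ll0 <- sum(purrr::map_dbl(fwd, function(s) sum(log(bg[s]))))
    score <- 2 * (best_w$ll - ll0) - 3 * w * penalty
    pwm <- new_pwm(best_w$probs, bg, pseudocount, best_w$n_sites,
                   score = score, ll = best_w$ll, ll_trace = best_w$trace,
                   gamma = best_w$gamma)
    if (is.null(best) || score > best$score) best <- pwm
  }
  best
}

# Phase-shift refinement: EM frequently converges to a registration of the
# true motif shifted by a column or two. Starting from the converged PWM,
# try shifting the window by -2..2 columns (vacated columns start at
# background), re-run EM warm-started, and keep any improvement; iterate
# until no shift helps.
shift_refine <- function(fit, fwd, rev, w, bg, mode, pseudocount,
                         max_iter, tol) {
  repeat {
    improved <- FALSE
    for (s in c(-2L, -1L, 1L, 2L)) {
      probs0 <- shift_pwm(fit$probs, s, bg)
      cand <- zoops_em(fwd, rev, w, bg, mode, pseudocount, max_iter, tol,
                       init_probs = probs0, init_gamma = fit$gamma)
      if (cand$objective > fit$objective + 1e-9) {
        fit <- cand
        improved <- TRUE
      }
    }
    if (!improved) return(fit)
  }
}

# Shift the motif window along the sequence: s > 0 moves it right (drop the
# leading columns, append background columns), s < 0 left.
shift_pwm <- function(probs, s, bg) {
  w <- ncol(probs)
  bgcol <- matrix(rep(bg, abs(s)), nrow = 4)
  if (s > 0) cbind(probs[, (s + 1):w, drop = FALSE], bgcol)
  else cbind(bgcol, probs[, 1:(w + s), drop = FALSE])
}

# One EM run at fixed width. Returns probs, gamma, data ll, MAP objective and
# per-iteration objective trace.
zoops_em <- function(fwd, rev, w, bg, mode, pseudocount, max_iter, tol,
                     init_probs = NULL, init_gamma = NULL) {
  n <- length(fwd)
  if (is.null(init_probs)) {
    # init: PWM from one randomly chosen site, softened
    si <- sample.int(n, 1)
    m0 <- length(fwd[[si]]) - w + 1L
    st <- sample.int(m0, 1)
    site <- fwd[[si]][st:(st + w - 1L)]
    probs <- matrix(rep(bg, w), nrow = 4)
    for (j in seq_len(w)) {
      probs[, j] <- 0.4 * probs[, j]
      probs[site[j], j] <- probs[site[j], j] + 0.6
      probs[, j] <- probs[, j] / sum(probs[, j])
    }
  } else {
    probs <- init_probs
  }
  gamma <- init_gamma %||% (if (mode == "oops") 1 else 0.5)

  log_prior <- function(p) pseudocount * sum(log(p))
  trace <- numeric()
  obj_old <- -Inf
  ll <- NA_real_
  obj <- NA_real_
  bg_ll <- purrr::map_dbl(fwd, function(s) sum(log(bg[s])))

  for (iter in seq_len(max_iter)) {
    log_odds <- log(probs / bg)
    counts <- matrix(0, nrow = 4, ncol = w)
    occ <- 0
    ll <- 0
    for (i in seq_len(n)) {
      lf <- site_llr(fwd[[i]], log_odds)
      lr <- site_llr(rev[[i]], log_odds)
      llr <- c(lf, lr)
      m2 <- length(llr)
      # P(Z = j | seq) with uniform site prior gamma / m2 per offset/strand
      lw <- llr + log(gamma / m2)
      l0 <- if (mode == "oops") -Inf else log(1 - gamma)
      mx <- max(lw, l0)
      denom <- exp(l0 - mx) + sum(exp(lw - mx))
      ll <- ll + mx + log(denom) + bg_ll[i]
      z <- exp(lw - mx) / denom
      occ <- occ + sum(z)
      # expected site counts, accumulated column-wise (vectorized over offsets)
      mlen <- length(lf)
      idx <- seq_len(mlen)
      for (j in seq_len(w)) {
        bases <- c(fwd[[i]][idx + j - 1L], rev[[i]][idx + j - 1L])
        cs <- rowsum(z, bases)
        counts[as.integer(rownames(cs)), j] <-
          counts[as.integer(rownames(cs)), j] + cs[, 1]
      }
    }
    # penalized (MAP) objective at the parameters the E-step just used;
    # MAP-EM guarantees this is non-decreasing across iterations
    obj <- ll + log_prior(probs)
    trace <- c(trace, obj)
    if (is.finite(obj_old) && obj - obj_old < tol) break
    obj_old <- obj
    probs <- sweep(counts + pseudocount, 2,
                   colSums(counts) + 4 * pseudocount, "/")
    gamma <- if (mode == "oops") 1 else min(max(occ / n, 1e-6), 1 - 1e-6)
  }
  list(probs = probs, gamma = gamma, ll = ll, n_sites = occ,
       objective = obj, trace = trace)
}

#' Scan a genome for PWM occurrences
#'
#' Computes the log-odds score (PWM versus background, in bits) at every
#' position of both strands and returns positions scoring at or above the
#' threshold, sorted by start. On a palindrome the same start can be reported
#' on both strands.
#'
#' @param genome A `synthetic_genome` or named character vector of contigs.
#' @param pwm An `mrpr_pwm`.
#' @param threshold Minimum log-odds in bits; `max_logodds(pwm) * frac` is a
#'   convenient choice.
#' @return Tibble of class `motif_hits`: `contig`, `start` (0-based),
#'   `strand`, `log_odds`.
#' @export
scan_genome <- function(genome, pwm, threshold) {
  if (!is.finite(threshold)) abort("`threshold` must be finite")
  seqs <- if (inherits(genome, "synthetic_genome")) {
    setNames(genome$sequence, genome$name)
  } else genome
  lo <- log2(pwm$probs / pwm$background)
  lo_rc <- lo[4:1, rev(seq_len(pwm$width)), drop = FALSE]  # minus-strand scores at same start
  res <- purrr::imap(seqs, function(s, ctg) {
    code <- seq_to_int(s)
    if (length(code) < pwm$width) return(NULL)
    sf <- site_llr(code, lo)
    sr <- site_llr(code, lo_rc)
    hi_f <- which(sf >= threshold)
    hi_r <- which(sr >= threshold)
    tibble::tibble(
      contig = ctg,
      start = c(hi_f, hi_r) - 1L,
      strand = rep(c("+", "-"), c(length(hi_f), length(hi_r))),
      log_odds = c(sf[hi_f], sr[hi_r])
    )
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    out <- tibble::tibble(contig = character(), start = integer(),
                          strand = character(), log_odds = double())
  }
  out <- dplyr::arrange(out, .data$contig, .data$start, .data$strand)
  class(out) <- c("motif_hits", class(out))
  out
}

#' Maximum attainable log-odds score of a PWM (bits)
#' @param pwm An `mrpr_pwm`.
#' @return Scalar bits.
#' @export
max_logodds <- function(pwm) {
  sum(apply(log2(pwm$probs / pwm$background), 2, max))
}

#' Write a PWM in MEME minimal text format
#'
#' @param pwm An `mrpr_pwm`.
#' @param path Output path.
#' @param name Motif name.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwm, path, name = "MOTIF_1") {
  lines <- c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    sprintf("A %.6f C %.6f G %.6f T %.6f",
            pwm$background[1], pwm$background[2],
            pwm$background[3], pwm$background[4]), "",
    paste("MOTIF", name),
    sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
            pwm$width, max(1L, round(pwm$n_sites))),
    apply(pwm$probs, 2, function(p) sprintf(" %.6f %.6f %.6f %.6f",
                                            p[1], p[2], p[3], p[4]))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write motif hits as BED6
#' @param hits A `motif_hits` tibble.
#' @param pwm The scanned `mrpr_pwm` (for the interval width).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, pwm, path) {
  writeLines(sprintf("%s\t%d\t%d\thit_%d\t%.3f\t%s",
                     hits$contig, hits$start, hits$start + pwm$width,
                     seq_len(nrow(hits)), hits$log_odds, hits$strand),
             path)
  invisible(path)
}
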