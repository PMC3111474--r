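#' Parameters of the scan-based sequence likelihood
#'
#' `q` is the marginal probability that a hidden position-state within the
#' regulatory region of a *target* gene is a motif (for non-targets the
#' hidden layer stays at background with probability 1). `threshold` is the
#' minimum per-segment log likelihood-ratio for the scan to call a motif;
#' the default `NULL` resolves, per PSSM, to `threshold_frac` times the
#' PSSM's maximum achievable score, a scale-free rule that adapts to motif
#' information content.
#'
#' @param q motif-state probability, in (0, 1).
#' @param threshold absolute calling threshold (natural-log scale), or
#'   `NULL` to use the fractional rule.
#' @param threshold_frac fraction of the maximum PSSM score used when
#'   `threshold` is `NULL`; default 0.6.
#' @return An object of class `tn_seq_params`.
#' @export
tn_seq_params <- function(q = 0.005, threshold = NULL, threshold_frac = 0.6) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q <= 0 || q >= 1)
    stop_tn("'q' must be in (0, 1)")
  if (!is.null(threshold) && (!is.numeric(threshold) || !is.finite(threshold)))
    stop_tn("'threshold' must be finite or NULL")
  structure(list(q = q, threshold = threshold, threshold_frac = threshold_frac),
            class = "tn_seq_params")
}

resolve_threshold <- function(params, pssm) {
  if (!is.null(params$threshold)) params$threshold
  else params$threshold_frac * pssm_max_score(pssm)
}

# Encode A/C/G/T -> 1..4; N and other IUPAC ambiguity codes -> NA
encode_dna <- function(seq) {
  v <- strsplit(toupper(seq), "")[[1L]]
  bad <- !v %in% c(BASES, "N")
  if (any(bad))
    v[bad] <- "N"
  match(v, BASES)
}

# per-offset log likelihood-ratio scores on one strand
segment_scores <- function(code, log_ratio) {
  w <- nrow(log_ratio)
  n <- length(code) - w + 1L
  if (n < 1L) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    contrib <- unname(log_ratio[j, ])[code[j:(j + n - 1L)]]
    contrib[is.na(contrib)] <- 0  # N bases are neutral
    sc <- sc + contrib
  }
  sc
}

# log_ratio matrix for scoring the reverse strand on forward coordinates
rc_log_ratio <- function(pssm) {
  m <- pssm$log_ratio[rev(seq_len(pssm$width)), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(m) <- BASES
  m
}

#' Log likelihood-ratio score of one motif-width segment
#'
#' `sum_k log( probs[k, base_k] / background[base_k] )`; `N` bases
#' contribute 0. Natural logarithms throughout.
#'
#' @param segment character string whose length equals the PSSM width.
#' @param pssm a [build_pssm()] object.
#' @return A single score.
#' @export
score_segment <- function(segment, pssm) {
  stopifnot(inherits(pssm, "tn_pssm"))
  code <- encode_dna(segment)
  if (length(code) != pssm$width)
    stop_tn("segment length must equal the PSSM width")
  s <- segment_scores(code, pssm$log_ratio)
  s[1L]
}

#' Scan a promoter window for motif occurrences
#'
#' Scores every offset on both strands, keeps segments whose score reaches
#' the calling threshold, and resolves overlaps greedily by descending
#' score (ties: leftmost, then forward strand). The scan summary carries
#' the sufficient statistics of the sequence likelihood: `n_background`
#' (N_b, bases not covered by a called motif), `n_motifs` (N_m), and
#' `log_r` (log R, the summed log likelihood-ratio scores of the called
#' motifs), plus the background log-probability of the whole window.
#'
#' @param window character string (A/C/G/T/N; other codes are treated as N).
#' @param pssm a `tn_pssm`.
#' @param params a [tn_seq_params()].
#' @param seqid,offset sequence id and 1-based start of the window on its
#'   parent sequence, recorded for provenance/export.
#' @return An object of class `tn_scan`.
#' @export
scan_window <- function(window, pssm, params = tn_seq_params(),
                        seqid = NA_character_, offset = 1L) {
  stopifnot(inherits(pssm, "tn_pssm"), inherits(params, "tn_seq_params"))
  if (!is.character(window) || length(window) != 1L || !nzchar(window))
    stop_tn("'window' must be one nonempty sequence string")
  code <- encode_dna(window)
  len <- length(code)
  thr <- resolve_threshold(params, pssm)
  w <- pssm$width

  hits <- data.frame(position = integer(0), strand = character(0),
                     score = numeric(0))
  if (len >= w) {
    fwd <- segment_scores(code, pssm$log_ratio)
    rev_ <- segment_scores(code, rc_log_ratio(pssm))
    fi <- which(fwd >= thr)
    ri <- which(rev_ >= thr)
    cand <- rbind(
      data.frame(position = fi, strand = rep("+", length(fi)), score = fwd[fi]),
      data.frame(position = ri, strand = rep("-", length(ri)), score = rev_[ri])
    )
    if (nrow(cand)) {
      cand <- cand[order(-cand$score, cand$position, cand$strand), , drop = FALSE]
      taken <- logical(len)
      keep <- logical(nrow(cand))
      for (i in seq_len(nrow(cand))) {
        span <- cand$position[i]:(cand$position[i] + w - 1L)
        if (!any(taken[span])) {
          taken[span] <- TRUE
          keep[i] <- TRUE
        }
      }
      hits <- cand[keep, , drop = FALSE]
      hits <- hits[order(hits$position), , drop = FALSE]
      rownames(hits) <- NULL
    }
  }

  lbg <- log(pssm$background)[code]
  lbg[is.na(lbg)] <- 0
  structure(list(
    n_background = len - nrow(hits) * w,
    n_motifs = nrow(hits),
    log_r = sum(hits$score),
    log_bg = sum(lbg),
    width = w,
    length = len,
    threshold = thr,
    window = list(seqid = seqid, start = offset, end = offset + len - 1L),
    hits = hits
  ), class = "tn_scan")
}

#' @export
print.tn_scan <- function(x, ...) {
  cat(sprintf("tn_scan: %d bp, N_m = %d, N_b = %d, log R = %.4g\n",
              x$length, x$n_motifs, x$n_background, x$log_r))
  invisible(x)
}

#' Conditional log-likelihood of a scanned window given the regulatory state
#'
#' For a non-target (`z = 0`) the window is pure background:
#' `sum_k log p_b(base_k)`. For a target (`z = 1`) the hidden layer emits
#' motifs with marginal probability `q`, giving
#' `log P(S | z = 1) = log P(S | z = 0) + N_b log(1 - q) + N_m log(q) + log R`,
#' so the target-vs-background log-likelihood difference is exactly
#' `N_b log(1 - q) + N_m log(q) + log R`.
#'
#' @param scan a [scan_window()] summary.
#' @param z 0 or 1.
#' @param params a [tn_seq_params()] supplying `q`.
#' @return Log-probability (natural log).
#' @export
seq_loglik <- function(scan, z, params) {
  stopifnot(inherits(scan, "tn_scan"), inherits(params, "tn_seq_params"))
  if (!z %in% c(0, 1)) stop_tn("'z' must be 0 or 1")
  if (z == 0) return(scan$log_bg)
  scan$log_bg + scan$n_background * log(1 - params$q) +
    scan$n_motifs * log(params$q) + scan$log_r
}

# target-vs-background log-likelihood difference of a scan under q
scan_delta <- function(scan, q) {
  scan$n_background * log(1 - q) + scan$n_motifs * log(q) + scan$log_r
}

#' Pick the most informative fixed-size window of a long regulatory region
#'
#' Evaluates every `window_size` window at the given `step` (plus a final
#' flush-to-end window so the tail is always covered) and returns the scan
#' summary of the window maximizing the target-vs-background log-likelihood
#' difference; ties go to the leftmost window. That summary represents the
#' whole region in the sequence likelihood.
#'
#' @param sequence character string, e.g. the 20 kb region flanking a TSS.
#' @param pssm a `tn_pssm`.
#' @param params a [tn_seq_params()].
#' @param window_size,step window length and stride in bp; defaults 500
#'   and 250 (half-overlap).
#' @param seqid id recorded in the returned summary.
#' @return A `tn_scan` for the selected window (coordinates refer to
#'   `sequence`, 1-based start stored in `$window`).
#' @export
select_best_window <- function(sequence, pssm, params = tn_seq_params(),
                               window_size = 500L, step = 250L,
                               seqid = NA_character_) {
  len <- nchar(sequence)
  if (len < window_size) {
    warning("sequence shorter than window_size; scanning it whole", call. = FALSE)
    return(scan_window(sequence, pssm, params, seqid = seqid, offset = 1L))
  }
  starts <- seq.int(1L, len - window_size + 1L, by = step)
  if (starts[length(starts)] != len - window_size + 1L)
    starts <- c(starts, len - window_size + 1L)
  best <- NULL
  best_delta <- -Inf
  for (s in starts) {
    sc <- scan_window(substr(sequence, s, s + window_size - 1L), pssm, params,
                      seqid = seqid, offset = s)
    d <- scan_delta(sc, params$q)
    if (d > best_delta) {
      best <- sc
      best_delta <- d
    }
  }
  best
}

#' Motif-based binding affinity of a regulatory region
#'
#' The target-vs-background log-likelihood difference of the best window
#' (see [select_best_window()]): one number per gene per species. The
#' interspecies difference of a gene pair is the absolute difference of
#' their affinities.
#'
#' @inheritParams select_best_window
#' @return A single affinity score.
#' @export
binding_affinity <- function(sequence, pssm, params = tn_seq_params(),
                             window_size = 500L, step = 250L) {
  sc <- suppressWarnings(
    select_best_window(sequence, pssm, params, window_size, step))
  scan_delta(sc, params$q)
}

#' Pool scan summaries from several motifs over the same window
#'
#' With several TF matrices, R becomes the product of the likelihood-ratio
#' scores of the motifs called by every scan; N_m sums, and N_b is the
#' window length minus the motif-covered bases.
#'
#' @param scans list of `tn_scan` objects over the same window.
#' @return A pooled `tn_scan`.
#' @export
pool_scans <- function(scans) {
  stopifnot(length(scans) >= 1L, all(vapply(scans, inherits, TRUE, "tn_scan")))
  len <- scans[[1L]]$length
  if (any(vapply(scans, `[[`, 0L, "length") != len))
    stop_tn("all scans must cover the same window length")
  covered <- sum(vapply(scans, function(s) s$n_motifs * s$width, 0))
  out <- scans[[1L]]
  out$n_motifs <- sum(vapply(scans, `[[`, 0L, "n_motifs"))
  out$n_background <- len - covered
  out$log_r <- sum(vapply(scans, `[[`, 0, "log_r"))
  out$hits <- do.call(rbind, lapply(scans, `[[`, "hits"))
  out
}

#' Export scan hits as a BED-like tab-delimited table
#'
#' Coordinates are 0-based half-open; columns: sequence id, start, end,
#' strand, score. The header line starts with `#`.
#'
#' @param scans a `tn_scan` or list of them.
#' @param path output path.
#' @export
write_hits_bed <- function(scans, path) {
  if (inherits(scans, "tn_scan")) scans <- list(scans)
  rows <- do.call(rbind, lapply(scans, function(s) {
    if (!nrow(s$hits)) return(NULL)
    data.frame(seqid = s$window$seqid,
               start = s$window$start + s$hits$position - 2L,
               end = s$window$start + s$hits$position - 2L + s$width,
               strand = s$hits$strand,
               score = s$hits$score)
  }))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#seqid\tstart\tend\tstrand\tscore", con)
  if (!is.null(rows))
    utils::write.table(rows, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}
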