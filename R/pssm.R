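BASES <- c("A", "C", "G", "T")

#' Build a position-specific score matrix (PSSM)
#'
#' Normalizes a count or probability matrix over `{A, C, G, T}` into
#' per-position base probabilities, together with the background base
#' frequencies against which motif segments are scored as log
#' likelihood ratios.
#'
#' Orientation is positions-in-rows, bases-in-columns (a matrix with 4
#' columns); a 4-row matrix with base rownames is transposed
#' automatically. A count matrix receives `pseudocount` added to every
#' cell before normalization. A matrix whose rows already sum to 1 is
#' treated as probabilities and passed through unchanged (up to
#' renormalization) unless a pseudocount is supplied explicitly.
#'
#' @param x numeric matrix of counts or probabilities.
#' @param pseudocount nonnegative value added to every cell; default 0.5
#'   for counts, 0 for probability input.
#' @param background base frequencies `p_b` over A, C, G, T; default
#'   uniform.
#' @return An object of class `tn_pssm` with elements `probs` (width x 4),
#'   `background`, `width`, `pseudocount`, and `log_ratio` (the
#'   per-position log( prob / background ) score matrix).
#' @examples
#' build_pssm(matrix(c(9, 1, 0, 0), nrow = 1), pseudocount = 1)
#' @export
build_pssm <- function(x, pseudocount = NULL, background = rep(0.25, 4)) {
  x <- as.matrix(x)
  if (ncol(x) == 4L && !is.null(colnames(x)) && setequal(toupper(colnames(x)), BASES)) {
    x <- x[, match(BASES, toupper(colnames(x))), drop = FALSE]
  } else if (nrow(x) == 4L && !is.null(rownames(x)) && setequal(toupper(rownames(x)), BASES)) {
    x <- t(x[match(BASES, toupper(rownames(x))), , drop = FALSE])
  } else if (ncol(x) != 4L && nrow(x) == 4L) {
    x <- t(x)
  }
  if (ncol(x) != 4L) stop_tn("PSSM matrix must cover the four bases A, C, G, T")
  if (any(is.na(x)) || any(x < 0)) stop_tn("PSSM entries must be nonnegative numbers")
  if (nrow(x) < 1L) stop_tn("PSSM must have at least one position")
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop_tn("'background' must be four positive frequencies")
  background <- background / sum(background)

  is_prob <- all(abs(rowSums(x) - 1) < 1e-6)
  if (is.null(pseudocount)) pseudocount <- if (is_prob) 0 else 0.5
  if (pseudocount < 0) stop_tn("'pseudocount' must be nonnegative")
  x <- x + pseudocount
  if (any(rowSums(x) == 0)) stop_tn("PSSM has an all-zero position and no pseudocount")
  if (any(x == 0)) stop_tn("PSSM has zero cells; supply a positive pseudocount")
  probs <- x / rowSums(x)
  dimnames(probs) <- list(NULL, BASES)
  structure(list(
    probs = probs,
    background = stats::setNames(background, BASES),
    width = nrow(probs),
    pseudocount = pseudocount,
    log_ratio = log(probs / rep(background, each = nrow(probs)))
  ), class = "tn_pssm")
}

#' @export
print.tn_pssm <- function(x, ...) {
  cat(sprintf("tn_pssm: width %d, consensus %s\n", x$width,
              paste(BASES[apply(x$probs, 1L, which.max)], collapse = "")))
  print(round(x$probs, 3))
  invisible(x)
}

# maximum achievable log likelihood-ratio score of a PSSM
pssm_max_score <- function(pssm) sum(apply(pssm$log_ratio, 1L, max))

#' Read a PSSM from a 4-column TSV or MEME-minimal file
#'
#' The TSV dialect has a header line naming the four bases (leading `#`
#' allowed) and one row per motif position, counts or probabilities. The
#' MEME-minimal dialect is recognized by its `MEME version` header; the
#' first motif's letter-probability matrix is used, together with the
#' file's `Background letter frequencies` when present.
#'
#' @param path file path.
#' @param pseudocount,background passed to [build_pssm()]; a background in
#'   the MEME file takes precedence.
#' @return A `tn_pssm`.
#' @export
read_pssm <- function(path, pseudocount = NULL, background = rep(0.25, 4)) {
  lines <- readLines(path, warn = FALSE)
  if (any(grepl("^MEME version", lines, ignore.case = TRUE))) {
    bg_i <- grep("^Background letter frequencies", lines, ignore.case = TRUE)
    if (length(bg_i)) {
      toks <- strsplit(trimws(lines[bg_i[1L] + 1L]), "\\s+")[[1L]]
      vals <- suppressWarnings(as.numeric(toks))
      bg <- vals[!is.na(vals)]
      nm <- toupper(toks[is.na(suppressWarnings(as.numeric(toks)))])
      if (length(bg) == 4L && setequal(nm, BASES)) background <- bg[match(BASES, nm)]
    }
    lp_i <- grep("^letter-probability matrix", lines, ignore.case = TRUE)
    if (!length(lp_i)) stop_tn(sprintf("%s: no letter-probability matrix found", path))
    rows <- list()
    i <- lp_i[1L] + 1L
    while (i <= length(lines)) {
      toks <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1L]]))
      if (length(toks) != 4L || any(is.na(toks))) break
      rows[[length(rows) + 1L]] <- toks
      i <- i + 1L
    }
    if (!length(rows)) stop_tn(sprintf("%s: empty letter-probability matrix", path))
    m <- do.call(rbind, rows)
    colnames(m) <- BASES
    return(build_pssm(m, pseudocount = pseudocount, background = background))
  }
  lines <- lines[nzchar(trimws(lines))]
  header <- sub("^#\\s*", "", lines[1L])
  cols <- toupper(strsplit(trimws(header), "\t|\\s+")[[1L]])
  if (!setequal(intersect(cols, BASES), BASES))
    stop_tn(sprintf("%s: header must name the four bases A C G T", path))
  body <- lines[-1L]
  m <- do.call(rbind, lapply(seq_along(body), function(i) {
    toks <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\t|\\s+")[[1L]]))
    if (length(toks) != length(cols) || any(is.na(toks)))
      stop_tn(sprintf("%s: line %d is not numeric over %d columns", path, i + 1L, length(cols)))
    toks
  }))
  colnames(m) <- cols
  build_pssm(m[, BASES, drop = FALSE], pseudocount = pseudocount, background = background)
}

#' Write a PSSM as a 4-column TSV (round-trips with [read_pssm()])
#' @param pssm a `tn_pssm`.
#' @param path output path.
#' @export
write_pssm <- function(pssm, path) {
  stopifnot(inherits(pssm, "tn_pssm"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(BASES, collapse = "\t")), con)
  utils::write.table(format(pssm$probs, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Randomly permute a PSSM (null-model control)
#'
#' Independently shuffles motif positions (rows) and base identities
#' (columns), once each. Feeding permuted matrices through the full
#' pipeline yields the null distribution of rewiring rates against which
#' the observed rate is compared.
#'
#' @param pssm a `tn_pssm` with at least 2 positions.
#' @param seed integer seed; the permutation is reproducible given the seed.
#' @return A `tn_pssm` with permuted probabilities, same background.
#' @export
permute_pssm <- function(pssm, seed) {
  stopifnot(inherits(pssm, "tn_pssm"))
  if (pssm$width < 2L) stop_tn("PSSM must have >= 2 positions to permute")
  set.seed(as.integer(seed))
  p <- pssm$probs[sample.int(pssm$width), sample.int(4L), drop = FALSE]
  colnames(p) <- BASES
  build_pssm(p, pseudocount = 0, background = pssm$background)
}
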