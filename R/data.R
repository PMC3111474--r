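#' Assemble ortholog-group data from promoter windows and cluster labels
#'
#' The unit of analysis is an orthologous gene group: one gene per leaf
#' species, each contributing the scan summary of its (already selected)
#' promoter window and an expression-cluster label. Windows are scanned
#' here with the supplied PSSM so that the sufficient statistics
#' (N_b, N_m, log R, background log-probability) are consistent across the
#' whole dataset.
#'
#' @param windows M x N character matrix of window sequences (rows =
#'   groups, columns = species, sorted species order).
#' @param labels M x N integer matrix of cluster labels (1..K per species).
#' @param pssm a `tn_pssm`.
#' @param seq_params a [tn_seq_params()] (fixes the calling threshold).
#' @param K named integer vector of cluster counts per species; default
#'   `max` of each label column.
#' @param groups group ids; default rownames of `windows`.
#' @param genes optional M x N matrix of gene ids.
#' @return An object of class `tn_data`.
#' @export
tn_data_from_windows <- function(windows, labels, pssm,
                                 seq_params = tn_seq_params(),
                                 K = NULL, groups = rownames(windows),
                                 genes = NULL) {
  stopifnot(is.matrix(windows), is.matrix(labels),
            all(dim(windows) == dim(labels)),
            inherits(pssm, "tn_pssm"), inherits(seq_params, "tn_seq_params"))
  species <- colnames(windows)
  if (is.null(species)) stop_tn("'windows' needs species column names")
  if (is.unsorted(species)) {
    o <- order(species)
    windows <- windows[, o, drop = FALSE]
    labels <- labels[, o, drop = FALSE]
    if (!is.null(genes)) genes <- genes[, o, drop = FALSE]
    species <- species[o]
  }
  M <- nrow(windows)
  N <- ncol(windows)
  if (is.null(groups)) groups <- paste0("grp", seq_len(M))
  if (is.null(K)) K <- apply(labels, 2L, max)
  K <- stats::setNames(as.integer(K), species)
  if (any(labels < 1L | labels > rep(K, each = M)))
    stop_tn("labels out of 1..K range")

  n_bg <- n_m <- log_r <- log_bgp <- matrix(0, M, N, dimnames = list(groups, species))
  for (j in seq_len(N)) {
    for (i in seq_len(M)) {
      sc <- scan_window(windows[i, j], pssm, seq_params,
                        seqid = paste0(species[j], "|", groups[i]))
      n_bg[i, j] <- sc$n_background
      n_m[i, j] <- sc$n_motifs
      log_r[i, j] <- sc$log_r
      log_bgp[i, j] <- sc$log_bg
    }
  }
  structure(list(
    species = species, groups = as.character(groups), genes = genes,
    n_background = n_bg, n_motifs = n_m, log_r = log_r, log_bgp = log_bgp,
    labels = matrix(as.integer(labels), M, N, dimnames = list(groups, species)),
    K = K, windows = windows, pssm = pssm, seq_params = seq_params
  ), class = "tn_data")
}

#' @export
print.tn_data <- function(x, ...) {
  cat(sprintf("tn_data: %d ortholog groups x %d species (%s)\n",
              length(x$groups), length(x$species),
              paste(x$species, collapse = ", ")))
  cat(sprintf("  motif width %d, clusters: %s\n", x$pssm$width,
              paste(sprintf("%s=%d", names(x$K), x$K), collapse = ", ")))
  invisible(x)
}

#' @export
`[.tn_data` <- function(x, i, ...) {
  out <- x
  for (f in c("n_background", "n_motifs", "log_r", "log_bgp", "labels"))
    out[[f]] <- x[[f]][i, , drop = FALSE]
  if (!is.null(x$windows)) out$windows <- x$windows[i, , drop = FALSE]
  if (!is.null(x$genes)) out$genes <- x$genes[i, , drop = FALSE]
  out$groups <- x$groups[i]
  out
}

n_groups <- function(data) length(data$groups)

#' Assemble ortholog-group data from long regulatory regions
#'
#' Runs [select_best_window()] on each gene's region (e.g. 20 kb flanking
#' the TSS) and keeps the most informative `window_size` window as that
#' gene's representative in the likelihood. Groups with a member missing a
#' sequence or a label in any species are dropped with a message.
#'
#' @param sequences named character vector of regions, names `species|gene`
#'   (as produced by [read_fasta_sequences()]), or a named-by-species list
#'   of named-by-gene vectors.
#' @param labels data frame with columns `species`, `gene`, `label`.
#' @param ortholog_map data frame with column `group` plus one gene-id
#'   column per species.
#' @param pssm,seq_params scanning model, as in [tn_data_from_windows()].
#' @param window_size,step sliding-window size and stride (bp).
#' @param K optional named cluster counts per species.
#' @return A `tn_data`.
#' @export
prepare_tn_data <- function(sequences, labels, ortholog_map, pssm,
                            seq_params = tn_seq_params(),
                            window_size = 500L, step = 250L, K = NULL) {
  if (is.list(sequences)) {
    sequences <- unlist(lapply(names(sequences), function(sp)
      stats::setNames(sequences[[sp]], paste0(sp, "|", names(sequences[[sp]])))))
  }
  stopifnot(is.data.frame(labels),
            all(c("species", "gene", "label") %in% names(labels)),
            is.data.frame(ortholog_map), "group" %in% names(ortholog_map))
  species <- sort(setdiff(names(ortholog_map), "group"))
  lab_key <- paste0(labels$species, "|", labels$gene)
  if (anyDuplicated(lab_key)) stop_tn("duplicate (species, gene) label entries")
  lab_lookup <- stats::setNames(as.integer(labels$label), lab_key)

  M0 <- nrow(ortholog_map)
  keep <- logical(M0)
  for (i in seq_len(M0)) {
    keys <- paste0(species, "|", vapply(species, function(sp)
      as.character(ortholog_map[[sp]][i]), ""))
    keep[i] <- all(keys %in% names(sequences)) && all(keys %in% names(lab_lookup))
  }
  if (any(!keep))
    message(sprintf("dropping %d of %d groups lacking a sequence or label in some species",
                    sum(!keep), M0))
  om <- ortholog_map[keep, , drop = FALSE]
  if (!nrow(om)) stop_tn("no complete ortholog groups left")

  M <- nrow(om)
  win <- matrix("", M, length(species),
                dimnames = list(om$group, species))
  lab <- matrix(0L, M, length(species), dimnames = dimnames(win))
  genes <- matrix("", M, length(species), dimnames = dimnames(win))
  for (j in seq_along(species)) {
    gs <- as.character(om[[species[j]]])
    keys <- paste0(species[j], "|", gs)
    genes[, j] <- gs
    lab[, j] <- lab_lookup[keys]
    for (i in seq_len(M)) {
      sc <- select_best_window(sequences[[keys[i]]], pssm, seq_params,
                               window_size = window_size, step = step,
                               seqid = keys[i])
      win[i, j] <- substr(sequences[[keys[i]]], sc$window$start, sc$window$end)
    }
  }
  tn_data_from_windows(win, lab, pssm, seq_params, K = K,
                       groups = as.character(om$group), genes = genes)
}
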