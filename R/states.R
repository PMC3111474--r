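new_tn_states <- function(gp, data) {
  species <- colnames(gp$configs)
  cats <- classify_conservation(gp$map)
  tab <- data.frame(group = data$groups, stringsAsFactors = FALSE)
  for (sp in species) tab[[paste0("map_", sp)]] <- gp$map[, sp]
  for (sp in species) tab[[paste0("marginal_", sp)]] <- gp$marginal[, sp]
  tab$category <- cats
  structure(list(table = tab, map = gp$map, marginal = gp$marginal,
                 posterior = gp$posterior, configs = gp$configs,
                 species = species, groups = data$groups,
                 category = cats, loglik = gp$loglik),
            class = "tn_states")
}

#' @export
print.tn_states <- function(x, ...) {
  cat(sprintf("tn_states: %d groups x %d species\n",
              length(x$groups), length(x$species)))
  print(table(x$category))
  invisible(x)
}

#' @export
as.data.frame.tn_states <- function(x, ...) x$table

#' Conservation category of a leaf regulatory-state configuration
#'
#' For N species: all ones is `conserved_all`; all zeros `non_target`;
#' exactly one target `species_specific:<species>`; exactly N-1 targets
#' `conserved_partial:missing_<species>`; anything else (N > 4) `mixed`.
#'
#' @param config 0/1 vector named by species, or a 0/1 matrix with species
#'   columns (one row per group).
#' @return Character vector of categories.
#' @export
classify_conservation <- function(config) {
  if (!is.matrix(config)) config <- matrix(config, nrow = 1L,
                                           dimnames = list(NULL, names(config)))
  species <- colnames(config)
  if (is.null(species)) species <- paste0("sp", seq_len(ncol(config)))
  n <- ncol(config)
  s <- rowSums(config)
  out <- rep("mixed", nrow(config))
  out[s == n] <- "conserved_all"
  out[s == 0] <- "non_target"
  one <- which(s == 1)
  if (length(one))
    out[one] <- paste0("species_specific:",
                       species[apply(config[one, , drop = FALSE], 1L, which.max)])
  if (n > 2L) {
    part <- which(s == n - 1L)
    if (length(part))
      out[part] <- paste0("conserved_partial:missing_",
                          species[apply(1 - config[part, , drop = FALSE], 1L, which.max)])
  }
  out
}

#' Network rewiring rate from inferred regulatory states
#'
#' The rewiring rate is the fraction of non-conserved TF-target links:
#' `1 - (# conserved-in-all-species groups) / denominator`. The default
#' denominator counts all analyzed groups (so 823 conserved of 1489 groups
#' gives 44.7%); the alternative counts only groups that are a target in
#' at least one species. The convention used is recorded in the report.
#'
#' @param x a `tn_states` object, or a character vector of conservation
#'   categories as produced by [classify_conservation()].
#' @param denominator `"all_groups"` (default) or `"groups_with_any_link"`.
#' @return An object of class `tn_rewiring`: category counts, `rate` in
#'   `[0, 1]`, and the denominator convention.
#' @export
rewiring_rate <- function(x, denominator = c("all_groups", "groups_with_any_link")) {
  denominator <- match.arg(denominator)
  cats <- if (inherits(x, "tn_states")) x$category else as.character(x)
  if (!length(cats)) stop_tn("no groups to compute a rewiring rate from")
  n_all <- length(cats)
  n_cons <- sum(cats == "conserved_all")
  n_linked <- sum(cats != "non_target")
  denom <- if (denominator == "all_groups") n_all else n_linked
  if (denom == 0) stop_tn("rewiring rate undefined: empty denominator")
  structure(list(counts = table(cats), n_groups = n_all,
                 n_conserved = n_cons, n_linked = n_linked,
                 rate = 1 - n_cons / denom, denominator = denominator),
            class = "tn_rewiring")
}

#' @export
print.tn_rewiring <- function(x, ...) {
  cat(sprintf("rewiring rate: %.1f%% (denominator: %s, %d conserved of %d)\n",
              100 * x$rate, x$denominator, x$n_conserved,
              if (x$denominator == "all_groups") x$n_groups else x$n_linked))
  print(x$counts)
  invisible(x)
}

#' Accuracy of predicted regulatory states against a truth table
#'
#' The ratio between the number of correct (species, gene) predictions and
#' the total number of (species, gene) pairs.
#'
#' @param predicted a `tn_states` object or a 0/1 matrix (groups x
#'   species).
#' @param truth 0/1 matrix with the same groups and species.
#' @return Fraction in `[0, 1]`.
#' @export
prediction_accuracy <- function(predicted, truth) {
  pred <- if (inherits(predicted, "tn_states")) predicted$map else as.matrix(predicted)
  truth <- as.matrix(truth)
  if (!is.null(colnames(pred)) && !is.null(colnames(truth))) {
    if (!all(colnames(pred) %in% colnames(truth)))
      stop_tn("truth table must cover every (species, gene) pair of the predictions")
    truth <- truth[, colnames(pred), drop = FALSE]
  }
  if (!all(dim(pred) == dim(truth)))
    stop_tn("truth table must cover every (species, gene) pair of the predictions")
  if (any(is.na(truth))) stop_tn("truth table has missing entries")
  mean(pred == truth)
}

#' Interspecies binding-affinity differences by conservation category
#'
#' For every ortholog group, the mean over species pairs of the absolute
#' difference in binding affinity (see [binding_affinity()]); groups are
#' stratified by collapsed conservation category (conserved in all /
#' conserved in all-but-one / target in exactly one / non-target) and each
#' category is reported with its mean and a normal-approximation 95%
#' confidence interval. Empty categories are absent from the result.
#'
#' @param data a `tn_data` (window sequences are rescanned per species).
#' @param states a `tn_states` for the same groups.
#' @param params a [tn_params()]; supplies `q` and the threshold.
#' @return Data frame: `category`, `n`, `mean`, `lower`, `upper`.
#' @export
affinity_by_conservation <- function(data, states, params) {
  stopifnot(inherits(data, "tn_data"), inherits(states, "tn_states"))
  aff <- affinity_matrix(data, params)
  N <- ncol(aff)
  pairs <- utils::combn(N, 2L)
  pairdiff <- sapply(seq_len(ncol(pairs)), function(p)
    abs(aff[, pairs[1L, p]] - aff[, pairs[2L, p]]))
  if (!is.matrix(pairdiff)) pairdiff <- matrix(pairdiff, nrow = nrow(aff))
  per_group <- rowMeans(pairdiff)
  cat_collapsed <- sub(":.*$", "", states$category)
  lv <- c("conserved_all", "conserved_partial", "species_specific", "non_target")
  out <- do.call(rbind, lapply(lv, function(cc) {
    v <- per_group[cat_collapsed == cc]
    if (!length(v)) return(NULL)
    se <- if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_
    data.frame(category = cc, n = length(v), mean = mean(v),
               lower = mean(v) - 1.96 * se, upper = mean(v) + 1.96 * se)
  }))
  rownames(out) <- NULL
  out
}

# per-gene, per-species binding affinity of the stored windows
affinity_matrix <- function(data, params) {
  M <- n_groups(data)
  N <- length(data$species)
  aff <- matrix(0, M, N, dimnames = list(data$groups, data$species))
  for (j in seq_len(N)) for (i in seq_len(M)) {
    sc <- scan_window(data$windows[i, j], data$pssm, params$seq)
    aff[i, j] <- scan_delta(sc, params$seq$q)
  }
  aff
}

#' Write inferred states as a tab-delimited results table
#'
#' Columns: group, per-species gene id (when known), per-species MAP
#' state, per-species marginal, conservation category. Header line starts
#' with `#`.
#'
#' @param states a `tn_states`.
#' @param path output path.
#' @param data optional `tn_data` supplying gene ids.
#' @export
write_states_tsv <- function(states, path, data = NULL) {
  tab <- states$table
  if (!is.null(data) && !is.null(data$genes)) {
    for (sp in rev(states$species))
      tab <- cbind(tab[1L], stats::setNames(data.frame(data$genes[, sp]),
                                            paste0("gene_", sp)),
                   tab[-1L])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(tab), collapse = "\t")), con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
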