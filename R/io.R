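#' Read promoter sequences from FASTA
#'
#' Record ids follow the `species|gene` convention; the ortholog map is
#' the single source of cross-species correspondence.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  if (anyDuplicated(names(ss))) stop_tn(sprintf("%s: duplicate sequence ids", path))
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write promoter sequences to FASTA
#' @param seqs named character vector (`species|gene` ids).
#' @param path output path.
#' @export
write_fasta_sequences <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

# TSV with a header line that may carry a leading '#'
read_headed_tsv <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(trimws(first)))
    stop_tn(sprintf("%s: empty file", path))
  cols <- strsplit(sub("^#\\s*", "", first), "\t")[[1L]]
  df <- utils::read.delim(path, header = FALSE, sep = "\t", skip = 1L,
                          comment.char = "", stringsAsFactors = FALSE)
  if (ncol(df) != length(cols))
    stop_tn(sprintf("%s: line 2 onward has %d columns, header names %d",
                    path, ncol(df), length(cols)))
  names(df) <- cols
  df
}

read_tsv_checked <- function(path, required, what) {
  df <- read_headed_tsv(path)
  if (!all(required %in% names(df)))
    stop_tn(sprintf("%s: %s needs columns %s", path, what,
                    paste(required, collapse = ", ")))
  df
}

#' Read an expression matrix TSV (rows = genes, columns = conditions)
#' @param path TSV with a header line and gene ids in the first column.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_tsv <- function(path) {
  df <- read_headed_tsv(path)
  if (ncol(df) < 2L) stop_tn(sprintf("%s: expected gene column plus conditions", path))
  if (anyDuplicated(df[[1L]])) stop_tn(sprintf("%s: duplicate gene ids", path))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop_tn(sprintf("%s: non-numeric expression values", path))
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Read per-species cluster labels (columns: species, gene, label)
#' @param path TSV path.
#' @return Data frame with columns species, gene, label.
#' @export
read_labels_tsv <- function(path) {
  df <- read_tsv_checked(path, c("species", "gene", "label"), "label table")
  df$label <- suppressWarnings(as.integer(df$label))
  if (any(is.na(df$label)) || any(df$label < 1L))
    stop_tn(sprintf("%s: labels must be positive integers", path))
  df
}

#' Write cluster labels TSV
#' @param labels data frame with species, gene, label (or a
#'   [kmeans_cluster()] result plus a species id).
#' @param path output path.
#' @param species species id when `labels` is a `tn_clustering`.
#' @export
write_labels_tsv <- function(labels, path, species = NULL) {
  if (inherits(labels, "tn_clustering")) {
    stopifnot(!is.null(species))
    labels <- data.frame(species = species, gene = names(labels$labels),
                         label = unname(labels$labels))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#species\tgene\tlabel", con)
  utils::write.table(labels[, c("species", "gene", "label")], con, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ortholog map (column `group` plus one gene column per species)
#' @param path TSV path.
#' @return Data frame.
#' @export
read_ortholog_map <- function(path) {
  df <- read_tsv_checked(path, "group", "ortholog map")
  if (ncol(df) < 2L) stop_tn(sprintf("%s: need at least one species column", path))
  if (anyDuplicated(df$group)) stop_tn(sprintf("%s: duplicate group ids", path))
  for (sp in setdiff(names(df), "group"))
    if (anyDuplicated(stats::na.omit(df[[sp]])))
      stop_tn(sprintf("%s: duplicate gene ids in species '%s'", path, sp))
  df
}

#' Serialize model parameters to a plain-text key/value file
#'
#' Round-trips with [read_params_file()].
#'
#' @param params a [tn_params()].
#' @param path output path.
#' @export
write_params_file <- function(params, path) {
  stopifnot(inherits(params, "tn_params"))
  lines <- c(
    sprintf("lam: %.17g", params$rates$lam),
    sprintf("mu: %.17g", params$rates$mu),
    sprintf("pi_root: %.17g", params$rates$pi_root),
    sprintf("q: %.17g", params$seq$q),
    sprintf("threshold: %s",
            if (is.null(params$seq$threshold)) "auto"
            else sprintf("%.17g", params$seq$threshold)),
    sprintf("threshold_frac: %.17g", params$seq$threshold_frac),
    sprintf("weight: %.17g", params$weight))
  for (sp in names(params$expr$theta0)) {
    lines <- c(lines,
               sprintf("theta0.%s: %s", sp,
                       paste(sprintf("%.17g", params$expr$theta0[[sp]]), collapse = ",")),
               sprintf("theta1.%s: %s", sp,
                       paste(sprintf("%.17g", params$expr$theta1[[sp]]), collapse = ",")))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_params_file
#' @return `read_params_file()` returns the reconstructed [tn_params()].
#' @export
read_params_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, "", 1L)
  vals <- vapply(kv, function(x) paste(x[-1L], collapse = ":"), "")
  get1 <- function(k) as.numeric(vals[keys == k][1L])
  thr <- vals[keys == "threshold"][1L]
  theta0 <- theta1 <- list()
  for (i in which(startsWith(keys, "theta0."))) {
    theta0[[sub("^theta0\\.", "", keys[i])]] <-
      as.numeric(strsplit(vals[i], ",")[[1L]])
  }
  for (i in which(startsWith(keys, "theta1."))) {
    theta1[[sub("^theta1\\.", "", keys[i])]] <-
      as.numeric(strsplit(vals[i], ",")[[1L]])
  }
  tn_params(
    tn_rates(get1("lam"), get1("mu"), get1("pi_root")),
    tn_seq_params(q = get1("q"),
                  threshold = if (identical(thr, "auto")) NULL else as.numeric(thr),
                  threshold_frac = get1("threshold_frac")),
    tn_expr_params(theta0, theta1),
    weight = get1("weight"))
}

#' Write an EM log-likelihood trace as CSV
#' @param fit a [tn_fit()].
#' @param path output path.
#' @export
write_trace_csv <- function(fit, path) {
  utils::write.csv(data.frame(iteration = seq_along(fit$trace),
                              loglik = fit$trace),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a run-configuration file (plain-text `key: value` lines)
#'
#' Recognized keys: `tree`, `fasta`, `pssm`, `labels`, `ortholog_map`,
#' `expression.<species>`, `out_dir`, `weight`, `threshold`, `window_size`,
#' `step`, `smoothing`, `max_iter`, `tol`, `seed`. Numeric values are
#' converted; everything else stays character. Input checksums (md5) are
#' attached for provenance.
#'
#' @param path config file path.
#' @param check_paths validate that referenced files exist (default TRUE).
#' @return A named list of class `tn_config`.
#' @export
read_run_config <- function(path, check_paths = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop_tn(sprintf("%s: malformed line %d", path, which(bad)[1L]))
  cfg <- stats::setNames(lapply(kv, function(x) {
    v <- trimws(x[[3L]])
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  }), vapply(kv, function(x) trimws(x[[2L]]), ""))
  path_keys <- intersect(c("tree", "fasta", "pssm", "labels", "ortholog_map"),
                         names(cfg))
  path_keys <- c(path_keys, grep("^expression\\.", names(cfg), value = TRUE))
  if (check_paths) {
    for (k in path_keys) {
      if (!file.exists(cfg[[k]]))
        stop_tn(sprintf("%s: file for '%s' not found: %s", path, k, cfg[[k]]))
    }
    cfg$checksums <- tools::md5sum(unlist(cfg[path_keys]))
  }
  class(cfg) <- "tn_config"
  cfg
}

#' Load and cross-validate all pipeline inputs from a run config
#'
#' Reads the tree, PSSM, FASTA sequences, labels and ortholog map, then
#' assembles complete ortholog groups; groups missing a sequence or a
#' label in any species are dropped with a logged count.
#'
#' @param config a [read_run_config()] result or a path to a config file.
#' @return List with `tree`, `pssm`, `data` (a `tn_data`), `config`.
#' @export
read_inputs <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "tn_config"))
  for (k in c("tree", "fasta", "pssm", "labels", "ortholog_map"))
    if (is.null(config[[k]]))
      stop_tn(sprintf("run config is missing required key '%s'", k))
  tree <- tn_tree(config$tree)
  pssm <- read_pssm(config$pssm)
  seqs <- read_fasta_sequences(config$fasta)
  labels <- read_labels_tsv(config$labels)
  om <- read_ortholog_map(config$ortholog_map)
  sp_cols <- sort(setdiff(names(om), "group"))
  if (!setequal(sp_cols, tree$species))
    stop_tn("ortholog-map species columns must match the tree's leaves")
  params <- tn_seq_params(
    q = config$q %||% 0.005,
    threshold = config$threshold,
    threshold_frac = config$threshold_frac %||% 0.6)
  data <- prepare_tn_data(seqs, labels, om, pssm, params,
                          window_size = as.integer(config$window_size %||% 500),
                          step = as.integer(config$step %||% 250))
  list(tree = tree, pssm = pssm, data = data, config = config)
}
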