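# Shared I/O (FASTA via Biostrings, TSV interchange, YAML config) and the
# end-to-end pipeline tying the stages together.

#' Read coding sequences from FASTA
#'
#' Sequences are normalized to uppercase DNA (RNA input accepted) and
#' validated as in-frame coding sequences.
#'
#' @param path path to a (multi-)FASTA file.
#' @return named list of `coding_sequence` objects.
#' @export
read_cds_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(grepl("[Uu]", seqs) | grepl("[a-z]", seqs)))
    message("note: RNA and/or lowercase input normalized to uppercase DNA")
  out <- mapply(coding_sequence, ids, seqs, SIMPLIFY = FALSE)
  names(out) <- ids
  out
}

#' Write coding sequences to FASTA
#'
#' @param genes a `coding_sequence` or list of them.
#' @param path output path.
#' @param width line-wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genes, path, width = 60L) {
  if (inherits(genes, "coding_sequence")) genes <- list(genes)
  set <- Biostrings::DNAStringSet(vapply(genes, `[[`, "", "seq"))
  names(set) <- vapply(genes, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read / write tab-separated tables
#'
#' The interchange dialect for all tabular inputs and outputs: tab
#' separator, header row, '.' decimal mark, no quoting, stable column order.
#'
#' @param path file path.
#' @return `read_tsv`: a data.frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' @rdname read_tsv
#' @param x data.frame to write.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file of key-value pairs (see [run_pipeline()]).
#' @return named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  yaml::read_yaml(path)
}

.log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes design -> sequence features -> competition fitness ->
#' decomposition -> correlations and returns (and optionally writes) a
#' merged per-allele table: substitution count N, log relative adaptiveness
#' and translation-time increase of the substitution (N-weighted means for
#' multi-amino-acid designs), folding free-energy change, anti-SD hexamer
#' counts, total and per-codon selective disadvantage.
#'
#' @param config named list (or path to a YAML file) with entries:
#'   `parent_fasta` (wild-type CDS), `reference_fasta` (highly expressed
#'   gene set), `designs` (data.frame or TSV path: `allele`, `amino_acid`,
#'   `target`, optional `source`, optional `region` in
#'   full/first_half/second_half), `trajectories` (data.frame or TSV path),
#'   optional `trna_table` (TSV path; default: bundled synthetic fixture),
#'   optional `ddg` (TSV path), and optional scalars `control` ("tufA"),
#'   `prefix` (40), `window` (0.008), `thresholds` (c(-4, -6)),
#'   `exclude_first` (40), `out_dir`.
#' @return a `pipeline_report`: list with `table` (the merged data.frame),
#'   `adaptiveness`, `fitness`, `correlations`, `alleles`. Written to
#'   `out_dir` (merged.tsv, report.txt) when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  need <- c("parent_fasta", "reference_fasta", "designs", "trajectories")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L)
    stop("pipeline config missing: ", paste(miss, collapse = ", "))
  prefix <- config$prefix %||% 40L
  window <- config$window %||% 0.008
  control <- config$control %||% "tufA"
  thresholds <- config$thresholds %||% c(-4, -6)
  exclude_first <- config$exclude_first %||% 40L

  .log_stage("io", "reading inputs")
  parent <- read_cds_fasta(config$parent_fasta)[[1L]]
  refs <- read_cds_fasta(config$reference_fasta)
  designs <- if (is.character(config$designs)) read_tsv(config$designs) else config$designs
  stopifnot(all(c("allele", "amino_acid", "target") %in% names(designs)))
  traj <- if (is.character(config$trajectories)) read_tsv(config$trajectories) else config$trajectories
  trna <- if (!is.null(config$trna_table)) read_trna_table(config$trna_table)
          else example_trna_table()
  ddg <- if (!is.null(config$ddg)) load_ddg(config$ddg) else NULL

  .log_stage("codon_usage", "relative adaptiveness from ", length(refs), " genes")
  wa_tbl <- relative_adaptiveness(refs, exclude_first = exclude_first)

  .log_stage("design", nrow(designs), " allele design rows")
  model <- hexamer_affinity_model()
  per_allele <- lapply(split(designs, designs$allele), function(d) {
    aa <- aa_one_letter(d$amino_acid)
    repl <- stats::setNames(as.character(d$target), aa)
    src <- NULL
    if ("source" %in% names(d) && any(nzchar(d$source) & !is.na(d$source))) {
      keep <- nzchar(d$source) & !is.na(d$source)
      src <- stats::setNames(as.character(d$source[keep]), aa[keep])
    }
    region <- if ("region" %in% names(d)) d$region[1L] else "full"
    spec <- design_spec(repl, source_filter = src, region = region,
                        protected_prefix = prefix)
    allele <- design_allele(parent, spec)
    subs <- allele$substitutions
    # N-weighted feature summaries over the substitution types present
    lw <- if (nrow(subs) > 0L) mean(log_wa(wa_tbl, subs$to)) else 0
    dt <- if (nrow(subs) > 0L)
      mean(mapply(function(a, b) delta_t_trans(trna, a, b)$delta_t,
                  subs$to, subs$from)) else 0
    scan <- scan_anti_sd(allele$seq, model, thresholds)
    list(allele = allele, log_wa = lw, delta_t = dt, scan = scan)
  })

  .log_stage("fitness", "competition chain (control = ", control, ")")
  fit <- fit_competition(traj, control = control, window = window)

  alleles <- names(per_allele)
  tab <- data.frame(
    allele = alleles,
    N = vapply(per_allele, function(p) p$allele$N, 0L),
    log_wa = vapply(per_allele, `[[`, 0, "log_wa"),
    delta_t = vapply(per_allele, `[[`, 0, "delta_t"),
    ddg = if (is.null(ddg)) NA_real_ else ddg$ddg[match(alleles, ddg$allele)],
    hex_m4 = vapply(per_allele, function(p) unname(p$scan$counts[1L]), 0L),
    hex_m6 = vapply(per_allele, function(p) unname(p$scan$counts[2L]), 0L),
    stringsAsFactors = FALSE, row.names = NULL)
  fi <- match(tab$allele, fit$allele)
  tab$total_s <- fit$disadvantage[fi]
  tab$ci_low <- fit$ci_low[fi]
  tab$ci_high <- fit$ci_high[fi]
  tab$p_value <- fit$p_value[fi]
  tab$per_codon_s <- NA_real_
  ok <- tab$N > 0 & !is.na(tab$total_s)
  # a slightly negative measured total maps to a zero cost, not an error
  tab$per_codon_s[ok] <- per_codon_s(pmax(tab$total_s[ok], 0), tab$N[ok])

  .log_stage("decomposition", "correlations over ", nrow(tab), " alleles")
  corr <- list()
  ok <- !is.na(tab$per_codon_s) & tab$N > 0
  if (sum(ok) >= 3L) {
    corr$log_wa <- correlate(tab$log_wa[ok], tab$per_codon_s[ok])
    corr$delta_t <- correlate(tab$delta_t[ok], tab$per_codon_s[ok])
    if (!all(is.na(tab$ddg)))
      corr$ddg <- correlate(tab$ddg[ok], tab$total_s[ok])
    if (stats::var(tab$hex_m4[ok]) > 0)
      corr$hex_m4 <- correlate(as.numeric(tab$hex_m4[ok]), tab$total_s[ok])
  }

  report <- structure(list(table = tab, adaptiveness = wa_tbl, fitness = fit,
                           correlations = corr, alleles = per_allele),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(tab, file.path(config$out_dir, "merged.tsv"))
    writeLines(utils::capture.output(print(report)),
               file.path(config$out_dir, "report.txt"))
    .log_stage("io", "wrote ", config$out_dir)
  }
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("== codonfit pipeline report ==\n\n")
  print(format(x$table, digits = 4), row.names = FALSE)
  cat("\nCorrelations with per-codon cost:\n")
  for (nm in names(x$correlations)) {
    r <- x$correlations[[nm]]
    cat(sprintf("  %-8s slope = %.4g, r2 = %.3f, p = %.3g\n",
                nm, r$slope, r$r_squared, r$p_value))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
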