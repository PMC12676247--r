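# Summary proportions over pipeline outputs. Percentages are rounded
# half-up to 2 decimals, the convention that reproduces every
# count-consistent printed percentage in the source literature.

#' Percentage of a count pair, rounded half-up to 2 decimals
#'
#' @param numerator,denominator non-negative integers,
#'   `numerator <= denominator`, `denominator > 0`.
#' @return `100 * numerator / denominator`, rounded half-up to 2 decimals.
#' @export
proportion_pct <- function(numerator, denominator) {
  if (any(denominator <= 0)) stop("proportion_pct: denominator must be > 0")
  if (any(numerator < 0) || any(numerator > denominator)) {
    stop("proportion_pct: need 0 <= numerator <= denominator")
  }
  x <- 100 * numerator / denominator
  # round half-up (base round() is half-even); epsilon guards the
  # representation of exact halves after the division
  floor(x * 100 + 0.5 + 1e-9) / 100
}

.prop_row <- function(label, num, den) {
  data.frame(label = label, numerator = num, denominator = den,
             pct = proportion_pct(num, den), stringsAsFactors = FALSE)
}

#' Summary table over pipeline stage outputs
#'
#' Builds labelled proportion rows from whichever stage outputs are
#' supplied; missing stages are skipped with a warning. Partition rows
#' (e.g. the lifestyle split) share a denominator and their percentages
#' sum to it up to rounding.
#'
#' @param triage data.frame from [triage_genomes()], or NULL.
#' @param clusters data.frame from [greedy_species_clusters()] with
#'   novelty flags, or NULL.
#' @param codes data.frame from [call_genetic_codes()], or NULL.
#' @param host_map list from [assign_hosts()], or NULL (needs `n_phages`).
#' @param pairs data.frame from [classify_pairs()], or NULL.
#' @param cas data.frame of [cas_acquisition_status()] rows, or NULL.
#' @param n_phages total phage count (denominator for host assignment).
#' @return data.frame of rows: `label`, `numerator`, `denominator`, `pct`.
#' @export
build_summary <- function(triage = NULL, clusters = NULL, codes = NULL,
                          host_map = NULL, pairs = NULL, cas = NULL,
                          n_phages = NULL) {
  rows <- list()
  add <- function(r) rows[[length(rows) + 1L]] <<- r
  if (!is.null(triage)) {
    n <- nrow(triage)
    add(.prop_row("phage_fraction", sum(triage$is_phage), n))
    kept <- triage[!is.na(triage$lifestyle), , drop = FALSE]
    if (nrow(kept) > 0L) {
      for (ls in c("virulent", "uncertain", "temperate")) {
        add(.prop_row(paste0("lifestyle_", ls), sum(kept$lifestyle == ls),
                      nrow(kept)))
      }
    }
  } else warning("build_summary: triage output missing; rows omitted")
  if (!is.null(clusters)) {
    per <- clusters[!duplicated(clusters$cluster_id), , drop = FALSE]
    add(.prop_row("novel_cluster_fraction", sum(per$is_novel), nrow(per)))
    add(.prop_row("genomes_in_novel_clusters", sum(clusters$is_novel),
                  nrow(clusters)))
  } else warning("build_summary: cluster output missing; rows omitted")
  if (!is.null(codes)) {
    add(.prop_row("standard_code_fraction", sum(codes$called_code == 11L),
                  nrow(codes)))
    add(.prop_row("alt_code_fraction", sum(codes$called_code != 11L),
                  nrow(codes)))
  } else warning("build_summary: code calls missing; rows omitted")
  if (!is.null(host_map) && !is.null(n_phages)) {
    add(.prop_row("host_assigned_fraction", length(host_map), n_phages))
    if (length(host_map) > 0L) {
      cls <- classify_host_range(host_map)
      add(.prop_row("specialist_fraction", sum(cls == "specialist"),
                    length(cls)))
      add(.prop_row("generalist_fraction", sum(cls == "generalist"),
                    length(cls)))
    }
  } else warning("build_summary: host map missing; rows omitted")
  if (!is.null(pairs)) {
    n <- nrow(pairs)
    if (n > 0L) {
      add(.prop_row("single_directed_fraction",
                    sum(pairs$direction == "single_directed"), n))
      add(.prop_row("double_directed_fraction",
                    sum(pairs$direction == "double_directed"), n))
      add(.prop_row("same_host_pair_fraction", sum(pairs$same_host), n))
    }
  } else warning("build_summary: pair table missing; rows omitted")
  if (!is.null(cas)) {
    if (nrow(cas) > 0L) {
      add(.prop_row("acquisition_incomplete_fraction",
                    sum(!cas$acquisition_complete), nrow(cas)))
    }
  } else warning("build_summary: cas table missing; rows omitted")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Printed count pairs used by the acceptance report
#'
#' Reads the shipped table of headline numerator/denominator pairs.
#'
#' @return data.frame: `target_id`, `label`, `numerator`, `denominator`.
#' @export
printed_counts <- function() {
  path <- system.file("extdata", "printed_counts.tsv", package = "phagenet")
  utils::read.delim(path, stringsAsFactors = FALSE)
}
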