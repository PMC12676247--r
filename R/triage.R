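# Decision rules turning annotated contigs into a curated phage set with
# lifestyle calls: four-signature viral triage, hallmark-keyword phage
# identification, BUSCO/VPF false-positive filtering, size/completeness
# quality gates, and lifestyle assignment from a lysogeny score.

#' Virus hallmark keywords
#'
#' Case-insensitive substrings that mark a gene description as
#' virus-specific, and the prokaryote-specific exclusion terms.
#' @format character vectors.
#' @name keyword_sets
NULL

#' @rdname keyword_sets
#' @export
VIRAL_KEYWORDS <- c("capsid", "phage", "terminase", "base plate", "baseplate",
                    "prohead", "virion", "virus", "viral", "tape measure",
                    "tapemeasure", "neck", "tail", "head", "bacteriophage",
                    "prophage", "portal", "DNA packaging", "T4", "p22",
                    "holin")

#' @rdname keyword_sets
#' @export
PROK_KEYWORDS <- c("ribosomal protein", "preprotein translocase",
                   "DNA gyrase subunit A")

#' Strand switch rate of an ordered gene-call list
#'
#' The number of adjacent gene pairs on opposite strands divided by the gene
#' count. Compact viral genomes show low rates (run-length strand layout).
#'
#' @param calls data.frame of gene calls for one genome, sorted by `start`.
#' @return numeric in `[0, (n-1)/n]`.
#' @export
strand_switch_rate <- function(calls) {
  if (is.data.frame(calls)) {
    strands <- calls$strand
  } else {
    strands <- calls
  }
  n <- length(strands)
  if (n == 0L) stop("strand_switch_rate: no genes")
  if (n == 1L) return(0)
  sum(strands[-1] != strands[-n]) / n
}

#' Default thresholds for the four-signature viral call
#'
#' @param k minimum number of signature predicates that must hold.
#' @param min_viral_hits minimum viral-family hits for the "viral families
#'   present, microbial absent" predicate.
#' @param min_nt_score minimum nucleotide-classifier score.
#' @param max_switch_rate maximum strand switch rate (with at least
#'   `min_genes_for_switch` genes) for the genome-organisation predicate.
#' @param min_genes_for_switch see above.
#' @return a named list of thresholds.
#' @export
viral_signature_thresholds <- function(k = 2L, min_viral_hits = 1L,
                                       min_nt_score = 0.9,
                                       max_switch_rate = 0.25,
                                       min_genes_for_switch = 4L) {
  list(k = k, min_viral_hits = min_viral_hits, min_nt_score = min_nt_score,
       max_switch_rate = max_switch_rate,
       min_genes_for_switch = min_genes_for_switch)
}

#' Four-signature viral call
#'
#' Evaluates the four viral evidence predicates -- (1) viral protein
#' families present with no microbial families, (2) high nucleotide-
#' classifier score, (3) low strand switch rate over enough genes,
#' (4) viral hits outnumber microbial hits -- and calls a contig viral when
#' at least `k` of them hold. The combination rule is configurable because
#' no canonical combination is established for multi-evidence triage.
#'
#' @param signals list or one-row data.frame with fields `n_genes`,
#'   `viral_family_hits`, `microbial_family_hits`, `nucleotide_score`,
#'   `strand_switch_rate`. A missing/NA `nucleotide_score` counts as 0.
#' @param thresholds see [viral_signature_thresholds()].
#' @return logical scalar with attribute `reasons`, the predicates fired.
#' @export
viral_signature_call <- function(signals,
                                 thresholds = viral_signature_thresholds()) {
  ns <- signals$nucleotide_score
  if (is.null(ns) || is.na(ns)) ns <- 0
  preds <- c(
    viral_present_microbial_absent =
      signals$viral_family_hits >= thresholds$min_viral_hits &&
      signals$microbial_family_hits == 0L,
    nucleotide_signature = ns >= thresholds$min_nt_score,
    strand_layout =
      signals$strand_switch_rate <= thresholds$max_switch_rate &&
      signals$n_genes >= thresholds$min_genes_for_switch,
    viral_exceeds_microbial =
      signals$viral_family_hits > signals$microbial_family_hits)
  out <- sum(preds) >= thresholds$k
  attr(out, "reasons") <- names(preds)[preds]
  out
}

#' Hallmark-keyword phage call
#'
#' A genome is called a phage when (a) at least two genes carry a virus
#' hallmark keyword, (b) no gene carries a prokaryote-specific term, and
#' (c) the genome has at least one CRISPR spacer match from a prokaryote
#' spacer catalogue. Matching is case-insensitive substring over the whole
#' description, faithful to the listed terms (short terms such as "neck"
#' may over-match inside longer words).
#'
#' @param calls data.frame of gene calls with a `description` column.
#' @param has_spacer_match logical: any spacer match from a bacterial or
#'   archaeal genome.
#' @return logical scalar.
#' @export
keyword_phage_call <- function(calls, has_spacer_match) {
  desc <- tolower(calls$description)
  desc[is.na(desc)] <- ""
  hits_any <- function(keys) {
    m <- rep(FALSE, length(desc))
    for (k in tolower(keys)) m <- m | grepl(k, desc, fixed = TRUE)
    m
  }
  n_viral <- sum(hits_any(VIRAL_KEYWORDS))
  n_prok <- sum(hits_any(PROK_KEYWORDS))
  isTRUE(has_spacer_match) && n_viral >= 2L && n_prok == 0L
}

#' BUSCO/VPF false-positive filter
#'
#' Keeps a genome when its BUSCO ratio (bacterial universal single-copy
#' ortholog hits over gene count) is below 0.067, or when the ratio is at
#' or above 0.067 but at least three viral-protein-family (VPF) hits back
#' the viral call. A ratio of exactly 0.067 is routed to the VPF clause so
#' every genome is classifiable.
#'
#' @param n_genes gene count (> 0).
#' @param busco_hits genes hitting BUSCOs (`<= n_genes`).
#' @param vpf_hits genes hitting VPFs.
#' @param ratio_max BUSCO ratio threshold.
#' @param vpf_min minimum VPF hits for the rescue clause.
#' @return logical: keep the genome.
#' @export
false_positive_filter <- function(n_genes, busco_hits, vpf_hits,
                                  ratio_max = 0.067, vpf_min = 3L) {
  if (n_genes <= 0L) stop("false_positive_filter: n_genes must be > 0")
  stopifnot(busco_hits <= n_genes)
  ratio <- busco_hits / n_genes
  ratio < ratio_max || vpf_hits >= vpf_min
}

#' Size and completeness quality gates
#'
#' @param seq_len genome length (bp).
#' @param completeness estimated completeness percent, or `NA` (fails).
#' @param min_len minimum genome size (default 3 kb, inclusive).
#' @param min_completeness minimum completeness (default 50, inclusive).
#' @return logical: keep the genome.
#' @export
apply_quality_filters <- function(seq_len, completeness, min_len = 3000L,
                                  min_completeness = 50) {
  if (is.na(seq_len)) return(FALSE)
  if (is.null(completeness) || is.na(completeness)) return(FALSE)
  seq_len >= min_len && completeness >= min_completeness
}

#' Lifestyle assignment from a lysogeny score
#'
#' Scores below 0.5 are virulent, 0.5--0.9 uncertain, above 0.9 temperate.
#' A genome flagged as an integrated provirus is temperate regardless of
#' score (proviruses are direct evidence of lysogeny).
#'
#' @param score lysogeny score in `[0,1]`.
#' @param provirus logical provirus flag.
#' @return one of `"virulent"`, `"uncertain"`, `"temperate"`.
#' @export
lifestyle_assign <- function(score, provirus = FALSE) {
  if (isTRUE(provirus)) return("temperate")
  if (is.na(score) || score < 0 || score > 1) {
    stop("lifestyle score must lie in [0,1]")
  }
  if (score < 0.5) "virulent" else if (score <= 0.9) "uncertain" else "temperate"
}

#' Run the full triage over a genome collection
#'
#' Combines the four-signature viral call, the hallmark-keyword phage call,
#' the BUSCO/VPF false-positive filter and the quality gates, then assigns
#' lifestyles to genomes passing quality.
#'
#' @param genomes named character vector of sequences.
#' @param gene_calls data.frame of gene calls (all genomes).
#' @param metadata data.frame with per-genome `completeness`,
#'   `lifestyle_score`, `provirus`, `nucleotide_score`, `spacer_match`.
#' @param thresholds see [viral_signature_thresholds()].
#' @return data.frame with one decision row per genome: `genome_id`,
#'   `is_viral`, `is_phage`, `passes_fp_filter`, `passes_quality`,
#'   `lifestyle`, `reasons`.
#' @export
triage_genomes <- function(genomes, gene_calls, metadata,
                           thresholds = viral_signature_thresholds()) {
  ids <- names(genomes)
  meta <- metadata[match(ids, metadata$genome_id), , drop = FALSE]
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    calls <- gene_calls[gene_calls$genome_id == id, , drop = FALSE]
    calls <- calls[order(calls$start), , drop = FALSE]
    n_genes <- nrow(calls)
    ssr <- if (n_genes > 0L) strand_switch_rate(calls) else 1
    signals <- list(
      n_genes = n_genes,
      viral_family_hits = sum(calls$source_db == "viral_family"),
      microbial_family_hits = sum(calls$source_db == "microbial_family"),
      nucleotide_score = meta$nucleotide_score[i],
      strand_switch_rate = ssr)
    is_viral <- viral_signature_call(signals, thresholds)
    is_phage <- is_viral &&
      keyword_phage_call(calls, isTRUE(meta$spacer_match[i]))
    busco <- sum(calls$source_db == "busco")
    vpf <- sum(calls$source_db == "vpf")
    fp <- if (n_genes > 0L) false_positive_filter(n_genes, busco, vpf)
          else FALSE
    q <- apply_quality_filters(nchar(genomes[[i]]), meta$completeness[i])
    lifestyle <- NA_character_
    if (is_phage && fp && q) {
      lifestyle <- lifestyle_assign(meta$lifestyle_score[i],
                                    isTRUE(meta$provirus[i]))
    }
    data.frame(genome_id = id, is_viral = as.logical(is_viral),
               is_phage = is_phage, passes_fp_filter = fp,
               passes_quality = q, lifestyle = lifestyle,
               reasons = paste(attr(is_viral, "reasons"), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
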