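# Alternative genetic-code detection. Stop-codon reassignment (TAG->Q,
# TAA->Q, TGA->G in recoded phage lineages) shows up as a jump in protein-
# coding density when ORFs are called with the reduced stop set; the
# decision rule contrasts coding density under the four candidate codes.

# code id -> stop-codon set
GENETIC_CODE_STOPS <- list(`11` = c("TAA", "TAG", "TGA"),
                           `15` = c("TAA", "TGA"),   # TAG recoded
                           `90` = c("TAG", "TGA"),   # TAA recoded
                           `91` = c("TAA", "TAG"))   # TGA recoded

START_CODONS <- c("ATG", "GTG", "TTG")

# ORFs in the three forward frames of s (no strand mapping). Codon-level
# scan: within each stop-to-stop region the ORF runs from the first start
# codon to the closing stop (inclusive), or to the sequence end (run-off).
.orfs_forward <- function(s, stop_set, min_len) {
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    ncod <- (n - f) %/% 3L
    if (ncod < 1L) next
    cstart <- f + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, cstart, cstart + 2L)
    stops <- which(codons %in% stop_set)
    starts <- which(codons %in% START_CODONS)
    if (length(starts) == 0L) next
    bounds <- c(0L, stops)                      # region r: (bounds[r], ends[r]]
    ends <- c(stops, ncod)                      # last region runs off
    reg <- findInterval(starts, bounds)         # region of each start codon
    # a start sitting on a stop codon is impossible (disjoint sets)
    first_start <- tapply(starts, reg, min)
    r_idx <- as.integer(names(first_start))
    orf_s <- as.integer(first_start)
    orf_e <- ends[r_idx]
    keep <- orf_e >= orf_s
    orf_s <- orf_s[keep]; orf_e <- orf_e[keep]
    if (length(orf_s) == 0L) next
    nt_s <- f + 1L + 3L * (orf_s - 1L)
    nt_e <- f + 3L * orf_e
    len <- nt_e - nt_s + 1L
    ok <- len >= min_len
    if (any(ok)) {
      out[[length(out) + 1L]] <- data.frame(start = nt_s[ok], end = nt_e[ok],
                                            frame = f, stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      frame = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Find open reading frames under a stop-codon set
#'
#' Scans all six frames. In each frame, an ORF runs from the first start
#' codon (ATG/GTG/TTG) after the previous stop to the next in-frame stop
#' (inclusive), or to the sequence end (run-off ORFs are reported). All
#' maximal ORFs of at least `min_len` nt are returned without overlap
#' resolution. This is a deliberately simple stand-in for a trained gene
#' caller: only stop-set membership matters for the density contrast.
#'
#' @param seq DNA string.
#' @param stop_set non-empty subset of `{TAA, TAG, TGA}`.
#' @param min_len minimum ORF length in nt (stop codon included).
#' @return data.frame: `start`, `end` (1-based, forward-strand), `strand`.
#' @export
find_orfs <- function(seq, stop_set = GENETIC_CODE_STOPS[["11"]],
                      min_len = 90L) {
  if (length(stop_set) == 0L) stop("find_orfs: empty stop set")
  if (!all(stop_set %in% c("TAA", "TAG", "TGA"))) {
    stop("find_orfs: stop_set must be a subset of {TAA, TAG, TGA}")
  }
  seq <- unname(seq[[1]])
  n <- nchar(seq)
  fw <- .orfs_forward(seq, stop_set, min_len)
  fw$strand <- rep("+", nrow(fw))
  rv <- .orfs_forward(revcomp(seq), stop_set, min_len)
  if (nrow(rv) > 0L) {
    s <- n - rv$end + 1L
    e <- n - rv$start + 1L
    rv$start <- s; rv$end <- e
  }
  rv$strand <- rep("-", nrow(rv))
  out <- rbind(fw, rv)
  out$frame <- NULL
  out[order(out$start, out$end, out$strand), , drop = FALSE]
}

#' Protein-coding density
#'
#' Fraction of the genome covered by the union of ORF intervals (both
#' strands projected onto genome coordinates). Union coverage, not summed
#' gene length: bounded by 1 and monotone under stop-set reduction.
#'
#' @param seq_len genome length (bp), or a sequence string.
#' @param orfs data.frame with `start`, `end` columns.
#' @return density in `[0,1]`.
#' @export
coding_density <- function(seq_len, orfs) {
  if (is.character(seq_len)) seq_len <- nchar(unname(seq_len[[1]]))
  if (nrow(orfs) == 0L) return(0)
  if (any(orfs$start < 1L) || any(orfs$end > seq_len)) {
    stop("coding_density: ORF interval outside sequence")
  }
  interval_union_length(orfs$start, orfs$end) / seq_len
}

#' Call the genetic code of a genome
#'
#' Computes coding density under the standard code (11) and the three
#' stop-reassignment codes (15: TAG recoded; 90: TAA recoded; 91: TGA
#' recoded). The relative density gain of each alternative over code 11,
#' `(d_alt - d11)/d11`, is compared against a genome-size-dependent
#' threshold: >10% for genomes under 100 kb, >5% at or above 100 kb. The
#' best gaining code above threshold is called (ties broken in order
#' 15, 90, 91); otherwise the standard code stands.
#'
#' @param seq DNA string (optionally named; the name becomes `genome_id`).
#' @param genome_id optional id.
#' @param min_orf minimum ORF length (nt).
#' @param size_threshold genome size (bp) switching the gain threshold.
#' @param gain_small,gain_large relative-gain thresholds below/at-or-above
#'   `size_threshold`.
#' @param gain_mode `"relative"` (default; gains are fractions of d11) or
#'   `"absolute"` (gains are density differences in absolute points).
#' @return one-row data.frame: `genome_id`, `d11`, `d15`, `d90`, `d91`,
#'   `called_code`, `gain`.
#' @export
call_genetic_code <- function(seq, genome_id = NA_character_, min_orf = 90L,
                              size_threshold = 1e5, gain_small = 0.10,
                              gain_large = 0.05,
                              gain_mode = c("relative", "absolute")) {
  gain_mode <- match.arg(gain_mode)
  if (!is.null(names(seq)) && is.na(genome_id)) genome_id <- names(seq)[1]
  seq <- unname(seq[[1]])
  n <- nchar(seq)
  if (n < 300L) stop("call_genetic_code: genome shorter than 300 nt")
  dens <- vapply(names(GENETIC_CODE_STOPS), function(code) {
    coding_density(n, find_orfs(seq, GENETIC_CODE_STOPS[[code]], min_orf))
  }, numeric(1))
  d11 <- dens[["11"]]
  alt <- c("15", "90", "91")
  gains <- if (gain_mode == "relative") {
    if (d11 == 0) ifelse(dens[alt] > 0, Inf, 0) else (dens[alt] - d11) / d11
  } else {
    dens[alt] - d11
  }
  thr <- if (n < size_threshold) gain_small else gain_large
  above <- which(gains > thr)
  if (length(above) == 0L) {
    called <- 11L
    gain <- 0
  } else {
    # argmax gain; ties resolved by the fixed order 15, 90, 91
    best <- above[which.max(gains[above])]
    called <- as.integer(alt[best])
    gain <- unname(gains[best])
  }
  data.frame(genome_id = genome_id, d11 = d11, d15 = dens[["15"]],
             d90 = dens[["90"]], d91 = dens[["91"]], called_code = called,
             gain = gain, stringsAsFactors = FALSE)
}

#' Call genetic codes for a genome collection
#'
#' @param genomes named character vector.
#' @param ... passed to [call_genetic_code()].
#' @return data.frame with one row per genome.
#' @export
call_genetic_codes <- function(genomes, ...) {
  out <- do.call(rbind, lapply(names(genomes), function(id) {
    call_genetic_code(genomes[[id]], genome_id = id, ...)
  }))
  rownames(out) <- NULL
  out
}
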