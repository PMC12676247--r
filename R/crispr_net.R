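# CRISPR array detection, mismatch-bounded spacer matching, phage-host
# assignment and host-range classes, phage-phage targeting networks, and
# the Cas acquisition-module completeness rule.

#' Detect CRISPR arrays
#'
#' Finds maximal runs of at least `min_repeats` exact copies of a repeat
#' (length within `repeat_len`) separated by unique spacers (length within
#' `spacer_len`). Candidate repeats are seeded from recurring 23-mers,
#' extended in both directions while all copies agree, and overlapping
#' candidates are resolved by most repeat copies, then leftmost start.
#' Repeat copies must be exact (the simplification over degenerate-repeat
#' detectors is a documented limitation).
#'
#' @param genome sequence string (optionally named; name becomes the id).
#' @param genome_id optional id.
#' @param min_repeats minimum repeat copies (default 3).
#' @param repeat_len length-2 repeat-length bounds (default 23-47 nt).
#' @param spacer_len length-2 spacer-length bounds (default 26-50 nt).
#' @return list of arrays; each is a list with `genome_id`, `repeat_seq`,
#'   `repeat_len`, `positions` (repeat starts), and `spacers`, a data.frame
#'   `spacer_id`, `start`, `end`, `seq`.
#' @export
detect_crispr_arrays <- function(genome, genome_id = NA_character_,
                                 min_repeats = 3L, repeat_len = c(23L, 47L),
                                 spacer_len = c(26L, 50L)) {
  if (!is.null(names(genome)) && is.na(genome_id)) genome_id <- names(genome)[1]
  g <- unname(genome[[1]])
  n <- nchar(g)
  k <- repeat_len[1]
  if (n < 2L * k + spacer_len[1]) return(list())
  kmers <- substring(g, 1:(n - k + 1L), k:n)
  tab <- table(kmers)
  seeds <- names(tab)[tab >= min_repeats]
  seeds <- seeds[!grepl("N", seeds, fixed = TRUE)]
  if (length(seeds) == 0L) return(list())
  gap_min <- repeat_len[1] + spacer_len[1]
  gap_max <- repeat_len[2] + spacer_len[2]
  cands <- list()
  for (s in seeds) {
    pos <- which(kmers == s)
    # break the position list into runs with plausible array spacing
    grp <- cumsum(c(TRUE, diff(pos) < gap_min | diff(pos) > gap_max))
    for (run in split(pos, grp)) {
      if (length(run) < min_repeats) next
      # extend the repeat left/right while all copies agree
      left <- 0L
      while (run[1] - left - 1L >= 1L &&
             k + left + 1L <= repeat_len[2] &&
             length(unique(substring(g, run - left - 1L,
                                     run - left - 1L))) == 1L) {
        left <- left + 1L
      }
      right <- 0L
      while (run[length(run)] + k + right <= n &&
             k + left + right + 1L <= repeat_len[2] &&
             min(diff(run)) - (k + left + right + 1L) >= spacer_len[1] &&
             length(unique(substring(g, run + k + right,
                                     run + k + right))) == 1L) {
        right <- right + 1L
      }
      rstart <- run - left
      rlen <- k + left + right
      sp_start <- rstart[-length(rstart)] + rlen
      sp_end <- rstart[-1] - 1L
      sp_len <- sp_end - sp_start + 1L
      if (any(sp_len < spacer_len[1] | sp_len > spacer_len[2])) next
      sp_seq <- substring(g, sp_start, sp_end)
      if (anyDuplicated(sp_seq)) next
      cands[[length(cands) + 1L]] <-
        list(genome_id = genome_id,
             repeat_seq = substr(g, rstart[1], rstart[1] + rlen - 1L),
             repeat_len = rlen, positions = rstart,
             spacers = data.frame(start = sp_start, end = sp_end,
                                  seq = sp_seq, stringsAsFactors = FALSE))
    }
  }
  if (length(cands) == 0L) return(list())
  # resolve overlapping candidates: most repeats, then leftmost
  span <- t(vapply(cands, function(a) {
    c(a$positions[1], a$positions[length(a$positions)] + a$repeat_len - 1L,
      length(a$positions))
  }, numeric(3)))
  ord <- order(-span[, 3], span[, 1])
  chosen <- integer(0)
  for (i in ord) {
    clash <- any(vapply(chosen, function(j) {
      span[i, 1] <= span[j, 2] && span[i, 2] >= span[j, 1]
    }, logical(1)))
    if (!clash) chosen <- c(chosen, i)
  }
  chosen <- chosen[order(span[chosen, 1])]
  out <- cands[chosen]
  for (i in seq_along(out)) {
    out[[i]]$spacers <- cbind(
      spacer_id = sprintf("%s_arr%d_sp%d", genome_id, i,
                          seq_len(nrow(out[[i]]$spacers))),
      out[[i]]$spacers, stringsAsFactors = FALSE)
  }
  out
}

#' Match a spacer against a genome with bounded mismatches
#'
#' Reports every position on either strand where the full-length, ungapped
#' spacer aligns with at most `max_mm` mismatches (100% alignment length,
#' no gaps). `N` matches nothing on either side. Coordinates are 1-based on
#' the forward strand. The exhaustive bounded-mismatch scan replaces a
#' heuristic aligner: the acceptance rule is exactly computable.
#'
#' @param spacer spacer sequence (string).
#' @param genome target sequence (string, optionally named).
#' @param max_mm maximum mismatches (default 1).
#' @return data.frame: `start`, `end`, `strand`, `mismatches`.
#' @export
match_spacer <- function(spacer, genome, max_mm = 1L) {
  spacer <- unname(spacer[[1]]); g <- unname(genome[[1]])
  m <- nchar(spacer); n <- nchar(g)
  if (m > n) stop("match_spacer: spacer longer than genome")
  sp <- .encode_dna(spacer, -1L)
  scan <- function(gv) {
    nw <- n - m + 1L
    mm <- integer(nw)
    for (j in seq_len(m)) mm <- mm + (gv[j:(j + nw - 1L)] != sp[j])
    mm
  }
  gf <- .encode_dna(g, -2L)
  gr <- .encode_dna(revcomp(g), -2L)
  mmf <- scan(gf)
  mmr <- scan(gr)
  fw <- which(mmf <= max_mm)
  rv <- which(mmr <= max_mm)
  out <- rbind(
    if (length(fw) > 0L) data.frame(start = fw, end = fw + m - 1L,
                                    strand = "+", mismatches = mmf[fw],
                                    stringsAsFactors = FALSE),
    if (length(rv) > 0L) data.frame(start = n - (rv + m - 1L) + 1L,
                                    end = n - rv + 1L, strand = "-",
                                    mismatches = mmr[rv],
                                    stringsAsFactors = FALSE))
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE)
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Match host spacers against phage genomes
#'
#' Runs [match_spacer()] for every spacer of every (host) array against
#' every phage genome, excluding a genome's own spacers.
#'
#' @param arrays list of arrays from [detect_crispr_arrays()] (any owner).
#' @param genomes named character vector of target genomes.
#' @param max_mm mismatch bound.
#' @param exclude_self drop matches where the spacer owner is the target.
#' @return data.frame of interaction edges: `source`, `target`,
#'   `spacer_id`, `mismatches`, `target_start`, `target_strand`.
#' @export
match_all_spacers <- function(arrays, genomes, max_mm = 1L,
                              exclude_self = TRUE) {
  rows <- list()
  for (arr in arrays) {
    for (si in seq_len(nrow(arr$spacers))) {
      sp <- arr$spacers$seq[si]
      for (tid in names(genomes)) {
        if (exclude_self && identical(tid, arr$genome_id)) next
        if (nchar(sp) > nchar(genomes[[tid]])) next
        hits <- match_spacer(sp, genomes[[tid]], max_mm)
        if (nrow(hits) == 0L) next
        rows[[length(rows) + 1L]] <- data.frame(
          source = arr$genome_id, target = tid,
          spacer_id = arr$spacers$spacer_id[si], mismatches = hits$mismatches,
          target_start = hits$start, target_end = hits$end,
          target_strand = hits$strand, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(source = character(0), target = character(0),
                      spacer_id = character(0), mismatches = integer(0),
                      target_start = integer(0), target_end = integer(0),
                      target_strand = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign hosts to phages from spacer-match edges
#'
#' A phage's host set is the distinct genus set of every host whose
#' spacers match it; unmatched phages are absent from the map.
#'
#' @param edges data.frame with `source` (host) and `target` (phage).
#' @param host_taxa named genus vector over host genome ids.
#' @return named list: phage id -> character vector of host genera.
#' @export
assign_hosts <- function(edges, host_taxa) {
  if (nrow(edges) == 0L) return(stats::setNames(list(), character(0)))
  miss <- setdiff(unique(edges$source), names(host_taxa))
  miss <- c(miss, unique(edges$source[is.na(host_taxa[edges$source])]))
  if (length(miss) > 0L) {
    stop("missing genus for matched host(s): ",
         paste(unique(miss), collapse = ", "))
  }
  lapply(split(host_taxa[edges$source], edges$target),
         function(g) sort(unique(unname(g))))
}

#' Specialist/generalist host-range classes
#'
#' @param host_map named list from [assign_hosts()].
#' @return named character vector: `"specialist"` (exactly one host genus)
#'   or `"generalist"` (two or more).
#' @export
classify_host_range <- function(host_map) {
  if (any(vapply(host_map, length, integer(1)) == 0L)) {
    stop("classify_host_range: empty genus set")
  }
  vapply(host_map, function(g) {
    if (length(g) == 1L) "specialist" else "generalist"
  }, character(1))
}

#' Build the phage-phage targeting network
#'
#' A directed edge A -> B is drawn for each spacer of phage A matching
#' phage B, excluding self-matches and matches whose target interval
#' overlaps any detected CRISPR array in B: a hit inside B's own array is
#' shared spacer content (shared immunity), not targeting. Multi-edges are
#' collapsed to one edge with a match count.
#'
#' @param phage_arrays arrays detected on the phage genomes.
#' @param phage_genomes named character vector.
#' @param max_mm mismatch bound.
#' @param exclude_array_hits set `FALSE` to keep spacer-vs-spacer hits.
#' @return list with `edges` (collapsed: `source`, `target`, `n_matches`)
#'   and `matches` (per-spacer rows as in [match_all_spacers()]).
#' @export
build_phage_network <- function(phage_arrays, phage_genomes, max_mm = 1L,
                                exclude_array_hits = TRUE) {
  hits <- match_all_spacers(phage_arrays, phage_genomes, max_mm,
                            exclude_self = TRUE)
  if (exclude_array_hits && nrow(hits) > 0L) {
    iv <- lapply(phage_arrays, function(a) {
      c(a$positions[1],
        a$positions[length(a$positions)] + a$repeat_len - 1L)
    })
    owner <- vapply(phage_arrays, `[[`, character(1), "genome_id")
    keep <- vapply(seq_len(nrow(hits)), function(r) {
      tiv <- iv[owner == hits$target[r]]
      !any(vapply(tiv, function(v) {
        hits$target_start[r] <= v[2] && hits$target_end[r] >= v[1]
      }, logical(1)))
    }, logical(1))
    hits <- hits[keep, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(list(edges = data.frame(source = character(0),
                                   target = character(0),
                                   n_matches = integer(0),
                                   stringsAsFactors = FALSE),
                matches = hits))
  }
  key <- paste(hits$source, hits$target, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  edges <- data.frame(source = vapply(parts, `[`, character(1), 1),
                      target = vapply(parts, `[`, character(1), 2),
                      n_matches = as.integer(tab), stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  list(edges = edges, matches = hits)
}

#' Classify targeted phage pairs
#'
#' Each unordered pair with at least one directed edge is labelled
#' `single_directed` (one direction only) or `double_directed` (reciprocal
#' targeting). `same_host` is true when both phages appear in the host map
#' and their genus sets intersect.
#'
#' @param edges collapsed edge table from [build_phage_network()].
#' @param host_map named list from [assign_hosts()].
#' @return data.frame: `phage_a`, `phage_b` (sorted within pair),
#'   `direction`, `same_host`.
#' @export
classify_pairs <- function(edges, host_map = list()) {
  if (nrow(edges) == 0L) {
    return(data.frame(phage_a = character(0), phage_b = character(0),
                      direction = character(0), same_host = logical(0),
                      stringsAsFactors = FALSE))
  }
  a <- pmin(edges$source, edges$target)
  b <- pmax(edges$source, edges$target)
  key <- paste(a, b, sep = "\r")
  dir_count <- table(key)
  parts <- strsplit(names(dir_count), "\r", fixed = TRUE)
  pa <- vapply(parts, `[`, character(1), 1)
  pb <- vapply(parts, `[`, character(1), 2)
  same <- vapply(seq_along(pa), function(i) {
    ha <- host_map[[pa[i]]]; hb <- host_map[[pb[i]]]
    !is.null(ha) && !is.null(hb) && length(intersect(ha, hb)) > 0L
  }, logical(1))
  out <- data.frame(
    phage_a = pa, phage_b = pb,
    direction = ifelse(as.integer(dir_count) >= 2L, "double_directed",
                       "single_directed"),
    same_host = same, stringsAsFactors = FALSE)
  out[order(out$phage_a, out$phage_b), , drop = FALSE]
}

#' Cas acquisition-module completeness
#'
#' The spacer-acquisition module is complete when the system encodes both
#' Cas1 and Cas2 (case-insensitive gene names). Cas4 presence is recorded
#' but not required: several complete acquisition modules lack Cas4.
#'
#' @param subtype system subtype label (e.g. "I-C").
#' @param genes character vector of cas gene names.
#' @param genome_id owning genome.
#' @return one-row data.frame: `genome_id`, `subtype`, `genes`,
#'   `has_cas4`, `acquisition_complete`.
#' @export
cas_acquisition_status <- function(subtype, genes, genome_id = NA_character_) {
  if (is.na(subtype) || !nzchar(subtype)) {
    stop("cas_acquisition_status: subtype must be non-empty")
  }
  gl <- tolower(genes)
  data.frame(genome_id = genome_id, subtype = subtype,
             genes = paste(genes, collapse = ";"),
             has_cas4 = "cas4" %in% gl,
             acquisition_complete = all(c("cas1", "cas2") %in% gl),
             stringsAsFactors = FALSE)
}
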