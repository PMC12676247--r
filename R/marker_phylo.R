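# Core-marker selection, alignment trimming, genome inclusion, an
# iterative driver that sweeps up genomes missed by earlier marker sets,
# neighbor-joining trees and patristic distances. Maximum-likelihood
# inference is out of scope; NJ on concatenated-marker p-distances keeps
# the same distance semantics at desk scale.

GAP_CHARS <- c("-", ".")

#' Summarise marker profiles over a genome set
#'
#' @param families data.frame with columns `genome_id`, `profile_id`,
#'   `copy_count`, `mean_protein_len`.
#' @param genome_ids the genome universe (prevalence denominator).
#' @return data.frame: `profile_id`, `prevalence`, `mean_copy`, `mean_len`.
#' @export
marker_profiles <- function(families, genome_ids) {
  if (length(genome_ids) == 0L) stop("marker_profiles: empty genome set")
  fam <- families[families$genome_id %in% genome_ids &
                    families$copy_count >= 1L, , drop = FALSE]
  if (nrow(fam) == 0L) {
    return(data.frame(profile_id = character(0), prevalence = numeric(0),
                      mean_copy = numeric(0), mean_len = numeric(0),
                      stringsAsFactors = FALSE))
  }
  sp <- split(fam, fam$profile_id)
  out <- do.call(rbind, lapply(sp, function(x) {
    data.frame(profile_id = x$profile_id[1],
               prevalence = length(unique(x$genome_id)) / length(genome_ids),
               # averaged over genomes containing the profile (>=1 copy)
               mean_copy = mean(x$copy_count),
               mean_len = mean(x$mean_protein_len),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Select core marker profiles
#'
#' Core profiles are present in at least `prev_min` of the genomes, carry
#' an average copy number at most `copy_max` (near single copy) and an
#' average protein length above `len_min` residues.
#'
#' @param profiles data.frame from [marker_profiles()].
#' @param prev_min minimum prevalence (default 0.10, inclusive).
#' @param copy_max maximum mean copy number (default 1.2, inclusive).
#' @param len_min minimum mean protein length (default 100, exclusive).
#' @return the qualifying rows of `profiles`.
#' @export
select_core_profiles <- function(profiles, prev_min = 0.10, copy_max = 1.2,
                                 len_min = 100) {
  keep <- profiles$prevalence >= prev_min & profiles$mean_copy <= copy_max &
    profiles$mean_len > len_min
  profiles[keep, , drop = FALSE]
}

#' Trim alignment columns by gap fraction
#'
#' Retains columns whose gap fraction is strictly below `max_gap_frac`.
#' Row order is preserved; trimming is idempotent.
#'
#' @param aln named character vector of equal-length gapped rows.
#' @param max_gap_frac columns with at least this gap fraction are dropped.
#' @return trimmed alignment (possibly zero-width, with a warning).
#' @export
trim_alignment <- function(aln, max_gap_frac = 0.5) {
  if (length(aln) == 0L) stop("trim_alignment: empty alignment")
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("trim_alignment: rows of unequal length")
  if (w == 0L) return(aln)
  mat <- do.call(rbind, strsplit(aln, "", fixed = TRUE))
  gap_frac <- colMeans(matrix(mat %in% GAP_CHARS, nrow = nrow(mat)))
  keep <- gap_frac < max_gap_frac
  if (!any(keep)) {
    warning("trim_alignment: all columns removed")
    return(stats::setNames(rep("", length(aln)), names(aln)))
  }
  out <- apply(mat[, keep, drop = FALSE], 1, paste, collapse = "")
  stats::setNames(out, names(aln))
}

#' Genome inclusion rule for tree building
#'
#' A genome counts a marker when its alignment row exists and has non-gap
#' characters in strictly more than `min_col_frac` of that marker's
#' (trimmed) columns; the genome is included when at least `min_markers`
#' markers count.
#'
#' @param genome_id genome to test.
#' @param alignments named list of trimmed alignments (named character
#'   vectors; rows keyed by genome id).
#' @param min_markers minimum qualifying markers (default 3).
#' @param min_col_frac column-coverage fraction (default 0.05, exclusive).
#' @return logical.
#' @export
genome_inclusion <- function(genome_id, alignments, min_markers = 3L,
                             min_col_frac = 0.05) {
  qual <- vapply(alignments, function(aln) {
    if (!genome_id %in% names(aln)) return(FALSE)
    row <- aln[[genome_id]]
    w <- nchar(row)
    if (w == 0L) return(FALSE)
    ch <- strsplit(row, "", fixed = TRUE)[[1]]
    mean(!(ch %in% GAP_CHARS)) > min_col_frac
  }, logical(1))
  sum(qual) >= min_markers
}

#' Neighbor-joining tree
#'
#' Standard NJ via [ape::nj()]; on additive distance matrices it recovers
#' the generating topology and branch lengths. Small negative branch
#' lengths (an NJ artefact on non-additive input) are clamped to zero.
#'
#' @param distances symmetric numeric matrix with zero diagonal and row
#'   and column names, or a `dist` object.
#' @return an [ape::phylo] tree.
#' @export
nj_tree <- function(distances) {
  if (inherits(distances, "dist")) distances <- as.matrix(distances)
  if (nrow(distances) < 3L) stop("nj_tree: need at least 3 taxa")
  if (any(distances < 0)) stop("nj_tree: negative distances")
  if (any(abs(diag(distances)) > 1e-12)) stop("nj_tree: non-zero diagonal")
  tr <- ape::nj(as.dist(distances))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Patristic distances from a tree
#'
#' Entry (i, j) is the sum of branch lengths on the path between leaves i
#' and j; the result is a valid tree metric (four-point condition).
#'
#' @param tree an [ape::phylo] with branch lengths.
#' @return symmetric matrix over the tip labels.
#' @export
patristic_distances <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("patristic_distances: tree lacks branch lengths")
  }
  stats::cophenetic(tree)
}

# p-distance between concatenated alignment rows over shared non-gap
# columns; pairs sharing no columns get `missing_dist`.
.pdistance_matrix <- function(rows, missing_dist = 0.75) {
  ids <- names(rows)
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  ok <- !(matrix(mat %in% GAP_CHARS, nrow = nrow(mat)))
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- ok[i, ] & ok[j, ]
      d[i, j] <- d[j, i] <- if (!any(shared)) missing_dist
      else mean(mat[i, shared] != mat[j, shared])
    }
  }
  d
}

# Restrict alignment rows to a genome subset, dropping absent rows.
.restrict_aln <- function(aln, genome_ids) {
  aln[names(aln) %in% genome_ids]
}

#' Iterative core-marker phylogeny driver
#'
#' Iteration 1 selects core profiles over all genomes and builds a tree
#' for the genomes passing the inclusion rule; each later iteration
#' re-selects core profiles over the genomes excluded so far, inferring
#' marker sets specific to the diversity the earlier trees missed. Stops
#' early when no genomes remain, no profiles qualify, or an iteration
#' includes nobody.
#'
#' @param genome_ids genome universe.
#' @param families data.frame for [marker_profiles()].
#' @param alignments named list (by profile id) of per-marker alignments
#'   (named character vectors keyed by genome id).
#' @param n_iter maximum iterations (default 5).
#' @param prev_min,copy_max,len_min core-profile criteria.
#' @param max_gap_frac column-trim threshold.
#' @param min_markers,min_col_frac inclusion rule.
#' @return list of per-iteration lists: `core` (profile ids), `included`
#'   (genome ids), `tree` ([ape::phylo] or NULL when fewer than 3 genomes
#'   were included).
#' @export
iterate_markers <- function(genome_ids, families, alignments, n_iter = 5L,
                            prev_min = 0.10, copy_max = 1.2, len_min = 100,
                            max_gap_frac = 0.5, min_markers = 3L,
                            min_col_frac = 0.05) {
  remaining <- genome_ids
  iterations <- list()
  for (it in seq_len(n_iter)) {
    if (length(remaining) == 0L) break
    prof <- marker_profiles(families, remaining)
    core <- select_core_profiles(prof, prev_min, copy_max, len_min)
    if (nrow(core) == 0L) break
    core_aln <- lapply(alignments[intersect(core$profile_id,
                                            names(alignments))],
                       function(a) {
                         a <- .restrict_aln(a, remaining)
                         if (length(a) == 0L) return(a)
                         suppressWarnings(trim_alignment(a, max_gap_frac))
                       })
    core_aln <- core_aln[vapply(core_aln, length, integer(1)) > 0L]
    included <- remaining[vapply(remaining, genome_inclusion,
                                 logical(1), alignments = core_aln,
                                 min_markers = min_markers,
                                 min_col_frac = min_col_frac)]
    if (length(included) == 0L) break
    tree <- NULL
    if (length(included) >= 3L) {
      rows <- vapply(included, function(g) {
        paste(vapply(core_aln, function(a) {
          w <- nchar(a[[1]])
          if (g %in% names(a)) a[[g]] else strrep("-", w)
        }, character(1)), collapse = "")
      }, character(1))
      tree <- nj_tree(.pdistance_matrix(rows))
    }
    iterations[[it]] <- list(core = core$profile_id, included = included,
                             tree = tree)
    remaining <- setdiff(remaining, included)
  }
  iterations
}
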