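# Genus-level clustering from amino-acid identity and gene sharing, Markov
# clustering of the resulting graph, and the habitat-divergence rank test
# comparing same-habitat against cross-habitat patristic distances within
# each qualifying cluster.

#' Pairwise average amino-acid identity
#'
#' Shared genes are reciprocal best matches by global protein alignment
#' score (BLOSUM62, affine gaps) with a positive alignment score --
#' unrelated random proteins align at negative global scores, so the
#' positive-score gate keeps chance reciprocal pairs out of the shared set.
#' AAI is the mean percent identity over those pairs and `shared_frac` the
#' pair count over the gene count of the smaller genome.
#'
#' @param genes_a,genes_b character vectors of protein sequences.
#' @param id_a,id_b optional genome ids for the result row.
#' @return one-row data.frame: `genome_a`, `genome_b`, `aai` (percent),
#'   `shared_frac`, `n_shared`. No shared genes gives `aai` 0.
#' @export
pairwise_aai <- function(genes_a, genes_b, id_a = NA_character_,
                         id_b = NA_character_) {
  if (length(genes_a) == 0L || length(genes_b) == 0L) {
    stop("pairwise_aai: empty gene list")
  }
  data("BLOSUM62", package = "Biostrings", envir = environment())
  pa <- Biostrings::AAStringSet(genes_a)
  score <- matrix(0, length(genes_a), length(genes_b))
  ident <- matrix(0, length(genes_a), length(genes_b))
  for (j in seq_along(genes_b)) {
    aln <- Biostrings::pairwiseAlignment(
      pa, Biostrings::AAString(genes_b[[j]]), type = "global",
      substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 0.5)
    score[, j] <- Biostrings::score(aln)
    ident[, j] <- Biostrings::pid(aln, type = "PID1")
  }
  best_for_a <- max.col(score, ties.method = "first")
  best_for_b <- max.col(t(score), ties.method = "first")
  idx <- cbind(seq_along(genes_a), best_for_a)
  # the 30% identity floor is the usual protein-homology twilight bound;
  # random pairs occasionally reach positive global scores but not 30% id
  recip <- which(best_for_b[best_for_a] == seq_along(genes_a) &
                   score[idx] > 0 & ident[idx] >= 30)
  n_shared <- length(recip)
  aai <- if (n_shared == 0L) 0 else {
    mean(ident[cbind(recip, best_for_a[recip])])
  }
  data.frame(genome_a = id_a, genome_b = id_b, aai = aai,
             shared_frac = n_shared / min(length(genes_a), length(genes_b)),
             n_shared = n_shared, stringsAsFactors = FALSE)
}

#' Build the genus-level similarity graph
#'
#' Pairs meeting both thresholds -- AAI at least `aai_min` percent and a
#' shared-gene fraction at least `shared_min` -- become edges weighted by
#' `aai / 100`.
#'
#' @param aai data.frame of [pairwise_aai()] rows.
#' @param aai_min AAI threshold (percent, default 50).
#' @param shared_min shared-gene fraction threshold (default 0.20).
#' @return data.frame of edges: `from`, `to`, `weight`.
#' @export
build_genus_graph <- function(aai, aai_min = 50, shared_min = 0.20) {
  keep <- aai$aai >= aai_min & aai$shared_frac >= shared_min
  data.frame(from = aai$genome_a[keep], to = aai$genome_b[keep],
             weight = aai$aai[keep] / 100, stringsAsFactors = FALSE)
}

#' Markov clustering (MCL)
#'
#' Standard MCL on the weighted undirected graph: self-loops of weight 1
#' are added, columns are normalised to stochastic, and expansion (matrix
#' squaring) alternates with inflation (entrywise power `inflation`, then
#' renormalisation) until the matrix is stable (max entry change below
#' `tol`) or `max_iter` rounds. Clusters are read off the attractor rows
#' of the limit matrix; overlapping attractor systems are merged.
#' Disconnected components are never merged, at any inflation.
#'
#' @param edges data.frame `from`, `to`, `weight` (weights > 0), or a
#'   symmetric adjacency matrix with dimnames.
#' @param inflation inflation exponent (default 2.0).
#' @param nodes optional node universe; isolated nodes become singletons.
#' @param tol,max_iter convergence controls.
#' @return list of character vectors, one per cluster, ordered by
#'   decreasing size then first member.
#' @export
mcl_cluster <- function(edges, inflation = 2.0, nodes = NULL, tol = 1e-6,
                        max_iter = 200L) {
  if (is.matrix(edges)) {
    adj <- edges
    ids <- rownames(adj)
  } else {
    ids <- sort(unique(c(edges$from, edges$to, nodes)))
    n <- length(ids)
    adj <- matrix(0, n, n, dimnames = list(ids, ids))
    if (nrow(edges) > 0L) {
      if (any(edges$weight <= 0)) stop("mcl_cluster: edge weights must be > 0")
      for (r in seq_len(nrow(edges))) {
        adj[edges$from[r], edges$to[r]] <- edges$weight[r]
        adj[edges$to[r], edges$from[r]] <- edges$weight[r]
      }
    }
  }
  n <- length(ids)
  if (n == 0L) return(list())
  diag(adj) <- 1
  m <- sweep(adj, 2, colSums(adj), "/")
  for (it in seq_len(max_iter)) {
    m2 <- m %*% m                      # expansion
    m2 <- m2^inflation                 # inflation
    m2[m2 < 1e-12] <- 0
    m2 <- sweep(m2, 2, colSums(m2), "/")
    delta <- max(abs(m2 - m))
    m <- m2
    if (delta < tol) break
  }
  # attractor rows have positive diagonal mass; each spans a cluster
  thr <- 1e-6
  attractors <- which(diag(m) > thr)
  covered <- rep(FALSE, n)
  sets <- list()
  for (a in attractors) {
    members <- which(m[a, ] > thr)
    merged <- FALSE
    for (s in seq_along(sets)) {
      if (any(members %in% sets[[s]])) {
        sets[[s]] <- union(sets[[s]], members)
        merged <- TRUE
        break
      }
    }
    if (!merged) sets[[length(sets) + 1L]] <- members
    covered[members] <- TRUE
  }
  # repeat merging until fixed point (chains of overlaps)
  repeat {
    done <- TRUE
    if (length(sets) > 1L) {
      for (i in seq_len(length(sets) - 1L)) {
        for (j in (i + 1L):length(sets)) {
          if (any(sets[[i]] %in% sets[[j]])) {
            sets[[i]] <- union(sets[[i]], sets[[j]])
            sets[[j]] <- integer(0)
            done <- FALSE
          }
        }
      }
      sets <- Filter(length, sets)
    }
    if (done) break
  }
  for (i in which(!covered)) sets[[length(sets) + 1L]] <- i
  out <- lapply(sets, function(s) sort(ids[s]))
  out[order(-vapply(out, length, integer(1)),
            vapply(out, `[`, character(1), 1))]
}

#' Select clusters eligible for the habitat-divergence test
#'
#' @param clusters list of member-id vectors (e.g. from [mcl_cluster()]).
#' @param habitats named habitat vector over all members.
#' @return the clusters with at least 4 members spanning at least 2
#'   distinct habitats.
#' @export
select_divergence_clusters <- function(clusters, habitats) {
  Filter(function(cl) {
    h <- habitats[cl]
    length(cl) >= 4L && length(unique(h[!is.na(h)])) >= 2L
  }, clusters)
}

#' One-tailed Wilcoxon rank-sum test
#'
#' Tests whether sample `y` is stochastically greater than sample `x`
#' (`alternative = "greater"`). The null distribution is enumerated
#' exactly when the combined sample size is at most 20 and tie-free;
#' otherwise the normal approximation with tie correction and continuity
#' correction is used. Degenerate data (zero rank variance) returns 1.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative only `"greater"` (y greater) is meaningful for the
#'   divergence designation; `"less"` and `"two.sided"` are passed through.
#' @return p-value in (0, 1].
#' @export
wilcoxon_rank_sum <- function(x, y, alternative = "greater") {
  if (length(x) == 0L || length(y) == 0L) {
    stop("wilcoxon_rank_sum: empty sample")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  p <- suppressWarnings(
    stats::wilcox.test(y, x, alternative = alternative, exact = exact,
                       correct = TRUE)$p.value)
  if (!is.finite(p)) p <- 1
  min(max(p, .Machine$double.xmin), 1)
}

#' Habitat-divergence test for one genus-level cluster
#'
#' Splits the pairwise patristic distances of the cluster's tree into
#' same-habitat and cross-habitat samples and asks whether cross-habitat
#' distances are significantly larger (one-tailed Wilcoxon rank-sum,
#' `p < alpha`). A habitat represented by a single genome contributes no
#' same-habitat pairs; when either sample is empty the cluster is reported
#' as non-divergent with p = 1 and a reason.
#'
#' @param tree [ape::phylo] over the cluster's genomes.
#' @param habitats named habitat vector covering the tree's tips.
#' @param alpha significance level (default 0.05).
#' @param cluster_id optional label for the report row.
#' @return one-row data.frame: `cluster_id`, `n_genomes`, `n_habitats`,
#'   `p_value` (cross > same), `p_opposite` (same > cross, reported for
#'   completeness), `divergent`, `reason`.
#' @export
habitat_divergence_test <- function(tree, habitats, alpha = 0.05,
                                    cluster_id = NA_character_) {
  tips <- tree$tip.label
  miss <- setdiff(tips, names(habitats))
  if (length(miss) > 0L) {
    stop("habitat missing for: ", paste(miss, collapse = ", "))
  }
  d <- patristic_distances(tree)
  h <- habitats[tips]
  same <- cross <- numeric(0)
  for (i in seq_len(length(tips) - 1L)) {
    for (j in (i + 1L):length(tips)) {
      if (is.na(h[i]) || is.na(h[j])) next
      if (h[i] == h[j]) same <- c(same, d[tips[i], tips[j]])
      else cross <- c(cross, d[tips[i], tips[j]])
    }
  }
  if (length(same) == 0L || length(cross) == 0L) {
    return(data.frame(cluster_id = cluster_id, n_genomes = length(tips),
                      n_habitats = length(unique(h[!is.na(h)])),
                      p_value = 1, p_opposite = 1, divergent = FALSE,
                      reason = "empty same- or cross-habitat sample",
                      stringsAsFactors = FALSE))
  }
  p <- wilcoxon_rank_sum(same, cross, "greater")
  p_opp <- wilcoxon_rank_sum(cross, same, "greater")
  data.frame(cluster_id = cluster_id, n_genomes = length(tips),
             n_habitats = length(unique(h[!is.na(h)])), p_value = p,
             p_opposite = p_opp, divergent = p < alpha, reason = "",
             stringsAsFactors = FALSE)
}
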