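# Pairwise average nucleotide identity by gapless seed-and-extend, exact
# strand-insensitive dereplication, and greedy centroid clustering into
# species-level viral clusters (95% ANI / >=85% member coverage).

# Integer encoding; N gets a per-side code so it never matches anything.
.encode_dna <- function(seq, n_code) {
  v <- utf8ToInt(seq)
  v[v == utf8ToInt("N")] <- n_code
  v
}

# Integer codes of all k-mers (base-4); NA where the window contains N.
# k <= 15 keeps codes within integer range.
.kmer_codes <- function(s, k) {
  v <- match(utf8ToInt(s), utf8ToInt("ACGT")) - 1L
  n <- length(v)
  if (n < k) return(integer(0))
  m <- n - k + 1L
  code <- integer(m)
  for (j in seq_len(k)) {
    code <- code + v[j:(j + m - 1L)] * as.integer(4^(k - j))
  }
  code
}

# Gapless alignment segments along shared-kmer diagonals of a vs b.
# Seeds are runs of >= k consecutive matches; runs on one diagonal are
# chained while the spanned identity stays >= min_ident, then each chained
# segment is extended outward as far as cumulative identity allows and
# trimmed to end on matches. Returns a data.frame of segments with 1-based
# coordinates in a (qs,qe) and b (ts,te), match counts and lengths.
.diagonal_segments <- function(a, b, k, min_ident, min_seg) {
  stopifnot(k <= 15L)
  na <- nchar(a); nb <- nchar(b)
  acode <- .kmer_codes(a, k)
  bcode <- .kmer_codes(b, k)
  aok <- which(!is.na(acode))
  bok <- which(!is.na(bcode))
  if (length(aok) == 0L || length(bok) == 0L) return(NULL)
  ordb <- bok[order(bcode[bok])]
  bs <- bcode[ordb]
  av <- acode[aok]
  hi <- findInterval(av, bs)
  lo <- findInterval(av - 1L, bs) + 1L
  cnt <- hi - lo + 1L
  sel <- which(cnt > 0L)
  if (length(sel) == 0L) return(NULL)
  iav <- rep(aok[sel], cnt[sel])
  dvec <- iav - ordb[sequence(cnt[sel], from = lo[sel])]
  smap <- split(iav, dvec)
  # diagonals carried by a single seed position are chance collisions
  # whenever the sequences are long enough to expect dense seeding
  if (min(na, nb) >= 4L * k) smap <- smap[lengths(smap) >= 2L]
  av <- .encode_dna(a, -1L)
  bv <- .encode_dna(b, -2L)
  segs <- list()
  for (dn in names(smap)) {
    d <- as.integer(dn)
    i0 <- max(1L, 1L + d); i1 <- min(na, nb + d)
    if (i1 - i0 + 1L < k) next
    # evaluate the diagonal inside a window around the seed span; identity-
    # bounded extension beyond the outermost seeds dies off quickly, so a
    # span-sized margin loses nothing in practice and avoids full-length
    # scans on chance diagonals
    spos <- smap[[dn]]
    span_lo <- min(spos); span_hi <- max(spos) + k - 1L
    ext <- (span_hi - span_lo + 1L) + min_seg + 4L * k
    i0 <- max(i0, span_lo - ext)
    i1 <- min(i1, span_hi + ext)
    m <- av[i0:i1] == bv[(i0 - d):(i1 - d)]
    cs <- c(0L, cumsum(m))
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed <- which(r$values & r$lengths >= k)
    if (length(seed) == 0L) next
    # chain seed runs while spanned identity holds; track run support
    spans <- list()
    cur <- c(starts[seed[1]], ends[seed[1]], 1L)
    for (si in seed[-1]) {
      cand <- c(cur[1], ends[si])
      ident <- (cs[cand[2] + 1L] - cs[cand[1]]) / (cand[2] - cand[1] + 1L)
      if (ident >= min_ident) { cur[2] <- ends[si]; cur[3] <- cur[3] + 1L }
      else { spans[[length(spans) + 1L]] <- cur
             cur <- c(starts[si], ends[si], 1L) }
    }
    spans[[length(spans) + 1L]] <- cur
    n <- length(m)
    for (sp in spans) {
      s <- sp[1]; e <- sp[2]
      cnt <- cs[e + 1L] - cs[s]
      # furthest left extension keeping cumulative identity
      if (s > 1L) {
        t <- seq_len(s - 1L)
        ident <- (cnt + (cs[s] - cs[t])) / (e - t + 1L)
        ok <- which(ident >= min_ident)
        if (length(ok) > 0L) { s <- min(ok); cnt <- cs[e + 1L] - cs[s] }
      }
      if (e < n) {
        t <- (e + 1L):n
        ident <- (cnt + (cs[t + 1L] - cs[e + 1L])) / (t - s + 1L)
        ok <- which(ident >= min_ident)
        if (length(ok) > 0L) { e <- t[max(ok)]; cnt <- cs[e + 1L] - cs[s] }
      }
      # trim to end on matches
      while (s <= e && !m[s]) s <- s + 1L
      while (e >= s && !m[e]) e <- e - 1L
      if (e - s + 1L < min_seg) next
      cnt <- cs[e + 1L] - cs[s]
      # a single chance 15-mer collision can extend to a marginal-identity
      # segment inside structured repeats; genuine homology at this length
      # carries either multiple seed runs or clearly higher identity
      if (sp[3] < 2L && cnt / (e - s + 1L) < 0.8) next
      qs <- i0 + s - 1L; qe <- i0 + e - 1L
      segs[[length(segs) + 1L]] <-
        c(qs = qs, qe = qe, ts = qs - d, te = qe - d,
          matches = cnt, len = e - s + 1L)
    }
  }
  if (length(segs) == 0L) return(NULL)
  out <- as.data.frame(do.call(rbind, segs))
  # merge duplicate/contained spans arising from overlapping seed kmers
  out[!duplicated(out[, c("qs", "qe", "ts")]), , drop = FALSE]
}

#' Pairwise average nucleotide identity
#'
#' Local gapless alignments are seeded with exact shared k-mers on both
#' strands and extended along their diagonals to maximal segments of at
#' least `min_ident` identity. ANI is the alignment-length-weighted mean
#' identity over all segments; coverage is the merged (non-double-counted)
#' fraction of each genome covered by segments. Substitution-level
#' divergence is handled exactly; indels are not chained across diagonals
#' (adequate for the desk-scale synthetic world, documented limitation).
#'
#' @param a,b sequences (character scalars) or single named elements.
#' @param k seed length (default 15).
#' @param min_ident minimum segment identity (default 0.70).
#' @param min_seg minimum retained segment length in nt; filters spurious
#'   short-motif hits.
#' @param query_id,target_id optional ids for the result row.
#' @return one-row data.frame: `query_id`, `target_id`, `ani`, `qcov`,
#'   `tcov` (percent). `ani` is 0 when no segment is found.
#' @export
pairwise_ani <- function(a, b, k = 15L, min_ident = 0.70, min_seg = 100L,
                         query_id = NA_character_, target_id = NA_character_) {
  if (!is.null(names(a)) && is.na(query_id)) query_id <- names(a)[1]
  if (!is.null(names(b)) && is.na(target_id)) target_id <- names(b)[1]
  a <- unname(a[[1]]); b <- unname(b[[1]])
  if (nchar(a) < k || nchar(b) < k) {
    stop("pairwise_ani: sequence shorter than seed length k")
  }
  min_seg <- min(min_seg, nchar(a), nchar(b))
  nb <- nchar(b)
  fw <- .diagonal_segments(a, b, k, min_ident, min_seg)
  rc <- .diagonal_segments(a, revcomp(b), k, min_ident, min_seg)
  if (!is.null(rc) && nrow(rc) > 0L) {
    # map reverse-strand target coordinates back to the forward strand
    ts <- nb - rc$te + 1L
    te <- nb - rc$ts + 1L
    rc$ts <- ts; rc$te <- te
  }
  segs <- rbind(fw, rc)
  if (is.null(segs) || nrow(segs) == 0L) {
    return(data.frame(query_id = query_id, target_id = target_id,
                      ani = 0, qcov = 0, tcov = 0, stringsAsFactors = FALSE))
  }
  ani <- 100 * sum(segs$matches) / sum(segs$len)
  qcov <- 100 * interval_union_length(segs$qs, segs$qe) / nchar(a)
  tcov <- 100 * interval_union_length(segs$ts, segs$te) / nb
  data.frame(query_id = query_id, target_id = target_id, ani = ani,
             qcov = qcov, tcov = tcov, stringsAsFactors = FALSE)
}

#' Exact strand-insensitive dereplication
#'
#' Collapses groups of identical sequences (a sequence equal to another's
#' reverse complement is a duplicate) to one representative: the
#' id-lexicographically-first member (identical sequences share a length).
#'
#' @param genomes named character vector.
#' @return the representatives, in input order.
#' @export
dereplicate_exact <- function(genomes) {
  if (length(genomes) == 0L) return(genomes)
  rc <- revcomp(genomes)
  canon <- ifelse(genomes <= rc, genomes, rc)
  reps <- vapply(split(names(genomes), canon), function(ids) min(ids),
                 character(1))
  genomes[names(genomes) %in% reps]
}

#' Greedy centroid species-level clustering
#'
#' Genomes are sorted by length (descending, ties by id) and the first
#' unassigned genome repeatedly seeds a cluster, absorbing every unassigned
#' genome with `ani >= ani_min` to the centroid and member coverage
#' `>= cov_min` (coverage of the member lets fragments join their parent
#' species). The result is a deterministic partition, invariant to input
#' order.
#'
#' @param genomes named character vector.
#' @param ani_min ANI threshold (percent, default 95).
#' @param cov_min member-coverage threshold (percent, default 85).
#' @param ... passed to [pairwise_ani()].
#' @return data.frame with one row per genome: `cluster_id`, `level`,
#'   `centroid_id`, `member_id`, `is_novel` (NA until
#'   [flag_novel_clusters()]).
#' @export
greedy_species_clusters <- function(genomes, ani_min = 95, cov_min = 85, ...) {
  if (length(genomes) == 0L) stop("no genomes to cluster")
  ord <- order(-nchar(genomes), names(genomes))
  ids <- names(genomes)[ord]
  assigned <- stats::setNames(rep(NA_character_, length(ids)), ids)
  cl <- 0L
  for (cid in ids) {
    if (!is.na(assigned[[cid]])) next
    cl <- cl + 1L
    lab <- sprintf("vc_%04d", cl)
    assigned[[cid]] <- lab
    pending <- ids[is.na(assigned[ids])]
    for (g in pending) {
      r <- pairwise_ani(genomes[cid], genomes[g], ...)
      if (r$ani >= ani_min && r$tcov >= cov_min) assigned[[g]] <- lab
    }
    attr(assigned, "centroids") <- c(attr(assigned, "centroids"),
                                     stats::setNames(cid, lab))
  }
  centroids <- attr(assigned, "centroids")
  out <- data.frame(cluster_id = unname(assigned[names(genomes)]),
                    level = "species",
                    centroid_id = unname(centroids[assigned[names(genomes)]]),
                    member_id = names(genomes), is_novel = NA,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Flag novel clusters
#'
#' A cluster is novel iff none of its members belongs to the reference
#' (known-genome) set.
#'
#' @param clusters data.frame from [greedy_species_clusters()].
#' @param in_reference named logical vector over all member ids.
#' @return `clusters` with `is_novel` filled in.
#' @export
flag_novel_clusters <- function(clusters, in_reference) {
  miss <- setdiff(clusters$member_id, names(in_reference))
  if (length(miss) > 0L) {
    stop("in_reference flag missing for: ", paste(miss, collapse = ", "))
  }
  has_ref <- tapply(in_reference[clusters$member_id], clusters$cluster_id, any)
  clusters$is_novel <- !as.logical(has_ref[clusters$cluster_id])
  clusters
}
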