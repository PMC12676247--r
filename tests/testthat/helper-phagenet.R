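# Shared fixtures and independent oracles. Oracles are deliberately naive
# re-implementations, kept separate from the package code paths they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

rand_protein <- function(n) paste(sample(AA20, n, TRUE), collapse = "")

# plant exactly n substitutions at distinct random positions
plant_subs <- function(seq, n) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- sample(length(ch), n)
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  ch[idx] <- vapply(ch[idx], function(b) sample(alt[[b]], 1L), character(1))
  paste(ch, collapse = "")
}

# adjusted Rand index between two labellings (contingency-table form)
ari_index <- function(x, y) {
  tab <- table(x, y)
  n <- sum(tab)
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  s <- sum(choose(tab, 2))
  e <- a * b / choose(n, 2)
  (s - e) / ((a + b) / 2 - e)
}

# naive bounded-mismatch scan: loops over every offset on both strands,
# comparing characters one by one (independent of the package scan)
oracle_spacer_scan <- function(spacer, genome, max_mm) {
  spl <- function(s) strsplit(s, "", fixed = TRUE)[[1]]
  sp <- spl(spacer)
  m <- length(sp)
  hits <- list()
  for (strand in c("+", "-")) {
    g <- spl(if (strand == "+") genome else revcomp(genome))
    n <- length(g)
    if (m > n) next
    for (off in 0:(n - m)) {
      w <- g[(off + 1):(off + m)]
      mm <- sum(w != sp | w == "N" | sp == "N")
      if (mm <= max_mm) {
        start <- if (strand == "+") off + 1L else n - (off + m) + 1L
        hits[[length(hits) + 1L]] <- data.frame(
          start = start, end = start + m - 1L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# naive ORF scan: for each frame and strand, walk codons in a plain loop
oracle_orf_scan <- function(seq, stop_set, min_len) {
  starts <- c("ATG", "GTG", "TTG")
  n <- nchar(seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 0:2) {
      i <- f + 1L
      orf_start <- NA
      while (i + 2L <= n) {
        cod <- substr(s, i, i + 2L)
        if (is.na(orf_start) && cod %in% starts) orf_start <- i
        if (!is.na(orf_start) && cod %in% stop_set) {
          if (i + 2L - orf_start + 1L >= min_len) {
            res[[length(res) + 1L]] <- c(orf_start, i + 2L, strand)
          }
          orf_start <- NA
        }
        i <- i + 3L
      }
      if (!is.na(orf_start) && (i - 1L) - orf_start + 1L >= min_len) {
        res[[length(res) + 1L]] <- c(orf_start, i - 1L, strand)  # run-off
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  }
  df <- as.data.frame(do.call(rbind, res), stringsAsFactors = FALSE)
  names(df) <- c("start", "end", "strand")
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  if (any(df$strand == "-")) {
    i <- df$strand == "-"
    s2 <- n - df$end[i] + 1L
    e2 <- n - df$start[i] + 1L
    df$start[i] <- s2; df$end[i] <- e2
  }
  df[order(df$start, df$end, df$strand), , drop = FALSE]
}

# exact one-sided rank-sum p-value (y greater) by enumerating all splits;
# only feasible for small tie-free samples
oracle_wilcoxon_exact <- function(x, y) {
  all <- c(x, y)
  stopifnot(!anyDuplicated(all))
  r <- rank(all)
  ry <- sum(r[(length(x) + 1):length(all)])
  combs <- utils::combn(length(all), length(y))
  ws <- colSums(matrix(r[combs], nrow = length(y)))
  mean(ws >= ry)
}

# one default community per test run, generated lazily and cached
.comm_cache <- new.env(parent = emptyenv())
get_community <- function(seed = 7, ...) {
  key <- paste(seed, paste(deparse(list(...)), collapse = ""), sep = "|")
  if (is.null(.comm_cache[[key]])) {
    .comm_cache[[key]] <- generate_community(community_config(seed = seed, ...))
  }
  .comm_cache[[key]]
}

# detect arrays over a whole named-sequence collection
detect_all_arrays <- function(genomes) {
  unlist(lapply(names(genomes), function(id) detect_crispr_arrays(genomes[id])),
         recursive = FALSE)
}
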