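# Valid characters after sanitisation. N never matches any base downstream.
DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Sanitise a DNA sequence
#'
#' Uppercases and maps every character outside `{A,C,G,T,N}` to `N`.
#' IUPAC ambiguity codes are deliberately collapsed: downstream comparisons
#' (ANI seeding, spacer matching) treat `N` as matching nothing, so mapping
#' rare ambiguity characters to `N` is conservative.
#'
#' @param seq character vector of DNA strings.
#' @param warn emit a warning when characters are replaced.
#' @return character vector over `{A,C,G,T,N}`.
#' @export
clean_dna <- function(seq, warn = TRUE) {
  out <- toupper(seq)
  bad <- grepl("[^ACGTN]", out)
  if (any(bad)) {
    if (warn) {
      warning(sprintf("%d sequence(s) contained non-ACGTN characters; mapped to N",
                      sum(bad)))
    }
    out[bad] <- gsub("[^ACGTN]", "N", out[bad])
  }
  out
}

#' Reverse complement
#'
#' @param seq character vector of DNA strings over `{A,C,G,T,N}`.
#' @return reverse-complemented strings; `N` maps to `N`.
#' @export
revcomp <- function(seq) {
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Read genome sequences from a FASTA file
#'
#' Identifiers are taken from the header line up to the first whitespace.
#' Sequences are uppercased and non-ACGTN characters are mapped to `N` with
#' a warning. Duplicate identifiers and empty sequences are errors.
#'
#' @param path path to an (uncompressed) FASTA file.
#' @return named character vector: names are record ids, values sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- clean_dna(as.character(set))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for id(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write genome sequences to a FASTA file
#'
#' Round-trips with [read_fasta()]: ids and sequences are preserved exactly.
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq.int(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse a newick tree
#'
#' Thin wrapper around [ape::read.tree()] adding the package's invariants:
#' unique leaf labels and non-negative branch lengths.
#'
#' @param text newick string (terminating `;` required).
#' @return an [ape::phylo] object.
#' @export
parse_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text), error = function(e) NULL,
                 warning = function(w) NULL)
  if (is.null(tr)) stop("malformed newick: ", substr(text, 1, 60))
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf labels in newick tree")
  if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
    stop("negative branch length in newick tree")
  }
  tr
}

#' Serialise a tree to newick
#'
#' @param tree an [ape::phylo] object.
#' @return newick string.
#' @export
write_newick <- function(tree) {
  ape::write.tree(tree)
}

#' Read a gene-call table
#'
#' Expected columns: `genome_id`, `start`, `end`, `strand`, `source_db`,
#' `description`. Coordinates are 1-based inclusive; strand is `+` or `-`.
#'
#' @param path TSV file with a header row.
#' @return data.frame of gene calls.
#' @export
read_gene_calls <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  req <- c("genome_id", "start", "end", "strand", "source_db", "description")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L) stop("gene-call table missing column(s): ",
                              paste(miss, collapse = ", "))
  validate_gene_calls(df)
  df
}

validate_gene_calls <- function(calls) {
  if (nrow(calls) == 0L) return(invisible(TRUE))
  if (any(calls$start < 1L) || any(calls$end < calls$start)) {
    stop("gene-call coordinates must satisfy 1 <= start <= end")
  }
  if (!all(calls$strand %in% c("+", "-"))) {
    stop("gene-call strand must be '+' or '-'")
  }
  invisible(TRUE)
}

#' Read a genome metadata table
#'
#' Expected columns include `genome_id` and any of `habitat`, `completeness`,
#' `lifestyle_score`, `provirus`, `in_reference`, `nucleotide_score`,
#' `spacer_match`, `host_taxon`. Missing values are `NA`.
#'
#' @param path TSV file with a header row.
#' @return data.frame keyed by `genome_id`.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "",
                          comment.char = "", na.strings = c("NA", ""))
  if (!"genome_id" %in% names(df)) stop("metadata table missing 'genome_id'")
  if (anyDuplicated(df$genome_id)) stop("duplicate genome_id in metadata")
  if ("completeness" %in% names(df)) {
    ok <- is.na(df$completeness) |
      (df$completeness >= 0 & df$completeness <= 100)
    if (!all(ok)) stop("completeness outside [0,100]")
  }
  df
}

#' Write a data frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Merge possibly-overlapping 1-based inclusive intervals; returns matrix
# with columns start, end. Used for coverage and coding-density unions.
merge_intervals <- function(start, end) {
  stopifnot(length(start) == length(end))
  if (length(start) == 0L) {
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  ms <- start[1]; me <- end[1]
  outs <- numeric(0); oute <- numeric(0)
  for (i in seq_along(start)[-1]) {
    if (start[i] <= me + 1) {
      me <- max(me, end[i])
    } else {
      outs <- c(outs, ms); oute <- c(oute, me)
      ms <- start[i]; me <- end[i]
    }
  }
  outs <- c(outs, ms); oute <- c(oute, me)
  cbind(start = outs, end = oute)
}

interval_union_length <- function(start, end) {
  m <- merge_intervals(start, end)
  if (nrow(m) == 0L) return(0)
  sum(m[, "end"] - m[, "start"] + 1)
}
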