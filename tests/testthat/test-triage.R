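test_that("strand switch rate counts adjacent opposite-strand pairs over gene count", {
  expect_equal(strand_switch_rate(c("+", "+", "-", "-", "+")), 2 / 5)
  expect_equal(strand_switch_rate(rep("+", 7)), 0)
  expect_equal(strand_switch_rate(rep(c("+", "-"), length.out = 10)), 9 / 10)
  expect_error(strand_switch_rate(character(0)), "no genes")
})

test_that("viral signature call equals brute force over the predicate truth table", {
  thr <- viral_signature_thresholds()
  # one signal configuration per corner of the 2^4 predicate table
  mk <- function(p1, p2, p3, p4) {
    list(n_genes = if (p3) 10L else 2L,
         viral_family_hits = if (p1) 3L else if (p4) 1L else 0L,
         microbial_family_hits = if (p1) 0L else if (p4) 0L else 2L,
         nucleotide_score = if (p2) 0.95 else 0.1,
         strand_switch_rate = if (p3) 0.1 else 0.9)
  }
  for (bits in 0:15) {
    p <- as.logical(bitwAnd(bits, c(1L, 2L, 4L, 8L)) > 0)
    sig <- mk(p[1], p[2], p[3], p[4])
    # independent evaluation of the four predicates on the same signals
    ref <- sum(
      sig$viral_family_hits >= 1L && sig$microbial_family_hits == 0L,
      sig$nucleotide_score >= 0.9,
      sig$strand_switch_rate <= 0.25 && sig$n_genes >= 4L,
      sig$viral_family_hits > sig$microbial_family_hits) >= thr$k
    expect_identical(as.logical(viral_signature_call(sig, thr)), ref,
                     label = paste("bits", bits))
  }
  # missing nucleotide score counts as zero
  sig <- mk(TRUE, TRUE, TRUE, TRUE); sig$nucleotide_score <- NA
  expect_true(as.logical(viral_signature_call(sig, thr)))
})

test_that("keyword phage call needs two hallmark genes, no prokaryote term, and a spacer match", {
  calls <- data.frame(description = c("major capsid protein",
                                      "terminase large subunit",
                                      "hypothetical protein"))
  expect_true(keyword_phage_call(calls, TRUE))
  expect_false(keyword_phage_call(calls, FALSE))
  expect_false(keyword_phage_call(
    rbind(calls, data.frame(description = "30S ribosomal protein S1")), TRUE))
  expect_false(keyword_phage_call(
    data.frame(description = c("major capsid protein", "DNA primase")), TRUE))
})

test_that("BUSCO/VPF filter applies the ratio rule, routes the boundary, and is monotone", {
  expect_true(false_positive_filter(30L, 1L, 0L))    # ratio 0.033
  expect_false(false_positive_filter(30L, 3L, 2L))   # ratio 0.10, 2 VPF
  expect_true(false_positive_filter(30L, 3L, 3L))    # rescued by VPF
  expect_error(false_positive_filter(0L, 0L, 0L), "> 0")
  # boundary ratio exactly 0.067 goes to the VPF clause
  expect_false(false_positive_filter(1000L, 67L, 0L))
  expect_true(false_positive_filter(1000L, 67L, 3L))
  # monotonicity over a grid: more VPF hits never flip keep->discard,
  # more BUSCO hits never flip discard->keep
  for (n in c(15L, 30L, 60L)) {
    for (b in 0:6) {
      for (v in 0:4) {
        keep <- false_positive_filter(n, b, v)
        expect_true(!keep || false_positive_filter(n, b, v + 1L))
        expect_true(keep || !false_positive_filter(n, b + 1L, v))
      }
    }
  }
})

test_that("quality gates use inclusive boundaries and fail closed on missing completeness", {
  expect_false(apply_quality_filters(2999L, 100))
  expect_true(apply_quality_filters(3000L, 50))
  expect_false(apply_quality_filters(10000L, NA))
})

test_that("lifestyle assignment follows score bands and the provirus merge", {
  expect_identical(lifestyle_assign(0.3, FALSE), "virulent")
  expect_identical(lifestyle_assign(0.5, FALSE), "uncertain")
  expect_identical(lifestyle_assign(0.9, FALSE), "uncertain")
  expect_identical(lifestyle_assign(0.95, FALSE), "temperate")
  expect_identical(lifestyle_assign(0.3, TRUE), "temperate")
  expect_error(lifestyle_assign(1.2, FALSE), "\\[0,1\\]")
})

test_that("keyword triage recovers exactly the planted phages on the community", {
  comm <- get_community(seed = 7)
  allg <- c(comm$phages, comm$hosts)
  is_phage <- vapply(names(allg), function(id) {
    calls <- comm$gene_calls[comm$gene_calls$genome_id == id, , drop = FALSE]
    sm <- comm$metadata$spacer_match[comm$metadata$genome_id == id]
    keyword_phage_call(calls, sm)
  }, logical(1))
  truth <- comm$metadata$type[match(names(allg), comm$metadata$genome_id)] == "phage"
  expect_identical(unname(is_phage), truth)
})

test_that("triage_genomes assigns lifestyles only past all gates", {
  comm <- get_community(seed = 7)
  tr <- triage_genomes(comm$phages, comm$gene_calls, comm$metadata)
  expect_identical(nrow(tr), length(comm$phages))
  expect_true(all(tr$is_viral[tr$is_phage]))          # is_phage => is_viral
  expect_true(all(is.na(tr$lifestyle) |
                    (tr$is_phage & tr$passes_fp_filter & tr$passes_quality)))
  meta <- comm$metadata[match(tr$genome_id, comm$metadata$genome_id), ]
  done <- !is.na(tr$lifestyle)
  expect_identical(tr$lifestyle[done],
                   mapply(lifestyle_assign, meta$lifestyle_score[done],
                          meta$provirus[done]))
})
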