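test_that("planted arrays are recovered verbatim; sparse repeats are not arrays", {
  set.seed(19)
  rep30 <- rand_dna(30)
  spacers <- replicate(3, rand_dna(32))
  arr <- paste0(rep30, paste(vapply(spacers, function(s) paste0(s, rep30),
                                    character(1)), collapse = ""))
  genome <- paste0(rand_dna(4000), "T", arr)   # buffer base, then the array
  got <- detect_crispr_arrays(c(g = genome))
  expect_length(got, 1L)
  expect_identical(got[[1]]$repeat_seq, rep30)
  expect_length(got[[1]]$positions, 4L)
  expect_identical(got[[1]]$spacers$seq, spacers)

  # two repeat copies only: below the minimum
  two <- paste0(rand_dna(2000), rep30, rand_dna(32), rep30, rand_dna(2000))
  expect_length(detect_crispr_arrays(c(g = two)), 0L)
})

test_that("random sequences rarely contain arrays", {
  set.seed(29)
  fp <- sum(vapply(1:40, function(i) {
    length(detect_crispr_arrays(c(g = rand_dna(10000)))) > 0L
  }, logical(1)))
  expect_lte(fp, 1L)
})

test_that("spacer matching agrees with the brute-force Hamming oracle", {
  set.seed(55)
  for (rep in 1:200) {
    g <- rand_dna(sample(60:250, 1))
    m <- sample(20:40, 1)
    mm_max <- sample(0:2, 1)
    if (rep %% 2 == 0) {
      # plant a (possibly mutated, possibly reverse) copy
      pos <- sample(nchar(g) - m + 1L, 1)
      sp <- substr(g, pos, pos + m - 1L)
      if (runif(1) < 0.5) sp <- revcomp(sp)
      if (runif(1) < 0.5) sp <- plant_subs(sp, sample(0:2, 1))
    } else {
      sp <- rand_dna(m)
    }
    if (runif(1) < 0.1) substr(sp, 1, 1) <- "N"
    got <- match_spacer(sp, g, mm_max)
    ref <- oracle_spacer_scan(sp, g, mm_max)
    rownames(got) <- rownames(ref) <- NULL
    expect_equal(got, ref, label = paste("case", rep))
  }
  expect_error(match_spacer(rand_dna(50), rand_dna(20)), "longer")
})

test_that("exact and one-mismatch contract examples", {
  set.seed(66)
  g <- rand_dna(500)
  sp <- substr(g, 101, 132)
  hits <- match_spacer(sp, g)
  expect_identical(hits$start, 101L)
  expect_identical(hits$mismatches, 0L)

  sp2 <- plant_subs(sp, 2)
  expect_identical(nrow(match_spacer(sp2, g, 1L)), 0L)

  sp3 <- revcomp(plant_subs(sp, 1))
  hits3 <- match_spacer(sp3, g, 1L)
  expect_identical(hits3$strand, "-")
  expect_identical(hits3$start, 101L)
})

test_that("host assignment deduplicates at genus level and fails on missing taxa", {
  edges <- data.frame(source = c("h1", "h2", "h3", "h1"),
                      target = c("p1", "p1", "p2", "p2"))
  taxa <- c(h1 = "Bacteroides", h2 = "Bacteroides", h3 = "Prevotella")
  hm <- assign_hosts(edges, taxa)
  expect_identical(hm[["p1"]], "Bacteroides")
  expect_setequal(hm[["p2"]], c("Bacteroides", "Prevotella"))
  expect_error(assign_hosts(edges, taxa[-3]), "h3")

  cls <- classify_host_range(hm)
  expect_identical(unname(cls[c("p1", "p2")]), c("specialist", "generalist"))
  expect_error(classify_host_range(list(p = character(0))), "empty")
})

test_that("phage network excludes spacer-vs-spacer hits and collapses multi-edges", {
  set.seed(91)
  shared <- rand_dna(32)           # spacer content shared by both arrays
  proto <- rand_dna(32)            # genuine protospacer in B
  repA <- rand_dna(30); repB <- rand_dna(30)
  arrA <- paste0(repA, shared, repA, proto, repA, rand_dna(32), repA)
  arrB <- paste0(repB, shared, repB, rand_dna(33), repB, rand_dna(34), repB)
  A <- paste0(rand_dna(3000), "T", arrA)
  B <- paste0(rand_dna(1500), proto, rand_dna(1500), "T", arrB)
  genomes <- c(A = A, B = B)
  arrays <- detect_all_arrays(genomes)
  expect_length(arrays, 2L)
  net <- build_phage_network(arrays, genomes)
  # single edge A->B via the protospacer; the shared spacer is not targeting
  expect_identical(net$edges,
                   data.frame(source = "A", target = "B", n_matches = 1L,
                              stringsAsFactors = FALSE))
  # disabling the exclusion re-admits the array hit
  net2 <- build_phage_network(arrays, genomes, exclude_array_hits = FALSE)
  expect_gte(net2$edges$n_matches[net2$edges$source == "A"], 2L)
})

test_that("pair classification distinguishes single/double direction and same host", {
  edges <- data.frame(source = c("A", "B", "C"), target = c("B", "A", "A"),
                      n_matches = 1L)
  hm <- list(A = "Bacteroides", B = c("Bacteroides", "Prevotella"),
             C = "Escherichia")
  pairs <- classify_pairs(edges, hm)
  ab <- pairs[pairs$phage_a == "A" & pairs$phage_b == "B", ]
  ac <- pairs[pairs$phage_a == "A" & pairs$phage_b == "C", ]
  expect_identical(ab$direction, "double_directed")
  expect_true(ab$same_host)
  expect_identical(ac$direction, "single_directed")
  expect_false(ac$same_host)
})

test_that("acquisition module needs cas1 and cas2; cas4 is recorded only", {
  expect_true(cas_acquisition_status("I-C", c("cas1", "cas2", "cas7"))$acquisition_complete)
  expect_false(cas_acquisition_status("I-F", c("cas3", "cas7"))$acquisition_complete)
  expect_false(cas_acquisition_status("II-C", "cas1")$acquisition_complete)
  st <- cas_acquisition_status("I-C", c("Cas1", "CAS2", "cas4"))
  expect_true(st$acquisition_complete)
  expect_true(st$has_cas4)
  expect_error(cas_acquisition_status("", "cas1"), "non-empty")
})
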