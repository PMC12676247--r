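test_that("core-profile selection applies the three criteria", {
  prof <- data.frame(profile_id = c("p1", "p2", "p3", "p4"),
                     prevalence = c(0.20, 0.05, 0.30, 0.10),
                     mean_copy = c(1.0, 1.0, 1.5, 1.2),
                     mean_len = c(150, 150, 150, 100.5))
  core <- select_core_profiles(prof)
  expect_setequal(core$profile_id, c("p1", "p4"))
  # length exactly 100 is excluded (strict >)
  prof$mean_len[1] <- 100
  expect_false("p1" %in% select_core_profiles(prof)$profile_id)
})

test_that("column trimming drops >=50%-gap columns and is idempotent", {
  aln <- c(a = "AC-GT", b = "A--GT", c = "AC-G-", d = "ACAG-", e = "AC-GT")
  tr <- trim_alignment(aln)
  # column 3 has 4/5 gaps, column 5 has 2/5: only column 3 removed
  expect_identical(unname(tr[["a"]]), "ACGT")
  expect_identical(trim_alignment(c(x = "ACGT", y = "AGGT")),
                   c(x = "ACGT", y = "AGGT"))
  set.seed(12)
  for (rep in 1:5) {
    rows <- stats::setNames(replicate(4, paste(
      sample(c("A", "C", "G", "-"), 30, TRUE, prob = c(1, 1, 1, 2)),
      collapse = "")), letters[1:4])
    once <- suppressWarnings(trim_alignment(rows))
    expect_identical(suppressWarnings(trim_alignment(once)), once)
  }
  expect_warning(trim_alignment(c(a = "--", b = "--")), "all columns")
})

test_that("genome inclusion needs three markers above strict 5% column coverage", {
  mk <- function(frac, w = 100L) {
    k <- round(frac * w)
    stats::setNames(paste0(strrep("A", k), strrep("-", w - k)), "g")
  }
  alns3 <- list(m1 = mk(0.10), m2 = mk(0.08), m3 = mk(0.06))
  expect_true(genome_inclusion("g", alns3))
  expect_false(genome_inclusion("g", list(m1 = mk(0.10), m2 = mk(0.04))))
  # exactly 5% does not count
  expect_false(genome_inclusion("g", list(m1 = mk(0.05), m2 = mk(0.05),
                                          m3 = mk(0.05))))
  expect_false(genome_inclusion("h", alns3))   # absent row
})

test_that("NJ recovers the 4-taxon additive fixture and ignores taxon order", {
  dm <- matrix(c(0, 3, 5, 4,
                 3, 0, 6, 5,
                 5, 6, 0, 5,
                 4, 5, 5, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  pd <- patristic_distances(tr)
  expect_equal(pd[rownames(dm), colnames(dm)], dm, tolerance = 1e-12)
  # leaf edges: A:1, B:2, C:3, D:2, internal 1 (implied by exact distances)
  tip_edge <- tr$edge.length[match(seq_along(tr$tip.label), tr$edge[, 2])]
  expect_equal(tip_edge[match(c("A", "B", "C", "D"), tr$tip.label)],
               c(1, 2, 3, 2))
  perm <- c("C", "A", "D", "B")
  pd2 <- patristic_distances(nj_tree(dm[perm, perm]))
  expect_equal(pd2[rownames(dm), colnames(dm)], dm, tolerance = 1e-12)

  expect_error(nj_tree(dm[1:2, 1:2]), "3 taxa")
})

test_that("patristic distances are path sums and valid tree metrics", {
  tr <- parse_newick("((A:1.0,B:2.0):0.5,C:3.0);")
  d <- patristic_distances(tr)
  expect_equal(d["A", "B"], 3.0)
  expect_equal(d["A", "C"], 4.5)
  expect_equal(d["B", "C"], 5.5)

  z <- tr; z$edge.length[] <- 0
  expect_true(all(patristic_distances(z) == 0))

  # four-point condition + NJ round trip on random trees
  set.seed(18)
  for (rep in 1:5) {
    rt <- ape::rtree(8)
    d1 <- patristic_distances(rt)
    labs <- rownames(d1)
    for (q in 1:20) {
      ij <- sample(labs, 4)
      s <- sort(c(d1[ij[1], ij[2]] + d1[ij[3], ij[4]],
                  d1[ij[1], ij[3]] + d1[ij[2], ij[4]],
                  d1[ij[1], ij[4]] + d1[ij[2], ij[3]]))
      expect_lte(s[2], s[3] + 1e-9)
      expect_equal(s[2], s[3], tolerance = 1e-6)
    }
    d2 <- patristic_distances(nj_tree(d1))
    expect_equal(d2[labs, labs], d1, tolerance = 1e-9)
  }

  bad <- tr; bad$edge.length <- NULL
  expect_error(patristic_distances(bad), "branch lengths")
})

test_that("the iteration driver captures disjoint marker worlds in successive rounds", {
  set.seed(3)
  gA <- sprintf("a%02d", 1:19); gB <- sprintf("b%02d", 1:2)
  fam <- rbind(
    expand.grid(genome_id = gA, profile_id = paste0("mA", 1:4),
                stringsAsFactors = FALSE),
    expand.grid(genome_id = gB, profile_id = paste0("mB", 1:4),
                stringsAsFactors = FALSE))
  fam$copy_count <- 1; fam$mean_protein_len <- 150
  mkaln <- function(g, w = 60L) stats::setNames(
    replicate(length(g), rand_protein(w)), g)
  alns <- c(stats::setNames(lapply(1:4, function(i) mkaln(gA)), paste0("mA", 1:4)),
            stats::setNames(lapply(1:4, function(i) mkaln(gB)), paste0("mB", 1:4)))
  # world B is below 10% prevalence overall, so round 1 is world A only
  it <- iterate_markers(c(gA, gB), fam, alns)
  expect_length(it, 2L)
  expect_setequal(it[[1]]$included, gA)
  expect_true(all(grepl("^mA", it[[1]]$core)))
  expect_setequal(it[[2]]$included, gB)
  expect_true(all(grepl("^mB", it[[2]]$core)))
  expect_s3_class(it[[1]]$tree, "phylo")
  expect_null(it[[2]]$tree)  # 2 genomes: no tree
  # iterations partition the included genomes
  expect_length(intersect(it[[1]]$included, it[[2]]$included), 0L)

  # universal-marker world: everything lands in iteration 1
  it2 <- iterate_markers(gA, fam[fam$genome_id %in% gA, ], alns[1:4])
  expect_length(it2, 1L)
  expect_setequal(it2[[1]]$included, gA)
})
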