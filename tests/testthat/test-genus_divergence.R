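test_that("pairwise AAI: identity, disjoint sets, and a planted-substitution oracle", {
  set.seed(8)
  genes <- replicate(6, rand_protein(120))
  r <- pairwise_aai(genes, genes, "a", "a2")
  expect_equal(r$aai, 100)
  expect_equal(r$shared_frac, 1)

  r2 <- pairwise_aai(genes, replicate(6, rand_protein(120)), "a", "b")
  expect_equal(r2$shared_frac, 0)
  expect_equal(r2$aai, 0)

  # 10% residue substitutions per gene -> AAI ~ 90
  mut <- vapply(genes, function(g) {
    ch <- strsplit(g, "", fixed = TRUE)[[1]]
    i <- sample(length(ch), round(0.1 * length(ch)))
    ch[i] <- vapply(ch[i], function(x) sample(setdiff(AA20, x), 1), character(1))
    paste(ch, collapse = "")
  }, character(1))
  r3 <- pairwise_aai(genes, mut, "a", "m")
  expect_gte(r3$aai, 88)
  expect_lte(r3$aai, 92)

  expect_error(pairwise_aai(character(0), genes), "empty")
})

test_that("genus graph edges require both AAI and shared-gene thresholds", {
  aai <- data.frame(genome_a = c("a", "a", "b"), genome_b = c("b", "c", "c"),
                    aai = c(60, 60, 40), shared_frac = c(0.5, 0.1, 0.5))
  g <- build_genus_graph(aai)
  expect_identical(nrow(g), 1L)
  expect_equal(g$weight, 0.6)
})

test_that("MCL separates weakly bridged cliques and never merges components", {
  tri <- data.frame(from = c("a", "b", "c", "d", "e", "f"),
                    to = c("b", "c", "a", "e", "f", "d"), weight = 1)
  expect_length(mcl_cluster(tri), 2L)
  expect_identical(mcl_cluster(data.frame(from = character(0),
                                          to = character(0),
                                          weight = numeric(0)),
                               nodes = "solo"), list("solo"))

  ca <- utils::combn(paste0("x", 1:5), 2)
  cb <- utils::combn(paste0("y", 1:5), 2)
  bridged <- data.frame(from = c(ca[1, ], cb[1, ], "x1"),
                        to = c(ca[2, ], cb[2, ], "y1"),
                        weight = c(rep(1, 20), 0.1))
  cl <- mcl_cluster(bridged, inflation = 2.0)
  expect_length(cl, 2L)
  expect_setequal(cl[[1]], paste0("x", 1:5))
  expect_setequal(cl[[2]], paste0("y", 1:5))

  # random disconnected graphs: the partition refines the components
  set.seed(77)
  for (rep in 1:5) {
    n1 <- sample(3:6, 1); n2 <- sample(3:6, 1)
    e1 <- utils::combn(paste0("p", seq_len(n1)), 2)
    e2 <- utils::combn(paste0("q", seq_len(n2)), 2)
    keep1 <- c(TRUE, runif(ncol(e1) - 1) < 0.7)
    edges <- data.frame(from = c(e1[1, keep1], e2[1, ]),
                        to = c(e1[2, keep1], e2[2, ]),
                        weight = runif(sum(keep1) + ncol(e2), 0.5, 1))
    for (cl in mcl_cluster(edges)) {
      expect_length(unique(substr(cl, 1, 1)), 1L)
    }
  }
})

test_that("divergence-eligible clusters need 4 genomes across 2 habitats", {
  hab <- c(a = "gut", b = "gut", c = "soil", d = "soil", e = "gut", f = "gut",
           g = "gut")
  cls <- list(c("a", "b", "c", "d"), c("e", "f", "g"), c("a", "b", "e", "f"))
  sel <- select_divergence_clusters(cls, hab)
  expect_identical(sel, cls[1])
})

test_that("rank-sum p-values: exact enumeration, ties, and the approximation boundary", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6), "greater"), 0.05)
  expect_equal(oracle_wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)), 0.05)
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3), "greater"), 0.5)

  set.seed(41)
  for (rep in 1:5) {
    x <- rnorm(30); y <- rnorm(30, 0.5)
    approx_p <- wilcoxon_rank_sum(x, y, "greater")
    exact_p <- stats::wilcox.test(y, x, alternative = "greater",
                                  exact = TRUE)$p.value
    expect_lt(abs(approx_p - exact_p), 0.01)
  }
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "empty")
})

test_that("habitat divergence is detected on separated clades and not on nulls", {
  # branch lengths chosen so all 15 pairwise distances are distinct
  tree <- parse_newick(
    "((A:0.001,(B:0.002,E:0.004):0.011):0.5,(C:0.008,(D:0.016,F:0.032):0.013):0.5);")
  hab <- c(A = "gut", B = "gut", E = "gut", C = "soil", D = "soil", F = "soil")
  rep1 <- habitat_divergence_test(tree, hab, cluster_id = "cl1")
  expect_true(rep1$divergent)
  expect_lt(rep1$p_value, 0.05)
  # enumeration oracle on the same distance samples
  d <- patristic_distances(tree)
  same <- cross <- numeric(0)
  tips <- tree$tip.label
  for (i in 1:5) for (j in (i + 1):6) {
    if (hab[tips[i]] == hab[tips[j]]) same <- c(same, d[tips[i], tips[j]])
    else cross <- c(cross, d[tips[i], tips[j]])
  }
  expect_equal(rep1$p_value, oracle_wilcoxon_exact(same, cross),
               tolerance = 1e-12)

  # all-zero branch lengths: total ties, no evidence
  z <- tree; z$edge.length[] <- 0
  rep2 <- habitat_divergence_test(z, hab)
  expect_gte(rep2$p_value, 0.5)
  expect_false(rep2$divergent)

  # a habitat with one genome only contributes no same-habitat pairs
  hab3 <- c(A = "gut", B = "soil", E = "lake", C = "sea", D = "pig", F = "cow")
  rep3 <- habitat_divergence_test(tree, hab3)
  expect_false(rep3$divergent)
  expect_match(rep3$reason, "empty")
})

test_that("type-I error is controlled under label permutation on a null tree", {
  set.seed(10)
  tr <- ape::rcoal(12)
  hits <- 0L
  nrep <- 200L
  for (r in seq_len(nrep)) {
    hab <- stats::setNames(sample(rep(c("gut", "soil"), 6)), tr$tip.label)
    if (habitat_divergence_test(tr, hab)$p_value < 0.05) hits <- hits + 1L
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lte(hits / nrep, 0.05 + 2 * se)
})

test_that("planted divergent genus groups are flagged and nulls are not", {
  comm <- get_community(seed = 23)
  ga <- comm$truth$genus_assignment
  hab <- stats::setNames(comm$metadata$habitat, comm$metadata$genome_id)
  for (g in unique(ga$group[!grepl("rec", ga$group)])) {
    ids <- ga$genome_id[ga$group == g]
    if (length(ids) < 4L || length(unique(hab[ids])) < 2L) next
    # genome-distance tree for the genus group
    dm <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
    for (i in seq_along(ids)) for (j in seq_len(i - 1L)) {
      r <- pairwise_ani(comm$phages[ids[i]], comm$phages[ids[j]])
      dm[i, j] <- dm[j, i] <- 1 - r$ani / 100
    }
    rep <- habitat_divergence_test(nj_tree(dm), hab, cluster_id = g)
    expect_identical(rep$divergent, unique(ga$divergent[ga$group == g]),
                     label = paste("genus", g))
  }
})
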