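test_that("identical config and seed give byte-identical output", {
  cfg <- community_config(n_phages = 12L, n_hosts = 3L,
                          phage_len = c(4000L, 5000L),
                          host_len = c(8000L, 9000L),
                          n_species_groups = 3L, seed = 7L)
  c1 <- generate_community(cfg)
  c2 <- generate_community(cfg)
  expect_identical(c1, c2)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_community(c1, d1); write_community(c2, d2)
  for (f in list.files(d1, recursive = TRUE)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("zero within-species rate makes members identical (array-free)", {
  comm <- get_community(seed = 3, within_species_sub_rate = 0,
                        spacer_mismatch_rate = 0,
                        frac_phage_with_array = 0,
                        n_phages = 16L, n_hosts = 3L,
                        n_species_groups = 4L)
  sp <- comm$truth$species_assignment
  for (grp in unique(sp$group)) {
    ids <- sp$genome_id[sp$group == grp]
    expect_length(unique(unname(comm$phages[ids])), 1L)
  }
})

test_that("with zero mismatch rate every planted host link is an exact substring relation", {
  comm <- get_community(seed = 3, within_species_sub_rate = 0,
                        spacer_mismatch_rate = 0,
                        frac_phage_with_array = 0,
                        n_phages = 16L, n_hosts = 3L,
                        n_species_groups = 4L)
  hl <- comm$truth$host_links
  expect_gt(nrow(hl), 0L)
  spacers <- comm$truth$spacers
  for (i in seq_len(nrow(hl))) {
    sp <- spacers$seq[spacers$spacer_id == hl$spacer_id[i]]
    g <- comm$phages[[hl$phage_id[i]]]
    expect_true(grepl(sp, g, fixed = TRUE) || grepl(revcomp(sp), g, fixed = TRUE),
                label = paste("substring relation for", hl$spacer_id[i]))
  }
})

test_that("member-vs-root identity tracks 100*(1 - within_species_sub_rate)", {
  comm <- get_community(seed = 7)
  rate <- comm$config$within_species_sub_rate
  sp <- comm$truth$species_assignment
  grp <- sp$group[duplicated(sp$group)][1]     # a multi-member group
  ids <- sp$genome_id[sp$group == grp]
  root <- comm$phages[ids[1]]
  anis <- vapply(ids[-1], function(i) pairwise_ani(root, comm$phages[i])$ani,
                 numeric(1))
  expect_true(all(abs(anis - 100 * (1 - rate)) <= 1),
              label = sprintf("mean identity %.2f within 1 point of %.1f",
                              mean(anis), 100 * (1 - rate)))
})

test_that("infeasible and invalid configs are rejected", {
  expect_error(community_config(spacer_len = 10000L,
                                phage_len = c(4000L, 5000L)), "infeasible")
  expect_error(community_config(frac_recode = 1.5), "\\[0,1\\]")
  expect_error(community_config(n_phages = -1L), ">= 0")
  expect_error(community_config(spacers_per_host_array = 1L), "2 spacers")
})

test_that("planted links reference existing records with <=1 mismatch", {
  comm <- get_community(seed = 7)
  tr <- comm$truth
  expect_true(all(tr$host_links$host_id %in% names(comm$hosts)))
  expect_true(all(tr$host_links$phage_id %in% names(comm$phages)))
  expect_true(all(tr$phage_links$source_phage %in% names(comm$phages)))
  expect_true(all(tr$host_links$planted_mismatches <= 1L))
  expect_true(all(tr$phage_links$planted_mismatches <= 1L))
  # spacer counts per planted array: copies - 1
  expect_true(all(tr$arrays$n_repeats >= 3L))
})

test_that("gene calls respect genome bounds and carry planted keywords", {
  comm <- get_community(seed = 7)
  lens <- c(nchar(comm$phages), nchar(comm$hosts))
  gc <- comm$gene_calls
  expect_true(all(gc$start >= 1L))
  expect_true(all(gc$end <= lens[gc$genome_id]))
  n_kw <- vapply(names(comm$phages), function(id) {
    d <- tolower(gc$description[gc$genome_id == id])
    sum(vapply(d, function(x) any(vapply(tolower(VIRAL_KEYWORDS), grepl, logical(1),
                                         x = x, fixed = TRUE)), logical(1)))
  }, numeric(1))
  expect_true(all(n_kw >= 2))
})
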