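# Seeded generator of a phage-host community with planted ground truth.
# Every downstream stage (triage, ANI clustering, code calling, phylogeny,
# divergence testing, CRISPR networks) can be tested against the planted
# structure without any external data.

STOP_CODONS <- c("TAA", "TAG", "TGA")

# ~60-nt intergenic stop unit. For every forward frame class it carries the
# three stop codons adjacently, and for every reverse frame class the three
# reverse-complement stop patterns adjacently. Two properties matter:
# (1) placing all three stop types within 9 nt makes the position of the
# class's blocking stop nearly identical under every single-stop-
# reassignment code, so intergenic ORF structure is code-symmetric and the
# coding-density contrast comes only from planted recoding; (2) two units
# per intergenic region keep every same-class stop gap below the 90-nt ORF
# minimum on clean genomes. Stop order and padding are randomised per
# occurrence so repeated units share no long exact substring (keeps ANI
# k-mer seeding clean).
stop_unit <- function() {
  out <- ""
  rc_types <- c("TTA", "CTA", "TCA")
  for (cls in 0:2) {
    for (rep in 1:2) {   # two copies per class: robust to lineage mutation
      pad <- (cls - nchar(out)) %% 3L
      out <- paste0(out, random_dna(pad),
                    paste(sample(STOP_CODONS), collapse = ""))
      pad <- (cls - nchar(out)) %% 3L
      out <- paste0(out, random_dna(pad),
                    paste(sample(rc_types), collapse = ""))
    }
  }
  out
}

# source_kind labels for spacers
.SPACER_HOST <- "host"
.SPACER_PHAGE <- "phage"

#' Configuration for the synthetic phage-host community
#'
#' The defaults describe the stated world the generator emulates: species
#' groups at ~2% within-group divergence (the species-threshold regime),
#' genus groups whose habitat lineages diverge at a structural 12% (placing
#' between-species identity below 80%), a small fraction of genomes built
#' with a reassigned stop codon, and CRISPR arrays on hosts and on a
#' fraction of phages with 32-nt spacers copied from phage genomes.
#'
#' @param n_phages,n_hosts genome counts.
#' @param phage_len,host_len length-2 integer ranges (bp).
#' @param n_species_groups planted species clusters among non-recoded phages.
#' @param within_species_sub_rate per-base substitution probability applied
#'   to each species-group member relative to its lineage root.
#' @param n_genus_groups planted genus clusters; species groups are assigned
#'   to genus groups round-robin.
#' @param habitats habitat labels cycled over lineages.
#' @param habitat_sub_rate per-base substitution rate separating habitat
#'   lineages (species groups) within a genus from the genus root.
#' @param frac_divergent fraction of genus groups whose habitat labels follow
#'   the lineage structure (planted habitat divergence); the rest get
#'   habitat labels assigned at random, planting the null.
#' @param frac_recode fraction of phages built with a recoded stop codon
#'   (codes 15/90/91 cycled); each is its own singleton species/genus group.
#' @param recode_every a recoded gene carries the reassigned stop codon at
#'   every this-many-th codon position.
#' @param spacer_len spacer length (nt).
#' @param spacers_per_host_array spacers in each host CRISPR array (>= 2).
#' @param spacer_mismatch_rate probability that a planted spacer copy carries
#'   exactly one mismatch to its protospacer (0 or 1 planted mismatches).
#' @param frac_phage_with_array fraction of phages carrying an array that
#'   targets other phages.
#' @param spacers_per_phage_array spacers per phage array (>= 2).
#' @param strand_switch_rate probability that consecutive genes lie on
#'   opposite strands.
#' @param frac_in_reference per-genome probability of membership in the
#'   reference (known-genome) set, used by novelty flagging.
#' @param repeat_len CRISPR repeat length (nt).
#' @param seed integer seed; identical config + seed gives byte-identical
#'   output.
#' @return a `community_config` list, validated.
#' @export
community_config <- function(n_phages = 40L, n_hosts = 10L,
                             phage_len = c(8000L, 12000L),
                             host_len = c(20000L, 30000L),
                             n_species_groups = 8L,
                             within_species_sub_rate = 0.02,
                             n_genus_groups = 3L,
                             habitats = c("human_gut", "pig_gut", "soil",
                                          "ocean"),
                             habitat_sub_rate = 0.12,
                             frac_divergent = 0.5,
                             frac_recode = 0.1,
                             recode_every = 8L,
                             spacer_len = 32L,
                             spacers_per_host_array = 3L,
                             spacer_mismatch_rate = 0,
                             frac_phage_with_array = 0.2,
                             spacers_per_phage_array = 2L,
                             strand_switch_rate = 0.1,
                             frac_in_reference = 0.3,
                             repeat_len = 30L,
                             seed = 1L) {
  cfg <- list(n_phages = as.integer(n_phages), n_hosts = as.integer(n_hosts),
              phage_len = as.integer(phage_len),
              host_len = as.integer(host_len),
              n_species_groups = as.integer(n_species_groups),
              within_species_sub_rate = within_species_sub_rate,
              n_genus_groups = as.integer(n_genus_groups),
              habitats = habitats, habitat_sub_rate = habitat_sub_rate,
              frac_divergent = frac_divergent, frac_recode = frac_recode,
              recode_every = as.integer(recode_every),
              spacer_len = as.integer(spacer_len),
              spacers_per_host_array = as.integer(spacers_per_host_array),
              spacer_mismatch_rate = spacer_mismatch_rate,
              frac_phage_with_array = frac_phage_with_array,
              spacers_per_phage_array = as.integer(spacers_per_phage_array),
              strand_switch_rate = strand_switch_rate,
              frac_in_reference = frac_in_reference,
              repeat_len = as.integer(repeat_len),
              seed = as.integer(seed))
  fracs <- c(cfg$within_species_sub_rate, cfg$habitat_sub_rate,
             cfg$frac_divergent, cfg$frac_recode, cfg$spacer_mismatch_rate,
             cfg$frac_phage_with_array, cfg$strand_switch_rate,
             cfg$frac_in_reference)
  if (any(fracs < 0 | fracs > 1)) stop("all rates/fractions must lie in [0,1]")
  counts <- c(cfg$n_phages, cfg$n_hosts, cfg$n_species_groups,
              cfg$n_genus_groups)
  if (any(counts < 0L)) stop("all counts must be >= 0")
  if (length(cfg$phage_len) != 2L || length(cfg$host_len) != 2L ||
      any(cfg$phage_len <= 0L) || diff(cfg$phage_len) < 0L ||
      diff(cfg$host_len) < 0L) {
    stop("phage_len and host_len must be increasing positive ranges")
  }
  if (cfg$spacer_len > cfg$phage_len[1]) {
    stop("infeasible config: spacer_len exceeds the minimum phage length")
  }
  if (cfg$spacers_per_host_array < 2L || cfg$spacers_per_phage_array < 2L) {
    stop("arrays need >= 2 spacers (>= 3 repeat copies)")
  }
  if (length(cfg$habitats) < 1L) stop("at least one habitat label required")
  class(cfg) <- "community_config"
  cfg
}

# Evaluate code under a fixed, restorable RNG state.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = .GlobalEnv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = .GlobalEnv)
    else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv)
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Frame-aware genome mutation: substitutions at the given rate, but a
# substitution creating an in-frame stop codon inside a gene (under the
# genome's true code) is reverted -- the purifying selection any real
# genome is under. Off-frame and intergenic changes are unconstrained.
mutate_genome <- function(root, rate, calls, true_stops = STOP_CODONS) {
  if (rate <= 0) return(root)
  mut <- mutate_seq(root, rate)
  ch <- strsplit(mut, "", fixed = TRUE)[[1]]
  rch <- strsplit(root, "", fixed = TRUE)[[1]]
  restore <- function(pos) {
    idx <- pos:(pos + 2L)
    ch[idx] <<- rch[idx]
  }
  tripl <- function(v, pos) paste0(v[pos], v[pos + 1L], v[pos + 2L])
  for (gi in seq_len(nrow(calls))) {
    s <- calls$start[gi]; e <- calls$end[gi]
    cs <- seq.int(s, e - 2L, by = 3L)
    fwd <- calls$strand[gi] == "+"
    pat <- if (fwd) true_stops else revcomp(true_stops)
    cods <- paste0(ch[cs], ch[cs + 1L], ch[cs + 2L])
    for (b in which(cods %in% pat)) restore(cs[b])
    # start and terminal-stop codons are conserved as well
    sc_pos <- if (fwd) s else e - 2L
    sc_pat <- if (fwd) START_CODONS else revcomp(START_CODONS)
    if (tripl(rch, sc_pos) %in% sc_pat && !(tripl(ch, sc_pos) %in% sc_pat)) {
      restore(sc_pos)
    }
    tc_pos <- if (fwd) e - 2L else s
    tc_pat <- if (fwd) true_stops else revcomp(true_stops)
    if (tripl(rch, tc_pos) %in% tc_pat && !(tripl(ch, tc_pos) %in% tc_pat)) {
      restore(tc_pos)
    }
  }
  paste(ch, collapse = "")
}

# Substitute bases at the given per-base rate; substituted bases always
# change. Length-preserving.
mutate_seq <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- which(stats::runif(length(ch)) < rate & ch != "N")
  if (length(hit) > 0L) {
    alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                G = c("A", "C", "T"), T = c("A", "C", "G"))
    ch[hit] <- vapply(ch[hit], function(b) sample(alt[[b]], 1L), character(1))
  }
  paste(ch, collapse = "")
}

# Codons other than the three stops, in fixed order.
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(sort(all64), STOP_CODONS)
}

# A 16-codon "frame guard": all codons are sense in the reading frame, but
# the off-frame (+1, +2) readings and the three reverse-strand frames each
# contain at least two distinct stop-codon types. Interleaved through gene
# bodies it pins coding density to the planted gene structure under every
# single-stop-reassignment code (removing any one stop type still leaves a
# stop in every non-coding frame within ~30 codons, below the ORF minimum).
# Free positions are randomised per occurrence so that repeated guards
# never share a 15-mer, keeping ANI seeding clean.
frame_guard_codons <- function() {
  b <- c("A", "C", "G", "T")
  N <- function(s = b) sample(s, 1L)
  c("TTA", "TCA", paste0(N(), "TA"), paste0("A", N(), N()),
    paste0(N(), "TA"), paste0("G", N(), N()), paste0(N(), "CT"),
    paste0("AA", N()), paste0(N(), N(), "T"), paste0("GA", N()),
    paste0(N(), "TT"), paste0("A", N(), N()), paste0(N(), N(), "T"),
    paste0("TA", N(c("C", "T"))), paste0(N(), N(), "C"),
    paste0("TA", N(c("C", "T"))))
}

# Build one coding genome: alternating intergenic stop-blocked spacers and
# genes (ATG + body + terminal stop), genes laid on +/- strands with the
# given switch rate. If recode_codon is given it is planted in-frame at
# every `recode_every`-th body codon and terminal stops are drawn from
# `terminal_stops` (the codons that remain stops under the genome's true
# code). Returns list(seq, calls) with 1-based inclusive coordinates.
build_coding_genome <- function(target_len, switch_rate,
                                descriptions, source_dbs,
                                recode_codon = NULL, recode_every = 8L,
                                terminal_stops = STOP_CODONS) {
  sc <- sense_codons()
  pieces <- character(0)
  starts <- integer(0); ends <- integer(0); strands <- character(0)
  pos <- 1L
  gi <- 0L
  strand <- "+"
  repeat {
    # reject intergenic draws with internal exact 23-mer repeats: unit
    # permutations can coincide by chance and mimic a CRISPR repeat at
    # array-like spacing
    repeat {
      ig <- paste0(stop_unit(), stop_unit())
      kmer23 <- substring(ig, 1:(nchar(ig) - 22L), 23:nchar(ig))
      if (!anyDuplicated(kmer23)) break
    }
    pieces <- c(pieces, ig)
    pos <- pos + nchar(ig)
    if (pos > target_len) break
    # gene body: blocks of (recode_every) free codons followed by a frame
    # guard; recoded genomes plant the reassigned stop at each block head
    n_blocks <- sample(6:12, 1L)
    body <- unlist(lapply(seq_len(n_blocks), function(bi) {
      free <- sample(sc, recode_every, replace = TRUE)
      if (!is.null(recode_codon)) free[1] <- recode_codon
      c(free, frame_guard_codons())
    }))
    gene <- paste0("ATG", paste(body, collapse = ""),
                   sample(terminal_stops, 1L))
    gi <- gi + 1L
    if (gi > 1L && stats::runif(1) < switch_rate) {
      strand <- if (strand == "+") "-" else "+"
    }
    gseq <- if (strand == "-") revcomp(gene) else gene
    pieces <- c(pieces, gseq)
    starts <- c(starts, pos)
    ends <- c(ends, pos + nchar(gseq) - 1L)
    strands <- c(strands, strand)
    pos <- pos + nchar(gseq)
    if (pos > target_len) break
  }
  n_genes <- length(starts)
  desc <- rep_len(descriptions, n_genes)
  dbs <- rep_len(source_dbs, n_genes)
  list(seq = paste(pieces, collapse = ""),
       calls = data.frame(start = starts, end = ends, strand = strands,
                          source_db = dbs, description = desc,
                          stringsAsFactors = FALSE))
}

# repeat + s1 + repeat + ... + sk + repeat  (k spacers, k+1 repeat copies)
assemble_array <- function(repeat_seq, spacers) {
  paste0(repeat_seq, paste(vapply(spacers, function(s) paste0(s, repeat_seq),
                                  character(1)), collapse = ""))
}

# Generator-internal exhaustive matcher used to build exact link ground
# truth. Independent of crispr_net::match_spacer by construction (kept
# deliberately separate so truth tables are not defined by the code under
# test). Returns data.frame(start, strand, mismatches) of all full-length
# placements with <= max_mm mismatches, forward-strand 1-based coordinates.
.truth_scan <- function(spacer, genome, max_mm = 1L) {
  enc <- function(s, n_code) {
    v <- utf8ToInt(s)
    v[s2 <- which(v == utf8ToInt("N"))] <- n_code
    v
  }
  hits <- function(sp, g) {
    m <- length(sp); n <- length(g)
    if (m > n) return(integer(0))
    nw <- n - m + 1L
    mm <- integer(nw)
    for (j in seq_len(m)) {
      mm <- mm + (g[j:(j + nw - 1L)] != sp[j])
      if (j %% 8L == 0L && all(mm > max_mm)) return(integer(0))
    }
    which(mm <= max_mm)
  }
  count_mm <- function(sp, g, at) {
    vapply(at, function(p) sum(g[p:(p + length(sp) - 1L)] != sp), integer(1))
  }
  sp <- enc(spacer, -1L)
  gf <- enc(genome, -2L)
  gr <- enc(revcomp(genome), -2L)
  n <- nchar(genome); m <- nchar(spacer)
  fw <- hits(sp, gf)
  rv <- hits(sp, gr)
  out <- data.frame(start = integer(0), strand = character(0),
                    mismatches = integer(0), stringsAsFactors = FALSE)
  if (length(fw) > 0L) {
    out <- rbind(out, data.frame(start = fw, strand = "+",
                                 mismatches = count_mm(sp, gf, fw),
                                 stringsAsFactors = FALSE))
  }
  if (length(rv) > 0L) {
    out <- rbind(out, data.frame(start = n - (rv + m - 1L) + 1L, strand = "-",
                                 mismatches = count_mm(sp, gr, rv),
                                 stringsAsFactors = FALSE))
  }
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Generate a synthetic phage-host community with planted ground truth
#'
#' See [community_config()] for the world being simulated. Output is fully
#' determined by the config (including its seed): the generation order is
#' fixed and a single Mersenne-Twister stream drives every draw.
#'
#' @param config a [community_config()] object.
#' @return list with elements `phages` and `hosts` (named sequence vectors),
#'   `gene_calls` (data.frame), `metadata` (data.frame), and `truth`, a list
#'   of data.frames: `species_assignment`, `genus_assignment`,
#'   `code_assignment`, `host_links`, `phage_links`, `arrays`, `spacers`.
#' @export
generate_community <- function(config = community_config()) {
  stopifnot(inherits(config, "community_config"))
  with_local_seed(config$seed, .generate_community_impl(config))
}

.generate_community_impl <- function(cfg) {
  viral_descs <- c("major capsid protein", "terminase large subunit",
                   "portal protein", "tail fiber protein",
                   "baseplate wedge subunit", "tape measure protein",
                   "head-tail connector protein", "virion structural protein")
  neutral_descs <- c("hypothetical protein", "DNA primase",
                     "replicative helicase", "thymidylate synthase",
                     "dCMP deaminase", "single-stranded DNA binding protein",
                     "nucleotide kinase", "methyltransferase")
  prok_descs <- c("30S ribosomal protein S1", "50S ribosomal protein L2",
                  "DNA gyrase subunit A", "preprotein translocase SecY")
  host_genera <- c("Bacteroides", "Prevotella", "Faecalibacterium",
                   "Escherichia", "Klebsiella", "Lactobacillus",
                   "Clostridium", "Ruminococcus")

  n_rec <- round(cfg$frac_recode * cfg$n_phages)
  n_norm <- cfg$n_phages - n_rec
  n_sp <- min(cfg$n_species_groups, n_norm)
  phage_ids <- sprintf("phage_%03d", seq_len(cfg$n_phages))
  host_ids <- sprintf("host_%03d", seq_len(cfg$n_hosts))

  # --- species/genus scaffolding -------------------------------------------
  # species groups (habitat lineages) assigned to genus groups round-robin
  sp_genus <- if (n_sp > 0L) ((seq_len(n_sp) - 1L) %% max(cfg$n_genus_groups, 1L)) + 1L
              else integer(0)
  n_div <- round(cfg$frac_divergent * cfg$n_genus_groups)
  genus_divergent <- seq_len(cfg$n_genus_groups) <= n_div
  # lineage habitats cycle within each genus so every genus spans >= 2
  sp_habitat <- character(n_sp)
  for (g in seq_len(cfg$n_genus_groups)) {
    idx <- which(sp_genus == g)
    sp_habitat[idx] <- rep_len(cfg$habitats, length(idx))
  }
  # member counts per species group, as even as possible
  sp_sizes <- if (n_sp > 0L) {
    base <- n_norm %/% n_sp
    extra <- n_norm %% n_sp
    base + as.integer(seq_len(n_sp) <= extra)
  } else integer(0)

  # --- genus roots and lineage roots ---------------------------------------
  genus_root <- character(cfg$n_genus_groups)
  genus_calls <- vector("list", cfg$n_genus_groups)
  for (g in seq_len(cfg$n_genus_groups)) {
    len <- sample(cfg$phage_len[1]:cfg$phage_len[2], 1L)
    dbs <- c("viral_family", "viral_family",
             sample(c("vpf", "none"), 12L, replace = TRUE, prob = c(0.3, 0.7)))
    bg <- build_coding_genome(len, cfg$strand_switch_rate,
                              descriptions = c(viral_descs[c(1, 2)],
                                               sample(neutral_descs, 6L)),
                              source_dbs = dbs)
    genus_root[g] <- bg$seq
    genus_calls[[g]] <- bg$calls
  }
  lineage_root <- character(n_sp)
  for (s in seq_len(n_sp)) {
    lineage_root[s] <- mutate_genome(genus_root[sp_genus[s]],
                                     cfg$habitat_sub_rate,
                                     genus_calls[[sp_genus[s]]])
  }

  # --- phage sequences ------------------------------------------------------
  seqs <- character(cfg$n_phages)
  calls_list <- vector("list", cfg$n_phages)
  species_of <- integer(cfg$n_phages)
  genus_of <- character(cfg$n_phages)
  divergent_of <- logical(cfg$n_phages)
  habitat_of <- character(cfg$n_phages)
  code_of <- integer(cfg$n_phages)
  i <- 0L
  for (s in seq_len(n_sp)) {
    for (k in seq_len(sp_sizes[s])) {
      i <- i + 1L
      # first member is the lineage root itself; the rest are mutated copies,
      # so member-vs-root identity is ~100*(1 - within_species_sub_rate)
      seqs[i] <- if (k == 1L) lineage_root[s]
                 else mutate_genome(lineage_root[s],
                                    cfg$within_species_sub_rate,
                                    genus_calls[[sp_genus[s]]])
      calls_list[[i]] <- genus_calls[[sp_genus[s]]]
      species_of[i] <- s
      genus_of[i] <- sprintf("genus_%02d", sp_genus[s])
      divergent_of[i] <- genus_divergent[sp_genus[s]]
      habitat_of[i] <- if (genus_divergent[sp_genus[s]]) sp_habitat[s]
                       else sample(cfg$habitats, 1L)
      code_of[i] <- 11L
    }
  }
  recode_codon_of <- c(`15` = "TAG", `90` = "TAA", `91` = "TGA")
  rec_codes <- rep_len(c(15L, 90L, 91L), n_rec)
  for (r in seq_len(n_rec)) {
    i <- i + 1L
    code <- rec_codes[r]
    codon <- recode_codon_of[[as.character(code)]]
    len <- sample(cfg$phage_len[1]:cfg$phage_len[2], 1L)
    bg <- build_coding_genome(len, cfg$strand_switch_rate,
                              descriptions = c(viral_descs[c(1, 2)],
                                               sample(neutral_descs, 6L)),
                              source_dbs = c("viral_family", "viral_family",
                                             rep("none", 6L)),
                              recode_codon = codon,
                              recode_every = cfg$recode_every,
                              terminal_stops = setdiff(STOP_CODONS, codon))
    seqs[i] <- bg$seq
    calls_list[[i]] <- bg$calls
    species_of[i] <- n_sp + r
    genus_of[i] <- sprintf("genus_rec_%02d", r)
    divergent_of[i] <- FALSE
    habitat_of[i] <- sample(cfg$habitats, 1L)
    code_of[i] <- code
  }
  base_len <- nchar(seqs)

  # --- spacer sampling ------------------------------------------------------
  # Protospacer windows are reserved per genus group (all lineages of a
  # genus share the genus root's coordinate system) so that no two planted
  # spacers overlap in sequence space, even across related lineages; this
  # keeps the link ground truth exact.
  used_windows <- new.env(parent = emptyenv())
  L <- cfg$spacer_len
  pick_window <- function(genus_key, max_start) {
    for (attempt in 1:200) {
      p <- sample.int(max_start, 1L)
      wins <- used_windows[[genus_key]]
      clash <- !is.null(wins) &&
        any(p <= wins[, 2] & p + L - 1L >= wins[, 1])
      if (!clash) {
        used_windows[[genus_key]] <- rbind(wins, c(p, p + L - 1L))
        return(p)
      }
    }
    stop("infeasible config: cannot place non-overlapping protospacers")
  }

  spacer_rows <- list()
  sp_count <- 0L
  new_spacer <- function(source_genome, source_kind, target_idx) {
    sp_count <<- sp_count + 1L
    grp <- species_of[target_idx]
    max_start <- base_len[target_idx] - L + 1L
    if (max_start < 1L) stop("infeasible config: spacer longer than target")
    p <- pick_window(genus_of[target_idx], max_start)
    proto <- substr(seqs[target_idx], p, p + L - 1L)
    strand <- if (sp_count %% 2L == 0L) "-" else "+"
    sseq <- if (strand == "-") revcomp(proto) else proto
    mm <- 0L
    if (stats::runif(1) < cfg$spacer_mismatch_rate) {
      mm <- 1L
      j <- sample.int(L, 1L)
      b <- substr(sseq, j, j)
      sub <- sample(setdiff(c("A", "C", "G", "T"), b), 1L)
      sseq <- paste0(substr(sseq, 1L, j - 1L), sub, substr(sseq, j + 1L, L))
    }
    list(spacer_id = sprintf("sp_%04d", sp_count), source_genome = source_genome,
         source_kind = source_kind, seq = sseq,
         target_genome = phage_ids[target_idx], target_group = grp,
         target_genus = genus_of[target_idx],
         target_start = p, target_strand = strand, planted_mismatches = mm)
  }

  # phage arrays first (carriers sample targets among other phages)
  n_carrier <- round(cfg$frac_phage_with_array * cfg$n_phages)
  carriers <- if (n_carrier > 0L) sort(sample.int(cfg$n_phages, n_carrier))
              else integer(0)
  phage_spacers <- list()
  for (ci in carriers) {
    targets <- sample(setdiff(seq_len(cfg$n_phages), ci),
                      min(cfg$spacers_per_phage_array, cfg$n_phages - 1L))
    for (t in targets) {
      phage_spacers[[length(phage_spacers) + 1L]] <-
        c(new_spacer(phage_ids[ci], .SPACER_PHAGE, t), carrier = ci)
    }
  }
  # host arrays
  host_spacers <- list()
  for (h in seq_len(cfg$n_hosts)) {
    targets <- sample.int(cfg$n_phages, cfg$spacers_per_host_array,
                          replace = cfg$n_phages < cfg$spacers_per_host_array)
    for (t in targets) {
      host_spacers[[length(host_spacers) + 1L]] <-
        c(new_spacer(host_ids[h], .SPACER_HOST, t), host = h)
    }
  }

  # --- append arrays --------------------------------------------------------
  arrays <- data.frame(genome_id = character(0), start = integer(0),
                       end = integer(0), repeat_seq = character(0),
                       n_repeats = integer(0), stringsAsFactors = FALSE)
  add_array <- function(genome_seq, genome_id, spacer_seqs) {
    repeat_seq <- random_dna(cfg$repeat_len)
    arr <- assemble_array(repeat_seq, spacer_seqs)
    # buffer base before the array: if every spacer ends in the same base,
    # the context base preceding the first repeat must differ, otherwise an
    # exact-repeat detector would legitimately absorb it into the repeat
    # and the recovered spacers would be off by one.
    sp_ends <- substring(spacer_seqs, nchar(spacer_seqs), nchar(spacer_seqs))
    buffer <- if (length(unique(sp_ends)) == 1L) {
      sample(setdiff(c("A", "C", "G", "T"), sp_ends[1]), 1L)
    } else sample(c("A", "C", "G", "T"), 1L)
    genome_seq <- paste0(genome_seq, buffer)
    start <- nchar(genome_seq) + 1L
    arrays <<- rbind(arrays, data.frame(
      genome_id = genome_id, start = start,
      end = start + nchar(arr) - 1L, repeat_seq = repeat_seq,
      n_repeats = length(spacer_seqs) + 1L, stringsAsFactors = FALSE))
    paste0(genome_seq, arr)
  }
  for (ci in carriers) {
    mine <- Filter(function(x) x$carrier == ci, phage_spacers)
    seqs[ci] <- add_array(seqs[ci], phage_ids[ci],
                          vapply(mine, `[[`, character(1), "seq"))
  }
  host_seqs <- character(cfg$n_hosts)
  for (h in seq_len(cfg$n_hosts)) {
    host_seqs[h] <- random_dna(sample(cfg$host_len[1]:cfg$host_len[2], 1L))
    mine <- Filter(function(x) x$host == h, host_spacers)
    if (length(mine) > 0L) {
      host_seqs[h] <- add_array(host_seqs[h], host_ids[h],
                                vapply(mine, `[[`, character(1), "seq"))
    }
  }
  names(seqs) <- phage_ids
  names(host_seqs) <- host_ids

  # --- exact link ground truth by exhaustive verification ------------------
  # A planted spacer can legitimately match several phages when species
  # members are nearly identical; the truth tables therefore record every
  # full-length <=1-mismatch placement outside CRISPR arrays, found by the
  # generator's own exhaustive scan.
  all_spacers <- c(host_spacers, phage_spacers)
  array_iv <- function(gid) {
    a <- arrays[arrays$genome_id == gid, , drop = FALSE]
    if (nrow(a) == 0L) NULL else a[, c("start", "end"), drop = FALSE]
  }
  link_rows <- list()
  for (sp in all_spacers) {
    for (ti in seq_len(cfg$n_phages)) {
      tid <- phage_ids[ti]
      if (tid == sp$source_genome) next
      if (genus_of[ti] != sp$target_genus) {
        # different genus groups have independent root sequences: a
        # full-length <=1-mismatch hit to a 32-mer has probability ~4^-30;
        # guard against exact collisions only. Same-genus lineages (~12%
        # divergence) are close enough for chance <=1-mismatch hits and are
        # scanned exhaustively.
        if (!grepl(sp$seq, seqs[[ti]], fixed = TRUE) &&
            !grepl(revcomp(sp$seq), seqs[[ti]], fixed = TRUE)) next
      }
      hits <- .truth_scan(sp$seq, seqs[[ti]], max_mm = 1L)
      if (nrow(hits) == 0L) next
      aiv <- array_iv(tid)
      if (!is.null(aiv)) {
        keep <- !vapply(hits$start, function(p) {
          any(p <= aiv[, "end"] & p + L - 1L >= aiv[, "start"])
        }, logical(1))
        hits <- hits[keep, , drop = FALSE]
      }
      if (nrow(hits) == 0L) next
      link_rows[[length(link_rows) + 1L]] <- data.frame(
        source = sp$source_genome, source_kind = sp$source_kind,
        target = tid, spacer_id = sp$spacer_id,
        planted_mismatches = min(hits$mismatches),
        stringsAsFactors = FALSE)
    }
  }
  links <- if (length(link_rows) > 0L) do.call(rbind, link_rows)
           else data.frame(source = character(0), source_kind = character(0),
                           target = character(0), spacer_id = character(0),
                           planted_mismatches = integer(0),
                           stringsAsFactors = FALSE)
  host_links <- links[links$source_kind == .SPACER_HOST,
                      c("source", "target", "spacer_id", "planted_mismatches")]
  names(host_links)[1:2] <- c("host_id", "phage_id")
  phage_links <- links[links$source_kind == .SPACER_PHAGE,
                       c("source", "target", "spacer_id", "planted_mismatches")]
  names(phage_links)[1:2] <- c("source_phage", "target_phage")
  rownames(host_links) <- rownames(phage_links) <- NULL

  # --- gene calls and metadata ---------------------------------------------
  gene_calls <- do.call(rbind, c(
    lapply(seq_len(cfg$n_phages), function(i) {
      cbind(genome_id = phage_ids[i], calls_list[[i]], stringsAsFactors = FALSE)
    }),
    lapply(seq_len(cfg$n_hosts), function(h) {
      n_genes <- max(3L, min(10L, nchar(host_seqs[h]) %/% 1000L))
      glen <- 900L
      starts <- 1L + (seq_len(n_genes) - 1L) * 1000L
      data.frame(genome_id = host_ids[h], start = starts,
                 end = starts + glen - 1L,
                 strand = sample(c("+", "-"), n_genes, replace = TRUE),
                 source_db = c("busco", "microbial_family",
                               sample(c("busco", "none"), n_genes - 2L,
                                      replace = TRUE)),
                 description = c(prok_descs[1], prok_descs[3],
                                 sample(c(prok_descs, neutral_descs),
                                        n_genes - 2L, replace = TRUE)),
                 stringsAsFactors = FALSE)
    })))
  rownames(gene_calls) <- NULL

  metadata <- rbind(
    data.frame(genome_id = phage_ids, type = "phage", habitat = habitat_of,
               completeness = round(stats::runif(cfg$n_phages, 50, 100), 1),
               lifestyle_score = round(stats::runif(cfg$n_phages), 3),
               provirus = stats::runif(cfg$n_phages) < 0.1,
               in_reference = stats::runif(cfg$n_phages) < cfg$frac_in_reference,
               nucleotide_score = round(stats::runif(cfg$n_phages, 0.9, 1), 3),
               spacer_match = TRUE, host_taxon = NA_character_,
               stringsAsFactors = FALSE),
    data.frame(genome_id = host_ids, type = "host", habitat = NA_character_,
               completeness = 100, lifestyle_score = NA_real_,
               provirus = FALSE, in_reference = TRUE,
               nucleotide_score = round(stats::runif(cfg$n_hosts, 0, 0.3), 3),
               spacer_match = FALSE,
               host_taxon = rep_len(host_genera, cfg$n_hosts),
               stringsAsFactors = FALSE))

  spacers <- do.call(rbind, lapply(all_spacers, function(x) {
    data.frame(spacer_id = x$spacer_id, source_genome = x$source_genome,
               source_kind = x$source_kind, seq = x$seq,
               target_genome = x$target_genome, target_start = x$target_start,
               target_strand = x$target_strand,
               planted_mismatches = x$planted_mismatches,
               stringsAsFactors = FALSE)
  }))
  if (is.null(spacers)) {
    spacers <- data.frame(spacer_id = character(0), source_genome = character(0),
                          source_kind = character(0), seq = character(0),
                          target_genome = character(0), target_start = integer(0),
                          target_strand = character(0),
                          planted_mismatches = integer(0),
                          stringsAsFactors = FALSE)
  }

  truth <- list(
    species_assignment = data.frame(genome_id = phage_ids,
                                    group = species_of,
                                    stringsAsFactors = FALSE),
    genus_assignment = data.frame(genome_id = phage_ids, group = genus_of,
                                  divergent = divergent_of,
                                  stringsAsFactors = FALSE),
    code_assignment = data.frame(genome_id = phage_ids, code = code_of,
                                 stringsAsFactors = FALSE),
    host_links = host_links, phage_links = phage_links,
    arrays = arrays, spacers = spacers)

  list(phages = seqs, hosts = host_seqs, gene_calls = gene_calls,
       metadata = metadata, truth = truth, config = cfg)
}

#' Write a generated community to disk
#'
#' Emits `genomes.fasta`, `hosts.fasta`, `gene_calls.tsv`, `metadata.tsv`
#' and `ground_truth/*.tsv` under `outdir`.
#'
#' @param community result of [generate_community()].
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_community <- function(community, outdir) {
  dir.create(file.path(outdir, "ground_truth"), recursive = TRUE,
             showWarnings = FALSE)
  write_fasta(community$phages, file.path(outdir, "genomes.fasta"))
  write_fasta(community$hosts, file.path(outdir, "hosts.fasta"))
  write_tsv(community$gene_calls, file.path(outdir, "gene_calls.tsv"))
  write_tsv(community$metadata, file.path(outdir, "metadata.tsv"))
  for (nm in names(community$truth)) {
    write_tsv(community$truth[[nm]],
              file.path(outdir, "ground_truth", paste0(nm, ".tsv")))
  }
  invisible(outdir)
}
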