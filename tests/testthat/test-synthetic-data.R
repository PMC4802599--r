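# Synthetic-study generator: determinism, planted-structure guarantees,
# conservation, and round-trips.

test_that("config invariants are enforced", {
  expect_error(sim_config(n_sa_mirnas = 100, n_known_mirnas = 10,
                          n_novel_mirnas = 2), "n_sa_mirnas")
  expect_error(sim_config(sa_fold_change = 2), "2\\^1.5")
  # infeasible layouts fail at assembly with the constraint named
  expect_error(generate_toy_genome(small_cfg(genome_length = 1500)),
               "infeasible")
})

test_that("generation is fully determined by the seed", {
  s1 <- generate_toy_genome(small_cfg(seed = 11))
  s2 <- generate_toy_genome(small_cfg(seed = 11))
  expect_identical(s1$genome, s2$genome)
  expect_identical(s1$truth$expression, s2$truth$expression)
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  expect_identical(unname(tools::md5sum(file.path(d1, "genome.fasta"))),
                   unname(tools::md5sum(file.path(d2, "genome.fasta"))))
  r1 <- simulate_srna_libraries(s1, dir = d1)
  r2 <- simulate_srna_libraries(s2, dir = d2)
  for (lib in names(r1)) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, paste0(lib, ".fastq")))),
      unname(tools::md5sum(file.path(d2, paste0(lib, ".fastq")))))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("every planted mature occurs at exactly one genomic position", {
  sim <- generate_toy_genome(small_cfg(seed = 17))
  g <- sim$genome[["chr1"]]
  for (i in seq_len(nrow(sim$truth$mirna))) {
    mat <- sim$truth$mirna$mature[i]
    hits <- oracle_map(mat, sim$genome)
    expect_length(hits, 1)
    # and the hit is at the recorded locus
    expect_identical(hits, sprintf("chr1:%d:%s", sim$truth$mirna$mat_start[i],
                                   sim$truth$mirna$strand[i]))
  }
})

test_that("a miRNA-free config yields only ncRNA and filler features", {
  sim <- generate_toy_genome(sim_config(seed = 3, genome_length = 20000,
                                        n_known_mirnas = 0,
                                        n_novel_mirnas = 0, n_sa_mirnas = 0,
                                        n_ncrna_loci = 5))
  expect_true(all(sim$features$type == "ncRNA"))
  expect_identical(nrow(sim$truth$mirna), 0L)
})

test_that("per-library read totals equal the configured depth", {
  cfg <- small_cfg(seed = 23)
  sim <- generate_toy_genome(cfg)
  reads <- simulate_srna_libraries(sim)
  for (lib in names(reads)) {
    expect_identical(nrow(reads[[lib]]), cfg$reads_per_library)
  }
})

test_that("a degenerate one-miRNA noise-free config yields only copies of its mature", {
  cfg <- sim_config(seed = 5, genome_length = 20000, n_known_mirnas = 1,
                    n_novel_mirnas = 0, n_sa_mirnas = 0, n_ncrna_loci = 0,
                    reads_per_library = 500, nb_dispersion = 0,
                    adapter_fraction = 0, lowq_read_fraction = 0,
                    ncrna_read_fraction = 0, n_transcripts_background = 2)
  sim <- generate_toy_genome(cfg)
  reads <- simulate_srna_libraries(sim)
  mat <- sim$truth$mirna$mature[1]
  for (lib in names(reads)) {
    expect_true(all(reads[[lib]]$seq == mat))
  }
})

test_that("simulated counts match the planted means within 3 SE over 20 seeds", {
  counts <- NULL
  for (s in 1:20) {
    cfg_s <- small_cfg(seed = 400 + s, adapter_fraction = 0,
                       lowq_read_fraction = 0, ncrna_read_fraction = 0.15,
                       reads_per_library = 4000L)
    sim <- generate_toy_genome(cfg_s)
    reads <- simulate_srna_libraries(sim)
    lib <- "ELS1_20DAP"
    n_target <- cfg_s$reads_per_library -
      round(cfg_s$ncrna_read_fraction * cfg_s$reads_per_library)
    mu <- sim$truth$expression[, lib] / 1e6 * n_target
    obs <- vapply(sim$truth$mirna$mature,
                  function(m) sum(reads[[lib]]$seq == m), numeric(1))
    # abundances are seed-specific, so standardize per seed and pool
    counts <- c(counts, (obs - mu) / sqrt(mu + cfg_s$nb_dispersion * mu^2))
  }
  z_mean <- mean(counts) / (1 / sqrt(length(counts)))
  expect_lt(abs(z_mean), 3)
})

test_that("degradome tags peak at the planted cleavage sites", {
  cfg <- small_cfg(seed = 31, degradome_peak_fraction = 1)
  sim <- generate_toy_genome(cfg)
  deg <- simulate_degradome_library(sim)
  prof <- build_tag_profile(deg, sim$transcripts)
  cs <- sim$truth$cleavage_sites
  for (i in seq_len(nrow(cs))) {
    p <- prof[[cs$transcript_id[i]]]
    on_site <- p[cs$cleavage_pos[i]]
    expect_gt(on_site, 0)
    # peak_fraction = 1: every tag of a targeted transcript sits on the site
    expect_identical(sum(p), as.integer(on_site))
  }
  # tag length is fixed, shorter only when clipped by the transcript end
  lens <- nchar(deg$seq)
  trunc <- grepl("trunc", deg$id)
  expect_true(all(lens[!trunc] == cfg$degradome_tag_length))
  expect_true(all(lens[trunc] < cfg$degradome_tag_length))
})

test_that("the modal degradome 5' end is the planted site in >= 95% of seeds", {
  hits <- 0; total <- 0
  for (s in 1:100) {
    cfg <- sim_config(seed = 600 + s, genome_length = 25000,
                      n_known_mirnas = 6, n_novel_mirnas = 1,
                      n_ncrna_loci = 2, n_sa_mirnas = 2,
                      reads_per_library = 1000, degradome_tags = 1500,
                      n_transcripts_background = 2)
    sim <- generate_toy_genome(cfg)
    deg <- simulate_degradome_library(sim)
    prof <- build_tag_profile(deg, sim$transcripts)
    cs <- sim$truth$cleavage_sites
    for (i in seq_len(nrow(cs))) {
      p <- prof[[cs$transcript_id[i]]]
      total <- total + 1
      if (which.max(p) == cs$cleavage_pos[i]) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("noise-free phenotype tables invert exactly", {
  cfg <- small_cfg(seed = 41, ct_sd = 0, absorbance_sd = 0)
  sim <- generate_toy_genome(cfg)
  ph <- simulate_phenotype_tables(sim)
  # chlorophyll round-trip: absorbances reproduce the planted trajectory
  ab <- ph$absorbance[ph$absorbance$replicate == 1, ]
  got <- chlorophyll_concentrations(ab$a645, ab$a663)
  want <- sim$truth$phenotype[order(sim$truth$phenotype$genotype,
                                    sim$truth$phenotype$dap), ]
  expect_equal(got$ca, want$chl_a, tolerance = 1e-9)
  expect_equal(got$cb, want$chl_b, tolerance = 1e-9)
  # ddCt round-trip: planted relative expression recovered to >= 6 decimals
  rq <- delta_delta_ct(ph$ct, "ELS1_20DAP")
  truth_rq <- sim$truth$qpcr
  m <- merge(rq, truth_rq, by.x = c("sample_id", "gene"),
             by.y = c("library", "gene"))
  expect_gt(nrow(m), 0)
  expect_equal(m$rq, m$rel_expression, tolerance = 1e-7)
})

test_that("the ELS-1 trajectory passes through the anchor chlorophyll values", {
  sim <- generate_toy_genome(small_cfg(seed = 43))
  ph <- sim$truth$phenotype
  expect_equal(ph$chl_a[ph$genotype == "ELS-1" & ph$dap == 25], 25.58)
  expect_equal(ph$chl_a[ph$genotype == "ELS-1" & ph$dap == 30], 0.35)
  expect_equal(ph$chl_a[ph$genotype == "Yu87-1" & ph$dap == 25], 27.41)
  expect_equal(ph$chl_a[ph$genotype == "Yu87-1" & ph$dap == 30], 23.01)
})

test_that("recomputing log2 ratios from the planted expression reproduces the SA flags", {
  sim <- generate_toy_genome(small_cfg(seed = 47))
  e <- sim$truth$expression
  flags <- abs(log2(e[, "ELS1_30DAP"] / e[, "ELS1_20DAP"])) > 1.5 &
    abs(log2(e[, "Yu871_30DAP"] / e[, "Yu871_20DAP"])) <= 1.5
  expect_identical(unname(flags), unname(sim$truth$sa_flags))
  expect_identical(sort(names(which(sim$truth$sa_flags))),
                   sort(sim$truth$mirna$id[sim$truth$mirna$sa]))
})

test_that("simulation artifacts round-trip through the package readers", {
  sim <- generate_toy_genome(small_cfg(seed = 53))
  d <- tempfile()
  paths <- write_simulation(sim, d)
  expect_identical(read_fasta(paths["genome"])[["chr1"]],
                   sim$genome[["chr1"]])
  expect_equal(read_fasta(paths["transcripts"]), sim$transcripts,
               ignore_attr = TRUE)
  feat <- read_features(paths["features"])
  expect_identical(feat$start, sim$features$start)
  expect_identical(feat$end, sim$features$end)
  expect_identical(feat$id, sim$features$id)
  reads <- simulate_srna_libraries(sim, dir = d)
  back <- read_fastq(file.path(d, "ELS1_20DAP.fastq"))
  expect_identical(back$seq, reads[["ELS1_20DAP"]]$seq)
  expect_identical(back$qual, reads[["ELS1_20DAP"]]$qual)
  unlink(d, recursive = TRUE)
})
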