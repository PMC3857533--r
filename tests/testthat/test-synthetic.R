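# small, fast configuration for module-level checks
small_config <- function(seed = 3, ...) {
  args <- list(
    seed = seed, n_chromosomes = 2, chromosome_length_bp = 2e5,
    n_circrnas = 30, circ_length_log_mean = log(800), circ_length_log_sd = 0.4,
    n_mirnas = 120, n_diseases = 4, disease_set_size_range = c(8, 12),
    planted_pairs = data.frame(circ = 1:2, disease = 1:2),
    n_mrnas = 40, n_lncrnas = 10)
  over <- list(...)
  for (nm in names(over)) args[nm] <- list(over[[nm]])  # keeps NULLs
  do.call(simulation_config, args)
}

test_that("invalid configurations are rejected", {
  expect_error(simulation_config(background_edge_prob = 0.5,
                                 planted_edge_prob = 0.1),
               "planted_edge_prob < background_edge_prob")
  expect_error(simulation_config(snp_rate_per_kb = 0), "snp_rate_per_kb")
  expect_error(small_config(planted_pairs = data.frame(circ = 99, disease = 1)),
               "planted pair index")
  expect_error(simulation_config(chromosome_length_bp = 10000),
               "length scale too large")
  expect_error(simulation_config(disease_set_size_range = c(10, 5)),
               "disease_set_size_range")
})

test_that("generation is byte-identical for identical config and seed", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_dataset(small_config(seed = 11), dir = d1)
  generate_dataset(small_config(seed = 11), dir = d2)
  files <- list.files(d1)
  expect_setequal(files, list.files(d2))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generate_dataset(small_config(seed = 12), dir = d3)
  expect_false(identical(readLines(file.path(d1, "circrna_loci.bed")),
                         readLines(file.path(d3, "circrna_loci.bed"))))
})

test_that("per-stream sub-seeds isolate the stages from each other", {
  a <- generate_dataset(small_config(seed = 4))
  b <- generate_dataset(small_config(seed = 4, ago_sites_per_circ_mean = 9))
  # changing the Ago stage leaves loci, interactions and SNPs untouched
  expect_identical(as.data.frame(a$loci), as.data.frame(b$loci))
  expect_identical(a$interactions$edges, b$interactions$edges)
  expect_identical(a$snps, b$snps)
  expect_false(identical(length(a$ago_sites), length(b$ago_sites)))
})

test_that("loci are in-bounds and non-overlapping by default", {
  ds <- generate_dataset(small_config(seed = 9))
  loci <- ds$loci
  expect_true(all(GenomicRanges::start(loci) >= 1))
  expect_true(all(GenomicRanges::end(loci) <= 2e5))
  expect_true(all(GenomicRanges::width(loci) >= 50))
  hits <- GenomicRanges::findOverlaps(loci, loci, ignore.strand = TRUE)
  expect_equal(length(hits), length(loci))  # self-hits only
})

test_that("planted truth matches a recount from the emitted tables", {
  ds <- generate_dataset(small_config(seed = 21))
  ed <- ds$interactions$edges
  for (k in seq_len(nrow(ds$truth))) {
    partners <- unique(ed$mirna_id[ed$target_id == ds$truth$circ_id[k] &
                                   ed$target_class == "circRNA"])
    dset <- ds$diseases$map[[ds$truth$disease[k]]]
    expect_equal(ds$truth$realized_m_d[k], length(intersect(partners, dset)))
  }
  # and against the files on disk
  dir <- withr::local_tempdir()
  generate_dataset(small_config(seed = 21), dir = dir)
  tab <- read_interactions(file.path(dir, "interactions.tsv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)$truth
  for (k in seq_len(nrow(truth))) {
    partners <- unique(tab$edges$mirna_id[tab$edges$target_id == truth$circ_id[k] &
                                          tab$edges$target_class == "circRNA"])
    dset <- ds$diseases$map[[truth$disease[k]]]
    expect_equal(truth$realized_m_d[k], length(intersect(partners, dset)))
  }
})

test_that("emitted files are valid pipeline inputs with matching content", {
  dir <- withr::local_tempdir()
  ds <- generate_dataset(small_config(seed = 13), dir = dir)
  loci <- read_bed(file.path(dir, "circrna_loci.bed"))
  expect_equal(as.data.frame(loci)[1:5], as.data.frame(ds$loci)[1:5])
  snps <- read_snps(file.path(dir, "snps_genome.tsv"))
  expect_equal(as.data.frame(snps), as.data.frame(ds$snps))
  tsnp <- read_snps(file.path(dir, "snps_trait.tsv"))
  expect_true(all(nzchar(tsnp$trait)))
  dm <- read_disease_map(file.path(dir, "disease_mirna.tsv"))
  expect_equal(dm$map, ds$diseases$map)
  ago <- read_bed(file.path(dir, "ago_sites.bed"))
  expect_equal(length(ago), length(ds$ago_sites))
  # every simulated SNP and Ago site lies within its generating locus set
  expect_equal(map_points_to_loci(snps, loci)$unique_feature_count, nrow(snps))
  if (length(ago) > 0)
    expect_equal(map_intervals_to_loci(ago, loci)$unique_feature_count,
                 length(ago))
})

test_that("degenerate configurations produce empty but well-formed data", {
  cfg <- small_config(seed = 2, n_circrnas = 0, planted_pairs = NULL)
  ds <- generate_dataset(cfg)
  expect_length(ds$loci, 0)
  expect_equal(nrow(ds$snps), 0)
  expect_length(ds$ago_sites, 0)
  expect_equal(nrow(ds$truth), 0)
  # no background and no planting: zero circRNA edges
  cfg0 <- small_config(seed = 2, background_edge_prob = 0,
                       planted_edge_prob = 0, mrna_lncrna_edge_prob = 0)
  ds0 <- generate_dataset(cfg0)
  expect_equal(nrow(ds0$interactions$edges), 0)
  expect_equal(sum(ds0$truth$realized_m_d), 0)
})

test_that("realized rates sit within 3 standard errors of configured rates", {
  cfg <- simulation_config(seed = 17)
  ds <- generate_dataset(cfg)
  st <- realized_statistics(ds)
  # SNPs: Poisson with mean rate * total kb
  expect_lt(abs(st$n_snps - cfg$snp_rate_per_kb * st$total_locus_kb),
            3 * sqrt(cfg$snp_rate_per_kb * st$total_locus_kb))
  # Ago sites: Poisson mean per circRNA
  se_ago <- sqrt(cfg$ago_sites_per_circ_mean / cfg$n_circrnas)
  expect_lt(abs(st$ago_sites_per_circ - cfg$ago_sites_per_circ_mean),
            3 * se_ago)
  # background Bernoulli edge rate
  n_bg <- cfg$n_mirnas * cfg$n_circrnas - 5 * 30
  se_bg <- sqrt(cfg$background_edge_prob * (1 - cfg$background_edge_prob) / n_bg)
  expect_lt(abs(st$background_edge_rate - cfg$background_edge_prob), 3 * se_bg)
})
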