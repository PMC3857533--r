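test_that("point mapping honours half-open boundaries of a BED locus", {
  loci <- make_loci("circA", "chr1", 100, 200, "+")
  snps <- snps_df(sprintf("rs%d", 1:5), "chr1", c(99, 100, 150, 199, 200))
  report <- map_points_to_loci(snps, loci)
  expect_equal(report$hits$feature_id, c("rs2", "rs3", "rs4"))
  expect_equal(report$mapping_count, 3)
  expect_equal(report$unique_feature_count, 3)
  # wrong chromosome never hits
  off <- snps_df("rs9", "chr2", 150)
  expect_equal(map_points_to_loci(off, loci)$mapping_count, 0)
})

test_that("a SNP inside two overlapping loci maps with multiplicity", {
  loci <- loci_df_to_granges(data.frame(
    id = c("c1", "c2"), chrom = "chr1", start0 = c(100, 140),
    end0 = c(200, 260), strand = "+", stringsAsFactors = FALSE))
  report <- map_points_to_loci(snps_df("rs1", "chr1", 150), loci)
  expect_equal(report$unique_feature_count, 1)
  expect_equal(report$mapping_count, 2)
  expect_equal(report$mapped_locus_count, 2)
  expect_equal(report$mean_per_mapped_locus, 1)
})

test_that("interval mapping needs >= 1 shared base and respects strand", {
  locus <- make_loci("circA", "chr1", 100, 200, "+")
  # 1-bp overlap at the last base of the locus
  edge_site <- make_loci("s1", "chr1", 199, 250, "+")
  report <- map_intervals_to_loci(edge_site, locus)
  expect_equal(report$mapping_count, 1)
  expect_equal(report$hits$overlap_bp, 1L)
  # adjacent but disjoint: no hit
  expect_equal(map_intervals_to_loci(
    make_loci("s2", "chr1", 200, 250, "+"), locus)$mapping_count, 0)
  # identical span, opposite strand
  anti <- make_loci("s3", "chr1", 100, 200, "-")
  expect_equal(map_intervals_to_loci(anti, locus, strand_aware = TRUE)$mapping_count, 0)
  expect_equal(map_intervals_to_loci(anti, locus, strand_aware = FALSE)$mapping_count, 1)
})

test_that("SNPs are counted only inside Ago-site/locus intersections", {
  loci <- make_loci("circA", "chr1", 0, 1000, "+")
  sites <- loci_df_to_granges(data.frame(
    id = c("a1", "a2", "a3"), chrom = "chr1",
    start0 = c(100, 500, 2000), end0 = c(130, 540, 2030), strand = "+",
    stringsAsFactors = FALSE))
  snps <- snps_df(sprintf("rs%d", 1:5), "chr1", c(110, 120, 520, 900, 2010))
  res <- snps_in_ago_sites_within_circrnas(snps, sites, loci)
  # rs4 is in the circRNA but outside every site; rs5 is in a site (a3)
  # that does not overlap the circRNA
  expect_equal(res$per_circ$n_snps, 3L)
  expect_equal(res$n_circ_with_snp, 1)
  expect_equal(res$mean_snps_when_present, 3)
})

test_that("density statistics distinguish aggregate and mean-of-densities", {
  loci <- loci_df_to_granges(data.frame(
    id = c("c1", "c2"), chrom = "chr1", start0 = c(0, 5000),
    end0 = c(1000, 8000), strand = "+", stringsAsFactors = FALSE))
  snps <- snps_df(sprintf("rs%d", 1:10), "chr1",
                  c(10, 20, 30, 40, 50, 5010, 5020, 5030, 5040, 5050))
  stats <- density_statistics(map_points_to_loci(snps, loci))
  expect_equal(stats$mean_per_locus_all, 5)
  expect_equal(stats$aggregate_density_per_kb, 10 / 4)
  expect_equal(stats$mean_of_per_locus_densities, (5 / 1 + 5 / 3) / 2)
  # zero mappings: all statistics zero; single locus: the two densities agree
  none <- density_statistics(map_points_to_loci(snps_df("rs0", "chrX", 5), loci))
  expect_equal(unlist(none), c(mean_per_locus_all = 0,
                               aggregate_density_per_kb = 0,
                               mean_of_per_locus_densities = 0))
  one <- density_statistics(map_points_to_loci(snps, loci[1]))
  expect_equal(one$aggregate_density_per_kb, one$mean_of_per_locus_densities)
})

test_that("GWAS breakdown uses trait labels and multiplicity counting", {
  loci <- loci_df_to_granges(data.frame(
    id = c("c1", "c2"), chrom = "chr1", start0 = c(100, 140),
    end0 = c(200, 260), stringsAsFactors = FALSE))
  snps <- snps_df(c("rs1", "rs2"), "chr1", c(150, 150), c("asthma", ""))
  bd <- gwas_trait_breakdown(snps, loci)
  expect_equal(bd$per_trait, list(asthma = c("c1", "c2")))
  expect_equal(bd$unique_snp_count, 1)
  expect_equal(bd$mapped_locus_count, 2)
  expect_equal(bd$mean_snps_per_mapped_locus, 1)
  # untraited rs2 contributes nothing; all-untraited catalog is empty
  bd0 <- gwas_trait_breakdown(snps_df("rs3", "chr1", 150, ""), loci)
  expect_equal(length(bd0$per_trait), 0)
  expect_equal(bd0$unique_snp_count, 0)
})

test_that("gene overlap count is plain set intersection", {
  expect_equal(gene_overlap_count(c("A", "B", "C"), c("B", "C", "D")), 2)
  expect_equal(gene_overlap_count(c("A", "A"), c("A")), 1)
  expect_equal(gene_overlap_count(character(), c("A")), 0)
})

test_that("reports conserve counts and are permutation-invariant", {
  set.seed(31)
  for (i in 1:10) {
    loci_df <- rand_loci_df(40)
    snps <- snps_df(sprintf("rs%04d", 1:300),
                    sample(c("chr1", "chr2"), 300, TRUE),
                    sample.int(100000, 300) - 1L)
    loci <- loci_df_to_granges(loci_df)
    report <- map_points_to_loci(snps, loci)
    expect_equal(sum(report$per_locus$n_hits), report$mapping_count)
    expect_lte(report$unique_feature_count, report$mapping_count)
    expect_equal(report$mapped_locus_count, sum(report$per_locus$n_hits > 0))
    # shuffling input order changes nothing
    perm <- sample(nrow(snps))
    report2 <- map_points_to_loci(snps[perm, ], loci[sample(length(loci))])
    expect_equal(report2$hits, report$hits)
    expect_equal(report2$per_locus[order(report2$per_locus$locus_id), ],
                 report$per_locus[order(report$per_locus$locus_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("mapping reports serialize to hit/locus TSVs plus a JSON summary", {
  loci <- make_loci(c("c1", "c2"), "chr1", c(0, 5000), c(1000, 8000), "+")
  snps <- snps_df(sprintf("rs%d", 1:4), "chr1", c(10, 20, 5010, 9999))
  report <- map_points_to_loci(snps, loci)
  prefix <- file.path(withr::local_tempdir(), "snps")
  write_mapping_report(report, prefix)
  hits <- read.delim(paste0(prefix, "_hits.tsv"))
  expect_equal(nrow(hits), 3)
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(summ$mapping_count, 3)
  expect_equal(summ$aggregate_density_per_kb, 3 / 4)
})
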