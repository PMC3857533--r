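test_that("hypergeometric tail matches hand-computed rational values", {
  # sum_{i=2}^{4} C(5,i) C(15,4-i) = 1050 + 150 + 5 = 1205; C(20,4) = 4845
  expect_equal(hypergeom_tail_p(20, 4, 5, 2), 1205 / 4845, tolerance = 1e-13)
  # all five partners disease-associated out of C(50,5) = 2118760 draws
  expect_equal(hypergeom_tail_p(50, 5, 5, 5), 1 / 2118760, tolerance = 1e-13)
  # the exact-rational oracle reproduces both before anything else relies on it
  expect_identical(hypergeom_tail_exact(20, 4, 5, 2), 1205 / 4845)
  expect_identical(hypergeom_tail_exact(50, 5, 5, 5), 1 / 2118760)
  # degenerate tails are certain events
  expect_equal(hypergeom_tail_p(10, 3, 4, 0), 1)
  expect_equal(hypergeom_tail_p(10, 3, 10, 3), 1)
})

test_that("precondition violations name the offending inequality", {
  expect_error(hypergeom_tail_p(0, 0, 0, 0), "M_T >= 1")
  expect_error(hypergeom_tail_p(10, 11, 5, 2), "m_c <= M_T")
  expect_error(hypergeom_tail_p(10, 5, 11, 2), "M_d <= M_T")
  expect_error(hypergeom_tail_p(10, 5, 5, -1), "m_d >= 0")
  expect_error(hypergeom_tail_p(10, 2, 5, 3), "m_d <= min\\(m_c, M_d\\)")
})

test_that("tail agrees with stats::phyper on large random parameter draws", {
  set.seed(11)
  for (i in 1:200) {
    MT <- sample(2:10000, 1)
    mc <- sample(0:MT, 1)
    Md <- sample(0:MT, 1)
    md <- sample(0:min(mc, Md), 1)
    p <- hypergeom_tail_p(MT, mc, Md, md)
    q <- stats::phyper(md - 1, Md, MT - Md, mc, lower.tail = FALSE)
    expect_equal(p, q, tolerance = 1e-10,
                 label = sprintf("p(%d,%d,%d,%d)", MT, mc, Md, md))
  }
})

test_that("tail is a normalized, monotone, symmetric distribution", {
  set.seed(23)
  for (i in 1:100) {
    MT <- sample(1:500, 1)
    mc <- sample(0:MT, 1)
    Md <- sample(0:MT, 1)
    # normalization: tail from zero covers the whole support
    expect_equal(hypergeom_tail_p(MT, mc, Md, 0), 1, tolerance = 1e-12)
    # monotonicity: non-increasing in m_d
    p_seq <- hypergeom_tail_p(MT, mc, Md, 0:min(mc, Md))
    expect_true(all(diff(p_seq) <= 1e-15))
    # duality: swapping m_c and M_d leaves p unchanged
    md <- sample(0:min(mc, Md), 1)
    expect_equal(hypergeom_tail_p(MT, mc, Md, md),
                 hypergeom_tail_p(MT, Md, mc, md), tolerance = 1e-12)
  }
})

test_that("Bonferroni threshold is alpha over the per-disease test count", {
  expect_equal(bonferroni_threshold(1), 0.05)
  expect_equal(bonferroni_threshold(50), 0.001)
  expect_equal(bonferroni_threshold(50, alpha = 0.10), 0.002)
  expect_error(bonferroni_threshold(0), "m >= 1")
})

test_that("count_parameters does the set arithmetic over the universe", {
  counts <- count_parameters(toy_interactions(), toy_diseases(),
                             "circX", "dz")
  expect_equal(counts, c(M_T = 5L, m_c = 3L, M_d = 3L, m_d = 2L))
  expect_error(count_parameters(toy_interactions(), toy_diseases(),
                                "circZ", "dz"), "unknown circRNA")
  expect_error(count_parameters(toy_interactions(), toy_diseases(),
                                "circX", "gout"), "unknown disease")
  # disease set disjoint from the circRNA's partners
  dm <- disease_mirna_map(list(dz2 = c("d", "e")))
  expect_equal(count_parameters(toy_interactions(), dm, "circX", "dz2")[["m_d"]],
               0L)
})

test_that("disease miRNAs outside the universe are dropped before testing", {
  dm <- disease_mirna_map(list(dz = c("b", "c", "zz1", "zz2")))
  expect_message(
    counts <- count_parameters(toy_interactions(), dm, "circX", "dz"),
    "2 disease miRNA\\(s\\) outside the universe")
  expect_equal(counts[["M_d"]], 2L)
})

test_that("association calls recover a planted fully-overlapping circRNA", {
  # universe of 50 miRNAs; disease set of 5; circA hits exactly those 5;
  # two more circRNAs each touch the set, so m = 3 and threshold = 0.05/3
  universe <- sprintf("u%02d", 1:50)
  dset <- universe[1:5]
  edges <- rbind(
    data.frame(mirna_id = dset, target_id = "circA",
               target_class = "circRNA", stringsAsFactors = FALSE),
    data.frame(mirna_id = c(universe[1], universe[10], universe[2]),
               target_id = c("circB", "circB", "circC"),
               target_class = "circRNA", stringsAsFactors = FALSE))
  tab <- interaction_table(edges, mirna_universe = universe)
  dm <- disease_mirna_map(list(dz = dset))
  res <- call_disease_associations(tab, dm)
  expect_equal(nrow(res), 3)
  expect_equal(unique(res$m), 3L)
  expect_equal(unique(res$p_threshold), 0.05 / 3)
  a <- res[res$circ_id == "circA", ]
  expect_equal(a$p_value, 1 / 2118760, tolerance = 1e-12)
  expect_true(a$significant)
  expect_false(any(res$significant[res$circ_id != "circA"]))
  # sorted by (disease, ascending p, circ_id)
  expect_equal(res$circ_id[1], "circA")
})

test_that("diseases without circRNA edges are absent; empty sets warn", {
  universe <- c("a", "b")
  tab <- interaction_table(
    data.frame(mirna_id = "a", target_id = "circA",
               target_class = "circRNA", stringsAsFactors = FALSE),
    mirna_universe = universe)
  dm <- disease_mirna_map(list(hit = "a", nohit = "b"))
  res <- call_disease_associations(tab, dm)
  expect_equal(unique(res$disease), "hit")
  # curation requested but undefined: every disease skipped with a warning
  w <- testthat::capture_warnings(
    res2 <- call_disease_associations(tab, dm, curated_only = TRUE))
  expect_length(w, 2)
  expect_match(w, "empty miRNA set after curation", all = TRUE)
  expect_equal(nrow(res2), 0)
  # empty disease map: empty results, no crash
  expect_equal(nrow(call_disease_associations(tab, disease_mirna_map(list()))),
               0)
})

test_that("enrichment TSV round-trips at full precision", {
  res <- call_disease_associations(toy_interactions(), toy_diseases())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_enrichment(res, path)
  back <- read_enrichment(path)
  expect_equal(back$p_value, res$p_value, tolerance = 1e-11)
  expect_equal(back[c("circ_id", "disease", "M_T", "m_c", "M_d", "m_d", "m",
                      "significant")],
               res[c("circ_id", "disease", "M_T", "m_c", "M_d", "m_d", "m",
                     "significant")])
  # p-values printed in scientific notation with >= 12 significant digits
  raw <- read.delim(path, colClasses = "character")
  expect_true(all(grepl("^\\d\\.\\d{12}e[+-]\\d+$", raw$p_value)))
})
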