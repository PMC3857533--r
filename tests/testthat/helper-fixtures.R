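# Shared fixtures and independent naive oracles for the test suite.
# Loci here are described in BED terms (0-based half-open data.frames) and
# converted through the package readers/constructors, so the external
# convention is exercised everywhere.

loci_df_to_granges <- function(df) {
  make_loci(df$id, df$chrom, df$start0, df$end0,
            if (is.null(df$strand)) "*" else df$strand)
}

snps_df <- function(rsid, chrom, pos0, trait = "") {
  df <- data.frame(rsid = rsid, chrom = chrom, pos = as.integer(pos0) + 1L,
                   trait = trait, stringsAsFactors = FALSE)
  class(df) <- c("snp_catalog", "data.frame")
  df
}

rand_loci_df <- function(n, chroms = c("chr1", "chr2"), glen = 100000,
                         max_len = 400, prefix = "L") {
  len <- sample.int(max_len, n, replace = TRUE)
  start0 <- vapply(len, function(l) sample.int(glen - l, 1), integer(1))
  data.frame(id = sprintf("%s%05d", prefix, seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start0 = start0, end0 = start0 + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# strand compatibility under the documented contract: equal, or either "*"
strands_compatible <- function(a, b) a == b | a == "*" | b == "*"

# naive all-pairs oracle for point-in-locus mapping (strand ignored)
naive_point_hits <- function(snps, loci_df) {
  pos0 <- snps$pos - 1L
  out <- lapply(seq_len(nrow(loci_df)), function(i) {
    hit <- snps$chrom == loci_df$chrom[i] &
      pos0 >= loci_df$start0[i] & pos0 < loci_df$end0[i]
    if (!any(hit)) return(NULL)
    data.frame(feature_id = snps$rsid[hit], locus_id = loci_df$id[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), locus_id = character(),
                      stringsAsFactors = FALSE)
  res <- res[order(res$feature_id, res$locus_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# naive all-pairs oracle for interval-overlap mapping (>= 1 shared bp)
naive_interval_hits <- function(sites_df, loci_df, strand_aware) {
  out <- lapply(seq_len(nrow(loci_df)), function(i) {
    ov <- pmin(sites_df$end0, loci_df$end0[i]) -
      pmax(sites_df$start0, loci_df$start0[i])
    hit <- sites_df$chrom == loci_df$chrom[i] & ov >= 1
    if (strand_aware)
      hit <- hit & strands_compatible(sites_df$strand, loci_df$strand[i])
    if (!any(hit)) return(NULL)
    data.frame(feature_id = sites_df$id[hit], locus_id = loci_df$id[i],
               overlap_bp = as.integer(ov[hit]), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(feature_id = character(), locus_id = character(),
                      overlap_bp = integer(), stringsAsFactors = FALSE)
  res <- res[order(res$feature_id, res$locus_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# small interaction fixture: universe {a..e}, circX edges {a,b,c},
# disease "dz" miRNAs {b,c,d}
toy_interactions <- function() {
  interaction_table(
    data.frame(
      mirna_id = c("a", "b", "c", "a", "b"),
      target_id = c("circX", "circX", "circX", "geneG", "lincL"),
      target_class = c("circRNA", "circRNA", "circRNA", "mRNA", "lncRNA"),
      stringsAsFactors = FALSE),
    mirna_universe = c("a", "b", "c", "d", "e"))
}

toy_diseases <- function() {
  disease_mirna_map(list(dz = c("b", "c", "d")))
}

# full hypergeometric parameter grid for one universe size
hyper_grid <- function(MT) {
  g <- expand.grid(m_c = 0:MT, M_d = 0:MT)
  k <- pmin(g$m_c, g$M_d)
  idx <- rep(seq_len(nrow(g)), k + 1)
  data.frame(M_T = MT, m_c = g$m_c[idx], M_d = g$M_d[idx],
             m_d = sequence(k + 1) - 1L)
}
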