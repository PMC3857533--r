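## Interval mapping of SNPs and Ago CLIP sites into circRNA loci.
## All overlap queries run through GenomicRanges::findOverlaps; the
## conventions are: point (SNP) mapping ignores strand, interval (Ago site)
## mapping is strand-aware by default, and "overlap" means >= 1 shared base,
## not containment.

#' Construct a mapping report
#'
#' @param hits data.frame with columns `feature_id`, `locus_id` and, for
#'   interval features, `overlap_bp`; one row per (feature, locus) mapping,
#'   multiplicity included.
#' @param loci the named `GRanges` that was queried (all loci, hit or not).
#' @return object of class `mapping_report`: list with `hits`, `per_locus`
#'   (locus_id, n_hits, length_bp, density_per_kb for every locus),
#'   `unique_feature_count`, `mapped_locus_count`, `mapping_count`,
#'   `mean_per_mapped_locus`.
#' @keywords internal
new_mapping_report <- function(hits, loci) {
  hits <- hits[order(hits$feature_id, hits$locus_id), , drop = FALSE]
  rownames(hits) <- NULL
  n_hits <- integer(length(loci))
  names(n_hits) <- names(loci)
  if (nrow(hits)) {
    tab <- table(hits$locus_id)
    n_hits[names(tab)] <- as.integer(tab)
  }
  len_bp <- GenomicRanges::width(loci)
  per_locus <- data.frame(
    locus_id = names(loci),
    n_hits = as.integer(n_hits),
    length_bp = as.integer(len_bp),
    density_per_kb = if (length(loci)) n_hits / (len_bp / 1000) else numeric(0),
    stringsAsFactors = FALSE
  )
  rownames(per_locus) <- NULL
  mapped <- sum(per_locus$n_hits > 0)
  structure(list(
    hits = hits,
    per_locus = per_locus,
    unique_feature_count = length(unique(hits$feature_id)),
    mapped_locus_count = mapped,
    mapping_count = nrow(hits),
    mean_per_mapped_locus = if (mapped > 0) nrow(hits) / mapped else 0
  ), class = "mapping_report")
}

#' @export
print.mapping_report <- function(x, ...) {
  cat("mapping_report:", x$mapping_count, "mappings of",
      x$unique_feature_count, "features into", x$mapped_locus_count, "of",
      nrow(x$per_locus), "loci\n")
  invisible(x)
}

snps_to_granges <- function(snps) {
  GenomicRanges::GRanges(
    seqnames = snps$chrom,
    ranges = IRanges::IRanges(start = snps$pos, width = 1L),
    strand = "*"
  )
}

# findOverlaps across possibly disjoint seqlevel sets
overlaps <- function(query, subject, ignore_strand) {
  lv <- union(GenomeInfoDb::seqlevels(query), GenomeInfoDb::seqlevels(subject))
  GenomeInfoDb::seqlevels(query) <- lv
  GenomeInfoDb::seqlevels(subject) <- lv
  GenomicRanges::findOverlaps(query, subject, minoverlap = 1L,
                              ignore.strand = ignore_strand)
}

#' Map SNPs (points) into loci
#'
#' A SNP hits a locus when it lies on the same chromosome inside the locus
#' span (half-open in BED terms: a locus `[start0, end0)` contains 0-based
#' positions `start0 .. end0 - 1`). Strand is ignored for point features. A
#' SNP inside several overlapping loci contributes one mapping per locus
#' (multiplicity counting).
#'
#' @param snps a `snp_catalog` data.frame ([read_snps()]).
#' @param loci named `GRanges` of circRNA loci.
#' @return a `mapping_report`.
#' @export
map_points_to_loci <- function(snps, loci) {
  stopifnot(is.data.frame(snps), is(loci, "GRanges"))
  if (nrow(snps) == 0 || length(loci) == 0)
    return(new_mapping_report(
      data.frame(feature_id = character(), locus_id = character(),
                 stringsAsFactors = FALSE), loci))
  ov <- overlaps(snps_to_granges(snps), loci, ignore_strand = TRUE)
  hits <- data.frame(
    feature_id = snps$rsid[S4Vectors::queryHits(ov)],
    locus_id = names(loci)[S4Vectors::subjectHits(ov)],
    stringsAsFactors = FALSE
  )
  new_mapping_report(hits, loci)
}

#' Map interval features (Ago sites) into loci
#'
#' A site hits a locus when they share at least one base on the same
#' chromosome and, when `strand_aware`, on the same strand (an unstranded
#' `*` matches either strand, the `GRanges` convention).
#'
#' @param sites named `GRanges` of interval features (e.g. Ago PAR-CLIP
#'   clusters from [read_bed()]).
#' @param loci named `GRanges` of circRNA loci.
#' @param strand_aware require equal strands (default `TRUE`: CLIP clusters
#'   and circRNAs are stranded).
#' @return a `mapping_report` whose `hits` carry `overlap_bp`.
#' @export
map_intervals_to_loci <- function(sites, loci, strand_aware = TRUE) {
  stopifnot(is(sites, "GRanges"), is(loci, "GRanges"))
  if (length(sites) == 0 || length(loci) == 0)
    return(new_mapping_report(
      data.frame(feature_id = character(), locus_id = character(),
                 overlap_bp = integer(), stringsAsFactors = FALSE), loci))
  ov <- overlaps(sites, loci, ignore_strand = !strand_aware)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ov_bp <- pmin(GenomicRanges::end(sites)[qh], GenomicRanges::end(loci)[sh]) -
    pmax(GenomicRanges::start(sites)[qh], GenomicRanges::start(loci)[sh]) + 1L
  hits <- data.frame(
    feature_id = names(sites)[qh],
    locus_id = names(loci)[sh],
    overlap_bp = as.integer(ov_bp),
    stringsAsFactors = FALSE
  )
  new_mapping_report(hits, loci)
}

#' Count SNPs falling inside Ago sites within each circRNA locus
#'
#' For every circRNA, counts the SNPs whose position lies inside the
#' intersection of an Ago binding site with that circRNA's locus: a SNP in
#' the locus but outside every Ago site, or in an Ago site that does not
#' overlap the locus, is not counted. A SNP covered by several distinct Ago
#' sites within the same circRNA is counted once per circRNA.
#'
#' @inheritParams map_intervals_to_loci
#' @param snps a `snp_catalog` data.frame.
#' @return list with `per_circ` (data.frame `circ_id`, `n_snps` over all
#'   loci), `n_circ_with_snp` and `mean_snps_when_present` (mean count over
#'   circRNAs with at least one such SNP; 0 when none).
#' @export
snps_in_ago_sites_within_circrnas <- function(snps, sites, loci,
                                              strand_aware = TRUE) {
  stopifnot(is.data.frame(snps), is(sites, "GRanges"), is(loci, "GRanges"))
  n_snps <- setNames(integer(length(loci)), names(loci))
  if (length(sites) && length(loci) && nrow(snps)) {
    ov <- overlaps(sites, loci, ignore_strand = !strand_aware)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    if (length(qh)) {
      # intersected site-within-locus pieces, labelled by circRNA
      pieces <- GenomicRanges::GRanges(
        seqnames = GenomicRanges::seqnames(sites)[qh],
        ranges = IRanges::IRanges(
          start = pmax(GenomicRanges::start(sites)[qh],
                       GenomicRanges::start(loci)[sh]),
          end = pmin(GenomicRanges::end(sites)[qh],
                     GenomicRanges::end(loci)[sh])),
        strand = "*"
      )
      ov2 <- overlaps(snps_to_granges(snps), pieces, ignore_strand = TRUE)
      if (length(ov2)) {
        df <- unique(data.frame(
          rsid = snps$rsid[S4Vectors::queryHits(ov2)],
          circ = names(loci)[sh[S4Vectors::subjectHits(ov2)]],
          stringsAsFactors = FALSE))
        tab <- table(df$circ)
        n_snps[names(tab)] <- as.integer(tab)
      }
    }
  }
  with_snp <- sum(n_snps > 0)
  list(
    per_circ = data.frame(circ_id = names(loci), n_snps = as.integer(n_snps),
                          row.names = NULL, stringsAsFactors = FALSE),
    n_circ_with_snp = with_snp,
    mean_snps_when_present = if (with_snp > 0) sum(n_snps) / with_snp else 0
  )
}

#' Density summary statistics for a mapping report
#'
#' Three related figures: the mean number of mappings per locus over all loci
#' (zero-hit loci included); the aggregate density, total mappings divided by
#' the summed locus length in kb; and the mean of the per-locus densities.
#' The last two differ whenever locus lengths vary, and both readings of a
#' "per kb frequency" are reported.
#'
#' @param report a `mapping_report`.
#' @return list with `mean_per_locus_all`, `aggregate_density_per_kb`,
#'   `mean_of_per_locus_densities`.
#' @export
density_statistics <- function(report) {
  stopifnot(inherits(report, "mapping_report"))
  pl <- report$per_locus
  if (nrow(pl) == 0) stop("no loci in report")
  total_kb <- sum(pl$length_bp) / 1000
  if (total_kb <= 0) stop("zero total locus length")
  list(
    mean_per_locus_all = report$mapping_count / nrow(pl),
    aggregate_density_per_kb = report$mapping_count / total_kb,
    mean_of_per_locus_densities = mean(pl$density_per_kb)
  )
}

#' Per-trait breakdown of GWAS SNPs mapped into loci
#'
#' Restricts the catalog to SNPs with a non-empty trait label, maps them into
#' the loci and reports, per trait, the set of loci containing at least one
#' SNP of that trait, plus the global unique-SNP count, mapped-locus count
#' and mean SNPs per mapped locus. The mean counts mappings with
#' multiplicity: a SNP lying in two overlapping loci contributes two events.
#'
#' @inheritParams map_points_to_loci
#' @return list with `per_trait` (named list trait -> character vector of
#'   locus ids), `unique_snp_count`, `mapped_locus_count`,
#'   `mean_snps_per_mapped_locus`, and the underlying `report`.
#' @export
gwas_trait_breakdown <- function(snps, loci) {
  stopifnot(is.data.frame(snps))
  tsnps <- snps[nzchar(snps$trait), , drop = FALSE]
  report <- map_points_to_loci(tsnps, loci)
  per_trait <- list()
  if (nrow(report$hits)) {
    trait_of <- setNames(tsnps$trait, tsnps$rsid)
    df <- data.frame(trait = unname(trait_of[report$hits$feature_id]),
                     locus_id = report$hits$locus_id,
                     stringsAsFactors = FALSE)
    per_trait <- lapply(split(df$locus_id, df$trait),
                        function(v) sort(unique(v)))
  }
  list(
    per_trait = per_trait,
    unique_snp_count = report$unique_feature_count,
    mapped_locus_count = report$mapped_locus_count,
    mean_snps_per_mapped_locus = report$mean_per_mapped_locus,
    report = report
  )
}

#' Overlap count between two gene sets
#'
#' Size of the intersection of two identifier sets (e.g. the protein-coding
#' genes in a disease's miRNA interactome versus a known disease-gene list).
#' Both sets must use the same identifier namespace.
#'
#' @param network_genes,known_genes character vectors of gene ids.
#' @return integer intersection size.
#' @export
gene_overlap_count <- function(network_genes, known_genes) {
  length(intersect(unique(network_genes), unique(known_genes)))
}

#' Write a mapping report to disk
#'
#' Three artifacts: `<prefix>_hits.tsv` (feature_id, locus_id and, when
#' present, overlap_bp), `<prefix>_loci.tsv` (locus_id, n_hits, length_bp,
#' density_per_kb) and `<prefix>_summary.json` with the aggregate statistics
#' including those of [density_statistics()].
#'
#' @param report a `mapping_report`.
#' @param prefix output path prefix.
#' @return character vector of the three paths, invisibly.
#' @export
write_mapping_report <- function(report, prefix) {
  stopifnot(inherits(report, "mapping_report"))
  paths <- paste0(prefix, c("_hits.tsv", "_loci.tsv", "_summary.json"))
  write_tsv_lf(report$hits, paths[1])
  write_tsv_lf(report$per_locus, paths[2])
  summ <- list(
    unique_feature_count = report$unique_feature_count,
    mapped_locus_count = report$mapped_locus_count,
    mapping_count = report$mapping_count,
    mean_per_mapped_locus = report$mean_per_mapped_locus
  )
  if (nrow(report$per_locus) > 0 && sum(report$per_locus$length_bp) > 0)
    summ <- c(summ, density_statistics(report))
  jsonlite::write_json(summ, paths[3], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
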