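## Seeded synthetic-data generator. Emits the exact input formats the
## pipeline consumes (BED6 loci, interaction TSV, disease-map TSV, SNP TSVs)
## with a known planted truth, so enrichment, mapping and network stages are
## all verifiable without any external dataset.

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: a universe of
#' 2000 miRNAs, 10 diseases of 30 miRNAs each, 200 circRNA loci with
#' lognormal lengths averaging ~9 kb, background miRNA-circRNA edge
#' probability 0.01 against 0.5 for the five planted (circRNA, disease)
#' pairs, SNPs as a per-locus Poisson process at 24.01 per kb (0.2% of them
#' carrying a trait label), and Poisson(2.658) Ago sites of 20-40 bp per
#' circRNA.
#'
#' @param seed integer root seed; all streams derive from it.
#' @param n_chromosomes,chromosome_length_bp synthetic genome shape.
#' @param n_circrnas number of circRNA loci.
#' @param circ_length_log_mean,circ_length_log_sd lognormal length
#'   parameters (log-bp scale).
#' @param n_mirnas miRNA universe size (M_T).
#' @param n_diseases number of diseases.
#' @param disease_set_size_range inclusive range of per-disease miRNA set
#'   sizes, sampled without replacement from the universe (sets may overlap
#'   between diseases).
#' @param background_edge_prob per-(miRNA, circRNA) background edge
#'   probability pi0.
#' @param planted_pairs data.frame with integer columns `circ` and `disease`
#'   (1-based indices) naming the enriched pairs, or `NULL` for none.
#' @param planted_edge_prob edge probability pi1 (>= pi0) between a planted
#'   circRNA and its disease's miRNAs.
#' @param snp_rate_per_kb Poisson SNP rate per kb of locus.
#' @param trait_snp_fraction fraction of SNPs receiving a trait label drawn
#'   uniformly from the disease names.
#' @param ago_sites_per_circ_mean Poisson mean of Ago sites per circRNA.
#' @param ago_site_length_range inclusive site length range (bp).
#' @param n_mrnas,n_lncrnas numbers of mRNA and lncRNA targets.
#' @param mrna_lncrna_edge_prob per-(miRNA, mRNA/lncRNA) edge probability.
#' @param allow_locus_overlap allow circRNA loci to overlap (default FALSE);
#'   the overlapping mode exercises multiplicity counting in the mapping
#'   stage.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 4L,
                              chromosome_length_bp = 5e6,
                              n_circrnas = 200L,
                              circ_length_log_mean = log(9043) - 0.8^2 / 2,
                              circ_length_log_sd = 0.8,
                              n_mirnas = 2000L,
                              n_diseases = 10L,
                              disease_set_size_range = c(30L, 30L),
                              background_edge_prob = 0.01,
                              planted_pairs = data.frame(circ = 1:5,
                                                         disease = 1:5),
                              planted_edge_prob = 0.5,
                              snp_rate_per_kb = 24.01,
                              trait_snp_fraction = 0.002,
                              ago_sites_per_circ_mean = 2.658,
                              ago_site_length_range = c(20L, 40L),
                              n_mrnas = 500L,
                              n_lncrnas = 150L,
                              mrna_lncrna_edge_prob = 0.01,
                              allow_locus_overlap = FALSE) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chromosome_length_bp = as.numeric(chromosome_length_bp),
              n_circrnas = as.integer(n_circrnas),
              circ_length_log_mean = circ_length_log_mean,
              circ_length_log_sd = circ_length_log_sd,
              n_mirnas = as.integer(n_mirnas),
              n_diseases = as.integer(n_diseases),
              disease_set_size_range = as.integer(disease_set_size_range),
              background_edge_prob = background_edge_prob,
              planted_pairs = planted_pairs,
              planted_edge_prob = planted_edge_prob,
              snp_rate_per_kb = snp_rate_per_kb,
              trait_snp_fraction = trait_snp_fraction,
              ago_sites_per_circ_mean = ago_sites_per_circ_mean,
              ago_site_length_range = as.integer(ago_site_length_range),
              n_mrnas = as.integer(n_mrnas), n_lncrnas = as.integer(n_lncrnas),
              mrna_lncrna_edge_prob = mrna_lncrna_edge_prob,
              allow_locus_overlap = isTRUE(allow_locus_overlap))
  validate_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_config <- function(cfg) {
  with(cfg, {
    if (n_chromosomes < 1 || chromosome_length_bp < 1000)
      stop("config error: genome too small")
    if (any(c(n_circrnas, n_mirnas, n_diseases, n_mrnas, n_lncrnas) < 0))
      stop("config error: negative counts")
    if (circ_length_log_sd < 0) stop("config error: negative length sd")
    if (background_edge_prob < 0 || background_edge_prob > 1 ||
        planted_edge_prob < 0 || planted_edge_prob > 1)
      stop("config error: edge probabilities must lie in [0, 1]")
    if (planted_edge_prob < background_edge_prob)
      stop("config error: planted_edge_prob < background_edge_prob")
    if (snp_rate_per_kb <= 0) stop("config error: snp_rate_per_kb must be > 0")
    if (trait_snp_fraction < 0 || trait_snp_fraction > 1)
      stop("config error: trait_snp_fraction must lie in [0, 1]")
    if (ago_sites_per_circ_mean < 0) stop("config error: negative Ago mean")
    if (diff(disease_set_size_range) < 0 ||
        disease_set_size_range[1] < 1 || disease_set_size_range[2] > n_mirnas)
      stop("config error: disease_set_size_range out of range")
    if (diff(ago_site_length_range) < 0 || ago_site_length_range[1] < 1)
      stop("config error: ago_site_length_range out of range")
    if (!is.null(planted_pairs) && nrow(planted_pairs) > 0) {
      if (any(planted_pairs$circ < 1) || any(planted_pairs$circ > n_circrnas) ||
          any(planted_pairs$disease < 1) ||
          any(planted_pairs$disease > n_diseases))
        stop("config error: planted pair index out of range")
    }
    if (exp(circ_length_log_mean) > chromosome_length_bp / 10)
      stop("config error: circRNA length scale too large for chromosome")
  })
  invisible(cfg)
}

# one fixed sub-seed per stream, drawn once from the root seed, so adding or
# re-running one stage never perturbs another's draws
sub_seeds <- function(seed) {
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, 5L),
           c("loci", "diseases", "edges", "snps", "ago"))
}

circ_ids <- function(n) sprintf("circ%04d", seq_len(n))
mirna_ids <- function(n) sprintf("mir%05d", seq_len(n))
disease_names <- function(n) sprintf("disease%02d", seq_len(n))

#' Simulate circRNA loci
#'
#' Lengths are lognormal (clamped to `[50, chromosome_length_bp / 5]` bp),
#' chromosomes and strands uniform, placement uniform within the chromosome;
#' by default loci are rejection-sampled to be non-overlapping.
#'
#' @param config a [simulation_config()].
#' @return named `GRanges` of `n_circrnas` loci.
#' @export
simulate_loci <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seeds(config$seed)[["loci"]])
  n <- config$n_circrnas
  if (n == 0) return(make_loci(character(), character(), integer(), integer()))
  len <- round(rlnorm(n, config$circ_length_log_mean, config$circ_length_log_sd))
  len <- pmin(pmax(len, 50), floor(config$chromosome_length_bp / 5))
  chrom <- paste0("chr", sample.int(config$n_chromosomes, n, replace = TRUE))
  start0 <- integer(n)
  placed <- list()  # per-chromosome accepted [start0, end0) pairs
  for (i in seq_len(n)) {
    L <- config$chromosome_length_bp - len[i]
    for (try in seq_len(1000)) {
      s <- floor(runif(1, 0, L + 1))
      if (config$allow_locus_overlap) break
      prev <- placed[[chrom[i]]]
      if (is.null(prev) ||
          !any(pmax(prev[, 1], s) < pmin(prev[, 2], s + len[i]))) break
      if (try == 1000)
        stop("config error: cannot place non-overlapping loci; ",
             "genome too crowded")
    }
    start0[i] <- s
    if (!config$allow_locus_overlap)
      placed[[chrom[i]]] <- rbind(placed[[chrom[i]]], c(s, s + len[i]))
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  make_loci(circ_ids(n), chrom, start0, start0 + len, strand)
}

#' Simulate the interaction table, disease map and planted truth
#'
#' Disease miRNA sets are drawn without replacement from the universe and
#' may overlap between diseases. Each (miRNA, circRNA) edge is an
#' independent Bernoulli draw: probability `planted_edge_prob` when the
#' circRNA belongs to a planted pair and the miRNA to that pair's disease
#' set, `background_edge_prob` otherwise. miRNA-mRNA and miRNA-lncRNA edges
#' are Bernoulli at `mrna_lncrna_edge_prob`.
#'
#' @param config a [simulation_config()].
#' @return list with `interactions` (an [interaction_table()] whose universe
#'   is all `n_mirnas` miRNAs), `diseases` (a [disease_mirna_map()]) and
#'   `truth` (data.frame `circ_id`, `disease`, `realized_m_d`: the planted
#'   pairs with their realized disease-miRNA edge counts).
#' @export
simulate_interaction_tables <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seeds <- sub_seeds(config$seed)
  mir <- mirna_ids(config$n_mirnas)
  circ <- circ_ids(config$n_circrnas)
  dis <- disease_names(config$n_diseases)

  set.seed(seeds[["diseases"]])
  rng <- config$disease_set_size_range
  sizes <- if (rng[1] == rng[2]) rep(rng[1], config$n_diseases) else
    sample(rng[1]:rng[2], config$n_diseases, replace = TRUE)
  dmap <- lapply(sizes, function(k) sample(mir, k))
  names(dmap) <- dis

  set.seed(seeds[["edges"]])
  pp <- config$planted_pairs
  prob <- matrix(config$background_edge_prob,
                 nrow = config$n_mirnas, ncol = config$n_circrnas)
  if (!is.null(pp) && nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      rows <- match(dmap[[pp$disease[k]]], mir)
      prob[rows, pp$circ[k]] <- config$planted_edge_prob
    }
  }
  hit <- which(matrix(runif(length(prob)), nrow = nrow(prob)) < prob,
               arr.ind = TRUE)
  circ_edges <- data.frame(mirna_id = mir[hit[, 1]],
                           target_id = circ[hit[, 2]],
                           target_class = rep("circRNA", nrow(hit)),
                           stringsAsFactors = FALSE)
  gene_edges <- local({
    n_t <- config$n_mrnas + config$n_lncrnas
    if (n_t == 0 || config$n_mirnas == 0)
      return(circ_edges[0, ])
    tid <- c(sprintf("gene%05d", seq_len(config$n_mrnas)),
             sprintf("linc%05d", seq_len(config$n_lncrnas)))
    tcl <- rep(c("mRNA", "lncRNA"), c(config$n_mrnas, config$n_lncrnas))
    hit2 <- which(matrix(runif(config$n_mirnas * n_t),
                         nrow = config$n_mirnas) < config$mrna_lncrna_edge_prob,
                  arr.ind = TRUE)
    data.frame(mirna_id = mir[hit2[, 1]], target_id = tid[hit2[, 2]],
               target_class = tcl[hit2[, 2]], stringsAsFactors = FALSE)
  })
  interactions <- interaction_table(rbind(circ_edges, gene_edges),
                                    mirna_universe = mir)
  truth <- if (is.null(pp) || nrow(pp) == 0) {
    data.frame(circ_id = character(), disease = character(),
               realized_m_d = integer(), stringsAsFactors = FALSE)
  } else {
    data.frame(
      circ_id = circ[pp$circ],
      disease = dis[pp$disease],
      realized_m_d = vapply(seq_len(nrow(pp)), function(k) {
        partners <- circ_edges$mirna_id[circ_edges$target_id == circ[pp$circ[k]]]
        length(intersect(unique(partners), dmap[[pp$disease[k]]]))
      }, integer(1)),
      stringsAsFactors = FALSE
    )
  }
  list(interactions = interactions,
       diseases = disease_mirna_map(dmap),
       truth = truth)
}

#' Simulate SNPs as per-locus Poisson processes
#'
#' Each locus receives `Poisson(rate * length_kb)` SNPs placed uniformly
#' within it; a `trait_snp_fraction` of all SNPs get a trait label drawn
#' uniformly from the disease names.
#'
#' @param config a [simulation_config()].
#' @param loci named `GRanges` from [simulate_loci()].
#' @return a `snp_catalog` data.frame (`rsid`, `chrom`, `pos`, `trait`).
#' @export
simulate_snps <- function(config, loci) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seeds(config$seed)[["snps"]])
  counts <- rpois(length(loci),
                  config$snp_rate_per_kb * GenomicRanges::width(loci) / 1000)
  idx <- rep(seq_along(loci), counts)
  n <- length(idx)
  if (n == 0) {
    df <- data.frame(rsid = character(), chrom = character(), pos = integer(),
                     trait = character(), stringsAsFactors = FALSE)
    class(df) <- c("snp_catalog", "data.frame")
    return(df)
  }
  offset <- floor(runif(n) * GenomicRanges::width(loci)[idx])
  pos <- GenomicRanges::start(loci)[idx] + as.integer(offset)
  trait <- rep("", n)
  labelled <- which(runif(n) < config$trait_snp_fraction)
  if (length(labelled) && config$n_diseases > 0)
    trait[labelled] <- sample(disease_names(config$n_diseases),
                              length(labelled), replace = TRUE)
  df <- data.frame(
    rsid = sprintf("rs%07d", seq_len(n)),
    chrom = as.character(GenomicRanges::seqnames(loci))[idx],
    pos = pos, trait = trait, stringsAsFactors = FALSE
  )
  class(df) <- c("snp_catalog", "data.frame")
  df
}

#' Simulate Ago binding sites within circRNA loci
#'
#' Per circRNA the site count is `Poisson(ago_sites_per_circ_mean)`; each
#' site's length is uniform in `ago_site_length_range` (clamped to the locus
#' length) and its placement uniform within the locus, on the locus strand.
#'
#' @inheritParams simulate_snps
#' @return named `GRanges` of Ago sites.
#' @export
simulate_ago_sites <- function(config, loci) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(sub_seeds(config$seed)[["ago"]])
  counts <- rpois(length(loci), config$ago_sites_per_circ_mean)
  idx <- rep(seq_along(loci), counts)
  n <- length(idx)
  if (n == 0) return(make_loci(character(), character(), integer(), integer()))
  rng <- config$ago_site_length_range
  len <- if (rng[1] == rng[2]) rep(rng[1], n) else
    sample(rng[1]:rng[2], n, replace = TRUE)
  w <- GenomicRanges::width(loci)[idx]
  len <- pmin(len, w)
  off <- floor(runif(n) * (w - len + 1))
  start0 <- GenomicRanges::start(loci)[idx] - 1L + as.integer(off)
  make_loci(sprintf("ago%05d", seq_len(n)),
            as.character(GenomicRanges::seqnames(loci))[idx],
            start0, start0 + len,
            as.character(GenomicRanges::strand(loci))[idx])
}

#' Generate a complete synthetic dataset
#'
#' Runs all simulation stages from one root seed and (optionally) writes the
#' pipeline's input files plus a JSON sidecar with the configuration and
#' planted truth. Identical config and seed yield byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param dir output directory (created if needed), or `NULL` to skip
#'   writing. Files: `circrna_loci.bed`, `interactions.tsv`,
#'   `mirna_universe.tsv` (explicit M_T universe), `disease_mirna.tsv`,
#'   `snps_genome.tsv` (full catalog, trait column flags GWAS SNPs),
#'   `snps_trait.tsv` (trait-labelled subset), `ago_sites.bed`,
#'   `truth.json` (config + planted-truth sidecar).
#' @return list with `loci`, `interactions`, `diseases`, `snps`,
#'   `ago_sites`, `truth`, `config` (and `dir` when written).
#' @export
generate_dataset <- function(config, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  loci <- simulate_loci(config)
  tabs <- simulate_interaction_tables(config)
  snps <- simulate_snps(config, loci)
  ago <- simulate_ago_sites(config, loci)
  ds <- list(loci = loci, interactions = tabs$interactions,
             diseases = tabs$diseases, snps = snps, ago_sites = ago,
             truth = tabs$truth, config = config)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_bed(loci, file.path(dir, "circrna_loci.bed"))
    write_interactions(tabs$interactions, file.path(dir, "interactions.tsv"))
    write_tsv_lf(data.frame(mirna_id = tabs$interactions$mirna_universe,
                            stringsAsFactors = FALSE),
                 file.path(dir, "mirna_universe.tsv"))
    write_disease_map(tabs$diseases, file.path(dir, "disease_mirna.tsv"))
    write_snps(snps, file.path(dir, "snps_genome.tsv"))
    write_snps(snps[nzchar(snps$trait), , drop = FALSE],
               file.path(dir, "snps_trait.tsv"))
    write_bed(ago, file.path(dir, "ago_sites.bed"))
    sidecar <- list(config = unclass(config), truth = tabs$truth)
    jsonlite::write_json(sidecar, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    ds$dir <- dir
  }
  ds
}

#' Realized rates of a simulated dataset
#'
#' Recomputes the empirical SNP density per kb, mean Ago sites per circRNA
#' and background edge rate from the generated objects, for comparison with
#' the configured rates.
#'
#' @param dataset list returned by [generate_dataset()].
#' @return list with `snp_density_per_kb`, `ago_sites_per_circ`,
#'   `background_edge_rate`, `n_snps`, `n_ago_sites`, `total_locus_kb`.
#' @export
realized_statistics <- function(dataset) {
  cfg <- dataset$config
  total_kb <- sum(GenomicRanges::width(dataset$loci)) / 1000
  ed <- dataset$interactions$edges
  ed <- ed[ed$target_class == "circRNA", , drop = FALSE]
  # background rate over non-planted (miRNA, circRNA) cells
  n_cells <- cfg$n_mirnas * cfg$n_circrnas
  planted_cells <- 0L
  n_planted_edges <- 0L
  pp <- cfg$planted_pairs
  if (!is.null(pp) && nrow(pp) > 0) {
    for (k in seq_len(nrow(pp))) {
      dset <- dataset$diseases$map[[disease_names(cfg$n_diseases)[pp$disease[k]]]]
      cid <- circ_ids(cfg$n_circrnas)[pp$circ[k]]
      planted_cells <- planted_cells + length(dset)
      n_planted_edges <- n_planted_edges +
        sum(ed$target_id == cid & ed$mirna_id %in% dset)
    }
  }
  bg_cells <- n_cells - planted_cells
  list(
    snp_density_per_kb = if (total_kb > 0) nrow(dataset$snps) / total_kb else 0,
    ago_sites_per_circ = if (length(dataset$loci) > 0)
      length(dataset$ago_sites) / length(dataset$loci) else 0,
    background_edge_rate = if (bg_cells > 0)
      (nrow(ed) - n_planted_edges) / bg_cells else 0,
    n_snps = nrow(dataset$snps),
    n_ago_sites = length(dataset$ago_sites),
    total_locus_kb = total_kb
  )
}
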