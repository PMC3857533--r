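## Pipeline wiring: run_* functions compose the modules end to end with
## deterministic outputs; circenrich_main() exposes them as shell
## subcommands (simulate, associate, map, network, stats) driven by a YAML
## config whose keys any CLI flag overrides.

#' Read a pipeline YAML configuration
#'
#' Recognised top-level keys: `inputs` (paths: `circrna_bed`,
#' `interactions`, `disease_map`, `curated_map`, `snps`, `ago_bed`,
#' `universe`), `simulate` (any [simulation_config()] argument), `out`
#' (output directory), and the flags `alpha`, `seed`, `curated_only`,
#' `strand_aware`, `coordinate_convention`.
#'
#' @param path YAML file path, or `NULL` for an empty config.
#' @return named list of settings.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  defaults <- list(alpha = 0.05, seed = 1L, curated_only = FALSE,
                   strand_aware = TRUE, coordinate_convention = "1-based",
                   out = "circenrich_out")
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$alpha <= 0 || cfg$alpha >= 1) stop("config error: alpha not in (0,1)")
  cfg
}

#' Run the simulate stage
#'
#' @param config pipeline config list ([read_pipeline_config()]); its
#'   `simulate` block is passed to [simulation_config()], with `seed`
#'   inherited from the top level when not set there.
#' @param out output directory (defaults to `config$out`).
#' @return the dataset list from [generate_dataset()], invisibly.
#' @export
run_simulate <- function(config = read_pipeline_config(), out = config$out) {
  args <- config$simulate
  if (is.null(args)) args <- list()
  if (is.null(args$seed)) args$seed <- config$seed
  if (!is.null(args$planted_pairs) && !is.data.frame(args$planted_pairs))
    args$planted_pairs <- as.data.frame(args$planted_pairs)
  sim <- do.call(simulation_config, args)
  ds <- generate_dataset(sim, dir = out)
  message("simulate: ", length(ds$loci), " loci, ",
          nrow(ds$interactions$edges), " edges, ", nrow(ds$snps), " SNPs, ",
          length(ds$ago_sites), " Ago sites -> ", out)
  invisible(ds)
}

#' Run the disease-association stage
#'
#' Reads the interaction table and disease map, calls
#' [call_disease_associations()] and writes `associations.tsv`.
#'
#' @param config pipeline config list with `inputs$interactions` and
#'   `inputs$disease_map` (plus optional `inputs$universe`,
#'   `inputs$curated_map`).
#' @param out output directory.
#' @return the results data.frame, invisibly.
#' @export
run_associate <- function(config, out = config$out) {
  ins <- required_inputs(config, c("interactions", "disease_map"))
  interactions <- read_interactions(ins$interactions,
                                    universe_path = config$inputs$universe)
  diseases <- read_disease_map(ins$disease_map,
                               curated_path = config$inputs$curated_map)
  message("associate: ", nrow(interactions$edges), " edges, ",
          length(interactions$mirna_universe), " miRNAs, ",
          length(diseases$map), " diseases, alpha = ", config$alpha)
  res <- call_disease_associations(interactions, diseases,
                                   curated_only = isTRUE(config$curated_only),
                                   alpha = config$alpha)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_enrichment(res, file.path(out, "associations.tsv"))
  message("associate: ", nrow(res), " tests, ", sum(res$significant),
          " significant -> ", file.path(out, "associations.tsv"))
  invisible(res)
}

#' Run the genomic mapping stage
#'
#' Maps the SNP catalog (and its trait-labelled subset) and, when supplied,
#' the Ago sites into the circRNA loci; writes per-hit/per-locus TSVs and a
#' JSON summary per mapping, plus `mapping_summary.json` with all aggregate
#' statistics.
#'
#' @param config pipeline config list with `inputs$circrna_bed` and
#'   `inputs$snps` (optional `inputs$ago_bed`).
#' @param out output directory.
#' @return list of the reports and the summary, invisibly.
#' @export
run_map <- function(config, out = config$out) {
  ins <- required_inputs(config, c("circrna_bed", "snps"))
  loci <- read_bed(ins$circrna_bed)
  snps <- read_snps(ins$snps, convention = config$coordinate_convention)
  if (length(loci) && nrow(snps) &&
      !any(unique(snps$chrom) %in% unique(as.character(GenomicRanges::seqnames(loci)))))
    warning("no chromosome name shared between SNP catalog and loci: ",
            "all point mappings will be empty", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  message("map: ", length(loci), " loci, ", nrow(snps), " SNPs (",
          sum(nzchar(snps$trait)), " trait-labelled)")

  snp_report <- map_points_to_loci(snps, loci)
  write_mapping_report(snp_report, file.path(out, "snps"))
  gwas <- gwas_trait_breakdown(snps, loci)
  write_mapping_report(gwas$report, file.path(out, "gwas_snps"))

  summ <- list(
    snps = c(list(unique_feature_count = snp_report$unique_feature_count,
                  mapped_locus_count = snp_report$mapped_locus_count,
                  mapping_count = snp_report$mapping_count,
                  mean_per_mapped_locus = snp_report$mean_per_mapped_locus),
             if (length(loci)) density_statistics(snp_report)),
    gwas_snps = list(unique_snp_count = gwas$unique_snp_count,
                     mapped_locus_count = gwas$mapped_locus_count,
                     mean_snps_per_mapped_locus = gwas$mean_snps_per_mapped_locus,
                     n_traits = length(gwas$per_trait))
  )
  reports <- list(snps = snp_report, gwas = gwas)
  if (!is.null(config$inputs$ago_bed)) {
    sites <- read_bed(config$inputs$ago_bed)
    ago_report <- map_intervals_to_loci(sites, loci,
                                        strand_aware = isTRUE(config$strand_aware))
    write_mapping_report(ago_report, file.path(out, "ago_sites"))
    in_ago <- snps_in_ago_sites_within_circrnas(
      snps, sites, loci, strand_aware = isTRUE(config$strand_aware))
    write_tsv_lf(in_ago$per_circ, file.path(out, "snps_in_ago_per_circ.tsv"))
    summ$ago_sites <- list(
      mapped_locus_count = ago_report$mapped_locus_count,
      mapping_count = ago_report$mapping_count,
      mean_per_mapped_locus = ago_report$mean_per_mapped_locus)
    summ$snps_in_ago_sites <- list(
      n_circ_with_snp = in_ago$n_circ_with_snp,
      mean_snps_when_present = in_ago$mean_snps_when_present)
    reports$ago <- ago_report
    reports$snps_in_ago <- in_ago
  } else {
    message("map: no Ago BED supplied; Ago sections omitted")
  }
  jsonlite::write_json(summ, file.path(out, "mapping_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  reports$summary <- summ
  invisible(reports)
}

#' Run the network construction stage
#'
#' Builds the per-disease network(s) and writes, per disease, a SIF file, a
#' GraphML file, the node attribute table and a degree summary TSV.
#'
#' @param config pipeline config list with `inputs$interactions` and
#'   `inputs$disease_map`.
#' @param disease disease name, or `NULL` for all diseases in the map.
#' @param out output directory.
#' @return named list of `disease_network` objects, invisibly.
#' @export
run_network <- function(config, disease = NULL, out = config$out) {
  ins <- required_inputs(config, c("interactions", "disease_map"))
  interactions <- read_interactions(ins$interactions,
                                    universe_path = config$inputs$universe)
  diseases <- read_disease_map(ins$disease_map,
                               curated_path = config$inputs$curated_map)
  todo <- if (is.null(disease)) names(diseases$map) else disease
  unknown <- setdiff(todo, names(diseases$map))
  if (length(unknown))
    stop("unknown disease: ", paste(unknown, collapse = ", "),
         " (available: ", paste(names(diseases$map), collapse = ", "), ")")
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  nets <- list()
  for (d in todo) {
    net <- build_disease_network(d, diseases, interactions,
                                 curated_only = isTRUE(config$curated_only))
    stem <- file.path(out, gsub("[^A-Za-z0-9_.-]", "_", d))
    export_sif(net, paste0(stem, ".sif"))
    export_graphml(net, paste0(stem, ".graphml"))
    export_node_table(net, paste0(stem, "_nodes.tsv"))
    degsum <- network_degree_summary(net)
    write_tsv_lf(degsum$degrees, paste0(stem, "_degrees.tsv"))
    message("network '", d, "': ", nrow(net$nodes), " nodes, ",
            nrow(net$edges), " edges (",
            paste(names(degsum$class_counts), degsum$class_counts,
                  sep = "=", collapse = ", "), ")")
    nets[[d]] <- net
  }
  invisible(nets)
}

required_inputs <- function(config, keys) {
  ins <- config$inputs
  missing <- keys[vapply(keys, function(k) is.null(ins[[k]]), logical(1))]
  if (length(missing))
    stop("missing input(s) in config: ", paste(missing, collapse = ", "))
  for (k in keys) if (!file.exists(ins[[k]]))
    stop("input file not found: ", ins[[k]])
  ins[keys]
}

#' Command-line entry point
#'
#' `circenrich_main(c("simulate", "--out", "d", "--seed", "7"))` etc.
#' Subcommands: `simulate`, `associate`, `map`, `network`, `stats`. Global
#' flags: `--config`, `--out`, `--seed`, `--alpha`, `--curated-only`,
#' `--no-strand-aware`, `--disease`/`--all` (network), plus per-input path
#' flags `--bed`, `--interactions`, `--disease-map`, `--snps`, `--ago-bed`.
#' Every flag overrides the corresponding config key.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly (0 on success, 2 on error).
#' @export
circenrich_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: circenrich <simulate|associate|map|network|stats> [options]\n")
    return(invisible(if (length(args)) 0L else 2L))
  }
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--out", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = NULL),
    optparse::make_option("--alpha", type = "double", default = NULL),
    optparse::make_option("--curated-only", action = "store_true",
                          dest = "curated_only", default = NULL),
    optparse::make_option("--strand-aware", action = "store_true",
                          dest = "strand_aware", default = NULL),
    optparse::make_option("--no-strand-aware", action = "store_false",
                          dest = "strand_aware", default = NULL),
    optparse::make_option("--disease", type = "character", default = NULL),
    optparse::make_option("--all", action = "store_true", default = FALSE),
    optparse::make_option("--bed", type = "character", default = NULL),
    optparse::make_option("--interactions", type = "character", default = NULL),
    optparse::make_option("--disease-map", type = "character",
                          dest = "disease_map", default = NULL),
    optparse::make_option("--snps", type = "character", default = NULL),
    optparse::make_option("--ago-bed", type = "character", dest = "ago_bed",
                          default = NULL),
    optparse::make_option("--universe", type = "character", default = NULL),
    optparse::make_option("--convention", type = "character", default = NULL)
  )
  status <- tryCatch({
    parsed <- optparse::parse_args(
      optparse::OptionParser(option_list = opts), args = args[-1])
    config <- read_pipeline_config(parsed$config)
    for (k in c("out", "seed", "alpha", "curated_only", "strand_aware"))
      if (!is.null(parsed[[k]])) config[[k]] <- parsed[[k]]
    if (!is.null(parsed$convention)) config$coordinate_convention <- parsed$convention
    if (is.null(config$inputs)) config$inputs <- list()
    path_map <- c(bed = "circrna_bed", interactions = "interactions",
                  disease_map = "disease_map", snps = "snps",
                  ago_bed = "ago_bed", universe = "universe")
    for (k in names(path_map))
      if (!is.null(parsed[[k]])) config$inputs[[path_map[[k]]]] <- parsed[[k]]
    switch(cmd,
      simulate = run_simulate(config),
      associate = run_associate(config),
      map = run_map(config),
      network = run_network(config,
        disease = if (isTRUE(parsed$all)) NULL else {
          if (is.null(parsed$disease))
            stop("network: give --disease <name> or --all")
          parsed$disease
        }),
      stats = {
        ins <- required_inputs(config, "circrna_bed")
        loci <- read_bed(ins$circrna_bed)
        cat(jsonlite::toJSON(list(
          n_loci = length(loci),
          total_locus_kb = sum(GenomicRanges::width(loci)) / 1000,
          mean_locus_bp = if (length(loci)) mean(GenomicRanges::width(loci)) else 0
        ), auto_unbox = TRUE, digits = NA, pretty = TRUE), "\n")
      },
      stop("unknown subcommand: ", cmd)
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  invisible(status)
}
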