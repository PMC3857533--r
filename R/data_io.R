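#' @import GenomicRanges
#' @import IRanges
#' @import S4Vectors
NULL

TARGET_CLASSES <- c("circRNA", "mRNA", "lncRNA")

## ---- genomic loci -----------------------------------------------------------

#' Build a named GRanges of loci from 0-based half-open coordinates
#'
#' Internal coordinate currency is the Bioconductor `GRanges` (1-based,
#' closed). External BED-style coordinates (0-based half-open) are converted
#' here, exactly once; [write_bed()] converts back. A BED interval
#' `[start0, end0)` therefore contains base positions `start0 .. end0 - 1`.
#'
#' @param id character vector of unique locus identifiers.
#' @param chrom chromosome names.
#' @param start0 0-based inclusive starts (bp).
#' @param end0 0-based exclusive ends (bp); must satisfy `start0 < end0`.
#' @param strand `"+"`, `"-"` or `"*"`/`"."` for unstranded.
#' @return A named `GRanges`.
#' @export
#' @examples
#' make_loci("circA", "chr1", 100, 200, "+")
make_loci <- function(id, chrom, start0, end0, strand = "*") {
  strand <- ifelse(strand == ".", "*", strand)
  n <- length(id)
  if (n == 0) {
    gr <- GenomicRanges::GRanges()
    return(gr)
  }
  if (any(duplicated(id)))
    stop("duplicate locus ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  bad <- which(!(start0 >= 0 & start0 < end0))
  if (length(bad))
    stop("invalid interval (need 0 <= start < end) for id(s): ",
         paste(id[head(bad, 5)], collapse = ", "))
  if (any(!nzchar(chrom))) stop("empty chromosome name")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  names(gr) <- id
  gr
}

#' Read a BED6 file of loci
#'
#' Native BED convention: 0-based half-open, strand `"."` meaning unstranded.
#' Lines starting with `#` and empty lines are ignored. Validation is
#' fail-fast: a malformed line raises an error naming its line number.
#'
#' @param path path to a BED file with at least 6 columns
#'   (chrom, chromStart, chromEnd, name, score, strand).
#' @return A named `GRanges` (see [make_loci()]) with a `score` metadata
#'   column.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(lines) & !startsWith(lines, "#"))
  if (!length(keep)) return(make_loci(character(), character(), integer(), integer()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6))
    stop("BED line ", keep[which(nf < 6)[1]], ": expected >= 6 fields, got ",
         nf[which(nf < 6)[1]])
  mat <- t(vapply(fields, function(f) f[1:6], character(6)))
  start0 <- suppressWarnings(as.integer(mat[, 2]))
  end0 <- suppressWarnings(as.integer(mat[, 3]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad))
    stop("BED line ", keep[bad[1]], ": non-integer coordinates")
  bad <- which(!(start0 >= 0 & start0 < end0))
  if (length(bad))
    stop("BED line ", keep[bad[1]], ": need 0 <= chromStart < chromEnd")
  bad <- which(!mat[, 6] %in% c("+", "-", "."))
  if (length(bad))
    stop("BED line ", keep[bad[1]], ": strand must be one of +, -, .")
  gr <- make_loci(mat[, 4], mat[, 1], start0, end0, mat[, 6])
  S4Vectors::mcols(gr)$score <- suppressWarnings(as.numeric(mat[, 5]))
  gr
}

#' Write loci to a BED6 file
#'
#' Inverse of [read_bed()] on (id, chrom, start, end, strand): coordinates are
#' emitted 0-based half-open and unstranded ranges as `"."`. LF line endings.
#'
#' @param gr named `GRanges`; an optional `score` metadata column is written
#'   to column 5 (default 0).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path) {
  stopifnot(is(gr, "GRanges"))
  if (length(gr) && is.null(names(gr))) stop("loci must be named")
  score <- S4Vectors::mcols(gr)$score
  if (is.null(score)) score <- rep(0, length(gr))
  strand_chr <- as.character(GenomicRanges::strand(gr))
  strand_chr[strand_chr == "*"] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   as.character(GenomicRanges::seqnames(gr)),
                   GenomicRanges::start(gr) - 1L,
                   GenomicRanges::end(gr),
                   names(gr),
                   format(score, trim = TRUE, scientific = FALSE),
                   strand_chr)
  writeLines(lines, path, sep = "\n")
  invisible(path)
}

## ---- interaction tables -----------------------------------------------------

#' Construct a miRNA-target interaction table
#'
#' Bipartite miRNA -> target edges with a target class. Duplicate
#' (mirna, target, class) triples are collapsed (a message reports how many):
#' unions of several target-prediction tools routinely repeat edges. The miRNA
#' universe defaults to the miRNAs observed in the edges; supplying an
#' explicit universe makes the total miRNA count M_T controllable, since the
#' number of annotated human miRNAs is release-dependent.
#'
#' @param edges data.frame with columns `mirna_id`, `target_id`,
#'   `target_class` (one of `"circRNA"`, `"mRNA"`, `"lncRNA"`).
#' @param mirna_universe optional character vector of all miRNA ids under
#'   consideration; must contain every edge miRNA.
#' @return An object of class `interaction_table`: a list with `edges`
#'   (deduplicated data.frame) and `mirna_universe` (character).
#' @export
interaction_table <- function(edges, mirna_universe = NULL) {
  stopifnot(is.data.frame(edges))
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% names(edges)))
    stop("edges needs columns: ", paste(need, collapse = ", "))
  edges <- edges[need]
  for (cc in need) edges[[cc]] <- as.character(edges[[cc]])
  bad <- setdiff(unique(edges$target_class), TARGET_CLASSES)
  if (length(bad))
    stop("unknown target_class: ", paste(bad, collapse = ", "),
         " (allowed: ", paste(TARGET_CLASSES, collapse = ", "), ")")
  dup <- duplicated(edges)
  if (any(dup)) {
    message(sum(dup), " duplicate interaction row(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  observed <- unique(edges$mirna_id)
  if (is.null(mirna_universe)) {
    mirna_universe <- sort(observed)
  } else {
    mirna_universe <- unique(as.character(mirna_universe))
    missing <- setdiff(observed, mirna_universe)
    if (length(missing))
      stop("edge miRNA(s) absent from the supplied universe: ",
           paste(head(missing, 5), collapse = ", "))
  }
  structure(list(edges = edges, mirna_universe = mirna_universe),
            class = "interaction_table")
}

#' @export
print.interaction_table <- function(x, ...) {
  cat("interaction_table:", nrow(x$edges), "edges,",
      length(x$mirna_universe), "miRNAs in universe\n")
  tab <- table(factor(x$edges$target_class, levels = TARGET_CLASSES))
  cat("  targets:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read a miRNA-target interaction TSV
#'
#' Tab-separated with header `mirna_id`, `target_id`, `target_class`;
#' `#` comment lines ignored.
#'
#' @inheritParams interaction_table
#' @param path path to the TSV.
#' @param universe_path optional path to a one-column (header `mirna_id`)
#'   universe file fixing M_T explicitly.
#' @return An `interaction_table`.
#' @export
read_interactions <- function(path, universe_path = NULL) {
  df <- read_tsv_checked(path, c("mirna_id", "target_id", "target_class"))
  universe <- NULL
  if (!is.null(universe_path))
    universe <- read_tsv_checked(universe_path, "mirna_id")$mirna_id
  interaction_table(df, universe)
}

#' Write an interaction table to TSV
#' @param x an `interaction_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(x, path) {
  stopifnot(inherits(x, "interaction_table"))
  write_tsv_lf(x$edges, path)
}

## ---- disease -> miRNA maps --------------------------------------------------

#' Construct a disease -> miRNA association map
#'
#' @param map named list: disease name -> character vector of miRNA ids
#'   (each non-empty).
#' @param curated optional named list with the curated subset per disease;
#'   each `curated[[d]]` must be a subset of `map[[d]]`. Diseases absent from
#'   `curated` have no curated information.
#' @return An object of class `disease_mirna_map`.
#' @export
disease_mirna_map <- function(map, curated = NULL) {
  stopifnot(is.list(map))
  if (length(map) && (is.null(names(map)) || any(!nzchar(names(map)))))
    stop("every disease needs a name")
  map <- lapply(map, function(v) sort(unique(as.character(v))))
  if (any(lengths(map) == 0)) stop("empty miRNA set for disease(s): ",
    paste(names(map)[lengths(map) == 0], collapse = ", "))
  if (!is.null(curated)) {
    stopifnot(is.list(curated))
    curated <- lapply(curated, function(v) sort(unique(as.character(v))))
    for (d in names(curated)) {
      if (!d %in% names(map)) stop("curated disease not in map: ", d)
      if (length(setdiff(curated[[d]], map[[d]])))
        stop("curated set for '", d, "' is not a subset of its miRNA set")
    }
  }
  structure(list(map = map, curated = curated), class = "disease_mirna_map")
}

#' @export
print.disease_mirna_map <- function(x, ...) {
  cat("disease_mirna_map:", length(x$map), "diseases,",
      length(unique(unlist(x$map))), "distinct miRNAs",
      if (!is.null(x$curated)) sprintf("(%d curated)", length(x$curated)) else "",
      "\n")
  invisible(x)
}

#' Read a disease -> miRNA association TSV
#'
#' Long format: columns `disease`, `mirna_id` (one association per row).
#'
#' @param path path to the TSV.
#' @param curated_path optional TSV in the same format restricting each
#'   disease to its curated (validated-role) miRNAs.
#' @return A `disease_mirna_map`.
#' @export
read_disease_map <- function(path, curated_path = NULL) {
  df <- read_tsv_checked(path, c("disease", "mirna_id"))
  map <- split(df$mirna_id, df$disease)
  curated <- NULL
  if (!is.null(curated_path)) {
    cdf <- read_tsv_checked(curated_path, c("disease", "mirna_id"))
    curated <- split(cdf$mirna_id, cdf$disease)
  }
  disease_mirna_map(map, curated)
}

#' Write a disease map to TSV (long format)
#' @param x a `disease_mirna_map`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_disease_map <- function(x, path) {
  stopifnot(inherits(x, "disease_mirna_map"))
  df <- data.frame(
    disease = rep(names(x$map), lengths(x$map)),
    mirna_id = unlist(x$map, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  write_tsv_lf(df, path)
}

## ---- SNP catalogs -----------------------------------------------------------

#' Read a SNP catalog TSV
#'
#' Columns `rsid`, `chrom`, `pos` and optionally `trait`. dbSNP/GWAS-catalog
#' style exports are 1-based; the coordinate convention of the file must be
#' declared and is converted exactly once, at read time, to the internal
#' 1-based representation. An empty/missing trait marks a genome-wide catalog
#' entry; any non-empty trait marks a trait-associated (GWAS) SNP.
#'
#' @param path path to the TSV.
#' @param convention `"1-based"` (default, dbSNP/GWAS style) or `"0-based"`.
#' @return data.frame of class `snp_catalog` with columns `rsid`, `chrom`,
#'   `pos` (internal 1-based position) and `trait` (`""` when none).
#' @export
read_snps <- function(path, convention = c("1-based", "0-based")) {
  convention <- match.arg(convention)
  df <- read_tsv_checked(path, c("rsid", "chrom", "pos"), optional = "trait")
  if (is.null(df$trait)) df$trait <- ""
  df$trait[is.na(df$trait)] <- ""
  df$pos <- suppressWarnings(as.numeric(df$pos))
  if (anyNA(df$pos)) stop("non-numeric SNP position in ", path)
  if (convention == "0-based") df$pos <- df$pos + 1
  if (any(df$pos < 1))
    stop("SNP position out of range (", convention, " input): ",
         paste(df$rsid[head(which(df$pos < 1), 5)], collapse = ", "))
  dup <- unique(df$rsid[duplicated(df$rsid)])
  if (length(dup))
    stop("duplicate rsid(s): ", paste(head(dup, 10), collapse = ", "))
  df <- df[c("rsid", "chrom", "pos", "trait")]
  df$pos <- as.integer(df$pos)
  class(df) <- c("snp_catalog", "data.frame")
  df
}

#' Write a SNP catalog to TSV
#'
#' Positions are written in the requested convention (inverse of
#' [read_snps()]).
#'
#' @param snps a `snp_catalog` data.frame.
#' @param path output path.
#' @param convention coordinate convention for the `pos` column on disk.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path, convention = c("1-based", "0-based")) {
  convention <- match.arg(convention)
  df <- as.data.frame(snps)[c("rsid", "chrom", "pos", "trait")]
  if (convention == "0-based") df$pos <- df$pos - 1L
  write_tsv_lf(df, path)
}

#' Read a one-column gene list (header `gene_id`)
#' @param path path to the TSV.
#' @return character vector of unique gene ids.
#' @export
read_gene_list <- function(path) {
  unique(read_tsv_checked(path, "gene_id")$gene_id)
}

## ---- TSV plumbing -----------------------------------------------------------

# Strict TSV reader: header row required, "#" comments skipped, required
# columns checked, character columns kept as-is.
read_tsv_checked <- function(path, required, optional = character()) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", check.names = FALSE,
                          quote = "", stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(path, ": missing column(s): ", paste(missing, collapse = ", "))
  df[c(required, intersect(optional, names(df)))]
}

# All writers: LF endings, no quoting, tab-separated, header row.
write_tsv_lf <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     eol = "\n")
  invisible(path)
}
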