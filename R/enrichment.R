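#' Hypergeometric upper-tail p-value for circRNA-disease enrichment
#'
#' The chance of drawing at least `m_d` disease-associated miRNAs when the
#' `m_c` interaction partners of a circRNA are drawn without replacement from
#' a universe of `M_T` miRNAs of which `M_d` are associated with the disease:
#'
#' \deqn{p = \sum_{i=m_d}^{\min(m_c, M_d)}
#'   \frac{\binom{M_d}{i}\binom{M_T-M_d}{m_c-i}}{\binom{M_T}{m_c}}}
#'
#' Evaluation is in log space (log-gamma binomials, max-shifted
#' exponentiation, compensated accumulation), numerically stable for
#' universes of at least tens of thousands of miRNAs. All arguments are
#' vectorized and recycled to a common length.
#'
#' @param M_T total number of miRNAs in the universe (>= 1).
#' @param m_c number of miRNAs interacting with the circRNA (<= `M_T`).
#' @param M_d number of miRNAs associated with the disease (<= `M_T`).
#' @param m_d number of disease miRNAs interacting with the circRNA
#'   (`0 <= m_d <= min(m_c, M_d)`).
#' @return numeric vector of p-values in (0, 1].
#' @seealso [hypergeom_tail_exact()] for the exact-rational reference
#'   evaluator, [bonferroni_threshold()] for the significance cutoff.
#' @export
#' @examples
#' hypergeom_tail_p(20, 4, 5, 2)   # 1205/4845
#' hypergeom_tail_p(50, 5, 5, 5)   # 1/choose(50, 5)
hypergeom_tail_p <- function(M_T, m_c, M_d, m_d) {
  p <- check_hyper_args(M_T, m_c, M_d, m_d)
  cpp_hyper_tail(p$M_T, p$m_c, p$M_d, p$m_d)
}

#' Exact-rational hypergeometric tail (reference evaluator)
#'
#' Computes the same tail sum as [hypergeom_tail_p()] by exact integer
#' arithmetic: binomial coefficients from an integer Pascal triangle and an
#' exactly accumulated numerator, divided in extended precision. Restricted
#' to `M_T <= 62` (the exact-integer range); intended for validation, not for
#' the production path.
#'
#' @inheritParams hypergeom_tail_p
#' @return numeric vector of p-values.
#' @export
hypergeom_tail_exact <- function(M_T, m_c, M_d, m_d) {
  p <- check_hyper_args(M_T, m_c, M_d, m_d)
  cpp_hyper_tail_exact(p$M_T, p$m_c, p$M_d, p$m_d)
}

check_hyper_args <- function(M_T, m_c, M_d, m_d) {
  n <- max(length(M_T), length(m_c), length(M_d), length(m_d))
  M_T <- as.integer(rep_len(M_T, n)); m_c <- as.integer(rep_len(m_c, n))
  M_d <- as.integer(rep_len(M_d, n)); m_d <- as.integer(rep_len(m_d, n))
  if (anyNA(M_T) || anyNA(m_c) || anyNA(M_d) || anyNA(m_d))
    stop("NA in hypergeometric parameters")
  if (any(M_T < 1)) stop("violated: M_T >= 1")
  if (any(m_c < 0) || any(m_c > M_T)) stop("violated: 0 <= m_c <= M_T")
  if (any(M_d < 0) || any(M_d > M_T)) stop("violated: 0 <= M_d <= M_T")
  if (any(m_d < 0)) stop("violated: m_d >= 0")
  if (any(m_d > pmin(m_c, M_d))) stop("violated: m_d <= min(m_c, M_d)")
  list(M_T = M_T, m_c = m_c, M_d = M_d, m_d = m_d)
}

#' Per-disease Bonferroni significance threshold
#'
#' `alpha / m`, where `m` is the number of circRNAs tested for the disease
#' (those interacting with at least one of its miRNAs). A disease with no
#' interacting circRNA is never tested, so `m >= 1` is required.
#'
#' @param m number of circRNAs tested for the disease (>= 1), vectorized.
#' @param alpha family-wise error level (default 0.05).
#' @return numeric vector of thresholds.
#' @export
#' @examples
#' bonferroni_threshold(50)  # 0.001
bonferroni_threshold <- function(m, alpha = 0.05) {
  m <- as.integer(m)
  if (anyNA(m) || any(m < 1))
    stop("violated: m >= 1 (a disease with no interacting circRNA is never tested)")
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  alpha / m
}

#' Count the four hypergeometric parameters for one (circRNA, disease) pair
#'
#' `M_T` is the size of the miRNA universe; `m_c` the number of miRNAs with
#' an edge to the circRNA; `M_d` the disease's miRNA set intersected with the
#' universe (disease miRNAs absent from the universe cannot appear in any
#' draw and are dropped, with a message reporting how many); `m_d` the
#' overlap of the two.
#'
#' @param interactions an [interaction_table()].
#' @param diseases a [disease_mirna_map()].
#' @param circ_id circRNA identifier (must appear as a circRNA-class target).
#' @param disease disease name (must be present in the map).
#' @param curated_only restrict the disease's miRNAs to its curated subset.
#' @return named integer vector `c(M_T, m_c, M_d, m_d)`.
#' @export
count_parameters <- function(interactions, diseases, circ_id, disease,
                             curated_only = FALSE) {
  stopifnot(inherits(interactions, "interaction_table"),
            inherits(diseases, "disease_mirna_map"))
  ed <- interactions$edges
  circ_edges <- ed$mirna_id[ed$target_id == circ_id & ed$target_class == "circRNA"]
  if (!length(circ_edges)) stop("unknown circRNA (no circRNA-class edges): ", circ_id)
  dset <- disease_mirnas(diseases, disease, curated_only)
  if (is.null(dset)) stop("unknown disease: ", disease)
  universe <- interactions$mirna_universe
  dropped <- length(setdiff(dset, universe))
  if (dropped > 0)
    message(dropped, " disease miRNA(s) outside the universe dropped for '",
            disease, "'")
  dset <- intersect(dset, universe)
  circ_set <- unique(circ_edges)
  c(M_T = length(universe), m_c = length(circ_set),
    M_d = length(dset), m_d = length(intersect(dset, circ_set)))
}

# Disease miRNA set under the optional curation filter; NULL if the disease
# is absent, character(0) if curation is requested but undefined for it.
disease_mirnas <- function(diseases, disease, curated_only) {
  if (!disease %in% names(diseases$map)) return(NULL)
  if (!curated_only) return(diseases$map[[disease]])
  if (is.null(diseases$curated) || !disease %in% names(diseases$curated))
    return(character(0))
  diseases$curated[[disease]]
}

#' Call circRNA-disease associations across all diseases
#'
#' For each disease with at least one interacting circRNA: every circRNA
#' having an edge to at least one of the disease's miRNAs is tested (their
#' number is `m`), each receives the hypergeometric tail p-value of
#' [hypergeom_tail_p()], and significance is called by strict comparison
#' against the per-disease Bonferroni threshold `alpha / m`. Diseases whose
#' miRNA set is empty after the optional curation filter (or after
#' restriction to the universe) are skipped with a warning; `m` is always
#' recomputed after filtering. circRNAs with no miRNA edge at all are never
#' tested.
#'
#' @inheritParams count_parameters
#' @param alpha family-wise error level for the Bonferroni threshold.
#' @return data.frame with columns `circ_id`, `disease`, `M_T`, `m_c`, `M_d`,
#'   `m_d`, `p_value`, `m`, `p_threshold`, `significant`, sorted by
#'   (disease, ascending p, circ_id).
#' @export
call_disease_associations <- function(interactions, diseases,
                                      curated_only = FALSE, alpha = 0.05) {
  stopifnot(inherits(interactions, "interaction_table"),
            inherits(diseases, "disease_mirna_map"))
  ed <- interactions$edges
  ed <- ed[ed$target_class == "circRNA", , drop = FALSE]
  universe <- interactions$mirna_universe
  M_T <- length(universe)
  # per-circRNA miRNA sets, deduplicated once
  key <- !duplicated(ed[c("mirna_id", "target_id")])
  ed <- ed[key, , drop = FALSE]
  circ_sets <- split(ed$mirna_id, ed$target_id)
  m_c_all <- lengths(circ_sets)
  out <- vector("list", length(diseases$map))
  names(out) <- names(diseases$map)
  for (d in names(diseases$map)) {
    dset <- disease_mirnas(diseases, d, curated_only)
    dset <- intersect(dset, universe)
    if (!length(dset)) {
      warning("disease '", d, "' skipped: empty miRNA set",
              if (curated_only) " after curation filter" else "",
              call. = FALSE)
      next
    }
    m_d <- vapply(circ_sets, function(s) sum(s %in% dset), integer(1))
    tested <- which(m_d >= 1)
    m <- length(tested)
    if (m == 0) next  # no circRNA interacts with this disease's miRNAs
    thr <- bonferroni_threshold(m, alpha)
    p <- hypergeom_tail_p(M_T, m_c_all[tested], length(dset), m_d[tested])
    res <- data.frame(
      circ_id = names(circ_sets)[tested],
      disease = d,
      M_T = M_T,
      m_c = as.integer(m_c_all[tested]),
      M_d = length(dset),
      m_d = as.integer(m_d[tested]),
      p_value = p,
      m = m,
      p_threshold = thr,
      significant = p < thr,
      stringsAsFactors = FALSE
    )
    out[[d]] <- res[order(res$p_value, res$circ_id), , drop = FALSE]
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out))
    return(data.frame(circ_id = character(), disease = character(),
                      M_T = integer(), m_c = integer(), M_d = integer(),
                      m_d = integer(), p_value = numeric(), m = integer(),
                      p_threshold = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out[order(names(out))])
  rownames(res) <- NULL
  res
}

#' Write enrichment results to TSV
#'
#' p-values and thresholds in scientific notation with 12 significant digits.
#'
#' @param results data.frame from [call_disease_associations()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  df <- results
  df$p_value <- sprintf("%.12e", df$p_value)
  df$p_threshold <- sprintf("%.12e", df$p_threshold)
  df$significant <- ifelse(df$significant, "true", "false")
  write_tsv_lf(df, path)
}

#' Read an enrichment results TSV written by [write_enrichment()]
#' @param path path to the TSV.
#' @return data.frame with the columns of [call_disease_associations()].
#' @export
read_enrichment <- function(path) {
  df <- read_tsv_checked(path, c("circ_id", "disease", "M_T", "m_c", "M_d",
                                 "m_d", "p_value", "m", "p_threshold",
                                 "significant"))
  for (cc in c("M_T", "m_c", "M_d", "m_d", "m")) df[[cc]] <- as.integer(df[[cc]])
  df$p_value <- as.numeric(df$p_value)
  df$p_threshold <- as.numeric(df$p_threshold)
  df$significant <- df$significant == "true"
  df
}
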