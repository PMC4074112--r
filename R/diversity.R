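#' Singleton adjustment: discard one sequence per MOTU
#'
#' Removes one sequence from every MOTU present in a sample, so that MOTUs
#' supported by a single sequence drop out before rarefaction.  Which
#' sequence is discarded is irrelevant at the count level, so the adjustment
#' is a deterministic decrement of every positive count.
#'
#' @param counts Non-negative count vector for one sample.
#' @return Adjusted counts (same length, names preserved).
#' @export
discard_one_per_motu <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  pmax(counts - (counts > 0), 0)
}

#' Analytic rarefaction richness
#'
#' Expected number of MOTUs in a random subsample of `depth` sequences drawn
#' without replacement: `E[S] = sum_m 1 - C(N - N_m, d) / C(N, d)`.
#' Binomial coefficients are evaluated in log space.
#'
#' @param counts Count vector for one sample.
#' @param depth Subsample size; must not exceed `sum(counts)`.
#' @param sample_id Optional label used in error messages.
#' @return Expected richness (numeric scalar).
#' @export
rarefied_richness <- function(counts, depth, sample_id = NULL) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  if (depth > N)
    stop("rarefied_richness: depth ", depth, " exceeds total count ", N,
         if (!is.null(sample_id)) paste0(" in sample ", sample_id))
  if (depth < 0) stop("rarefied_richness: depth must be non-negative")
  if (length(counts) == 0) return(0)
  sum(1 - exp(lchoose(N - counts, depth) - lchoose(N, depth)))
}

#' Rarefy a count vector by random subsampling
#'
#' Draws `depth` sequences without replacement (a multivariate hypergeometric
#' draw) from the sample's counts; reproducible given a seed.
#'
#' @param counts Count vector.
#' @param depth Subsample size.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param sample_id Optional label used in error messages.
#' @return Integer vector of subsampled counts, same length and names.
#' @export
rarefy_counts <- function(counts, depth, seed = NULL, sample_id = NULL) {
  if (depth > sum(counts))
    stop("rarefy_counts: depth ", depth, " exceeds total count ", sum(counts),
         if (!is.null(sample_id)) paste0(" in sample ", sample_id))
  with_seed(seed, {
    # rrarefy warns about count heuristics irrelevant to plain subsampling
    out <- suppressWarnings(
      vegan::rrarefy(matrix(as.integer(round(counts)), nrow = 1), depth))
    setNames(as.integer(out[1, ]), names(counts))
  })
}

#' Group richness by proportional redistribution of unknowns
#'
#' Estimates the richness of a taxonomic or functional group under the
#' assumption that the group's share among phylum-unknown MOTUs equals its
#' share among assigned MOTUs: `R_ij = (N_ij / N_assigned) * ER_j`.
#'
#' @param n_group Observed MOTUs of the group in the sample (`N_ij`).
#' @param n_assigned Observed phylum-assigned MOTUs in the sample.
#' @param total_richness Estimated total richness `ER_j` of the sample.
#' @return Estimated group richness `R_ij`.
#' @export
group_richness <- function(n_group, n_assigned, total_richness) {
  if (any(n_assigned == 0))
    stop("group_richness: no assigned MOTUs in sample; estimator undefined")
  if (any(n_group < 0) || any(n_group > n_assigned))
    stop("group_richness: need 0 <= n_group <= n_assigned")
  (n_group / n_assigned) * total_richness
}

#' Shannon diversity (natural log)
#'
#' `H = -sum p_m log(p_m)` over MOTUs with positive counts.
#'
#' @param counts Count vector with positive total.
#' @return Diversity in nats.
#' @export
shannon_diversity <- function(counts) {
  counts <- counts[counts > 0]
  if (length(counts) == 0) stop("shannon_diversity: all counts are zero")
  p <- counts / sum(counts)
  -sum(p * log(p))
}

#' Per-MOTU occurrence across the design hierarchy
#'
#' Counts, for every MOTU, the number of regions, sites and plots in which it
#' occurs, plus histograms over those classes (which partition the MOTU set).
#'
#' @param presence Samples x MOTUs binary (or count) matrix.
#' @param design Sample table with `sample_id`, `region`, `site`, `plot`.
#' @return list(per_motu, region_histogram, site_histogram) where
#'   `per_motu` has columns motu_id, n_regions, n_sites, n_plots.
#' @export
occurrence_summary <- function(presence, design) {
  idx <- match(rownames(presence), design$sample_id)
  if (anyNA(idx)) stop("occurrence_summary: samples missing from design")
  pres <- presence > 0
  count_levels <- function(labels) apply(pres, 2, function(col)
    length(unique(labels[col])))
  per_motu <- data.frame(motu_id = colnames(presence),
                         n_regions = count_levels(design$region[idx]),
                         n_sites = count_levels(design$site[idx]),
                         n_plots = count_levels(design$plot[idx]),
                         stringsAsFactors = FALSE)
  rownames(per_motu) <- NULL
  list(per_motu = per_motu,
       region_histogram = table(per_motu$n_regions),
       site_histogram = table(per_motu$n_sites))
}

#' Per-sample richness table
#'
#' Produces the per-plot richness table downstream mixed models consume: for
#' every sample, the singleton-adjusted rarefied total richness `ER`, the
#' redistributed group richnesses for ascomycetes, basidiomycetes and EcM
#' fungi, and the Shannon index.  Group proportions (`N_ij / N_assigned`) are
#' computed on the unrarefied post-filter sample; `ER` on the adjusted,
#' rarefied sample.  Samples whose adjusted total falls below the depth are
#' skipped with a warning.
#'
#' @param abundance Post-filter samples x MOTUs count matrix.
#' @param assignments Assignment table covering the columns.
#' @param design Sample table with `sample_id` and `habitat`.
#' @param depth_leaf,depth_root Rarefaction depths per habitat (defaults
#'   1400 and 500 sequences).
#' @return data.frame: sample_id, habitat, depth, ER, R_asco, R_basidio,
#'   R_ecm, shannon, n_assigned.
#' @export
richness_table <- function(abundance, assignments, design,
                           depth_leaf = 1400, depth_root = 500) {
  asg <- assignments[match(colnames(abundance), assignments$motu_id), ]
  rows <- lapply(rownames(abundance), function(s) {
    counts <- abundance[s, ]
    hab <- design$habitat[match(s, design$sample_id)]
    depth <- if (identical(hab, "leaf")) depth_leaf else depth_root
    adj <- discard_one_per_motu(counts)
    if (sum(adj) < depth) {
      warning("sample ", s, " has fewer than ", depth,
              " sequences after singleton adjustment; skipped")
      return(NULL)
    }
    ER <- rarefied_richness(adj, depth, sample_id = s)
    present <- counts > 0
    assigned <- present & !is.na(asg$phylum)
    n_assigned <- sum(assigned)
    grp <- function(sel) if (n_assigned == 0) NA_real_ else
      group_richness(sum(assigned & sel), n_assigned, ER)
    data.frame(sample_id = s, habitat = hab, depth = depth, ER = ER,
               R_asco = grp(!is.na(asg$phylum) & asg$phylum == "Ascomycota"),
               R_basidio = grp(!is.na(asg$phylum) & asg$phylum == "Basidiomycota"),
               R_ecm = grp(asg$is_ecm),
               shannon = shannon_diversity(counts),
               n_assigned = n_assigned, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
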