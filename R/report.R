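#' Published dataset summary counts
#'
#' Loads the shipped count table of the beech elevation-gradient ITS1 survey
#' (66 samples: 33 leaf, 33 root): read totals, MOTU and non-singleton
#' counts, and non-singleton counts per taxonomic level, phylum and
#' ecological mode.  Assignment-level rows are exclusive (a species-assigned
#' MOTU is not counted again at genus level), so the four levels sum to the
#' non-singleton total.
#'
#' @param path Optional path to an alternative table with the same layout.
#' @return data.frame with columns item, combined, leaf, root.
#' @export
dataset_counts <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "beech_its1_counts.tsv",
                        package = "motupipe", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Derived percentages and means from dataset counts
#'
#' Recomputes the derived summary statistics of a count table as produced by
#' [dataset_counts()]: quality-retention and singleton percentages, mean
#' sequences per sample, the percentage of non-singletons at each
#' assignment level and in each phylum, and the Dikarya shares.  Percentages
#' are reported to one decimal, means to the nearest integer.
#'
#' @param counts A count table from [dataset_counts()].
#' @return data.frame with columns quantity, dataset, value.
#' @export
dataset_summary <- function(counts = dataset_counts()) {
  g <- function(item, ds) {
    v <- counts[[ds]][match(item, counts$item)]
    if (anyNA(v)) stop("dataset_summary: missing item ", item)
    v
  }
  rows <- list()
  add <- function(quantity, dataset, value)
    rows[[length(rows) + 1]] <<- data.frame(quantity = quantity,
                                            dataset = dataset, value = value,
                                            stringsAsFactors = FALSE)
  pct <- function(num, den) round(100 * num / den, 1)
  for (ds in c("combined", "leaf", "root")) {
    ns <- g("nonsingletons", ds)
    add("pct_quality_reads", ds, pct(g("quality_reads", ds), g("total_reads", ds)))
    add("mean_quality_reads_per_sample", ds,
        round(g("quality_reads", ds) / g("n_samples", ds)))
    add("pct_singleton_motus", ds,
        pct(g("motus", ds) - ns, g("motus", ds)))
    add("pct_assigned_phylum_only", ds, pct(g("assigned_phylum_only", ds), ns))
    add("pct_assigned_genus_only", ds, pct(g("assigned_genus_only", ds), ns))
    add("pct_assigned_species", ds, pct(g("assigned_species", ds), ns))
    add("pct_unknown", ds, pct(g("unknown", ds), ns))
    add("pct_ascomycota", ds, pct(g("ascomycota", ds), ns))
    add("pct_basidiomycota", ds, pct(g("basidiomycota", ds), ns))
    add("pct_zygomycota", ds, pct(g("zygomycota", ds), ns))
    add("pct_other_fungal", ds, pct(g("other_fungal", ds), ns))
    add("pct_dikarya", ds,
        pct(g("ascomycota", ds) + g("basidiomycota", ds), ns))
    add("pct_dikarya_of_assigned", ds,
        pct(g("ascomycota", ds) + g("basidiomycota", ds), ns - g("unknown", ds)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
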