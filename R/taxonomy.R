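# Split a semicolon taxonomy path (phylum first) into ranks.
parse_taxonomy <- function(path) {
  parts <- strsplit(trimws(path), ";", fixed = TRUE)
  data.frame(
    phylum = vapply(parts, function(p) if (length(p) >= 1) trimws(p[1]) else NA_character_, ""),
    genus = vapply(parts, function(p) if (length(p) >= 2) trimws(p[2]) else NA_character_, ""),
    species = vapply(parts, function(p) if (length(p) >= 3) trimws(p[3]) else NA_character_, ""),
    stringsAsFactors = FALSE)
}

# Hits passing the genus-level gates: identity strictly > 90 and
# e-value strictly < 1e-50.
valid_hits <- function(hits, identity_min = 90, evalue_max = 1e-50) {
  hits[hits$pct_identity > identity_min & hits$evalue < evalue_max, ,
       drop = FALSE]
}

#' Default phylum-specific ITS1 intraspecific variability
#'
#' Mean ITS1 intraspecific sequence variability per fungal phylum (percent),
#' weighted by the number of sequences in the reference compilation it was
#' derived from.  These values gate species-level assignment: a species name
#' is only considered when some BLAST hit reaches an identity of at least
#' `100 - variability` percent for the MOTU's phylum.
#'
#' @return Named numeric vector of percentages.
#' @export
default_phylum_variability <- function() {
  c(Ascomycota = 2.88, Basidiomycota = 4.98, Chytridiomycota = 7.81,
    Glomeromycota = 9.48, Zygomycota = 4.13)
}

#' Sequence-weighted ITS1 variability per phylum
#'
#' Aggregates per-species intraspecific variability records into a per-phylum
#' mean weighted by the number of sequences supporting each species record.
#'
#' @param records data.frame with columns `phylum`, `variability` (percent)
#'   and `n_sequences`.
#' @return Named numeric vector: per phylum, sum(v * n) / sum(n).
#' @export
weighted_variability <- function(records) {
  stopifnot(all(c("phylum", "variability", "n_sequences") %in% names(records)),
            all(records$n_sequences >= 1))
  out <- vapply(split(records, records$phylum), function(g)
    sum(g$variability * g$n_sequences) / sum(g$n_sequences), numeric(1))
  out[order(names(out))]
}

#' Consensus genus from the BLAST hits of one MOTU
#'
#' Hits with identity <= 90 percent or e-value >= 1e-50 are discarded.  The
#' genus is assigned when at least eight remaining hits agree on it, or, when
#' fewer than eight hits remain, when all of them agree.  Congruence is exact
#' string equality after whitespace trimming; a hit lacking a genus rank is
#' never congruent.
#'
#' @param hits data.frame of hits for a single query (columns `taxonomy`,
#'   `pct_identity`, `evalue`).
#' @param min_congruent Vote threshold (default 8).
#' @return Genus name, or `NA_character_` when unassigned.
#' @export
assign_genus <- function(hits, min_congruent = 8) {
  v <- valid_hits(hits)
  if (nrow(v) == 0) return(NA_character_)
  g <- parse_taxonomy(v$taxonomy)$genus
  if (nrow(v) < min_congruent) {
    u <- unique(g)
    if (length(u) == 1 && !is.na(u)) return(u)
    return(NA_character_)
  }
  tab <- table(g[!is.na(g)])
  if (length(tab) && max(tab) >= min_congruent)
    return(sort(names(tab)[tab == max(tab)])[1])
  NA_character_
}

#' Consensus species for a genus-assigned MOTU
#'
#' Species assignment requires (i) the identity gate: some valid hit reaches
#' `100 - variability[phylum]` percent identity, where the variability is the
#' phylum's ITS1 intraspecific variability, and (ii) the name rule: at least
#' six valid hits agree on the species binomial, or all of them when fewer
#' than six remain.
#'
#' @param hits Hits of one query.
#' @param genus Assigned genus ([assign_genus()]); `NA` short-circuits to
#'   unassigned.
#' @param phylum Assigned phylum; must appear in `variability`.
#' @param variability Named percentages, see [default_phylum_variability()].
#' @param min_congruent Vote threshold (default 6).
#' @return Species name, or `NA_character_` when unassigned.
#' @export
assign_species <- function(hits, genus, phylum,
                           variability = default_phylum_variability(),
                           min_congruent = 6) {
  if (is.na(genus) || is.na(phylum)) return(NA_character_)
  if (!phylum %in% names(variability)) {
    warning("no ITS1 variability known for phylum ", phylum,
            "; species left unassigned")
    return(NA_character_)
  }
  v <- valid_hits(hits)
  if (nrow(v) == 0) return(NA_character_)
  if (!any(v$pct_identity >= 100 - variability[[phylum]]))
    return(NA_character_)
  s <- parse_taxonomy(v$taxonomy)$species
  if (nrow(v) < min_congruent) {
    u <- unique(s)
    if (length(u) == 1 && !is.na(u)) return(u)
    return(NA_character_)
  }
  tab <- table(s[!is.na(s)])
  if (length(tab) && max(tab) >= min_congruent)
    return(sort(names(tab)[tab == max(tab)])[1])
  NA_character_
}

#' Majority-vote phylum from BLAST hits
#'
#' The phylum is taken from the hit taxonomy paths by majority vote over all
#' hits of the query (no identity gate: phylum information does not require
#' a close match).  Ties break lexicographically; no hits give unknown.
#'
#' @param hits Hits of one query.
#' @return Phylum name, or `NA_character_` (unknown) without hits.
#' @export
assign_phylum <- function(hits) {
  if (is.null(hits) || nrow(hits) == 0) return(NA_character_)
  ph <- parse_taxonomy(hits$taxonomy)$phylum
  tab <- table(ph[!is.na(ph)])
  if (!length(tab)) return(NA_character_)
  sort(names(tab)[tab == max(tab)])[1]
}

#' Assign taxonomy to every MOTU from a hit table
#'
#' Runs [assign_phylum()], [assign_genus()] and [assign_species()] per query
#' and returns one row per MOTU, including MOTUs absent from the hit table
#' (no hits, unknown phylum).  `is_fungal` is `TRUE` when the phylum is one
#' of the fungal phyla, `FALSE` for a known non-fungal phylum, and `NA` when
#' the phylum is unknown.
#'
#' @param hits Hit table (query_id, gi, taxonomy, pct_identity, evalue).
#' @param motu_ids All MOTU ids to report (defaults to those in `hits`).
#' @param variability Named percentages for the species identity gate.
#' @return data.frame: motu_id, phylum, genus, species, is_fungal, is_ecm
#'   (initialised `FALSE`, see [annotate_ecm()]), n_hits.
#' @export
assign_taxonomy <- function(hits, motu_ids = NULL,
                            variability = default_phylum_variability()) {
  if (is.null(motu_ids)) motu_ids <- unique(hits$query_id)
  by_q <- split(hits, factor(hits$query_id, levels = motu_ids))
  out <- do.call(rbind, lapply(motu_ids, function(m) {
    h <- by_q[[m]]
    ph <- assign_phylum(h)
    gn <- if (!is.null(h)) assign_genus(h) else NA_character_
    sp <- assign_species(h, gn, ph, variability)
    data.frame(motu_id = m, phylum = ph, genus = gn, species = sp,
               is_fungal = if (is.na(ph)) NA else ph %in% fungal_phyla,
               is_ecm = FALSE,
               n_hits = if (is.null(h)) 0L else nrow(h),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# minimal union-find
uf_find <- function(parent, i) {
  while (parent[i] != i) { parent[i] <- parent[parent[i]]; i <- parent[i] }
  i
}

#' Merge MOTUs by shared species or shared GI number
#'
#' Two MOTUs are linked when they carry the same assigned species, or when
#' their hit sets share a GI number among hits with identity strictly above
#' `identity_min` percent and e-value strictly below `evalue_max`.  Linked
#' MOTUs are merged by connected components (transitive closure); counts are
#' summed, and each merged MOTU keeps the id and representative of its most
#' abundant member (ties lexicographic) while inheriting the most resolved
#' member assignment (species > genus > phylum, ties by abundance).
#'
#' @param abundance Samples x MOTUs count matrix.
#' @param assignments Output of [assign_taxonomy()].
#' @param hits Hit table used for the GI rule.
#' @param identity_min,evalue_max GI-rule gates (defaults 90, 1e-45).
#' @return list(abundance, assignments, groups) where `groups` maps each
#'   input `motu_id` to its `merged_id`.
#' @export
merge_motus <- function(abundance, assignments, hits,
                        identity_min = 90, evalue_max = 1e-45) {
  mids <- colnames(abundance)
  stopifnot(all(mids %in% assignments$motu_id))
  n <- length(mids)
  if (n == 0)
    return(list(abundance = abundance, assignments = assignments[0, ],
                groups = data.frame(motu_id = character(),
                                    merged_id = character())))
  parent <- seq_len(n)
  link <- function(i, j) {
    ri <- uf_find(parent, i); rj <- uf_find(parent, j)
    if (ri != rj) parent[rj] <<- ri
  }
  # species edges
  asg <- assignments[match(mids, assignments$motu_id), ]
  sp <- asg$species
  for (s in unique(sp[!is.na(sp)])) {
    grp <- which(sp == s)
    if (length(grp) > 1) for (k in grp[-1]) link(grp[1], k)
  }
  # GI edges among gated hits
  h <- hits[hits$query_id %in% mids &
              hits$pct_identity > identity_min & hits$evalue < evalue_max, ,
            drop = FALSE]
  if (nrow(h)) {
    h$q <- match(h$query_id, mids)
    for (g in split(h$q, h$gi)) {
      grp <- unique(g)
      if (length(grp) > 1) for (k in grp[-1]) link(grp[1], k)
    }
  }
  comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
  total <- colSums(abundance)
  merged_ab <- NULL; keep_id <- character(0); asg_rows <- integer(0)
  for (cc in unique(comp)) {
    grp <- which(comp == cc)
    lead <- grp[order(-total[grp], mids[grp])][1]
    keep_id <- c(keep_id, mids[lead])
    merged_ab <- cbind(merged_ab,
                       if (length(grp) > 1) rowSums(abundance[, grp, drop = FALSE])
                       else abundance[, grp])
    depth <- ifelse(!is.na(asg$species[grp]), 3,
                    ifelse(!is.na(asg$genus[grp]), 2,
                           ifelse(!is.na(asg$phylum[grp]), 1, 0)))
    asg_rows <- c(asg_rows, grp[order(-depth, -total[grp], mids[grp])][1])
  }
  colnames(merged_ab) <- keep_id
  rownames(merged_ab) <- rownames(abundance)
  new_asg <- asg[asg_rows, , drop = FALSE]
  new_asg$motu_id <- keep_id
  new_asg$n_hits <- vapply(unique(comp), function(cc)
    sum(asg$n_hits[comp == cc]), integer(1))
  rownames(new_asg) <- NULL
  groups <- data.frame(motu_id = mids, merged_id = keep_id[match(comp, unique(comp))],
                       stringsAsFactors = FALSE)
  list(abundance = merged_ab, assignments = new_asg, groups = groups)
}

#' Discard low-quality MOTUs
#'
#' Applies the three discard criteria, in order: (1) non-fungal MOTUs
#' (assigned to a known non-fungal phylum); (2) singletons, MOTUs supported
#' by a single sequence in the combined dataset; (3) MOTUs with no BLAST hit
#' at all supported by fewer than `min_nohit_count` sequences.  Run after
#' merging, so singletons are counted on the merged dataset.
#'
#' @param abundance Samples x MOTUs count matrix (post-merge).
#' @param assignments Matching assignment table.
#' @param min_nohit_count Minimum combined count for no-hit MOTUs (default 10).
#' @return list(abundance, assignments, report) with `report` giving the
#'   number of MOTUs removed per criterion.
#' @export
apply_filters <- function(abundance, assignments, min_nohit_count = 10) {
  asg <- assignments[match(colnames(abundance), assignments$motu_id), ]
  total <- colSums(abundance)
  nonfungal <- !is.na(asg$is_fungal) & !asg$is_fungal
  singleton <- !nonfungal & total == 1
  nohit <- !nonfungal & !singleton & asg$n_hits == 0 & total < min_nohit_count
  drop <- nonfungal | singleton | nohit
  report <- data.frame(
    criterion = c("non_fungal", "singleton", "no_hit_low_count"),
    removed = c(sum(nonfungal), sum(singleton), sum(nohit)))
  list(abundance = abundance[, !drop, drop = FALSE],
       assignments = {
         a <- asg[!drop, , drop = FALSE]; rownames(a) <- NULL; a
       },
       report = report)
}

#' Flag ectomycorrhizal MOTUs
#'
#' A MOTU is ectomycorrhizal when its assigned genus appears in the EcM genus
#' lookup list (literature-based); unassigned genera are never flagged.
#'
#' @param assignments Assignment table.
#' @param ecm_genera Character vector of EcM genus names.
#' @return The assignment table with `is_ecm` filled in.
#' @export
annotate_ecm <- function(assignments, ecm_genera) {
  assignments$is_ecm <- !is.na(assignments$genus) &
    assignments$genus %in% ecm_genera &
    !is.na(assignments$is_fungal) & assignments$is_fungal
  assignments
}
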