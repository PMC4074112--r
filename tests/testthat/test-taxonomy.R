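hit_row <- function(query = "M1", genus = "Russula", species = NULL,
                    phylum = "Basidiomycota", identity = 98, evalue = 1e-80,
                    gi = 1) {
  tax <- if (is.null(species)) paste(phylum, genus, sep = ";")
         else paste(phylum, genus, species, sep = ";")
  data.frame(query_id = query, gi = gi, taxonomy = tax,
             pct_identity = identity, evalue = evalue, aln_len = 200,
             stringsAsFactors = FALSE)
}
hit_tab <- function(...) do.call(rbind, list(...))

test_that("weighted variability is the sequence-weighted mean per phylum", {
  one <- data.frame(phylum = "Ascomycota", variability = 2.88, n_sequences = 10)
  expect_equal(unname(weighted_variability(one)), 2.88)

  two <- data.frame(phylum = "Basidiomycota", variability = c(2, 4),
                    n_sequences = c(1, 1))
  expect_equal(unname(weighted_variability(two)), 3.0)

  set.seed(2)
  rec <- data.frame(phylum = rep(c("Ascomycota", "Zygomycota"), each = 5),
                    variability = runif(10, 1, 9),
                    n_sequences = sample(1:50, 10))
  got <- weighted_variability(rec)
  for (ph in unique(rec$phylum)) {             # arithmetic oracle
    g <- rec[rec$phylum == ph, ]
    expect_equal(got[[ph]], sum(g$variability * g$n_sequences) / sum(g$n_sequences))
  }
})

test_that("genus assignment enforces the 8-congruent-hit rule and its gates", {
  h8 <- do.call(rbind, c(lapply(1:8, function(i) hit_row()),
                         lapply(1:2, function(i) hit_row(genus = "Lactarius"))))
  expect_equal(assign_genus(h8), "Russula")

  h7 <- do.call(rbind, c(lapply(1:7, function(i) hit_row()),
                         lapply(1:3, function(i) hit_row(genus = "Lactarius"))))
  expect_true(is.na(assign_genus(h7)))

  all5 <- do.call(rbind, lapply(1:5, function(i) hit_row(genus = "Taphrina",
                                                         phylum = "Ascomycota")))
  expect_equal(assign_genus(all5), "Taphrina")

  mixed5 <- rbind(do.call(rbind, lapply(1:4, function(i)
    hit_row(genus = "Taphrina", phylum = "Ascomycota"))),
    hit_row(genus = "Venturia", phylum = "Ascomycota"))
  expect_true(is.na(assign_genus(mixed5)))

  expect_true(is.na(assign_genus(hit_row()[0, ])))

  # identity and e-value gates are strict at 90 and 1e-50
  at90 <- do.call(rbind, lapply(1:10, function(i) hit_row(identity = 90)))
  expect_true(is.na(assign_genus(at90)))
  over90 <- do.call(rbind, lapply(1:10, function(i) hit_row(identity = 90.1)))
  expect_equal(assign_genus(over90), "Russula")
  at50 <- do.call(rbind, lapply(1:10, function(i) hit_row(evalue = 1e-50)))
  expect_true(is.na(assign_genus(at50)))
  under50 <- do.call(rbind, lapply(1:10, function(i) hit_row(evalue = 0.9e-50)))
  expect_equal(assign_genus(under50), "Russula")
})

test_that("species assignment requires the phylum identity gate and 6 congruent hits", {
  mk <- function(n_sp, n_other, best_id) {
    rbind(do.call(rbind, lapply(seq_len(n_sp), function(i)
      hit_row(genus = "Taphrina", species = "Taphrina_carpini",
              phylum = "Ascomycota", identity = best_id))),
      if (n_other > 0) do.call(rbind, lapply(seq_len(n_other), function(i)
        hit_row(genus = "Taphrina", species = sprintf("Taphrina_x%d", i),
                phylum = "Ascomycota", identity = 95))))
  }
  # Ascomycota gate is 100 - 2.88 = 97.12
  expect_equal(assign_species(mk(6, 4, 97.5), "Taphrina", "Ascomycota"),
               "Taphrina_carpini")
  expect_true(is.na(assign_species(mk(6, 4, 96.0), "Taphrina", "Ascomycota")))
  expect_true(is.na(assign_species(mk(5, 5, 98), "Taphrina", "Ascomycota")))
  # all-congruent rule under 6 hits
  expect_equal(assign_species(mk(4, 0, 98), "Taphrina", "Ascomycota"),
               "Taphrina_carpini")
  # no genus, no species
  expect_true(is.na(assign_species(mk(6, 0, 98), NA_character_, "Ascomycota")))
  # unknown phylum variability: warning and unassigned
  expect_warning(
    out <- assign_species(mk(6, 0, 99), "Taphrina", "Mortierellomycota"),
    "variability")
  expect_true(is.na(out))
})

test_that("phylum is a majority vote over hits, unknown without hits", {
  hb <- do.call(rbind, lapply(1:5, function(i) hit_row()))
  expect_equal(assign_phylum(hb), "Basidiomycota")
  expect_true(is.na(assign_phylum(hb[0, ])))

  h64 <- rbind(do.call(rbind, lapply(1:6, function(i)
    hit_row(phylum = "Ascomycota", genus = "Taphrina"))),
    do.call(rbind, lapply(1:4, function(i) hit_row())))
  # counting oracle
  counts <- table(sub(";.*", "", h64$taxonomy))
  expect_equal(assign_phylum(h64), names(counts)[which.max(counts)])
  expect_equal(assign_phylum(h64), "Ascomycota")
})

test_that("assignment table keeps the species => genus => phylum chain", {
  d <- tiny_design()
  cm <- generate_community(community_spec(pool_size = 80,
                                          singleton_target_fraction = NULL),
                           d, seed = 3)
  hits <- generate_blast_table(cm$reference, hit_noise_spec(seed = 11))
  asg <- assign_taxonomy(hits, motu_ids = cm$reference$taxon_id)
  expect_equal(nrow(asg), 80)
  expect_true(all(is.na(asg$species) | !is.na(asg$genus)))
  expect_true(all(is.na(asg$genus) | !is.na(asg$phylum)))
  expect_true(all(asg$n_hits[is.na(asg$phylum)] == 0))
})

test_that("assignment monotonicity: congruent hits never revoke, incongruent never create", {
  base <- do.call(rbind, lapply(1:8, function(i) hit_row()))
  expect_equal(assign_genus(base), "Russula")
  more <- rbind(base, hit_row(), hit_row())
  expect_equal(assign_genus(more), "Russula")

  few <- do.call(rbind, lapply(1:5, function(i) hit_row(genus = "Cortinarius")))
  plus_bad <- rbind(few, hit_row(genus = "Inocybe"))
  expect_equal(assign_genus(few), "Cortinarius")
  expect_true(is.na(assign_genus(plus_bad)))
})

test_that("MOTU merging groups by species and shared GI with transitive closure", {
  ab <- matrix(c(5L, 3L, 2L, 7L, 1L, 4L), nrow = 1,
               dimnames = list("S1", paste0("M", 1:6)))
  asg <- data.frame(
    motu_id = paste0("M", 1:6),
    phylum = "Basidiomycota",
    genus = c("Russula", "Russula", "Amanita", "Amanita", "Boletus", "Boletus"),
    species = c("Russula_solaris", "Russula_solaris", NA, NA, NA, NA),
    is_fungal = TRUE, is_ecm = FALSE, n_hits = 10L, stringsAsFactors = FALSE)
  # chain: M3-M4 share a GI; M4-M5 share a species? no - GI again; M6 isolated
  hits <- rbind(hit_row("M3", gi = 500, identity = 95, evalue = 1e-60),
                hit_row("M4", gi = 500, identity = 95, evalue = 1e-60),
                hit_row("M4", gi = 600, identity = 92, evalue = 1e-60),
                hit_row("M5", gi = 600, identity = 92, evalue = 1e-60),
                hit_row("M6", gi = 700, identity = 90.0, evalue = 1e-60),
                hit_row("M1", gi = 700, identity = 95, evalue = 1e-60))
  m <- merge_motus(ab, asg, hits)
  # M1+M2 (species), M3+M4+M5 (GI chain), M6 alone (90.0 is not > 90)
  expect_equal(ncol(m$abundance), 3)
  expect_equal(sum(m$abundance), sum(ab))            # conservation
  expect_equal(unname(m$abundance[1, "M1"]), 8L)     # most abundant leads
  grp <- m$groups$merged_id
  expect_equal(grp[m$groups$motu_id == "M3"], grp[m$groups$motu_id == "M5"])
  expect_false(grp[m$groups$motu_id == "M6"] %in%
                 grp[m$groups$motu_id != "M6"])

  # gates are strict: e-value must be < 1e-45
  hits2 <- rbind(hit_row("M3", gi = 500, identity = 95, evalue = 1e-45),
                 hit_row("M4", gi = 500, identity = 95, evalue = 1e-45))
  m2 <- merge_motus(ab, asg[, ], rbind(hits2),
                    identity_min = 90, evalue_max = 1e-45)
  expect_equal(grep("^M3$|^M4$", colnames(m2$abundance), value = TRUE),
               c("M3", "M4"))
})

test_that("merging matches an igraph connected-components oracle on random fixtures", {
  skip_if_not_installed("igraph")
  set.seed(14)
  n <- 30
  mids <- sprintf("M%02d", 1:n)
  ab <- matrix(rpois(2 * n, 4) + 1L, nrow = 2,
               dimnames = list(c("S1", "S2"), mids))
  sp_pool <- c(sprintf("Sp%02d", 1:8), rep(NA, 10))
  asg <- data.frame(motu_id = mids, phylum = "Ascomycota",
                    genus = "G", species = sample(sp_pool, n, TRUE),
                    is_fungal = TRUE, is_ecm = FALSE, n_hits = 1L,
                    stringsAsFactors = FALSE)
  hits <- do.call(rbind, lapply(1:n, function(i)
    hit_row(mids[i], gi = sample(1:12, 1), identity = runif(1, 88, 99),
            evalue = 10^runif(1, -60, -40))))
  m <- merge_motus(ab, asg, hits)

  g <- igraph::make_empty_graph(n, directed = FALSE)
  for (s in unique(na.omit(asg$species))) {
    grp <- which(asg$species == s)
    if (length(grp) > 1) g <- igraph::add_edges(g, as.vector(combn(grp, 2)))
  }
  hv <- hits[hits$pct_identity > 90 & hits$evalue < 1e-45, ]
  for (gi in unique(hv$gi)) {
    grp <- match(unique(hv$query_id[hv$gi == gi]), mids)
    if (length(grp) > 1) g <- igraph::add_edges(g, as.vector(combn(grp, 2)))
  }
  comp <- igraph::components(g)$membership
  expect_equal(ncol(m$abundance), max(comp))
  merged_of <- m$groups$merged_id
  expect_true(all(tapply(merged_of, comp, function(x) length(unique(x)) == 1)))
  expect_equal(sum(m$abundance), sum(ab))
  expect_lte(ncol(m$abundance), ncol(ab))
})

test_that("discard criteria remove non-fungal, singleton and weak no-hit MOTUs", {
  mids <- paste0("M", 1:6)
  ab <- matrix(c(500L, 1L, 9L, 10L, 1L, 50L), nrow = 1,
               dimnames = list("S1", mids))
  asg <- data.frame(
    motu_id = mids,
    phylum = c("Streptophyta", "Ascomycota", NA, NA, NA, "Ascomycota"),
    genus = NA_character_, species = NA_character_,
    is_fungal = c(FALSE, TRUE, NA, NA, NA, TRUE),
    is_ecm = FALSE,
    n_hits = c(10L, 10L, 0L, 0L, 0L, 5L), stringsAsFactors = FALSE)
  f <- apply_filters(ab, asg)
  # M1 plant (despite 500 reads), M2 singleton, M3 no-hit with 9 reads,
  # M5 singleton; M4 no-hit with exactly 10 reads stays, M6 stays
  expect_setequal(colnames(f$abundance), c("M4", "M6"))
  expect_equal(f$report$removed, c(1L, 2L, 1L))
})

test_that("EcM annotation is a set lookup on assigned genera", {
  asg <- data.frame(motu_id = paste0("M", 1:4),
                    phylum = c("Basidiomycota", "Basidiomycota", NA, "Basidiomycota"),
                    genus = c("Russula", "Mycena", NA, "Laccaria"),
                    species = NA_character_,
                    is_fungal = c(TRUE, TRUE, NA, TRUE),
                    is_ecm = FALSE, n_hits = 10L, stringsAsFactors = FALSE)
  lookup <- c("Russula", "Laccaria", "Cortinarius")
  out <- annotate_ecm(asg, lookup)
  expect_equal(out$is_ecm, c(TRUE, FALSE, FALSE, TRUE))
  # random fixture equals set-membership oracle
  set.seed(4)
  gen <- sample(c(lookup, "Mycena", "Taphrina", NA), 30, TRUE)
  asg2 <- data.frame(motu_id = sprintf("X%02d", 1:30), phylum = "Basidiomycota",
                     genus = gen, species = NA_character_,
                     is_fungal = TRUE, is_ecm = FALSE, n_hits = 1L,
                     stringsAsFactors = FALSE)
  expect_equal(annotate_ecm(asg2, lookup)$is_ecm,
               !is.na(gen) & gen %in% lookup)
})

test_that("noise-free synthetic hits give perfect recovery at the hit-count gates", {
  d <- tiny_design()
  cm <- generate_community(community_spec(pool_size = 120,
                                          singleton_target_fraction = NULL),
                           d, seed = 21)
  ref <- cm$reference
  hits <- generate_blast_table(ref, hit_noise_spec(
    n_hits_per_motu = 10, congruent_hits_genus = 8, congruent_hits_species = 6,
    identity_noise_sd = 0, p_no_hit = 0, p_nonfungal = 0, seed = 1))
  asg <- assign_taxonomy(hits, motu_ids = ref$taxon_id)
  known <- ref$phylum_known
  expect_equal(asg$genus[known], ref$genus[known])
  expect_equal(asg$phylum[known], ref$phylum[known])
  # species recovery applies to phyla with a variability entry (identity gate)
  sp_ok <- known & ref$phylum %in% names(default_phylum_variability())
  expect_equal(asg$species[sp_ok], ref$species[sp_ok])
  expect_true(all(is.na(asg$phylum[!known])))

  # 7 congruent of 10: genus assignment rate must be exactly 0
  hits7 <- generate_blast_table(ref, hit_noise_spec(
    n_hits_per_motu = 10, congruent_hits_genus = 7, congruent_hits_species = 6,
    identity_noise_sd = 0, p_no_hit = 0, p_nonfungal = 0, seed = 2))
  asg7 <- assign_taxonomy(hits7, motu_ids = ref$taxon_id)
  expect_true(all(is.na(asg7$genus)))
})
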