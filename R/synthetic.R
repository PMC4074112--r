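#' Sampling-design specification
#'
#' Describes the hierarchical sampling design to simulate: regions, elevation
#' sites per region, plots per site, and the per-sample sequencing-depth
#' ranges of the two habitats.  Defaults reproduce the beech elevation-
#' gradient survey layout: 3 regions with 3, 5 and 3 sites, 3 plots per site
#' (33 plots, one leaf and one root sample each), leaf depths 1506-15830 and
#' root depths 552-3622 sequences.
#'
#' @param n_regions Number of mountain regions.
#' @param sites_per_region Integer vector, one entry per region.
#' @param plots_per_site Plots per elevation site.
#' @param depth_range_leaf,depth_range_root `(min, max)` sequences per sample.
#' @param seed Integer seed controlling all design randomness.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(n_regions = 3,
                        sites_per_region = c(3, 5, 3),
                        plots_per_site = 3,
                        depth_range_leaf = c(1506, 15830),
                        depth_range_root = c(552, 3622),
                        seed = 1L) {
  if (length(sites_per_region) == 1)
    sites_per_region <- rep(sites_per_region, n_regions)
  stopifnot(length(sites_per_region) == n_regions)
  if (n_regions < 1 || any(sites_per_region < 1) || plots_per_site < 1)
    stop("design_spec: all counts must be >= 1")
  for (rg in list(depth_range_leaf, depth_range_root))
    if (length(rg) != 2 || any(rg <= 0) || rg[1] > rg[2])
      stop("design_spec: depth ranges must be positive with min <= max")
  structure(list(n_regions = as.integer(n_regions),
                 sites_per_region = as.integer(sites_per_region),
                 plots_per_site = as.integer(plots_per_site),
                 depth_range_leaf = as.integer(depth_range_leaf),
                 depth_range_root = as.integer(depth_range_root),
                 seed = as.integer(seed)),
            class = "design_spec")
}

#' Generate a sampling design and environment table
#'
#' Simulates the plot hierarchy and per-plot environmental covariates.
#' Within each region, site elevations are spread over a montane range and
#' mean annual temperature follows a negative lapse rate, so temperature
#' decreases with elevation within every region; precipitation increases with
#' elevation; soil pH is drawn independently of elevation (as observed in the
#' field data); soil C, N and P covary loosely with elevation.  One sample
#' row is emitted per plot and habitat (leaf, root), with a sequencing depth
#' drawn uniformly from the habitat's depth range.
#'
#' @param spec A [design_spec()].
#' @return A list with `samples` (sample_id, region, site, plot, habitat,
#'   depth) and `env` (per plot: elevation m, temperature degC, precipitation
#'   mm, soil_pH, C, N, P g/kg, C_N_ratio).
#' @export
generate_design <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  with_seed(spec$seed, {
    env <- NULL
    for (r in seq_len(spec$n_regions)) {
      region <- sprintf("R%d", r)
      ns <- spec$sites_per_region[r]
      lo <- runif(1, 100, 500); hi <- runif(1, 1100, 1600)
      elev <- if (ns == 1) mean(c(lo, hi)) else seq(lo, hi, length.out = ns)
      elev <- round(elev + runif(ns, -40, 40))
      base_t <- runif(1, 12.5, 14.5)          # sea-level mean annual temp
      lapse <- runif(1, 0.005, 0.0065)        # degC per m
      temp <- round(base_t - lapse * elev + rnorm(ns, 0, 0.15), 1)
      prec <- round(900 + 0.35 * elev + rnorm(ns, 0, 80), 1)
      pH_site <- runif(ns, 4.0, 6.4)          # independent of elevation
      C_site <- runif(ns, 20, 120)
      N_site <- C_site / runif(ns, 14, 18)
      P_site <- runif(ns, 0.05, 0.35)
      for (s in seq_len(ns)) {
        site <- sprintf("%sS%d", region, s)
        for (p in seq_len(spec$plots_per_site)) {
          pH <- round(min(7.5, max(3.5, pH_site[s] + rnorm(1, 0, 0.15))), 1)
          C <- round(C_site[s] * exp(rnorm(1, 0, 0.08)), 2)
          N <- round(N_site[s] * exp(rnorm(1, 0, 0.08)), 2)
          env <- rbind(env, data.frame(
            region = region, site = site, plot = sprintf("%sP%d", site, p),
            elevation = elev[s], temperature = temp[s], precipitation = prec[s],
            soil_pH = pH, C = C, N = N,
            P = round(P_site[s] * exp(rnorm(1, 0, 0.08)), 3),
            C_N_ratio = round(C / N, 2), stringsAsFactors = FALSE))
        }
      }
    }
    samples <- do.call(rbind, lapply(c("leaf", "root"), function(h) {
      rg <- if (h == "leaf") spec$depth_range_leaf else spec$depth_range_root
      data.frame(sample_id = paste0(env$plot, "_", h),
                 region = env$region, site = env$site, plot = env$plot,
                 habitat = h,
                 depth = sample(rg[1]:rg[2], nrow(env), replace = TRUE),
                 stringsAsFactors = FALSE)
    }))
    rownames(samples) <- rownames(env) <- NULL
    list(samples = samples, env = env)
  })
}

#' Community specification
#'
#' Parameters of the simulated fungal species pool and its response to the
#' environment.  Default phylum proportions follow the combined-dataset
#' composition of the beech survey (Ascomycota 55.4%, Basidiomycota 31.0%,
#' Zygomycota 3.2%, other fungal lineages 0.3%, unknown 10.1%); the default
#' singleton target matches its observed 37.8% singleton fraction.  Taxa of
#' the "unknown" class carry a true phylum in the ground truth but their
#' taxonomy is withheld from reference databases, which is how unknowns arise
#' in practice (no usable BLAST hits).
#'
#' @param pool_size Number of true taxa in the regional pool.
#' @param phylum_proportions Named simplex over Ascomycota, Basidiomycota,
#'   Zygomycota, other, unknown.
#' @param ecm_fraction_of_basidiomycetes Fraction of basidiomycete taxa whose
#'   genus is ectomycorrhizal.
#' @param abundance_lognormal `(mu, sigma)` of the lognormal regional
#'   abundance distribution (sigma is recalibrated when a singleton target is
#'   set).
#' @param singleton_target_fraction Target fraction of observed MOTUs that
#'   are singletons in the combined dataset, or `NULL` to use sigma as given.
#' @param niche_breadth_temperature Gaussian niche breadth on mean annual
#'   temperature (degC); `Inf` removes the temperature response, `0` makes
#'   each taxon a single-site specialist.
#' @param niche_breadth_pH Gaussian niche breadth on soil pH (pH units).
#' @return An object of class `community_spec`.
#' @export
community_spec <- function(pool_size = 2000,
                           phylum_proportions = c(Ascomycota = 0.554,
                                                  Basidiomycota = 0.310,
                                                  Zygomycota = 0.032,
                                                  other = 0.003,
                                                  unknown = 0.101),
                           ecm_fraction_of_basidiomycetes = 0.31,
                           abundance_lognormal = c(mu = 0, sigma = 1.5),
                           singleton_target_fraction = 0.378,
                           niche_breadth_temperature = 2,
                           niche_breadth_pH = 0.75) {
  if (pool_size < 1) stop("community_spec: pool_size must be >= 1")
  if (abs(sum(phylum_proportions) - 1) > 1e-9)
    stop("community_spec: phylum_proportions must sum to 1")
  if (any(phylum_proportions < 0))
    stop("community_spec: proportions must be non-negative")
  stopifnot(ecm_fraction_of_basidiomycetes >= 0,
            ecm_fraction_of_basidiomycetes <= 1,
            is.null(singleton_target_fraction) ||
              (singleton_target_fraction >= 0 && singleton_target_fraction <= 1),
            niche_breadth_temperature >= 0, niche_breadth_pH >= 0)
  structure(list(pool_size = as.integer(pool_size),
                 phylum_proportions = phylum_proportions,
                 ecm_fraction_of_basidiomycetes = ecm_fraction_of_basidiomycetes,
                 abundance_lognormal = abundance_lognormal,
                 singleton_target_fraction = singleton_target_fraction,
                 niche_breadth_temperature = niche_breadth_temperature,
                 niche_breadth_pH = niche_breadth_pH),
            class = "community_spec")
}

# Gaussian niche weight; breadth 0 is a delta function on the nearest value.
niche_weight <- function(x, opt, breadth) {
  d <- abs(x - opt)
  if (breadth == 0) as.numeric(d == min(d))
  else if (is.infinite(breadth)) rep(1, length(x))
  else exp(-d^2 / (2 * breadth^2))
}

#' Generate a true community and its sampled abundance matrix
#'
#' Draws a taxon pool (phylum, genus, species, GI number, EcM flag, true
#' reference identity), regional lognormal abundances, Gaussian niche optima
#' on temperature and soil pH, and a habitat affinity (EcM taxa are
#' root-restricted).  Per-sample counts are multinomial draws at the sample's
#' sequencing depth from niche-modulated relative abundances.  When the spec
#' carries a singleton target, the lognormal sigma is calibrated so that the
#' expected combined-dataset singleton fraction (under a Poisson
#' approximation of the pooled counts) matches the target.
#'
#' @param spec A [community_spec()].
#' @param design Output of [generate_design()].
#' @param seed Integer seed.
#' @return A list with `reference` (per taxon: taxon_id, phylum,
#'   phylum_known, genus, species, gi, is_ecm, identity_true), `abundance`
#'   (integer matrix samples x taxa) and `ecm_genera` (character vector, the
#'   EcM lookup list).
#' @export
generate_community <- function(spec, design, seed = NULL) {
  stopifnot(inherits(spec, "community_spec"))
  if (spec$pool_size < 1) stop("generate_community: empty pool")
  with_seed(seed, {
    S <- spec$pool_size
    pp <- spec$phylum_proportions
    cls <- sample(names(pp), S, replace = TRUE, prob = pp)
    known_fungal <- c(Ascomycota = "Ascomycota", Basidiomycota = "Basidiomycota",
                      Zygomycota = "Zygomycota", other = "Fungi incertae sedis")
    phylum <- ifelse(cls == "unknown", NA, known_fungal[cls])
    # unknown-class taxa still have a true phylum, drawn from the known classes
    if (any(cls == "unknown")) {
      pk <- pp[names(known_fungal)]
      pk <- if (sum(pk) > 0) pk / sum(pk) else c(Ascomycota = 1, Basidiomycota = 0,
                                                 Zygomycota = 0, other = 0)
      phylum[cls == "unknown"] <-
        known_fungal[sample(names(pk), sum(cls == "unknown"), TRUE, pk)]
    }
    phylum_known <- cls != "unknown"

    # genus pool per phylum (~8 taxa per genus on average)
    genus <- character(S)
    for (ph in unique(phylum)) {
      i <- which(phylum == ph)
      ng <- max(3, round(length(i) / 8))
      tag <- gsub("[^A-Za-z]", "", substr(ph, 1, 5))
      genus[i] <- sample(sprintf("%sgenus%03d", tag, seq_len(ng)),
                         length(i), replace = TRUE)
    }
    species <- paste0(genus, "_sp", stats::ave(seq_len(S), genus, FUN = seq_along))

    # EcM flag at genus level among basidiomycetes
    ecm_genera <- character(0)
    bas <- phylum == "Basidiomycota"
    if (any(bas) && spec$ecm_fraction_of_basidiomycetes > 0) {
      gs <- sample(unique(genus[bas]))
      cum <- cumsum(vapply(gs, function(g) sum(genus[bas] == g), numeric(1)))
      ecm_genera <- gs[seq_len(max(1, which.min(
        abs(cum / sum(bas) - spec$ecm_fraction_of_basidiomycetes))))]
    }
    is_ecm <- genus %in% ecm_genera

    gi <- sample(10^6, S)
    identity_true <- round(runif(S, 98.5, 100), 2)

    env <- design$env
    smp <- design$samples
    sidx <- match(smp$plot, env$plot)
    Tj <- env$temperature[sidx]; pHj <- env$soil_pH[sidx]
    topt <- runif(S, min(env$temperature) - 1, max(env$temperature) + 1)
    phopt <- runif(S, min(env$soil_pH) - 0.3, max(env$soil_pH) + 0.3)
    w_leaf <- ifelse(is_ecm, 0, rbeta(S, 0.7, 0.7))
    hw <- outer(smp$habitat == "leaf", w_leaf,
                function(l, w) ifelse(l, w, 1 - w))

    z <- rnorm(S)  # fixed lognormal quantiles; sigma scales them
    weight_mat <- function(sig) {
      base <- exp(spec$abundance_lognormal[["mu"]] + sig * z)
      W <- matrix(base, nrow(smp), S, byrow = TRUE) * hw
      nt <- vapply(seq_len(S), function(i)
        niche_weight(Tj, topt[i], spec$niche_breadth_temperature),
        numeric(nrow(smp)))
      np <- vapply(seq_len(S), function(i)
        niche_weight(pHj, phopt[i], spec$niche_breadth_pH), numeric(nrow(smp)))
      W * nt * np
    }
    prob_mat <- function(sig) {
      W <- weight_mat(sig)
      rs <- rowSums(W)
      rs[rs == 0] <- 1
      W / rs
    }

    # expected pooled count per taxon (Poisson approximation), optionally
    # with a rare-tail floor: taxa whose expected pooled count falls below
    # `floor_m` are lifted to it, emulating the trace-level transients and
    # artifacts that make real amplicon datasets singleton-rich
    tail_mult <- function(sig, floor_m) {
      lam <- colSums(prob_mat(sig) * smp$depth)
      if (floor_m > 0) pmax(lam, floor_m) / pmax(lam, 1e-300)
      else rep(1, length(lam))
    }
    prob_mat_adj <- function(sig, floor_m) {
      W <- sweep(weight_mat(sig), 2, tail_mult(sig, floor_m), "*")
      rs <- rowSums(W); rs[rs == 0] <- 1
      W / rs
    }
    sig <- spec$abundance_lognormal[["sigma"]]
    floor_m <- 0
    if (!is.null(spec$singleton_target_fraction)) {
      # calibrate the lognormal sigma (and, when sigma alone cannot reach
      # the target at this pool size and depth, the rare-tail floor) so the
      # expected combined-dataset singleton fraction matches the target
      singleton_gap <- function(s, m = 0) {
        lam <- colSums(prob_mat_adj(s, m) * smp$depth)
        sum(lam * exp(-lam)) / sum(1 - exp(-lam)) -
          spec$singleton_target_fraction
      }
      lo <- singleton_gap(0.2); hi <- singleton_gap(10)
      if (sign(lo) != sign(hi)) {
        sig <- uniroot(singleton_gap, c(0.2, 10), tol = 1e-3)$root
      } else if (lo < 0 && hi < 0) {
        sig <- stats::optimize(function(s) abs(singleton_gap(s)),
                               c(0.2, 10))$minimum
        g_hi <- singleton_gap(sig, 1.2)
        if (sign(singleton_gap(sig, 1e-6)) != sign(g_hi)) {
          floor_m <- uniroot(function(m) singleton_gap(sig, m),
                             c(1e-6, 1.2), tol = 1e-4)$root
        } else {
          floor_m <- 1.2
          message("singleton target not exactly attainable; ",
                  "using the closest achievable configuration")
        }
      } else {
        sig <- stats::optimize(function(s) abs(singleton_gap(s)),
                               c(0.2, 10))$minimum
        message("singleton target not exactly attainable; ",
                "using closest sigma ", round(sig, 2))
      }
    }

    P <- prob_mat_adj(sig, floor_m)
    ab <- t(vapply(seq_len(nrow(smp)), function(j)
      as.integer(rmultinom(1, smp$depth[j], P[j, ])), integer(S)))
    taxon_id <- sprintf("TAX%05d", seq_len(S))
    dimnames(ab) <- list(smp$sample_id, taxon_id)

    list(reference = data.frame(taxon_id = taxon_id, phylum = unname(phylum),
                                phylum_known = phylum_known, genus = genus,
                                species = species, gi = gi, is_ecm = is_ecm,
                                identity_true = identity_true,
                                stringsAsFactors = FALSE),
         abundance = ab,
         ecm_genera = sort(ecm_genera))
  })
}

#' Simulate reads from a community
#'
#' Each true taxon receives a random ancestor sequence (150-300 bp); every
#' sampled sequence is a copy of its taxon's ancestor with iid substitutions
#' at the given divergence rate.  Read ids carry the sample of origin.
#'
#' @param community Output of [generate_community()].
#' @param divergence Per-base substitution probability in \[0, 0.5\].
#' @param seed Integer seed.
#' @return A list with `reads` (named [Biostrings::DNAStringSet]) and
#'   `read_map` (seq_id, sample_id, taxon_id).
#' @export
generate_sequences <- function(community, divergence = 0.005, seed = NULL) {
  if (divergence < 0 || divergence > 0.5)
    stop("generate_sequences: divergence must be in [0, 0.5]")
  with_seed(seed, {
    ab <- community$abundance
    taxa <- colnames(ab)
    bases <- c("A", "C", "G", "T")
    anc <- lapply(taxa, function(t)
      sample(bases, sample(150:300, 1), replace = TRUE))
    names(anc) <- taxa

    ids <- character(0); seqs <- character(0)
    map_sample <- character(0); map_taxon <- character(0)
    serial <- setNames(integer(nrow(ab)), rownames(ab))
    for (t in seq_along(taxa)) {
      n <- sum(ab[, t])
      if (n == 0) next
      a <- anc[[t]]; L <- length(a)
      M <- matrix(rep(a, n), nrow = n, byrow = TRUE)
      if (divergence > 0) {
        mut <- which(matrix(runif(n * L) < divergence, n, L))
        if (length(mut))
          M[mut] <- vapply(M[mut], function(x)
            sample(setdiff(bases, x), 1), character(1))
      }
      reads_t <- apply(M, 1, paste0, collapse = "")
      sample_of <- rep(rownames(ab), ab[, t])
      id_t <- vapply(sample_of, function(s) {
        serial[s] <<- serial[s] + 1L
        sprintf("%s_r%05d", s, serial[s])
      }, character(1), USE.NAMES = FALSE)
      ids <- c(ids, id_t); seqs <- c(seqs, reads_t)
      map_sample <- c(map_sample, sample_of)
      map_taxon <- c(map_taxon, rep(taxa[t], n))
    }
    reads <- Biostrings::DNAStringSet(setNames(seqs, ids))
    list(reads = reads,
         read_map = data.frame(seq_id = ids, sample_id = map_sample,
                               taxon_id = map_taxon, stringsAsFactors = FALSE))
  })
}

#' Map MOTUs to their dominant true taxon
#'
#' For simulated data, links every MOTU to the ground-truth taxon
#' contributing most of its member reads (ties lexicographic), e.g. to build
#' a query table for [generate_blast_table()] or to score recovery.
#'
#' @param motus A `motu_set` from [greedy_cluster()].
#' @param read_map The `read_map` from [generate_sequences()].
#' @return data.frame (query_id = motu_id, taxon_id).
#' @export
motu_truth <- function(motus, read_map) {
  idx <- match(motus$members$seq_id, read_map$seq_id)
  if (anyNA(idx)) stop("motu_truth: read ids missing from read map")
  tab <- table(motus$members$motu_id, read_map$taxon_id[idx])
  data.frame(query_id = rownames(tab),
             taxon_id = colnames(tab)[apply(tab, 1, which.max)],
             stringsAsFactors = FALSE)
}

#' BLAST-hit noise specification
#'
#' Controls the simulated tabular BLAST results: hits per query (at most 10,
#' the number retained per query), how many of them agree with the true genus
#' and species, Gaussian noise on the percent identity, and the
#' probabilities of a query returning no hits or only non-fungal hits.
#'
#' @param n_hits_per_motu Hits per query (<= 10).
#' @param congruent_hits_genus,congruent_hits_species Counts of hits carrying
#'   the true genus / the true genus and species.
#' @param identity_noise_sd SD (percentage points) on the true identity.
#' @param p_no_hit,p_nonfungal Per-query probabilities.
#' @param seed Integer seed.
#' @return An object of class `hit_noise_spec`.
#' @export
hit_noise_spec <- function(n_hits_per_motu = 10,
                           congruent_hits_genus = 9,
                           congruent_hits_species = 8,
                           identity_noise_sd = 0.5,
                           p_no_hit = 0.08,
                           p_nonfungal = 0.03,
                           seed = NULL) {
  if (n_hits_per_motu < 0 || n_hits_per_motu > 10)
    stop("hit_noise_spec: n_hits_per_motu must be in 0..10")
  if (congruent_hits_genus > n_hits_per_motu ||
      congruent_hits_species > n_hits_per_motu)
    stop("hit_noise_spec: congruent counts must not exceed n_hits_per_motu")
  stopifnot(p_no_hit >= 0, p_no_hit <= 1, p_nonfungal >= 0, p_nonfungal <= 1,
            identity_noise_sd >= 0)
  structure(list(n_hits_per_motu = as.integer(n_hits_per_motu),
                 congruent_hits_genus = as.integer(congruent_hits_genus),
                 congruent_hits_species = as.integer(congruent_hits_species),
                 identity_noise_sd = identity_noise_sd,
                 p_no_hit = p_no_hit, p_nonfungal = p_nonfungal, seed = seed),
            class = "hit_noise_spec")
}

#' Generate a noisy BLAST-hit table with known ground truth
#'
#' Per query: taxa whose taxonomy is withheld (the "unknown" class) yield no
#' rows, as do queries hit by `p_no_hit`; `p_nonfungal` queries return only
#' plant hits.  Otherwise congruent hits carry the query taxon's genus (and,
#' for the species-congruent subset, its species) and its GI number, with
#' identities centred on the taxon's true reference identity; the remaining
#' hits are decoys drawn from other pool members, always valid under the
#' identity/e-value gates (identity 90.5-95, e-value < 1e-50) so they act as
#' incongruent votes.  E-values of congruent hits are log-uniform in
#' \[1e-180, 1e-55\].
#'
#' @param reference The `reference` data.frame from [generate_community()].
#' @param noise A [hit_noise_spec()].
#' @param queries Optional data.frame (query_id, taxon_id); defaults to one
#'   query per reference taxon.
#' @return data.frame with columns query_id, gi, taxonomy (semicolon path,
#'   phylum first), pct_identity, evalue, aln_len.
#' @export
generate_blast_table <- function(reference, noise, queries = NULL) {
  stopifnot(inherits(noise, "hit_noise_spec"))
  if (is.null(queries))
    queries <- data.frame(query_id = reference$taxon_id,
                          taxon_id = reference$taxon_id,
                          stringsAsFactors = FALSE)
  with_seed(noise$seed, {
    rows <- vector("list", nrow(queries))
    k <- noise$n_hits_per_motu
    for (q in seq_len(nrow(queries))) {
      i <- match(queries$taxon_id[q], reference$taxon_id)
      if (!reference$phylum_known[i]) next
      if (runif(1) < noise$p_no_hit) next
      qid <- queries$query_id[q]
      if (runif(1) < noise$p_nonfungal) {
        pg <- sample(20, k, TRUE)
        rows[[q]] <- data.frame(
          query_id = qid, gi = 2e6 + sample(1e5, k),
          taxonomy = sprintf("Streptophyta;Plantgenus%02d;Plantgenus%02d_sp1",
                             pg, pg),
          pct_identity = round(pmin(100, rnorm(k, 95, 2)), 2),
          evalue = 10^runif(k, -120, -55),
          aln_len = sample(150:300, k, TRUE), stringsAsFactors = FALSE)
        next
      }
      if (k == 0) next
      n_gen <- min(noise$congruent_hits_genus, k)
      n_sp <- min(noise$congruent_hits_species, n_gen)
      n_dec <- k - n_gen
      tax <- id <- ev <- gi <- numeric(0)
      ph <- reference$phylum[i]; gn <- reference$genus[i]
      sp <- reference$species[i]
      cong_id <- round(pmin(100, pmax(70, rnorm(
        n_gen, reference$identity_true[i], noise$identity_noise_sd))), 2)
      tax <- c(
        rep(paste(ph, gn, sp, sep = ";"), n_sp),
        if (n_gen > n_sp)
          paste(ph, gn, paste0(gn, "_spX", seq_len(n_gen - n_sp)), sep = ";"))
      gi <- rep(reference$gi[i], n_gen)
      id <- cong_id
      ev <- 10^runif(n_gen, -180, -55)
      if (n_dec > 0) {
        # decoys never share the query genus, so congruence counts are exact
        pool <- setdiff(which(reference$phylum_known &
                                reference$genus != reference$genus[i]), i)
        if (length(pool) == 0) pool <- i
        d <- sample(pool, n_dec, replace = length(pool) < n_dec)
        tax <- c(tax, paste(reference$phylum[d], reference$genus[d],
                            reference$species[d], sep = ";"))
        gi <- c(gi, reference$gi[d])
        id <- c(id, round(runif(n_dec, 90.5, 95), 2))
        ev <- c(ev, 10^runif(n_dec, -120, -52))
      }
      rows[[q]] <- data.frame(query_id = qid, gi = gi, taxonomy = tax,
                              pct_identity = id, evalue = ev,
                              aln_len = sample(150:300, k, TRUE),
                              stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
      out <- data.frame(query_id = character(), gi = numeric(),
                        taxonomy = character(), pct_identity = numeric(),
                        evalue = numeric(), aln_len = integer(),
                        stringsAsFactors = FALSE)
    rownames(out) <- NULL
    out
  })
}
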