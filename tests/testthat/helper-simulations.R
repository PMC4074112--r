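# One composition-analysis trial on simulated root samples: generate a
# community (null or niche-structured), rarefy/binarize, and return the
# temperature term's PERMANOVA p-value under strata-restricted permutations.
composition_trial <- function(seed, null = TRUE, pool = 150, depth = 400,
                              n_perm = 199) {
  d <- generate_design(design_spec(seed = seed))
  spec <- if (null)
    community_spec(pool_size = pool, singleton_target_fraction = NULL,
                   niche_breadth_temperature = Inf, niche_breadth_pH = Inf)
  else
    community_spec(pool_size = pool, singleton_target_fraction = NULL)
  cm <- generate_community(spec, d, seed = seed + 1)
  root <- d$samples[d$samples$habitat == "root", ]
  ab <- cm$abundance[root$sample_id, , drop = FALSE]
  comp <- prepare_composition(ab, d$samples, depth = depth, min_plots = 3,
                              seed = seed + 2)
  env <- d$env[match(comp$design$plot, d$env$plot), ]
  dat <- data.frame(region = comp$design$region, site = comp$design$site,
                    soil_pH = env$soil_pH, temperature = env$temperature)
  dd <- suppressWarnings(sorensen_dissimilarity(comp$matrix))
  fit <- permanova_nested(dd, dat, n_perm = n_perm, seed = seed + 3)
  fit$table$p[fit$table$term == "temperature"]
}
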