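# Independent oracles used across the test files.

# Full dynamic-programming Needleman-Wunsch in plain R, written directly from
# the scoring definition (match +1, mismatch -1, gap column -2, end gaps
# penalized).  Returns the optimal score and the identity of the traceback
# preferring diagonal, then up, then left.
oracle_nw <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  na <- length(a); nb <- length(b)
  m <- matrix(0, na + 1, nb + 1)
  m[1, ] <- -2 * (0:nb)
  m[, 1] <- -2 * (0:na)
  sub <- function(x, y) if (x == y && x %in% c("A", "C", "G", "T")) 1 else -1
  for (i in 1:na) for (j in 1:nb)
    m[i + 1, j + 1] <- max(m[i, j] + sub(a[i], b[j]),
                           m[i, j + 1] - 2, m[i + 1, j] - 2)
  i <- na; j <- nb; cols <- 0; ident <- 0
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && m[i + 1, j + 1] == m[i, j] + sub(a[i], b[j])) {
      ident <- ident + (sub(a[i], b[j]) == 1); i <- i - 1; j <- j - 1
    } else if (i > 0 && m[i + 1, j + 1] == m[i, j + 1] - 2) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  list(score = m[na + 1, nb + 1], identity = ident / cols)
}

# Greedy clustering replayed directly from its definition, using the R
# oracle identity, for tiny fixtures.
oracle_greedy <- function(seqs, ids, threshold) {
  grp <- split(ids, seqs)
  uniq <- data.frame(seq = names(grp),
                     rep_id = vapply(grp, min, character(1)),
                     n = lengths(grp), stringsAsFactors = FALSE)
  uniq <- uniq[order(-uniq$n, uniq$rep_id), ]
  centroids <- character(0)
  assign_to <- integer(nrow(uniq))
  for (k in seq_len(nrow(uniq))) {
    hit <- 0
    for (c in seq_along(centroids))
      if (oracle_nw(uniq$seq[k], centroids[c])$identity >= threshold) {
        hit <- c; break
      }
    if (hit == 0) { centroids <- c(centroids, uniq$seq[k]); hit <- length(centroids) }
    assign_to[k] <- hit
  }
  membership <- integer(0)
  for (k in seq_len(nrow(uniq)))
    membership[grp[[uniq$seq[k]]]] <- assign_to[k]
  membership[ids]
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

# mutate a sequence with iid substitutions at a given rate
mutate_dna <- function(seq, rate) {
  x <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(x)) < rate)
  for (i in hit) x[i] <- sample(setdiff(c("A", "C", "G", "T"), x[i]), 1)
  paste(x, collapse = "")
}

# small standard design used in several files
tiny_design <- function(seed = 11, depth_leaf = c(80, 160), depth_root = c(60, 120)) {
  generate_design(design_spec(n_regions = 2, sites_per_region = c(2, 2),
                              plots_per_site = 2, depth_range_leaf = depth_leaf,
                              depth_range_root = depth_root, seed = seed))
}
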