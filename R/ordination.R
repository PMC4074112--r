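#' Rarefied presence/absence composition matrix
#'
#' Rarefies every sample to a common depth, binarizes, and discards MOTUs
#' detected in fewer than `min_plots` plots, which would otherwise distort
#' the correspondence analysis.
#'
#' @param abundance Samples x MOTUs count matrix (one habitat).
#' @param design Sample table with `sample_id` and `plot` (and the design
#'   and covariate columns used downstream).
#' @param depth Rarefaction depth; every sample must reach it.
#' @param min_plots Minimum plot occupancy (default 3).
#' @param seed Integer seed for the rarefaction draw.
#' @return list(matrix = binary samples x MOTUs matrix, design = design rows
#'   aligned to the matrix rows).
#' @export
prepare_composition <- function(abundance, design, depth, min_plots = 3,
                                seed = NULL) {
  low <- rowSums(abundance) < depth
  if (any(low))
    stop("prepare_composition: sample(s) below depth ", depth, ": ",
         paste(rownames(abundance)[low], collapse = ", "))
  with_seed(seed, {
    rar <- t(apply(abundance, 1, function(x)
      rarefy_counts(x, depth)))
    dimnames(rar) <- dimnames(abundance)
    pres <- (rar > 0) * 1L
    idx <- match(rownames(pres), design$sample_id)
    if (anyNA(idx)) stop("prepare_composition: samples missing from design")
    occ <- apply(pres, 2, function(col)
      length(unique(design$plot[idx][col > 0])))
    pres <- pres[, occ >= min_plots, drop = FALSE]
    list(matrix = pres, design = design[idx, , drop = FALSE])
  })
}

#' Correspondence analysis
#'
#' Chi-square-metric ordination of a non-negative matrix: with
#' `P = X / sum(X)`, row and column margins `r`, `c`, the standardized
#' residuals `S = diag(1/sqrt(r)) (P - r c') diag(1/sqrt(c))` are decomposed
#' by SVD; eigenvalues are the squared singular values, rows are reported in
#' principal coordinates and columns in standard coordinates.
#'
#' @param x Non-negative matrix without all-zero rows or columns.
#' @return Object of class `motu_coa`: eigenvalues, inertia_fraction,
#'   total_inertia, row_scores (principal), col_scores (standard).
#' @export
coa <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("coa: matrix must be non-negative")
  rs <- rowSums(x); cs <- colSums(x)
  if (any(rs == 0))
    stop("coa: all-zero row: ", paste(rownames(x)[rs == 0], collapse = ", "))
  if (any(cs == 0))
    stop("coa: all-zero column: ", paste(colnames(x)[cs == 0], collapse = ", "))
  n <- sum(x)
  P <- x / n
  r <- rs / n; c <- cs / n
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, c)) %*% diag(1 / sqrt(c))
  sv <- svd(S)
  keep <- sv$d > max(sv$d[1], 1) * 1e-9
  d <- sv$d[keep]
  eig <- d^2
  if (length(eig) == 0) {
    out <- list(eigenvalues = numeric(0), inertia_fraction = numeric(0),
                total_inertia = 0,
                row_scores = matrix(0, nrow(x), 0,
                                    dimnames = list(rownames(x), NULL)),
                col_scores = matrix(0, ncol(x), 0,
                                    dimnames = list(colnames(x), NULL)))
    return(structure(out, class = "motu_coa"))
  }
  U <- sv$u[, keep, drop = FALSE]; V <- sv$v[, keep, drop = FALSE]
  row_scores <- diag(1 / sqrt(r)) %*% U %*% diag(d, length(d))
  col_scores <- diag(1 / sqrt(c)) %*% V
  dimnames(row_scores) <- list(rownames(x), paste0("CA", seq_along(d)))
  dimnames(col_scores) <- list(colnames(x), paste0("CA", seq_along(d)))
  structure(list(eigenvalues = eig, inertia_fraction = eig / sum(eig),
                 total_inertia = sum(eig),
                 row_scores = row_scores, col_scores = col_scores),
            class = "motu_coa")
}

#' @export
print.motu_coa <- function(x, ...) {
  cat("Correspondence analysis:", length(x$eigenvalues), "axes, total inertia",
      signif(x$total_inertia, 5), "\n")
  k <- min(5, length(x$eigenvalues))
  if (k > 0)
    print(data.frame(axis = paste0("CA", seq_len(k)),
                     eigenvalue = signif(x$eigenvalues[seq_len(k)], 5),
                     inertia_pct = round(100 * x$inertia_fraction[seq_len(k)], 2)))
  invisible(x)
}

#' Sorensen dissimilarity of binary community data
#'
#' `d = 1 - 2a / (2a + b + c)` per sample pair, with `a` shared MOTUs and
#' `b`, `c` the MOTUs unique to each sample (the presence/absence reduction
#' of Bray-Curtis).  An empty sample is at distance 1 from any non-empty
#' sample (with a warning) and 0 from another empty one.
#'
#' @param x Samples x MOTUs binary matrix.
#' @return A `dist` object.
#' @export
sorensen_dissimilarity <- function(x) {
  x <- (as.matrix(x) > 0) * 1
  n <- nrow(x)
  rs <- rowSums(x)
  if (any(rs == 0)) warning("sorensen_dissimilarity: empty sample(s): ",
                            paste(rownames(x)[rs == 0], collapse = ", "))
  A <- tcrossprod(x)                      # shared counts
  tot <- outer(rs, rs, "+")
  D <- 1 - 2 * A / tot
  D[tot == 0] <- 0                        # two empty samples
  diag(D) <- 0
  stats::as.dist(D)
}

# all permutations of 1..n (lexicographic), as a list of integer vectors
perms_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    sub <- perms_of(n - 1L)
    rest <- setdiff(seq_len(n), i)
    out <- c(out, lapply(sub, function(p) c(i, rest[p])))
  }
  out
}

# one random permutation of seq_len(n) restricted to strata blocks
strata_permutation <- function(n, blocks) {
  p <- seq_len(n)
  for (b in blocks) p[b] <- b[sample.int(length(b))]
  p
}

# every within-strata permutation (Cartesian product over blocks)
strata_enumeration <- function(n, blocks) {
  total <- prod(vapply(blocks, function(b) factorial(length(b)), numeric(1)))
  if (total > 2e5)
    stop("complete enumeration infeasible: ", total, " permutations")
  res <- list(seq_len(n))
  for (b in blocks) {
    bp <- perms_of(length(b))
    res <- unlist(lapply(res, function(base) lapply(bp, function(q) {
      base[b] <- b[q]; base
    })), recursive = FALSE)
  }
  res
}

#' Nested PERMANOVA with strata-restricted permutations
#'
#' Permutational multivariate analysis of variance on a distance matrix with
#' sequential (Type I) partitioning in the given term order.  The squared
#' distances are Gower-centered; each term's sum of squares is the trace of
#' its incremental hat-matrix projection of the centered matrix.  P-values
#' are obtained by permuting samples only within strata blocks (e.g. within
#' region, respecting the nesting of sites in regions), either by Monte
#' Carlo (`p = (1 + #{F* >= F}) / (1 + n_perm)`) or, with
#' `complete = TRUE`, by full enumeration of the within-strata permutation
#' group (`p = #{F* >= F} / n_total`, the identity included).
#'
#' @param d A `dist` object or square symmetric matrix.
#' @param data data.frame of design factors and covariates, rows aligned
#'   with `d`.
#' @param terms Character vector of model terms, fitted sequentially;
#'   interactions as `"a:b"`.
#' @param strata Column name of the blocking factor, or `NULL` for free
#'   permutation.
#' @param n_perm Number of random permutations (ignored when complete).
#' @param seed Integer seed for the permutation stream.
#' @param complete Enumerate all within-strata permutations instead.
#' @return Object of class `permanova`: a list with `table` (term, Df,
#'   SumOfSqs, R2, F, p) and attributes of the run.
#' @export
permanova_nested <- function(d, data,
                             terms = c("region", "soil_pH", "temperature",
                                       "region:site"),
                             strata = "region", n_perm = 999, seed = NULL,
                             complete = FALSE) {
  D <- as.matrix(d)
  n <- nrow(D)
  stopifnot(nrow(data) == n, isSymmetric(unname(D)))
  if (!complete && n_perm < 1) stop("permanova_nested: n_perm must be >= 1")
  vars <- unique(unlist(strsplit(terms, ":", fixed = TRUE)))
  miss <- setdiff(vars, names(data))
  if (length(miss)) stop("permanova_nested: missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyNA(data[vars])) stop("permanova_nested: incomplete term columns")

  # Gower-centered inner-product matrix
  A <- -0.5 * D^2
  C <- diag(n) - matrix(1 / n, n, n)
  G <- C %*% A %*% C
  ss_total <- sum(diag(G))

  # incremental hat matrices per sequential term
  hat_of <- function(fml) {
    X <- model.matrix(fml, data)
    q <- qr(X)
    Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
    tcrossprod(Q)
  }
  H_prev <- matrix(1 / n, n, n)           # intercept
  df <- numeric(length(terms)); dH <- vector("list", length(terms))
  for (k in seq_along(terms)) {
    fml <- as.formula(paste("~", paste(terms[seq_len(k)], collapse = " + ")))
    H_k <- hat_of(fml)
    dH[[k]] <- H_k - H_prev
    df[k] <- round(sum(diag(dH[[k]])))
    H_prev <- H_k
  }
  if (any(df == 0))
    warning("permanova_nested: collinear term(s) with zero df: ",
            paste(terms[df == 0], collapse = ", "))
  df_res <- n - 1 - sum(df)
  if (df_res <= 0) stop("permanova_nested: no residual degrees of freedom")

  ss <- vapply(dH, function(H) sum(H * G), numeric(1))
  ss_res <- ss_total - sum(ss)
  f_obs <- (ss / pmax(df, 1)) / (ss_res / df_res)
  f_obs[df == 0] <- NA

  # permutation null: permute the distance matrix, keep the design fixed
  blocks <- if (is.null(strata)) list(seq_len(n))
            else split(seq_len(n), data[[strata]])
  dH_vec <- vapply(dH, as.vector, numeric(n * n))  # n^2 x n_terms
  f_star <- function(perm) {
    Gp <- G[perm, perm]
    ssp <- as.vector(crossprod(dH_vec, as.vector(Gp)))
    ssr <- ss_total - sum(ssp)
    (ssp / pmax(df, 1)) / (ssr / df_res)
  }
  eps <- 1e-12 * (1 + abs(f_obs))
  if (complete) {
    perms <- strata_enumeration(n, blocks)
    FS <- vapply(perms, f_star, numeric(length(terms)))
    exceed <- rowSums(FS >= f_obs - eps, na.rm = TRUE)
    p <- exceed / length(perms)
    n_used <- length(perms)
  } else {
    p <- with_seed(seed, {
      exceed <- numeric(length(terms))
      for (b in seq_len(n_perm)) {
        fs <- f_star(strata_permutation(n, blocks))
        exceed <- exceed + (fs >= f_obs - eps)
      }
      (1 + exceed) / (1 + n_perm)
    })
    n_used <- n_perm
  }
  p[df == 0] <- NA

  tab <- data.frame(term = c(terms, "Residual", "Total"),
                    Df = c(df, df_res, n - 1),
                    SumOfSqs = c(ss, ss_res, ss_total),
                    R2 = c(ss, ss_res, ss_total) / ss_total,
                    F = c(f_obs, NA, NA),
                    p = c(p, NA, NA))
  structure(list(table = tab, n_perm = n_used, strata = strata,
                 complete = complete), class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  cat("PERMANOVA (sequential SS,",
      if (x$complete) "complete enumeration of" else "", x$n_perm,
      "within-strata permutations",
      if (!is.null(x$strata)) paste0("; strata = ", x$strata), ")\n")
  tab <- x$table
  tab$SumOfSqs <- signif(tab$SumOfSqs, 5)
  tab$R2 <- round(tab$R2, 3)
  tab$F <- signif(tab$F, 4)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Pearson correlation table with tests
#'
#' Pairwise Pearson correlations among numeric columns with two-sided
#' p-values from the t distribution on `n - 2` degrees of freedom, the
#' screening step used to pick uncorrelated environmental covariates.
#'
#' @param env data.frame; non-numeric columns are dropped.
#' @return list(r, p, n) of symmetric matrices / sample size.
#' @export
pearson_table <- function(env) {
  num <- env[vapply(env, is.numeric, logical(1))]
  if (nrow(num) < 3) stop("pearson_table: need at least 3 rows")
  v <- names(num)
  k <- length(v)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(v, v))
  diag(r) <- 1; diag(p) <- 0
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    if (sd(num[[i]]) == 0 || sd(num[[j]]) == 0) {
      warning("pearson_table: zero variance in ", v[i], " or ", v[j])
      next
    }
    ct <- cor.test(num[[i]], num[[j]], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(r = r, p = p, n = nrow(num))
}

#' PCA of standardized environmental variables
#'
#' Principal component analysis of the correlation matrix, reporting
#' variance fractions and per-variable axis contributions (percent of each
#' axis's loading norm).
#'
#' @param env data.frame; non-numeric columns are dropped.
#' @return Object of class `env_pca`: loadings, scores,
#'   variance_fraction, contributions (percent).
#' @export
env_pca <- function(env) {
  num <- env[vapply(env, is.numeric, logical(1))]
  if (ncol(num) < 2) stop("env_pca: need at least 2 numeric variables")
  if (nrow(num) < 3) stop("env_pca: need at least 3 rows")
  const <- vapply(num, function(x) sd(x) == 0, logical(1))
  if (any(const))
    stop("env_pca: constant column(s): ", paste(names(num)[const], collapse = ", "))
  fit <- prcomp(num, center = TRUE, scale. = TRUE)
  vf <- fit$sdev^2 / sum(fit$sdev^2)
  contrib <- 100 * fit$rotation^2
  structure(list(loadings = fit$rotation, scores = fit$x,
                 variance_fraction = vf, contributions = contrib),
            class = "env_pca")
}

#' @export
print.env_pca <- function(x, ...) {
  cat("PCA of", nrow(x$loadings), "standardized variables\n")
  cat("variance explained (%):",
      paste0(round(100 * x$variance_fraction, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Quadratic richness-temperature trend
#'
#' Least-squares fit of `richness = b0 + b1 T + b2 T^2` with a two-sided
#' t-test on the quadratic coefficient; a significantly negative `b2` with
#' an interior peak indicates a mid-domain (hump-shaped) richness pattern.
#'
#' @param richness,temperature Numeric vectors (>= 4 points).
#' @return Object of class `quad_trend`: coefficients, r_squared,
#'   p_quadratic, peak (at `-b1 / 2 b2` when `b2 < 0`, else `NA`), model.
#' @export
quadratic_trend <- function(richness, temperature) {
  stopifnot(length(richness) == length(temperature))
  if (length(richness) < 4) stop("quadratic_trend: need at least 4 points")
  if (length(unique(temperature)) < 3)
    stop("quadratic_trend: collinear design (fewer than 3 distinct temperatures)")
  fit <- lm(richness ~ temperature + I(temperature^2))
  sm <- summary(fit)
  b <- coef(fit)
  p_quad <- sm$coefficients["I(temperature^2)", "Pr(>|t|)"]
  peak <- if (is.finite(b[3]) && b[3] < 0) unname(-b[2] / (2 * b[3])) else NA_real_
  structure(list(coefficients = b, r_squared = sm$r.squared,
                 p_quadratic = p_quad, peak = peak, model = fit),
            class = "quad_trend")
}

#' @export
print.quad_trend <- function(x, ...) {
  cat("Quadratic trend: R2 =", round(x$r_squared, 3),
      "; p(quadratic) =", signif(x$p_quadratic, 3), "\n")
  if (!is.na(x$peak)) cat("estimated peak at", round(x$peak, 2), "degC\n")
  invisible(x)
}
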