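#' @name community_distance
#' @title Community distances, PCoA, PERMANOVA and PERMDISP
#'
#' @description
#' First-principles implementations of the distance-based machinery:
#' Bray-Curtis, Sorensen (Bray-Curtis on presence/absence) and Hellinger
#' distances; classical principal coordinate analysis; PERMANOVA with free
#' permutation of sample labels; and PERMDISP on distances to group spatial
#' medians with both a parametric ANOVA p and a permutation p. All
#' permutation p values use the (1 + count) / (1 + n_perm) convention, so
#' the minimum attainable p with 999 permutations is 0.001.
NULL

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (sum(x) + sum(y) == 0) stop("both vectors are all-zero: distance undefined")
}

#' Bray-Curtis dissimilarity
#'
#' `sum(|x - y|) / sum(x + y)`, in `[0, 1]`.
#' @param x,y non-negative count vectors of equal length
#' @return a number in `[0, 1]`
#' @export
bray_curtis <- function(x, y) {
  check_pair(x, y)
  sum(abs(x - y)) / sum(x + y)
}

#' Sorensen dissimilarity
#'
#' Bray-Curtis applied to presence/absence; equals `(b + c) / (2a + b + c)`
#' for shared richness `a` and unique richness `b`, `c`.
#' @inheritParams bray_curtis
#' @return a number in `[0, 1]`
#' @export
sorensen <- function(x, y) {
  check_pair(x, y)
  bray_curtis(as.numeric(x > 0), as.numeric(y > 0))
}

#' Hellinger distance
#'
#' Euclidean distance between square-root relative-abundance vectors;
#' range `[0, sqrt(2)]`.
#' @inheritParams bray_curtis
#' @return a number in `[0, sqrt(2)]`
#' @export
hellinger_distance <- function(x, y) {
  check_pair(x, y)
  if (sum(x) == 0 || sum(y) == 0) stop("zero-sum vector: Hellinger undefined")
  sqrt(sum((sqrt(x / sum(x)) - sqrt(y / sum(y)))^2))
}

#' Pairwise distance matrix of an ASV table
#'
#' @param table an [asv_table] (samples in rows)
#' @param method `"bray"`, `"sorensen"` or `"hellinger"`
#' @return a symmetric numeric matrix with zero diagonal, sample IDs as
#'   dimnames, class `distance_matrix`
#' @export
distance_matrix <- function(table, method = c("bray", "sorensen", "hellinger")) {
  method <- match.arg(method)
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (method == "sorensen") m <- (m > 0) * 1
  n <- nrow(m)
  if (method == "hellinger") {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("zero-sum sample(s): ",
                           paste(rownames(m)[rs == 0], collapse = ", "))
    h <- sqrt(m / rs)
    g <- tcrossprod(h)
    d2 <- outer(diag(g), diag(g), "+") - 2 * g
    d <- sqrt(pmax(d2, 0))
  } else {
    rs <- rowSums(m)
    if (any(rs == 0)) stop("all-zero sample(s): ",
                           paste(rownames(m)[rs == 0], collapse = ", "))
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      xi <- m[i, ]
      rest <- m[(i + 1):n, , drop = FALSE]
      num <- rowSums(abs(rest - rep(xi, each = nrow(rest))))
      den <- rs[(i + 1):n] + rs[i]
      d[i, (i + 1):n] <- d[(i + 1):n, i] <- num / den
    }
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

as_distance_matrix <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d) || max(abs(d - t(d))) > 1e-10)
    stop("distance matrix must be square and symmetric")
  if (any(!is.finite(d)) || any(d < 0)) stop("distances must be finite and >= 0")
  d
}

#' Principal coordinate analysis (classical metric scaling)
#'
#' Gower-centers `-d^2 / 2`, eigendecomposes, and returns coordinates for
#' the positive-eigenvalue axes (eigenvector times sqrt(eigenvalue)), in
#' descending eigenvalue order. Negative eigenvalues (non-Euclidean input)
#' are reported, and their "imaginary" coordinates are kept separately for
#' the PERMDISP correction. Eigenvalues with `|lambda| < 1e-9 * max(lambda)`
#' are treated as zero.
#'
#' @param d a square symmetric distance matrix (or `distance_matrix`)
#' @return list of class `pcoa` with `ids`, `coordinates` (positive axes),
#'   `imaginary_coordinates`, `eigenvalues` (all, descending),
#'   `proportion_explained` (positive axes, relative to the positive sum)
#' @export
pcoa <- function(d) {
  d <- as_distance_matrix(d)
  n <- nrow(d)
  if (n < 3) stop("PCoA needs at least 3 samples")
  a <- -0.5 * d^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  g <- (g + t(g)) / 2
  e <- eigen(g, symmetric = TRUE)
  tol <- 1e-9 * max(abs(e$values))
  pos <- e$values > tol
  neg <- e$values < -tol
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  imag <- e$vectors[, neg, drop = FALSE] %*%
    diag(sqrt(-e$values[neg]), sum(neg))
  rownames(coords) <- rownames(imag) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  structure(list(ids = rownames(d),
                 coordinates = coords,
                 imaginary_coordinates = imag,
                 eigenvalues = e$values,
                 proportion_explained = e$values[pos] / sum(e$values[pos])),
            class = "pcoa")
}

#' @export
print.pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d positive axes (%d negative eigenvalues)\n",
              length(x$ids), ncol(x$coordinates), ncol(x$imaginary_coordinates)))
  pe <- utils::head(x$proportion_explained, 3)
  cat("first axes explain: ", paste(sprintf("%.1f%%", 100 * pe), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[lower.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- d2[idx, idx, drop = FALSE]
    ss_within <- ss_within + sum(sub[lower.tri(sub)]) / length(idx)
  }
  c(ss_total = ss_total, ss_within = ss_within,
    ss_among = ss_total - ss_within)
}

pseudo_f <- function(d2, groups) {
  n <- nrow(d2)
  g <- length(unique(groups))
  ss <- permanova_ss(d2, groups)
  if (ss[["ss_among"]] <= 0 && ss[["ss_within"]] <= 0) return(0)  # degenerate: all points identical
  unname((ss[["ss_among"]] / (g - 1)) / (ss[["ss_within"]] / (n - g)))
}

#' PERMANOVA (one-way)
#'
#' Distance-based pseudo-F with a permutation p value from free permutation
#' of the group labels.
#'
#' @param d square symmetric distance matrix
#' @param groups vector of group labels, one per sample
#' @param n_perm number of permutations (default 999)
#' @param seed integer seed
#' @return list of class `permutation_test`: `statistic` (pseudo-F),
#'   `permutation_p`, `n_permutations`, `seed`, `df` (among, within), `r2`
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  d <- as_distance_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups must match the matrix dimension")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  if (n_perm < 1) stop("n_perm must be >= 1")
  d2 <- d^2
  n <- nrow(d2); g <- length(tab)
  ss <- permanova_ss(d2, groups)
  f_obs <- pseudo_f(d2, groups)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    fp <- pseudo_f(d2, groups[sample.int(n)])
    if (fp >= f_obs) count <- count + 1L
  }
  structure(list(statistic = unname(f_obs),
                 permutation_p = (1 + count) / (1 + n_perm),
                 n_permutations = n_perm, seed = seed,
                 df = c(among = g - 1, within = n - g),
                 r2 = unname(ss[["ss_among"]] / ss[["ss_total"]])),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("pseudo-F = %.4f, permutation P = %.4g (%d permutations)\n",
              x$statistic, x$permutation_p, x$n_permutations))
  invisible(x)
}

#' Pairwise PERMANOVA contrasts
#'
#' One PERMANOVA per unordered pair of groups on the corresponding
#' sub-matrix, with multiplicity adjustment.
#'
#' @inheritParams permanova
#' @param adjust `"fdr_bh"` (default), `"bonferroni"` or `"none"`
#' @return data.frame with one row per contrast: group1, group2, statistic,
#'   p, p_adjusted
#' @export
pairwise_permanova <- function(d, groups, n_perm = 999, seed = 1L,
                               adjust = c("fdr_bh", "bonferroni", "none")) {
  adjust <- match.arg(adjust)
  d <- as_distance_matrix(d)
  groups <- as.character(groups)
  lev <- unique(groups)
  cmb <- utils::combn(lev, 2)
  res <- apply(cmb, 2, function(pair) {
    idx <- groups %in% pair
    r <- permanova(d[idx, idx, drop = FALSE], groups[idx],
                   n_perm = n_perm, seed = seed)
    c(statistic = r$statistic, p = r$permutation_p)
  })
  method <- switch(adjust, fdr_bh = "BH", bonferroni = "bonferroni", none = "none")
  data.frame(group1 = cmb[1, ], group2 = cmb[2, ],
             statistic = res["statistic", ], p = res["p", ],
             p_adjusted = stats::p.adjust(res["p", ], method = method),
             stringsAsFactors = FALSE)
}

#' Spatial median (geometric median) of a point set
#'
#' Weiszfeld iteration minimizing the summed Euclidean distances, tolerance
#' `1e-8`. Points coinciding with the current iterate get a capped weight,
#' which keeps the iteration defined at data points.
#'
#' @param x numeric matrix (points in rows)
#' @param tol convergence tolerance on the iterate displacement
#' @param max_iter iteration cap; exceeding it is an error
#' @return numeric vector, the coordinate-wise spatial median
#' @export
spatial_median <- function(x, tol = 1e-8, max_iter = 10000) {
  x <- as.matrix(x)
  if (nrow(x) == 1) return(drop(x[1, ]))
  m <- colMeans(x)
  for (it in seq_len(max_iter)) {
    dif <- sweep(x, 2, m)
    d <- sqrt(rowSums(dif^2))
    if (all(d < tol)) return(m)   # all points coincide with the iterate
    w <- 1 / pmax(d, tol)
    m_new <- colSums(x * w) / sum(w)
    if (sqrt(sum((m_new - m)^2)) < tol) return(m_new)
    m <- m_new
  }
  stop("spatial median iteration did not converge within ", max_iter,
       " iterations")
}

#' PERMDISP: homogeneity of multivariate dispersions
#'
#' Embeds the distance matrix by PCoA (keeping real and imaginary axes),
#' finds each group's spatial median in the embedded space, and measures
#' each sample's distance to its group median with the negative-eigenvalue
#' correction `sqrt(max(0, d_real^2 - d_imag^2))`. A classical one-way
#' ANOVA on these distances gives the parametric F and `Pr(>F)` (the
#' primary p value); a permutation p of the same F (shuffling the distances
#' across groups) is reported as a companion.
#'
#' @inheritParams permanova
#' @param type `"median"` (spatial median, default) or `"centroid"`
#' @return list of class `permdisp`: `distances` (per sample),
#'   `group_means` (average distance to median per group), `anova_f`,
#'   `anova_df`, `anova_p` (parametric), `anova_table`, `permutation`
#'   (a `permutation_test` of F)
#' @export
permdisp <- function(d, groups, n_perm = 999, seed = 1L,
                     type = c("median", "centroid")) {
  type <- match.arg(type)
  d <- as_distance_matrix(d)
  groups <- as.character(groups)
  if (length(groups) != nrow(d)) stop("groups must match the matrix dimension")
  tab <- table(groups)
  if (length(tab) < 2) stop("need at least 2 groups")
  if (any(tab < 2)) stop("singleton group(s): ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  emb <- pcoa(d)
  re <- emb$coordinates
  im <- emb$imaginary_coordinates
  z <- numeric(nrow(d))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ctr_fun <- if (type == "median") spatial_median else colMeans
    m_re <- ctr_fun(re[idx, , drop = FALSE])
    d_re2 <- rowSums(sweep(re[idx, , drop = FALSE], 2, m_re)^2)
    d_im2 <- 0
    if (ncol(im) > 0) {
      m_im <- ctr_fun(im[idx, , drop = FALSE])
      d_im2 <- rowSums(sweep(im[idx, , drop = FALSE], 2, m_im)^2)
    }
    z[idx] <- sqrt(pmax(0, d_re2 - d_im2))
  }
  names(z) <- rownames(d)
  # classical one-way ANOVA on the distances
  n <- length(z); k <- length(tab)
  grand <- mean(z)
  means <- c(tapply(z, groups, mean))
  ss_groups <- sum(tab * (means - grand)^2)
  ss_resid <- sum((z - means[groups])^2)
  df1 <- k - 1; df2 <- n - k
  f_obs <- (ss_groups / df1) / (ss_resid / df2)
  p_param <- stats::pf(f_obs, df1, df2, lower.tail = FALSE)
  anova_f_stat <- function(zz) {
    mm <- tapply(zz, groups, mean)
    ssg <- sum(tab * (mm - mean(zz))^2)
    ssr <- sum((zz - mm[groups])^2)
    (ssg / df1) / (ssr / df2)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (anova_f_stat(z[sample.int(n)]) >= f_obs) count <- count + 1L
  }
  anova_table <- data.frame(
    term = c("Groups", "Residuals"),
    Df = c(df1, df2),
    `Sum Sq` = c(ss_groups, ss_resid),
    `Mean Sq` = c(ss_groups / df1, ss_resid / df2),
    `F value` = c(f_obs, NA),
    `Pr(>F)` = c(p_param, NA),
    check.names = FALSE
  )
  structure(list(distances = z,
                 group_means = means,
                 anova_f = f_obs, anova_df = c(df1, df2), anova_p = p_param,
                 anova_table = anova_table,
                 permutation = structure(
                   list(statistic = f_obs,
                        permutation_p = (1 + count) / (1 + n_perm),
                        n_permutations = n_perm, seed = seed),
                   class = "permutation_test")),
            class = "permdisp")
}

#' @export
print.permdisp <- function(x, ...) {
  cat("PERMDISP (distances to group spatial median)\n")
  cat("average distance to median:\n")
  print(round(x$group_means, 4))
  cat(sprintf("ANOVA F = %.4f on %d and %d df, Pr(>F) = %.4g; permutation P = %.4g\n",
              x$anova_f, x$anova_df[1], x$anova_df[2], x$anova_p,
              x$permutation$permutation_p))
  invisible(x)
}
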