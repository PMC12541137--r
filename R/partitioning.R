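## Ordination-based trophic resource partitioning: Hellinger transform,
## Bray-Curtis dissimilarity, PCoA, pairwise permutation tests of species
## separation, and taxon-vector fitting.

#' Hellinger transform of a diet profile
#'
#' Rows are already relative abundances, so the transform is the elementwise
#' square root; each transformed row has unit sum of squares.
#'
#' @param profile A `diet_profile` table or RRA matrix.
#' @return Numeric matrix of square-root RRA.
#' @export
hellinger <- function(profile) {
  m <- if (is.data.frame(profile)) profile_matrix(profile) else profile
  sqrt(m)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(x, y) = sum|x - y| / sum(x + y)`; symmetric with zero diagonal, in
#' \[0,1\] for non-negative rows. Computed with [vegan::vegdist()].
#'
#' @param m Non-negative numeric matrix (rows = samples).
#' @return A `dist` object.
#' @export
bray_curtis <- function(m) {
  if (any(m < 0)) stop("Bray-Curtis requires non-negative entries")
  if (any(rowSums(m) == 0))
    stop("Bray-Curtis undefined for all-zero rows: ",
         paste(utils::head(rownames(m)[rowSums(m) == 0]), collapse = ", "))
  vegan::vegdist(m, method = "bray")
}

#' Principal coordinates analysis
#'
#' Gower double-centering `B = -1/2 J D^2 J` followed by eigendecomposition.
#' Scores are eigenvectors scaled by the square root of their (positive)
#' eigenvalues; axes are ordered by decreasing eigenvalue, negative
#' eigenvalues are reported but carry no axes (no Cailliez/Lingoes
#' correction), and each axis' sign is fixed so its largest-magnitude score
#' is positive.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix with zero
#'   diagonal.
#' @param n_axes Number of axes to retain (truncated with a warning if it
#'   exceeds the positive-eigenvalue count).
#' @return List: `scores` (n x n_axes matrix), `eigenvalues` (all, sorted
#'   decreasing), `prop_explained` (share of the positive eigenvalue sum per
#'   retained axis).
#' @export
pcoa <- function(d, n_axes = 2) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 observations")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  pos <- which(e$values > max(e$values[1], 0) * 1e-12 & e$values > 0)
  if (n_axes > length(pos)) {
    warning("only ", length(pos), " positive eigenvalues; truncating axes")
    n_axes <- length(pos)
  }
  scores <- e$vectors[, pos[seq_len(n_axes)], drop = FALSE] %*%
    diag(sqrt(e$values[pos[seq_len(n_axes)]]), n_axes)
  for (a in seq_len(ncol(scores)))
    if (scores[which.max(abs(scores[, a])), a] < 0)
      scores[, a] <- -scores[, a]
  rownames(scores) <- rownames(D)
  colnames(scores) <- paste0("PCoA", seq_len(ncol(scores)))
  list(scores = scores, eigenvalues = e$values,
       prop_explained = e$values[pos[seq_len(n_axes)]] /
         sum(e$values[e$values > 0]))
}

## centroid R2 of 2D scores relative to group labels
.centroid_r2 <- function(scores, labels) {
  gm <- rowsum(scores, labels) / as.vector(table(labels)[sort(unique(labels))])
  centered <- sweep(scores, 2, colMeans(scores))
  ss_tot <- sum(centered^2)
  within <- scores - gm[labels, , drop = FALSE]
  1 - sum(within^2) / ss_tot
}

#' Pairwise permutation tests of species separation in ordination space
#'
#' For each species pair, the statistic is the centroid R2 of the first two
#' PCoA axes (`1 - SS_within / SS_total`); its p-value is the add-one
#' permutation estimate under label shuffling, Bonferroni-corrected across
#' pairs. Significance letters are derived from the corrected p matrix:
#' species that never differ significantly share a letter.
#'
#' @param scores Matrix of sample scores (first two axes used).
#' @param labels Species label per row.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed for the permutation stream.
#' @param alpha Significance level for the letter display (default 0.05).
#' @return List: `tests` (per-pair `species_a`, `species_b`, `r2`, `p`,
#'   `p_bonferroni`) and `letters` (named vector of group letters).
#' @export
pairwise_species_test <- function(scores, labels, n_perm = 10000,
                                  seed = 1L, alpha = 0.05) {
  scores <- as.matrix(scores)[, 1:2, drop = FALSE]
  labels <- as.character(labels)
  counts <- table(labels)
  groups <- names(counts)[counts >= 2]
  if (length(groups) < 2) stop("need >= 2 species with >= 2 samples")
  pairs <- utils::combn(sort(groups), 2, simplify = FALSE)
  set.seed(seed)
  rows <- lapply(pairs, function(pr) {
    idx <- which(labels %in% pr)
    sc <- scores[idx, , drop = FALSE]
    lb <- labels[idx]
    obs <- .centroid_r2(sc, lb)
    ## vectorized two-group permutation: R2 = SSb/SStot with
    ## SSb = n1 n2 / n * ||m1 - m2||^2 for group sizes fixed by the labels
    n <- length(lb); n1 <- sum(lb == pr[1]); n2 <- n - n1
    centered <- sweep(sc, 2, colMeans(sc))
    ss_tot <- sum(centered^2)
    Z <- vapply(seq_len(n_perm), function(b) {
      z <- numeric(n); z[sample.int(n, n1)] <- 1; z
    }, numeric(n))
    m1 <- crossprod(Z, centered) / n1              # n_perm x 2
    m2 <- crossprod(1 - Z, centered) / n2
    r2_perm <- (n1 * n2 / n) * rowSums((m1 - m2)^2) / ss_tot
    exceed <- sum(r2_perm >= obs - 1e-12)
    data.frame(species_a = pr[1], species_b = pr[2], r2 = obs,
               p = (1 + exceed) / (1 + n_perm), stringsAsFactors = FALSE)
  })
  tests <- do.call(rbind, rows)
  tests$p_bonferroni <- pmin(1, tests$p * nrow(tests))
  list(tests = tests,
       letters = .significance_letters(tests, sort(groups), alpha))
}

## Insertion algorithm for compact-letter display: start with one letter
## covering all groups, split on each significant pair.
.significance_letters <- function(tests, groups, alpha = 0.05) {
  sets <- list(groups)
  for (r in seq_len(nrow(tests))) {
    if (tests$p_bonferroni[r] >= alpha) next
    a <- tests$species_a[r]; b <- tests$species_b[r]
    new_sets <- list()
    for (s in sets) {
      if (all(c(a, b) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    ## drop sets contained in another
    keep <- vapply(seq_along(new_sets), function(i)
      !any(vapply(seq_along(new_sets), function(j)
        i != j && all(new_sets[[i]] %in% new_sets[[j]]), logical(1))),
      logical(1))
    sets <- unique(new_sets[keep])
  }
  lt <- stats::setNames(rep("", length(groups)), groups)
  for (k in seq_along(sets))
    lt[sets[[k]]] <- paste0(lt[sets[[k]]], letters[k])
  lt
}

#' Fit taxon abundance vectors onto the first two ordination axes
#'
#' Each taxon's RRA column is regressed on the two axis-score columns by
#' least squares; R2 is the squared multiple correlation, the arrow is the
#' normalized coefficient direction scaled by `sqrt(R2)`, and the p-value is
#' an add-one permutation estimate under row shuffling. The `top_k` taxa by
#' R2 are returned.
#'
#' @param scores Matrix of sample scores (first two axes used).
#' @param profile A `diet_profile` table row-aligned with `scores`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param top_k Number of taxa to return (default 6).
#' @return Data frame `taxon`, `dx`, `dy` (arrow components), `r2`, `p`,
#'   sorted by decreasing R2.
#' @export
taxon_vector_fit <- function(scores, profile, n_perm = 10000, seed = 1L,
                             top_k = 6) {
  sc <- as.matrix(scores)[, 1:2, drop = FALSE]
  m <- profile_matrix(profile)
  if (nrow(m) != nrow(sc)) stop("scores and profile must be row-aligned")
  X <- cbind(1, sc)
  XtXi <- solve(crossprod(X))
  hat <- X %*% XtXi %*% t(X)
  fit_one <- function(y) {
    yc <- y - mean(y)
    sst <- sum(yc^2)
    if (sst == 0) return(c(NA, NA, 0))
    res <- y - hat %*% y
    r2 <- 1 - sum(res^2) / sst
    beta <- (XtXi %*% crossprod(X, y))[2:3]
    nb <- sqrt(sum(beta^2))
    dir <- if (nb > 0) beta / nb else c(NA, NA)
    c(dir * sqrt(max(r2, 0)), max(r2, 0))
  }
  fits <- apply(m, 2, fit_one)
  out <- data.frame(taxon = colnames(m), dx = fits[1, ], dy = fits[2, ],
                    r2 = fits[3, ], p = NA_real_, stringsAsFactors = FALSE,
                    row.names = NULL)
  out <- out[order(-out$r2), , drop = FALSE]
  out <- utils::head(out, top_k)
  ## permutation p-values for the retained taxa only, vectorized through an
  ## orthonormal basis of the centered axis columns: R2 = ||U'y||^2 / ||y||^2
  U <- qr.Q(qr(sweep(sc, 2, colMeans(sc))))
  n <- nrow(sc)
  set.seed(seed)
  for (r in seq_len(nrow(out))) {
    y <- m[, out$taxon[r]]
    if (stats::var(y) == 0) next
    P <- vapply(seq_len(n_perm), function(b) y[sample.int(n)],
                numeric(n))
    Pc <- sweep(P, 2, colMeans(P))
    r2_perm <- colSums(crossprod(U, Pc)^2) / colSums(Pc^2)
    out$p[r] <- (1 + sum(r2_perm >= out$r2[r] - 1e-12)) / (1 + n_perm)
  }
  out
}

#' Full ordination of one landscape x season stratum
#'
#' Hellinger transform, Bray-Curtis, PCoA, pairwise species tests and taxon
#' vectors in one call.
#'
#' @param profile A `diet_profile` table (one stratum's rows).
#' @param labels Species label per profile row.
#' @param n_perm,seed,top_k Passed to the test and vector-fit stages.
#' @return List: `pcoa`, `tests`, `letters`, `vectors`, `centroids`.
#' @export
ordinate_stratum <- function(profile, labels, n_perm = 10000, seed = 1L,
                             top_k = 6) {
  H <- hellinger(profile)
  d <- bray_curtis(H)
  ord <- pcoa(d, n_axes = 2)
  pt <- pairwise_species_test(ord$scores, labels, n_perm = n_perm,
                              seed = seed)
  vec <- taxon_vector_fit(ord$scores, profile, n_perm = n_perm, seed = seed,
                          top_k = top_k)
  cent <- rowsum(ord$scores, labels) /
    as.vector(table(labels)[sort(unique(labels))])
  list(pcoa = ord, tests = pt$tests, letters = pt$letters, vectors = vec,
       centroids = cent)
}
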