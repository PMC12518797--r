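#' Pairwise beta diversity with turnover partitioning
#'
#' Sorensen and Jaccard dissimilarity between two presence sets, partitioned
#' into spatial turnover and nestedness following Baselga: with `a` shared
#' species, `b` and `c` unique to each sample,
#' `beta_sor = (b + c) / (2a + b + c)`, the turnover component
#' `beta_sim = min(b, c) / (a + min(b, c))`, the nestedness component
#' `beta_sne = beta_sor - beta_sim`, `beta_jac = (b + c) / (a + b + c)` and
#' its turnover `beta_jtu = 2 min(b, c) / (a + 2 min(b, c))`.
#'
#' @param set_i,set_j character vectors (or logical vectors over a common
#'   universe) of species present in each sample.
#' @return A list of class `beta_pair` with the five indices and the
#'   `pair_counts` (a, b, c).
#' @examples
#' beta_diversity_pair(c("x", "y", "z"), c("x", "y"))
#' @export
beta_diversity_pair <- function(set_i, set_j) {
  if (is.logical(set_i)) set_i <- which(set_i)
  if (is.logical(set_j)) set_j <- which(set_j)
  a <- length(intersect(set_i, set_j))
  b <- length(setdiff(set_i, set_j))
  c_ <- length(setdiff(set_j, set_i))
  if (a + b + c_ == 0L) stop("both sets empty: beta diversity undefined")
  m <- min(b, c_)
  beta_sor <- (b + c_) / (2 * a + b + c_)
  beta_sim <- if (a + m == 0) 1 else m / (a + m)
  structure(list(
    beta_sor = beta_sor, beta_sim = beta_sim, beta_sne = beta_sor - beta_sim,
    beta_jac = (b + c_) / (a + b + c_),
    beta_jtu = if (a + 2 * m == 0) 1 else 2 * m / (a + 2 * m),
    pair_counts = c(a = a, b = b, c = c_)
  ), class = "beta_pair")
}

#' Sample-by-sample beta diversity matrices
#'
#' Applies [beta_diversity_pair()] to every sample pair of a presence matrix.
#'
#' @param presence logical sample x species matrix.
#' @param index which dissimilarity to tabulate.
#' @return Symmetric `DistanceMatrix` over samples.
#' @export
beta_diversity_matrix <- function(presence,
                                  index = c("beta_sim", "beta_sor",
                                            "beta_sne", "beta_jac",
                                            "beta_jtu")) {
  index <- match.arg(index)
  n <- nrow(presence)
  dm <- matrix(0, n, n, dimnames = list(rownames(presence),
                                        rownames(presence)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      dm[i, j] <- dm[j, i] <-
        beta_diversity_pair(presence[i, ], presence[j, ])[[index]]
    }
  }
  dm
}

#' One-way PERMANOVA with omega-squared effect size
#'
#' Permutational multivariate ANOVA on a distance matrix (Anderson's
#' pseudo-F): `SS_total = sum_{i<j} d_ij^2 / N`, `SS_within` is the analogous
#' within-group sum, `F = (SS_between / df_effect) / (SS_within / df_resid)`,
#' and significance comes from freely permuting sample labels. Alongside
#' `R^2 = SS_between / SS_total`, the sample-size-adjusted effect size
#' `omega^2 = (SS_between - df_effect * MS_within) / (SS_total + MS_within)`
#' is reported; it is centred near zero under the null, unlike `R^2`.
#'
#' @param dm distance matrix (square symmetric with labels, or `dist`).
#' @param groups factor-like group membership, aligned with `dm` rows (or
#'   named by its labels).
#' @param n_perm number of label permutations.
#' @param seed RNG seed for the permutations.
#' @return An object of class `permanova` with the fields `SS_total`,
#'   `SS_between`, `SS_within`, `df_effect`, `df_resid`, `F`, `R2`, `omega2`,
#'   `p`, `n_perm`.
#' @export
permanova <- function(dm, groups, n_perm = 999L, seed = NULL) {
  dm <- check_dm(dm, require_labels = FALSE)
  n <- nrow(dm)
  if (!is.null(names(groups)) && !is.null(rownames(dm)))
    groups <- groups[rownames(dm)]
  groups <- as.factor(groups)
  if (length(groups) != n) stop("'groups' must align with the matrix")
  k <- nlevels(droplevels(groups))
  if (k < 2L) stop("need at least 2 groups")
  if (k >= n) stop("need more samples than groups")
  d2 <- dm^2
  ss_total <- sum(d2[lower.tri(d2)]) / n
  if (ss_total == 0) {
    # all samples coincide: nothing to partition, no evidence of structure
    return(structure(list(SS_total = 0, SS_between = 0, SS_within = 0,
                          df_effect = k - 1L, df_resid = n - k, F = NA_real_,
                          R2 = 0, omega2 = 0, p = 1,
                          n_perm = as.integer(n_perm), degenerate = TRUE),
                     class = "permanova"))
  }
  ss_within_of <- function(g) {
    s <- 0
    for (lev in levels(g)) {
      idx <- which(g == lev)
      if (length(idx) > 1L)
        s <- s + sum(d2[idx, idx]) / (2 * length(idx))
    }
    s
  }
  df_e <- k - 1L; df_r <- n - k
  f_of <- function(g) {
    ssw <- ss_within_of(g)
    ((ss_total - ssw) / df_e) / (ssw / df_r)
  }
  ss_within <- ss_within_of(groups)
  ss_between <- ss_total - ss_within
  f_obs <- (ss_between / df_e) / (ss_within / df_r)
  ms_w <- ss_within / df_r
  omega2 <- (ss_between - df_e * ms_w) / (ss_total + ms_w)
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    if (f_of(groups[sample.int(n)]) >= f_obs) exceed <- exceed + 1L
  }
  structure(list(SS_total = ss_total, SS_between = ss_between,
                 SS_within = ss_within, df_effect = df_e, df_resid = df_r,
                 F = f_obs, R2 = ss_between / ss_total, omega2 = omega2,
                 p = (1 + exceed) / (1 + n_perm), n_perm = as.integer(n_perm),
                 degenerate = FALSE),
            class = "permanova")
}

#' @export
print.permanova <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("PERMANOVA: degenerate (all distances zero), p = 1\n")
    return(invisible(x))
  }
  cat(sprintf(
    "PERMANOVA: F(%d, %d) = %.4f, R2 = %.4f, omega2 = %.4f, p = %.4g (%d permutations)\n",
    x$df_effect, x$df_resid, x$F, x$R2, x$omega2, x$p, x$n_perm))
  invisible(x)
}

#' Mantel test between two distance matrices
#'
#' Rank (Spearman, default) or Pearson correlation of the lower-triangle
#' distances, with a permutation p-value obtained by jointly permuting rows
#' and columns of the second matrix. For `N <= 6` labels (and
#' `exact_if_small`), all `N!` relabelings are enumerated, giving an exact
#' p-value with granularity `1 / N!`.
#'
#' @param dm1,dm2 square symmetric distance matrices over the same labels.
#' @param method correlation type.
#' @param n_perm Monte Carlo permutations when enumeration is not used.
#' @param seed RNG seed for Monte Carlo permutations.
#' @param exact_if_small enumerate all permutations when `N <= 6`.
#' @return A list of class `mantel_result`: `r`, `p`, `n_perm`, `exact`,
#'   `degenerate` (constant distances make `r` undefined and `p = 1`).
#' @export
mantel_test <- function(dm1, dm2, method = c("spearman", "pearson"),
                        n_perm = 999L, seed = NULL, exact_if_small = TRUE) {
  method <- match.arg(method)
  dm1 <- check_dm(dm1, "dm1", require_labels = FALSE)
  dm2 <- check_dm(dm2, "dm2", require_labels = FALSE)
  n <- nrow(dm1)
  if (n < 4L) stop("need at least 4 labels")
  if (nrow(dm2) != n) stop("matrices must match")
  if (!is.null(rownames(dm1)) && !is.null(rownames(dm2)))
    dm2 <- dm2[rownames(dm1), rownames(dm1)]
  x <- lower_tri(dm1)
  if (method == "spearman") {
    x <- rank(x)
    corfun <- function(y) stats::cor(x, rank(y))
  } else {
    corfun <- function(y) stats::cor(x, y)
  }
  if (stats::sd(x) == 0 || stats::sd(lower_tri(dm2)) == 0) {
    return(structure(list(r = NA_real_, p = 1, n_perm = 0L, exact = FALSE,
                          degenerate = TRUE), class = "mantel_result"))
  }
  r_obs <- corfun(lower_tri(dm2))
  if (exact_if_small && n <= 6L) {
    P <- all_perms(n)
    r_all <- vapply(seq_len(nrow(P)), function(k) {
      p <- P[k, ]
      corfun(lower_tri(dm2[p, p]))
    }, numeric(1L))
    p_val <- mean(r_all >= r_obs - 1e-12)
    return(structure(list(r = r_obs, p = p_val, n_perm = nrow(P),
                          exact = TRUE, degenerate = FALSE),
                     class = "mantel_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (corfun(lower_tri(dm2[p, p])) >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + n_perm),
                 n_perm = as.integer(n_perm), exact = FALSE,
                 degenerate = FALSE), class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  if (x$degenerate) cat("Mantel test: degenerate (zero distance variance), p = 1\n")
  else cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %d permutations)\n",
                   x$r, x$p, if (x$exact) "exact" else "Monte Carlo",
                   x$n_perm))
  invisible(x)
}

#' Subsampled Mantel test for phylosymbiosis
#'
#' Tests whether community dissimilarity tracks host phylogenetic divergence
#' while avoiding pseudo-replication: each of `n_iter` iterations draws one
#' sample per host species uniformly at random, runs a Mantel test between the
#' induced community distances and the host distances (exact enumeration over
#' the 5! relabelings by default), and the collected p-values are adjusted by
#' Benjamini-Hochberg FDR. The summary is the mean and sd of the q-values.
#'
#' @param community_dm sample-level community distance matrix (e.g. Sorensen
#'   turnover from [beta_diversity_matrix()]).
#' @param host_dm host-level distance matrix (e.g. [patristic_matrix()] of
#'   the host tree).
#' @param metadata data frame with `sample_id`, `host_species`.
#' @param n_iter number of subsampling iterations.
#' @param seed RNG seed.
#' @param method Mantel correlation type.
#' @return An object of class `phylosymbiosis_result`: `iterations` (data
#'   frame with `r`, `p`, `q` and the drawn samples), `mean_q`, `sd_q`,
#'   `n_iter`.
#' @export
phylosymbiosis_test <- function(community_dm, host_dm, metadata,
                                n_iter = 1000L, seed = NULL,
                                method = "spearman") {
  if (n_iter < 1L) stop("n_iter must be >= 1")
  community_dm <- check_dm(community_dm, "community_dm")
  host_dm <- check_dm(host_dm, "host_dm")
  hosts <- rownames(host_dm)
  by_host <- lapply(hosts, function(h)
    metadata$sample_id[metadata$host_species == h])
  if (any(lengths(by_host) == 0L))
    stop("every host needs at least one sample")
  if (!all(unlist(by_host) %in% rownames(community_dm)))
    stop("metadata samples missing from community_dm")
  if (!is.null(seed)) set.seed(seed)
  r <- p <- numeric(n_iter)
  picks <- matrix(NA_character_, n_iter, length(hosts),
                  dimnames = list(NULL, hosts))
  for (it in seq_len(n_iter)) {
    sel <- vapply(by_host, function(s) s[sample.int(length(s), 1L)],
                  character(1L))
    picks[it, ] <- sel
    sub <- community_dm[sel, sel]
    dimnames(sub) <- list(hosts, hosts)
    m <- mantel_test(sub, host_dm, method = method, exact_if_small = TRUE)
    r[it] <- if (m$degenerate) NA_real_ else m$r
    p[it] <- m$p
  }
  q <- stats::p.adjust(p, method = "BH")
  structure(list(
    iterations = data.frame(r = r, p = p, q = q, picks,
                            stringsAsFactors = FALSE),
    mean_q = mean(q), sd_q = stats::sd(q), n_iter = as.integer(n_iter)
  ), class = "phylosymbiosis_result")
}

#' @export
print.phylosymbiosis_result <- function(x, ...) {
  cat(sprintf("Phylosymbiosis test: mean q = %.3f +/- %.3f over %d Mantel tests\n",
              x$mean_q, x$sd_q, x$n_iter))
  invisible(x)
}

#' Species accumulation curve
#'
#' Mean cumulative species richness as samples are added in random order,
#' averaged over `n_orders` orderings; optionally one curve per group.
#'
#' @param presence logical sample x species matrix.
#' @param groups optional grouping vector aligned with rows; one curve each.
#' @param n_orders random orderings averaged.
#' @param seed RNG seed.
#' @return A numeric vector (mean richness after 1..N samples), or a named
#'   list of such vectors when `groups` is given.
#' @export
accumulation_curve <- function(presence, groups = NULL, n_orders = 100L,
                               seed = NULL) {
  if (!is.null(groups)) {
    idx <- split(seq_len(nrow(presence)), groups)
    return(lapply(idx, function(i)
      accumulation_curve(presence[i, , drop = FALSE], NULL, n_orders, seed)))
  }
  n <- nrow(presence)
  if (n < 1L) stop("need at least one sample")
  if (!is.null(seed)) set.seed(seed)
  acc <- numeric(n)
  for (o in seq_len(n_orders)) {
    ord <- sample.int(n)
    seen <- rep(FALSE, ncol(presence))
    for (k in seq_len(n)) {
      seen <- seen | presence[ord[k], ]
      acc[k] <- acc[k] + sum(seen)
    }
  }
  acc / n_orders
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (double-centred
#' `-0.5 * D^2`); negative eigenvalues are reported rather than dropped so
#' non-Euclidean distances are visible to the caller.
#'
#' @param dm square symmetric distance matrix.
#' @return A list of class `pcoa_result`: `points` (samples x axes) and
#'   `eig` (all eigenvalues).
#' @export
pcoa <- function(dm) {
  dm <- check_dm(dm, require_labels = FALSE)
  n <- nrow(dm)
  if (n == 1L)
    return(structure(list(points = matrix(0, 1L, 0L), eig = numeric(0)),
                     class = "pcoa_result"))
  # cmdscale warns when fewer than k eigenvalues are positive; expected here
  # since we always request the full n - 1 axes
  fit <- withCallingHandlers(
    stats::cmdscale(dm, k = n - 1L, eig = TRUE),
    warning = function(w) {
      if (grepl("eigenvalues", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  pts <- fit$points
  rownames(pts) <- rownames(dm)
  structure(list(points = pts, eig = fit$eig), class = "pcoa_result")
}

#' @export
print.pcoa_result <- function(x, ...) {
  pos <- sum(x$eig > 1e-12)
  cat(sprintf("PCoA: %d samples, %d positive eigenvalues (%d negative)\n",
              nrow(x$points), pos, sum(x$eig < -1e-12)))
  invisible(x)
}
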