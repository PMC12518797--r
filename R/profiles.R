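#' Species presence from genome breadth
#'
#' A species is called present in a sample when at least `breadth_threshold`
#' of its genome is covered by reads (default: half the genome).
#'
#' @param profiles data frame with columns `sample_id`, `species_id`,
#'   `breadth` (and optionally `mean_coverage`).
#' @param breadth_threshold presence threshold in (0, 1].
#' @return Logical sample x species matrix.
#' @export
detect_species <- function(profiles, breadth_threshold = 0.5) {
  if (breadth_threshold <= 0 || breadth_threshold > 1)
    stop("breadth_threshold must be in (0, 1]")
  if (nrow(profiles) == 0L)
    return(matrix(FALSE, 0L, 0L))
  samples <- unique(profiles$sample_id)
  species <- unique(profiles$species_id)
  m <- matrix(FALSE, length(samples), length(species),
              dimnames = list(samples, species))
  keep <- profiles$breadth >= breadth_threshold
  m[cbind(match(profiles$sample_id[keep], samples),
          match(profiles$species_id[keep], species))] <- TRUE
  m
}

#' Per-sample relative coverage of species
#'
#' Divides each species' mean coverage by the per-sample total, giving
#' compositional proportions that sum to one.
#'
#' @param profiles data frame with `sample_id`, `species_id`, `mean_coverage`.
#' @return Numeric sample x species matrix of proportions; samples whose
#'   coverages are all zero get `NA` rows with a warning.
#' @export
relative_coverage <- function(profiles) {
  samples <- unique(profiles$sample_id)
  species <- unique(profiles$species_id)
  m <- matrix(0, length(samples), length(species),
              dimnames = list(samples, species))
  m[cbind(match(profiles$sample_id, samples),
          match(profiles$species_id, species))] <- profiles$mean_coverage
  tot <- rowSums(m)
  zero <- tot == 0
  if (any(zero))
    warning("sample(s) with all-zero coverage: ",
            paste(samples[zero], collapse = ", "))
  out <- sweep(m, 1L, tot, "/")
  out[zero, ] <- NA_real_
  out
}

# Integer bitmask (bits A=1, C=2, G=4, T=8) of alleles at frequency >= min_freq.
allele_mask <- function(freqs, min_freq) {
  (freqs[, 1L] >= min_freq) + 2L * (freqs[, 2L] >= min_freq) +
    4L * (freqs[, 3L] >= min_freq) + 8L * (freqs[, 4L] >= min_freq)
}

freq_cols <- c("freq_A", "freq_C", "freq_G", "freq_T")

check_freqs <- function(sites) {
  f <- as.matrix(sites[, freq_cols])
  s <- rowSums(f)
  bad <- sites$coverage > 0 & abs(s - 1) > 1e-6
  if (any(bad))
    stop("allele frequencies deviate from 1 by more than 1e-6 at position(s) ",
         paste(utils::head(sites$position[bad], 3L), collapse = ", "))
  fix <- sites$coverage > 0 & s > 0
  f[fix, ] <- f[fix, ] / s[fix]
  f
}

#' SNV calling and percent variable sites
#'
#' A site is a single-nucleotide variant when it is covered at least
#' `min_cov` x and carries at least two alleles each at frequency >=
#' `min_freq`. Sites in regions mapping with read ANI below `read_ani_min`
#' (supplied as a per-site `read_ani` column, since mapping itself is
#' upstream) or with coverage below 1x are excluded from both the SNV count
#' and the covered length. Percent variable sites is
#' `100 * n_snvs / covered_length`.
#'
#' @param sites allele table for one (species, sample): columns `position`,
#'   `coverage`, `freq_A`..`freq_T`, optional `read_ani`.
#' @param min_cov minimum depth for a site to be SNV-eligible.
#' @param min_freq minimum allele frequency.
#' @param read_ani_min sites with `read_ani` below this are masked.
#' @return A list of class `snv_summary`: `n_snvs`, `covered_length`,
#'   `pct_variable` (`NA` when no site passes the mask).
#' @export
call_snvs <- function(sites, min_cov = 5, min_freq = 0.05,
                      read_ani_min = 0.92) {
  f <- check_freqs(sites)
  keep <- sites$coverage >= 1
  if (!is.null(sites$read_ani)) keep <- keep & sites$read_ani >= read_ani_min
  covered_length <- sum(keep)
  n_alleles <- rowSums(f >= min_freq)
  snv <- keep & sites$coverage >= min_cov & n_alleles >= 2L
  n_snvs <- sum(snv)
  structure(list(
    n_snvs = n_snvs, covered_length = covered_length,
    pct_variable = if (covered_length > 0) 100 * n_snvs / covered_length
                   else NA_real_
  ), class = "snv_summary")
}

#' @export
print.snv_summary <- function(x, ...) {
  cat(sprintf("SNV summary: %d SNVs over %d covered bp (%.4g%% variable)\n",
              x$n_snvs, x$covered_length,
              if (is.na(x$pct_variable)) NaN else x$pct_variable))
  invisible(x)
}

#' Pairwise popANI dissimilarity between two samples' strain profiles
#'
#' Population-ANI comparison of one species across two samples. A pair is
#' eligible only if both samples cover the genome at mean depth >=
#' `min_mean_cov` and breadth >= `min_breadth`. Positions covered at least
#' `min_site_cov` x in both samples are compared; each sample's allele set at
#' a position holds the nucleotides at frequency >= `min_freq`, and the
#' position is a popANI substitution when the two sets are disjoint (a single
#' shared low-frequency allele is enough to avoid a substitution). The
#' returned dissimilarity is substitutions / compared positions.
#'
#' @param alleles_i,alleles_j allele tables (columns as in
#'   [simulate_allele_profiles()]) for the same species in two samples.
#' @param min_site_cov per-position depth required in both samples.
#' @param min_freq allele-frequency threshold.
#' @param min_breadth,min_mean_cov per-sample eligibility thresholds.
#' @param genome_length genome length used for breadth/mean coverage; defaults
#'   to the largest position observed in either table.
#' @param denominator `"all_covered"` counts every jointly well-covered
#'   position; `"multiallelic"` restricts to positions where the union of the
#'   two allele sets holds more than one allele.
#' @return Numeric dissimilarity in `[0, 1]`, with attributes `n_compared`
#'   and `n_substitutions`; `NA` (attribute `reason`) for ineligible pairs or
#'   when no position is compared.
#' @export
popani_pair <- function(alleles_i, alleles_j, min_site_cov = 5,
                        min_freq = 0.05, min_breadth = 0.5, min_mean_cov = 5,
                        genome_length = NULL,
                        denominator = c("all_covered", "multiallelic")) {
  denominator <- match.arg(denominator)
  L <- genome_length %||% max(alleles_i$position, alleles_j$position)
  eligible <- function(a) {
    mean_cov <- sum(a$coverage) / L
    breadth <- sum(a$coverage >= 1) / L
    mean_cov >= min_mean_cov && breadth >= min_breadth
  }
  miss <- function(reason) structure(NA_real_, reason = reason)
  if (!eligible(alleles_i) || !eligible(alleles_j))
    return(miss("sample below coverage/breadth eligibility"))
  ij <- match(alleles_i$position, alleles_j$position)
  ok <- !is.na(ij)
  cov_i <- alleles_i$coverage[ok]
  cov_j <- alleles_j$coverage[ij[ok]]
  m_i <- allele_mask(check_freqs(alleles_i)[ok, , drop = FALSE], min_freq)
  m_j <- allele_mask(check_freqs(alleles_j)[ij[ok], , drop = FALSE], min_freq)
  cmp <- cov_i >= min_site_cov & cov_j >= min_site_cov & m_i > 0L & m_j > 0L
  if (denominator == "multiallelic")
    cmp <- cmp & bitwOr(m_i, m_j) %in% c(3L, 5L, 6L, 7L, 9L, 10L, 11L,
                                         12L, 13L, 14L, 15L)
  n_compared <- sum(cmp)
  if (n_compared == 0L) return(miss("no compared positions"))
  n_sub <- sum(cmp & bitwAnd(m_i, m_j) == 0L)
  structure(n_sub / n_compared, n_compared = n_compared,
            n_substitutions = n_sub)
}

#' Per-species popANI distance matrix with eligibility report
#'
#' Builds the strain-level dissimilarity matrix of one species over all
#' eligible samples. Following the study design, the species is flagged
#' analyzable only when at least `min_samples` eligible samples span at least
#' `min_hosts` host species.
#'
#' @param alleles allele table covering multiple samples (one species).
#' @param metadata data frame with `sample_id`, `host_species`.
#' @param species_id species to analyse.
#' @param min_samples,min_hosts analyzability thresholds.
#' @param ... thresholds passed to [popani_pair()].
#' @return An object of class `strain_dm`: `dm` (symmetric matrix, `NA` for
#'   masked pairs), `eligible_samples`, `analyzable`, `reason`.
#' @export
strain_distance_matrix <- function(alleles, metadata, species_id,
                                   min_samples = 5L, min_hosts = 2L, ...) {
  a <- alleles[alleles$species_id == species_id, , drop = FALSE]
  if (nrow(a) == 0L) stop("no allele data for species ", species_id)
  dots <- list(...)
  min_breadth <- dots$min_breadth %||% 0.5
  min_mean_cov <- dots$min_mean_cov %||% 5
  L <- dots$genome_length %||% max(a$position)
  by_sample <- split(a, a$sample_id)
  elig <- vapply(by_sample, function(s) {
    sum(s$coverage) / L >= min_mean_cov && sum(s$coverage >= 1) / L >= min_breadth
  }, logical(1L))
  samples <- names(by_sample)[elig]
  hosts <- metadata$host_species[match(samples, metadata$sample_id)]
  analyzable <- length(samples) >= min_samples &&
    length(unique(hosts)) >= min_hosts
  reason <- if (analyzable) NA_character_ else
    sprintf("only %d eligible samples spanning %d host species",
            length(samples), length(unique(stats::na.omit(hosts))))
  if (length(samples) < 2L) {
    return(structure(list(dm = matrix(numeric(0), 0L, 0L),
                          eligible_samples = samples, analyzable = FALSE,
                          reason = reason %||% "fewer than 2 eligible samples"),
                     class = "strain_dm"))
  }
  n <- length(samples)
  dm <- matrix(0, n, n, dimnames = list(samples, samples))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- popani_pair(by_sample[[samples[i]]], by_sample[[samples[j]]],
                       genome_length = L, ...)
      dm[i, j] <- dm[j, i] <- as.numeric(d)
    }
  }
  structure(list(dm = dm, eligible_samples = samples,
                 analyzable = analyzable, reason = reason),
            class = "strain_dm")
}

#' @export
print.strain_dm <- function(x, ...) {
  cat(sprintf("popANI strain matrix: %d eligible samples; analyzable: %s\n",
              length(x$eligible_samples), x$analyzable))
  if (!is.na(x$reason %||% NA)) cat(" reason:", x$reason, "\n")
  invisible(x)
}

#' Cluster MAGs into species by average nucleotide identity
#'
#' Average-linkage agglomerative clustering on `1 - ANI`, cut at
#' `1 - threshold` (95% ANI is the conventional bacterial species boundary).
#' Each cluster's representative is its highest-quality MAG, scored as
#' `completeness - 5 * contamination`, ties broken by lexicographic MAG id.
#'
#' @param ani_matrix symmetric MAG x MAG ANI matrix with entries in `[0, 1]`.
#' @param quality data frame with `mag_id`, `completeness`, `contamination`
#'   covering every MAG.
#' @param threshold ANI species threshold.
#' @return An object of class `species_clustering`: data frame `clusters`
#'   (`mag_id`, `cluster_id`, `quality_score`, `is_representative`) plus
#'   `representatives`.
#' @export
cluster_by_ani <- function(ani_matrix, quality, threshold = 0.95) {
  ani_matrix <- check_dm(ani_matrix, "ani_matrix")
  if (any(ani_matrix < 0 | ani_matrix > 1)) stop("ANI entries must be in [0, 1]")
  mags <- rownames(ani_matrix)
  qi <- match(mags, quality$mag_id)
  if (anyNA(qi)) stop("quality missing for MAG(s): ",
                      paste(mags[is.na(qi)], collapse = ", "))
  score <- quality$completeness[qi] - 5 * quality$contamination[qi]
  cl <- if (length(mags) == 1L) 1L else
    stats::cutree(stats::hclust(stats::as.dist(1 - ani_matrix),
                                method = "average"),
                  h = 1 - threshold)
  names(cl) <- mags
  reps <- vapply(split(seq_along(mags), cl), function(idx) {
    idx <- idx[order(-score[idx], mags[idx])]
    mags[idx[1L]]
  }, character(1L))
  structure(list(
    clusters = data.frame(mag_id = mags, cluster_id = unname(cl),
                          quality_score = score,
                          is_representative = mags %in% reps,
                          stringsAsFactors = FALSE),
    representatives = reps
  ), class = "species_clustering")
}

#' @export
print.species_clustering <- function(x, ...) {
  cat(sprintf("ANI clustering: %d MAGs in %d clusters\n",
              nrow(x$clusters), length(x$representatives)))
  invisible(x)
}
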