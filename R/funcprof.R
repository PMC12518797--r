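#' Gene detection filter
#'
#' A gene is detected in a sample when strictly more than 5 reads map to it
#' and strictly more than 90% of its bases are covered.
#'
#' @param records `GeneRecord` data frame (see [simulate_gene_table()]).
#' @param min_reads,min_fraction strict lower bounds.
#' @return The detected subset of `records`.
#' @export
detect_genes <- function(records, min_reads = 5, min_fraction = 0.9) {
  records[records$reads_mapped > min_reads &
            records$fraction_bases_covered > min_fraction, , drop = FALSE]
}

#' Reads per kilobase per million (RPKM)
#'
#' `RPKM = reads_mapped / ((length_bp / 1000) * (total_reads / 1e6))`:
#' gene abundance normalized for gene length and library size.
#'
#' @param reads_mapped reads mapped to the gene.
#' @param length_bp gene length in bp.
#' @param total_reads total reads in the sample.
#' @return Numeric RPKM (vectorized).
#' @examples
#' rpkm(10, 500, 1e6)  # 20
#' @export
rpkm <- function(reads_mapped, length_bp, total_reads) {
  if (any(total_reads <= 0)) stop("total_reads must be positive")
  if (any(length_bp <= 0)) stop("length_bp must be positive")
  reads_mapped / ((length_bp / 1000) * (total_reads / 1e6))
}

#' Aggregate detected-gene RPKM into a feature matrix
#'
#' Sums RPKM of detected genes per sample over a functional key (KO or
#' CAZyme family); unannotated genes contribute to no feature, and
#' undetected genes contribute nothing.
#'
#' @param records `GeneRecord` data frame.
#' @param key `"ko"` or `"cazyme_family"`.
#' @param detected_only apply [detect_genes()] first.
#' @return Numeric samples x features matrix of summed RPKM (0 = undetected).
#' @export
aggregate_features <- function(records, key = c("ko", "cazyme_family"),
                               detected_only = TRUE) {
  key <- match.arg(key)
  samples <- unique(records$sample_id)
  if (detected_only) records <- detect_genes(records)
  records <- records[!is.na(records[[key]]), , drop = FALSE]
  feats <- sort(unique(records[[key]]))
  m <- matrix(0, length(samples), length(feats),
              dimnames = list(samples, feats))
  if (nrow(records)) {
    v <- rpkm(records$reads_mapped, records$length_bp,
              records$total_reads_sample)
    idx <- cbind(match(records$sample_id, samples),
                 match(records[[key]], feats))
    for (r in seq_len(nrow(records)))
      m[idx[r, 1L], idx[r, 2L]] <- m[idx[r, 1L], idx[r, 2L]] + v[r]
  }
  m
}

cazyme_class <- function(family) sub("^([A-Za-z]+).*$", "\\1", family)

#' Genus-level CAZyme contribution per host
#'
#' For each host species: the RPKM of all detected CAZyme genes (families
#' other than the GT and AA classes) is summed per genus per sample, averaged
#' over that host's samples, and converted to relative proportions across the
#' genera with prevalence above `prevalence_min` in that host.
#'
#' @param records `GeneRecord` data frame.
#' @param metadata data frame with `sample_id`, `host_species`.
#' @param prevalence genus x host prevalence matrix (rows genera).
#' @param prevalence_min strict prevalence threshold for a genus to count in
#'   a host.
#' @param exclude_classes CAZyme classes excluded from the sums.
#' @return Numeric host x genus matrix of proportions (rows sum to 1; hosts
#'   without an eligible genus get `NA` with a warning).
#' @export
cazyme_genus_share <- function(records, metadata, prevalence,
                               prevalence_min = 0.05,
                               exclude_classes = c("GT", "AA")) {
  det <- detect_genes(records)
  det <- det[!is.na(det$cazyme_family) &
               !(cazyme_class(det$cazyme_family) %in% exclude_classes), ,
             drop = FALSE]
  hosts <- colnames(prevalence)
  genera <- rownames(prevalence)
  out <- matrix(NA_real_, length(hosts), length(genera),
                dimnames = list(hosts, genera))
  det$rpkm <- if (nrow(det)) rpkm(det$reads_mapped, det$length_bp,
                                  det$total_reads_sample) else numeric(0)
  for (h in hosts) {
    smp <- metadata$sample_id[metadata$host_species == h]
    elig <- genera[prevalence[, h] > prevalence_min]
    if (!length(elig)) {
      warning("no eligible genus in host ", h)
      next
    }
    means <- vapply(elig, function(g) {
      per_sample <- vapply(smp, function(s)
        sum(det$rpkm[det$sample_id == s & det$genus == g]), numeric(1L))
      mean(per_sample)
    }, numeric(1L))
    out[h, ] <- 0
    out[h, elig] <- if (sum(means) > 0) means / sum(means) else 0
  }
  out
}

#' Robust centred log-ratio transform
#'
#' Per sample, positive entries are replaced by `log(x)` minus the mean log
#' of that sample's positive entries (the log of the geometric mean over the
#' observed part of the composition); zeros are treated as uninformative and
#' mapped to 0.
#'
#' @param m non-negative samples x features matrix; every sample needs at
#'   least one positive entry.
#' @return Transformed matrix of the same shape.
#' @export
rclr_transform <- function(m) {
  if (any(m < 0)) stop("matrix must be non-negative")
  if (any(rowSums(m > 0) == 0L)) stop("sample with all-zero features")
  out <- m * 0
  for (i in seq_len(nrow(m))) {
    pos <- m[i, ] > 0
    lg <- log(m[i, pos])
    out[i, pos] <- lg - mean(lg)
  }
  out
}

#' Robust Aitchison distance matrix
#'
#' Euclidean distance between [rclr_transform()]ed rows; proportional
#' samples with identical support are at distance zero.
#'
#' @param m non-negative samples x features matrix.
#' @return Symmetric `DistanceMatrix` over samples.
#' @export
robust_aitchison <- function(m) {
  as.matrix(stats::dist(rclr_transform(m)))
}
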