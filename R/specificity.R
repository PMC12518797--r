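#' Species-by-host prevalence matrix
#'
#' Fraction of each host species' samples in which each bacterial species is
#' present.
#'
#' @param presence logical sample x species matrix (e.g. [detect_species()]).
#' @param metadata data frame with `sample_id`, `host_species`; every row of
#'   `presence` must have a host label.
#' @return A list of class `prevalence_matrix`: `prevalence`
#'   (species x host), `n_samples` (per host).
#' @export
prevalence_matrix <- function(presence, metadata) {
  hosts_of <- metadata$host_species[match(rownames(presence),
                                          metadata$sample_id)]
  if (anyNA(hosts_of)) stop("every sample must have a host label")
  hosts <- unique(metadata$host_species)
  n_h <- vapply(hosts, function(h) sum(hosts_of == h), integer(1L))
  empty <- n_h == 0L
  if (any(empty)) {
    warning("host(s) with zero samples excluded: ",
            paste(hosts[empty], collapse = ", "))
    hosts <- hosts[!empty]; n_h <- n_h[!empty]
  }
  prev <- vapply(hosts, function(h) {
    colMeans(presence[hosts_of == h, , drop = FALSE])
  }, numeric(ncol(presence)))
  prev <- matrix(prev, ncol = length(hosts),
                 dimnames = list(colnames(presence), hosts))
  structure(list(prevalence = prev, n_samples = n_h),
            class = "prevalence_matrix")
}

#' Rohde's index of host specificity
#'
#' Prevalence-rank form of Rohde's specificity index: hosts are ranked by
#' descending prevalence (consecutive ranks 1..H, ties broken by host-name
#' order) and `S = sum(p_j / r_j) / sum(p_j)`. S equals 1 for a species found
#' in a single host and `(sum_{j=1..H} 1/j) / H` for a uniform generalist —
#' about 0.457 for five hosts.
#'
#' @param prevalence named numeric vector of per-host prevalences (one
#'   species).
#' @return A list of class `rohde_result`: `index`, `ranks`, `hosts_present`.
#' @examples
#' rohde_index(c(A = 0.9, B = 0.1, C = 0, D = 0, E = 0))$index  # 0.95
#' @export
rohde_index <- function(prevalence) {
  if (any(prevalence < 0 | prevalence > 1))
    stop("prevalences must be in [0, 1]")
  if (all(prevalence == 0)) stop("all-zero prevalence: index undefined")
  hn <- names(prevalence) %||% as.character(seq_along(prevalence))
  ord <- order(-prevalence, hn)
  ranks <- integer(length(prevalence))
  ranks[ord] <- seq_along(prevalence)
  names(ranks) <- hn
  structure(list(
    index = sum(prevalence / ranks) / sum(prevalence),
    ranks = ranks,
    hosts_present = sum(prevalence > 0)
  ), class = "rohde_result")
}

#' @export
print.rohde_result <- function(x, ...) {
  cat(sprintf("Rohde's specificity index: %.4f (present in %d host(s))\n",
              x$index, x$hosts_present))
  invisible(x)
}

#' Three-way host-specificity classification of a species
#'
#' A species detected in exactly one host species is `species_specific`. A
#' shared species is `strain_specific` when its strain-level popANI profile
#' clusters significantly by host (PERMANOVA p below `alpha`), and
#' `non_specific` otherwise; shared species without analyzable strain data
#' remain `non_specific` but are flagged untested.
#'
#' @param presence logical sample x species matrix.
#' @param metadata data frame with `sample_id`, `host_species`.
#' @param species_id species to classify.
#' @param strain_permanova optional [permanova()] result on the species'
#'   strain distance matrix.
#' @param alpha significance level for strain-level clustering.
#' @return A list of class `specificity_call`: `species_id`, `category`,
#'   `p_value`, `untested`, `hosts_detected`.
#' @export
classify_specificity <- function(presence, metadata, species_id,
                                 strain_permanova = NULL, alpha = 0.01) {
  if (!species_id %in% colnames(presence))
    stop("unknown species: ", species_id)
  pres <- presence[, species_id]
  if (!any(pres)) stop("species absent from all samples: ", species_id)
  hosts <- unique(metadata$host_species[
    match(rownames(presence)[pres], metadata$sample_id)])
  p <- if (!is.null(strain_permanova)) strain_permanova$p else NA_real_
  if (length(hosts) == 1L) {
    category <- "species_specific"; untested <- FALSE
  } else if (!is.na(p) && p < alpha) {
    category <- "strain_specific"; untested <- FALSE
  } else {
    category <- "non_specific"; untested <- is.na(p)
  }
  structure(list(species_id = species_id, category = category,
                 p_value = p, untested = untested,
                 hosts_detected = hosts),
            class = "specificity_call")
}

#' @export
print.specificity_call <- function(x, ...) {
  cat(sprintf("%s: %s%s (detected in %d host(s)%s)\n", x$species_id,
              x$category, if (x$untested) " [untested]" else "",
              length(x$hosts_detected),
              if (!is.na(x$p_value))
                sprintf("; strain PERMANOVA p = %.4g", x$p_value) else ""))
  invisible(x)
}
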