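#' Specification of a synthetic bacterial community
#'
#' Describes species archetypes (per-host prevalence, abundance distribution)
#' and the sampling design used by [simulate_community()].
#'
#' @param archetypes data frame with columns `species_id`, `genus`, one
#'   prevalence column per host (named `prev_<host>`), `mean_abundance`
#'   (lognormal median coverage) and `dispersion` (lognormal sdlog).
#' @param hosts character vector of host species names; must match the
#'   prevalence columns.
#' @param n_samples_per_host samples drawn per host species.
#' @param locations labels cycled over samples within each host.
#' @param location_effect multiplicative abundance effect of the non-reference
#'   location (1 = none).
#' @param seed RNG seed.
#' @return A validated list of class `community_spec`.
#' @export
community_spec <- function(archetypes, hosts, n_samples_per_host = 10L,
                           locations = c("india", "malaysia"),
                           location_effect = 1, seed = 1L) {
  prev_cols <- paste0("prev_", hosts)
  if (!all(prev_cols %in% names(archetypes)))
    stop("archetypes must have columns ", paste(prev_cols, collapse = ", "))
  pm <- as.matrix(archetypes[, prev_cols])
  if (any(pm < 0 | pm > 1)) stop("prevalence entries must be in [0, 1]")
  if (n_samples_per_host < 1) stop("n_samples_per_host must be >= 1")
  structure(list(archetypes = archetypes, hosts = hosts,
                 n_samples_per_host = as.integer(n_samples_per_host),
                 locations = locations, location_effect = location_effect,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Default community archetypes for the five-host design
#'
#' Three archetype groups mirroring the observed prevalence structure:
#' core generalists present in every host, host specialists private to one
#' host, and patchy intermediates shared by a host subset.
#'
#' @param hosts host species names (default: tips of [default_host_tree()]).
#' @return An archetype data frame suitable for [community_spec()].
#' @export
default_archetypes <- function(hosts = default_host_tree()$tip.label) {
  H <- length(hosts)
  rows <- list()
  mk <- function(id, genus, prev, mean_ab, disp) {
    r <- data.frame(species_id = id, genus = genus, mean_abundance = mean_ab,
                    dispersion = disp, stringsAsFactors = FALSE)
    r[paste0("prev_", hosts)] <- as.list(prev)
    r
  }
  for (i in 1:4)
    rows[[length(rows) + 1L]] <- mk(sprintf("core_%02d", i), "Lactobacillus",
                                    rep(0.9, H), 40, 0.6)
  for (i in seq_len(H))
    rows[[length(rows) + 1L]] <- mk(sprintf("spec_%02d", i), "Dysgonomonas",
                                    ifelse(seq_len(H) == i, 0.8, 0), 25, 0.6)
  for (i in 1:4) {
    prev <- rep(0, H); prev[((i - 1L) %% H) + 1L] <- 0.7
    prev[(i %% H) + 1L] <- 0.5; prev[((i + 1L) %% H) + 1L] <- 0.3
    rows[[length(rows) + 1L]] <- mk(sprintf("patchy_%02d", i), "Gilliamella",
                                    prev, 15, 0.8)
  }
  do.call(rbind, rows)
}

#' Simulate presence/abundance of a bacterial community
#'
#' Per sample, each species is present with its host-specific prevalence
#' (Bernoulli) and, when present, receives a lognormal abundance (a stand-in
#' for mean genome coverage). Deterministic given the spec's seed.
#'
#' @param host host tree ([ape::phylo]); its tip labels define the hosts.
#' @param spec a [community_spec()].
#' @return A list with `abundance` (samples x species matrix, 0 = absent),
#'   `presence` (logical matrix) and `metadata` (data frame with `sample_id`,
#'   `host_species`, `location`).
#' @export
simulate_community <- function(host, spec) {
  stopifnot(inherits(spec, "community_spec"))
  hosts <- spec$hosts
  if (!all(hosts %in% host$tip.label))
    stop("spec hosts must be tips of the host tree")
  set.seed(spec$seed)
  arch <- spec$archetypes
  pm <- as.matrix(arch[, paste0("prev_", hosts)])
  n_h <- spec$n_samples_per_host
  meta <- data.frame(
    sample_id = sprintf("s_%s_%03d", rep(hosts, each = n_h),
                        rep(seq_len(n_h), length(hosts))),
    host_species = rep(hosts, each = n_h),
    location = rep_len(spec$locations, n_h * length(hosts)),
    stringsAsFactors = FALSE
  )
  n_s <- nrow(meta); n_sp <- nrow(arch)
  presence <- matrix(FALSE, n_s, n_sp,
                     dimnames = list(meta$sample_id, arch$species_id))
  abundance <- matrix(0, n_s, n_sp,
                      dimnames = list(meta$sample_id, arch$species_id))
  loc_mult <- ifelse(meta$location == spec$locations[[1L]], 1,
                     spec$location_effect)
  for (j in seq_len(n_sp)) {
    p <- pm[j, match(meta$host_species, hosts)]
    pres <- stats::runif(n_s) < p
    ab <- stats::rlnorm(n_s, log(arch$mean_abundance[j]), arch$dispersion[j])
    presence[, j] <- pres
    abundance[, j] <- ifelse(pres, ab * loc_mult, 0)
  }
  list(abundance = abundance, presence = presence, metadata = meta)
}
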