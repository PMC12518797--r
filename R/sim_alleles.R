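#' Specification of a strain-mixture allele simulation
#'
#' Parameters for [simulate_allele_profiles()]: a genome of `genome_length`
#' positions with `n_variant_positions` strain-discriminating sites, a pool of
#' `n_strains` haplotypes, and per-sample Dirichlet strain mixtures observed
#' through Poisson-coverage multinomial read sampling.
#'
#' @param genome_length genome length L in bp (positions simulated).
#' @param n_variant_positions number of variable positions V (V <= L).
#' @param n_strains number of strain haplotypes.
#' @param host_partition if `TRUE`, strains are private to hosts (round-robin
#'   assignment) so strain composition segregates by host; if `FALSE` every
#'   sample draws from the full shared pool.
#' @param concentration Dirichlet concentration of sample mixtures; small
#'   values give near-single-strain samples.
#' @param mean_coverage Poisson mean per-position read depth.
#' @param seed RNG seed.
#' @return A validated list of class `strain_sim_spec`.
#' @export
strain_sim_spec <- function(genome_length = 1000L, n_variant_positions = 100L,
                            n_strains = 4L, host_partition = TRUE,
                            concentration = 0.8, mean_coverage = 20,
                            seed = 1L) {
  if (n_variant_positions > genome_length) stop("V must be <= L")
  if (n_strains < 1) stop("n_strains must be >= 1")
  if (mean_coverage < 0) stop("coverage must be >= 0")
  structure(list(genome_length = as.integer(genome_length),
                 n_variant_positions = as.integer(n_variant_positions),
                 n_strains = as.integer(n_strains),
                 host_partition = isTRUE(host_partition),
                 concentration = concentration, mean_coverage = mean_coverage,
                 seed = as.integer(seed)),
            class = "strain_sim_spec")
}

#' Simulate per-position allele-frequency profiles from strain mixtures
#'
#' Strain haplotypes are drawn over the variant positions (uniform nucleotide
#' per strain per site; the remaining genome is monomorphic reference). Each
#' sample receives a Dirichlet mixture over its allowed strains — all strains,
#' or only its host's private strains when `host_partition` — and observed
#' allele frequencies are multinomial read counts at Poisson coverage divided
#' by depth. The output emulates a per-species inStrain-style profile table.
#'
#' @param spec a [strain_sim_spec()].
#' @param samples data frame with columns `sample_id` and `host_species`.
#' @param species_id label written into the output table.
#' @return A data frame with columns `species_id`, `sample_id`, `position`
#'   (1-based), `coverage`, `freq_A`, `freq_C`, `freq_G`, `freq_T`
#'   (frequencies sum to 1 where coverage > 0).
#' @export
simulate_allele_profiles <- function(spec, samples, species_id = "sp_01") {
  stopifnot(inherits(spec, "strain_sim_spec"))
  if (nrow(samples) == 0L) stop("'samples' must be non-empty")
  set.seed(spec$seed)
  L <- spec$genome_length; V <- spec$n_variant_positions
  K <- spec$n_strains
  bases <- c("A", "C", "G", "T")
  var_pos <- sort(sample.int(L, V))
  # haplotypes: L x K integer codes into `bases`; reference allele is A
  hap <- matrix(1L, L, K)
  hap[var_pos, ] <- sample.int(4L, V * K, replace = TRUE)

  hosts <- unique(samples$host_species)
  allowed <- lapply(seq_len(nrow(samples)), function(i) {
    if (!spec$host_partition) return(seq_len(K))
    own <- which((seq_len(K) - 1L) %% length(hosts) + 1L ==
                   match(samples$host_species[i], hosts))
    if (length(own)) own else seq_len(K)
  })

  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    ok <- allowed[[i]]
    w <- stats::rgamma(length(ok), shape = spec$concentration)
    if (sum(w) == 0) w <- rep(1, length(ok))
    w <- w / sum(w)
    # expected per-base frequency at each position: mixture-weighted indicator
    prob <- matrix(0, L, 4L)
    for (k in seq_along(ok))
      prob[cbind(seq_len(L), hap[, ok[k]])] <-
        prob[cbind(seq_len(L), hap[, ok[k]])] + w[k]
    cov <- stats::rpois(L, spec$mean_coverage)
    freq <- matrix(0, L, 4L)
    pos_cov <- which(cov > 0)
    for (p in pos_cov)
      freq[p, ] <- stats::rmultinom(1L, cov[p], prob[p, ]) / cov[p]
    out[[i]] <- data.frame(
      species_id = species_id, sample_id = samples$sample_id[i],
      position = seq_len(L), coverage = cov,
      freq_A = freq[, 1L], freq_C = freq[, 2L],
      freq_G = freq[, 3L], freq_T = freq[, 4L],
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
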