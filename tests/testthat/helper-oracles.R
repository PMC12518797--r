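# Independent oracles and small fixture builders, kept free of the package's
# own computation paths.

# Pearson correlation of host vs symbiont distances over all link pairs,
# written as explicit double loops from the definition.
hommola_brute_r <- function(host_dm, sym_dm, links) {
  n <- nrow(links)
  xs <- ys <- c()
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      xs <- c(xs, host_dm[links$host[i], links$host[j]])
      ys <- c(ys, sym_dm[links$symbiont[i], links$symbiont[j]])
    }
  }
  mx <- mean(xs); my <- mean(ys)
  sum((xs - mx) * (ys - my)) /
    sqrt(sum((xs - mx)^2) * sum((ys - my)^2))
}

# Exact Hommola p by exhaustive enumeration of host x symbiont relabelings.
hommola_brute_exact_p <- function(host_dm, sym_dm, links) {
  n <- nrow(links)
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perm_list(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  P <- perm_list(seq_len(n))
  r_obs <- hommola_brute_r(host_dm, sym_dm, links)
  r_all <- c()
  for (ph in P) {
    for (ps in P) {
      lk <- data.frame(host = links$host[ph], symbiont = links$symbiont[ps],
                       stringsAsFactors = FALSE)
      r_all <- c(r_all, hommola_brute_r(host_dm, sym_dm, lk))
    }
  }
  mean(r_all >= r_obs - 1e-12)
}

# Naive per-position popANI: explicit loop over positions shared by the two
# tables, allele sets collected by scanning the four frequencies.
popani_brute <- function(ai, aj, min_site_cov = 5, min_freq = 0.05) {
  n_cmp <- n_sub <- 0L
  for (r in seq_len(nrow(ai))) {
    pos <- ai$position[r]
    jr <- which(aj$position == pos)
    if (!length(jr)) next
    if (ai$coverage[r] < min_site_cov || aj$coverage[jr] < min_site_cov) next
    set_i <- c("A", "C", "G", "T")[c(ai$freq_A[r], ai$freq_C[r],
                                     ai$freq_G[r], ai$freq_T[r]) >= min_freq]
    set_j <- c("A", "C", "G", "T")[c(aj$freq_A[jr], aj$freq_C[jr],
                                     aj$freq_G[jr], aj$freq_T[jr]) >= min_freq]
    if (!length(set_i) || !length(set_j)) next
    n_cmp <- n_cmp + 1L
    if (!any(set_i %in% set_j)) n_sub <- n_sub + 1L
  }
  if (n_cmp == 0L) return(NA_real_)
  n_sub / n_cmp
}

# Allele-table row builder: one position with given coverage and frequencies.
allele_row <- function(position, coverage, A = 0, C = 0, G = 0, T = 0,
                       sample_id = "s", species_id = "sp") {
  data.frame(species_id = species_id, sample_id = sample_id,
             position = position, coverage = coverage,
             freq_A = A, freq_C = C, freq_G = G, freq_T = T,
             stringsAsFactors = FALSE)
}

# A uniform-coverage allele table fixed at a single nucleotide everywhere,
# with optional overrides at chosen positions.
fixed_allele_table <- function(L, base = "A", coverage = 10,
                               sample_id = "s") {
  f <- matrix(0, L, 4, dimnames = list(NULL, c("A", "C", "G", "T")))
  f[, base] <- 1
  data.frame(species_id = "sp", sample_id = sample_id, position = seq_len(L),
             coverage = coverage, freq_A = f[, 1], freq_C = f[, 2],
             freq_G = f[, 3], freq_T = f[, 4], stringsAsFactors = FALSE)
}

# Random labelled distance matrix from points in R^2 (Euclidean, hence valid).
random_euclid_dm <- function(n, labels = paste0("t", seq_len(n))) {
  pts <- matrix(stats::rnorm(2 * n), n, 2)
  dm <- as.matrix(stats::dist(pts))
  dimnames(dm) <- list(labels, labels)
  dm
}

# Fraction of internal nodes of a symbiont tree whose tip sets mix hosts.
mixed_host_fraction <- function(tree_set) {
  tree <- tree_set$tree
  ntip <- ape::Ntip(tree)
  host_of <- tree_set$tip_map$host_species[
    match(tree$tip.label, tree_set$tip_map$tip_id)]
  mixed <- 0L
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  for (nd in nodes) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    if (length(unique(host_of[match(tips, tree$tip.label)])) > 1L)
      mixed <- mixed + 1L
  }
  mixed / length(nodes)
}
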