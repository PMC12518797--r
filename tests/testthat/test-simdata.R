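test_that("default host tree has the expected topology and is ultrametric", {
  tr <- default_host_tree()
  expect_setequal(tr$tip.label, c("A_mellifera", "A_cerana", "A_dorsata",
                                  "A_florea", "A_andreniformis"))
  # dwarf honeybees are sisters
  mrca <- ape::getMRCA(tr, c("A_florea", "A_andreniformis"))
  dwarf_clade <- ape::extract.clade(tr, mrca)$tip.label
  expect_setequal(dwarf_clade, c("A_florea", "A_andreniformis"))
  depths <- ape::node.depth.edgelength(tr)[seq_len(5)]
  expect_equal(depths, rep(1, 5))
})

test_that("pure co-speciation copies the host topology for any seed", {
  host <- default_host_tree()
  for (s in c(1, 17, 101)) {
    ts <- simulate_symbiont_tree(host, symbiont_sim_params(seed = s))
    tr <- ts$tree
    tr$tip.label <- ts$tip_map$host_species[match(tr$tip.label,
                                                  ts$tip_map$tip_id)]
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(host)), 0)
  }
})

test_that("no host switching keeps every node's host set phylogenetically closed", {
  # with full co-speciation, no loss and no switching, a genealogy node living
  # on a host branch has descendants in every host below that branch, so its
  # host set must be a complete host-tree clade; any other host set would
  # require a switch.
  host <- default_host_tree()
  ts <- simulate_symbiont_tree(host, symbiont_sim_params(
    seed = 5, dup_rate = 1.2, tips_per_lineage = 2))
  tree <- ts$tree
  host_of <- ts$tip_map$host_species[match(tree$tip.label,
                                           ts$tip_map$tip_id)]
  ntip <- ape::Ntip(tree)
  for (nd in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    hosts_under <- unique(host_of[match(tips, tree$tip.label)])
    if (length(hosts_under) == 1L) next
    mh <- ape::getMRCA(host, hosts_under)
    expect_setequal(hosts_under, ape::extract.clade(host, mh)$tip.label)
  }
})

test_that("host switching increases host mixing among internal nodes", {
  host <- default_host_tree()
  base <- simulate_symbiont_tree(host, symbiont_sim_params(
    seed = 11, switch_rate = 0, dup_rate = 0.5, tips_per_lineage = 2))
  switched <- simulate_symbiont_tree(host, symbiont_sim_params(
    seed = 11, switch_rate = 5, dup_rate = 0.5, tips_per_lineage = 2))
  expect_gt(mixed_host_fraction(switched), mixed_host_fraction(base))
})

test_that("symbiont simulation is deterministic and errors on extinction", {
  host <- default_host_tree()
  p <- symbiont_sim_params(seed = 3, switch_rate = 1, dup_rate = 0.5,
                           loss_rate = 0.4, rate_noise = 0.2,
                           tips_per_lineage = 2)
  t1 <- simulate_symbiont_tree(host, p)
  t2 <- simulate_symbiont_tree(host, p)
  expect_identical(ape::write.tree(t1$tree), ape::write.tree(t2$tree))
  expect_identical(t1$tip_map, t2$tip_map)
  expect_error(
    simulate_symbiont_tree(host, symbiont_sim_params(seed = 2,
                                                     loss_rate = 400)),
    "extinct")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(symbiont_sim_params(cospec_prob = 1.2), "cospec_prob")
  expect_error(symbiont_sim_params(switch_rate = -1), "non-negative")
  expect_error(symbiont_sim_params(n0 = 0), ">= 1")
  expect_error(strain_sim_spec(genome_length = 10, n_variant_positions = 20),
               "V must be")
  expect_error(strain_sim_spec(n_strains = 0), "n_strains")
})

test_that("community simulation respects prevalence structure", {
  host <- default_host_tree()
  hosts <- host$tip.label
  arch <- default_archetypes(hosts)
  spec <- community_spec(arch, hosts, n_samples_per_host = 200, seed = 42)
  com <- simulate_community(host, spec)
  # specialists never occur outside their host
  pres <- com$presence[, "spec_01"]
  off_host <- com$metadata$host_species != hosts[1]
  expect_false(any(pres[off_host]))
  # determinism
  com2 <- simulate_community(host, spec)
  expect_identical(com$abundance, com2$abundance)
  expect_error(community_spec(arch, hosts, n_samples_per_host = 0),
               "n_samples_per_host")
})

test_that("uniform generalist prevalence recovers the flat Rohde index", {
  host <- default_host_tree()
  hosts <- host$tip.label
  arch <- data.frame(species_id = "gen", genus = "g", mean_abundance = 20,
                     dispersion = 0.5, stringsAsFactors = FALSE)
  arch[paste0("prev_", hosts)] <- as.list(rep(0.8, 5))
  com <- simulate_community(host, community_spec(arch, hosts,
                                                 n_samples_per_host = 200,
                                                 seed = 7))
  prev <- prevalence_matrix(com$presence, com$metadata)
  s <- rohde_index(prev$prevalence["gen", ])$index
  expect_lt(abs(s - sum(1 / (1:5)) / 5), 0.02)
})

test_that("empirical prevalence converges to the specified prevalence", {
  host <- default_host_tree()
  hosts <- host$tip.label
  arch <- default_archetypes(hosts)
  com <- simulate_community(host, community_spec(arch, hosts,
                                                 n_samples_per_host = 500,
                                                 seed = 13))
  prev <- prevalence_matrix(com$presence, com$metadata)
  target <- as.matrix(arch[, paste0("prev_", hosts)])
  dimnames(target) <- list(arch$species_id, hosts)
  se <- sqrt(target * (1 - target) / 500)
  expect_true(all(abs(prev$prevalence - target) <= 3 * se + 1e-12))
})

test_that("allele profiles: single strain gives zero popANI everywhere", {
  host <- default_host_tree()
  samples <- data.frame(sample_id = paste0("s", 1:6),
                        host_species = rep(host$tip.label[1:2], each = 3),
                        stringsAsFactors = FALSE)
  a <- simulate_allele_profiles(strain_sim_spec(n_strains = 1,
                                                genome_length = 400,
                                                n_variant_positions = 40,
                                                seed = 3), samples)
  sd <- strain_distance_matrix(a, samples, "sp_01", min_samples = 5,
                               min_hosts = 2)
  expect_true(all(sd$dm == 0, na.rm = TRUE))
})

test_that("low coverage defeats the 5x site rule downstream", {
  samples <- data.frame(sample_id = "s1", host_species = "A_dorsata",
                        stringsAsFactors = FALSE)
  a <- simulate_allele_profiles(strain_sim_spec(mean_coverage = 2,
                                                genome_length = 500,
                                                n_variant_positions = 50,
                                                seed = 1), samples)
  expect_gt(mean(a$coverage < 5), 0.5)
})

test_that("allele profile frequencies are consistent and deterministic", {
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        host_species = rep(c("h1", "h2"), 2),
                        stringsAsFactors = FALSE)
  spec <- strain_sim_spec(genome_length = 300, n_variant_positions = 30,
                          seed = 9)
  a <- simulate_allele_profiles(spec, samples)
  b <- simulate_allele_profiles(spec, samples)
  expect_identical(a, b)
  f <- rowSums(a[, c("freq_A", "freq_C", "freq_G", "freq_T")])
  expect_true(all(abs(f[a$coverage > 0] - 1) < 1e-6))
  expect_true(all(f[a$coverage == 0] == 0))
})

test_that("gene tables keep per-sample accounting and determinism", {
  cat <- default_gene_catalog(n_genes = 30, seed = 2)
  samples <- data.frame(sample_id = paste0("s", 1:4),
                        host_species = rep(c("h1", "h2"), each = 2),
                        stringsAsFactors = FALSE)
  g1 <- simulate_gene_table(cat, samples, host_effect = 1, seed = 5)
  g2 <- simulate_gene_table(cat, samples, host_effect = 1, seed = 5)
  expect_identical(g1, g2)
  sums <- tapply(g1$reads_mapped, g1$sample_id, sum)
  totals <- tapply(g1$total_reads_sample, g1$sample_id, unique)
  expect_true(all(sums <= unlist(totals)))
  expect_error(simulate_gene_table(cat[0, ], samples), "empty catalog")
})

test_that("without a host effect the KO PERMANOVA rejects at the nominal rate", {
  cat <- default_gene_catalog(n_genes = 24, seed = 3)
  samples <- data.frame(sample_id = paste0("s", 1:12),
                        host_species = rep(c("h1", "h2", "h3"), each = 4),
                        stringsAsFactors = FALSE)
  rej <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    g <- simulate_gene_table(cat, samples, host_effect = 0, seed = 1000 + r)
    ko <- aggregate_features(g, "ko")
    dm <- robust_aitchison(ko)
    pv <- permanova(dm, stats::setNames(samples$host_species,
                                        samples$sample_id),
                    n_perm = 99, seed = r)
    if (pv$p <= 0.05) rej <- rej + 1L
  }
  # 95% binomial band around 0.05 with 100 replicates
  expect_gte(rej / n_rep, 0.0)
  expect_lte(rej / n_rep, 0.12)
})
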