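profile_row <- function(sample, species, breadth, cov = 10) {
  data.frame(sample_id = sample, species_id = species, breadth = breadth,
             mean_coverage = cov, stringsAsFactors = FALSE)
}

test_that("species presence switches exactly at the breadth threshold", {
  pr <- rbind(profile_row("s1", "a", 0.50), profile_row("s1", "b", 0.499),
              profile_row("s2", "a", 0.80), profile_row("s2", "b", 0.10))
  m <- detect_species(pr)
  expect_true(m["s1", "a"]); expect_false(m["s1", "b"])
  expect_true(m["s2", "a"]); expect_false(m["s2", "b"])
  # presence sets are nested as the threshold rises
  for (t in c(0.2, 0.5, 0.9)) {
    lo <- detect_species(pr, t); hi <- detect_species(pr, min(t + 0.2, 1))
    expect_true(all(lo | !hi))
  }
  expect_equal(dim(detect_species(pr[0, ])), c(0L, 0L))
})

test_that("relative coverage normalizes per sample and flags empty samples", {
  pr <- rbind(profile_row("s1", "a", 1, 2), profile_row("s1", "b", 1, 3),
              profile_row("s1", "c", 1, 5), profile_row("s2", "a", 1, 0),
              profile_row("s2", "b", 1, 0), profile_row("s2", "c", 1, 0))
  expect_warning(rc <- relative_coverage(pr), "all-zero")
  expect_equal(rc["s1", ], c(a = 0.2, b = 0.3, c = 0.5))
  expect_true(all(is.na(rc["s2", ])))
  one <- relative_coverage(profile_row("s1", "a", 1, 7))
  expect_equal(unname(one[1, 1]), 1)
})

test_that("SNV calling applies coverage, frequency and read-ANI rules", {
  sites <- rbind(
    allele_row(1, 5, A = 0.95, C = 0.05),    # SNV at both boundaries
    allele_row(2, 4, A = 0.5, C = 0.5),      # below 5x: not an SNV
    allele_row(3, 20, A = 0.96, C = 0.04),   # allele below 0.05: not an SNV
    allele_row(4, 20, A = 0.5, G = 0.5),     # SNV
    allele_row(5, 0),                        # uncovered: excluded
    allele_row(6, 20, A = 1)                 # covered, monomorphic
  )
  s <- call_snvs(sites)
  expect_equal(s$n_snvs, 2L)
  expect_equal(s$covered_length, 5L)
  expect_equal(s$pct_variable, 100 * 2 / 5)
  # read-ANI mask removes sites from numerator and denominator
  sites$read_ani <- c(0.99, 0.99, 0.99, 0.90, 0.99, 0.99)
  s2 <- call_snvs(sites)
  expect_equal(s2$n_snvs, 1L)
  expect_equal(s2$covered_length, 4L)
  # printed-ratio worked case: 2 SNVs over 1000 covered bp -> 0.2%
  tab <- fixed_allele_table(1000)
  tab[1, c("freq_A", "freq_C")] <- c(0.9, 0.1)
  tab[2, c("freq_A", "freq_G")] <- c(0.5, 0.5)
  expect_equal(call_snvs(tab)$pct_variable, 0.2)
})

test_that("SNV counts are monotone in the thresholds", {
  set.seed(31)
  tab <- fixed_allele_table(200)
  idx <- sample(200, 80)
  alt <- runif(80, 0, 0.5)
  tab$freq_A[idx] <- 1 - alt
  tab$freq_C[idx] <- alt
  tab$coverage <- rpois(200, 8)
  n_by_freq <- sapply(c(0.01, 0.05, 0.2, 0.4),
                      function(f) call_snvs(tab, min_freq = f)$n_snvs)
  n_by_cov <- sapply(c(1, 5, 10, 15),
                     function(cv) call_snvs(tab, min_cov = cv)$n_snvs)
  expect_true(all(diff(n_by_freq) <= 0))
  expect_true(all(diff(n_by_cov) <= 0))
})

test_that("popANI boundary semantics are exact", {
  a <- fixed_allele_table(100, base = "A", sample_id = "i")
  b <- fixed_allele_table(100, base = "A", sample_id = "j")
  expect_equal(as.numeric(popani_pair(a, b)), 0)
  d <- fixed_allele_table(100, base = "C", sample_id = "j")
  expect_equal(as.numeric(popani_pair(a, d)), 1)
  # shared minor allele at 0.05 rescues a site from being a substitution
  a2 <- fixed_allele_table(100, base = "A", sample_id = "i")
  b2 <- fixed_allele_table(100, base = "G", sample_id = "j")
  a2[1, c("freq_A", "freq_C")] <- c(0.95, 0.05)
  b2[1, c("freq_G", "freq_C")] <- c(0.95, 0.05)
  v <- popani_pair(a2, b2)
  expect_equal(attr(v, "n_substitutions"), 99L)
  expect_equal(as.numeric(v), 99 / 100)
})

test_that("popANI eligibility and missingness are distinguishable from zero", {
  a <- fixed_allele_table(100)
  shallow <- fixed_allele_table(100, coverage = 2)  # mean coverage below 5x
  v <- popani_pair(a, shallow)
  expect_true(is.na(v))
  expect_match(attr(v, "reason"), "eligibility")
  # eligible but no jointly well-covered position
  b <- fixed_allele_table(100)
  b$coverage <- c(rep(10, 50), rep(0, 50))
  a$coverage <- c(rep(0, 50), rep(10, 50))
  b$freq_A[b$coverage == 0] <- 0
  a$freq_A[a$coverage == 0] <- 0
  v2 <- popani_pair(a, b, min_breadth = 0.4, min_mean_cov = 4)
  expect_true(is.na(v2))
  expect_match(attr(v2, "reason"), "no compared positions")
})

test_that("popANI agrees with the naive per-position oracle", {
  set.seed(77)
  for (rep in 1:8) {
    mk <- function(id) {
      L <- 60
      cov <- rpois(L, 8)
      f <- matrix(0, L, 4)
      for (p in 1:L) {
        k <- sample(1:2, 1)
        alleles <- sample(4, k)
        w <- if (k == 1) 1 else {
          u <- runif(1, 0.02, 0.5); c(1 - u, u)
        }
        f[p, alleles] <- w
      }
      data.frame(species_id = "sp", sample_id = id, position = 1:L,
                 coverage = cov, freq_A = f[, 1], freq_C = f[, 2],
                 freq_G = f[, 3], freq_T = f[, 4], stringsAsFactors = FALSE)
    }
    ai <- mk("i"); aj <- mk("j")
    got <- popani_pair(ai, aj, min_breadth = 0, min_mean_cov = 0)
    expect_identical(as.numeric(got), popani_brute(ai, aj))
  }
})

test_that("popANI is symmetric, bounded and a monotone filter", {
  set.seed(5)
  a <- fixed_allele_table(80); b <- fixed_allele_table(80, base = "C")
  b$freq_C[1:30] <- 0; b$freq_A[1:30] <- 1
  a$coverage <- rpois(80, 9); b$coverage <- rpois(80, 9)
  v_ab <- popani_pair(a, b, min_breadth = 0, min_mean_cov = 0)
  v_ba <- popani_pair(b, a, min_breadth = 0, min_mean_cov = 0)
  expect_identical(as.numeric(v_ab), as.numeric(v_ba))
  expect_true(as.numeric(v_ab) >= 0 && as.numeric(v_ab) <= 1)
  n_cmp <- sapply(c(1, 5, 8, 12), function(cv) {
    nc <- attr(popani_pair(a, b, min_site_cov = cv, min_breadth = 0,
                           min_mean_cov = 0), "n_compared")
    if (is.null(nc)) 0L else nc
  })
  expect_true(all(diff(n_cmp) <= 0))
})

test_that("strain matrices respect the 5-samples / 2-hosts analyzability rule", {
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     host_species = c("h1", "h1", "h2", "h2", "h1", "h2"),
                     stringsAsFactors = FALSE)
  mk_tab <- function(ids) do.call(rbind, lapply(ids, function(s) {
    t <- fixed_allele_table(100, sample_id = s); t
  }))
  a4 <- mk_tab(paste0("s", 1:4))
  sd4 <- strain_distance_matrix(a4, meta, "sp")
  expect_false(sd4$analyzable)
  expect_match(sd4$reason, "4 eligible")
  a6 <- mk_tab(paste0("s", 1:6))
  sd6 <- strain_distance_matrix(a6, meta, "sp")
  expect_true(sd6$analyzable)
  expect_true(isSymmetric(sd6$dm))
  expect_true(all(diag(sd6$dm) == 0))
  # single eligible sample: empty matrix with a reason
  one <- strain_distance_matrix(mk_tab("s1"), meta, "sp")
  expect_equal(nrow(one$dm), 0L)
  expect_false(one$analyzable)
})

test_that("host-partitioned strains give smaller within-host popANI", {
  meta <- data.frame(sample_id = paste0("s", 1:12),
                     host_species = rep(c("h1", "h2", "h3"), each = 4),
                     stringsAsFactors = FALSE)
  a <- simulate_allele_profiles(
    strain_sim_spec(n_strains = 6, genome_length = 600,
                    n_variant_positions = 90, seed = 21), meta)
  sd <- strain_distance_matrix(a, meta, "sp_01")
  hosts <- meta$host_species[match(rownames(sd$dm), meta$sample_id)]
  same <- outer(hosts, hosts, "==")
  lt <- lower.tri(sd$dm)
  expect_lt(mean(sd$dm[lt & same], na.rm = TRUE),
            mean(sd$dm[lt & !same], na.rm = TRUE))
})

test_that("ANI clustering separates blocks and picks quality representatives", {
  mags <- paste0("m", 1:4)
  ani <- matrix(0.80, 4, 4, dimnames = list(mags, mags))
  ani[1:2, 1:2] <- 0.99; ani[3:4, 3:4] <- 0.99; diag(ani) <- 1
  q <- data.frame(mag_id = mags, completeness = c(95, 99, 90, 90),
                  contamination = c(1, 4, 2, 2), stringsAsFactors = FALSE)
  cl <- cluster_by_ani(ani, q)
  expect_equal(length(cl$representatives), 2L)
  # scores 90 vs 79: the (95, 1) MAG represents its cluster
  expect_true("m1" %in% cl$representatives)
  # tie in the second cluster broken lexicographically
  expect_true("m3" %in% cl$representatives)
  # all within threshold: one cluster
  ani1 <- matrix(0.97, 4, 4, dimnames = list(mags, mags)); diag(ani1) <- 1
  expect_equal(length(cluster_by_ani(ani1, q)$representatives), 1L)
  expect_error(cluster_by_ani(ani, q[-2, ]), "quality missing")
})
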