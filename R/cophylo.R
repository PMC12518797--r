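#' Configuration of the node-by-node co-phylogeny scan
#'
#' Node filters and significance tiers for [node_scan()] /
#' [second_order_test()]. The defaults follow the study design: a node is
#' testable when its subtree holds at least 7 MAGs from at least three host
#' species with a maximum patristic tip-tip distance of at most 1 (in the
#' tree's substitutions-per-site units), and the Hommola test runs 100
#' permutations. Tiers: relaxed (p < 0.05), medium (p < 0.05 and r > 0.75),
#' strict (p < 0.01 and r > 0.75).
#'
#' @param min_tips minimum MAG tips in a testable subtree.
#' @param min_hosts minimum host species spanned.
#' @param max_tip_tip_dist maximum pairwise patristic tip distance.
#' @param n_perm Hommola permutations per node.
#' @param tier tier used when counting significant nodes.
#' @param seed master seed; per-node streams are derived from it so results
#'   do not depend on scan order.
#' @return A validated list of class `cophylo_config`.
#' @export
cophylo_config <- function(min_tips = 7L, min_hosts = 3L,
                           max_tip_tip_dist = 1.0, n_perm = 100L,
                           tier = c("strict", "medium", "relaxed"),
                           seed = 1L) {
  tier <- match.arg(tier)
  if (min_tips < 2L) stop("min_tips must be >= 2")
  if (n_perm < 1L) stop("n_perm must be >= 1")
  structure(list(min_tips = as.integer(min_tips),
                 min_hosts = as.integer(min_hosts),
                 max_tip_tip_dist = max_tip_tip_dist,
                 n_perm = as.integer(n_perm), tier = tier,
                 seed = as.integer(seed)),
            class = "cophylo_config")
}

tier_thresholds <- list(relaxed = list(p = 0.05, r = -Inf),
                        medium = list(p = 0.05, r = 0.75),
                        strict = list(p = 0.01, r = 0.75))

tiers_met <- function(r, p) {
  if (is.na(r)) return(character(0))
  names(tier_thresholds)[vapply(tier_thresholds, function(th)
    p < th$p && r > th$r, logical(1L))]
}

# tip indices under each internal node (postorder accumulation)
tips_under_nodes <- function(tree) {
  ntip <- ape::Ntip(tree)
  nn <- ntip + tree$Nnode
  sets <- vector("list", nn)
  for (i in seq_len(ntip)) sets[[i]] <- i
  reord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(reord$edge))) {
    p <- reord$edge[e, 1L]; ch <- reord$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

#' Hommola cospeciation test
#'
#' Permutation test for congruence between host and symbiont phylogenies over
#' a set of host-symbiont links: across all unordered pairs of links, the
#' statistic is the Pearson correlation between host patristic distances and
#' symbiont patristic distances. The null distribution is generated by
#' independently permuting the host side and the symbiont side of the
#' association (host-only shuffling is available), with the +1-corrected
#' p-value `(1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param host_dm host distance matrix (labelled).
#' @param symbiont_dm symbiont tip distance matrix (labelled).
#' @param links data frame with columns `symbiont` (labels in `symbiont_dm`)
#'   and `host` (labels in `host_dm`), one row per link.
#' @param n_perm number of permutations; ignored when `exact = TRUE`.
#' @param seed RNG seed.
#' @param exact enumerate all `n! x n!` (or `n!` for host-only) relabelings;
#'   only allowed for `n <= 5` links.
#' @param perm_mode shuffle both sides (the original test) or hosts only.
#' @return A list of class `hommola_result`: `r`, `p`, `n_links`,
#'   `degenerate` (zero variance on either side gives `r = NA`, `p = 1`).
#' @export
hommola_test <- function(host_dm, symbiont_dm, links, n_perm = 100L,
                         seed = NULL, exact = FALSE,
                         perm_mode = c("both", "host")) {
  perm_mode <- match.arg(perm_mode)
  host_dm <- check_dm(host_dm, "host_dm")
  symbiont_dm <- check_dm(symbiont_dm, "symbiont_dm")
  if (nrow(links) < 3L) stop("need at least 3 host-symbiont links")
  if (!all(links$host %in% rownames(host_dm)))
    stop("link host(s) missing from host_dm")
  if (!all(links$symbiont %in% rownames(symbiont_dm)))
    stop("link symbiont(s) missing from symbiont_dm")
  n <- nrow(links)
  HD <- host_dm[links$host, links$host]
  SD <- symbiont_dm[links$symbiont, links$symbiont]
  x <- lower_tri(HD); y <- lower_tri(SD)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p = 1, n_links = n,
                          degenerate = TRUE), class = "hommola_result"))
  }
  r_obs <- stats::cor(x, y)
  lt <- lower.tri(HD)
  if (exact) {
    if (n > 5L) stop("exact enumeration limited to 5 links")
    P <- all_perms(n)
    hp <- if (perm_mode == "host") P else P[rep(seq_len(nrow(P)),
                                                each = nrow(P)), , drop = FALSE]
    sp <- if (perm_mode == "host") matrix(rep(seq_len(n), nrow(P)),
                                          ncol = n, byrow = TRUE)
          else P[rep(seq_len(nrow(P)), times = nrow(P)), , drop = FALSE]
    r_all <- vapply(seq_len(nrow(hp)), function(k) {
      stats::cor(HD[hp[k, ], hp[k, ]][lt], SD[sp[k, ], sp[k, ]][lt])
    }, numeric(1L))
    return(structure(list(r = r_obs, p = mean(r_all >= r_obs - 1e-12),
                          n_links = n, degenerate = FALSE, exact = TRUE,
                          n_perm = length(r_all)),
                     class = "hommola_result"))
  }
  if (!is.null(seed)) set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    p1 <- sample.int(n)
    p2 <- if (perm_mode == "both") sample.int(n) else seq_len(n)
    rb <- stats::cor(HD[p1, p1][lt], SD[p2, p2][lt])
    if (!is.na(rb) && rb >= r_obs - 1e-12) exceed <- exceed + 1L
  }
  structure(list(r = r_obs, p = (1 + exceed) / (1 + n_perm), n_links = n,
                 degenerate = FALSE, exact = FALSE,
                 n_perm = as.integer(n_perm)),
            class = "hommola_result")
}

#' @export
print.hommola_result <- function(x, ...) {
  if (x$degenerate)
    cat("Hommola test: degenerate (zero distance variance), p = 1\n")
  else cat(sprintf("Hommola test: r = %.4f, p = %.4g (%d links)\n",
                   x$r, x$p, x$n_links))
  invisible(x)
}

#' Enumerate subtrees eligible for the co-phylogeny test
#'
#' Applies the node filters to every internal node of the symbiont tree:
#' at least `min_tips` non-outgroup MAG tips, spanning at least `min_hosts`
#' host species, with maximum pairwise patristic tip distance at most
#' `max_tip_tip_dist`. Excluded nodes carry their failure reason.
#'
#' @param tree_set a [symbiont_tree_set()].
#' @param config a [cophylo_config()].
#' @return Data frame with one row per internal node: `node_id`, `n_tips`,
#'   `n_hosts`, `max_tip_tip_dist`, `contains_outgroup`, `testable`,
#'   `reason`.
#' @export
enumerate_testable_nodes <- function(tree_set, config = cophylo_config()) {
  stopifnot(inherits(tree_set, "symbiont_tree_set"))
  tree <- tree_set$tree
  ntip <- ape::Ntip(tree)
  pd <- patristic_matrix(tree)
  sets <- tips_under_nodes(tree)
  tm <- tree_set$tip_map
  host_of <- tm$host_species
  outg <- tm$is_outgroup
  nodes <- (ntip + 1L):(ntip + tree$Nnode)
  res <- lapply(nodes, function(nd) {
    tips <- sets[[nd]]
    focal <- tips[!outg[tips]]
    labs <- tree$tip.label[focal]
    n_hosts <- length(unique(host_of[focal]))
    maxd <- if (length(labs) >= 2L) max(pd[labs, labs]) else 0
    reason <- if (length(focal) < config$min_tips) "too few MAGs"
      else if (n_hosts < config$min_hosts) "too few hosts"
      else if (maxd > config$max_tip_tip_dist) "tip-tip distance too large"
      else NA_character_
    data.frame(node_id = nd, n_tips = length(focal), n_hosts = n_hosts,
               max_tip_tip_dist = maxd,
               contains_outgroup = any(outg[tips]),
               testable = is.na(reason), reason = reason,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Node-by-node Hommola co-phylogeny scan
#'
#' Runs [hommola_test()] on every testable internal node of a symbiont tree
#' (subtree patristic distances vs host patristic distances, one link per
#' non-outgroup MAG tip), assigns the significance tiers met by each node,
#' and excludes nodes whose subtree contains outgroup tips from the
#' significant set (they are still reported). Per-node permutation streams
#' are derived from the master seed, so results are independent of scan
#' order.
#'
#' @param tree_set a [symbiont_tree_set()].
#' @param host_tree host phylogeny ([ape::phylo]); every host in the tip map
#'   (outgroups aside) must be one of its tips.
#' @param config a [cophylo_config()].
#' @return An object of class `cophylo_scan`: `nodes` (per-node data frame
#'   with `r`, `p`, tiers and filters), `n_tested`, `n_significant`
#'   (at `config$tier`, outgroup nodes excluded), `config`.
#' @export
node_scan <- function(tree_set, host_tree, config = cophylo_config()) {
  stopifnot(inherits(tree_set, "symbiont_tree_set"))
  tm <- tree_set$tip_map
  focal_hosts <- unique(tm$host_species[!tm$is_outgroup])
  if (!all(focal_hosts %in% host_tree$tip.label))
    stop("host(s) in tip map missing from host tree: ",
         paste(setdiff(focal_hosts, host_tree$tip.label), collapse = ", "))
  filt <- enumerate_testable_nodes(tree_set, config)
  host_dm <- patristic_matrix(host_tree)
  sym_dm <- patristic_matrix(tree_set$tree)
  sets <- tips_under_nodes(tree_set$tree)
  outg <- tm$is_outgroup
  test_rows <- which(filt$testable)
  rres <- pres <- rep(NA_real_, nrow(filt))
  tier_str <- rep("", nrow(filt))
  for (i in test_rows) {
    nd <- filt$node_id[i]
    tips <- sets[[nd]]
    focal <- tips[!outg[tips]]
    links <- data.frame(symbiont = tree_set$tree$tip.label[focal],
                        host = tm$host_species[focal],
                        stringsAsFactors = FALSE)
    h <- hommola_test(host_dm, sym_dm, links, n_perm = config$n_perm,
                      seed = derive_seed(config$seed, nd))
    rres[i] <- if (h$degenerate) NA_real_ else h$r
    pres[i] <- h$p
    tier_str[i] <- paste(tiers_met(rres[i], pres[i]), collapse = ",")
  }
  nodes <- cbind(filt, r = rres, p = pres, significant_at = tier_str,
                 stringsAsFactors = FALSE)
  sig <- nodes$testable & !nodes$contains_outgroup &
    vapply(strsplit(nodes$significant_at, ","),
           function(s) config$tier %in% s, logical(1L))
  structure(list(nodes = nodes, n_tested = length(test_rows),
                 n_significant = sum(sig), config = config),
            class = "cophylo_scan")
}

#' @export
print.cophylo_scan <- function(x, ...) {
  cat(sprintf("Co-phylogeny scan: %d nodes tested, %d significant at the %s tier\n",
              x$n_tested, x$n_significant, x$config$tier))
  invisible(x)
}

#' Second-order permutation test of the co-phylogeny scan
#'
#' Estimates how many significant nodes the node-by-node scan would report by
#' chance: the host assignments of the non-outgroup tips are shuffled
#' uniformly (tree topology untouched), the node filters are re-applied and
#' the scan re-run, `n_shuffles` times. The empirical p-value is
#' `(1 + #{null_count >= observed_count}) / (1 + n_shuffles)`.
#'
#' @param tree_set a [symbiont_tree_set()].
#' @param host_tree host phylogeny.
#' @param config a [cophylo_config()]; `config$tier` sets the significance
#'   tier that is counted.
#' @param n_shuffles number of label shuffles.
#' @return An object of class `second_order_result`: `observed_count`,
#'   `null_counts`, `tested_counts` (testable nodes per shuffle),
#'   `empirical_p`, `n_shuffles`.
#' @export
second_order_test <- function(tree_set, host_tree, config = cophylo_config(),
                              n_shuffles = 100L) {
  if (n_shuffles < 1L) stop("n_shuffles must be >= 1")
  observed <- node_scan(tree_set, host_tree, config)
  focal <- which(!tree_set$tip_map$is_outgroup)
  null_counts <- tested_counts <- integer(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    set.seed(derive_seed(config$seed, 100000L + s))
    shuf <- tree_set
    shuf$tip_map$host_species[focal] <-
      tree_set$tip_map$host_species[focal][sample.int(length(focal))]
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 200000L + s)
    sc <- node_scan(shuf, host_tree, cfg)
    null_counts[s] <- sc$n_significant
    tested_counts[s] <- sc$n_tested
  }
  structure(list(
    observed_count = observed$n_significant,
    null_counts = null_counts, tested_counts = tested_counts,
    empirical_p = (1 + sum(null_counts >= observed$n_significant)) /
      (1 + n_shuffles),
    n_shuffles = as.integer(n_shuffles), scan = observed
  ), class = "second_order_result")
}

#' @export
print.second_order_result <- function(x, ...) {
  cat(sprintf(
    "Second-order permutation test: %d significant node(s) observed vs null median %g over %d shuffles (empirical p = %.4g)\n",
    x$observed_count, stats::median(x$null_counts), x$n_shuffles,
    x$empirical_p))
  invisible(x)
}
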