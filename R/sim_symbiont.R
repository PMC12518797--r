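#' Parameters for the symbiont tree simulator
#'
#' Bundles and validates the parameters of the continuous-time
#' co-speciation / host-switch / loss / duplication model used by
#' [simulate_symbiont_tree()].
#'
#' @param n0 initial symbiont lineages at the host root.
#' @param cospec_prob probability (rho) that a lineage follows both daughter
#'   host branches at a host split; otherwise it follows one, chosen uniformly.
#' @param switch_rate per-lineage rate (sigma) of host-switch events; a switch
#'   copies the lineage into a uniformly chosen contemporaneous host branch
#'   (the donor is retained unless `switch_moves = TRUE`).
#' @param loss_rate per-lineage extinction rate (mu).
#' @param dup_rate per-lineage within-host diversification rate (lambda).
#' @param rate_scale symbiont branch-length units (substitutions per site)
#'   per unit of host time; the default 0.4 puts root-to-tip symbiont
#'   divergence on the scale observed for genus-level core-genome trees, so
#'   tip-tip distances stay within the co-phylogeny scan's depth filter.
#' @param rate_noise lognormal standard deviation (eta) of per-branch rate
#'   multipliers; 0 gives a strict clock.
#' @param tips_per_lineage number of MAG tips attached as a star to each
#'   surviving lineage, mimicking repeated genome recovery of one species.
#' @param tip_jitter branch length (epsilon) of the star edges, i.e.
#'   within-lineage divergence among MAGs.
#' @param switch_moves logical; if `TRUE` a switch moves the lineage instead of
#'   copying it.
#' @param seed RNG seed; the simulation is bit-reproducible given the seed.
#' @return A validated list of class `symbiont_sim_params`.
#' @export
symbiont_sim_params <- function(n0 = 1L, cospec_prob = 1, switch_rate = 0,
                                loss_rate = 0, dup_rate = 0, rate_scale = 0.4,
                                rate_noise = 0, tips_per_lineage = 1L,
                                tip_jitter = 0.01, switch_moves = FALSE,
                                seed = 1L) {
  if (cospec_prob < 0 || cospec_prob > 1) stop("cospec_prob must be in [0, 1]")
  if (switch_rate < 0 || loss_rate < 0 || dup_rate < 0)
    stop("rates must be non-negative")
  if (rate_noise < 0 || tip_jitter < 0)
    stop("rate_noise and tip_jitter must be non-negative")
  if (n0 < 1 || tips_per_lineage < 1)
    stop("n0 and tips_per_lineage must be >= 1")
  if (rate_scale <= 0) stop("rate_scale must be positive")
  structure(list(
    n0 = as.integer(n0), cospec_prob = cospec_prob,
    switch_rate = switch_rate, loss_rate = loss_rate, dup_rate = dup_rate,
    rate_scale = rate_scale, rate_noise = rate_noise,
    tips_per_lineage = as.integer(tips_per_lineage), tip_jitter = tip_jitter,
    switch_moves = isTRUE(switch_moves), seed = as.integer(seed)
  ), class = "symbiont_sim_params")
}

#' Construct a symbiont tree set
#'
#' Pairs a rooted symbiont phylogeny with the map from its tips to MAG
#' identifiers, source host species and outgroup status — the unit of input
#' for the co-phylogeny scan.
#'
#' @param tree an [ape::phylo] object.
#' @param tip_map data frame with columns `tip_id`, `mag_id`, `host_species`,
#'   `is_outgroup`; `tip_id` must cover every tip of `tree` exactly once.
#' @return An object of class `symbiont_tree_set`.
#' @export
symbiont_tree_set <- function(tree, tip_map) {
  if (!inherits(tree, "phylo")) stop("'tree' must be a phylo object")
  need <- c("tip_id", "mag_id", "host_species", "is_outgroup")
  if (!all(need %in% names(tip_map)))
    stop("tip_map must have columns ", paste(need, collapse = ", "))
  if (!setequal(tip_map$tip_id, tree$tip.label) ||
      anyDuplicated(tip_map$tip_id))
    stop("tip_map must map every tree tip exactly once")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  tip_map <- tip_map[match(tree$tip.label, tip_map$tip_id), , drop = FALSE]
  rownames(tip_map) <- NULL
  structure(list(tree = tree, tip_map = tip_map), class = "symbiont_tree_set")
}

#' @export
print.symbiont_tree_set <- function(x, ...) {
  hosts <- unique(x$tip_map$host_species[!x$tip_map$is_outgroup])
  cat("Symbiont tree set:", ape::Ntip(x$tree), "tips,",
      length(hosts), "host species,",
      sum(x$tip_map$is_outgroup), "outgroup tips\n")
  invisible(x)
}

#' Simulate a symbiont phylogeny along a host tree
#'
#' Gillespie simulation of symbiont lineages evolving inside the branches of a
#' timed host phylogeny. Lineages duplicate (within-host diversification), go
#' extinct, or switch host (a copy invades a uniformly chosen contemporaneous
#' host branch) with exponential waiting times; at each host split a lineage
#' follows both daughter branches with probability `cospec_prob`, else one
#' chosen uniformly. Lineages alive when a host branch reaches its tip become
#' symbiont species, each contributing `tips_per_lineage` MAG tips attached as
#' a short star. Branch lengths are host-time spans scaled by `rate_scale`
#' and, when `rate_noise > 0`, multiplied by per-branch lognormal factors.
#'
#' With `cospec_prob = 1` and all rates zero the symbiont tree is a copy of
#' the host topology; with `switch_rate = 0` every symbiont clade is
#' host-monophyletic.
#'
#' @param host a rooted [ape::phylo] host tree with branch lengths.
#' @param params a [symbiont_sim_params()] object.
#' @return A [symbiont_tree_set()] whose tips are simulated MAGs.
#' @examples
#' host <- default_host_tree()
#' ts <- simulate_symbiont_tree(host, symbiont_sim_params(seed = 1))
#' @export
simulate_symbiont_tree <- function(host, params) {
  if (!inherits(host, "phylo")) stop("'host' must be a phylo object")
  if (!inherits(params, "symbiont_sim_params"))
    params <- do.call(symbiont_sim_params, params)
  set.seed(params$seed)

  ntip <- ape::Ntip(host)
  depth <- ape::node.depth.edgelength(host)
  e_par <- host$edge[, 1L]; e_chi <- host$edge[, 2L]
  e_t0 <- depth[e_par]; e_t1 <- depth[e_chi]
  root <- ntip + 1L
  # host nodes ordered by depth; the root split (depth 0) comes first
  host_nodes <- order(depth)
  in_edge <- match(seq_along(depth), e_chi)      # NA for root

  # genealogy: grown vectors; node 1 is the stem point at time 0
  g_parent <- 0; g_time <- 0; g_host <- NA_character_
  add_gnode <- function(parent, time, hostlab = NA_character_) {
    g_parent[length(g_parent) + 1L] <<- parent
    g_time[length(g_time) + 1L] <<- time
    g_host[length(g_host) + 1L] <<- hostlab
    length(g_parent)
  }

  # lineage state: anchor genealogy node, host edge (0 = stem above root),
  # status: 1 active, 0 dead/replaced, 2 frozen at a host tip
  lin_anchor <- rep(1L, params$n0)
  lin_edge <- rep(0L, params$n0)
  lin_status <- rep(1L, params$n0)
  n_leaves <- 0L

  spawn <- function(anchor, edge) {
    lin_anchor[length(lin_anchor) + 1L] <<- anchor
    lin_edge[length(lin_edge) + 1L] <<- edge
    lin_status[length(lin_status) + 1L] <<- 1L
  }

  per_rate <- params$switch_rate + params$loss_rate + params$dup_rate
  ev_prob <- c(params$switch_rate, params$loss_rate, params$dup_rate)

  run_events <- function(ta, tb) {
    if (per_rate <= 0 || tb <= ta) return(invisible())
    t <- ta
    repeat {
      act <- which(lin_status == 1L)
      if (!length(act)) break
      t <- t + stats::rexp(1L, length(act) * per_rate)
      if (t >= tb) break
      k <- act[sample.int(length(act), 1L)]
      ev <- sample.int(3L, 1L, prob = ev_prob)
      if (ev == 2L) {                                     # loss
        lin_status[k] <<- 0L
        if (n_leaves == 0L && !any(lin_status == 1L))
          stop("extinct clade: all symbiont lineages died before any host tip")
      } else if (ev == 3L) {                              # duplication
        nn <- add_gnode(lin_anchor[k], t)
        lin_anchor[k] <<- nn
        spawn(nn, lin_edge[k])
      } else {                                            # host switch
        alive <- which(e_t0 <= t & e_t1 > t)
        alive <- setdiff(alive, lin_edge[k])
        if (length(alive)) {
          target <- alive[sample.int(length(alive), 1L)]
          if (params$switch_moves) {
            lin_edge[k] <<- target
          } else {
            nn <- add_gnode(lin_anchor[k], t)
            lin_anchor[k] <<- nn
            spawn(nn, target)
          }
        }
      }
    }
    invisible()
  }

  t_prev <- 0
  for (h in host_nodes) {
    t_h <- depth[h]
    run_events(t_prev, t_h)
    t_prev <- t_h
    e_in <- if (h == root) 0L else in_edge[h]
    on_edge <- which(lin_status == 1L & lin_edge == e_in)
    if (h <= ntip) {                                      # host tip reached
      for (k in on_edge) {
        add_gnode(lin_anchor[k], t_h, host$tip.label[h])
        lin_status[k] <- 2L
        n_leaves <- n_leaves + 1L
      }
    } else {                                              # host split
      daughters <- which(e_par == h)
      for (k in on_edge) {
        if (stats::runif(1L) < params$cospec_prob) {
          nn <- add_gnode(lin_anchor[k], t_h)
          lin_status[k] <- 0L
          for (d in daughters) spawn(nn, d)
        } else {
          lin_edge[k] <- daughters[sample.int(length(daughters), 1L)]
        }
      }
    }
  }
  if (n_leaves == 0L)
    stop("extinct clade: all symbiont lineages died before any host tip")

  # attach MAG tips as a star of length tip_jitter under each surviving lineage
  leaf_nodes <- which(!is.na(g_host))
  mag_labels <- character(0); mag_hosts <- character(0)
  mag_counter <- 0L
  for (ln in leaf_nodes) {
    for (j in seq_len(params$tips_per_lineage)) {
      mag_counter <- mag_counter + 1L
      lab <- sprintf("mag_%04d", mag_counter)
      add_gnode(ln, g_time[ln] + params$tip_jitter, paste0("TIP:", lab))
      mag_labels <- c(mag_labels, lab)
      mag_hosts <- c(mag_hosts, g_host[ln])
    }
    g_host[ln] <- NA_character_
  }
  if (mag_counter < 2L)
    stop("fewer than 2 surviving symbiont tips; increase n0 or lower loss_rate")

  # emit Newick, pruning dead branches and collapsing single-child chains
  n_g <- length(g_parent)
  children <- vector("list", n_g)
  for (i in seq_len(n_g)[-1L]) {
    p <- g_parent[i]
    children[[p]] <- c(children[[p]], i)
  }
  is_tip <- startsWith(ifelse(is.na(g_host), "", g_host), "TIP:")
  has_tip <- logical(n_g)
  for (i in n_g:1L) {
    has_tip[i] <- is_tip[i] || any(has_tip[children[[i]]])
  }
  live_kids <- function(i) {
    k <- children[[i]]
    k[has_tip[k]]
  }
  skip_chain <- function(i) {
    repeat {
      k <- live_kids(i)
      if (length(k) != 1L) return(i)
      i <- k
    }
  }
  blen <- function(from, to) {
    span <- (g_time[to] - g_time[from]) * params$rate_scale
    if (params$rate_noise > 0)
      span <- span * stats::rlnorm(1L, -params$rate_noise^2 / 2,
                                   params$rate_noise)
    span
  }
  emit <- function(i) {
    if (is_tip[i]) return(sub("^TIP:", "", g_host[i]))
    kk <- vapply(live_kids(i), skip_chain, integer(1L))
    parts <- vapply(kk, function(k) {
      paste0(emit(k), ":", sprintf("%.12f", blen(i, k)))
    }, character(1L))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  top <- skip_chain(1L)
  if (is_tip[top]) stop("degenerate simulation: a single surviving tip")
  tree <- ape::read.tree(text = paste0(emit(top), ";"))

  symbiont_tree_set(tree, data.frame(
    tip_id = mag_labels, mag_id = mag_labels, host_species = mag_hosts,
    is_outgroup = FALSE, stringsAsFactors = FALSE
  ))
}

#' Attach an outgroup clade to a symbiont tree set
#'
#' Adds a small clade of outgroup genomes (e.g. bumblebee-derived relatives
#' used to root genus trees) as sister to the existing tree. Outgroup tips are
#' flagged `is_outgroup = TRUE` and carry a host label outside the focal host
#' set.
#'
#' @param tree_set a [symbiont_tree_set()].
#' @param n_tips number of outgroup tips.
#' @param host_label host label recorded for the outgroup tips.
#' @param stem_length branch length of the outgroup stem and of the new stem
#'   leading to the original tree.
#' @param tip_length branch length of each outgroup tip.
#' @return A new [symbiont_tree_set()].
#' @export
add_outgroup <- function(tree_set, n_tips = 2L, host_label = "Bombus_sp",
                         stem_length = 0.5, tip_length = 0.1) {
  stopifnot(inherits(tree_set, "symbiont_tree_set"), n_tips >= 1)
  labs <- sprintf("outgroup_%02d", seq_len(n_tips))
  og <- paste0("(", paste0(labs, ":", tip_length, collapse = ","), ")")
  if (n_tips == 1L) og <- labs
  base <- sub(";$", "", ape::write.tree(tree_set$tree))
  nwk <- paste0("(", base, ":", stem_length, ",", og, ":", stem_length, ");")
  tree <- ape::read.tree(text = nwk)
  tm <- rbind(tree_set$tip_map, data.frame(
    tip_id = labs, mag_id = labs, host_species = host_label,
    is_outgroup = TRUE, stringsAsFactors = FALSE
  ))
  symbiont_tree_set(tree, tm)
}
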