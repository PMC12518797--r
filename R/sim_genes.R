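#' Default annotation catalog for the gene-table simulator
#'
#' A small gene catalog with lengths, genus assignments, and partial KO /
#' CAZyme annotations, shaped like the per-gene annotation tables produced by
#' ORF calling plus functional annotation (which are inputs here, not
#' computed).
#'
#' @param n_genes number of genes.
#' @param genera genus labels cycled over genes.
#' @param seed RNG seed.
#' @return Data frame with columns `gene_id`, `genus`, `length_bp`, `ko`,
#'   `cazyme_family` (`NA` where unannotated).
#' @export
default_gene_catalog <- function(n_genes = 60L,
                                 genera = c("Lactobacillus", "Gilliamella",
                                            "Bifidobacterium", "Dysgonomonas"),
                                 seed = 1L) {
  if (n_genes < 1) stop("empty catalog")
  set.seed(seed)
  fam_pool <- c("GH13", "GH43", "GH28", "PL1", "CE4", "GT2", "AA3")
  data.frame(
    gene_id = sprintf("gene_%04d", seq_len(n_genes)),
    genus = rep_len(genera, n_genes),
    length_bp = sample(300:3000, n_genes, replace = TRUE),
    ko = ifelse(stats::runif(n_genes) < 0.7,
                sprintf("K%05d", sample.int(200L, n_genes, replace = TRUE)),
                NA_character_),
    cazyme_family = ifelse(stats::runif(n_genes) < 0.35,
                           sample(fam_pool, n_genes, replace = TRUE),
                           NA_character_),
    stringsAsFactors = FALSE
  )
}

#' Simulate a per-sample gene read-count table
#'
#' Reads per gene follow a negative binomial whose log-mean carries a
#' host-dependent shift (standard deviation `host_effect`; 0 removes all host
#' structure). The fraction of gene bases covered rises monotonically with
#' reads and saturates (`1 - exp(-reads * read_length / length_bp)`), and the
#' recorded per-sample library size always exceeds the sum of mapped reads.
#'
#' @param catalog gene catalog as from [default_gene_catalog()].
#' @param samples data frame with `sample_id` and `host_species`.
#' @param host_effect sd of per-(gene, host) log-mean shifts.
#' @param base_mean negative-binomial baseline mean reads per gene.
#' @param nb_size negative-binomial size (inverse overdispersion).
#' @param read_length_bp read length used in the coverage saturation model.
#' @param seed RNG seed.
#' @return A `GeneRecord` data frame: `sample_id`, `gene_id`, `genus`,
#'   `length_bp`, `reads_mapped`, `fraction_bases_covered`,
#'   `total_reads_sample`, `ko`, `cazyme_family`.
#' @export
simulate_gene_table <- function(catalog, samples, host_effect = 1,
                                base_mean = 50, nb_size = 5,
                                read_length_bp = 150, seed = 1L) {
  if (is.null(catalog) || nrow(catalog) == 0L) stop("empty catalog")
  set.seed(seed)
  hosts <- unique(samples$host_species)
  shift <- matrix(stats::rnorm(nrow(catalog) * length(hosts), 0, host_effect),
                  nrow(catalog), length(hosts),
                  dimnames = list(catalog$gene_id, hosts))
  out <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    mu <- base_mean * exp(shift[, samples$host_species[i]])
    reads <- stats::rnbinom(nrow(catalog), mu = mu, size = nb_size)
    fbc <- 1 - exp(-reads * read_length_bp / catalog$length_bp)
    total <- ceiling(sum(reads) * stats::runif(1L, 1.15, 1.4)) + 1000L
    out[[i]] <- data.frame(
      sample_id = samples$sample_id[i], gene_id = catalog$gene_id,
      genus = catalog$genus, length_bp = catalog$length_bp,
      reads_mapped = reads, fraction_bases_covered = fbc,
      total_reads_sample = total, ko = catalog$ko,
      cazyme_family = catalog$cazyme_family, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}
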