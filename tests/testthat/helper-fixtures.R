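# Small in-code fixtures shared across test files.

# dense matrix with the same value at every pair (OE identically 1)
uniform_matrix <- function(n_bins = 60, resolution = 250, value = 5,
                           normalization = "balanced", chrom = "chrU") {
  p <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
             arr.ind = TRUE)
  contact_matrix(chrom, n_bins * resolution, resolution,
                 p[, 1] - 1L, p[, 2] - 1L, rep(value, nrow(p)),
                 normalization = normalization)
}

# dense matrix from an explicit symmetric value function v(i, j)
matrix_from_fun <- function(n_bins, resolution, vfun,
                            normalization = "balanced", chrom = "chrF") {
  p <- which(upper.tri(matrix(0, n_bins, n_bins), diag = TRUE),
             arr.ind = TRUE)
  vals <- mapply(vfun, p[, 1] - 1L, p[, 2] - 1L)
  contact_matrix(chrom, n_bins * resolution, resolution,
                 p[, 1] - 1L, p[, 2] - 1L, vals,
                 normalization = normalization)
}

# a small simulated chromosome with planted single-gene domains
small_planted_sim <- function(seed = 1, n_genes = 40,
                              gene_length_range = c(2500, 5000),
                              frac = 0.3, depth_c = 20, enrichment = 2,
                              chrom_length = 4e5, ...) {
  cfg <- simulation_config(chrom_length = chrom_length, n_genes = n_genes,
                           gene_length_range = gene_length_range,
                           frac_single_domains = frac, depth_c = depth_c,
                           enrichment = enrichment, seed = seed, ...)
  ann <- simulate_annotation(cfg)
  m <- simulate_contacts(ann$genes, ann$truth, cfg)
  list(cfg = cfg, genes = ann$genes, truth = ann$truth, m = m)
}

one_gene <- function(start, end, strand = "+", chrom = "chrU", id = "g1") {
  gene_model_set(gene_id = id, chrom = chrom, start = start, end = end,
                 strand = strand)
}

sorted_pairs <- function(p) {
  p <- p[order(p[, 1], p[, 2]), , drop = FALSE]
  dimnames(p) <- NULL
  p
}
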