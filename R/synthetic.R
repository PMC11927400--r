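#' Configuration for the synthetic Hi-C simulator
#'
#' The simulator draws Poisson (optionally negative-binomial) counts from a
#' multiplicative intensity model: `lambda(i, j) = depth_c * (1 + (j - i))^
#' (-decay_alpha) * f(i, j)`, where `f` multiplies `enrichment` for pairs
#' inside the target triangle of a planted single-gene domain (the same
#' geometric predicate the caller tests), multiplies the cluster enrichment
#' over the corner/stripe targets of planted multigene clusters, and divides
#' by `insulation` for pairs crossing a planted domain border within 2 kb.
#' The map is banded at `max_sep` bp from the diagonal; all of the package's
#' statistics live well inside the default band.
#'
#' @param chrom chromosome name of the simulated contig.
#' @param chrom_length contig length in bp.
#' @param resolution bin width in bp.
#' @param n_genes number of non-overlapping genes to place.
#' @param gene_length_range min/max gene length in bp (uniform draw).
#' @param intergenic_gap_range min/max intergenic gap in bp.
#' @param frac_single_domains fraction of genes carrying a planted
#'   single-gene domain.
#' @param enrichment multiplicative OE boost inside planted target
#'   triangles (>= 1).
#' @param insulation divisor applied to pairs crossing a planted domain
#'   border within 2 kb (>= 1).
#' @param decay_alpha distance-decay exponent.
#' @param depth_c expected count at one-bin separation.
#' @param seed integer seed; fixed seed gives full determinism.
#' @param max_sep band width in bp beyond which no contacts are simulated.
#' @param multigene_clusters list of `list(first =, last =, enrichment =)`
#'   describing planted clusters by gene index.
#' @param diff_spec optional data.frame `(gene_id, body_mult, surr_mult)` of
#'   multipliers applied in the treatment condition only; when set,
#'   [simulate_contacts()] returns a condition pair.
#' @param nb_size optional negative-binomial size parameter for
#'   overdispersed counts (default `NULL` = Poisson).
#' @param whole_body if `TRUE`, plant enrichment over all intra-gene /
#'   intra-cluster pairs instead of the target triangles (model-mismatch
#'   robustness mode).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(chrom = "chrS", chrom_length = 2e6,
                              resolution = 250, n_genes = 250,
                              gene_length_range = c(1000, 5000),
                              intergenic_gap_range = c(500, 2000),
                              frac_single_domains = 0.3, enrichment = 2,
                              insulation = 1.5, decay_alpha = 1,
                              depth_c = 20, seed = 1L, max_sep = 1e5,
                              multigene_clusters = NULL, diff_spec = NULL,
                              nb_size = NULL, whole_body = FALSE) {
  stopifnot(chrom_length > 0, resolution >= 1, n_genes >= 1,
            length(gene_length_range) == 2L, all(gene_length_range > 0),
            gene_length_range[1] <= gene_length_range[2],
            length(intergenic_gap_range) == 2L,
            all(intergenic_gap_range > 0),
            intergenic_gap_range[1] <= intergenic_gap_range[2],
            frac_single_domains >= 0, frac_single_domains <= 1,
            enrichment >= 1, insulation >= 1, decay_alpha > 0, depth_c > 0,
            max_sep >= resolution)
  if (n_genes * (max(gene_length_range) + max(intergenic_gap_range)) >
      chrom_length)
    stop("genes do not fit: n_genes * max(gene + gap) exceeds chrom_length; ",
         "reduce n_genes or the ranges, or enlarge the chromosome")
  structure(list(chrom = chrom, chrom_length = chrom_length,
                 resolution = as.integer(resolution),
                 n_genes = as.integer(n_genes),
                 gene_length_range = gene_length_range,
                 intergenic_gap_range = intergenic_gap_range,
                 frac_single_domains = frac_single_domains,
                 enrichment = enrichment, insulation = insulation,
                 decay_alpha = decay_alpha, depth_c = depth_c,
                 seed = as.integer(seed), max_sep = max_sep,
                 multigene_clusters = multigene_clusters,
                 diff_spec = diff_spec, nb_size = nb_size,
                 whole_body = isTRUE(whole_body)),
            class = "simulation_config")
}

#' Simulate a gene annotation with planted ground truth
#'
#' Places `n_genes` non-overlapping genes left to right with lengths and
#' gaps drawn uniformly from the configured ranges, random strands, and
#' single-domain flags drawn with probability `frac_single_domains`.
#' Deterministic under the configuration seed.
#'
#' @param cfg a `simulation_config`.
#' @return List with `genes` (a `gene_model_set`) and `truth` (a
#'   `ground_truth`: per-gene `has_single_domain`, planted cluster list,
#'   differential spec, and the planted-domain interval table used by
#'   [evaluate_calls()]).
#' @export
simulate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  n <- cfg$n_genes
  lens <- floor(stats::runif(n, cfg$gene_length_range[1],
                             cfg$gene_length_range[2] + 1))
  gaps <- floor(stats::runif(n, cfg$intergenic_gap_range[1],
                             cfg$intergenic_gap_range[2] + 1))
  strands <- sample(c("+", "-"), n, replace = TRUE)
  has_domain <- stats::runif(n) < cfg$frac_single_domains
  starts <- cumsum(gaps) + cumsum(c(0, lens[-n]))
  ends <- starts + lens - 1
  if (ends[n] > cfg$chrom_length)
    stop("placed genes exceed chrom_length; relax the ranges")
  genes <- gene_model_set(gene_id = sprintf("g%04d", seq_len(n)),
                          chrom = cfg$chrom, start = starts, end = ends,
                          strand = strands)
  clusters <- lapply(cfg$multigene_clusters, function(cl) {
    stopifnot(cl$first >= 1, cl$last <= n, cl$last - cl$first + 1 >= 2)
    list(first = cl$first, last = cl$last,
         enrichment = if (is.null(cl$enrichment)) cfg$enrichment
                      else cl$enrichment,
         gene_ids = genes$gene_id[cl$first:cl$last],
         chrom = cfg$chrom, start = genes$start[cl$first],
         end = genes$end[cl$last])
  })
  planted <- genes[has_domain, c("chrom", "start", "end"), drop = FALSE]
  rownames(planted) <- NULL
  truth <- structure(list(has_single_domain =
                            stats::setNames(has_domain, genes$gene_id),
                          clusters = clusters, diff_spec = cfg$diff_spec,
                          single_domain_intervals = planted),
                     class = "ground_truth")
  list(genes = genes, truth = truth)
}

# row indices into the banded pair enumeration for explicit (i, j) pairs
pair_index <- function(pairs, n_bins, d_max, offsets) {
  d <- pairs[, 2L] - pairs[, 1L]
  ok <- d <= d_max
  idx <- offsets[d[ok] + 1L] + pairs[ok, 1L] + 1
  idx
}

#' Simulate a contact map over an annotation
#'
#' Draws counts from the intensity model described in
#' [simulation_config()]. With a `diff_spec` in the configuration, two
#' independent condition maps are drawn (the treatment map with the per-gene
#' body/surrounding multipliers applied).
#'
#' @param genes the annotation from [simulate_annotation()].
#' @param truth its `ground_truth`.
#' @param cfg the `simulation_config`.
#' @return A raw `contact_matrix`, or `list(control =, treat =)` when
#'   `diff_spec` is set.
#' @export
simulate_contacts <- function(genes, truth, cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  n_bins <- as.integer(ceiling(cfg$chrom_length / cfg$resolution))
  d_max <- min(n_bins - 1L, as.integer(floor(cfg$max_sep / cfg$resolution)))
  nvec <- n_bins - 0:d_max
  offsets <- c(0, cumsum(nvec))
  dvec <- rep.int(0:d_max, nvec)
  ivec <- sequence(nvec) - 1L
  lambda <- cfg$depth_c * (1 + dvec)^(-cfg$decay_alpha)
  f <- rep(1, length(lambda))
  bump <- function(pairs, mult) {
    if (!length(pairs) || nrow(pairs) == 0L) return()
    idx <- pair_index(pairs, n_bins, d_max, offsets)
    f[idx] <<- f[idx] * mult
  }
  border_pairs <- function(p) {
    bins <- bins_with_midpoint_in(p - 2000, p + 2000, cfg$resolution, n_bins)
    if (!length(bins)) return(cbind(i = integer(0), j = integer(0)))
    x <- bin_midpoint(bins, cfg$resolution)
    left <- bins[x < p]; right <- bins[x > p]
    expand_pairs(left, right)
  }
  for (g in which(truth$has_single_domain)) {
    gene <- genes[g, ]
    if (cfg$whole_body) {
      bins <- bins_with_midpoint_in(gene$start, gene$end, cfg$resolution,
                                    n_bins)
      p <- expand_pairs(bins, bins)
      bump(p[p[, 1L] < p[, 2L], , drop = FALSE], cfg$enrichment)
    } else {
      reg <- single_gene_regions(gene, cfg$resolution, n_bins,
                                 min_pairs = 1L)
      if (!is.null(reg$target)) bump(reg$target$pairs, cfg$enrichment)
    }
    if (cfg$insulation > 1) {
      bump(border_pairs(gene$start - 0.5), 1 / cfg$insulation)
      bump(border_pairs(gene$end + 0.5), 1 / cfg$insulation)
    }
  }
  for (cl in truth$clusters) {
    cluster <- genes[cl$first:cl$last, , drop = FALSE]
    if (cfg$whole_body) {
      bins <- bins_with_midpoint_in(cl$start, cl$end, cfg$resolution, n_bins)
      p <- expand_pairs(bins, bins)
      bump(p[p[, 1L] < p[, 2L], , drop = FALSE], cl$enrichment)
    } else {
      mg <- multigene_regions(cluster, cfg$resolution, n_bins, min_pairs = 1L)
      seen <- NULL
      for (cmp in mg$comparisons) {
        p <- cmp$target$pairs
        key <- p[, 1L] * n_bins + p[, 2L]
        new <- !(key %in% seen)
        bump(p[new, , drop = FALSE], cl$enrichment)
        seen <- c(seen, key[new])
      }
    }
    if (cfg$insulation > 1) {
      bump(border_pairs(cl$start - 0.5), 1 / cfg$insulation)
      bump(border_pairs(cl$end + 0.5), 1 / cfg$insulation)
    }
  }
  draw <- function(intensity, seed) {
    set.seed(seed)
    counts <- if (is.null(cfg$nb_size))
      stats::rpois(length(intensity), intensity)
    else stats::rnbinom(length(intensity), size = cfg$nb_size,
                        mu = intensity)
    nz <- counts > 0L
    contact_matrix(cfg$chrom, cfg$chrom_length, cfg$resolution,
                   ivec[nz], ivec[nz] + dvec[nz], counts[nz])
  }
  if (is.null(truth$diff_spec)) return(draw(lambda * f, cfg$seed + 1L))
  fB <- f
  for (r in seq_len(nrow(truth$diff_spec))) {
    gid <- truth$diff_spec$gene_id[r]
    gene <- genes[genes$gene_id == gid, , drop = FALSE]
    if (nrow(gene) != 1L) stop("diff_spec gene not in annotation: ", gid)
    dr <- diff_regions(gene, flank = 2000, resolution = cfg$resolution,
                       n_bins = n_bins)
    idx_b <- pair_index(dr$gene_body$pairs, n_bins, d_max, offsets)
    idx_s <- pair_index(dr$surrounding$pairs, n_bins, d_max, offsets)
    fB[idx_b] <- fB[idx_b] * truth$diff_spec$body_mult[r]
    fB[idx_s] <- fB[idx_s] * truth$diff_spec$surr_mult[r]
  }
  list(control = draw(lambda * f, cfg$seed + 1L),
       treat = draw(lambda * fB, cfg$seed + 2L))
}

#' Compare domain calls against planted ground truth
#'
#' A planted domain is recovered when a positive call matches it on the same
#' chromosome with both boundaries within `tol_bins` bins (one-to-one,
#' greedy by boundary distance).
#'
#' @param calls calls data.frame (rows filtered to positive calls via their
#'   `is_domain`/`passes` column) or a plain interval data.frame.
#' @param truth_intervals data.frame of planted `chrom`, `start`, `end`.
#' @param tol_bins boundary tolerance in bins.
#' @param resolution bin width in bp.
#' @return List with `sensitivity`, `precision`,
#'   `false_discovery_proportion`, `n_matched`, `n_truth`, `n_called`.
#' @export
evaluate_calls <- function(calls, truth_intervals, tol_bins = 1L,
                           resolution) {
  A <- domain_intervals(calls)
  B <- truth_intervals[, c("chrom", "start", "end"), drop = FALSE]
  tol <- tol_bins * resolution
  matches <- 0L
  if (nrow(A) && nrow(B)) {
    cand <- expand.grid(a = seq_len(nrow(A)), b = seq_len(nrow(B)))
    ds <- abs(A$start[cand$a] - B$start[cand$b])
    de <- abs(A$end[cand$a] - B$end[cand$b])
    ok <- A$chrom[cand$a] == B$chrom[cand$b] & ds <= tol & de <= tol
    cand <- cand[ok, , drop = FALSE]
    o <- order((ds + de)[ok], cand$a, cand$b)
    used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
    for (r in o) {
      if (!used_a[cand$a[r]] && !used_b[cand$b[r]]) {
        used_a[cand$a[r]] <- TRUE; used_b[cand$b[r]] <- TRUE
        matches <- matches + 1L
      }
    }
  }
  sensitivity <- if (nrow(B) == 0L) 1 else matches / nrow(B)
  precision <- if (nrow(A) == 0L) 1 else matches / nrow(A)
  list(sensitivity = sensitivity, precision = precision,
       false_discovery_proportion = 1 - precision,
       n_matched = matches, n_truth = nrow(B), n_called = nrow(A))
}

#' Write planted ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(
    list(has_single_domain = as.list(truth$has_single_domain),
         clusters = truth$clusters,
         single_domain_intervals = truth$single_domain_intervals),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
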