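#' Bin-pair regions
#'
#' A `bin_pair_region` is an explicit set of upper-triangular bin pairs
#' `(i, j)`, `i <= j`, on a contact map, with a label describing its role.
#' Bin membership along the genome is decided by bin midpoints, giving
#' symmetric, deterministic rounding at gene borders.
#'
#' @param label region role, e.g. `"target"` or `"control_left"`.
#' @param i,j 0-based bin indices, `i <= j` pairwise.
#' @return A `bin_pair_region`: list with `label`, `pairs` (2-column integer
#'   matrix in row-major order) and `separations` (`j - i` per pair).
#' @export
bin_pair_region <- function(label, i, j) {
  i <- as.integer(i); j <- as.integer(j)
  stopifnot(length(i) == length(j))
  if (length(i) && any(i > j)) stop("bin_pair_region requires i <= j")
  o <- order(i, j)
  p <- cbind(i = i[o], j = j[o])
  structure(list(label = label, pairs = p, separations = p[, 2L] - p[, 1L]),
            class = "bin_pair_region")
}

#' @exportS3Method base::print
print.bin_pair_region <- function(x, ...) {
  cat(sprintf("bin_pair_region '%s': %d pairs, separations %s\n", x$label,
              nrow(x$pairs),
              if (nrow(x$pairs)) paste0(min(x$separations), "-",
                                        max(x$separations)) else "-"))
  invisible(x)
}

# midpoint (in bp, 1-based genome) of 0-based bin i
bin_midpoint <- function(i, resolution) i * resolution + (resolution + 1) / 2

# 0-based bins whose midpoints fall in [lo, hi]
bins_with_midpoint_in <- function(lo, hi, resolution, n_bins) {
  half <- (resolution + 1) / 2
  i_lo <- max(0L, as.integer(ceiling((lo - half) / resolution)))
  i_hi <- min(n_bins - 1L, as.integer(floor((hi - half) / resolution)))
  if (i_lo > i_hi) integer(0) else i_lo:i_hi
}

translate_clip <- function(region, shift, n_bins, label) {
  p <- region$pairs
  i <- p[, 1L] + shift; j <- p[, 2L] + shift
  keep <- i >= 0L & j < n_bins
  bin_pair_region(label, i[keep], j[keep])
}

#' Target and control regions for single-gene domain testing
#'
#' For a gene spanning `[a, b]` (length `L = b - a + 1`), the target region
#' is the triangle of bin pairs hanging from the gene-border anchor: all
#' pairs whose bin midpoints both lie inside the gene and are at least `L/2`
#' apart, i.e. the intragenic region of height half the gene length nearest
#' the TSS-TES corner. The two controls are the same pair set translated by
#' `-ceiling(L/2)` and `+ceiling(L/2)` bp along the genome, so each control
#' is equidistant from the diagonal (identical separation multiset before
#' chromosome-edge clipping) and straddles a gene border with one anchor
#' inside and one outside the gene body.
#'
#' @param gene one-row `gene_model_set` (or list with `start`, `end`).
#' @param resolution bin width in bp.
#' @param n_bins number of bins on the chromosome.
#' @param min_pairs minimum pairs each region must retain after clipping.
#' @param min_gene_bins genes spanning fewer bins are untestable.
#' @return List with elements `target`, `control_left`, `control_right`
#'   (`bin_pair_region`s), `shift_bins`, and `untestable` (logical with a
#'   `reason` when `TRUE`).
#' @export
single_gene_regions <- function(gene, resolution, n_bins, min_pairs = 3L,
                                min_gene_bins = 2L) {
  a <- gene$start[1L]; b <- gene$end[1L]
  L <- b - a + 1
  gb <- gene_bins(data.frame(start = a, end = b), resolution)
  if (gb[1L, 2L] - gb[1L, 1L] + 1L < min_gene_bins)
    return(list(untestable = TRUE, reason = "gene spans too few bins"))
  bins <- bins_with_midpoint_in(a, b, resolution, n_bins)
  min_sep <- as.integer(ceiling(L / (2 * resolution)))
  pairs <- expand_pairs(bins, bins)
  sel <- pairs[, 2L] - pairs[, 1L] >= min_sep & pairs[, 1L] < pairs[, 2L]
  target <- bin_pair_region("target", pairs[sel, 1L], pairs[sel, 2L])
  shift <- as.integer(round(ceiling(L / 2) / resolution))
  cl <- translate_clip(target, -shift, n_bins, "control_left")
  cr <- translate_clip(target, +shift, n_bins, "control_right")
  out <- list(target = target, control_left = cl, control_right = cr,
              shift_bins = shift, untestable = FALSE)
  if (nrow(target$pairs) < min_pairs || nrow(cl$pairs) < min_pairs ||
      nrow(cr$pairs) < min_pairs) {
    out$untestable <- TRUE
    out$reason <- "fewer than min_pairs pairs after clipping"
  }
  out
}

# all (i, j) combinations of two bin vectors, i < j not enforced
expand_pairs <- function(bi, bj) {
  if (!length(bi) || !length(bj))
    return(cbind(i = integer(0), j = integer(0)))
  cbind(i = rep(bi, times = length(bj)), j = rep(bj, each = length(bi)))
}

cross_region <- function(label, bi, bj) {
  p <- expand_pairs(bi, bj)
  sel <- p[, 1L] < p[, 2L]
  bin_pair_region(label, p[sel, 1L], p[sel, 2L])
}

#' Target and control regions for multigene domain testing
#'
#' For an ordered run of `k >= 2` adjacent genes the candidate domain spans
#' the outer borders of the first and last gene. Two kinds of comparisons are
#' emitted: (i) the boundary-to-boundary corner, `B_L x B_R`, the block of
#' pairs connecting the bins of the first gene with those of the last; and
#' (ii) for `k >= 3`, the two boundary stripes `B_L x D` (first gene against
#' the rest of the domain) and `D' x B_R` (the domain against the last
#' gene). Each target's controls are the target translated along the genome
#' by the width of the boundary block on either side, preserving
#' distance-from-diagonal. For `k = 2` the stripes coincide with the corner
#' and only comparison (i) is emitted.
#'
#' @param cluster `gene_model_set` rows of the adjacent genes, in genomic
#'   order.
#' @param resolution bin width in bp.
#' @param n_bins number of bins on the chromosome.
#' @param min_pairs minimum pairs per region.
#' @return List with `comparisons` (each a list with `label`, `target`,
#'   `controls`), `start`, `end`, `k` and `untestable`.
#' @export
multigene_regions <- function(cluster, resolution, n_bins, min_pairs = 3L) {
  k <- nrow(cluster)
  if (k < 2L) stop("a multigene cluster needs at least 2 genes")
  if (is.unsorted(cluster$start) || length(unique(cluster$chrom)) != 1L)
    stop("cluster genes must be adjacent and in genomic order on one chromosome")
  gb <- gene_bins(cluster, resolution)
  B_L <- gb[1L, 1L]:gb[1L, 2L]
  B_R <- gb[k, 1L]:gb[k, 2L]
  D <- gb[2L, 1L]:gb[k, 2L]          # rest of the domain, left border removed
  Dp <- gb[1L, 1L]:gb[k - 1L, 2L]    # domain without its right border gene
  wL <- length(B_L); wR <- length(B_R)
  make_cmp <- function(label, bi, bj, w_left, w_right) {
    target <- cross_region(label, bi, bj)
    list(label = label, target = target,
         controls = list(
           translate_clip(target, -w_left, n_bins,
                          paste0(label, "_control_left")),
           translate_clip(target, +w_right, n_bins,
                          paste0(label, "_control_right"))))
  }
  comparisons <- list(make_cmp("corner", B_L, B_R, wL, wR))
  if (k >= 3L) {
    comparisons <- c(comparisons,
                     list(make_cmp("stripe_left", B_L, D, wL, wL)),
                     list(make_cmp("stripe_right", Dp, B_R, wR, wR)))
  }
  untestable <- any(vapply(comparisons, function(cmp) {
    nrow(cmp$target$pairs) < min_pairs ||
      any(vapply(cmp$controls, function(ct) nrow(ct$pairs) < min_pairs,
                 logical(1)))
  }, logical(1)))
  list(comparisons = comparisons, start = cluster$start[1L],
       end = cluster$end[k], k = k, untestable = untestable)
}

#' Gene-body and surrounding regions for differential analysis
#'
#' The gene body region contains every pair with both bin midpoints inside
#' the gene; the surrounding region contains every pair bridging the gene
#' body and its immediate flanks (exactly one midpoint inside the gene, the
#' other within `flank` bp upstream or downstream). The two sets are
#' disjoint by construction.
#'
#' @param gene one-row `gene_model_set`.
#' @param flank flank width in bp (default 2 kb).
#' @param resolution bin width in bp.
#' @param n_bins number of bins on the chromosome.
#' @return List with `gene_body` and `surrounding` `bin_pair_region`s.
#' @export
diff_regions <- function(gene, flank = 2000, resolution, n_bins) {
  a <- gene$start[1L]; b <- gene$end[1L]
  bins <- bins_with_midpoint_in(a - flank, b + flank, resolution, n_bins)
  x <- bin_midpoint(bins, resolution)
  in_body <- x >= a & x <= b
  in_flank <- (x >= a - flank & x < a) | (x > b & x <= b + flank)
  p <- expand_pairs(bins, bins)
  ib <- rep(in_body, times = length(bins)); jb <- rep(in_body, each = length(bins))
  if_ <- rep(in_flank, times = length(bins)); jf <- rep(in_flank, each = length(bins))
  lt <- p[, 1L] < p[, 2L]
  body_sel <- lt & ib & jb
  surr_sel <- lt & ((ib & jf) | (if_ & jb))
  list(gene_body = bin_pair_region("gene_body", p[body_sel, 1L], p[body_sel, 2L]),
       surrounding = bin_pair_region("surrounding", p[surr_sel, 1L],
                                     p[surr_sel, 2L]))
}
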