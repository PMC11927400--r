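#' One-sided Mann-Whitney U test (x stochastically greater than y)
#'
#' Tie-corrected normal approximation with continuity correction, via
#' [stats::wilcox.test()]. Samples smaller than 3 on either side are
#' untestable and yield `NA`.
#'
#' @param x,y numeric samples.
#' @return One-sided p-value, or `NA_real_` when untestable.
#' @export
mannwhitney_greater <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) return(NA_real_)
  if (stats::var(c(x, y)) == 0) return(1)   # fully tied: no evidence
  suppressWarnings(stats::wilcox.test(x, y, alternative = "greater",
                                      exact = FALSE, correct = TRUE))$p.value
}

#' Two-sided Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped (Wilcoxon convention); the tie-corrected
#' normal approximation with continuity correction is used. Fewer than 5
#' nonzero differences is untestable (`NA`).
#'
#' @param diffs paired differences.
#' @return Two-sided p-value, or `NA_real_` when untestable.
#' @export
wilcoxon_signed_rank <- function(diffs) {
  nz <- diffs[diffs != 0 & !is.na(diffs)]
  if (length(nz) < 5L) return(NA_real_)
  suppressWarnings(stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                                      exact = FALSE, correct = TRUE))$p.value
}

#' Benjamini-Hochberg adjustment over the testable family
#'
#' `NA` entries (untestable records) are excluded from the family size and
#' returned as `NA`.
#'
#' @param pvals p-values, possibly containing `NA`.
#' @return Q-values in input order.
#' @export
bh_adjust <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  if (any(ok)) q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

#' Call single-gene contact domains
#'
#' For every testable gene the distance-normalized (OE) contact frequencies
#' of the intragenic target triangle are compared against each of the two
#' diagonal-equidistant controls with one-sided Mann-Whitney U tests. The
#' combined p-value is the maximum of the two (intersection-union: the gene
#' must beat both controls); Q-values are Benjamini-Hochberg adjusted across
#' all testable genes, and a gene is a single-gene domain when `q < q_cutoff`.
#'
#' @param m a normalized `contact_matrix`.
#' @param genes `gene_model_set`; genes on other chromosomes are ignored.
#' @param e optional precomputed `expected_profile` of `m`.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param min_pairs minimum OE samples per region (default 3).
#' @return A data.frame of class `single_domain_calls`: one row per gene on
#'   the chromosome with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `status` (`"tested"`/`"untestable"`), `n_target`,
#'   `mean_oe_target`, `mean_oe_control_left`, `mean_oe_control_right`,
#'   `p_value`, `q_value`, `is_domain`.
#' @export
call_single_domains <- function(m, genes, e = NULL, q_cutoff = 0.05,
                                min_pairs = 3L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization == "raw")
    stop("matrix must be normalized (balance_matrix) before calling")
  if (is.null(e)) e <- expected_profile(m)
  genes <- genes[genes$chrom == m$chrom, , drop = FALSE]
  n <- nrow(genes)
  res <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    strand = genes$strand,
                    status = rep("untestable", n), n_target = NA_integer_,
                    mean_oe_target = NA_real_, mean_oe_control_left = NA_real_,
                    mean_oe_control_right = NA_real_, p_value = NA_real_,
                    q_value = NA_real_, is_domain = FALSE,
                    stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    reg <- single_gene_regions(genes[g, ], m$resolution, m$n_bins,
                               min_pairs = min_pairs)
    if (reg$untestable) next
    oe_t <- oe_values(m, e, reg$target)
    oe_l <- oe_values(m, e, reg$control_left)
    oe_r <- oe_values(m, e, reg$control_right)
    if (length(oe_t) < min_pairs || length(oe_l) < min_pairs ||
        length(oe_r) < min_pairs) next
    p_l <- mannwhitney_greater(oe_t, oe_l)
    p_r <- mannwhitney_greater(oe_t, oe_r)
    if (is.na(p_l) || is.na(p_r)) next
    res$status[g] <- "tested"
    res$n_target[g] <- length(oe_t)
    res$mean_oe_target[g] <- mean(oe_t)
    res$mean_oe_control_left[g] <- mean(oe_l)
    res$mean_oe_control_right[g] <- mean(oe_r)
    res$p_value[g] <- max(p_l, p_r)
  }
  if (!any(res$status == "tested"))
    warning("no testable genes on ", m$chrom)
  res$q_value <- bh_adjust(res$p_value)
  res$is_domain <- !is.na(res$q_value) & res$q_value < q_cutoff
  class(res) <- c("single_domain_calls", "data.frame")
  res
}

#' Call multigene contact domains
#'
#' Every window of `k = 2..max_genes` adjacent genes is a candidate domain.
#' For each comparison emitted by [multigene_regions()] the p-value is the
#' maximum over its two controls of the one-sided Mann-Whitney U test; the
#' cluster p-value is the maximum over comparisons (the domain must beat all
#' its controls). Q-values are BH-adjusted across all tested windows;
#' nested and overlapping passing windows are all retained.
#'
#' @param m a normalized `contact_matrix`.
#' @param genes `gene_model_set` sorted by position.
#' @param e optional precomputed `expected_profile`.
#' @param q_cutoff FDR cutoff.
#' @param max_genes maximum cluster size (default 10).
#' @param min_pairs minimum OE samples per region.
#' @return A data.frame of class `multi_domain_calls` with one row per
#'   candidate window: `gene_ids` (comma-separated), `chrom`, `start`,
#'   `end`, `k`, `status`, `p_value`, `q_value`, `is_domain`.
#' @export
call_multi_domains <- function(m, genes, e = NULL, q_cutoff = 0.05,
                               max_genes = 10L, min_pairs = 3L) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization == "raw")
    stop("matrix must be normalized (balance_matrix) before calling")
  if (is.null(e)) e <- expected_profile(m)
  genes <- genes[genes$chrom == m$chrom, , drop = FALSE]
  genes <- genes[order(genes$start, genes$end), , drop = FALSE]
  ng <- nrow(genes)
  rows <- list()
  for (s in seq_len(max(ng - 1L, 0L))) {
    for (k in 2L:min(max_genes, ng - s + 1L)) {
      cluster <- genes[s:(s + k - 1L), , drop = FALSE]
      reg <- multigene_regions(cluster, m$resolution, m$n_bins,
                               min_pairs = min_pairs)
      rec <- list(gene_ids = paste(cluster$gene_id, collapse = ","),
                  chrom = m$chrom, start = reg$start, end = reg$end, k = k,
                  status = "untestable", p_value = NA_real_)
      if (!reg$untestable) {
        p_cluster <- 0
        for (cmp in reg$comparisons) {
          oe_t <- oe_values(m, e, cmp$target)
          if (length(oe_t) < min_pairs) { p_cluster <- NA_real_; break }
          for (ctrl in cmp$controls) {
            oe_c <- oe_values(m, e, ctrl)
            if (length(oe_c) < min_pairs) { p_cluster <- NA_real_; break }
            p <- mannwhitney_greater(oe_t, oe_c)
            p_cluster <- max(p_cluster, p)
          }
          if (is.na(p_cluster)) break
        }
        if (!is.na(p_cluster)) {
          rec$status <- "tested"
          rec$p_value <- p_cluster
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (is.null(res))
    res <- data.frame(gene_ids = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0), k = integer(0),
                      status = character(0), p_value = numeric(0))
  res$q_value <- bh_adjust(res$p_value)
  res$is_domain <- !is.na(res$q_value) & res$q_value < q_cutoff
  class(res) <- c("multi_domain_calls", "data.frame")
  res
}

#' Direction of a differential-insulation record
#'
#' Applies the Q-value and mean fold-change filters that classify a gene as
#' differentially insulated. With body ratio `r_body = body OE(control) /
#' body OE(treat)` and surrounding ratio `r_surr = surrounding OE(treat) /
#' surrounding OE(control)`, insulation is enhanced in the treatment when
#' `q < q_cutoff`, `r_body < 1 - fc_cutoff` and `r_surr < 1 - fc_cutoff`
#' (contacts up inside the gene body, down across its borders); enhanced in
#' the control under the reciprocal ratio conditions.
#'
#' @param q BH-adjusted p-value of the surrounding-region test.
#' @param r_body,r_surr fold-change ratios as defined above.
#' @param q_cutoff FDR cutoff (default 0.05).
#' @param fc_cutoff mean fold-change cutoff (default 0.1).
#' @return `"enhanced_in_treat"`, `"enhanced_in_control"` or `"none"`.
#' @export
diff_direction <- function(q, r_body, r_surr, q_cutoff = 0.05,
                           fc_cutoff = 0.1) {
  if (is.na(q) || !is.finite(r_body) || !is.finite(r_surr) ||
      r_body <= 0 || r_surr <= 0 || q >= q_cutoff) return("none")
  thr <- 1 - fc_cutoff
  if (r_body < thr && r_surr < thr) return("enhanced_in_treat")
  if (1 / r_body < thr && 1 / r_surr < thr) return("enhanced_in_control")
  "none"
}

#' Call differentially insulated genes between two conditions
#'
#' Pairs the surrounding-region OE values of each gene by identical bin pair
#' across the two matrices, tests the paired differences with a two-sided
#' Wilcoxon signed-rank test, BH-adjusts over testable genes, and applies
#' the mean fold-change filters of [diff_direction()] to the gene-body and
#' surrounding region means.
#'
#' @param m_control,m_treat raw-free (normalized) `contact_matrix` objects on
#'   the same chromosome at the same resolution; expected profiles are
#'   computed per matrix independently.
#' @param genes `gene_model_set`.
#' @param q_cutoff FDR cutoff.
#' @param fc_cutoff mean fold-change cutoff (default 0.1).
#' @param flank surrounding flank width in bp (default 2 kb).
#' @return A data.frame of class `diff_domain_calls` with per-gene columns
#'   `gene_id`, `chrom`, `start`, `end`, `strand`, `status`,
#'   `body_oe_control`, `body_oe_treat`, `surr_oe_control`, `surr_oe_treat`,
#'   `wilcoxon_p`, `q_value`, `r_body`, `r_surr`, `direction`, `passes`.
#' @export
call_diff_domains <- function(m_control, m_treat, genes, q_cutoff = 0.05,
                              fc_cutoff = 0.1, flank = 2000) {
  stopifnot(inherits(m_control, "contact_matrix"),
            inherits(m_treat, "contact_matrix"))
  if (m_control$resolution != m_treat$resolution ||
      m_control$n_bins != m_treat$n_bins ||
      m_control$chrom != m_treat$chrom)
    stop("the two matrices must share chromosome, length and resolution")
  if (m_control$normalization == "raw" || m_treat$normalization == "raw")
    stop("both matrices must be normalized before calling")
  eA <- expected_profile(m_control)
  eB <- expected_profile(m_treat)
  genes <- genes[genes$chrom == m_control$chrom, , drop = FALSE]
  n <- nrow(genes)
  both_unmasked <- function(region) {
    p <- region$pairs
    keep <- !m_control$mask[p[, 1L] + 1L] & !m_control$mask[p[, 2L] + 1L] &
      !m_treat$mask[p[, 1L] + 1L] & !m_treat$mask[p[, 2L] + 1L]
    bin_pair_region(region$label, p[keep, 1L], p[keep, 2L])
  }
  res <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = genes$start, end = genes$end,
                    strand = genes$strand, status = rep("untestable", n),
                    body_oe_control = NA_real_, body_oe_treat = NA_real_,
                    surr_oe_control = NA_real_, surr_oe_treat = NA_real_,
                    wilcoxon_p = NA_real_, q_value = NA_real_,
                    r_body = NA_real_, r_surr = NA_real_,
                    direction = "none", passes = FALSE,
                    stringsAsFactors = FALSE)
  for (g in seq_len(n)) {
    dr <- diff_regions(genes[g, ], flank = flank,
                       resolution = m_control$resolution,
                       n_bins = m_control$n_bins)
    body <- both_unmasked(dr$gene_body)
    surr <- both_unmasked(dr$surrounding)
    if (nrow(surr$pairs) == 0L || nrow(body$pairs) == 0L) next
    sA <- oe_values(m_control, eA, surr)
    sB <- oe_values(m_treat, eB, surr)
    bA <- oe_values(m_control, eA, body)
    bB <- oe_values(m_treat, eB, body)
    p <- wilcoxon_signed_rank(sB - sA)
    if (is.na(p)) next
    res$status[g] <- "tested"
    res$wilcoxon_p[g] <- p
    res$body_oe_control[g] <- mean(bA)
    res$body_oe_treat[g] <- mean(bB)
    res$surr_oe_control[g] <- mean(sA)
    res$surr_oe_treat[g] <- mean(sB)
    res$r_body[g] <- res$body_oe_control[g] / res$body_oe_treat[g]
    res$r_surr[g] <- res$surr_oe_treat[g] / res$surr_oe_control[g]
  }
  res$q_value <- bh_adjust(res$wilcoxon_p)
  for (g in which(res$status == "tested")) {
    res$direction[g] <- diff_direction(res$q_value[g], res$r_body[g],
                                       res$r_surr[g], q_cutoff, fc_cutoff)
  }
  res$passes <- res$direction != "none"
  class(res) <- c("diff_domain_calls", "data.frame")
  res
}

#' Write domain calls as BED6
#'
#' Scores are `min(1000, round(-10 * log10(q)))`; untestable records are
#' omitted.
#'
#' @param calls a calls data.frame with `chrom`, `start`, `end`, `q_value`
#'   and either `gene_id` or `gene_ids`.
#' @param path output file.
#' @param only_domains write only rows with `is_domain`/`passes` set.
#' @return `path`, invisibly.
#' @export
write_calls_bed <- function(calls, path, only_domains = TRUE) {
  qcol <- if ("q_value" %in% names(calls)) calls$q_value else NA_real_
  keep <- !is.na(qcol)
  if (only_domains) {
    flag <- if ("is_domain" %in% names(calls)) calls$is_domain else calls$passes
    keep <- keep & flag
  }
  d <- calls[keep, , drop = FALSE]
  name <- if ("gene_ids" %in% names(d)) d$gene_ids else d$gene_id
  strand <- if ("strand" %in% names(d)) d$strand else rep(".", nrow(d))
  score <- pmin(1000, round(-10 * log10(pmax(d$q_value, 1e-100))))
  utils::write.table(
    data.frame(d$chrom, format(d$start - 1, scientific = FALSE, trim = TRUE),
               format(d$end, scientific = FALSE, trim = TRUE),
               name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write domain calls with all statistics as TSV
#'
#' @param calls a calls data.frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_calls_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
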