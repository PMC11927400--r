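# dense symmetric OE block over 0-based bins lo..hi; masked bins -> NA
dense_oe_block <- function(m, e, lo, hi) {
  idx <- (lo:hi) + 1L
  sub <- as.matrix(m$mat[idx, idx, drop = FALSE])
  sym <- sub + t(sub) - diag(diag(sub), nrow = nrow(sub))
  d <- abs(outer(lo:hi, lo:hi, "-"))
  oe <- sym / e$expected[d + 1L]
  bad <- m$mask[idx]
  oe[bad, ] <- NA_real_
  oe[, bad] <- NA_real_
  oe
}

# separable cubic-convolution (Keys, a = -0.5) resampling weights:
# rows are renormalized so constant fields are preserved exactly
cubic_weights <- function(n_src, n_out) {
  a <- -0.5
  kern <- function(s) {
    s <- abs(s)
    ifelse(s <= 1, (a + 2) * s^3 - (a + 3) * s^2 + 1,
           ifelse(s < 2, a * s^3 - 5 * a * s^2 + 8 * a * s - 4 * a, 0))
  }
  W <- matrix(0, n_out, n_src)
  for (k in seq_len(n_out)) {
    u <- (k - 0.5) * n_src / n_out - 0.5     # 0-based source coordinate
    base <- floor(u)
    taps <- base + (-1:2)
    w <- kern(u - taps)
    taps <- pmin(pmax(taps, 0), n_src - 1)   # clamp at the edges
    for (t in seq_along(taps)) W[k, taps[t] + 1] <- W[k, taps[t] + 1] + w[t]
  }
  W / rowSums(W)
}

resize_bicubic <- function(mat, out_size) {
  Wr <- cubic_weights(nrow(mat), out_size)
  Wc <- cubic_weights(ncol(mat), out_size)
  Wr %*% mat %*% t(Wc)
}

#' Aggregate pile-up of rescaled domain windows
#'
#' For every domain the square OE window covering the domain plus flanks of
#' `flank_frac` times its length is extracted, expanded onto a `fine_bin`-bp
#' grid by nearest-neighbour replication of the native-resolution OE values,
#' resized to `out_size x out_size` by bicubic interpolation, flipped on
#' both axes for minus-strand domains to synchronize gene orientation, and
#' averaged element-wise across domains.
#'
#' @param m a normalized `contact_matrix`.
#' @param e its `expected_profile`.
#' @param domains data.frame with `chrom`, `start`, `end` and optional
#'   `strand` columns.
#' @param flank_frac flank size as a fraction of domain length (default 0.5).
#' @param fine_bin fine grid step in bp (default 10).
#' @param out_size side length of the output matrix (default 80).
#' @return A `pileup_result`: list with `matrix` (`out_size` square),
#'   `n_domains` aggregated and `flank_frac`. Domains whose window leaves
#'   the chromosome or touches masked bins are skipped with a warning.
#' @export
pileup <- function(m, e, domains, flank_frac = 0.5, fine_bin = 10,
                   out_size = 80) {
  stopifnot(nrow(domains) >= 1L)
  strand <- if ("strand" %in% names(domains)) domains$strand
            else rep("+", nrow(domains))
  acc <- matrix(0, out_size, out_size)
  n_used <- 0L
  skipped <- 0L
  for (d in seq_len(nrow(domains))) {
    len <- domains$end[d] - domains$start[d] + 1
    flank <- round(flank_frac * len)
    wstart <- domains$start[d] - flank
    wend <- domains$end[d] + flank
    if (wstart < 1 || wend > m$chrom_length) { skipped <- skipped + 1L; next }
    lo <- floor((wstart - 1) / m$resolution)
    hi <- floor((wend - 1) / m$resolution)
    block <- dense_oe_block(m, e, lo, hi)
    if (anyNA(block)) { skipped <- skipped + 1L; next }
    ncell <- as.integer(ceiling((wend - wstart + 1) / fine_bin))
    pos <- pmin(wstart + (seq_len(ncell) - 0.5) * fine_bin, wend)
    native <- floor((pos - 1) / m$resolution) - lo + 1L
    fine <- block[native, native, drop = FALSE]
    img <- resize_bicubic(fine, out_size)
    if (strand[d] == "-") img <- img[out_size:1, out_size:1]
    acc <- acc + img
    n_used <- n_used + 1L
  }
  if (skipped) warning(skipped, " domain(s) skipped (window out of bounds ",
                       "or overlapping masked bins)")
  if (n_used == 0L) stop("no usable domains for pile-up")
  structure(list(matrix = acc / n_used, n_domains = n_used,
                 flank_frac = flank_frac),
            class = "pileup_result")
}

#' Write a pile-up matrix as TSV
#'
#' @param p a `pileup_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(p, path) {
  utils::write.table(p$matrix, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Directionality index track
#'
#' For each bin the upstream sum `A` (contacts between the bin and the `w`
#' preceding bins) and downstream sum `B` (the `w` following bins) are
#' compared with the chi-square-like score
#' `DI = sign(B - A) * ((A - E)^2/E + (B - E)^2/E)`, `E = (A + B)/2`. The
#' sign flips at domain boundaries. Bins whose window is truncated by a
#' chromosome end, masked bins, and bins with `E = 0` get `NA`.
#'
#' @param m a normalized `contact_matrix`.
#' @param window window size in bp (default 5 kb).
#' @return data.frame with columns `bin` (0-based), `a_sum`, `b_sum`,
#'   `e_mid` and `di`.
#' @export
di_track <- function(m, window = 5000) {
  stopifnot(inherits(m, "contact_matrix"), window >= m$resolution)
  w <- as.integer(floor(window / m$resolution))
  n <- m$n_bins
  rec <- contact_records(m)
  s <- rec$j - rec$i
  sel <- s >= 1L & s <= w
  A <- numeric(n); B <- numeric(n)
  if (any(sel)) {
    ta <- rowsum(rec$count[sel], rec$j[sel])
    A[as.integer(rownames(ta)) + 1L] <- ta
    tb <- rowsum(rec$count[sel], rec$i[sel])
    B[as.integer(rownames(tb)) + 1L] <- tb
  }
  E <- (A + B) / 2
  di <- sign(B - A) * ((A - E)^2 / E + (B - E)^2 / E)
  bins <- 0:(n - 1L)
  invalid <- bins - w < 0L | bins + w > n - 1L | m$mask | E == 0
  di[invalid] <- NA_real_
  data.frame(bin = bins, a_sum = A, b_sum = B, e_mid = E, di = di)
}

#' Compartment eigenvector track
#'
#' Computes the Pearson correlation matrix of the dense OE map over unmasked
#' bins and returns the eigenvector of the largest-magnitude eigenvalue,
#' unit-normalized. When gene models are supplied the sign is oriented so
#' that bins overlapping transcription start sites have positive mean
#' (positive values are conventionally the active A compartment); otherwise
#' the sign is as computed, with a warning.
#'
#' @param m a normalized `contact_matrix` with at least 10 unmasked bins.
#' @param e its `expected_profile`.
#' @param genes optional `gene_model_set` used to orient the sign.
#' @return data.frame with columns `bin` (0-based, unmasked informative bins
#'   only) and `value`.
#' @export
compartment_track <- function(m, e = NULL, genes = NULL) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization == "raw")
    stop("matrix must be normalized before compartment analysis")
  if (sum(!m$mask) < 10L)
    stop("need at least 10 unmasked bins for compartment analysis")
  if (is.null(e)) e <- expected_profile(m)
  keep <- which(!m$mask)
  oe <- dense_oe_block(m, e, 0L, m$n_bins - 1L)[keep, keep, drop = FALSE]
  sdv <- apply(oe, 2L, stats::sd)
  informative <- sdv > 0
  if (!all(informative)) {
    warning(sum(!informative), " constant bin(s) dropped from correlation")
    keep <- keep[informative]
    oe <- oe[informative, informative, drop = FALSE]
  }
  if (length(keep) < 10L) stop("eigendecomposition degenerate")
  C <- stats::cor(oe)
  if (any(!is.finite(C))) stop("eigendecomposition degenerate")
  eig <- eigen(C, symmetric = TRUE)
  v <- eig$vectors[, which.max(abs(eig$values))]
  v <- v / sqrt(sum(v^2))
  oriented <- FALSE
  if (!is.null(genes)) {
    tss <- gene_tss(genes[genes$chrom == m$chrom, , drop = FALSE])
    tss_bins <- unique(floor((tss - 1) / m$resolution))
    hit <- match(tss_bins, keep - 1L)
    hit <- hit[!is.na(hit)]
    if (length(hit) && mean(v[hit]) != 0) {
      if (mean(v[hit]) < 0) v <- -v
      oriented <- TRUE
    }
  }
  if (!oriented)
    warning("compartment eigenvector sign not oriented (no usable gene starts)")
  data.frame(bin = keep - 1L, value = v)
}

#' Write a per-bin track as bedGraph
#'
#' @param track data.frame with `bin` and a value column (`value` or `di`).
#' @param m the `contact_matrix` the track was computed from.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_track_bedgraph <- function(track, m, path) {
  val <- if ("value" %in% names(track)) track$value else track$di
  keep <- !is.na(val)
  start <- track$bin[keep] * m$resolution
  end <- pmin(start + m$resolution, m$chrom_length)
  utils::write.table(
    data.frame(m$chrom, format(start, scientific = FALSE, trim = TRUE),
               format(end, scientific = FALSE, trim = TRUE), val[keep]),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Jaccard index between two domain call sets
#'
#' A call in one set matches a call in the other when they lie on the same
#' chromosome and both boundaries agree within `tol_bins` bins; one-to-one
#' matching is resolved greedily by total boundary distance. The index is
#' `|matches| / (|A| + |B| - |matches|)`.
#'
#' @param calls_a,calls_b data.frames with `chrom`, `start`, `end` (rows
#'   with an `is_domain`/`passes` column are filtered to the positive ones).
#' @param tol_bins boundary tolerance in bins (default 1).
#' @param resolution bin width in bp used to express the tolerance.
#' @return Jaccard index in [0, 1]; both sets empty yields 1 with a warning.
#' @export
jaccard_index <- function(calls_a, calls_b, tol_bins = 1L, resolution) {
  A <- domain_intervals(calls_a)
  B <- domain_intervals(calls_b)
  if (nrow(A) == 0L && nrow(B) == 0L) {
    warning("both call sets empty; Jaccard defined as 1")
    return(1)
  }
  if (nrow(A) == 0L || nrow(B) == 0L) return(0)
  tol <- tol_bins * resolution
  cand <- expand.grid(a = seq_len(nrow(A)), b = seq_len(nrow(B)))
  ds <- abs(A$start[cand$a] - B$start[cand$b])
  de <- abs(A$end[cand$a] - B$end[cand$b])
  ok <- A$chrom[cand$a] == B$chrom[cand$b] & ds <= tol & de <= tol
  cand <- cand[ok, , drop = FALSE]
  cost <- (ds + de)[ok]
  o <- order(cost, cand$a, cand$b)
  used_a <- logical(nrow(A)); used_b <- logical(nrow(B))
  matches <- 0L
  for (r in o) {
    ai <- cand$a[r]; bi <- cand$b[r]
    if (!used_a[ai] && !used_b[bi]) {
      used_a[ai] <- TRUE; used_b[bi] <- TRUE
      matches <- matches + 1L
    }
  }
  matches / (nrow(A) + nrow(B) - matches)
}

# positive-call intervals from a calls data.frame (or plain intervals)
domain_intervals <- function(calls) {
  flag <- if ("is_domain" %in% names(calls)) calls$is_domain
          else if ("passes" %in% names(calls)) calls$passes
          else rep(TRUE, nrow(calls))
  d <- calls[flag, c("chrom", "start", "end"), drop = FALSE]
  rownames(d) <- NULL
  d
}
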