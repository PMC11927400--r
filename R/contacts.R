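#' Construct a binned contact matrix
#'
#' Internal constructor for the `contact_matrix` container: an intra-
#' chromosomal, upper-triangular sparse matrix of binned contact frequencies
#' together with its resolution, normalization state and bin mask.
#'
#' Genomic positions are 1-based inclusive; bin `i` (0-based) covers
#' `[i*resolution + 1, (i+1)*resolution]` and a position `p` maps to bin
#' `floor((p - 1)/resolution)`. Only pairs with `i <= j` are stored; records
#' with `i > j` are transposed and duplicates are summed. Explicit zeros are
#' dropped: an unstored pair means zero contacts.
#'
#' @param chrom chromosome identifier.
#' @param chrom_length chromosome length in bp.
#' @param resolution bin width in bp.
#' @param i,j 0-based bin indices of the stored pairs.
#' @param x contact frequencies (finite, non-negative).
#' @param normalization one of `"raw"`, `"balanced"`, `"external"`.
#' @param mask logical vector of length `n_bins`; `TRUE` marks invalid bins.
#' @return An object of class `contact_matrix` with fields `chrom`,
#'   `chrom_length`, `resolution`, `n_bins`, `mat` (upper-triangular
#'   `dgCMatrix`), `normalization` and `mask`.
#' @export
contact_matrix <- function(chrom, chrom_length, resolution, i, j, x,
                           normalization = c("raw", "balanced", "external"),
                           mask = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(length(chrom) == 1L, chrom_length >= 1, resolution >= 1)
  n_bins <- as.integer(ceiling(chrom_length / resolution))
  i <- as.integer(i); j <- as.integer(j); x <- as.numeric(x)
  stopifnot(length(i) == length(j), length(j) == length(x))
  if (length(x) && (any(!is.finite(x)) || any(x < 0)))
    stop("contact values must be finite and non-negative")
  if (length(i) && (any(i < 0L) || any(j < 0L) || any(i >= n_bins) || any(j >= n_bins)))
    stop("bin indices out of range [0, ", n_bins, ")")
  # transpose lower-triangular records, sum duplicates, drop zeros
  swap <- i > j
  if (any(swap)) {
    tmp <- i[swap]; i[swap] <- j[swap]; j[swap] <- tmp
  }
  keep <- x != 0
  mat <- Matrix::sparseMatrix(i = i[keep] + 1L, j = j[keep] + 1L, x = x[keep],
                              dims = c(n_bins, n_bins))
  if (is.null(mask)) mask <- rep(FALSE, n_bins)
  stopifnot(is.logical(mask), length(mask) == n_bins)
  structure(list(chrom = as.character(chrom),
                 chrom_length = as.numeric(chrom_length),
                 resolution = as.integer(resolution),
                 n_bins = n_bins,
                 mat = mat,
                 normalization = normalization,
                 mask = mask),
            class = "contact_matrix")
}

#' @exportS3Method base::print
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %s (%s bp) at %d bp, %d bins, %d stored pairs, %s, %d masked\n",
              x$chrom, format(x$chrom_length, big.mark = ","), x$resolution,
              x$n_bins, length(x$mat@x), x$normalization, sum(x$mask)))
  invisible(x)
}

#' Stored contact records of a matrix
#'
#' @param m a `contact_matrix`.
#' @return data.frame with 0-based columns `i`, `j` (`i <= j`) and `count`,
#'   sorted row-major.
#' @export
contact_records <- function(m) {
  t <- methods::as(m$mat, "TsparseMatrix")
  df <- data.frame(i = t@i, j = t@j, count = t@x)
  df <- df[order(df$i, df$j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Read a binned contact matrix
#'
#' Reads one chromosome of binned contacts. The `triplet` format is plain
#' text with three tab/space-separated columns `start1 start2 count`, where
#' starts are 0-based bin start coordinates in bp; `#` comment lines are
#' allowed. The `cool` format reads cooler/mcool HDF5 files through the
#' system `python` interpreter (h5py); stored balancing weights, when
#' present, are applied and the matrix is returned with
#' `normalization = "external"`. A `.hic` backend is not provided.
#'
#' @param path input file.
#' @param format one of `"triplet"`, `"cool"`, `"hic"`.
#' @param chrom chromosome to load.
#' @param resolution bin width in bp; for cooler input it must match the
#'   stored resolution.
#' @param chrom_length chromosome length in bp (required for `triplet`;
#'   read from the file for `cool`).
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, format = c("triplet", "cool", "hic"),
                          chrom, resolution, chrom_length = NULL) {
  format <- match.arg(format)
  if (format == "hic")
    stop("the .hic backend is not available in this build; ",
         "convert to triplet text or cooler format")
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "triplet") {
    if (is.null(chrom_length))
      stop("chrom_length is required for triplet input")
    read_contacts_triplet(path, chrom, resolution, chrom_length)
  } else {
    read_contacts_cool(path, chrom, resolution)
  }
}

read_contacts_triplet <- function(path, chrom, resolution, chrom_length) {
  nf <- utils::count.fields(path, comment.char = "#")
  bad <- which(!is.na(nf) & nf != 3L)
  if (length(bad))
    stop("malformed triplet line ", bad[1L], " in ", path,
         ": expected 3 fields, found ", nf[bad[1L]])
  dat <- tryCatch(
    utils::read.table(path, comment.char = "#",
                      colClasses = c("numeric", "numeric", "numeric"),
                      col.names = c("start1", "start2", "count")),
    error = function(e) stop("malformed triplet file ", path, ": ",
                             conditionMessage(e)))
  if (nrow(dat) == 0L)
    return(contact_matrix(chrom, chrom_length, resolution,
                          integer(0), integer(0), numeric(0)))
  if (any(dat$start1 < 0) || any(dat$start2 < 0))
    stop("negative coordinates in ", path)
  contact_matrix(chrom, chrom_length, resolution,
                 i = floor(dat$start1 / resolution),
                 j = floor(dat$start2 / resolution),
                 x = dat$count)
}

read_contacts_cool <- function(path, chrom, resolution) {
  py <- Sys.which("python")
  if (!nzchar(py))
    stop("reading .cool files requires a python interpreter with h5py on PATH")
  helper <- system.file("scripts", "cool_dump.py", package = "genedomains",
                        mustWork = TRUE)
  out <- tempfile(fileext = ".tsv")
  res <- suppressWarnings(system2(
    py, c(helper, shQuote(path), shQuote(chrom), as.character(resolution),
          shQuote(out)),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status")
  if (!is.null(status) && status != 0L)
    stop("cool reader failed: ", paste(res, collapse = " "))
  hdr <- readLines(out, n = 3L)
  chrom_length <- as.numeric(sub("^#chrom_length\t", "", hdr[1L]))
  wfield <- sub("^#weights\t", "", hdr[3L])
  has_weights <- !identical(wfield, "none")
  nlines <- length(readLines(out))
  dat <- if (nlines > 3L)
    utils::read.table(out, comment.char = "#", col.names = c("i", "j", "count"))
  else data.frame(i = integer(0), j = integer(0), count = numeric(0))
  if (has_weights) {
    w <- suppressWarnings(as.numeric(strsplit(wfield, ",")[[1L]]))
    m <- contact_matrix(chrom, chrom_length, resolution, dat$i, dat$j,
                        ifelse(is.na(w[dat$i + 1L] * w[dat$j + 1L]), 0,
                               dat$count * w[dat$i + 1L] * w[dat$j + 1L]),
                        normalization = "external", mask = is.na(w))
  } else {
    m <- contact_matrix(chrom, chrom_length, resolution,
                        dat$i, dat$j, dat$count)
  }
  m
}

#' Write a contact matrix as triplet text
#'
#' Writes `start1 start2 count` lines (0-based bin start coordinates in bp),
#' the inverse of [read_contacts()] with `format = "triplet"`.
#'
#' @param m a `contact_matrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_contacts_triplet <- function(m, path) {
  rec <- contact_records(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# chrom=%s length=%.0f resolution=%d",
                     m$chrom, m$chrom_length, m$resolution), con)
  if (nrow(rec))
    utils::write.table(data.frame(rec$i * m$resolution, rec$j * m$resolution,
                                  rec$count),
                       con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Balance a raw contact matrix by iterative correction
#'
#' Applies iterative correction (alternating row/column scaling of the
#' implied symmetric matrix) so that every unmasked bin ends up with the same
#' total coverage. Bins with zero marginal are masked and their entries
#' removed. The balanced matrix is rescaled so the mean unmasked marginal is
#' preserved, keeping counts on their original scale.
#'
#' @param m a raw `contact_matrix`.
#' @param max_iter maximum number of scaling iterations.
#' @param tol convergence tolerance on the maximum relative deviation of the
#'   unmasked marginals from their mean.
#' @return A `contact_matrix` with `normalization = "balanced"`, updated
#'   `mask`, and attributes `biases` (per-bin divisors, `NA` for masked bins)
#'   and `converged`.
#' @export
balance_matrix <- function(m, max_iter = 200L, tol = 1e-6) {
  stopifnot(inherits(m, "contact_matrix"))
  if (m$normalization != "raw")
    stop("balance_matrix expects a raw matrix (got ", m$normalization, ")")
  n <- m$n_bins
  # symmetric view of the upper triangle, diagonal counted once
  sym <- m$mat + Matrix::t(m$mat) - Matrix::Diagonal(n, x = Matrix::diag(m$mat))
  marg_of <- function(b) {
    w <- ifelse(is.finite(b) & b > 0, 1 / b, 0)
    as.vector(sym %*% w) * w
  }
  marg0 <- marg_of(rep(1, n))
  active <- !m$mask & marg0 > 0
  if (!any(active)) stop("no bins with nonzero coverage to balance")
  target <- mean(marg0[active])
  b <- rep(1, n)
  b[!active] <- NA_real_
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    marg <- marg_of(b)
    s <- marg[active] / mean(marg[active])
    if (max(abs(s - 1)) < tol) { converged <- TRUE; break }
    b[active] <- b[active] * sqrt(s)   # damped update: plain s oscillates
  }
  if (!converged)
    warning("balancing did not converge within ", max_iter,
            " iterations; returning best-effort result")
  marg <- marg_of(b)
  b[active] <- b[active] / sqrt(target / mean(marg[active]))
  rec <- contact_records(m)
  ii <- rec$i + 1L; jj <- rec$j + 1L
  keep <- active[ii] & active[jj]
  v <- rec$count[keep] / (b[ii[keep]] * b[jj[keep]])
  out <- contact_matrix(m$chrom, m$chrom_length, m$resolution,
                        rec$i[keep], rec$j[keep], v,
                        normalization = "balanced", mask = !active)
  attr(out, "biases") <- ifelse(active, b, NA_real_)
  attr(out, "converged") <- converged
  out
}

#' Expected contact frequency by genomic separation
#'
#' The expected value at separation `d` bins is the mean normalized contact
#' over all valid (both bins unmasked) pairs at that separation, counting
#' unstored pairs as zero. Entries that would be zero or undefined are
#' replaced by a small positive floor so observed/expected ratios are always
#' defined.
#'
#' @param m a normalized `contact_matrix` (balanced or external).
#' @param floor_eps positive floor substituted for zero/undefined means.
#' @return An object of class `expected_profile`: list with `resolution`,
#'   `expected` (length `n_bins`, entry `d + 1` is the mean at separation
#'   `d`) and `floor_eps`.
#' @export
expected_profile <- function(m, floor_eps = 1e-9) {
  stopifnot(inherits(m, "contact_matrix"), floor_eps > 0)
  if (m$normalization == "raw")
    stop("expected_profile requires a normalized matrix; run balance_matrix() first")
  n <- m$n_bins
  rec <- contact_records(m)
  valid_pair <- !m$mask[rec$i + 1L] & !m$mask[rec$j + 1L]
  rec <- rec[valid_pair, , drop = FALSE]
  sums <- numeric(n)
  if (nrow(rec)) {
    a <- rowsum(rec$count, rec$j - rec$i)
    sums[as.integer(rownames(a)) + 1L] <- a
  }
  ok <- !m$mask
  expected <- rep(floor_eps, n)
  if (any(m$mask)) {
    v <- as.numeric(ok)
    for (d in which(sums > 0) - 1L) {
      cnt <- sum(v[1:(n - d)] * v[(1 + d):n])
      if (cnt > 0) expected[d + 1L] <- max(sums[d + 1L] / cnt, floor_eps)
    }
  } else {
    d_all <- 0:(n - 1L)
    cnt <- n - d_all
    mean_d <- sums / cnt
    expected <- pmax(mean_d, floor_eps)
  }
  structure(list(resolution = m$resolution, expected = expected,
                 floor_eps = floor_eps),
            class = "expected_profile")
}

#' Observed/expected values over a bin-pair region
#'
#' Returns one OE value per unmasked pair of the region, in row-major
#' `(i, j)` order. Unstored pairs contribute an observed value of zero, so
#' sparse regions yield explicit zero OE samples.
#'
#' @param m a normalized `contact_matrix`.
#' @param e the matching `expected_profile`.
#' @param region a `bin_pair_region` (see [single_gene_regions()]).
#' @return Numeric vector of OE values (empty if the region is entirely
#'   masked).
#' @export
oe_values <- function(m, e, region) {
  stopifnot(inherits(m, "contact_matrix"), inherits(e, "expected_profile"),
            inherits(region, "bin_pair_region"))
  p <- region$pairs
  if (nrow(p) == 0L) return(numeric(0))
  if (any(p < 0L) || any(p >= m$n_bins))
    stop("region pairs out of matrix bounds")
  keep <- !m$mask[p[, 1L] + 1L] & !m$mask[p[, 2L] + 1L]
  p <- p[keep, , drop = FALSE]
  if (nrow(p) == 0L) return(numeric(0))
  obs <- m$mat[p + 1L]
  obs / e$expected[p[, 2L] - p[, 1L] + 1L]
}

#' Binomially subsample a raw contact matrix
#'
#' Thins every stored count with independent `Binomial(count, frac)` draws,
#' emulating sequencing a fraction of the original library. Used by the
#' reproducibility harness (technical pseudo-replicates at, e.g., 80%).
#'
#' @param m a raw `contact_matrix` with integer counts.
#' @param frac retention probability in (0, 1].
#' @param seed integer seed for the draw.
#' @return A raw `contact_matrix` with thinned counts.
#' @export
subsample_contacts <- function(m, frac = 0.8, seed = 1L) {
  stopifnot(inherits(m, "contact_matrix"), frac > 0, frac <= 1)
  if (m$normalization != "raw")
    stop("subsampling applies to raw counts")
  rec <- contact_records(m)
  if (any(rec$count != round(rec$count)))
    stop("subsampling requires integer counts")
  set.seed(as.integer(seed))
  thinned <- stats::rbinom(nrow(rec), size = as.integer(round(rec$count)),
                           prob = frac)
  contact_matrix(m$chrom, m$chrom_length, m$resolution,
                 rec$i, rec$j, thinned, mask = m$mask)
}
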