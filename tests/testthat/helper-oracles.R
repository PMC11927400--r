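# Independent brute-force oracles used to pin down the analytic routines.
# These deliberately share no code with the package implementation.

# exact one-sided Mann-Whitney p (x greater) by enumerating all labelings
exact_mwu_greater <- function(x, y) {
  n1 <- length(x)
  pool <- c(x, y)
  r <- rank(pool)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pool), n1)
  u_all <- apply(combs, 2L, function(s) sum(r[s]) - n1 * (n1 + 1) / 2)
  mean(u_all >= u_obs - 1e-12)
}

# exact two-sided Wilcoxon signed-rank p by enumerating all sign flips
exact_wilcoxon_two_sided <- function(diffs) {
  nz <- diffs[diffs != 0]
  n <- length(nz)
  r <- rank(abs(nz))
  v_obs <- sum(r[nz > 0])
  mu <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- as.vector(signs %*% r)
  mean(abs(v_all - mu) >= abs(v_obs - mu) - 1e-12)
}

# exhaustive double-loop predicate evaluation for the single-gene target
oracle_single_target <- function(a, b, resolution, n_bins) {
  L <- b - a + 1
  out <- NULL
  for (i in 0:(n_bins - 2L)) {
    for (j in (i + 1L):(n_bins - 1L)) {
      xi <- i * resolution + (resolution + 1) / 2
      xj <- j * resolution + (resolution + 1) / 2
      if (xi >= a && xj <= b && xj - xi >= L / 2)
        out <- rbind(out, c(i, j))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

# exhaustive predicate evaluation for differential gene-body / surrounding
oracle_diff_regions <- function(a, b, flank, resolution, n_bins) {
  body <- NULL; surr <- NULL
  inb <- function(x) x >= a && x <= b
  inf <- function(x) (x >= a - flank && x < a) || (x > b && x <= b + flank)
  for (i in 0:(n_bins - 2L)) {
    for (j in (i + 1L):(n_bins - 1L)) {
      xi <- i * resolution + (resolution + 1) / 2
      xj <- j * resolution + (resolution + 1) / 2
      if (inb(xi) && inb(xj)) body <- rbind(body, c(i, j))
      else if ((inb(xi) && inf(xj)) || (inf(xi) && inb(xj)))
        surr <- rbind(surr, c(i, j))
    }
  }
  list(body = if (is.null(body)) matrix(integer(0), 0, 2) else body,
       surr = if (is.null(surr)) matrix(integer(0), 0, 2) else surr)
}

# exhaustive multigene corner/stripe targets from gene bin spans
oracle_multigene_targets <- function(spans, n_bins) {
  k <- nrow(spans)
  in_span <- function(i, s) i >= spans[s, 1] && i <= spans[s, 2]
  corner <- NULL; sl <- NULL; sr <- NULL
  for (i in 0:(n_bins - 2L)) {
    for (j in (i + 1L):(n_bins - 1L)) {
      if (in_span(i, 1) && in_span(j, k)) corner <- rbind(corner, c(i, j))
      if (k >= 3) {
        if (in_span(i, 1) && j >= spans[2, 1] && j <= spans[k, 2])
          sl <- rbind(sl, c(i, j))
        if (i >= spans[1, 1] && i <= spans[k - 1, 2] && in_span(j, k))
          sr <- rbind(sr, c(i, j))
      }
    }
  }
  fix <- function(m) if (is.null(m)) matrix(integer(0), 0, 2) else m
  list(corner = fix(corner), stripe_left = fix(sl), stripe_right = fix(sr))
}

# dense alternating-scaling fixed point (Sinkhorn) for balancing checks;
# returns the doubly stochastic form of a symmetric positive matrix
oracle_sinkhorn <- function(S, iters = 20000) {
  D <- S
  for (it in seq_len(iters)) {
    D <- D / rowSums(D)
    D <- t(t(D) / colSums(D))
  }
  D
}
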