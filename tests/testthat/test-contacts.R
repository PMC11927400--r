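test_that("triplet loader normalizes orientation, merges duplicates, handles empty input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# comment", "0\t500\t4", "500\t0\t2", "250\t250\t7"), tf)
  m <- read_contacts(tf, "triplet", chrom = "c1", resolution = 250,
                     chrom_length = 10000)
  expect_equal(m$n_bins, 40L)
  rec <- contact_records(m)
  expect_equal(rec, data.frame(i = c(0L, 1L), j = c(2L, 1L), count = c(6, 7)))

  writeLines("# empty", tf)
  m0 <- read_contacts(tf, "triplet", chrom = "c1", resolution = 250,
                      chrom_length = 10000)
  expect_equal(m0$n_bins, 40L)
  expect_equal(nrow(contact_records(m0)), 0L)

  # ceiling arithmetic for a non-divisible chromosome length
  writeLines("0\t0\t1", tf)
  expect_equal(read_contacts(tf, "triplet", chrom = "c1", resolution = 250,
                             chrom_length = 1001)$n_bins, 5L)
})

test_that("triplet write -> read round-trips counts exactly", {
  set.seed(42)
  n <- 30L
  p <- which(upper.tri(matrix(0, n, n), diag = TRUE), arr.ind = TRUE)
  keep <- sample(nrow(p), 100)
  m <- contact_matrix("cR", n * 250, 250, p[keep, 1] - 1L, p[keep, 2] - 1L,
                      rpois(100, 10) + 1)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_contacts_triplet(m, tf)
  m2 <- read_contacts(tf, "triplet", chrom = "cR", resolution = 250,
                      chrom_length = n * 250)
  expect_identical(contact_records(m2), contact_records(m))
})

test_that("malformed input is rejected with a line number", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("0\t250\t1", "250\t500"), tf)
  expect_error(read_contacts(tf, "triplet", chrom = "c", resolution = 250,
                             chrom_length = 1e4), "line 2")
  writeLines("-250\t0\t1", tf)
  expect_error(read_contacts(tf, "triplet", chrom = "c", resolution = 250,
                             chrom_length = 1e4), "negative")
  expect_error(read_contacts(tf, "hic", chrom = "c", resolution = 250),
               "not available")
})

test_that("iterative correction equalizes marginals and matches the Sinkhorn oracle", {
  # equal-coverage matrix: balancing must only rescale proportionally
  m_eq <- matrix_from_fun(12, 250, function(i, j) 3 + (i == j),
                          normalization = "raw")
  b_eq <- balance_matrix(m_eq, tol = 1e-12)
  r <- contact_records(b_eq)$count / contact_records(m_eq)$count
  expect_lt(diff(range(r)), 1e-9)

  # 3x3 dense toy vs the dense alternating-scaling fixed point
  S <- matrix(c(4, 2, 1, 2, 6, 3, 1, 3, 9), 3, 3)
  p <- which(upper.tri(S, diag = TRUE), arr.ind = TRUE)
  m3 <- contact_matrix("c3", 750, 250, p[, 1] - 1L, p[, 2] - 1L,
                       S[p], normalization = "raw")
  b3 <- balance_matrix(m3, max_iter = 10000, tol = 1e-13)
  rec <- contact_records(b3)
  B <- matrix(0, 3, 3); B[cbind(rec$i + 1, rec$j + 1)] <- rec$count
  B <- B + t(B) - diag(diag(B))
  expect_equal(B / rowSums(B)[1], oracle_sinkhorn(S), tolerance = 1e-10)

  # an all-zero row is masked, the rest balanced (bins 0,2,3 dense)
  m0 <- contact_matrix("c4", 1000, 250,
                       c(0L, 0L, 0L, 2L, 2L, 3L), c(0L, 2L, 3L, 2L, 3L, 3L),
                       c(5, 3, 4, 6, 2, 7), normalization = "raw")
  b0 <- balance_matrix(m0)
  expect_true(b0$mask[2])
  expect_false(any(contact_records(b0)$i == 1L | contact_records(b0)$j == 1L))
  rec0 <- contact_records(b0)
  marg <- tapply(c(rec0$count, rec0$count[rec0$i != rec0$j]),
                 c(rec0$i, rec0$j[rec0$i != rec0$j]), sum)
  expect_lt(diff(range(marg)), 1e-5 * mean(marg))
})

test_that("re-balancing an already balanced matrix is a no-op within tolerance", {
  sim <- small_planted_sim(seed = 7, n_genes = 10, chrom_length = 1e5)
  b1 <- balance_matrix(sim$m, tol = 1e-10)
  r1 <- contact_records(b1)
  m_again <- contact_matrix(b1$chrom, b1$chrom_length, b1$resolution,
                            r1$i, r1$j, r1$count, normalization = "raw",
                            mask = b1$mask)
  b2 <- balance_matrix(m_again, tol = 1e-10)
  expect_equal(contact_records(b2)$count, r1$count, tolerance = 1e-6)
})

test_that("expected profile averages per separation, counting unstored pairs as zero", {
  # 4-bin toy: {(0,1):2,(1,2):4,(0,2):3}, (2,3) unstored
  toy <- contact_matrix("t", 1000, 250, c(0L, 1L, 0L), c(1L, 2L, 2L),
                        c(2, 4, 3), normalization = "balanced")
  e <- expected_profile(toy)
  expect_equal(e$expected[2], 2.0)   # (2 + 4 + 0)/3
  expect_equal(e$expected[3], 1.5)   # (3 + 0)/2
  expect_equal(e$expected[4], e$floor_eps)

  u <- uniform_matrix(20, 250, value = 7)
  expect_true(all(abs(expected_profile(u)$expected - 7) < 1e-12))

  # pairs touching a masked bin are excluded from the means
  msk <- rep(FALSE, 4); msk[2] <- TRUE
  toy_m <- contact_matrix("t", 1000, 250, c(0L, 1L, 0L), c(1L, 2L, 2L),
                          c(2, 4, 3), normalization = "balanced", mask = msk)
  em <- expected_profile(toy_m)
  expect_equal(em$expected[3], 3)    # only (0,2) remains at separation 2
})

test_that("OE values follow the definition and respect the mask", {
  u <- uniform_matrix(30, 250, value = 4)
  e <- expected_profile(u)
  reg <- bin_pair_region("r", c(0, 3, 5), c(2, 7, 20))
  expect_equal(oe_values(u, e, reg), rep(1, 3))

  # observed 6 at separation 4 with expected 2 -> OE 3
  m <- contact_matrix("c", 10 * 250, 250, 3L, 7L, 6, normalization = "balanced")
  e2 <- structure(list(resolution = 250L, expected = rep(2, 10),
                       floor_eps = 1e-9), class = "expected_profile")
  expect_equal(oe_values(m, e2, bin_pair_region("r", 3, 7)), 3)
  # unstored pairs yield explicit zeros
  expect_equal(oe_values(m, e2, bin_pair_region("r", c(0, 3), c(1, 7))),
               c(0, 3))

  # masked pairs are dropped from the ordered list
  msk <- rep(FALSE, 30); msk[c(4, 11)] <- TRUE
  um <- uniform_matrix(30, 250, value = 4)
  um$mask <- msk
  reg5 <- bin_pair_region("r", c(0, 3, 5, 10, 12), c(2, 7, 20, 15, 22))
  expect_length(oe_values(um, expected_profile(um), reg5), 3L)
})

test_that("mean OE per fully covered separation is 1 by construction", {
  sim <- small_planted_sim(seed = 3, n_genes = 12, chrom_length = 1.2e5)
  b <- balance_matrix(sim$m)
  e <- expected_profile(b)
  rec <- contact_records(b)
  for (d in c(1L, 5L, 20L)) {
    n_pairs <- b$n_bins - d
    s <- sum(rec$count[rec$j - rec$i == d])
    expect_equal(s / n_pairs / e$expected[d + 1], 1, tolerance = 1e-9)
  }
})

test_that("cooler files round-trip through the HDF5 backend with weights applied", {
  py <- Sys.which("python")
  expect_true(nzchar(py))   # part of the supported toolchain
  cool <- withr::local_tempfile(fileext = ".cool")
  script <- sprintf('
import h5py, numpy as np
f = h5py.File(%s, "w")
f.attrs["bin-size"] = 250
f.create_dataset("chroms/name", data=np.array([b"chr1", b"chr2"]))
f.create_dataset("chroms/length", data=np.array([2000, 1000]))
chrom = np.array([0]*8 + [1]*4)
start = np.concatenate([np.arange(8)*250, np.arange(4)*250])
end = np.minimum(start + 250, np.concatenate([[2000]*8, [1000]*4]))
f.create_dataset("bins/chrom", data=chrom)
f.create_dataset("bins/start", data=start)
f.create_dataset("bins/end", data=end)
w = np.array([1.0]*12); w[3] = np.nan; w[1] = 2.0
f.create_dataset("bins/weight", data=w)
f.create_dataset("pixels/bin1_id", data=np.array([0,1,3,8]))
f.create_dataset("pixels/bin2_id", data=np.array([2,1,5,9]))
f.create_dataset("pixels/count", data=np.array([4.0,7.0,3.0,9.0]))
f.close()
', deparse(cool))
  pyf <- withr::local_tempfile(fileext = ".py")
  writeLines(script, pyf)
  expect_equal(system2(py, pyf), 0L)

  m <- read_contacts(cool, "cool", chrom = "chr1", resolution = 250)
  expect_equal(m$normalization, "external")
  expect_equal(m$chrom_length, 2000)
  expect_true(m$mask[4])   # NaN weight -> masked bin
  rec <- contact_records(m)
  # weights multiply: (1,1) stored 7 * 2 * 2; pair with masked bin dropped
  expect_equal(rec, data.frame(i = c(0L, 1L), j = c(2L, 1L),
                               count = c(4, 28)))
  expect_error(read_contacts(cool, "cool", chrom = "chrX", resolution = 250),
               "chr1,chr2")
  expect_error(read_contacts(cool, "cool", chrom = "chr1", resolution = 500),
               "resolution")
})

test_that("binomial subsampling is deterministic under seed and bounded by source counts", {
  sim <- small_planted_sim(seed = 5, n_genes = 8, chrom_length = 8e4)
  s1 <- subsample_contacts(sim$m, frac = 0.8, seed = 9)
  s2 <- subsample_contacts(sim$m, frac = 0.8, seed = 9)
  expect_identical(contact_records(s1), contact_records(s2))
  src <- contact_records(sim$m)
  sub <- merge(src, contact_records(s1), by = c("i", "j"), all.x = TRUE)
  sub$count.y[is.na(sub$count.y)] <- 0
  expect_true(all(sub$count.y <= sub$count.x))
  expect_equal(sum(sub$count.y) / sum(sub$count.x), 0.8, tolerance = 0.02)
})
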