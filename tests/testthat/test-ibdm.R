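test_that("identity and integer-translation resampling are exact", {
  g <- random_dose(seed = 6)
  ident <- map_to_reference(g, reference_transform(diag(3), c(0, 0, 0)))
  expect_equal(ident$values, g$values, tolerance = 1e-12)
  # translation by whole reference voxels: x_ref = x_pat + t means the
  # reference voxel at x samples the patient map at x - t
  k <- c(1L, -2L, 0L)
  tr <- reference_transform(diag(3), k * g$spacing)
  mapped <- map_to_reference(g, tr)
  oracle <- index_shift_oracle(g$values, -k)
  # compare where the oracle is in-field; out-of-field voxels must be NA
  edge <- is.na(mapped$values)
  expect_equal(mapped$values[!edge], oracle[!edge], tolerance = 1e-12)
  expect_true(all(oracle[edge] == 0))
  expect_error(reference_transform(matrix(0, 3, 3)), "singular")
})

test_that("misregistration beyond tolerance fails QA", {
  tr_good <- reference_transform(diag(3), c(2, 0, 0))
  tr_bad <- reference_transform(diag(3), c(20, 0, 0))
  hc <- c(-20, 10, -30)
  expect_true(qa_transform(tr_good, hc, hc + c(2, 0, 0), tolerance = 10)$qa_passed)
  q <- qa_transform(tr_bad, hc, hc + c(2, 0, 0), tolerance = 10)
  expect_false(q$qa_passed)
  expect_equal(q$heart_com_deviation, 18)
})

test_that("Gaussian blur has a unit-sum kernel and preserves constants", {
  g <- random_dose(seed = 7)
  expect_identical(blur_map(g, 0)$values, g$values)
  expect_error(blur_map(g, -1), ">= 0")
  # unit impulse away from the boundary: output sums to 1 (kernel
  # normalisation; near the boundary gather-style reflection would re-count)
  imp <- array(0, c(15, 15, 13))
  imp[8, 8, 7] <- 1
  bi <- blur_map(dose_grid(imp, c(4, 4, 4)), sigma_mm = c(3, 4, 5))
  expect_equal(sum(bi$values), 1, tolerance = 1e-6)
  expect_lt(max(bi$values), 1)
  # constants are exactly preserved (reflecting boundary)
  cst <- dose_grid(array(7, c(10, 10, 8)), c(4, 4, 4))
  expect_equal(blur_map(cst, 5)$values, cst$values, tolerance = 1e-12)
})

test_that("permutation p matches exhaustive enumeration on a tiny cohort", {
  # 4 patients, 2 x 2 x 1 maps, 2 dead vs 2 alive: only choose(4,2) = 6
  # distinct label splits exist
  maps <- with_seed(17, lapply(1:4, function(i)
    dose_grid(array(rnorm(4), c(2, 2, 1)), 4, signed = TRUE)))
  X <- stack_maps(maps)
  labels <- c("dead", "dead", "alive", "alive")
  splits <- utils::combn(4, 2)
  diff_for <- function(dead_idx) {
    rowMeans(X[, dead_idx, drop = FALSE]) -
      rowMeans(X[, -dead_idx, drop = FALSE])
  }
  perm_diffs <- vapply(seq_len(ncol(splits)), function(s)
    diff_for(splits[, s]), numeric(4))
  # the estimator's scaling: SD of the permuted difference at each voxel
  obs <- diff_for(1:2)
  enumerate_p <- function(sd_fun) {
    psd <- apply(perm_diffs, 1L, sd_fun)
    t_obs <- max(obs / psd)
    mean(apply(abs(perm_diffs / psd), 2L, max) >= t_obs)
  }
  p_exact <- enumerate_p(stats::sd)
  res <- permutation_test(X, labels, n_perm = 4000, seed = 23)
  # sampled permutations estimate the exhaustive p within Monte-Carlo error
  mc <- 3 * sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(res$global_p - p_exact), mc + 2 / 4000 + 0.02)
  expect_equal(as.vector(res$diff), obs)
})

test_that("degenerate constant maps give a null difference and p = 1", {
  maps <- lapply(1:6, function(i)
    dose_grid(array(5, c(3, 3, 2)), 4, signed = TRUE))
  res <- permutation_test(stack_maps(maps),
                          rep(c("dead", "alive"), each = 3), n_perm = 50,
                          seed = 1)
  expect_equal(res$global_p, 1)
  expect_equal(res$max_t, 0)
  expect_true(all(abs(res$diff[!is.na(res$diff)]) < 1e-12))
})

test_that("a planted group effect yields the two-sample t magnitude", {
  # block effect delta = 1 Gy on 5^3 voxels, noise SD 1, 100 per group:
  # perm SD ~ sqrt(1/n1 + 1/n2), so t ~ 1 / 0.141 ~ 7 inside the block
  dm <- c(9, 9, 7)
  n_per <- 100L
  block <- array(FALSE, dm)
  block[3:7, 3:7, 2:6] <- TRUE
  X <- with_seed(29, {
    m <- matrix(rnorm(prod(dm) * 2 * n_per), prod(dm))
    m[as.vector(block), seq_len(n_per)] <-
      m[as.vector(block), seq_len(n_per)] + 1
    m
  })
  attr(X, "dim3") <- dm
  attr(X, "spacing") <- c(4, 4, 4)
  attr(X, "origin") <- -(dm - 1) / 2 * 4
  labels <- rep(c("dead", "alive"), each = n_per)
  res <- permutation_test(X, labels, n_perm = 500, seed = 31)
  t_expected <- 1 / sqrt(1 / n_per + 1 / n_per)
  expect_equal(mean(res$t[block]), t_expected, tolerance = 0.2)
  expect_lt(res$global_p, 0.01)
})

test_that("label swap negates the statistic and the identity permutation
           reproduces the observed difference", {
  maps <- with_seed(37, lapply(1:10, function(i)
    dose_grid(array(rnorm(24), c(4, 3, 2)), 4, signed = TRUE)))
  X <- stack_maps(maps)
  labels <- rep(c("dead", "alive"), 5)
  a <- permutation_test(X, labels, n_perm = 100, seed = 41)
  b <- permutation_test(X, ifelse(labels == "dead", "alive", "dead"),
                        n_perm = 100, seed = 41)
  expect_equal(a$t, -b$t, tolerance = 1e-10)
  expect_equal(a$diff, -b$diff, tolerance = 1e-12)
  dead <- labels == "dead"
  expect_equal(as.vector(a$diff),
               rowMeans(X[, dead]) - rowMeans(X[, !dead]), tolerance = 1e-12)
})

test_that("region extraction keeps the peak's connected component", {
  # constant positive map: everything is at the max, so the whole mask
  t_const <- array(1, c(4, 4, 2))
  r <- extract_region(fake_tstat_map(t_const))
  expect_equal(r$n_voxels, length(t_const))
  # two disjoint blobs: only the one holding the global max survives
  t2 <- array(0, c(12, 6, 2))
  t2[2:3, 2:3, 1] <- 5      # blob A (contains max)
  t2[9:10, 2:3, 1] <- 4.5   # blob B, above threshold but disconnected
  r2 <- extract_region(fake_tstat_map(t2), fraction = 0.8)
  expect_equal(r2$threshold_t, 4)
  expect_equal(r2$n_voxels, 4L)
  expect_true(all(which(r2$mask) %in% which(t2 == 5)))
  # contract: mask within the suprathreshold set and contains the argmax
  t3 <- with_seed(43, array(abs(rnorm(200)), c(10, 10, 2)))
  tm3 <- fake_tstat_map(t3)
  r3 <- extract_region(tm3, fraction = 0.6)
  expect_true(all(t3[r3$mask] >= 0.6 * max(t3)))
  expect_true(r3$mask[tm3$argmax])
  # 6-connectivity is stricter than 26
  t4 <- array(0, c(5, 5, 1))
  t4[2, 2, 1] <- 5; t4[3, 3, 1] <- 4.9  # diagonal neighbours
  expect_equal(extract_region(fake_tstat_map(t4), connectivity = 26)$n_voxels, 2L)
  expect_equal(extract_region(fake_tstat_map(t4), connectivity = 6)$n_voxels, 1L)
})

test_that("region dose summaries are plain arithmetic means", {
  dm <- c(2, 2, 1)
  region <- structure(list(mask = array(TRUE, dm), threshold_t = 1,
                           connectivity = 26L, n_voxels = 4L, dim = dm,
                           spacing = c(4, 4, 4), origin = c(0, 0, 0)),
                      class = "dose_region")
  delta <- matrix(c(1, 2, 3, 4, 10, 20, 30, 40), nrow = 4)
  planned <- matrix(5, nrow = 4, ncol = 2)
  s <- region_dose_summary(region, delta, planned, c("a", "b"))
  expect_equal(s$mean_delta_region_gy, c(2.5, 25))
  expect_equal(s$mean_planned_region_gy, c(5, 5))
  # single-voxel region
  region1 <- region; region1$mask <- array(c(TRUE, FALSE, FALSE, FALSE), dm)
  expect_equal(region_dose_summary(region1, delta)$mean_delta_region_gy,
               c(1, 10))
  # a patient with no valid voxels in the region is an error
  delta_na <- delta; delta_na[, 2] <- NA
  expect_error(region_dose_summary(region, delta_na, patient_ids = c("a", "b")),
               "patient b")
})

test_that("analysis mask tracks per-voxel coverage", {
  X <- matrix(1, 4, 10)
  X[1, 1:2] <- NA  # voxel 1 valid in 80% of patients
  X[2, 1] <- NA    # voxel 2 valid in 90%
  expect_equal(analysis_mask(X, 0.9), c(FALSE, TRUE, TRUE, TRUE))
  maps <- list(dose_grid(array(0, c(2, 2, 2)), 4),
               dose_grid(array(0, c(2, 2, 2)), 5))
  expect_error(stack_maps(maps), "common lattice")
})
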