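test_that("ROI time courses are binned ratios against the pre-stimulus baseline", {
  # constant stack: all-zero trace
  st <- make_stack(const_frames(8, 10, 25))
  tc <- timecourse(st)
  expect_equal(max(abs(tc$dff)), 0)

  # step to 1.1x baseline at onset: 0 before, 0.1 after
  fr <- const_frames(8, 10, 25, 100)
  fr[, , 11:25] <- 110
  tc2 <- timecourse(make_stack(fr))
  onset_t <- 10 / 5
  expect_equal(tc2$dff[tc2$time < onset_t], rep(0, 4), tolerance = 1e-12)
  expect_equal(tc2$dff[tc2$time >= onset_t],
               rep(0.1, sum(tc2$time >= onset_t)), tolerance = 1e-12)

  # one bin per frame when bin_s equals the frame period
  tc3 <- timecourse(st, bin_s = 1 / 5)
  expect_equal(nrow(tc3), 25)

  expect_error(timecourse(st, roi = matrix(FALSE, 8, 10)), "empty")
  expect_error(timecourse(st, bin_s = 0.1), "frame period")
})

test_that("stimulus-response curves follow the saturating amplitude gain", {
  pulses <- c(1, 2, 5, 10)
  blob <- function(label) setNames(list(list(center = c(10, 8),
                                             sigma_px = 3,
                                             peak_dFF = 0.1)), label)
  blobs <- do.call(c, lapply(sprintf("elec_%dp_100uA", pulses), function(l)
    setNames(list(list(center = c(10, 8), sigma_px = 3, peak_dFF = 0.1)),
             l)))
  cfg <- clean_config(blobs = blobs, n_trials_per_condition = 2)
  trials <- lapply(pulses, function(p)
    lapply(1:2, function(i)
      generate_trial(cfg, electrical_stimulus(n_pulses = p), seed = i)))
  names(trials) <- pulses
  curve <- stimulus_response_curve(trials)
  expect_true(all(diff(curve$peak_mean) > 0))

  # noiseless peaks are proportional to the analytic gain p/(p+k)
  gain <- (pulses / (pulses + 2)) / (5 / 7)
  ratio <- curve$peak_mean / curve$peak_mean[curve$param == 5]
  expect_equal(ratio, gain, tolerance = 1e-9)

  expect_error(stimulus_response_curve(trials[1]), "2 parameter")

  # blank trials peak at zero
  blanks <- lapply(1:2, function(i)
    generate_trial(cfg, blank_stimulus(), seed = i))
  curve2 <- stimulus_response_curve(list("0" = blanks,
                                         "5" = trials[["5"]]))
  expect_equal(curve2$peak_mean[curve2$param == 0], 0, tolerance = 1e-12)
})

test_that("quadrant partition covers the field with disjoint subregions", {
  part <- partition_subregions(c(64, 84))
  counts <- table(factor(unclass(part)))
  expect_equal(as.numeric(counts), c(32 * 42, 32 * 42, 32 * 42, 32 * 42),
               ignore_attr = TRUE)
  expect_equal(sum(counts), 64 * 84)

  # degenerate split: anterior empty
  p0 <- partition_subregions(c(10, 10), ap_split_col = 0)
  expect_false(any(unclass(p0) %in% c("APCd", "APCv")))
  expect_error(partition_subregions(c(10, 10), ap_split_col = 11),
               "outside")
})

test_that("response vectors count subregion means and mask fractions", {
  part <- partition_subregions(c(8, 8), 4, 4)
  mean_dff <- matrix(0.02, 8, 8)

  v0 <- response_vector(fake_map(mean_dff, matrix(FALSE, 8, 8)), part)
  expect_equal(unname(v0[5:8]), rep(0, 4))

  apcd <- unclass(part) == "APCd"
  v1 <- response_vector(fake_map(mean_dff, apcd), part)
  expect_equal(unname(v1[5:8]), c(1, 0, 0, 0))

  set.seed(6)
  rnd <- matrix(runif(64) < 0.3, 8, 8)
  v2 <- response_vector(fake_map(mean_dff, rnd), part)
  for (r in attr(part, "subregions")) {
    px <- unclass(part) == r
    expect_equal(unname(v2[paste0("frac.", r)]), sum(rnd & px) / sum(px))
  }

  # relabeling-by-permutation leaves the multiset of fractions intact
  expect_equal(sort(unname(v2[5:8])),
               sort(unname(vapply(attr(part, "subregions"), function(r)
                 sum(rnd & unclass(part) == r) / sum(unclass(part) == r),
                 numeric(1)))))

  # empty subregion is flagged, not silently zero
  pd <- partition_subregions(c(8, 8), ap_split_col = 0)
  expect_warning(ve <- response_vector(fake_map(mean_dff, rnd), pd),
                 "empty")
  expect_true(all(is.na(ve[c("frac.APCd", "frac.APCv")])))
})

test_that("pairwise distances are Euclidean and permutation-consistent", {
  v <- list(a = c(0, 0, 0, 0), b = c(3, 4, 0, 0), c = c(1, 1, 1, 1))
  D <- pairwise_distances(v)
  expect_equal(D["a", "b"], 5)
  expect_equal(D["a", "a"], 0)
  expect_equal(D, t(D))
  D2 <- pairwise_distances(v[c("b", "c", "a")])
  expect_equal(D2["a", "b"], D["a", "b"])
  expect_error(pairwise_distances(list(1:3, 1:4)), "length")
  expect_error(pairwise_distances(list(1:3)), "at least 2")
})

test_that("UPGMA merge heights match a hand computation", {
  D <- matrix(c(0, 1, 10,
                1, 0, 10,
                10, 10, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  res <- hierarchical_cluster(D)
  expect_equal(res$linkage_distances, c(1, 10))

  # all-identical points: all merge heights zero
  Dz <- matrix(0, 4, 4)
  expect_equal(hierarchical_cluster(Dz)$linkage_distances, rep(0, 3))

  expect_error(hierarchical_cluster(matrix(0, 1, 1)), "at least 2")
  expect_error(hierarchical_cluster(matrix(c(0, 1, 2, 0), 2, 2)),
               "symmetric")
})

test_that("within/between summaries separate tight classes", {
  set.seed(7)
  near <- lapply(1:5, function(i) rnorm(4, 0, 0.01))
  far <- lapply(1:5, function(i) rnorm(4, 5, 0.01))
  D <- pairwise_distances(c(near, far))
  cl <- rep(c("A", "B"), each = 5)
  res <- hierarchical_cluster(D, classes = cl, permutations = 200)
  wb <- res$within_between
  expect_lt(wb$within_mean, wb$between_mean)
  expect_lt(wb$p_value, 1e-6)
  expect_lt(wb$p_permutation, 0.05)
  expect_equal(length(unique(res$top_split[cl == "A"])), 1)
  expect_equal(length(unique(res$top_split[cl == "B"])), 1)
  expect_false(res$top_split[1] == res$top_split[6])
  # every within-class distance below every between-class distance
  expect_lt(max(D[1:5, 1:5]), min(D[1:5, 6:10]))
})

test_that("expression rates are tabulated with integer rounding", {
  toy <- data.frame(construct = rep("MCE-gV", 7),
                    line_id = sprintf("l%d", 1:7),
                    mitral_tufted = rep(TRUE, 7))
  r <- expression_rate(toy, "MCE-gV", "mitral_tufted")
  expect_equal(r, list(positive = 7, total = 7, percent = 100))
  expect_error(expression_rate(toy, "Tbx5.0gV", "mitral_tufted"),
               "not present")
  expect_error(expression_rate(toy, "MCE-gV", "granule"), "unknown")
})
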