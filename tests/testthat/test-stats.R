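# independent enumeration oracle for the two-sided Mann-Whitney p-value
mw_exact_oracle <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  u_of <- function(idx) sum(r[idx]) - nx * (nx + 1) / 2
  dev_obs <- abs(u_of(seq_len(nx)) - nx * length(y) / 2)
  combs <- utils::combn(n, nx)
  devs <- apply(combs, 2, function(idx) abs(u_of(idx) - nx * length(y) / 2))
  mean(devs >= dev_obs - 1e-12)
}

test_that("optimal 1D clustering beats seeded Lloyd iteration everywhere", {
  set.seed(42)
  for (rep in 1:50) {
    n <- sample(8:40, 1)
    k <- sample(2:4, 1)
    x <- c(rnorm(n, 0, 1), rnorm(n, sample(2:6, 1), 1))
    dp <- kmeans_1d_dp(x, k)
    lloyd <- suppressWarnings(
      min(vapply(1:20, function(s) {
        set.seed(s)
        kmeans(x, k, nstart = 5)$tot.withinss
      }, numeric(1))))
    expect_lte(dp$tot_withinss, lloyd + 1e-8)
  }
  # worked example: exact split and exact means
  km <- kmeans_1d_dp(c(1.0, 1.1, 0.9, 5.0, 5.2, 4.8), 2)
  expect_equal(km$centers, c(1.0, 5.0))
  expect_equal(as.integer(table(km$cluster)), c(3L, 3L))
  # order invariance
  x2 <- c(5.2, 1.0, 4.8, 1.1, 0.9, 5.0)
  km2 <- kmeans_1d_dp(x2, 2)
  expect_equal(km2$centers, km$centers)
})

test_that("the WSS curve is monotone and the elbow finds planted stages", {
  set.seed(7)
  vols <- exp(rnorm(40, rep(log(c(500, 1000, 2000, 4000)), each = 10), 0.1))
  sm <- wss_curve_and_elbow(vols, 8)
  expect_true(all(diff(sm$wss$wss) <= 1e-9))
  expect_equal(sm$suggested_k, 4L)
  expect_false(sm$low_confidence)
  # a single tight cluster has no pronounced elbow
  one <- exp(rnorm(40, log(1000), 0.1))
  sm1 <- wss_curve_and_elbow(one, 8)
  expect_true(sm1$low_confidence)
  # stage assignment recovers the planted grouping
  st <- assign_stages(vols, 4)
  expect_gte(mean(st$assignments == rep(1:4, each = 10)), 0.95)
  expect_true(all(diff(st$means) > 0))
  # stage-0 organs are excluded but kept in the output
  st0 <- assign_stages(c(100, vols), 4, stage0_mask = c(TRUE, rep(FALSE, 40)))
  expect_equal(st0$assignments[1], 0L)
  expect_equal(st0$assignments[-1], st$assignments)
})

test_that("Mann-Whitney p-values match full enumeration when exact", {
  expect_equal(mann_whitney_u(1:3, 4:6)$p_value, 0.1)
  expect_equal(mann_whitney_u(1:3, 4:6)$statistic, 0)
  set.seed(3)
  for (rep in 1:20) {
    nx <- sample(2:5, 1); ny <- sample(2:5, 1)
    x <- round(rnorm(nx), 6); y <- round(rnorm(ny, 0.5), 6)
    expect_equal(mann_whitney_u(x, y)$p_value, mw_exact_oracle(x, y),
                 tolerance = 1e-10)
  }
  # symmetry under sample swap
  x <- rnorm(6); y <- rnorm(5)
  expect_equal(mann_whitney_u(x, y)$p_value, mann_whitney_u(y, x)$p_value)
  # the large-sample path tracks the exact path at n = 10 + 10
  set.seed(9)
  x <- rnorm(10); y <- rnorm(10, 0.8)
  p_exact <- wilcox.test(x, y, exact = TRUE)$p.value
  p_approx <- suppressWarnings(
    wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  expect_lt(abs(p_exact - p_approx), 0.01)
  expect_equal(mann_whitney_u(c(x, 21:15), c(y, 31:25))$p_value,
               suppressWarnings(wilcox.test(c(x, 21:15), c(y, 31:25),
                                            exact = FALSE,
                                            correct = TRUE)$p.value))
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("Fisher's exact p equals hypergeometric table enumeration", {
  fisher_oracle <- function(tab) {
    m <- rowSums(tab); n <- colSums(tab)
    a_range <- max(0, n[1] - m[2]):min(m[1], n[1])
    probs <- stats::dhyper(a_range, m[1], m[2], n[1])
    obs <- stats::dhyper(tab[1, 1], m[1], m[2], n[1])
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))$p_value, 0.1)
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2))$p_value, 1)
  set.seed(5)
  for (rep in 1:25) {
    tab <- matrix(sample(0:15, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    p <- fisher_exact_2x2(tab)$p_value
    expect_equal(p, fisher_oracle(tab), tolerance = 1e-7)
    expect_equal(p, fisher_exact_2x2(t(tab))$p_value)
    expect_equal(p, fisher_exact_2x2(tab[2:1, ])$p_value)
  }
  zero <- fisher_exact_2x2(matrix(c(0, 0, 2, 3), 2, byrow = TRUE))
  expect_equal(zero$p_value, 1)
  expect_equal(zero$flag, "zero margin")
})

test_that("chi-square on three classes follows the closed form", {
  flat <- chi_square_contingency(matrix(10, 2, 3))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  hard <- chi_square_contingency(rbind(c(20, 10, 0), c(0, 10, 20)))
  expect_equal(hard$statistic, 40)
  expect_equal(hard$p_value, exp(-20), tolerance = 1e-12)
  perm <- chi_square_contingency(rbind(c(10, 0, 20), c(10, 20, 0)))
  expect_equal(perm$statistic, 40)
  expect_error(chi_square_contingency(rbind(c(0, 1), c(0, 2))), "merge")
})

test_that("tertile binning splits pooled samples into balanced classes", {
  tab <- bin_three_classes(1:9, 1:9)
  expect_equal(unname(tab), matrix(3L, 2, 3))
  shifted <- bin_three_classes(1:9, 1:9 + 100)
  # pooled tertiles put the top third (all from the shifted sample) in the
  # high class, and none of the unshifted sample reaches it
  expect_equal(unname(shifted["A", "high"]), 0L)
  expect_equal(unname(shifted["B", "high"]), 6L)
  expect_equal(unname(shifted["B", "low"]), 0L)
  expect_equal(sum(shifted), 18L)
  expect_error(bin_three_classes(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("group summaries report means, SEM and staged comparisons", {
  set.seed(11)
  tab <- empty_cell_table()
  mk <- function(class, stage, n, mu) tibble::tibble(
    ovule_id = sprintf("ov%d", stage), cell_label = seq_len(n),
    layer = "L2", contact_class = class,
    volume_um3 = rnorm(n, mu, mu / 10),
    semi_axis_a = NA_real_, semi_axis_b = NA_real_, semi_axis_c = NA_real_,
    norm_axis_a = NA_real_, norm_axis_b = NA_real_, norm_axis_c = NA_real_,
    two_axis_anisotropy = NA_real_, sphericity = NA_real_,
    prolate_ellipticity = NA_real_, oblate_ellipticity = NA_real_,
    surface_area_um2 = NA_real_, apical_wall_area_um2 = NA_real_,
    basal_wall_area_um2 = NA_real_, stage = as.integer(stage))
  tab <- dplyr::bind_rows(mk("central_L2", 1, 8, 500),
                          mk("central_L2", 2, 8, 1500),
                          mk("contact1", 1, 8, 500),
                          mk("contact1", 2, 8, 510))
  gs <- group_summary(tab)
  expect_equal(nrow(gs), 4L)
  expect_true(all(abs(gs$mean - c(500, 1500, 500, 510)) / gs$mean < 0.15))
  pc <- gs$p_vs_prev[gs$class == "central_L2" & gs$stage == 2]
  expect_lt(pc, 0.01)
  p1 <- gs$p_vs_prev[gs$class == "contact1" & gs$stage == 2]
  expect_gt(p1, 0.05)
  expect_equal(attr(gs, "correction"), "none (raw p-values)")
})

test_that("significance codes switch exactly at their thresholds", {
  expect_equal(significance_code(c(0.049, 0.051, 0.009, 0.0009, 9e-5, NA)),
               c("*", "ns", "**", "***", "****", NA))
})
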