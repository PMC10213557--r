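#' Globally optimal 1D k-means by dynamic programming
#'
#' Exact minimizer of the within-cluster sum of squares for 1D data: optimal
#' clusters are contiguous in sorted order, so the optimum is found by
#' dynamic programming over split points (O(k n^2) with prefix sums).
#' Deterministic — no seeding, unlike Lloyd-style iteration.
#'
#' @param x numeric vector.
#' @param k number of clusters (1 <= k <= length(x)).
#' @return list `cluster` (1-based assignment in the original order, clusters
#'   numbered by ascending mean), `centers` (ascending), `withinss`,
#'   `tot_withinss`.
#' @export
kmeans_1d_dp <- function(x, k) {
  n <- length(x)
  if (k < 1L || k > n) stop("k must be in 1..length(x)")
  ord <- order(x)
  s <- x[ord]
  cs <- cumsum(s)
  cs2 <- cumsum(s^2)
  segcost <- function(i, j) {          # sum of squares of s[i..j] about mean
    sm <- cs[j] - if (i > 1) cs[i - 1] else 0
    s2 <- cs2[j] - if (i > 1) cs2[i - 1] else 0
    s2 - sm^2 / (j - i + 1)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(1L, k, n)
  for (j in 1:n) D[1, j] <- segcost(1, j)
  if (k > 1) for (m in 2:k) {
    for (j in m:n) {
      best <- Inf; bi <- m
      for (i in m:j) {
        v <- D[m - 1, i - 1] + segcost(i, j)
        if (v < best) { best <- v; bi <- i }
      }
      D[m, j] <- best
      B[m, j] <- bi
    }
  }
  bounds <- integer(k + 1)
  bounds[k + 1] <- n
  j <- n
  for (m in k:1) {
    i <- if (m == 1) 1L else B[m, j]
    bounds[m] <- i
    j <- i - 1L
  }
  cl_sorted <- rep(NA_integer_, n)
  for (m in seq_len(k)) {
    to <- if (m == k) n else bounds[m + 1] - 1L
    cl_sorted[bounds[m]:to] <- m
  }
  cluster <- integer(n)
  cluster[ord] <- cl_sorted
  centers <- vapply(seq_len(k), function(m) mean(x[cluster == m]), numeric(1))
  withinss <- vapply(seq_len(k), function(m)
    sum((x[cluster == m] - centers[m])^2), numeric(1))
  list(cluster = cluster, centers = centers, withinss = withinss,
       tot_withinss = sum(withinss))
}

#' WSS curve and elbow suggestion for stage number selection
#'
#' Computes the globally optimal within-cluster sum of squares for each
#' k = 1..k_max (dynamic programming, so the curve is exactly
#' non-increasing) and suggests the elbow as the k maximizing the locally
#' normalized curvature `(WSS(k-1) - 2 WSS(k) + WSS(k+1)) / WSS(k)`.
#' Clustering is done on log volumes by default: central-cell growth across
#' stages is multiplicative, and the log scale keeps per-stage spread
#' comparable so late (large, variable) stages do not dominate the WSS. The
#' suggestion is advisory; a maximum curvature below 2 flags low confidence
#' (no pronounced elbow).
#'
#' @param values central L2 cell volumes, um^3.
#' @param k_max largest k scanned.
#' @param log_scale cluster `log(values)` instead of raw values.
#' @return a `stage_model` (no stage assignment yet): `wss` tibble
#'   (k, wss), `suggested_k`, `low_confidence`, `log_scale`.
#' @export
wss_curve_and_elbow <- function(values, k_max = 8L, log_scale = TRUE) {
  if (length(values) < 2L) stop("need at least 2 values")
  if (length(values) < k_max) k_max <- length(values)
  v <- if (log_scale) log(values) else values
  wss <- vapply(seq_len(k_max), function(k)
    kmeans_1d_dp(v, k)$tot_withinss, numeric(1))
  eps <- max(wss[1], .Machine$double.eps) * 1e-12
  curv <- rep(NA_real_, k_max)
  for (k in 2:(k_max - 1))
    curv[k] <- (wss[k - 1] - 2 * wss[k] + wss[k + 1]) / max(wss[k], eps)
  suggested <- which.max(curv)
  structure(list(
    wss = tibble::tibble(k = seq_len(k_max), wss = wss,
                         curvature = curv),
    suggested_k = as.integer(suggested),
    low_confidence = max(curv, na.rm = TRUE) < 2,
    log_scale = log_scale, k = NA_integer_, means = NULL,
    assignments = NULL),
    class = "stage_model")
}

#' Assign developmental stages by optimal 1D clustering
#'
#' Clusters central L2 cell volumes into `k` stages (globally optimal 1D
#' k-means, deterministic), numbered 1..k by ascending cluster mean. Organs
#' flagged Stage 0 (floret meristems, identified by independent
#' morphological criteria) are excluded from fitting and assigned stage 0.
#'
#' @param values central L2 cell volumes, um^3 (one per organ).
#' @param k number of stages (the pipeline default is 4).
#' @param stage0_mask logical; TRUE marks organs excluded from clustering.
#' @param log_scale cluster on the log scale (see [wss_curve_and_elbow()]).
#' @return a `stage_model`: `assignments` (0 for excluded organs), `means`
#'   (raw-scale cluster means, strictly increasing), `k`, `wss` curve slot
#'   empty.
#' @export
assign_stages <- function(values, k = 4L, stage0_mask = NULL,
                          log_scale = TRUE) {
  n <- length(values)
  if (is.null(stage0_mask)) stage0_mask <- rep(FALSE, n)
  use <- !stage0_mask
  if (k > sum(use)) stop("k exceeds the number of non-excluded organs")
  v <- if (log_scale) log(values[use]) else values[use]
  km <- kmeans_1d_dp(v, k)
  assignments <- integer(n)
  assignments[use] <- km$cluster
  means <- vapply(seq_len(k), function(m)
    mean(values[use][km$cluster == m]), numeric(1))
  structure(list(k = as.integer(k), means = means,
                 assignments = assignments, wss = NULL,
                 suggested_k = NA_integer_, low_confidence = NA,
                 log_scale = log_scale),
            class = "stage_model")
}

#' @exportS3Method base::print
print.stage_model <- function(x, ...) {
  if (!is.null(x$assignments)) {
    cat(sprintf("<stage_model> k = %d stages, cluster means (um^3): %s\n",
                x$k, paste(signif(x$means, 4), collapse = ", ")))
    cat("  organs per stage:",
        paste(names(table(x$assignments)), table(x$assignments),
              sep = "=", collapse = " "), "\n")
  } else {
    cat(sprintf("<stage_model> WSS curve (k <= %d), suggested k = %d%s\n",
                max(x$wss$k), x$suggested_k,
                if (isTRUE(x$low_confidence)) " (low confidence)" else ""))
  }
  invisible(x)
}

#' Significance code for a p-value
#'
#' Standard ladder: `ns` (p >= 0.05), `*` (< 0.05), `**` (< 0.01),
#' `***` (< 0.001), `****` (< 0.0001).
#'
#' @param p p-value(s).
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 1e-4 ~ "****", p < 1e-3 ~ "***",
                   p < 1e-2 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

test_result <- function(test, statistic, p, n, flag = NA_character_) {
  tibble::tibble(test = test, statistic = statistic,
                 p_value = p, n = list(n),
                 sig_code = significance_code(p), flag = flag)
}

#' Mann-Whitney U test (two-sided)
#'
#' U statistic with midranks for ties. p-value paths: exact by full
#' enumeration when `n_x + n_y <= 20` and the pooled sample is tie-free;
#' seeded Monte Carlo permutation (20,000 draws) for small tied samples;
#' normal approximation with tie and continuity correction otherwise.
#'
#' @param x,y numeric samples.
#' @param n_permutations Monte Carlo draws for the tied small-sample path.
#' @param seed seed for the permutation path.
#' @return one-row tibble: test, statistic (U of `x`), p_value, n, sig_code.
#' @export
mann_whitney_u <- function(x, y, n_permutations = 20000L, seed = 1L) {
  if (length(x) < 1L || length(y) < 1L) stop("empty sample")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (nx + ny <= 20 && !ties) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
  } else if (nx + ny <= 20 && ties) {
    p <- with_seed(seed, {
      pooled <- c(x, y)
      uobs <- U
      dev_obs <- abs(uobs - nx * ny / 2)
      hits <- 0L
      for (b in seq_len(n_permutations)) {
        idx <- sample.int(nx + ny, nx)
        rb <- rank(pooled)           # midranks fixed; resample group labels
        ub <- sum(rb[idx]) - nx * (nx + 1) / 2
        if (abs(ub - nx * ny / 2) >= dev_obs - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_permutations + 1)
    })
  } else {
    p <- suppressWarnings(
      wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
  }
  test_result("mann_whitney_u", U, min(p, 1), c(nx = nx, ny = ny))
}

#' Fisher's exact test on a 2x2 table (two-sided)
#'
#' Two-sided p as the sum of hypergeometric probabilities (margins fixed) of
#' every table at most as probable as the observed one. A zero margin makes
#' the table degenerate: p = 1 with a flag.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return one-row tibble (statistic = odds ratio estimate).
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0),
            all(table == round(table)))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    return(test_result("fisher_exact", NA_real_, 1, sum(table),
                       flag = "zero margin"))
  ft <- fisher.test(table)
  test_result("fisher_exact", unname(ft$estimate), ft$p.value, sum(table))
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson statistic with `df = (rows - 1)(cols - 1)` and upper-tail
#' p-value; all expected counts must be positive.
#'
#' @param observed matrix of counts (e.g. 2x3 anisotropy classes).
#' @return one-row tibble.
#' @export
chi_square_contingency <- function(observed) {
  observed <- as.matrix(observed)
  expd <- outer(rowSums(observed), colSums(observed)) / sum(observed)
  if (any(expd <= 0))
    stop("expected count of 0; merge classes before testing")
  ct <- suppressWarnings(chisq.test(observed, correct = FALSE))
  test_result("chi_square", unname(ct$statistic), ct$p.value, sum(observed))
}

#' Bin two samples into three pooled-tertile classes
#'
#' Class boundaries are the tertiles of the pooled values; returns the 2x3
#' count table (rows = groups) used for the chi-square comparison of
#' anisotropy distributions before vs at division.
#'
#' @param values_a,values_b numeric samples.
#' @return 2x3 integer matrix, rows named A/B, columns low/mid/high.
#' @export
bin_three_classes <- function(values_a, values_b) {
  pooled <- c(values_a, values_b)
  if (length(pooled) < 6L) stop("need a pooled n of at least 6")
  q <- quantile(pooled, c(1, 2) / 3, names = FALSE)
  if (diff(q) <= 0) stop("degenerate tertiles (massive ties)")
  brk <- c(-Inf, q, Inf)
  ta <- table(cut(values_a, brk))
  tb <- table(cut(values_b, brk))
  out <- rbind(A = as.integer(ta), B = as.integer(tb))
  colnames(out) <- c("low", "mid", "high")
  out
}

#' Per-class per-stage descriptor summary with consecutive-stage tests
#'
#' For every (cell class, stage) group: mean, SEM (`sd / sqrt(n)`) and n of
#' the chosen descriptor, plus a Mann-Whitney test between each pair of
#' consecutive stages within the class with its significance code. Groups
#' with n < 2 get no SEM and their tests are skipped with a flag. p-values
#' are reported raw (no multiple-testing correction), with this noted in the
#' output attribute `correction`.
#'
#' @param cell_table a validated cell table with a non-NA `stage` column.
#' @param descriptor column to summarise (default `volume_um3`).
#' @param class_column grouping column (default `contact_class`).
#' @return tibble: class, stage, n, mean, sem, p_vs_prev, sig_code, flag.
#' @export
group_summary <- function(cell_table, descriptor = "volume_um3",
                          class_column = "contact_class") {
  tab <- cell_table[!is.na(cell_table[[descriptor]]) &
                      !is.na(cell_table$stage), ]
  grp <- tab |>
    dplyr::group_by(class = .data[[class_column]], stage = .data$stage) |>
    dplyr::summarise(n = dplyr::n(),
                     mean = mean(.data[[descriptor]]),
                     sem = if (dplyr::n() >= 2)
                       sd(.data[[descriptor]]) / sqrt(dplyr::n())
                     else NA_real_,
                     .groups = "drop") |>
    dplyr::arrange(.data$class, .data$stage)
  grp$p_vs_prev <- NA_real_
  grp$flag <- NA_character_
  for (i in seq_len(nrow(grp))) {
    prev <- which(grp$class == grp$class[i] & grp$stage == grp$stage[i] - 1L)
    if (length(prev) != 1L) next
    xa <- tab[[descriptor]][tab[[class_column]] == grp$class[i] &
                              tab$stage == grp$stage[i] - 1L]
    xb <- tab[[descriptor]][tab[[class_column]] == grp$class[i] &
                              tab$stage == grp$stage[i]]
    if (length(xa) < 2L || length(xb) < 2L) {
      grp$flag[i] <- "test skipped (n < 2)"
      next
    }
    grp$p_vs_prev[i] <- mann_whitney_u(xa, xb)$p_value
  }
  grp$sig_code <- significance_code(grp$p_vs_prev)
  attr(grp, "correction") <- "none (raw p-values)"
  grp
}

# run code with a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
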