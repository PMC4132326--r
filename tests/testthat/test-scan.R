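test_that("threshold formulas match direct evaluation", {
  # hand evaluation of the gene-count threshold formulas
  f_hand <- function(n) 0.12 * 1600 / n - (n / 40000)^18
  c_hand <- function(n) 160 - (15 / 20000 + 14 / 18400) / 2 * n
  for (n in c(2, 118, 1416, 1600, 20000)) {
    expect_equal(f_threshold(n), f_hand(n), tolerance = 1e-12)
    expect_equal(curvature_threshold(n), c_hand(n), tolerance = 1e-12)
  }
  # frozen spot values
  expect_equal(f_threshold(1416), 0.1355932, tolerance = 1e-6)
  expect_equal(f_threshold(1600), 0.12, tolerance = 1e-6)
  expect_equal(curvature_threshold(1416), 158.9303, tolerance = 1e-4)
  expect_equal(curvature_threshold(20000), 144.8913, tolerance = 1e-4)
  # degenerate regimes raise configuration errors
  expect_error(f_threshold(40000), "degenerate")
  expect_error(f_threshold(1), ">= 2")
  expect_error(curvature_threshold(250000), "degenerate")
})

test_that("scan_pair classifies planted pairs by construction", {
  set.seed(21)
  n <- 60
  x <- seq(-1, 1, length.out = n)
  vals <- rbind(
    GA = x + rnorm(n, 0, 0.05),
    GB = x + rnorm(n, 0, 0.05),
    GC = exp(3 * (x + 1) / 2),
    GD = rnorm(n),
    GE = rnorm(n))
  colnames(vals) <- paste0("S", 1:n)
  m <- standardize(expression_matrix(vals))
  cfg <- scan_config(f_threshold_override = 0.3,
                     curvature_threshold_override = 158.93)
  lin <- scan_pair(m, "GA", "GB", cfg, f_thr = 0.3, curvature_thr = 158.93)
  expect_identical(lin$relation_class, "linear")
  expect_identical(lin$curve_type, "LIN_POS")
  expect_identical(lin$n_curvature_points, 0L)

  nl <- scan_pair(m, "GA", "GC", cfg, f_thr = 0.3, curvature_thr = 158.93)
  expect_identical(nl$relation_class, "nonlinear")
  expect_identical(nl$curve_type, "EXP_POS")

  rej <- scan_pair(m, "GD", "GE", cfg, f_thr = 0.3, curvature_thr = 158.93)
  expect_identical(rej$relation_class, "rejected")
  expect_error(scan_pair(m, "GA", "nope", cfg), "unknown gene")
})

test_that("scan_all emits one canonical record per unordered pair", {
  set.seed(5)
  vals <- matrix(rnorm(5 * 30), 5, 30,
                 dimnames = list(paste0("G", 1:5), paste0("S", 1:30)))
  scan <- scan_all(expression_matrix(vals),
                   scan_config(online_correction = FALSE))
  expect_equal(nrow(scan$table), choose(5, 2))
  expect_true(all(scan$table$gene_a < scan$table$gene_b))
  expect_false(any(duplicated(scan$table[, c("gene_a", "gene_b")])))
  # accepted pairs respect the threshold in force
  acc <- scan$table$relation_class != "rejected"
  expect_true(all(scan$table$f[acc] <= scan$state$current_f_threshold))
  # linear implies no curvature points
  lin <- scan$table$relation_class == "linear"
  expect_true(all(scan$table$n_curvature_points[lin] == 0))
})

test_that("pairs without enough complete samples are skipped with a reason", {
  set.seed(8)
  vals <- matrix(rnorm(3 * 25), 3, 25,
                 dimnames = list(paste0("G", 1:3), paste0("S", 1:25)))
  vals["G1", 1:10] <- NA  # G1 pairs have only 15 complete samples
  scan <- scan_all(expression_matrix(vals),
                   scan_config(online_correction = FALSE))
  expect_equal(nrow(scan$table), 1L)  # only G2-G3 analysable
  expect_equal(nrow(scan$skipped), 2L)
  expect_match(scan$skipped$reason, "complete samples", all = TRUE)
})

test_that("tightening the f threshold never adds accepted pairs", {
  set.seed(31)
  n <- 40
  x <- seq(-1, 1, length.out = n)
  vals <- rbind(G1 = x + rnorm(n, 0, 0.05), G2 = x + rnorm(n, 0, 0.1),
                G3 = exp(x) + rnorm(n, 0, 0.2), G4 = rnorm(n), G5 = rnorm(n),
                G6 = x^2 + rnorm(n, 0, 0.3))
  colnames(vals) <- paste0("S", 1:n)
  m <- expression_matrix(vals)
  prev <- NULL
  for (thr in c(1, 0.5, 0.2, 0.05, 0.001)) {
    scan <- scan_all(m, scan_config(f_threshold_override = thr,
                                    curvature_threshold_override = 158.93,
                                    online_correction = FALSE))
    acc <- with(scan$table, paste(gene_a, gene_b)[relation_class != "rejected"])
    if (!is.null(prev)) expect_true(all(acc %in% prev))
    prev <- acc
  }
})

test_that("online threshold correction follows the projection rule", {
  st <- function(done, passed, thr)
    list(n_pairs_total = 1000, n_pairs_done = done, n_passed = passed,
         current_f_threshold = thr)
  band <- c(100, 400)
  # projected 2x above the band: threshold strictly decreases
  expect_lt(update_threshold_online(st(100, 80, 0.2), band, 0.5), 0.2)
  expect_equal(update_threshold_online(st(100, 80, 0.2), band, 0.5), 0.19)
  # inside the band: unchanged
  expect_equal(update_threshold_online(st(100, 20, 0.2), band, 0.5), 0.2)
  # below the band: loosened but capped at the formula ceiling
  expect_equal(update_threshold_online(st(100, 5, 0.2), band, 0.5), 0.21)
  expect_equal(update_threshold_online(st(100, 5, 0.499), band, 0.5), 0.5)
  # scripted 10-checkpoint scenario equals a hand-simulated sequence
  thr <- 0.3
  passed <- c(90, 85, 80, 20, 15, 40, 41, 42, 43, 44)
  hand <- thr
  for (i in 1:10) {
    proj <- passed[i] / (i * 100) * 1000
    hand <- if (proj > band[2]) hand * 0.95
            else if (proj < band[1]) min(hand * 1.05, 0.5) else hand
    thr <- update_threshold_online(st(i * 100, passed[i], thr), band, 0.5)
    expect_equal(thr, hand, tolerance = 1e-12)
  }
})

test_that("scan is a pure function of the matrix when correction is off", {
  set.seed(13)
  vals <- matrix(rnorm(4 * 30), 4, 30,
                 dimnames = list(paste0("G", 1:4), paste0("S", 1:30)))
  m <- expression_matrix(vals)
  cfg <- scan_config(f_threshold_override = 0.5,
                     curvature_threshold_override = 158.93,
                     online_correction = FALSE)
  a <- scan_all(m, cfg)
  b <- scan_all(m, cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$state, b$state)
})

test_that("relationship tables survive a write/read round trip", {
  res <- e2e_result()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_relationships(res$scan, path)
  tab <- read_relationships(path)
  expect_equal(nrow(tab), nrow(res$scan$table))
  expect_equal(tab$f, res$scan$table$f, tolerance = 1e-12)
  expect_identical(tab$curve_type, res$scan$table$curve_type)
  # malformed file is a schema error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", bad)
  expect_error(read_relationships(bad), "missing column")
})
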