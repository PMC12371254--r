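make_profiles <- function(props, states) {
  data.frame(donor_id = sprintf("d%02d", seq_along(props)), state = states,
             n_cells = 100L, n_risk = as.integer(round(props * 100)),
             proportion = props, stringsAsFactors = FALSE)
}

test_that("donor proportions are exact cell-count ratios", {
  sim <- small_sim()
  risk <- data.frame(cell_id = sim$cohort$cells$cell_id,
                     is_risk = sim$truth$cells$is_risk_true,
                     threshold = 0.5, method = "fixed", cell_type = "beta")
  prof <- donor_risk_proportions(risk, sim$cohort)
  expect_equal(prof$proportion, prof$n_risk / prof$n_cells)
  expect_equal(sum(prof$n_cells), nrow(sim$cohort$counts))
  m <- match(prof$donor_id, sim$truth$donor_fraction$donor_id)
  expect_equal(prof$proportion, sim$truth$donor_fraction$true_fraction[m])

  none <- risk; none$is_risk <- FALSE
  expect_true(all(donor_risk_proportions(none, sim$cohort)$proportion == 0))
  bad <- risk; bad$cell_id[1] <- "nope"
  expect_error(donor_risk_proportions(bad, sim$cohort),
               class = "cellrisk_integrity_error")
})

test_that("rule staging follows the 10%/20% bands and partitions [0,1]", {
  expect_identical(stage_by_rule(0.05), 0L)
  expect_identical(stage_by_rule(0.15), 1L)
  expect_identical(stage_by_rule(0.25), 2L)
  # closed preT2D band at both edges
  expect_identical(stage_by_rule(c(0.10, 0.20)), c(1L, 1L))
  p <- seq(0, 1, by = 0.001)
  s <- stage_by_rule(p)
  expect_true(all(s %in% 0:2))
  expect_identical(s, sort(s))   # monotone in p
  expect_error(stage_by_rule(0.5, 0.3, 0.2), class = "cellrisk_value_error")
})

test_that("roc_auc equals brute-force pairwise concordance", {
  r <- roc_auc(c(1, 2, 3), c(0, 0, 1))
  expect_equal(r$auc, 1.0)
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5))$auc, 0.5)
  expect_equal(r$curve[1, ], data.frame(fpr = 0, tpr = 0))
  expect_equal(unlist(r$curve[nrow(r$curve), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$curve$tpr) >= 0) && all(diff(r$curve$fpr) >= 0))

  set.seed(7)
  for (i in 1:100) {
    n <- sample(10:200, 1)
    s <- sample(round(runif(n), 2))          # induces ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) next
    brute <- mean(outer(s[y == 1], s[y == 0],
                        function(a, b) (a > b) + 0.5 * (a == b)))
    expect_lt(abs(roc_auc(s, y)$auc - brute), 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), class = "cellrisk_value_error")
})

test_that("score negation mirrors the AUC for tie-free scores", {
  set.seed(12)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1:2] <- c(0, 1)
  expect_equal(roc_auc(s, y)$auc + roc_auc(-s, y)$auc, 1)
})

test_that("bootstrap CI is deterministic, degenerate when separable, and calibrated", {
  s <- c(1:5, 11:15); y <- rep(c(0, 1), each = 5)
  ci <- bootstrap_auc_ci(s, y, n_boot = 200, seed = 3)
  expect_equal(c(ci$lower, ci$upper), c(1, 1))
  ci2 <- bootstrap_auc_ci(s, y, n_boot = 200, seed = 3)
  expect_identical(ci, ci2)

  # coverage of the large-sample AUC over repeated small datasets
  set.seed(41)
  mu <- 1.2
  true_auc <- pnorm(mu / sqrt(2))
  hits <- vapply(1:200, function(i) {
    s <- c(rnorm(20), rnorm(20, mean = mu))
    y <- rep(c(0, 1), each = 20)
    ci <- bootstrap_auc_ci(s, y, n_boot = 400, seed = i)
    ci$lower <= true_auc && true_auc <= ci$upper
  }, logical(1))
  expect_gte(mean(hits), 0.88)
  expect_lte(mean(hits), 0.99)
})

test_that("pearson_assoc matches the closed-form t transform", {
  out <- pearson_assoc(1:10, 2 * (1:10) + 1)
  expect_equal(out$r, 1.0)

  x <- c(1, 2, 4, 6, 9); y <- c(2, 1, 5, 4, 8)
  out <- pearson_assoc(x, y)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((5 - 2) / (1 - r^2))
  expect_lt(abs(out$r - r), 1e-10)
  expect_lt(abs(out$p - 2 * pt(-abs(tstat), df = 3)), 1e-10)

  # pairwise-complete behavior reports n used
  out <- pearson_assoc(c(x, NA), c(y, 1))
  expect_equal(out$n, 5L)

  set.seed(2)
  out <- pearson_assoc(rnorm(1000), rnorm(1000))
  expect_lt(abs(out$r), 0.1)
  expect_error(pearson_assoc(1:2, 2:3), class = "cellrisk_value_error")
  expect_error(pearson_assoc(rep(1, 5), 1:5), class = "cellrisk_value_error")
})

test_that("group comparison reproduces the exact rank-sum null", {
  prof <- make_profiles(c(0.01, 0.02, 0.03, 0.11, 0.12, 0.13, 0.4, 0.5, 0.6),
                        rep(c(0L, 1L, 2L), each = 3))
  out <- group_compare(prof)
  # fully separated groups of 3: two-sided exact p = 2 / C(6,3) = 0.1
  expect_equal(out$p, rep(0.1, 3))
  expect_equal(out$p_adj, rep(0.1, 3))

  same <- make_profiles(rep(c(0.1, 0.2, 0.3), 3), rep(c(0L, 1L, 2L), each = 3))
  out <- group_compare(same)
  expect_true(all(out$p > 0.99))
  expect_error(group_compare(make_profiles(c(0.1, 0.2, 0.3), c(0L, 1L, 2L))),
               class = "cellrisk_value_error")
})

test_that("group comparison holds its size under the null", {
  set.seed(19)
  rej <- replicate(100, {
    prof <- make_profiles(runif(24, 0, 0.3), rep(c(0L, 1L, 2L), each = 8))
    group_compare(prof)$p < 0.05
  })
  expect_true(all(rowMeans(rej) <= 0.10))
})

test_that("bh_adjust matches a brute-force step-up reference", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  bh_ref <- function(p) {
    n <- length(p); o <- order(p, decreasing = TRUE)
    ro <- order(o)
    pmin(1, cummin(n / (n:1) * p[o]))[ro]
  }
  set.seed(23)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_identical(bh_adjust(p), bh_ref(p))
  }
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "cellrisk_value_error")
})

test_that("the margin classifier separates staged donors and is order-invariant", {
  prof <- make_profiles(c(0.02, 0.03, 0.04, 0.05, 0.12, 0.13, 0.14, 0.15,
                          0.25, 0.28, 0.30, 0.33), rep(c(0L, 1L, 2L), each = 4))
  fs <- fit_stage_classifier(prof)
  expect_equal(fs$pairs$auc, rep(1, 3))

  shuf <- prof[sample(nrow(prof)), ]
  fs2 <- fit_stage_classifier(shuf)
  expect_equal(fs2$pairs$auc, fs$pairs$auc)

  expect_error(fit_stage_classifier(prof[prof$state != 1, ]),
               class = "cellrisk_value_error")
})

test_that("the margin classifier is at chance on permuted labels", {
  set.seed(37)
  prof <- make_profiles(runif(60, 0, 0.4), sample(rep(c(0L, 1L, 2L), each = 20)))
  fs <- fit_stage_classifier(prof)
  expect_true(all(fs$pairs$auc >= 0.3 & fs$pairs$auc <= 0.7))
})
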