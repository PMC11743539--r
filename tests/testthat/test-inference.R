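test_that("design matrix encodes group and nuisance columns, checking rank", {
  cov <- data.frame(subject_id = letters[1:6],
                    group = rep(c("control", "treatment"), each = 3),
                    age = c(20, 21, 22, 23, 24, 25),
                    mean_fd = c(0.1, 0.15, 0.2, 0.1, 0.12, 0.3))
  x <- design_matrix(cov)
  expect_equal(colnames(x), c("intercept", "group", "age", "mean_fd"))
  expect_equal(unname(x[, "group"]), c(0, 0, 0, 1, 1, 1))
  cov$mean_fd <- cov$age  # collinear with age
  expect_error(design_matrix(cov), "collinear")
})

test_that("edgewise GLM without covariates equals the pooled two-sample t", {
  ch <- shifted_cohort(8, 9, 6, seed = 21)
  x <- design_matrix(ch$covariates, use_covariates = FALSE)
  res <- edgewise_glm(ch$z_matrices, x)
  em <- edge_matrix(ch$z_matrices)
  grp <- ch$covariates$group == "treatment"
  for (e in c(1, 7, 15)) {
    tt <- t.test(em$values[grp, e], em$values[!grp, e], var.equal = TRUE)
    expect_equal(res$t[e], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("equal group means give a zero group statistic", {
  # subjects come in pairs with identical matrices, one per group, so the
  # group means coincide exactly while residual variance stays positive
  set.seed(20)
  base <- replicate(3, {
    m <- matrix(0, 4, 4)
    m[upper.tri(m)] <- rnorm(6, 0.3, 0.2)
    m + t(m)
  }, simplify = FALSE)
  z <- lapply(1:6, function(s) {
    zmatrix(base[[ceiling(s / 2)]], subject_id = paste0("s", s))
  })
  cov <- data.frame(subject_id = paste0("s", 1:6),
                    group = rep(c("control", "treatment"), 3),
                    age = 22, mean_fd = 0.1)
  res <- edgewise_glm(z, design_matrix(cov, use_covariates = FALSE))
  expect_true(all(abs(res$t) < 1e-10))
  expect_true(all(abs(res$effect) < 1e-12))
})

test_that("edgewise GLM concentrates signal on planted edges", {
  planted <- rbind(c(1, 2), c(3, 4), c(5, 6))
  ch <- shifted_cohort(20, 20, 8, shift_edges = planted, shift = 0.5,
                       noise_sd = 0.1, seed = 22)
  res <- edgewise_glm(ch$z_matrices, design_matrix(ch$covariates))
  top3 <- order(-abs(res$t))[1:3]
  got <- res[top3, c("i", "j")]
  expect_setequal(paste(got$i, got$j), paste(planted[, 1], planted[, 2]))
})

test_that("edgewise permutation FDR flags planted edges and respects BH", {
  planted <- rbind(c(1, 2), c(1, 3))
  ch <- shifted_cohort(15, 15, 5, shift_edges = planted, shift = 0.6,
                       noise_sd = 0.1, seed = 23)
  res <- edgewise_fdr(ch$z_matrices, design_matrix(ch$covariates),
                      n_perm = 500L, seed = 1L, q = 0.05)
  expect_true(all(res$significant[res$i == 1 & res$j %in% c(2, 3)]))
  expect_true(all(res$p_fdr >= res$p_perm - 1e-15))
  expect_identical(res$significant, res$p_fdr <= 0.05)
  # permutation p floor
  expect_gte(min(res$p_perm), 1 / 501)
})

test_that("permutation shuffles are seed-reproducible and shared", {
  ch <- shifted_cohort(6, 6, 5, seed = 24)
  x <- design_matrix(ch$covariates)
  r1 <- edgewise_fdr(ch$z_matrices, x, n_perm = 100L, seed = 5L)
  r2 <- edgewise_fdr(ch$z_matrices, x, n_perm = 100L, seed = 5L)
  expect_identical(r1, r2)
})

test_that("NBS recovers a planted connected component", {
  comp_edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(5, 1))
  ch <- shifted_cohort(20, 20, 10, shift_edges = comp_edges, shift = 0.5,
                       noise_sd = 0.1, seed = 25)
  res <- nbs_fwe(ch$z_matrices, design_matrix(ch$covariates),
                 primary_p = 0.001, n_perm = 200L, seed = 2L)
  expect_gte(nrow(res$components), 1L)
  expect_equal(res$components$size[1], 5)
  expect_lte(res$components$p_fwe[1], 0.05)
  got <- res$component_edges[res$component_edges$component ==
                               res$components$component[1], c("i", "j")]
  expect_setequal(paste(got$i, got$j),
                  paste(pmin(comp_edges[, 1], comp_edges[, 2]),
                        pmax(comp_edges[, 1], comp_edges[, 2])))
  # estimator floor: observed max never exceeded in any permutation
  expect_equal(res$components$p_fwe[1], 1 / 201, tolerance = 1e-12)
})

test_that("NBS with no suprathreshold edge returns an empty result", {
  ch <- shifted_cohort(6, 6, 5, seed = 26)
  res <- nbs_fwe(ch$z_matrices, design_matrix(ch$covariates),
                 primary_p = 1e-6, n_perm = 100L, seed = 3L)
  expect_equal(nrow(res$components), 0L)
})

test_that("summary t reproduces printed demographics and scales correctly", {
  # worked examples from the published summary table
  bdi <- summary_t(6.15, 5.55, 67, 5.18, 5.59, 72)
  expect_lt(abs(bdi$t - 1.025), 0.01)
  asq <- summary_t(21.54, 8.87, 67, 20.21, 7.42, 72)
  expect_lt(abs(asq$t - 0.954), 0.01)
  expect_equal(summary_t(5, 1, 10, 5, 2, 12)$t, 0)
  # doubling both group sizes scales t by about sqrt(2)
  t1 <- summary_t(10, 3, 30, 9, 3, 30)$t
  t2 <- summary_t(10, 3, 60, 9, 3, 60)$t
  expect_equal(t2 / t1, sqrt(2), tolerance = 1e-6)
  expect_true(is.na(summary_t(5, 0, 10, 5, 0, 10)$t))
})

test_that("Benjamini-Hochberg decision rule matches the hand-worked case", {
  p <- c(0.001, 0.02, 0.04, 0.2)
  rejected <- stats::p.adjust(p, method = "BH") <= 0.05
  expect_identical(rejected, c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(sum(stats::p.adjust(rep(1, 5), "BH") <= 0.05), 0L)
})

test_that("AUC group tests find planted nodal effects, null cells behave", {
  set.seed(27)
  n1 <- 15; n2 <- 15
  nodes <- paste0("R", 1:8)
  subj <- sprintf("s%02d", 1:(n1 + n2))
  grp <- rep(c("control", "treatment"), c(n1, n2))
  rows <- expand.grid(subject_id = subj, node = nodes,
                      stringsAsFactors = FALSE)
  rows$metric <- "clustering"
  rows$auc <- rnorm(nrow(rows), 0.3, 0.05)
  planted_node <- "R3"
  sel <- rows$node == planted_node & rows$subject_id %in% subj[grp == "treatment"]
  rows$auc[sel] <- rows$auc[sel] + 0.2
  cov <- data.frame(subject_id = subj, group = grp, age = 22, mean_fd = 0.1)
  res <- auc_group_test(rows, cov, n_perm = 400L, seed = 4L)
  expect_true(res$significant[res$node == planted_node])
  expect_gt(res$mean_diff[res$node == planted_node], 0.1)
  expect_gt(res$r_pb[res$node == planted_node], 0.5)
  expect_lt(mean(res$significant[res$node != planted_node]), 0.3)
})

test_that("identical groups give t = 0 and permutation p near 1", {
  nodes <- paste0("R", 1:3)
  subj <- sprintf("s%02d", 1:12)
  rows <- expand.grid(subject_id = subj, node = nodes,
                      stringsAsFactors = FALSE)
  rows$metric <- "degree"
  # first six subjects are controls, last six treatments, with the same
  # six AUC values in each group
  rows$auc <- rep(rep(seq(0.1, 0.6, length.out = 6), 2), length(nodes))
  cov <- data.frame(subject_id = subj,
                    group = rep(c("control", "treatment"), each = 6),
                    age = 22, mean_fd = 0.1)
  res <- auc_group_test(rows, cov, n_perm = 200L, seed = 5L)
  expect_true(all(abs(res$t) < 1e-12))
  expect_true(all(res$p_perm > 0.9))
})

test_that("degenerate zero-variance cells are excluded from the FDR family", {
  subj <- sprintf("s%02d", 1:10)
  rows <- expand.grid(subject_id = subj, node = c("R1", "R2"),
                      stringsAsFactors = FALSE)
  rows$metric <- "degree"
  rows$auc <- ifelse(rows$node == "R1", 1, rnorm(nrow(rows)))
  cov <- data.frame(subject_id = subj,
                    group = rep(c("control", "treatment"), 5),
                    age = 22, mean_fd = 0.1)
  res <- auc_group_test(rows, cov, n_perm = 100L, seed = 6L)
  expect_true(is.na(res$t[res$node == "R1"]))
  expect_true(is.na(res$p_fdr[res$node == "R1"]))
  expect_false(is.na(res$p_fdr[res$node == "R2"]))
  expect_equal(attr(res, "n_degenerate"), 1L)
})
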