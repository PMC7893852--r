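binary_features <- function(...) {
  as.data.frame(lapply(list(...), function(v) factor(v, levels = c("0", "1"))))
}

test_that("a constant outcome yields a root-only tree", {
  feats <- binary_features(a = rep(c("0", "1"), 10))
  tree <- fit_chaid(feats, rep(TRUE, 20), chaid_params(min_node_size = 2))
  expect_true(tree$root$is_leaf)
  expect_equal(tree$root$prob_frail, 1)
})

test_that("a perfectly aligned binary feature splits with chi-square 20 at n = 20", {
  y <- rep(c(TRUE, FALSE), each = 10)
  feats <- binary_features(a = ifelse(y, "1", "0"))
  tree <- fit_chaid(feats, y, chaid_params(min_node_size = 2, max_depth = 2))
  expect_false(tree$root$is_leaf)
  expect_equal(tree$root$feature, "a")
  expect_equal(tree$root$statistic, 20) # all mass on the 2x2 diagonal
  expect_true(all(vapply(tree$root$children, `[[`, logical(1), "is_leaf")))
  preds <- predict(tree, feats)
  expect_identical(preds, y)
  expect_error(fit_chaid(data.frame(a = rnorm(20)), y), "not categorical")
})

test_that("category merging matches an independent greedy oracle on small features", {
  # independent re-implementation operating on the contingency table
  merge_oracle <- function(x, y, alpha) {
    groups <- lapply(sort(unique(x)), identity)
    repeat {
      if (length(groups) <= 2) break
      best_p <- -1; best_pair <- NULL
      for (i in seq_along(groups)) {
        for (j in seq_along(groups)) {
          if (j <= i) next
          sel <- x %in% c(groups[[i]], groups[[j]])
          gi <- x[sel] %in% groups[[i]]
          tab <- table(gi, y[sel])
          p <- if (any(dim(tab) < 2)) 1 else
            suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
          if (p > best_p) { best_p <- p; best_pair <- c(i, j) }
        }
      }
      if (best_p <= alpha) break
      groups[[best_pair[1]]] <- c(groups[[best_pair[1]]],
                                  groups[[best_pair[2]]])
      groups[[best_pair[2]]] <- NULL
    }
    groups
  }
  set.seed(99)
  for (rep in 1:20) {
    n <- 120
    x <- sample(letters[1:4], n, replace = TRUE)
    y <- runif(n) < ifelse(x %in% c("a", "b"), 0.7, 0.2)
    got <- frailscan:::merge_categories(x, y, 0.05)
    want <- merge_oracle(x, y, 0.05)
    canon <- function(gs) sort(vapply(gs, function(g)
      paste(sort(g), collapse = "+"), ""))
    expect_identical(canon(got), canon(want), label = paste("rep", rep))
  }
})

test_that("the Bonferroni multiplier is the Stirling partition count", {
  expect_equal(frailscan:::stirling2(4, 2), 7)
  expect_equal(frailscan:::stirling2(3, 2), 3)
  expect_equal(frailscan:::stirling2(5, 3), 25)
  expect_equal(frailscan:::stirling2(2, 2), 1)
})

test_that("predictions are invariant to row order", {
  set.seed(4)
  n <- 300
  a <- sample(c("0", "1"), n, replace = TRUE)
  b <- sample(c("0", "1"), n, replace = TRUE)
  y <- (a == "1" & b == "1") | runif(n) < 0.05
  feats <- binary_features(a = a, b = b)
  perm <- sample(n)
  t1 <- fit_chaid(feats, y, chaid_params(min_node_size = 5, max_depth = 2))
  t2 <- fit_chaid(feats[perm, ], y[perm],
                  chaid_params(min_node_size = 5, max_depth = 2))
  expect_identical(predict(t1, feats), predict(t2, feats))
})

test_that("bootstrap selection prefers the generating depth, ties go to simplicity", {
  set.seed(12)
  n <- 800
  a <- sample(c("0", "1"), n, replace = TRUE)
  b <- sample(c("0", "1"), n, replace = TRUE)
  y <- a == "1" & b == "1"
  feats <- binary_features(a = a, b = b)
  grid <- list(chaid_params(max_depth = 1, min_node_size = 10),
               chaid_params(max_depth = 2, min_node_size = 10))
  sel <- bootstrap_select(feats, y, grid, n_boot = 10, seed = 3)
  expect_equal(sel$max_depth, 2L)
  # pure noise: every candidate's tree is a root leaf, identical OOB error,
  # so the tie resolves to the simplest candidate
  y_noise <- runif(n) < 0.3
  feats_noise <- binary_features(a = sample(c("0", "1"), n, TRUE))
  grid2 <- list(chaid_params(max_depth = 2, min_node_size = 10),
                chaid_params(max_depth = 1, min_node_size = 10),
                chaid_params(max_depth = 1, min_node_size = 50))
  sel2 <- bootstrap_select(feats_noise, y_noise, grid2, n_boot = 8, seed = 5)
  expect_equal(sel2$max_depth, 1L)
  expect_equal(sel2$min_node_size, 50L)
  # a single-candidate grid returns that candidate
  only <- bootstrap_select(feats, y, grid[1], n_boot = 2, seed = 1)
  expect_equal(only$max_depth, 1L)
})

test_that("cross-validation pools out-of-fold predictions into one confusion matrix", {
  set.seed(9)
  n <- 200
  a <- sample(c("0", "1"), n, replace = TRUE)
  y <- a == "1"
  feats <- binary_features(a = a)
  rep10 <- cross_validate(feats, y, chaid_params(min_node_size = 5), k = 10,
                          seed = 2)
  expect_equal(rep10$sensitivity$est, 1)
  expect_equal(rep10$specificity$est, 1)
  expect_equal(sum(rep10$confusion), n)
  # leave-one-out equals the direct computation on a tiny set
  n2 <- 24
  a2 <- rep(c("0", "1"), each = n2 / 2)
  y2 <- a2 == "1"
  f2 <- binary_features(a = a2)
  loo <- cross_validate(f2, y2, chaid_params(min_node_size = 2), k = n2,
                        seed = 1)
  direct <- vapply(seq_len(n2), function(i) {
    fit <- fit_chaid(f2[-i, , drop = FALSE], y2[-i],
                     chaid_params(min_node_size = 2))
    predict(fit, f2[i, , drop = FALSE])
  }, logical(1))
  expect_equal(unname(loo$confusion["tp"]), sum(direct & y2))
  expect_equal(unname(loo$confusion["tn"]), sum(!direct & !y2))
})

test_that("validity metrics reproduce the reference confusion matrix", {
  vm <- validity_metrics(tp = 42, fp = 43, tn = 682, fn = 108)
  expect_equal(round(vm$sensitivity$est, 3), 0.280)
  expect_equal(round(vm$specificity$est, 3), 0.941)
  expect_equal(round(vm$npv$est, 3), 0.863)
  expect_equal(round(vm$ppv$est, 3), 0.494)
  # exact CI endpoints against the beta-quantile identity
  expect_equal(vm$sensitivity$lower, qbeta(0.025, 42, 150 - 42 + 1))
  expect_equal(vm$sensitivity$upper, qbeta(0.975, 42 + 1, 150 - 42))
  # a reported 21.0-36.0 interval for 42/150 is consistent with the exact
  # method to within rounding
  expect_lt(abs(100 * vm$sensitivity$lower - 21.0), 0.5)
  expect_lt(abs(100 * vm$sensitivity$upper - 36.0), 0.5)
  # perfect matrix: all 1, CIs inside [0,1]
  perfect <- validity_metrics(10, 0, 10, 0)
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    expect_equal(perfect[[m]]$est, 1)
    expect_true(perfect[[m]]$lower >= 0 && perfect[[m]]$upper == 1)
    expect_true(perfect[[m]]$lower <= perfect[[m]]$est)
  }
  # always-negative classifier: sensitivity 0, NPV = 1 - prevalence
  always_neg <- suppressWarnings(validity_metrics(0, 0, 70, 30))
  expect_equal(always_neg$sensitivity$est, 0)
  expect_equal(always_neg$npv$est, 0.7)
  expect_warning(validity_metrics(0, 0, 70, 30), "ppv")
  # CI width shrinks with n at a fixed proportion
  w1 <- validity_metrics(28, 72, 1, 72)$sensitivity
  w2 <- validity_metrics(280, 720, 1, 720)$sensitivity
  expect_lt(w2$upper - w2$lower, w1$upper - w1$lower)
})

test_that("a learned tree converts to an applicable case definition", {
  cfg <- plant_rule(sim_config(1500, seed = 31),
                    c("dementia_dx", "furosemide_rx"), 0.95, 0.03)
  g <- generate_cohort(cfg)
  rs <- build_reference_set(g$emr, g$truth, 2014)
  tree <- fit_chaid(rs$features, rs$labels, chaid_params(max_depth = 2))
  def <- as_case_definition(tree)
  expect_s3_class(def, "case_definition")
  expect_true(all(names(def$atoms) %in% names(reference_atoms())))
})
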