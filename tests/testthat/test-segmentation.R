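make_ts <- function(x, y) pcleQuant:::training_set(x, y)

test_that("collect_instances counts labelled pixels exactly", {
  ph <- quick_phantom(3, size = 96)
  st <- compute_features(ph$image, scales = c(1, 2))
  lab <- matrix(0L, 96, 96)
  fg <- which(ph$truth$true_mask)[1:10]
  bg <- which(!ph$truth$true_mask & ph$truth$fov_mask)[1:10]
  lab[fg] <- 1L; lab[bg] <- 2L
  ts <- collect_instances(st, lab)
  expect_equal(nrow(ts$x), 20)
  expect_equal(as.integer(table(ts$y)), c(10, 10))
  expect_error(collect_instances(st, matrix(0L, 96, 96)), "no labelled")
  lab2 <- lab; lab2[lab2 == 2L] <- 0L
  expect_error(collect_instances(st, lab2), "both classes")
  # counting property on random sparse labels
  set.seed(11)
  lab3 <- make_training_labels(ph$truth, 0.07, seed = 5)
  expect_equal(nrow(collect_instances(st, lab3)$x), sum(lab3 != 0))
})

test_that("undersampling balances classes without touching the minority", {
  set.seed(2)
  x <- matrix(rnorm(700 * 3), 700, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("background", "elastin"), c(500, 200))
  ts <- undersample(make_ts(x, y), seed = 3)
  expect_equal(as.integer(table(ts$y)), c(200, 200))
  # minority instances all retained
  expect_true(all(x[y == "elastin", 1] %in% ts$x[ts$y == "elastin", 1]))
  # the paper's ~2.5:1 imbalance rebalances to exactly 1
  x2 <- matrix(rnorm(350 * 2), 350, 2)
  y2 <- rep(c("background", "elastin"), c(250, 100))
  t2 <- undersample(make_ts(x2, y2), seed = 1)
  expect_equal(sum(t2$y == "background") / sum(t2$y == "elastin"), 1.0)
  # already balanced set is unchanged
  t3 <- make_ts(x2[c(1:100, 251:350), ], y2[c(1:100, 251:350)])
  expect_identical(undersample(t3, 1)$x, t3$x)
  # deterministic by seed
  expect_identical(undersample(make_ts(x, y), 3)$x, ts$x)
})

test_that("CFS drops a duplicated feature and beats every singleton", {
  set.seed(4)
  n <- 600
  cls <- rep(c("background", "elastin"), each = n / 2)
  informative <- ifelse(cls == "elastin", 1, 0) + rnorm(n, 0, 0.3)
  x <- cbind(f_inf = informative, f_dup = informative,
             f_noise = rnorm(n))
  sel <- select_features_cfs(make_ts(x, cls))
  expect_equal(sum(c("f_inf", "f_dup") %in% sel), 1)
  expect_false("f_noise" %in% sel)

  # exhaustive merit over all 7 non-empty subsets: selected >= any singleton
  disc <- apply(x, 2, pcleQuant:::discretize_ef)
  cint <- as.integer(factor(cls))
  su <- pcleQuant:::symmetrical_uncertainty
  merit_of <- function(sub) {
    k <- length(sub)
    rcf <- mean(vapply(sub, function(j) su(disc[, j], cint), numeric(1)))
    rff <- if (k < 2) 0 else
      mean(apply(utils::combn(sub, 2), 2,
                 function(p) su(disc[, p[1]], disc[, p[2]])))
    pcleQuant:::cfs_merit(k, rcf, rff)
  }
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(3, k, simplify = FALSE)), recursive = FALSE)
  merits <- vapply(subsets, merit_of, numeric(1))
  sel_idx <- sort(match(sel, colnames(x)))
  sel_merit <- merit_of(sel_idx)
  expect_gte(sel_merit + 1e-9, max(vapply(1:3, function(j) merit_of(j),
                                          numeric(1))))
  # greedy pick is the global optimum here
  expect_equal(sel_merit, max(merits), tolerance = 1e-9)
})

test_that("CFS result is invariant to feature order", {
  set.seed(5)
  n <- 400
  cls <- rep(c("background", "elastin"), each = n / 2)
  x <- cbind(a = ifelse(cls == "elastin", 2, 0) + rnorm(n),
             b = rnorm(n), c = ifelse(cls == "elastin", -1, 1) + rnorm(n))
  s1 <- select_features_cfs(make_ts(x, cls))
  s2 <- select_features_cfs(make_ts(x[, c(3, 1, 2)], cls))
  expect_setequal(s1, s2)
})

test_that("gain ratio: perfect predictor 1.0 and first; noise ~0; constant 0", {
  set.seed(6)
  n <- 10000
  cls <- rep(c("background", "elastin"), each = n / 2)
  x <- cbind(perfect = as.numeric(cls == "elastin"),
             noise = rnorm(n), const = rep(1, n))
  rk <- suppressWarnings(rank_information_gain_ratio(make_ts(x, cls)))
  expect_equal(rk$feature[1], "perfect")
  expect_equal(rk$gain_ratio[rk$feature == "perfect"], 1.0)
  expect_lt(rk$gain_ratio[rk$feature == "noise"], 0.01)
  expect_equal(rk$gain_ratio[rk$feature == "const"], 0)
})

test_that("forest separates Gaussian blobs and is seed-deterministic", {
  set.seed(7)
  n <- 400
  cls <- rep(c("background", "elastin"), each = n / 2)
  x <- cbind(u = rnorm(n) + ifelse(cls == "elastin", 4, 0),
             v = rnorm(n))
  ts <- make_ts(x, cls)
  model <- train_forest(ts, n_trees = 50, seed = 1)
  p <- pcleQuant:::predict_prob(model, x)
  acc <- mean((p >= 0.5) == (cls == "elastin"))
  expect_gte(acc, 0.99)
  model2 <- train_forest(ts, n_trees = 50, seed = 1)
  expect_identical(pcleQuant:::predict_prob(model2, x), p)
  expect_error(train_forest(ts, n_trees = 0), "n_trees")
})

test_that("more trees do not hurt held-out AUC on noisy data", {
  set.seed(8)
  wins <- 0
  for (rep in 1:20) {
    n <- 300
    cls <- rep(c("background", "elastin"), each = n / 2)
    x <- matrix(rnorm(n * 6), n, 6,
                dimnames = list(NULL, paste0("f", 1:6)))
    x[, 1] <- x[, 1] + ifelse(cls == "elastin", 1.0, 0)
    tr <- sample(n, n / 2)
    ts <- make_ts(x[tr, ], cls[tr])
    m1 <- train_forest(ts, n_trees = 1, seed = rep)
    m200 <- train_forest(ts, n_trees = 100, seed = rep)
    pos <- cls[-tr] == "elastin"
    a1 <- pcleQuant:::auc_rank(pcleQuant:::predict_prob(m1, x[-tr, ]), pos)
    a200 <- pcleQuant:::auc_rank(pcleQuant:::predict_prob(m200, x[-tr, ]), pos)
    wins <- wins + (a200 >= a1)
  }
  expect_gte(wins, 18)
})

test_that("predict_mask respects threshold extremes and the FOV", {
  ph <- quick_phantom(9, size = 96)
  st <- compute_features(ph$image, scales = c(1, 2))
  ts <- phantom_training_set(9, size = 96)
  # restrict to the two-scale bank for this test
  keep <- colnames(ts$x)[grepl("_s1$|_s2$", colnames(ts$x))]
  ts <- pcleQuant:::training_set(ts$x[, keep], as.character(ts$y))
  model <- train_forest(ts, n_trees = 30, seed = 1)
  m0 <- predict_mask(model, st, threshold = 0)
  fov <- matrix(st$fov, 96, 96)
  expect_true(all(m0$mask[fov]))
  expect_false(any(m0$mask[!fov]))
  m1 <- predict_mask(model, st, threshold = 1)
  p <- pcleQuant:::predict_prob(model, st)
  expect_equal(sum(m1$mask), sum(p >= 1 & st$fov))
  # feature-name mismatch errors informatively
  st_small <- compute_features(ph$image, scales = 1, families = "gauss")
  expect_error(predict_mask(model, st_small), "missing model features")
})

test_that("AUC: perfect separation, permutation null, pair-counting oracle", {
  auc <- pcleQuant:::auc_rank
  expect_equal(auc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1.0)
  set.seed(10)
  scores <- rnorm(2000)
  labels <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  expect_lt(abs(auc(scores, labels) - 0.5), 0.05)
  # exhaustive pair counting with ties -> midrank AUC
  s <- c(0.1, 0.4, 0.4, 0.7, 0.2, 0.4)
  pos <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  pairs <- expand.grid(p = which(pos), n = which(!pos))
  oracle <- mean(ifelse(s[pairs$p] > s[pairs$n], 1,
                        ifelse(s[pairs$p] == s[pairs$n], 0.5, 0)))
  expect_equal(auc(s, pos), oracle)
  # invariance under strictly monotone transforms
  expect_equal(auc(exp(s), pos), auc(s, pos))
  expect_equal(auc(rank(s), pos), auc(s, pos))
})

test_that("model archives round-trip and refuse foreign banks", {
  ts <- make_ts(matrix(rnorm(100), 50, 2,
                       dimnames = list(NULL, c("a", "b"))),
                rep(c("background", "elastin"), 25))
  model <- train_forest(ts, n_trees = 5, seed = 1)
  f <- tempfile(fileext = ".rds")
  save_model(model, f)
  back <- load_model(f)
  expect_identical(back$trees, model$trees)
  bad <- model; bad$bank_version <- 99L
  saveRDS(bad, f)
  expect_error(load_model(f), "incompatible")
})
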