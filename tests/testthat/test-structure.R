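# Interface partition and free-energy classification: distances, the
# strict-cutoff classifier, and group summaries.

test_that("minimum distances follow Euclid (3-4-5) and the oracle", {
  a <- data.frame(resno = 1, resid = "ALA", elety = "CA", x = 0, y = 0,
                  z = 0)
  b <- data.frame(resno = 1, resid = "ALA", elety = "CA", x = 3, y = 4,
                  z = 0)
  expect_equal(minDistanceToChain(1, a, b), 5)
  expect_equal(minDistanceToChain(1, a, a), 0)
  # multi-atom residues vs a brute-force all-pairs oracle
  set.seed(61)
  A <- data.frame(resno = rep(1:3, each = 4), resid = "ALA", elety = "X",
                  x = rnorm(12), y = rnorm(12), z = rnorm(12))
  B <- data.frame(resno = rep(1:5, each = 3), resid = "GLY", elety = "X",
                  x = rnorm(15) + 2, y = rnorm(15), z = rnorm(15))
  for (site in 1:3) {
    aa <- A[A$resno == site, ]
    oracle <- min(vapply(seq_len(nrow(aa)), function(i)
      min(sqrt((aa$x[i] - B$x)^2 + (aa$y[i] - B$y)^2 +
                 (aa$z[i] - B$z)^2)), numeric(1)))
    expect_equal(minDistanceToChain(site, A, B), oracle, tolerance = 1e-12)
  }
})

test_that("unresolved residues are flagged missing with a warning", {
  a <- data.frame(resno = 1, resid = "A", elety = "CA", x = 0, y = 0, z = 0)
  expect_warning(res <- minDistanceToChain(99, a, a), "unresolved")
  expect_true(is.na(res))
  expect_identical(attr(res, "reason"), "missing")
})

test_that("the classifier is total with strict cutoffs", {
  expect_identical(as.character(classifyMutation(2.5, 0, 3)),
                   "binding_disruptive")
  expect_identical(as.character(classifyMutation(0, 0, 10)),
                   "far_from_interface")
  # boundary values fall in the permissive class under strict inequalities
  expect_identical(as.character(classifyMutation(2.0, 0, 3)), "functional")
  expect_identical(as.character(classifyMutation(0, 3, 3)),
                   "fold_perturbed")
  expect_identical(as.character(classifyMutation(0, 0, 5)), "functional")
  expect_identical(as.character(classifyMutation(9, 0, 5.0001)),
                   "far_from_interface")
  # grid partition: every point lands in exactly one class
  grid <- expand.grid(bind = seq(-1, 4, by = 0.5),
                      fold = seq(-5, 5, by = 1),
                      dist = c(1, 4.9, 5.1, 12))
  cls <- classifyMutation(grid$bind, grid$fold, grid$dist)
  expect_false(anyNA(cls))
  expect_identical(length(cls), nrow(grid))
  far <- grid$dist > 5
  expect_true(all(cls[far] == "far_from_interface"))
  fold <- !far & (grid$fold <= -3 | grid$fold >= 3)
  expect_true(all(cls[fold] == "fold_perturbed"))
  bind <- !far & !fold & grid$bind > 2
  expect_true(all(cls[bind] == "binding_disruptive"))
  expect_true(all(cls[!far & !fold & !bind] == "functional"))
})

test_that("classifyDdgTable joins distances and classes onto the table", {
  chainA <- toyChain(20)
  chainA$z <- ifelse(chainA$resno <= 10, 0, 50)
  chainB <- toyChain(20, xoff = 1.5)
  tab <- data.frame(site = c(1:4, 5, 15, 99),
                    wt_aa = "A", mut_aa = "V",
                    ddg_bind = c(2.5, 3.0, 2.1, 2.6, 0.5, 0.1, 1),
                    ddg_fold = 0)
  suppressWarnings(cls <- classifyDdgTable(tab, chainA, chainB))
  expect_identical(sum(cls$class == "binding_disruptive", na.rm = TRUE), 4L)
  expect_identical(as.character(cls$class[cls$site == 15]),
                   "far_from_interface")
  expect_true(is.na(cls$class[cls$site == 99]))
})

test_that("group summaries use the sample SD and flag singletons", {
  d <- data.frame(ddg_bind = c(rep(0.04, 11), 9),
                  ddg_fold = c(rep(0, 11), 1),
                  grp = c(rep("far", 11), "one"))
  s <- summarizeDdg(d, by = "grp")
  far <- s[s$group == "far", ]
  expect_equal(far$mean_ddg_bind, 0.04)
  expect_equal(far$sd_ddg_bind, 0)
  one <- s[s$group == "one", ]
  expect_true(one$singleton)
  expect_identical(one$sd_ddg_bind, 0)
  # random group vs an independent two-pass oracle
  set.seed(62)
  x <- rnorm(50)
  d2 <- data.frame(ddg_bind = x, ddg_fold = x, grp = "g")
  s2 <- summarizeDdg(d2, by = "grp")
  expect_equal(s2$mean_ddg_bind, sum(x) / 50, tolerance = 1e-12)
  expect_equal(s2$sd_ddg_bind, sqrt(sum((x - mean(x))^2) / 49),
               tolerance = 1e-12)
})
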