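test_that("diameter thresholding follows the 0.8 mm rule", {
  expect_identical(segment_state_from_diameter(c(0.8, 0.79, 1.4, NA)),
                   c("normal", "hypoplastic", "normal", "absent"))
  expect_error(segment_state_from_diameter(-1), "non-negative")
})

test_that("the worked variant examples classify correctly", {
  s <- all_normal_segments()
  expect_equal(as.integer(classify_cow(s)), 1L)

  s2 <- s; s2["acom"] <- "hypoplastic"
  expect_equal(as.integer(classify_cow(s2)), 2L)

  s3 <- s; s3["pcom_contra"] <- "absent"
  expect_equal(as.integer(classify_cow(s3)), 3L)

  s4 <- s; s4["a1_contra"] <- "hypoplastic"; s4["p1_ipsi"] <- "hypoplastic"
  expect_equal(as.integer(classify_cow(s4)), 4L)

  s5 <- s; s5["acom"] <- "absent"; s5["pcom_ipsi"] <- "absent"
  expect_equal(as.integer(classify_cow(s5)), 5L)
  # group 5 requires interruption of the ipsilateral posterior path:
  # a contralateral posterior absence does not isolate the operated MCA
  s5b <- s; s5b["acom"] <- "absent"; s5b["pcom_contra"] <- "absent"
  expect_equal(as.integer(classify_cow(s5b)), 4L)
})

test_that("classification is total and matches the rule-table oracle on all 3^7 states", {
  states <- c("normal", "hypoplastic", "absent")
  grid <- expand.grid(rep(list(states), 7L), stringsAsFactors = FALSE)
  names(grid) <- seg_names
  got <- integer(nrow(grid))
  want <- integer(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    s <- unlist(grid[i, ])
    got[i] <- as.integer(classify_cow(s))
    want[i] <- cow_oracle(s)
  }
  expect_identical(got, want)
  expect_true(all(got %in% 1:5))
  # group 5 always implies both semicircles compromised (group-4 condition)
  g5 <- grid[got == 5L, ]
  both_bad <- apply(g5, 1, function(s) {
    any(s[c("a1_contra", "acom", "a1_ipsi")] != "normal") &&
      any(s[c("pcom_ipsi", "pcom_contra", "p1_ipsi", "p1_contra")] != "normal")
  })
  expect_true(all(both_bad))
})

test_that("classifier validates inputs and flags multi-segment variants", {
  s <- all_normal_segments()
  expect_error(classify_cow(s[-1]), "Missing")
  s_bad <- s; s_bad["acom"] <- "patent"
  expect_error(classify_cow(s_bad), "patent")

  s_multi <- s; s_multi["acom"] <- "hypoplastic"; s_multi["a1_ipsi"] <- "absent"
  g <- classify_cow(s_multi)
  expect_equal(as.integer(g), 2L)
  expect_true(attr(g, "multi_segment"))
})

test_that("one-way ANOVA matches the hand-computed sums of squares", {
  df <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   g = rep(c("a", "b", "c"), each = 3))
  out <- anova_oneway(df, y, g)
  # oracle: group means 2,3,4, grand mean 3 -> SSB = 3*(1+0+1) = 6 on 2 df;
  # SSW = 6 on 6 df -> F = (6/2)/(6/6) = 3
  expect_equal(out$statistic, 3)
  expect_equal(out$df1, 2)
  expect_equal(out$df2, 6)
  expect_equal(out$p_value, stats::pf(3, 2, 6, lower.tail = FALSE))

  expect_error(anova_oneway(data.frame(y = 1:5, g = "a"), y, g), "2 groups")
  expect_warning(
    out2 <- anova_oneway(data.frame(y = c(1, 2, 3, 4, 9),
                                    g = c("a", "a", "b", "b", "c")), y, g),
    "fewer than 2"
  )
  expect_equal(out2$n_groups, 2)
})

test_that("ANOVA type-I error under the global null is nominal", {
  withr::with_seed(2024, {
    rejections <- purrr::map_lgl(1:1000, function(i) {
      df <- data.frame(y = rnorm(30), g = rep(c("a", "b"), each = 15))
      anova_oneway(df, y, g)$p_value < 0.05
    })
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("Tukey HSD agrees with a studentized-range oracle", {
  df <- data.frame(y = c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                   g = rep(c("a", "b", "c"), each = 3))
  out <- tukey_hsd(df, y, g)
  expect_equal(nrow(out), 3)
  # oracle: MSW = 1, n = 3 per group; q = |diff| / sqrt(MSW/n);
  # p_adj = P(studentized range(3 groups, 6 df) > q)
  for (i in seq_len(nrow(out))) {
    q <- abs(out$estimate[i]) / sqrt(1 / 3)
    p_or <- stats::ptukey(q, nmeans = 3, df = 6, lower.tail = FALSE)
    expect_equal(out$p_adj[i], p_or, tolerance = 1e-6)
  }

  # identical groups: adjusted p ~ 1
  df2 <- data.frame(y = c(1, 2, 3, 1, 2, 3), g = rep(c("a", "b"), each = 3))
  expect_gt(tukey_hsd(df2, y, g)$p_adj, 0.999)

  # enormous separation: adjusted p ~ 0
  withr::with_seed(1, {
    df3 <- data.frame(y = c(rnorm(10, 0, 1), rnorm(10, 100, 1)),
                      g = rep(c("a", "b"), each = 10))
  })
  expect_lt(tukey_hsd(df3, y, g)$p_adj, 1e-6)
})

test_that("correlation tests behave on identities and the rank example", {
  df <- data.frame(x = c(1, 3, 2, 5, 4))
  df$y <- df$x
  expect_equal(correlate(df, x, y, "pearson")$estimate, 1)
  expect_equal(correlate(df, x, y, "spearman")$estimate, 1)
  df$z <- -df$x
  expect_equal(correlate(df, x, z, "pearson")$estimate, -1)

  # Sum d^2 = 4 over n = 4 -> rho = 1 - 6*4/(4*15) = 0.6
  df2 <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
  expect_equal(correlate(df2, a, b, "spearman")$estimate, 0.6)

  expect_error(correlate(data.frame(x = c(1, 1, 1), y = 1:3), x, y),
               "zero variance")
  expect_error(correlate(data.frame(x = 1:2, y = 1:2), x, y), "at least 3")
})

test_that("categorical tests follow the expected-count selection rule", {
  # diagonal 10/10: Fisher; oracle by hypergeometric enumeration
  out <- categorical_test(matrix(c(10, 0, 0, 10), 2))
  expect_identical(out$test_used, "fisher")
  expect_equal(out$p_value, 2 / choose(20, 10), tolerance = 1e-10)

  out2 <- categorical_test(matrix(c(50, 50, 50, 50), 2))
  expect_identical(out2$test_used, "chi_square")
  expect_gt(out2$p_value, 0.99)

  out3 <- categorical_test(matrix(c(2, 1, 3, 4), 2))
  expect_identical(out3$test_used, "fisher")

  expect_warning(
    out4 <- categorical_test(matrix(c(2, 1, 3, 4, 1, 0), 2)),
    "chi-square"
  )
  expect_identical(out4$test_used, "chi_square")

  expect_error(categorical_test(matrix(0, 2, 2)), "zero")
  expect_error(categorical_test(matrix(c(1.5, 1, 1, 1), 2)), "integer")
  expect_error(categorical_test(matrix(1:3, 1)), "2x2")
})
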