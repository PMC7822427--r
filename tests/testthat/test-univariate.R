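test_that("one-way ANOVA matches the hand decomposition", {
  a <- one_way_anova(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5)))
  expect_equal(a$F, 3)
  expect_equal(a$df_between, 2)
  expect_equal(a$df_within, 6)
  expect_equal(a$p, pf(3, 2, 6, lower.tail = FALSE))
  # identical group means: F = 0
  a0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(a0$F, 0)
  # near-degenerate separation: tiny p
  set.seed(1)
  a1 <- one_way_anova(list(c(0, 0) + rnorm(2, sd = 1e-3),
                           c(10, 10) + rnorm(2, sd = 1e-3)))
  expect_lt(a1$p, 0.001)
  expect_error(one_way_anova(list(c(1, 1), c(1, 1))), "degenerate")
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
})

test_that("Tukey comparisons behave at the separable and null limits", {
  set.seed(2)
  far <- lapply(c(0, 50, 100), function(m) rnorm(5, m, 1))
  names(far) <- c("lo", "mid", "hi")
  tk <- tukey_hsd(far)
  expect_equal(nrow(tk), 3)
  expect_true(all(tk$significant))
  same <- lapply(1:3, function(i) rnorm(5, 0, 1))
  names(same) <- letters[1:3]
  set.seed(7)
  tk0 <- tukey_hsd(same)
  expect_false(any(tk0$significant))
})

test_that("Tukey p-values dominate pooled-variance pairwise t-tests", {
  set.seed(3)
  for (rep in 1:10) {
    groups <- lapply(1:4, function(i) rnorm(4, mean = runif(1, 0, 3)))
    names(groups) <- paste0("g", 1:4)
    tk <- tukey_hsd(groups)
    mse <- mean(vapply(groups, var, numeric(1)))  # balanced design
    df_w <- sum(lengths(groups)) - length(groups)
    for (r in seq_len(nrow(tk))) {
      tstat <- abs(tk$diff[r]) / sqrt(mse * (1 / 4 + 1 / 4))
      p_t <- 2 * pt(tstat, df_w, lower.tail = FALSE)
      expect_gte(tk$p[r] + 1e-10, p_t)
    }
  }
})

test_that("separated treatment means recover the published letter pattern", {
  # RLR of the primary root: 63/123/83/117 with SE 4/12/2/15 (n = 4);
  # drought and combined should split from control in most seeds
  fx <- builtin_table_fixtures()
  sub <- fx[fx$root_type == "primary" & fx$trait == "rlr", ]
  hits <- 0L
  for (s in 1:20) {
    d <- generate_dataset(synthetic_config(seed = 100 + s, specs = sub))
    groups <- split(d$value, d$treatment)[treatment_levels()]
    cld <- compact_letter_display(
      tukey_hsd(groups), vapply(groups, mean, numeric(1)))
    lett <- setNames(cld$letters, cld$group)
    disjoint <- function(a, b) {
      !any(strsplit(a, ",")[[1]] %in% strsplit(b, ",")[[1]])
    }
    if (disjoint(lett["Drought"], lett["Control"]) &&
        disjoint(lett["Combined"], lett["Control"])) {
      hits <- hits + 1L
    }
  }
  expect_gt(hits, 10L)
})

test_that("compact letter displays encode forced patterns", {
  # A differs from both B and C, which do not differ: a / b / b
  pw1 <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                    significant = c(TRUE, TRUE, FALSE))
  cld1 <- compact_letter_display(pw1, c(A = 10, B = 2, C = 1))
  expect_equal(setNames(cld1$letters, cld1$group)[c("A", "B", "C")],
               c(A = "a", B = "b", C = "b"))
  # nothing significant: everyone shares one letter
  pw2 <- pw1
  pw2$significant <- FALSE
  cld2 <- compact_letter_display(pw2, c(A = 3, B = 2, C = 1))
  expect_true(all(cld2$letters == "a"))
  # chain: A-C significant, B bridges both
  pw3 <- data.frame(group1 = c("A", "A", "B"), group2 = c("B", "C", "C"),
                    significant = c(FALSE, TRUE, FALSE))
  cld3 <- compact_letter_display(pw3, c(A = 3, B = 2, C = 1))
  expect_equal(setNames(cld3$letters, cld3$group)[c("A", "B", "C")],
               c(A = "a", B = "a,b", C = "b"))
})

test_that("letters regenerate exactly the significance relation they encode", {
  set.seed(11)
  grps <- LETTERS[1:5]
  pairs <- t(combn(grps, 2))
  for (rep in 1:50) {
    pw <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                     significant = runif(nrow(pairs)) < 0.4)
    cld <- compact_letter_display(pw, setNames(rnorm(5), grps))
    lett <- setNames(strsplit(cld$letters, ","), cld$group)
    shared <- mapply(function(a, b) any(lett[[a]] %in% lett[[b]]),
                     pw$group1, pw$group2)
    expect_equal(unname(!shared), pw$significant)
    expect_true(all(lengths(lett) >= 1L))
  }
})

test_that("trait screen flags everything under zero noise and formats tables", {
  specs0 <- builtin_table_fixtures()
  specs0 <- specs0[specs0$root_type == "primary", ]
  specs0$se <- 0.0001 * specs0$mean  # effectively zero noise, distinct means
  d <- generate_dataset(synthetic_config(seed = 2, specs = specs0))
  scr <- trait_screen(d)
  expect_true(all(scr$anova$significant))
  expect_equal(scr$anova$df_between, rep(3, 11))
  expect_equal(scr$anova$df_within, rep(12, 11))
  tab <- format_screen_table(scr)
  expect_equal(nrow(tab), 11)
  expect_true(all(treatment_levels() %in% names(tab)))
  # degenerate trait is flagged, not fatal
  d0 <- d
  d0$value[d0$trait == "length"] <- 50
  scr0 <- trait_screen(d0)
  expect_true(scr0$anova$degenerate[scr0$anova$trait == "length"])
  expect_false(any(scr0$anova$degenerate[scr0$anova$trait != "length"]))
})
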