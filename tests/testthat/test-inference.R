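test_that("one-way ANOVA: identical groups give F = 0; two groups give t^2", {
  g <- list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3))
  expect_equal(one_way_anova(g)$f, 0)
  set.seed(21)
  x <- rnorm(8); y <- rnorm(10, 0.5)
  fit <- one_way_anova(list(x = x, y = y))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(fit$f, unname(tt$statistic)^2)
  expect_equal(fit$p, tt$p.value)
})

test_that("one-way ANOVA matches the brute-force sums-of-squares oracle", {
  set.seed(22)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(2:8, 1), mean = rnorm(1, sd = 2)))
    names(groups) <- letters[seq_len(k)]
    expect_equal(one_way_anova(groups)$f, brute_anova_f(groups),
                 tolerance = 1e-10)
  }
})

test_that("degenerate inputs are flagged or rejected, not mangled", {
  flat <- list(a = c(5, 5), b = c(5, 5))
  fit <- one_way_anova(flat)
  expect_true(fit$degenerate)
  expect_true(is.na(fit$f))
  expect_error(one_way_anova(list(a = 1:3)), "two groups")
  expect_error(one_way_anova(list(a = 1:3, b = 2)), "at least two values")
})

balanced_cells <- function(f, reps = 3) {
  grid <- expand.grid(light = c("white", "green", "red"),
                      temperature = c("hot", "neutral", "cold"),
                      rep = seq_len(reps), stringsAsFactors = FALSE)
  grid$value <- mapply(f, grid$light, grid$temperature) +
    rnorm(nrow(grid), 0, 1)
  grid
}

test_that("two-way ANOVA: additive cells have vanishing interaction SS", {
  light_eff <- c(white = 3, green = -1, red = 0)
  temp_eff <- c(hot = -2, neutral = 0, cold = 2)
  grid <- expand.grid(light = names(light_eff), temperature = names(temp_eff),
                      rep = 1:2, stringsAsFactors = FALSE)
  # purely additive, noise-free cells (replicates jittered equally per cell)
  grid$value <- light_eff[grid$light] + temp_eff[grid$temperature] +
    ifelse(grid$rep == 1, 0.5, -0.5)
  tab <- two_way_anova(grid)
  expect_equal(tab$sum_sq[tab$term == "light:temperature"], 0,
               tolerance = 1e-20)
})

test_that("two-way ANOVA partitions the total sum of squares", {
  set.seed(23)
  for (i in 1:10) {
    cells <- balanced_cells(function(l, t) rnorm(1, sd = 2), reps = 3)
    tab <- two_way_anova(cells)
    oracle <- brute_twoway_ss(cells)
    expect_equal(sum(tab$sum_sq), unname(oracle["total"]), tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$term == "light"], unname(oracle["light"]),
                 tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$term == "temperature"],
                 unname(oracle["temperature"]), tolerance = 1e-8)
    expect_equal(tab$sum_sq[tab$term == "light:temperature"],
                 unname(oracle["interaction"]), tolerance = 1e-8)
  }
})

test_that("two-way ANOVA rejects unbalanced or incomplete layouts; flat cells flagged", {
  cells <- balanced_cells(function(l, t) 0, reps = 2)
  expect_silent(two_way_anova(cells))
  expect_error(two_way_anova(cells[-1, ]), "balanced|Unbalanced|unbalanced")
  missing_cell <- cells[!(cells$light == "red" & cells$temperature == "hot"), ]
  expect_error(two_way_anova(missing_cell), "missing cell")
  flat <- cells; flat$value <- 7
  expect_warning(tab <- two_way_anova(flat), "constant")
  expect_true(all(is.na(tab$f[1:3])))   # 0/0: undefined, flagged
  expect_true(isTRUE(attr(tab, "degenerate")))
})

test_that("a simulated light-by-temperature interaction is detected", {
  # heat flattens the light effect: strong contrast when cold, none when hot
  set.seed(24)
  eff <- function(l, t) if (t == "hot") 0 else
    c(white = 4, green = -4, red = 0)[[l]]
  cells <- balanced_cells(eff, reps = 4)
  tab <- two_way_anova(cells)
  expect_lt(tab$p[tab$term == "light:temperature"], 0.01)
})

test_that("Tukey HSD agrees with the reference implementation", {
  set.seed(25)
  for (i in 1:10) {
    k <- sample(3:4, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(sample(3:7, 1), mean = rnorm(1, sd = 1.5)))
    names(groups) <- letters[seq_len(k)]
    mine <- tukey_hsd(groups)
    d <- data.frame(value = unlist(groups),
                    group = factor(rep(names(groups), lengths(groups))))
    ref <- as.data.frame(TukeyHSD(aov(value ~ group, data = d))$group)
    key <- paste(mine$group_j, mine$group_i, sep = "-")
    expect_equal(mine$mean_diff, ref[key, "diff"], tolerance = 1e-10)
    expect_equal(mine$p_adj, ref[key, "p adj"], tolerance = 1e-3)
  }
})

test_that("Tukey HSD separates what is separated and only that", {
  same <- list(a = c(1, 2, 3), b = c(1.1, 2.1, 2.9), c = c(0.9, 2, 3.1))
  expect_false(any(tukey_hsd(same)$significant))
  far <- list(a = c(0, 0, 0.1), b = c(10, 10, 10.1), c = c(20, 20, 20.1))
  expect_true(all(tukey_hsd(far)$significant))
  two_near_one_far <- list(a = c(1, 1.1, 0.9), b = c(1.05, 0.95, 1.1),
                           c = c(30, 30.2, 29.8))
  tk <- tukey_hsd(two_near_one_far)
  expect_equal(sum(tk$significant), 2)
  # degenerate within-variance: distinct means significant with p -> 0
  degen <- list(a = c(1, 1), b = c(1, 1), c = c(2, 2))
  tkd <- tukey_hsd(degen)
  expect_equal(tkd$p_adj[tkd$group_i == "a" & tkd$group_j == "b"], 1)
  expect_equal(tkd$p_adj[tkd$group_i == "a" & tkd$group_j == "c"], 0)
})

test_that("compact letter display encodes exactly the non-significance graph", {
  groups <- c("A", "B", "C")
  none <- data.frame(group_i = c("A", "A", "B"), group_j = c("B", "C", "C"),
                     significant = FALSE)
  expect_equal(unname(as.character(letter_display(none, groups))),
               rep("a", 3))
  all_sig <- transform(none, significant = TRUE)
  expect_equal(length(unique(as.character(letter_display(all_sig, groups)))),
               3)
  chain <- data.frame(group_i = c("A", "A", "B"), group_j = c("B", "C", "C"),
                      significant = c(FALSE, TRUE, FALSE))
  ld <- letter_display(chain, groups)
  expect_equal(as.character(ld[c("A", "B", "C")]), c("a", "ab", "b"))
})

test_that("letter sharing equals non-significance on Tukey-derived patterns", {
  set.seed(26)
  for (i in 1:20) {
    k <- sample(3:5, 1)
    groups <- lapply(seq_len(k), function(j)
      rnorm(4, mean = sample(c(0, 0, 5, 12), 1)))
    names(groups) <- LETTERS[seq_len(k)]
    tk <- tukey_hsd(groups)
    ld <- letter_display(tk, names(groups))
    for (r in seq_len(nrow(tk)))
      expect_equal(shares_letter(ld, tk$group_i[r], tk$group_j[r]),
                   !tk$significant[r])
  }
})
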