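test_that("pooled_anova pools variances and agrees across raw/summary modes", {
  # identical means, nonzero spread -> F = 0, p = 1
  an <- pooled_anova(data.frame(label = c("a", "b"), n = c(10, 12),
                                mean = c(5, 5), sd = c(2, 3)))
  expect_equal(an$F, 0)
  expect_equal(an$p, 1)
  # hand-pooled MSE from the printed four-group summaries:
  # (24*10.1^2 + 90*24.2^2 + 27*18.2^2 + 45*21.3^2) / 186 = 454.3837...
  an2 <- pooled_anova(table1_sd1("Guangzhou"))
  expect_equal(an2$mse, 84515.37 / 186, tolerance = 1e-12)
  expect_identical(an2$df_error, 186L + 0L)
  # raw-mode vs summary-mode agree
  set.seed(4)
  raw <- list(g1 = rnorm(20, 10, 2), g2 = rnorm(35, 12, 3), g3 = rnorm(15, 9, 1.5))
  summ <- data.frame(label = names(raw),
                     n = vapply(raw, length, 1L),
                     mean = vapply(raw, mean, 1),
                     sd = vapply(raw, sd, 1))
  a1 <- pooled_anova(raw); a2 <- pooled_anova(summ)
  expect_equal(a1$mse, a2$mse)
  expect_equal(a1$F, a2$F)
  expect_equal(a1$p, a2$p)
  expect_error(pooled_anova(list(a = c(1, 1), b = c(2, 2))), "variances")
  expect_error(pooled_anova(list(a = 1:3)), "2 groups")
})

test_that("duncan_mrt reproduces published letter displays from summaries", {
  out_gz <- duncan_mrt(table1_sd1("Guangzhou"))
  tab <- out_gz$table[order(out_gz$table$mean), ]
  expect_identical(tab$letter, c("a", "b", "c", "c"))
  expect_identical(tab$label, paste0("Hap", 1:4))
  out_yj <- duncan_mrt(table1_sd1("Yangjiang"))
  tab2 <- out_yj$table[order(out_yj$table$mean), ]
  expect_identical(tab2$letter, c("a", "b", "c", "c"))
  # the all-group harmonic-mean variant gives the same display here
  out_all <- duncan_mrt(table1_sd1("Guangzhou"), n_h = "all")
  expect_identical(out_all$table$letter, out_gz$table$letter)
  # single group
  expect_identical(duncan_mrt(data.frame(label = "g", n = 5, mean = 1, sd = 1))$table$letter, "a")
  expect_error(duncan_mrt(data.frame(label = character(0), n = integer(0),
                                     mean = numeric(0), sd = numeric(0))), "group")
})

test_that("k = 2 Duncan decision coincides with the pooled two-sample t-test", {
  set.seed(7)
  for (i in 1:60) {
    gs <- data.frame(label = c("A", "B"),
                     n = sample(5:60, 2, replace = TRUE),
                     mean = runif(2, 0, 20),
                     sd = runif(2, 1, 8))
    dn <- duncan_mrt(gs, alpha = 0.05)
    tt <- two_sample_t(as.list(gs[1, -1]), as.list(gs[2, -1]), mode = "pooled")
    # for p = 2 the protection level is alpha and q(2, df) = sqrt(2) t(df):
    # sharing a letter <=> pooled t fails to reject, up to the Kramer
    # harmonic-mean approximation which is exact here (single pair)
    expect_identical(shares_letter(dn, "A", "B"), tt$p >= 0.05,
                     info = paste("case", i))
  }
})

test_that("Duncan letters are shift-invariant and scale MSE without changing letters", {
  set.seed(12)
  for (i in 1:20) {
    k <- sample(3:6, 1)
    gs <- random_summary_groups(k)
    base <- duncan_mrt(gs)
    shifted <- gs; shifted$mean <- shifted$mean + 123.4
    sh <- duncan_mrt(shifted)
    expect_identical(sh$table$letter, base$table$letter)
    expect_equal(sh$mse, base$mse)
    scaled <- gs; scaled$mean <- scaled$mean * 10; scaled$sd <- scaled$sd * 10
    sc <- duncan_mrt(scaled)
    expect_identical(sc$table$letter, base$table$letter)
    expect_equal(sc$mse, base$mse * 100)
  }
})

test_that("compact letter display is valid: disjoint letters imply a large range", {
  set.seed(31)
  for (i in 1:40) {
    k <- sample(2:6, 1)
    gs <- random_summary_groups(k)
    dn <- duncan_mrt(gs)
    tab <- dn$table  # descending means
    an <- pooled_anova(gs)
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      if (!shares_letter(dn, tab$label[a], tab$label[b])) {
        span <- b - a + 1
        alpha_p <- 1 - 0.95^(span - 1)
        nh <- 2 / (1 / tab$n[a] + 1 / tab$n[b])
        Rp <- qtukey(1 - alpha_p, span, an$df_error) * sqrt(an$mse / nh)
        expect_gte(tab$mean[a] - tab$mean[b], Rp)
      }
    }
  }
})

test_that("two_sample_t closed forms, symmetry and degenerate conventions", {
  s <- list(n = 20, mean = 10, sd = 3)
  expect_equal(two_sample_t(s, s)$t, 0)
  expect_equal(two_sample_t(s, s)$p, 1)
  tg <- table1_two_hap("Guangzhou")
  for (m in c("welch", "pooled")) {
    r <- two_sample_t(tg$h1, tg$h2, mode = m)
    expect_lt(r$p, 0.01)
    r2 <- two_sample_t(tg$h2, tg$h1, mode = m)
    expect_equal(r2$t, -r$t)
    expect_equal(r2$p, r$p)
  }
  # raw vectors are summarized; pooled mode then matches stats::t.test
  set.seed(3)
  x <- rnorm(15, 5); y <- rnorm(20, 6)
  ours <- two_sample_t(x, y, mode = "pooled")
  ref <- t.test(x, y, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p, ref$p.value)
  oursw <- two_sample_t(x, y, mode = "welch")
  refw <- t.test(x, y)
  expect_equal(oursw$df, unname(refw$parameter))
  expect_equal(oursw$p, refw$p.value)
  z0 <- list(n = 5, mean = 3, sd = 0)
  expect_equal(two_sample_t(z0, z0)$p, 1)
  expect_equal(two_sample_t(z0, list(n = 5, mean = 4, sd = 0))$p, 0)
  expect_error(two_sample_t(list(n = 1, mean = 1, sd = 0), s), "n >= 2")
})

test_that("pearson correlation and its p value behave", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson(x, x)$r, 1)
  expect_equal(pearson(x, -x)$r, -1)
  expect_equal(pearson(x, x)$p, 0)
  # pearson(x, a + b x) = sign(b)
  set.seed(2)
  z <- rnorm(30)
  for (b in c(-3, -0.5, 0.2, 7))
    expect_equal(pearson(z, 5 + b * z)$r, sign(b))
  # agreement with cor.test on noisy data
  y <- z + rnorm(30)
  ref <- cor.test(z, y)
  ours <- pearson(z, y)
  expect_equal(ours$r, unname(ref$estimate))
  expect_equal(ours$p, ref$p.value)
  # Monte-Carlo recovery of rho = 0.5
  set.seed(1234)
  n <- 10000
  a <- rnorm(n); bvar <- 0.5 * a + sqrt(1 - 0.25) * rnorm(n)
  expect_lt(abs(pearson(a, bvar)$r - 0.5), 0.03)
  expect_true(is.na(pearson(rep(1, 10), rnorm(10))$r))
  expect_error(pearson(1:2, 1:2), "3 pairwise")
})

test_that("percent_reduction averages per-line reductions", {
  expect_equal(round(percent_reduction(20.5, c(16.6, 16.8)), 1), 18.5)
  expect_equal(percent_reduction(10, 10), 0)
  expect_equal(percent_reduction(10, 5), 50)
  # averaging per line differs from pooling the KO means first when it matters
  expect_equal(percent_reduction(10, c(5, 10)), 25)
  expect_error(percent_reduction(0, 5), "> 0")
  expect_error(percent_reduction(10, numeric(0)), ">= 1")
})

test_that("duncan TSV output mirrors the publication layout", {
  p <- tempfile(fileext = ".tsv")
  write_duncan_tsv(duncan_mrt(table1_sd1("Guangzhou")), p)
  tab <- data.table::fread(p)
  expect_identical(nrow(tab), 4L)
  expect_match(tab$display[tab$label == "Hap1"], "^91.8 ± 10.1 a \\(25\\)$")
})
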