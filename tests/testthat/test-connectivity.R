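# star on A (degree 3) plus pendant edge: degrees A=3, B=1, C=1, D=1
starA <- build_network(records(c("A", "A", "A"), c("B", "C", "D")))

test_that("degree ranking is degree-descending with lexicographic ties", {
  rk <- rank_by_degree(starA)
  expect_equal(rk$gene, c("A", "B", "C", "D"))
  expect_equal(rk$rank, 1:4)
  expect_true(all(diff(rk$degree) <= 0))
})

test_that("degree ranking agrees with an independent sort oracle", {
  set.seed(8)
  genes <- sprintf("N%02d", 1:20)
  rec <- records(sample(genes, 40, TRUE), sample(genes, 40, TRUE))
  rec <- rec[rec$gene_a != rec$gene_b, ]
  net <- build_network(rec)
  rk <- rank_by_degree(net)
  deg <- degree_oracle(rec)
  oracle_order <- names(deg)[order(-deg, names(deg))]
  expect_equal(rk$gene, oracle_order)
  expect_length(rk$rank, length(net$genes))
  expect_setequal(rk$rank, seq_along(net$genes))
})

ring_network <- function(n) {
  g <- sprintf("R%03d", 1:n)
  build_network(records(g, g[c(2:n, 1)]))
}

test_that("bins hold equal universe quotas; uniform case is exact deciles", {
  net <- ring_network(100)  # all degrees equal: ranking is lexicographic
  rk <- rank_by_degree(net)
  sch <- make_bins(rk, net$genes, 10L)
  expect_equal(sch$lo, seq(1, 91, by = 10))
  expect_equal(sch$hi, seq(10, 100, by = 10))
  expect_equal(sch$n_universe, rep(10L, 10L))

  # 10 universe genes in 10 bins: one each
  sch2 <- make_bins(rk, rk$gene[seq(5, 95, by = 10)], 10L)
  expect_equal(sch2$n_universe, rep(1L, 10L))
  expect_error(make_bins(rk, rk$gene[1:3], 10L), "at least")
})

test_that("bin walk matches a hand-computed trace and conserves genes", {
  net <- ring_network(12)
  rk <- rank_by_degree(net)
  uni <- rk$gene[c(2, 3, 5, 8, 9, 12)]
  sch <- make_bins(rk, uni, 3L)
  # quota 2 per bin: bin 1 closes at the 2nd universe gene (rank 3),
  # bin 2 at the 4th (rank 8), bin 3 absorbs the tail
  expect_equal(sch$lo, c(1L, 4L, 9L))
  expect_equal(sch$hi, c(3L, 8L, 12L))
  expect_equal(sch$n_universe, c(2L, 2L, 2L))
  expect_equal(sum(sch$hi - sch$lo + 1L), 12L)

  # remainder goes one-per-bin to the earliest bins
  sch2 <- make_bins(rk, rk$gene[c(1, 2, 4, 6, 7, 10, 11)], 3L)
  expect_equal(sch2$n_universe, c(3L, 2L, 2L))
})

test_that("bin profiles count rank-interval membership", {
  net <- ring_network(100)
  rk <- rank_by_degree(net)
  sch <- make_bins(rk, net$genes, 10L)

  pf <- bin_profile(sch, rk, rk$gene[1])
  expect_equal(pf$count, c(1L, rep(0L, 9L)))

  # the universe itself spreads uniformly by construction
  pf2 <- bin_profile(sch, rk, net$genes)
  expect_equal(pf2$fraction, sch$n_universe / 100)

  # brute-force interval membership for a random list
  set.seed(3)
  lst <- sample(net$genes, 15)
  pf3 <- bin_profile(sch, rk, lst)
  brute <- integer(10)
  for (g in lst) {
    r <- rk$rank[rk$gene == g]
    for (b in 1:10) if (r >= sch$lo[b] && r <= sch$hi[b])
      brute[b] <- brute[b] + 1L
  }
  expect_equal(pf3$count, brute)
  expect_equal(sum(pf3$count), 15L)
})

test_that("absent list genes reduce fraction mass and are reported", {
  net <- ring_network(20)
  rk <- rank_by_degree(net)
  sch <- make_bins(rk, net$genes, 4L)
  pf <- bin_profile(sch, rk, c(rk$gene[1:3], "ZZZ"))
  expect_equal(attr(pf, "absent"), "ZZZ")
  expect_equal(sum(pf$fraction), 3 / 4)
})

test_that("log-log slopes match closed forms", {
  fake_profile <- function(counts, fractions) {
    structure(data.frame(bin = seq_along(counts), count = counts,
                         fraction = fractions),
              class = c("bin_profile", "data.frame"))
  }
  fake_scheme <- function(hi) {
    structure(data.frame(bin = seq_along(hi),
                         lo = c(1L, head(hi, -1) + 1L), hi = hi,
                         n_universe = 1L),
              class = c("binning_scheme", "data.frame"))
  }
  # flat profile: slope 0
  f <- loglog_slope(fake_profile(rep(6L, 10), rep(0.1, 10)),
                    fake_scheme(seq(10, 100, by = 10)))
  expect_equal(f$slope, 0, tolerance = 1e-12)

  # two bins: (log10(0.05) - log10(0.5)) / (log10(100) - log10(10)) = -1
  f2 <- loglog_slope(fake_profile(c(10L, 1L), c(0.5, 0.05)),
                     fake_scheme(c(10L, 100L)))
  expect_equal(f2$slope, -1, tolerance = 1e-12)

  # three collinear points: exact slope, zero residuals
  hi <- c(10L, 100L, 1000L)
  fr <- 10^(-0.7 * log10(hi) + 0.2)
  f3 <- loglog_slope(fake_profile(rep(1L, 3), fr), fake_scheme(hi))
  expect_equal(f3$slope, -0.7, tolerance = 1e-10)
  expect_lt(max(abs(residuals(f3$fit))), 1e-10)

  # zero-count bins are excluded and accounted for
  f4 <- loglog_slope(fake_profile(c(5L, 0L, 2L), c(0.5, 0, 0.2)),
                     fake_scheme(c(10L, 50L, 100L)))
  expect_equal(f4$excluded_bins, 2L)
  expect_equal(f4$n_points + length(f4$excluded_bins), 3L)

  # scale invariance: multiplying fractions shifts only the intercept
  f5 <- loglog_slope(fake_profile(c(10L, 1L), c(0.5, 0.05) * 0.37),
                     fake_scheme(c(10L, 100L)))
  expect_equal(f5$slope, f2$slope, tolerance = 1e-12)
  expect_error(loglog_slope(fake_profile(c(1L, 0L), c(1, 0)),
                            fake_scheme(c(10L, 100L))),
               "fewer than 2")
})

test_that("the one-sample t against the MC slope sample matches hand algebra", {
  mc <- c(-0.1, 0, 0.1)
  tt <- netoverlap:::.slope_t(mc, -1, "two")
  se <- sd(mc) / sqrt(3)
  t_hand <- (mean(mc) - (-1)) / se
  expect_equal(tt$t, t_hand, tolerance = 1e-12)
  expect_equal(tt$df, 2)
  expect_equal(tt$p, 2 * pt(-abs(t_hand), df = 2), tolerance = 1e-12)

  # one-tailed: MC slopes greater than the experimental reference
  t1 <- netoverlap:::.slope_t(mc, -1, "one")
  expect_equal(t1$p, pt(t_hand, df = 2, lower.tail = FALSE),
               tolerance = 1e-12)

  # reference equal to the sample mean: t = 0, two-tailed p = 1
  t0 <- netoverlap:::.slope_t(mc, mean(mc), "two")
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
})

test_that("hub-enriched lists are detected; random lists centre on slope 0", {
  st <- small_study()
  rk <- rank_by_degree(st$net)
  sch <- make_bins(rk, st$lists$universe, 5L)
  cfg <- mc_config(n_lists = 100L, rng_seed = 23)

  # experimental list sampled with degree-squared weights: strong hub bias
  # but spread over several bins, as a real screen-hit list would be
  set.seed(55)
  uni_genes <- st$lists$universe$genes
  hubs <- sample(uni_genes, 25,
                 prob = (st$net$degree[uni_genes] + 1)^2)
  sc <- slope_comparison(st$net, st$lists$universe, sch, hubs, cfg)
  expect_lt(sc$experimental_slope, 0)
  expect_lt(sc$p, 0.05)
  # random MC lists segregate evenly: mean slope within 2 SE of 0
  se <- sd(sc$mc_slopes) / sqrt(length(sc$mc_slopes))
  expect_lt(abs(mean(sc$mc_slopes)), 2 * se)
  # bin construction conserves genes
  expect_equal(sum(sch$hi - sch$lo + 1L), length(st$net$genes))
  expect_equal(sum(sch$n_universe),
               sum(st$lists$universe$genes %in% rk$gene))
})
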