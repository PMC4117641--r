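star <- build_network(records(rep("X", 4), c("P", "Q", "R", "S")))
triangle <- build_network(records(c("A", "B", "C"), c("B", "C", "A")))

test_that("random +1 interactomes have exactly the requested size", {
  set.seed(1)
  # saturation: target = whole network, universe = all genes
  expect_setequal(random_plus_one(star, star$genes, 5L), star$genes)
  # hand-traced single-seed draw: X's +1 is {X,P,Q,R,S}; truncation to 3
  for (rep in 1:20) {
    got <- random_plus_one(star, "X", 3L)
    expect_length(got, 3L)
    expect_true(all(got %in% c("X", "P", "Q", "R", "S")))
  }
  # exactness contract on a bigger graph
  st <- small_study()
  for (target in c(1L, 7L, 40L)) {
    expect_length(random_plus_one(st$net, st$lists$universe, target), target)
  }
})

test_that("an exhausted universe is a simulation error naming the size", {
  # P's +1 interactome is {P, X}: universe {P} cannot reach size 4
  expect_error(random_plus_one(star, "P", 4L), "size 2 of requested 4")
})

test_that("tie saturation yields n_right = n_left = n_sim and p = 1", {
  gwas_p1 <- plus_one(triangle, c("A", "B", "C"))
  r <- overlap_test(triangle, "A", gwas_p1, triangle$genes,
                    mc_config(n_sim = 50L, rng_seed = 2))
  expect_equal(r$observed, 3L)
  expect_equal(r$n_right, 50L)
  expect_equal(r$n_left, 50L)
  expect_equal(r$p, 1)
  expect_equal(r$direction, "larger")  # exact tie is assigned larger
  expect_true(r$tie)
})

test_that("empirical p matches exhaustive enumeration on the toy network", {
  net <- toy_network()
  universe <- c("H", "A", "D", "F", "K")
  gwas_p1 <- plus_one(net, c("C", "E"))
  cfg <- mc_config(n_sim = 3000L, rng_seed = 31)
  r <- overlap_test(net, "B", gwas_p1, universe, cfg)

  dist <- exact_overlap_dist(net, universe, r$size, gwas_p1$members)
  ks <- seq_along(dist) - 1L
  p_right <- sum(dist[ks >= r$observed])
  p_left <- sum(dist[ks <= r$observed])
  se_r <- sqrt(p_right * (1 - p_right) / cfg$n_sim)
  se_l <- sqrt(p_left * (1 - p_left) / cfg$n_sim)
  expect_lt(abs(r$n_right / cfg$n_sim - p_right), 3 * se_r + 1e-12)
  expect_lt(abs(r$n_left / cfg$n_sim - p_left), 3 * se_l + 1e-12)
})

test_that("absent genes are skipped with a warning", {
  gwas_p1 <- plus_one(star, "P")
  expect_warning(r <- overlap_test(star, "NOPE", gwas_p1, star$genes,
                                   mc_config(n_sim = 10L, rng_seed = 1)),
                 "not in network")
  expect_null(r)
})

test_that("screen results carry the tail identity, the p grid and sorting", {
  st <- small_study()
  cfg <- mc_config(n_sim = 100L, rng_seed = 7)
  scr <- screen_overlap_tests(st$net, st$lists$hits, st$lists$gwas,
                              st$lists$universe, cfg)
  expect_s3_class(scr, "overlap_screen")
  expect_equal(nrow(scr), length(st$lists$hits$genes))
  # p = min(n_right, n_left)/n_sim, on the discrete grid
  expect_equal(scr$p, pmin(scr$n_right, scr$n_left) / cfg$n_sim)
  expect_true(all(abs(scr$p * cfg$n_sim - round(scr$p * cfg$n_sim)) < 1e-9))
  # two one-sided counts overlap exactly in the ties:
  # n_right + n_left - ties = n_sim, so both tails cover the support
  expect_true(all(scr$n_right + scr$n_left >= cfg$n_sim))
  # direction is determined by the smaller tail
  expect_equal(scr$direction,
               ifelse(scr$n_right <= scr$n_left, "larger", "smaller"))
  # sorted by ascending p, ties by symbol
  expect_equal(order(scr$p, scr$gene), seq_len(nrow(scr)))
})

test_that("tie counts reconcile the two one-sided tails with n_sim", {
  net <- toy_network()
  gwas_p1 <- plus_one(net, c("C", "E"))
  cfg <- mc_config(n_sim = 200L, rng_seed = 3)
  r <- overlap_test(net, "B", gwas_p1, c("H", "A", "D", "F", "K"), cfg,
                    mid_p = TRUE)
  # with ties counted in both tails, mid-p removes half the tie mass
  n_tie <- r$n_right + r$n_left - cfg$n_sim
  expect_gte(n_tie, 0L)
  expect_equal(r$p_mid, (min(r$n_right, r$n_left) - n_tie / 2) / cfg$n_sim)
  expect_lte(r$p_mid, r$p)
})

test_that("identical seeds reproduce identical result tables", {
  st <- small_study()
  cfg <- mc_config(n_sim = 60L, rng_seed = 99)
  a <- screen_overlap_tests(st$net, st$lists$hits, st$lists$gwas,
                            st$lists$universe, cfg)
  b <- screen_overlap_tests(st$net, st$lists$hits, st$lists$gwas,
                            st$lists$universe, cfg)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("direct-interactor flags reflect adjacency to GWAS seeds", {
  # W-G edge, G in the GWAS list; V is two steps away
  net <- build_network(records(c("W", "G", "V"), c("G", "U", "W")))
  scr <- screen_overlap_tests(net, c("W", "V"), "G", net$genes,
                              mc_config(n_sim = 20L, rng_seed = 5))
  expect_true(scr$direct_interactor[scr$gene == "W"])
  expect_false(scr$direct_interactor[scr$gene == "V"])
})

test_that("screen genes missing from the network propagate as skips", {
  expect_warning(
    screen_overlap_tests(star, c("X", "ZZ"), "P", star$genes,
                         mc_config(n_sim = 20L, rng_seed = 5)),
    "skipped")
  scr <- suppressWarnings(
    screen_overlap_tests(star, c("X", "ZZ"), "P", star$genes,
                         mc_config(n_sim = 20L, rng_seed = 5)))
  expect_equal(nrow(scr), 1L)
  expect_equal(attr(scr, "skipped"), "ZZ")
})

test_that("list-level counts are bounded and the empty tail gives 0", {
  st <- small_study()
  gwas_p1 <- plus_one(st$net, st$lists$gwas)
  cfg <- mc_config(n_sim = 50L, n_lists = 8L, list_size = 6L,
                   alpha = 0.05, rng_seed = 13)
  lls <- null_list_significance(st$net, st$lists$universe, gwas_p1, cfg,
                                k_observed = 2L)
  expect_length(lls$counts_per_list, 8L)
  expect_true(all(lls$counts_per_list >= 0L &
                    lls$counts_per_list <= cfg$list_size))
  expect_equal(lls$p_ge_k, mean(lls$counts_per_list >= 2L))
  # a k beyond the maximum observed count has an empty tail
  lls2 <- null_list_significance(st$net, st$lists$universe, gwas_p1, cfg,
                                 k_observed = max(lls$counts_per_list) + 1L)
  expect_equal(lls2$p_ge_k, 0)
})

test_that("a vanishing alpha sends all list counts to zero", {
  # degenerate saturated network: every per-gene p is exactly 1
  gwas_p1 <- plus_one(triangle, c("A", "B", "C"))
  cfg <- mc_config(n_sim = 20L, n_lists = 4L, list_size = 2L,
                   alpha = 1e-9, rng_seed = 17)
  lls <- null_list_significance(triangle, triangle$genes, gwas_p1, cfg)
  expect_equal(lls$counts_per_list, rep(0L, 4L))
  expect_equal(lls$mean, 0)
})
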