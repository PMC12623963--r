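sim_from <- function(m, ids) {
  dimnames(m) <- list(ids, ids)
  m
}

test_that("PSS is the off-diagonal row mean", {
  ids <- c("A", "B", "C", "D")
  expect_equal(pss(sim_from(matrix(1, 4, 4), ids)),
               setNames(rep(1, 4), ids))

  m <- diag(3)
  m[1, 2] <- m[2, 1] <- 0.9
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.2
  p <- pss(sim_from(m, c("A", "B", "C")))
  expect_equal(unname(p), c(0.55, 0.55, 0.2))

  # permuting model order permutes PSS identically
  perm <- c(3, 1, 2)
  p2 <- pss(sim_from(m[perm, perm], c("A", "B", "C")[perm]))
  expect_equal(p2[names(p)], p)

  expect_error(pss(matrix(1, 1, 1)), "size >= 2")
})

test_that("PSS of a duplicated model is non-decreasing in its copy count", {
  ref <- make_reference_chain(30, "helix", 2)
  pool <- make_decoys(ref, decoy_pool_spec(n_models = 6, sigma_grid = 2,
                                           rng_seed = 31))
  models <- pool$models
  target <- models[[1]]
  last <- -Inf
  for (k in 0:3) {
    extra <- replicate(k, target, simplify = FALSE)
    for (i in seq_len(k)) extra[[i]]$model_id <- paste0("dup", i)
    p <- pss(pairwise_matrix(c(models, extra), "tm"))
    expect_gte(p[[target$model_id]] + 1e-9, last)
    last <- p[[target$model_id]]
  }
})

test_that("score aggregation normalizes, averages and breaks ties deterministically", {
  tab <- score_table(data.frame(model_id = c("m1", "m2", "m3"),
                                a = c(10, 0, 5), b = c(0, 1, NA),
                                const = c(2, 2, 2)))
  # single column: ranking identical to the column
  expect_equal(rank_order <- names(sort(-aggregate_scores(tab, "a"))),
               c("m1", "m3", "m2"))

  # two exactly opposed columns tie; lexicographic id order breaks the tie
  tab2 <- score_table(data.frame(model_id = c("mB", "mA"),
                                 a = c(1, 0), b = c(0, 1)))
  agg <- aggregate_scores(tab2, c("a", "b"))
  expect_equal(unname(agg), c(0.5, 0.5))
  expect_equal(foldrank:::rank_ids(agg), c("mA", "mB"))

  # constant column contributes 0.5 after degenerate normalization
  expect_equal(unname(aggregate_scores(tab, "const")), rep(0.5, 3))

  # model missing all named scores ranks last
  tab3 <- score_table(data.frame(model_id = c("m1", "m2"), g = c(NA, 0.2)))
  expect_equal(foldrank:::rank_ids(aggregate_scores(tab3, "g")),
               c("m2", "m1"))

  expect_error(aggregate_scores(tab, "nope"), "lookup")
})

test_that("K-means clustering recovers planted conformations and is deterministic", {
  ref <- make_reference_chain(48, "helix", 3)
  spec <- decoy_pool_spec(
    n_models = 40, sigma_grid = 0.8,
    conformations = list(list(weight = 0.5, hinge_angle = 0, generator = "af2"),
                         list(weight = 0.5, hinge_angle = 80,
                              generator = "af2")),
    rng_seed = 17)
  pool <- make_decoys(ref, spec, truth_scores = "tm")
  sim <- pairwise_matrix(pool$models, "tm")
  tab <- score_table(data.frame(model_id = pool$truth$model_id,
                                gate = pool$truth$plddt / 100))
  cfg <- selection_config("multicom_gate", n_clusters = 2, rng_seed = 5)
  cl <- cluster_models(sim, tab, cfg)
  # planted partition recovered exactly (two well-separated conformations)
  planted <- pool$truth$conformation
  tab12 <- table(cl$labels, planted)
  expect_equal(sum(apply(tab12, 1, max)), length(planted))
  expect_true(all(cl$representatives %in% names(cl$labels)))

  cl2 <- cluster_models(sim, tab, cfg)
  expect_identical(cl$labels, cl2$labels)  # same seed, same labels

  # all-identical pool collapses to one cluster
  same <- replicate(4, pool$models[[1]], simplify = FALSE)
  for (k in 1:4) same[[k]]$model_id <- paste0("s", k)
  sim1 <- pairwise_matrix(same, "tm")
  tabs <- score_table(data.frame(model_id = paste0("s", 1:4),
                                 gate = c(0.2, 0.9, 0.5, 0.1)))
  cl3 <- cluster_models(sim1, tabs, selection_config("multicom_gate"))
  expect_equal(length(cl3$representatives), 1L)
  expect_equal(cl3$representatives[[1]], "s2")
})

test_that("diversity selection implements the greedy TM cutoff and AF3 guarantee", {
  ids <- paste0("m", 1:10)
  # degenerate: everything identical -> top-5 by rank via fill rule
  sim <- sim_from(matrix(1, 10, 10), ids)
  cfg <- selection_config("multicom_ai", require_af3 = FALSE)
  expect_equal(diversity_select(ids, sim, cfg), ids[1:5])

  # 5 mutually dissimilar models are picked in rank order
  m <- matrix(0.95, 10, 10); diag(m) <- 1
  dissim <- c(1, 3, 5, 7, 9)
  m[dissim, dissim] <- 0.3; diag(m) <- 1
  sim2 <- sim_from(m, ids)
  expect_equal(diversity_select(ids, sim2, cfg), ids[dissim])

  # greedy recomputation oracle on random matrices
  set.seed(23)
  for (trial in 1:20) {
    mm <- matrix(runif(100, 0.2, 1), 10)
    mm <- (mm + t(mm)) / 2; diag(mm) <- 1
    simr <- sim_from(mm, ids)
    got <- diversity_select(ids, simr, cfg)
    kept <- ids[1]
    for (id in ids[-1]) {
      if (length(kept) >= 5) break
      if (all(simr[id, kept] < 0.8)) kept <- c(kept, id)
    }
    if (length(kept) < 5) kept <- c(kept, setdiff(ids, kept)[seq_len(5 - length(kept))])
    expect_equal(got, kept)
  }

  # af3 guarantee: last slot replaced by the best-ranked af3 model
  gens <- setNames(rep("af2", 10), ids)
  gens["m7"] <- "af3"
  cfg2 <- selection_config("multicom_ai", require_af3 = TRUE)
  got <- diversity_select(ids, sim, cfg2, generators = gens)
  expect_equal(got[5], "m7")
  expect_equal(got[1:4], ids[1:4])
})

test_that("the five ranking strategies follow their selection rules", {
  set.seed(41)
  n <- 12
  ids <- sprintf("m%02d", 1:n)
  mm <- matrix(runif(n * n, 0.3, 0.9), n)
  mm <- (mm + t(mm)) / 2; diag(mm) <- 1
  sim <- sim_from(mm, ids)
  tab <- score_table(data.frame(
    model_id = ids,
    plddt_global = round(runif(n, 40, 95), 1),
    gate = round(runif(n), 3),
    af3_ranking = round(runif(n), 3),
    gcpnet_ema = round(runif(n), 3),
    enqa = round(runif(n), 3),
    pss = pss(sim)))
  models <- lapply(seq_len(n), function(i) {
    toy_model(toy_chain_coords(5), ids[i],
              generator = ifelse(i %% 4 == 0, "af3", "af2"))
  })

  # multicom_ai == diversity_select over the plddt ranking
  cfg <- selection_config("multicom_ai", rng_seed = 2)
  sel <- select_top(models, sim, tab, cfg)
  gens <- setNames(vapply(models, `[[`, character(1), "generator"), ids)
  manual <- diversity_select(foldrank:::rank_ids(
    setNames(tab$plddt_global, ids)), sim, cfg, gens)
  expect_equal(sel$model_id, manual)

  # multicom_llm top-1 is argmax af3_ranking
  sel <- select_top(models, sim, tab, selection_config("multicom_llm"))
  expect_equal(sel$model_id[1], ids[which.max(tab$af3_ranking)])
  expect_equal(nrow(sel), 5L)

  # multicom_human top-1 maximizes the normalized gate/plddt mean
  sel <- select_top(models, sim, tab, selection_config("multicom_human"))
  agg <- aggregate_scores(tab, c("gate", "plddt_global"))
  expect_equal(sel$model_id[1], names(which.max(agg)))

  # multicom top-1 averages af3 ranking and gate; slots are distinct
  sel <- select_top(models, sim, tab, selection_config("multicom"))
  agg2 <- aggregate_scores(tab, c("af3_ranking", "gate"))
  expect_equal(sel$model_id[1], names(which.max(agg2)))
  expect_equal(anyDuplicated(sel$model_id), 0L)
  expect_equal(nrow(sel), 5L)

  # every strategy returns n_select distinct ids when the pool allows
  for (st in c("multicom_ai", "multicom_gate", "multicom_llm", "multicom",
               "multicom_human")) {
    sel <- select_top(models, sim, tab, selection_config(st, rng_seed = 3))
    expect_equal(nrow(sel), 5L)
    expect_equal(anyDuplicated(sel$model_id), 0L)
  }

  # missing required column errors with the strategy name
  tab2 <- tab; tab2$gate <- NULL
  expect_error(select_top(models, sim, score_table(tab2),
                          selection_config("multicom_gate")),
               "multicom_gate.*gate")

  # manual adjustment is an explicit override applied last
  sel <- select_top(models, sim, tab, selection_config("multicom"),
                    override = c("m09", "m01"))
  expect_equal(sel$model_id[1:2], c("m09", "m01"))
  expect_equal(sel$criterion[1:2], c("override", "override"))
})
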