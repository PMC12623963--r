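#' Average pairwise similarity score (PSS)
#'
#' The consensus quality score of a model is its mean structural similarity
#' (typically TM-score) to every other model in the pool: models resembling
#' many pool members score high. This makes PSS powerful when good models
#' dominate the pool and systematically misleading when a wrong conformation
#' does.
#'
#' @param similarity Symmetric similarity matrix (>= 2 x 2) with model ids
#'   as dimnames.
#' @return Named vector of per-model PSS values.
#' @export
pss <- function(similarity) {
  similarity <- as.matrix(similarity)
  n <- nrow(similarity)
  if (n < 2L || ncol(similarity) != n) {
    stop("similarity must be a symmetric matrix of size >= 2", call. = FALSE)
  }
  out <- (rowSums(similarity) - diag(similarity)) / (n - 1)
  names(out) <- rownames(similarity)
  out
}

#' Selection configuration for model ranking strategies
#'
#' @param strategy One of `"multicom_ai"`, `"multicom_gate"`,
#'   `"multicom_llm"`, `"multicom"`, `"multicom_human"`.
#' @param n_select Number of models to select (default 5, the CASP
#'   submission count).
#' @param diversity_tm_cutoff Models are "structurally diverse" when their
#'   pairwise TM-score is below this cutoff (default 0.8).
#' @param n_clusters K for K-means model clustering (default 5).
#' @param require_af3 Guarantee at least one AlphaFold3-generated model in
#'   the selection when one exists in the pool.
#' @param rng_seed Seed for the K-means restarts.
#' @param normalize Min-max normalize score columns before averaging; set
#'   `FALSE` to average raw scores.
#' @param primary_score Column used to pick cluster representatives
#'   (fallback `plddt_global`).
#' @return A `selection_config` list.
#' @export
selection_config <- function(strategy = "multicom", n_select = 5,
                             diversity_tm_cutoff = 0.8, n_clusters = 5,
                             require_af3 = TRUE, rng_seed = 1L,
                             normalize = TRUE, primary_score = "gate") {
  strategy <- match.arg(strategy, c("multicom_ai", "multicom_gate",
                                    "multicom_llm", "multicom",
                                    "multicom_human"))
  stopifnot(n_select >= 1, diversity_tm_cutoff > 0, diversity_tm_cutoff <= 1)
  structure(list(strategy = strategy, n_select = as.integer(n_select),
                 diversity_tm_cutoff = diversity_tm_cutoff,
                 n_clusters = as.integer(n_clusters),
                 require_af3 = require_af3, rng_seed = as.integer(rng_seed),
                 normalize = normalize, primary_score = primary_score),
            class = "selection_config")
}

get_column <- function(table, name) {
  if (!name %in% names(table)) {
    stop("lookup error: score column '", name, "' not in table", call. = FALSE)
  }
  setNames(table[[name]], table$model_id)
}

minmax <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!is.finite(r[1L])) return(x)
  if (r[1L] == r[2L]) return(ifelse(is.na(x), NA, 0.5))  # constant column
  (x - r[1L]) / (r[2L] - r[1L])
}

#' Aggregate score columns into one ranking score
#'
#' Each named column is min-max normalized to \[0, 1\] over the models where
#' it is present (a constant column contributes 0.5 everywhere), then the
#' per-model mean over present values is taken, optionally weighted. Models
#' missing every named score get `-Inf` so they rank last.
#'
#' @param table A `score_table`.
#' @param names Score column names to combine.
#' @param weights Optional positive weights, one per column.
#' @param normalize Min-max normalize before averaging (default `TRUE`).
#' @return Named per-model vector of aggregate scores.
#' @export
aggregate_scores <- function(table, names, weights = NULL, normalize = TRUE) {
  cols <- lapply(names, function(nm) {
    x <- get_column(table, nm)
    if (normalize) minmax(x) else x
  })
  if (is.null(weights)) weights <- rep(1, length(cols))
  stopifnot(length(weights) == length(cols), all(weights > 0))
  num <- rep(0, nrow(table)); den <- rep(0, nrow(table))
  for (k in seq_along(cols)) {
    ok <- !is.na(cols[[k]])
    num[ok] <- num[ok] + weights[k] * cols[[k]][ok]
    den[ok] <- den[ok] + weights[k]
  }
  out <- ifelse(den > 0, num / den, -Inf)
  setNames(out, table$model_id)
}

# Model ids ordered by score descending, NA/-Inf last, ties lexicographic.
rank_ids <- function(scores) {
  scores[is.na(scores)] <- -Inf
  names(scores)[order(-scores, names(scores))]
}

#' Cluster a model pool by structural similarity
#'
#' K-means on the rows of the dissimilarity matrix `1 - similarity` groups
#' structurally similar models; the representative of each cluster is its
#' highest-scoring member under the configured primary score (fallback
#' `plddt_global`). Clusters are ordered by representative score descending.
#' The seed and restart count are fixed for determinism.
#'
#' @param similarity Symmetric similarity matrix with model-id dimnames.
#' @param table A `score_table` covering the pool.
#' @param config A [selection_config()].
#' @return A `cluster_assignment`: list with `labels` (named integer
#'   vector), `representatives` and `cluster_sizes`, in cluster order.
#' @export
cluster_models <- function(similarity, table, config = selection_config()) {
  ids <- rownames(similarity)
  if (length(ids) < 2L) stop("need at least two models", call. = FALSE)
  feat <- 1 - similarity
  k <- min(config$n_clusters, nrow(unique(feat)))
  if (k <= 1L) {
    labels <- setNames(rep(1L, length(ids)), ids)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$rng_seed)
    km <- kmeans(feat, centers = k, nstart = 10L, iter.max = 50L)
    labels <- setNames(km$cluster, ids)
  }
  score <- cluster_primary_score(table, config)
  reps <- vapply(sort(unique(labels)), function(cl) {
    members <- names(labels)[labels == cl]
    rank_ids(score[members])[1L]
  }, character(1))
  o <- order(-score[reps], reps)
  reps <- reps[o]
  # relabel clusters in representative-score order
  relabel <- setNames(seq_along(o), sort(unique(labels))[o])
  labels <- setNames(as.integer(relabel[as.character(labels)]), ids)
  structure(list(labels = labels, representatives = reps,
                 cluster_sizes = tabulate(labels, nbins = length(reps))),
            class = "cluster_assignment")
}

cluster_primary_score <- function(table, config) {
  nm <- config$primary_score
  if (!nm %in% names(table) || all(is.na(table[[nm]]))) nm <- "plddt_global"
  if (!nm %in% names(table)) {
    stop("configuration error: neither '", config$primary_score,
         "' nor 'plddt_global' available for cluster representatives",
         call. = FALSE)
  }
  get_column(table, nm)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Greedy structural-diversity selection
#'
#' Walks the ranked list keeping a model only if its TM-score to every
#' already-kept model is below the diversity cutoff; if fewer than
#' `n_select` survive, the best remaining models by rank fill the gap. When
#' `require_af3` is set and no kept model came from AlphaFold3 while one
#' exists in the pool, the last slot is replaced by the best-ranked
#' AlphaFold3 model.
#'
#' @param ranked_ids Model ids in rank order (best first).
#' @param similarity Symmetric TM-score matrix with model-id dimnames.
#' @param config A [selection_config()].
#' @param generators Optional named character vector of generator tags
#'   (`"af2"`, `"af3"`, ...) used by the AlphaFold3 guarantee.
#' @return Up to `n_select` model ids in selection order.
#' @export
diversity_select <- function(ranked_ids, similarity,
                             config = selection_config(),
                             generators = NULL) {
  stopifnot(length(ranked_ids) >= 1L)
  kept <- ranked_ids[1L]
  for (id in ranked_ids[-1L]) {
    if (length(kept) >= config$n_select) break
    if (all(similarity[id, kept] < config$diversity_tm_cutoff)) {
      kept <- c(kept, id)
    }
  }
  if (length(kept) < config$n_select) {
    fill <- setdiff(ranked_ids, kept)
    kept <- c(kept, fill[seq_len(min(config$n_select - length(kept),
                                     length(fill)))])
  }
  if (config$require_af3 && !is.null(generators)) {
    af3 <- ranked_ids[generators[ranked_ids] == "af3"]
    if (length(af3) && !any(kept %in% af3)) {
      kept[length(kept)] <- af3[1L]
    }
  }
  kept
}

strategy_columns <- list(
  multicom_ai = "plddt_global",
  multicom_gate = "gate",
  multicom_llm = c("af3_ranking", "gate", "plddt_global"),
  multicom = c("af3_ranking", "gate", "plddt_global", "gcpnet_ema", "enqa",
               "pss"),
  multicom_human = c("gate", "plddt_global"))

#' Select top models with a CASP16 MULTICOM ranking strategy
#'
#' Implements the five predictor strategies:
#' \describe{
#'   \item{multicom_ai}{Rank by global plDDT; top-1 plus up to four
#'     structurally diverse models (pairwise TM < cutoff); an AlphaFold3
#'     model is guaranteed a slot if present.}
#'   \item{multicom_gate}{Rank by GATE; K-means clustering of the pool; the
#'     top-GATE model of each cluster is selected, clusters ordered by
#'     representative score; AlphaFold3 guarantee as above.}
#'   \item{multicom_llm}{Top-1 by AlphaFold3 ranking score; remaining slots
#'     by the average of GATE and global plDDT.}
#'   \item{multicom}{Top-1 by the average of AlphaFold3 ranking score and
#'     GATE; remaining slots drawn in turn from the average of GATE and
#'     plDDT, then GATE, GCPNet-EMA, EnQA and PSS individually, taking the
#'     next-best unused model under each criterion.}
#'   \item{multicom_human}{Top-1 by the average of GATE and global plDDT;
#'     remaining slots by global plDDT.}
#' }
#' Manual-adjustment steps are represented by an explicit `override` list
#' applied last, never by heuristics.
#'
#' @param models List of `structure_model` (for generator tags), or `NULL`
#'   to skip the AlphaFold3 guarantee.
#' @param similarity Pairwise TM-score matrix of the pool.
#' @param table A `score_table` with the columns the strategy needs.
#' @param config A [selection_config()].
#' @param override Optional character vector of model ids forced, in order,
#'   into the leading slots.
#' @return Data frame with columns `rank`, `model_id`, `criterion`, `score`.
#' @export
select_top <- function(models, similarity, table,
                       config = selection_config(), override = NULL) {
  need <- strategy_columns[[config$strategy]]
  miss <- setdiff(need, names(table))
  if (length(miss)) {
    stop("configuration error: strategy ", config$strategy,
         " requires score column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  generators <- NULL
  if (!is.null(models)) {
    generators <- setNames(vapply(models, `[[`, character(1), "generator"),
                           vapply(models, `[[`, character(1), "model_id"))
  }
  norm <- config$normalize
  sel <- switch(config$strategy,
    multicom_ai = {
      ranked <- rank_ids(get_column(table, "plddt_global"))
      ids <- diversity_select(ranked, similarity, config, generators)
      data.frame(model_id = ids, criterion = "plddt_global+diversity",
                 score = get_column(table, "plddt_global")[ids])
    },
    multicom_gate = {
      gate <- get_column(table, "gate")
      cl <- cluster_models(similarity, table, config)
      ids <- cl$representatives
      if (length(ids) < config$n_select) {
        fill <- setdiff(rank_ids(gate), ids)
        ids <- c(ids, fill[seq_len(min(config$n_select - length(ids),
                                       length(fill)))])
      }
      ids <- ids[seq_len(min(config$n_select, length(ids)))]
      if (config$require_af3 && !is.null(generators)) {
        af3 <- rank_ids(gate)[generators[rank_ids(gate)] == "af3"]
        if (length(af3) && !any(ids %in% af3)) ids[length(ids)] <- af3[1L]
      }
      data.frame(model_id = ids, criterion = "gate+kmeans",
                 score = gate[ids])
    },
    multicom_llm = {
      top1 <- rank_ids(get_column(table, "af3_ranking"))[1L]
      rest <- aggregate_scores(table, c("gate", "plddt_global"),
                               normalize = norm)
      rest_ids <- setdiff(rank_ids(rest), top1)
      ids <- c(top1, rest_ids[seq_len(min(config$n_select - 1L,
                                          length(rest_ids)))])
      data.frame(model_id = ids,
                 criterion = c("af3_ranking",
                               rep("mean(gate,plddt)", length(ids) - 1L)),
                 score = c(get_column(table, "af3_ranking")[top1],
                           rest[ids[-1L]]))
    },
    multicom = {
      top_sc <- aggregate_scores(table, c("af3_ranking", "gate"),
                                 normalize = norm)
      picked <- rank_ids(top_sc)[1L]
      crit <- "mean(af3_ranking,gate)"
      scores <- top_sc[picked]
      criteria <- list(
        list(name = "mean(gate,plddt)",
             sc = aggregate_scores(table, c("gate", "plddt_global"),
                                   normalize = norm)),
        list(name = "gate", sc = get_column(table, "gate")),
        list(name = "gcpnet_ema", sc = get_column(table, "gcpnet_ema")),
        list(name = "enqa", sc = get_column(table, "enqa")),
        list(name = "pss", sc = get_column(table, "pss")))
      k <- 1L
      while (length(picked) < config$n_select) {
        cr <- criteria[[(k - 1L) %% length(criteria) + 1L]]
        cand <- setdiff(rank_ids(cr$sc), picked)
        if (length(cand) == 0L) break
        picked <- c(picked, cand[1L])
        crit <- c(crit, cr$name)
        scores <- c(scores, cr$sc[cand[1L]])
        k <- k + 1L
      }
      data.frame(model_id = picked, criterion = crit, score = scores)
    },
    multicom_human = {
      top_sc <- aggregate_scores(table, c("gate", "plddt_global"),
                                 normalize = norm)
      top1 <- rank_ids(top_sc)[1L]
      plddt <- get_column(table, "plddt_global")
      rest_ids <- setdiff(rank_ids(plddt), top1)
      ids <- c(top1, rest_ids[seq_len(min(config$n_select - 1L,
                                          length(rest_ids)))])
      data.frame(model_id = ids,
                 criterion = c("mean(gate,plddt)",
                               rep("plddt_global", length(ids) - 1L)),
                 score = c(top_sc[top1], plddt[ids[-1L]]))
    })

  if (!is.null(override) && length(override)) {
    override <- override[override %in% table$model_id]
    keep <- sel$model_id[!sel$model_id %in% override]
    ids <- c(override, keep)[seq_len(min(config$n_select,
                                         length(override) + length(keep)))]
    sel <- data.frame(model_id = ids,
                      criterion = ifelse(ids %in% override, "override",
                                         sel$criterion[match(ids,
                                                             sel$model_id)]),
                      score = NA_real_)
  }
  rownames(sel) <- NULL
  cbind(rank = seq_len(nrow(sel)), sel)
}
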