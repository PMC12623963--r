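#' Scoring parameters for superposition-search scores
#'
#' Houses the TM-score distance scale floor, the GDT threshold set and the
#' deterministic search hyperparameters (seed windows, refinement caps).
#' Window lengths `NA` are placeholders resolved per call to `L/2` and `L`
#' for the matched length L.
#'
#' @param d0_floor Lower bound on the TM-score distance scale d0 (Angstrom).
#' @param gdt_thresholds Ascending positive distance cutoffs (Angstrom).
#' @param seed_window_lengths Seed superposition window lengths; `NA` entries
#'   stand for L/2 and L.
#' @param max_refine_iters Cap on select/re-superpose refinement iterations.
#' @param convergence_tol Score-change convergence tolerance.
#' @return A `scoring_params` list.
#' @export
scoring_params <- function(d0_floor = 0.5, gdt_thresholds = c(1, 2, 4, 8),
                           seed_window_lengths = c(3, 5, 7, NA, NA),
                           max_refine_iters = 20, convergence_tol = 1e-5) {
  stopifnot(all(diff(gdt_thresholds) > 0), all(gdt_thresholds > 0))
  structure(list(d0_floor = d0_floor, gdt_thresholds = gdt_thresholds,
                 seed_window_lengths = seed_window_lengths,
                 max_refine_iters = as.integer(max_refine_iters),
                 convergence_tol = convergence_tol),
            class = "scoring_params")
}

resolve_seeds <- function(params, L) {
  if (L <= 30L) return(3:L)  # short chains: exhaustive window lengths
  s <- params$seed_window_lengths
  s[is.na(s)] <- c(L %/% 2L, L)[seq_len(sum(is.na(s)))]
  s <- unique(pmin(as.integer(s), L))
  sort(s[s >= 3L])
}

#' TM-score distance scale
#'
#' `d0 = max(d0_floor, 1.24 (L - 15)^(1/3) - 1.8)` for reference length L.
#'
#' @param l_ref Reference length (residues).
#' @param d0_floor Lower bound, Angstrom.
#' @return d0 in Angstrom.
#' @export
tm_d0 <- function(l_ref, d0_floor = 0.5) {
  if (l_ref <= 15) return(d0_floor)
  max(d0_floor, 1.24 * (l_ref - 15)^(1 / 3) - 1.8)
}

#' Optimal rigid superposition of two coordinate sets
#'
#' Least-squares (Kabsch) superposition of `mov` onto `ref`, reflection
#' corrected so the rotation is proper.
#'
#' @param ref,mov Equal-length n x 3 coordinate matrices, n >= 3.
#' @return A `superposition_result`: list with `rotation` (3 x 3, det +1),
#'   `translation`, `rmsd` and `per_residue_distance`; the transform maps
#'   `mov` onto `ref` as `mov %*% t(rotation) + translation`.
#' @export
kabsch_superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov) || ncol(ref) != 3L || ncol(mov) != 3L) {
    stop("ref and mov must be equal-length n x 3 matrices", call. = FALSE)
  }
  if (nrow(ref) < 3L) stop("need at least 3 points", call. = FALSE)
  out <- cpp_kabsch(ref, mov)
  structure(out, class = "superposition_result")
}

#' Apply a superposition to coordinates
#'
#' @param sp A `superposition_result`.
#' @param coords n x 3 coordinate matrix.
#' @return The transformed coordinates.
#' @export
apply_superposition <- function(sp, coords) {
  sweep(as.matrix(coords) %*% t(sp$rotation), 2L, -sp$translation)
}

# Residue correspondence by shared residue numbers; errors below min_shared.
match_residues <- function(ref, model, min_shared = 3L) {
  shared <- intersect(ref$residue_ids, model$residue_ids)
  if (length(shared) < min_shared) {
    stop("fewer than ", min_shared, " shared residues between ",
         ref$model_id, " and ", model$model_id, call. = FALSE)
  }
  list(ref = ref$ca_coords[match(shared, ref$residue_ids), , drop = FALSE],
       mov = model$ca_coords[match(shared, model$residue_ids), , drop = FALSE],
       shared = shared)
}

#' TM-score of a model against a reference
#'
#' Length-normalized structural similarity in (0, 1\]; values above 0.5
#' conventionally indicate the same fold and above 0.9 near-native accuracy.
#' Residues correspond by shared residue numbers; the score is normalized by
#' the reference length. The superposition search is deterministic: each
#' seed window is superposed by Kabsch, then refined by iteratively
#' re-superposing on residues closer than the d0-derived cutoff.
#'
#' @param ref Reference `structure_model` (normalization length source).
#' @param model Model `structure_model`.
#' @param params A [scoring_params()].
#' @return TM-score in (0, 1].
#' @export
tm_score <- function(ref, model, params = scoring_params()) {
  mt <- match_residues(ref, model)
  L <- length(ref$residue_ids)
  d0 <- tm_d0(L, params$d0_floor)
  cpp_tm(mt$ref, mt$mov, L, d0, resolve_seeds(params, nrow(mt$ref)),
         params$max_refine_iters, params$convergence_tol)
}

#' GDT-TS of a model against a reference
#'
#' Mean over the 1/2/4/8 Angstrom cutoffs of the maximal fraction of
#' reference residues superimposable within the cutoff, searched over the
#' same deterministic seed-and-refine scheme as [tm_score()] with the cutoff
#' itself as the refinement radius.
#'
#' @inheritParams tm_score
#' @return GDT-TS in \[0, 1\].
#' @export
gdt_ts <- function(ref, model, params = scoring_params()) {
  mt <- match_residues(ref, model)
  L <- length(ref$residue_ids)
  cpp_gdt(mt$ref, mt$mov, L, params$gdt_thresholds,
          resolve_seeds(params, nrow(mt$ref)),
          params$max_refine_iters, params$convergence_tol)
}

#' Pairwise similarity matrix over a model pool
#'
#' Entry (i, j) is the chosen metric with model i as reference and model j
#' as mobile, symmetrized as the mean of the two directions; the diagonal is
#' 1. When all models share an identical residue set the computation runs in
#' compiled code over the whole pool.
#'
#' @param models List of two or more `structure_model` sharing residues.
#' @param metric `"tm"` or `"gdt"`.
#' @param params A [scoring_params()].
#' @return Symmetric similarity matrix with model ids as dimnames.
#' @export
pairwise_matrix <- function(models, metric = c("tm", "gdt"),
                            params = scoring_params()) {
  metric <- match.arg(metric)
  n <- length(models)
  if (n < 2L) stop("need at least two models", call. = FALSE)
  ids <- vapply(models, `[[`, character(1), "model_id")

  same_space <- all(vapply(models, function(m) {
    identical(m$residue_ids, models[[1L]]$residue_ids)
  }, logical(1)))

  if (metric == "tm" && same_space) {
    L <- length(models[[1L]]$residue_ids)
    stacked <- do.call(rbind, lapply(models, function(m) t(m$ca_coords)))
    mm <- cpp_tm_matrix(stacked, n, tm_d0(L, params$d0_floor),
                        resolve_seeds(params, L),
                        params$max_refine_iters, params$convergence_tol)
  } else {
    fn <- if (metric == "tm") tm_score else gdt_ts
    mm <- diag(1, n)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j) mm[i, j] <- fn(models[[i]], models[[j]], params)
      }
    }
  }
  mm <- (mm + t(mm)) / 2
  diag(mm) <- 1
  dimnames(mm) <- list(ids, ids)
  mm
}
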