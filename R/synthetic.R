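# Synthetic fixtures: CA reference chains, noise-controlled decoy pools with
# planted conformational clusters, MSAs with controlled per-column depth, and
# template-hit tables. All generators are pure functions of (spec, seed).

unit_vec <- function(v) v / sqrt(sum(v^2))

# Rodrigues rotation matrix about unit axis u by angle (radians).
rotation_about <- function(u, angle) {
  u <- unit_vec(u)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3L, 3L,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

random_rotation <- function() {
  # uniform over SO(3) via QR of a Gaussian matrix, sign-corrected
  qr_ <- qr(matrix(rnorm(9), 3L))
  Q <- qr.Q(qr_) %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}

random_sequence <- function(n) paste0(sample(AA20, n, replace = TRUE),
                                      collapse = "")

#' Generate a synthetic CA reference chain
#'
#' Builds a CA trace with the canonical consecutive CA-CA distance of
#' 3.8 Angstrom, either as an ideal alpha-helix or a self-avoiding random
#' walk (minimum non-consecutive CA distance 4 Angstrom).
#'
#' @param length Number of residues (>= 5).
#' @param style `"helix"` or `"random_walk"`.
#' @param rng_seed Integer seed; the chain is a pure function of it.
#' @param model_id Identifier for the model.
#' @return A `structure_model`.
#' @export
make_reference_chain <- function(length, style = c("helix", "random_walk"),
                                 rng_seed = 1L, model_id = "ref") {
  style <- match.arg(style)
  stopifnot(length >= 5L)
  set.seed(rng_seed)
  if (style == "helix") {
    # rise 1.5 A/residue, 100 degrees/residue; radius chosen so the
    # consecutive CA-CA chord is 3.8 A
    rise <- 1.5; turn <- 100 * pi / 180
    radius <- sqrt(3.8^2 - rise^2) / (2 * sin(turn / 2))
    i <- seq_len(length) - 1L
    xyz <- cbind(radius * cos(i * turn), radius * sin(i * turn), rise * i)
  } else {
    xyz <- self_avoiding_walk(length, step = 3.8, min_sep = 4)
  }
  structure_model(model_id, seq_len(length), xyz,
                  sequence = random_sequence(length))
}

self_avoiding_walk <- function(n, step, min_sep, max_restarts = 50L) {
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(0, n, 3L)
    dir <- unit_vec(rnorm(3))
    xyz[2L, ] <- xyz[1L, ] + step * dir
    ok <- TRUE
    for (i in 3:n) {
      placed <- FALSE
      for (try in 1:60) {
        # directional persistence keeps the walk extended enough to avoid
        # immediate collisions while still exploring folds
        nd <- unit_vec(dir + 0.9 * rnorm(3))
        cand <- xyz[i - 1L, ] + step * nd
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= min_sep) {
          xyz[i, ] <- cand
          dir <- nd
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(xyz)
  }
  stop("generation error: self-avoiding walk failed after ", max_restarts,
       " restarts", call. = FALSE)
}

#' Specification of a synthetic decoy pool
#'
#' @param n_models Pool size.
#' @param sigma_grid Isotropic Gaussian coordinate noise levels (Angstrom);
#'   models are spread round-robin across the grid.
#' @param conformations List of conformation specs, each a list with
#'   `weight` (sampling probability), `hinge_angle` (degrees; the chain is
#'   hinged at its midpoint by this angle, 0 = the reference conformation)
#'   and `generator` tag.
#' @param plddt_rho Target correlation between simulated global plDDT and
#'   true model quality.
#' @param rng_seed Integer seed.
#' @return A `decoy_pool_spec` list.
#' @export
decoy_pool_spec <- function(n_models = 200, sigma_grid = 1,
                            conformations = list(list(weight = 1,
                                                      hinge_angle = 0,
                                                      generator = "af2")),
                            plddt_rho = 0.5, rng_seed = 1L) {
  w <- vapply(conformations, `[[`, numeric(1), "weight")
  if (abs(sum(w) - 1) > 1e-8) {
    stop("conformation weights must sum to 1", call. = FALSE)
  }
  stopifnot(all(unlist(sigma_grid) >= 0))
  structure(list(n_models = as.integer(n_models),
                 sigma_grid = as.numeric(sigma_grid),
                 conformations = conformations, plddt_rho = plddt_rho,
                 rng_seed = as.integer(rng_seed)),
            class = "decoy_pool_spec")
}

# Hinge the second half of a chain about a random axis through the midpoint CA.
hinge_chain <- function(xyz, angle_deg, axis) {
  if (angle_deg == 0) return(xyz)
  mid <- nrow(xyz) %/% 2L
  R <- rotation_about(axis, angle_deg * pi / 180)
  pivot <- xyz[mid, ]
  tail_idx <- (mid + 1L):nrow(xyz)
  xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2L, pivot) %*%
                             t(R), 2L, -pivot)
  xyz
}

#' Generate a decoy pool with known ground truth
#'
#' Each decoy samples a conformation by weight (alternative conformations
#' are hinge perturbations of the reference), adds isotropic Gaussian
#' coordinate noise from the sigma grid, and is placed in a random rigid
#' frame. The returned truth table records, per model, the conformation,
#' noise level, true TM-score and GDT-TS against the reference, and a
#' simulated global plDDT whose correlation with true quality is calibrated
#' to `plddt_rho` — emulating self-confidence scores that are informative
#' but fallible.
#'
#' @param ref Reference `structure_model`.
#' @param spec A [decoy_pool_spec()].
#' @param params [scoring_params()] used for the truth-table scores.
#' @param truth_scores `"both"` to record true TM and GDT-TS, `"tm"` to
#'   record TM only (`true_gdt` set `NA`).
#' @return List with `models` (list of `structure_model`) and `truth`
#'   (data frame: model_id, conformation, generator, sigma, true_tm,
#'   true_gdt, plddt).
#' @export
make_decoys <- function(ref, spec, params = scoring_params(),
                        truth_scores = c("both", "tm")) {
  truth_scores <- match.arg(truth_scores)
  set.seed(spec$rng_seed)
  n <- spec$n_models
  w <- vapply(spec$conformations, `[[`, numeric(1), "weight")
  conf_idx <- sample.int(length(w), n, replace = TRUE, prob = w)
  sigma <- rep_len(spec$sigma_grid, n)
  # one fixed hinge axis per conformation: cluster geometry is deterministic
  axes <- lapply(spec$conformations, function(cf) unit_vec(rnorm(3)))
  L <- length(ref$residue_ids)

  models <- vector("list", n)
  for (i in seq_len(n)) {
    cf <- spec$conformations[[conf_idx[i]]]
    xyz <- hinge_chain(ref$ca_coords, cf$hinge_angle, axes[[conf_idx[i]]])
    xyz <- xyz + matrix(rnorm(3L * L, sd = sigma[i]), L, 3L)
    xyz <- sweep(xyz %*% t(random_rotation()), 2L, -runif(3, -50, 50))
    gen <- if (is.null(cf$generator)) "af2" else cf$generator
    models[[i]] <- structure_model(sprintf("decoy_%03d", i), ref$residue_ids,
                                   xyz, ref$sequence, generator = gen)
  }
  true_tm <- vapply(models, function(m) tm_score(ref, m, params), numeric(1))
  true_gdt <- if (truth_scores == "both") {
    vapply(models, function(m) gdt_ts(ref, m, params), numeric(1))
  } else rep(NA_real_, n)

  # plddt: mix standardized true quality with independent noise at the
  # target correlation, then map onto a realistic 30-95 confidence band
  zq <- if (sd(true_tm) > 0) (true_tm - mean(true_tm)) / sd(true_tm) else
    rep(0, n)
  mix <- spec$plddt_rho * zq + sqrt(max(0, 1 - spec$plddt_rho^2)) * rnorm(n)
  plddt <- pmin(100, pmax(0, 62.5 + 12.5 * mix))
  for (i in seq_len(n)) models[[i]]$plddt <- rep(plddt[i], L)

  truth <- data.frame(
    model_id = vapply(models, `[[`, character(1), "model_id"),
    conformation = conf_idx,
    generator = vapply(models, `[[`, character(1), "generator"),
    sigma = sigma, true_tm = true_tm, true_gdt = true_gdt, plddt = plddt,
    stringsAsFactors = FALSE)
  list(models = models, truth = truth)
}

#' Generate a synthetic MSA with controlled per-column depth
#'
#' Rows are sampled independently: column c of a row is aligned (non-gap)
#' with probability `coverage_profile[c]`; aligned residues copy the query
#' mutated at `substitution_rate` to a uniformly chosen different residue.
#' Step-shaped profiles emulate targets whose terminal regions are covered
#' by only a handful of homologs.
#'
#' @param length Number of match columns.
#' @param n_rows Number of non-query rows.
#' @param coverage_profile Per-column alignment probability (scalar or
#'   length-`length` vector).
#' @param substitution_rate Per-residue mutation probability.
#' @param rng_seed Integer seed.
#' @return A `foldrank_msa` with `n_rows + 1` rows (query first), row ids
#'   `S000001`, ...
#' @export
make_msa <- function(length, n_rows, coverage_profile = 1,
                     substitution_rate = 0.2, rng_seed = 1L) {
  p <- rep_len(coverage_profile, length)
  set.seed(rng_seed)
  q <- sample(AA20, length, replace = TRUE)
  seqs <- character(n_rows)
  for (r in seq_len(n_rows)) {
    row <- q
    mut <- runif(length) < substitution_rate
    if (any(mut)) {
      row[mut] <- vapply(q[mut], function(a) sample(setdiff(AA20, a), 1L),
                         character(1))
    }
    row[runif(length) >= p] <- "-"
    seqs[r] <- paste0(row, collapse = "")
  }
  new_msa(ids = c("query", sprintf("S%06d", seq_len(n_rows))),
          seqs = c(paste0(q, collapse = ""), seqs))
}

#' Generate a template-hit table around a planted segmentation
#'
#' Emits one significant hit per planted domain, shrunk by `margin` at
#' internal boundaries (so the short-gap midpoint rule reconstructs the
#' planted boundary exactly at zero jitter) and jittered by up to `jitter`
#' residues, plus `decoy_hits` insignificant hits that the standard filter
#' removes (e-value > 1, aligned length <= 40, or coverage <= 0.5).
#'
#' @param segmentation A `domain_segmentation`; internal domains should be
#'   longer than `40 + 2 * margin` residues for exact round-trip recovery.
#' @param jitter Maximum uniform boundary perturbation (residues).
#' @param decoy_hits Number of filter-failing hits to add.
#' @param margin Residues trimmed from each internal boundary (default 10).
#' @param rng_seed Integer seed.
#' @return A template-hit data frame (see [read_hit_table()]).
#' @export
make_hit_table <- function(segmentation, jitter = 0, decoy_hits = 0,
                           margin = 10, rng_seed = 1L) {
  set.seed(rng_seed)
  dm <- segmentation$domains
  L <- segmentation$target_length
  nd <- nrow(dm)
  rows <- list()
  for (i in seq_len(nd)) {
    s <- dm[i, 1L] + if (i > 1L) margin else 0L
    e <- dm[i, 2L] - if (i < nd) margin else 0L
    if (jitter > 0) {
      s <- max(1L, s + sample(-jitter:jitter, 1L))
      e <- min(L, e + sample(-jitter:jitter, 1L))
    }
    alen <- e - s + 1L
    tlen <- ceiling(alen / 0.9)
    rows[[i]] <- data.frame(template_id = sprintf("tpl_%02d", i),
                            target_start = s, target_end = e,
                            evalue = 10^runif(1L, -8, -2),
                            template_length = tlen,
                            coverage = alen / tlen)
  }
  for (j in seq_len(decoy_hits)) {
    s <- sample.int(max(1L, L - 30L), 1L)
    e <- min(L, s + sample(10:80, 1L))
    fail_mode <- sample(3L, 1L)
    alen <- e - s + 1L
    if (fail_mode == 2L) { e <- min(L, s + sample(5:39, 1L)); alen <- e - s + 1L }
    rows[[nd + j]] <- data.frame(
      template_id = sprintf("junk_%02d", j),
      target_start = s, target_end = e,
      evalue = if (fail_mode == 1L) runif(1L, 1.5, 50) else 10^runif(1L, -6, -2),
      template_length = if (fail_mode == 3L) alen * 3L else ceiling(alen / 0.9),
      coverage = if (fail_mode == 3L) 1 / 3 else alen / ceiling(alen / 0.9))
  }
  do.call(rbind, rows)
}
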