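#' Z-score evaluation configuration
#'
#' @param outlier_cutoff First-pass Z below which a model is treated as an
#'   outlier and excluded from the re-standardization (default -2).
#' @param clip_at_zero Accumulate only positive Z-scores (default `TRUE`).
#' @param alt_pairs List of length-2 character vectors naming alternative
#'   conformation domains whose Z-scores are averaged into one unit.
#' @param sd_mode `"population"` (divide by n) or `"sample"` (n - 1).
#' @return A `zscore_config` list.
#' @export
zscore_config <- function(outlier_cutoff = -2, clip_at_zero = TRUE,
                          alt_pairs = list(), sd_mode = c("population",
                                                          "sample")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(outlier_cutoff < 0)
  structure(list(outlier_cutoff = outlier_cutoff,
                 clip_at_zero = clip_at_zero, alt_pairs = alt_pairs,
                 sd_mode = sd_mode),
            class = "zscore_config")
}

zsd <- function(x, mode) {
  n <- length(x)
  if (mode == "population") sqrt(sum((x - mean(x))^2) / n) else sd(x)
}

#' Per-domain Z-scores with outlier re-standardization
#'
#' Two-pass standardization of one domain's per-predictor accuracy scores
#' (GDT-TS): scores are first standardized against the mean and standard
#' deviation of all present scores; entries below `outlier_cutoff` are then
#' excluded and all present entries are re-standardized against the mean and
#' standard deviation of the survivors. A zero standard deviation yields
#' all-zero Z; absent scores stay absent.
#'
#' @param scores Per-predictor numeric vector (`NA` = no submission).
#' @param config A [zscore_config()].
#' @return Numeric vector of Z-scores, same names and length as `scores`.
#' @export
domain_zscores <- function(scores, config = zscore_config()) {
  present <- which(!is.na(scores))
  out <- rep(NA_real_, length(scores))
  names(out) <- names(scores)
  if (length(present) < 2L) {
    warning("fewer than 2 present scores; all Z set absent", call. = FALSE)
    return(out)
  }
  x <- scores[present]
  s1 <- zsd(x, config$sd_mode)
  z1 <- if (s1 == 0) rep(0, length(x)) else (x - mean(x)) / s1
  survivors <- x[z1 >= config$outlier_cutoff]
  if (length(survivors) < 2L) survivors <- x
  m2 <- mean(survivors)
  s2 <- zsd(survivors, config$sd_mode)
  out[present] <- if (s2 == 0) 0 else (x - m2) / s2
  out
}

#' Cumulative Z-scores over an evaluation table
#'
#' Applies [domain_zscores()] per domain, averages the raw Z of each
#' configured alternative-conformation pair into one virtual domain (an
#' absent member contributes the other member's value; both absent stays
#' absent), then accumulates per predictor the positive part of each unique
#' domain's Z (absent contributes 0). With `clip_at_zero = FALSE` the raw
#' sum is taken instead.
#'
#' @param table Predictor-by-domain numeric matrix of GDT-TS scores in
#'   \[0, 1\] (see [read_eval_table()]).
#' @param config A [zscore_config()].
#' @return A `zscore_report`: list with `per_domain_z` (matrix),
#'   `unit_z` (matrix after pair merging), `cumulative` and `mean_z`
#'   (named per-predictor vectors) and `unique_domain_count`.
#' @export
cumulative_zscore <- function(table, config = zscore_config()) {
  z <- apply(table, 2L, domain_zscores, config = config)
  if (is.null(dim(z))) z <- matrix(z, nrow = nrow(table),
                                   dimnames = dimnames(table))
  units <- z
  for (pair in config$alt_pairs) {
    if (!all(pair %in% colnames(z))) {
      stop("configuration error: alternative pair references unknown ",
           "domain(s): ", paste(setdiff(pair, colnames(z)), collapse = ", "),
           call. = FALSE)
    }
    a <- z[, pair[1L]]; b <- z[, pair[2L]]
    merged <- rowMeans(cbind(a, b), na.rm = TRUE)  # one absent -> the other
    merged[is.na(a) & is.na(b)] <- NA_real_
    units[, pair[1L]] <- merged
    units <- units[, colnames(units) != pair[2L], drop = FALSE]
  }
  contrib <- units
  if (config$clip_at_zero) contrib[!is.na(contrib) & contrib < 0] <- 0
  contrib[is.na(contrib)] <- 0
  cumulative <- rowSums(contrib)
  structure(list(per_domain_z = z, unit_z = units, cumulative = cumulative,
                 mean_z = rowMeans(units, na.rm = TRUE),
                 unique_domain_count = ncol(units)),
            class = "zscore_report")
}

#' @export
print.zscore_report <- function(x, ...) {
  cat("zscore_report: ", nrow(x$per_domain_z), " predictors, ",
      ncol(x$per_domain_z), " domains (", x$unique_domain_count,
      " unique units)\n", sep = "")
  o <- order(-x$cumulative)
  top <- head(o, 10L)
  for (i in top) {
    cat(sprintf("  %-20s cumulative Z = %6.2f (mean %5.3f)\n",
                rownames(x$per_domain_z)[i], x$cumulative[i], x$mean_z[i]))
  }
  invisible(x)
}

#' Summarize per-domain TM-scores against fold-quality thresholds
#'
#' @param per_domain_tm Named numeric vector of TM-scores in (0, 1].
#' @param thresholds Quality cutoffs; by default 0.9 ("near-native") and
#'   0.5 ("correct fold").
#' @return List with `n`, `mean`, and per threshold the count and fraction
#'   strictly above it plus the domains at or below it.
#' @export
summarize_tm <- function(per_domain_tm, thresholds = c(0.9, 0.5)) {
  stopifnot(length(per_domain_tm) > 0)
  x <- per_domain_tm
  out <- list(n = length(x), mean = mean(x))
  for (t in thresholds) {
    key <- sub("^0\\.", "", format(t))
    out[[paste0("n_above_", key)]] <- sum(x > t)
    out[[paste0("frac_above_", key)]] <- mean(x > t)
    out[[paste0("below_", key)]] <- names(x)[x <= t]
  }
  out
}

#' Head-to-head per-domain comparison of two predictors
#'
#' @param a,b Named numeric vectors of per-domain scores sharing keys.
#' @param gap Difference magnitude that counts as a clear win (default 0.1).
#' @return List with the shared-domain difference vector `diff` (a - b),
#'   `a_better` / `b_better` (domains with a clear win either way) and the
#'   two means over shared domains.
#' @export
head_to_head <- function(a, b, gap = 0.1) {
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) {
    stop("no shared domains between the two predictors", call. = FALSE)
  }
  d <- a[shared] - b[shared]
  list(diff = d,
       a_better = shared[d > gap],
       b_better = shared[-d > gap],
       mean_a = mean(a[shared]), mean_b = mean(b[shared]))
}

#' One-sided paired Wilcoxon signed-rank test
#'
#' Tests whether predictor `a`'s per-domain scores are systematically larger
#' than `b`'s (alternative: a > b). Zero differences are dropped; the exact
#' null distribution is used for small samples without ties, the
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b Equal-length paired score vectors.
#' @return The one-sided p-value.
#' @export
paired_onesided_test <- function(a, b) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    stop("all paired differences are zero; test undefined", call. = FALSE)
  }
  if (n < 5L) {
    warning("fewer than 5 non-zero differences; p-value has little power",
            call. = FALSE)
  }
  if (n <= 25L) {
    # exact distribution of the signed-rank sum by convolution over sign
    # patterns; midranks doubled so tied ranks stay integral
    r2 <- round(2 * rank(abs(nz)))
    v_obs <- sum(r2[nz > 0])
    counts <- 1
    for (r in r2) {
      grown <- c(counts, rep(0, r))
      grown[(r + 1):(r + length(counts))] <-
        grown[(r + 1):(r + length(counts))] + counts
      counts <- grown
    }
    sum(counts[(v_obs + 1):length(counts)]) / 2^n
  } else {
    suppressWarnings(
      wilcox.test(a, b, paired = TRUE, alternative = "greater",
                  exact = FALSE)$p.value)
  }
}
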