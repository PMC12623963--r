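#' Per-column alignment depth
#'
#' Depth of a match column is the number of rows (query included) with a
#' non-gap residue in it. Shallow regions — e.g. a C-terminal tail covered by
#' only a handful of homologs — carry little co-evolutionary signal and are
#' a common cause of locally wrong predictions.
#'
#' @param msa A `foldrank_msa`.
#' @return Integer vector, one depth per match column.
#' @export
column_depth <- function(msa) {
  stopifnot(inherits(msa, "foldrank_msa"))
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  as.integer(colSums(m != "-"))
}

#' @rdname column_depth
#' @param start,end 1-based inclusive column interval.
#' @return `depth_window()`: the mean depth over the interval.
#' @export
depth_window <- function(msa, start, end) {
  d <- column_depth(msa)
  if (start < 1L || end > length(d) || start > end) {
    stop("interval [", start, ",", end, "] outside 1..", length(d),
         call. = FALSE)
  }
  mean(d[start:end])
}

#' Filter insignificant template hits
#'
#' Keeps hits with e-value <= 1, aligned target length
#' (`target_end - target_start + 1`) strictly greater than 40 residues, and
#' alignment coverage strictly greater than 0.5. Order is preserved and the
#' filter is idempotent.
#'
#' @param hits Data frame of template hits (see [read_hit_table()]).
#' @param max_evalue,min_length,min_coverage Cutoffs; defaults are the
#'   standard significance filter.
#' @return The surviving rows of `hits`.
#' @export
filter_hits <- function(hits, max_evalue = 1, min_length = 40,
                        min_coverage = 0.5) {
  if (nrow(hits) == 0L) return(hits)
  len <- hits$target_end - hits$target_start + 1L
  keep <- hits$evalue <= max_evalue & len > min_length &
    hits$coverage > min_coverage
  hits[keep, , drop = FALSE]
}

#' Derive a domain segmentation from template hits
#'
#' Each maximal continuous region of the target aligned to surviving
#' templates becomes a domain; unaligned gaps longer than 40 residues become
#' their own domains; shorter internal gaps are split at their midpoint
#' between the flanking domains, and short leading/trailing gaps are absorbed
#' into the first/last domain. If a disorder track is supplied, any boundary
#' strictly inside a disordered run of at least `min_disorder_run` residues
#' is moved to the midpoint of that run.
#'
#' @param hits Filtered template hits (see [filter_hits()]).
#' @param target_length Number of residues in the target.
#' @param disorder Optional logical disorder track of length `target_length`.
#' @param max_gap Unaligned gaps longer than this become separate domains.
#' @param min_disorder_run Minimum disordered-run length used for boundary
#'   refinement.
#' @return A `domain_segmentation`: list with `target_length` and `domains`
#'   (two-column start/end matrix partitioning `1..target_length`).
#' @export
segment_domains <- function(hits, target_length, disorder = NULL,
                            max_gap = 40, min_disorder_run = 5) {
  if (target_length < 1) stop("target_length must be >= 1", call. = FALSE)
  regions <- merge_intervals(hits$target_start, hits$target_end, target_length)
  if (nrow(regions) == 0L) {
    return(domain_segmentation(target_length, matrix(c(1L, target_length), 1L)))
  }

  doms <- list()
  # leading gap
  lead <- regions[1L, 1L] - 1L
  if (lead > max_gap) {
    doms[[1L]] <- c(1L, lead)
  } else if (lead > 0L) {
    regions[1L, 1L] <- 1L
  }
  for (i in seq_len(nrow(regions))) {
    if (i > 1L) {
      gap <- regions[i, 1L] - regions[i - 1L, 2L] - 1L
      if (gap > max_gap) {
        doms[[length(doms) + 1L]] <- c(regions[i - 1L, 2L] + 1L,
                                       regions[i, 1L] - 1L)
      } else if (gap > 0L) {
        # split at midpoint: left half extends the previous domain
        cut <- regions[i - 1L, 2L] + gap %/% 2L
        doms[[length(doms)]][2L] <- cut
        regions[i, 1L] <- cut + 1L
      }
    }
    doms[[length(doms) + 1L]] <- regions[i, ]
  }
  trail <- target_length - regions[nrow(regions), 2L]
  if (trail > max_gap) {
    doms[[length(doms) + 1L]] <- c(regions[nrow(regions), 2L] + 1L,
                                   target_length)
  } else if (trail > 0L) {
    doms[[length(doms)]][2L] <- target_length
  }
  dm <- do.call(rbind, doms)

  if (!is.null(disorder)) {
    stopifnot(length(disorder) == target_length)
    dm <- refine_boundaries(dm, disorder, min_disorder_run)
  }
  domain_segmentation(target_length, dm)
}

# Union of [start,end] intervals merged into maximal continuous runs,
# clamped to 1..target_length. Touching intervals merge (no gap between).
merge_intervals <- function(starts, ends, target_length) {
  if (length(starts) == 0L) return(matrix(integer(0), 0L, 2L))
  starts <- pmax(1L, as.integer(starts))
  ends <- pmin(as.integer(target_length), as.integer(ends))
  o <- order(starts, ends)
  starts <- starts[o]; ends <- ends[o]
  out <- list(c(starts[1L], ends[1L]))
  for (i in seq_along(starts)[-1L]) {
    last <- out[[length(out)]]
    if (starts[i] <= last[2L] + 1L) {
      out[[length(out)]][2L] <- max(last[2L], ends[i])
    } else {
      out[[length(out) + 1L]] <- c(starts[i], ends[i])
    }
  }
  do.call(rbind, out)
}

# Move boundaries strictly inside long disordered runs to the run midpoint.
refine_boundaries <- function(dm, disorder, min_run) {
  r <- rle(disorder)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  runs <- cbind(run_start, run_end)[r$values & r$lengths >= min_run, ,
                                    drop = FALSE]
  if (nrow(runs) == 0L || nrow(dm) < 2L) return(dm)
  for (i in seq_len(nrow(dm) - 1L)) {
    b <- dm[i, 2L]  # boundary: last residue of the left domain
    hit <- which(runs[, 1L] < b & b < runs[, 2L])
    if (length(hit)) {
      mid <- (runs[hit[1L], 1L] + runs[hit[1L], 2L]) %/% 2L
      # keep intervals valid with respect to neighbours
      mid <- max(dm[i, 1L], min(mid, dm[i + 1L, 2L] - 1L))
      dm[i, 2L] <- mid
      dm[i + 1L, 1L] <- mid + 1L
    }
  }
  dm
}

#' @rdname segment_domains
#' @param domains Two-column integer matrix of \[start, end\] intervals.
#' @export
domain_segmentation <- function(target_length, domains) {
  domains <- matrix(as.integer(domains), ncol = 2L)
  o <- order(domains[, 1L])
  domains <- domains[o, , drop = FALSE]
  covered <- unlist(apply(domains, 1L, function(d) d[1L]:d[2L],
                          simplify = FALSE))
  if (!identical(as.integer(covered), seq_len(target_length))) {
    stop("domains must partition 1..", target_length,
         " without overlap", call. = FALSE)
  }
  structure(list(target_length = as.integer(target_length), domains = domains),
            class = "domain_segmentation")
}

#' @export
print.domain_segmentation <- function(x, ...) {
  cat("domain_segmentation over ", x$target_length, " residues:\n", sep = "")
  for (i in seq_len(nrow(x$domains))) {
    cat(sprintf("  D%d: %d-%d (%d residues)\n", i, x$domains[i, 1L],
                x$domains[i, 2L], diff(x$domains[i, ]) + 1L))
  }
  invisible(x)
}

#' Pair domain alignments by shared sequence identifiers
#'
#' A homolog that appears (by stripped identifier, range suffix ignored) in
#' every domain MSA contributes one paired full-length row: its domain rows
#' concatenated in domain order. First occurrence per identifier per MSA is
#' used. Remaining rows are reported per domain as unpaired residuals.
#'
#' @param domain_msas List of two or more `foldrank_msa`, one per domain,
#'   each query-anchored to its domain interval.
#' @return List with `paired` (data frame: `id` plus one sequence column per
#'   domain) and `unpaired` (per-domain list of row indices into each MSA,
#'   query excluded).
#' @export
pair_domain_alignments <- function(domain_msas) {
  if (length(domain_msas) < 2L) {
    stop("need at least two domain MSAs to pair", call. = FALSE)
  }
  ids_per <- lapply(domain_msas, function(m) m$ids[-1L])
  shared <- Reduce(intersect, ids_per)
  paired <- data.frame(id = shared, stringsAsFactors = FALSE)
  for (d in seq_along(domain_msas)) {
    first_idx <- match(shared, ids_per[[d]]) + 1L  # skip query row
    paired[[paste0("domain", d)]] <- domain_msas[[d]]$seqs[first_idx]
  }
  unpaired <- lapply(seq_along(domain_msas), function(d) {
    idx <- setdiff(seq_along(domain_msas[[d]]$ids)[-1L],
                   match(shared, ids_per[[d]]) + 1L)
    idx
  })
  list(paired = paired, unpaired = unpaired)
}

#' Gap-pad a domain row to full target length
#'
#' @param row Aligned residue string of the domain's match-column length.
#' @param domain `c(start, end)` interval of the domain (1-based inclusive).
#' @param target_length Full target length.
#' @return The row embedded in a full-length string of `'-'`.
#' @export
pad_unpaired <- function(row, domain, target_length) {
  dlen <- domain[2L] - domain[1L] + 1L
  if (nchar(row) != dlen) {
    stop("row length ", nchar(row), " != domain length ", dlen, call. = FALSE)
  }
  paste0(strrep("-", domain[1L] - 1L), row,
         strrep("-", target_length - domain[2L]))
}

#' Combine full-length and domain alignments into a domain-based MSA
#'
#' The output stacks, in order: the query, rows of the full-length MSA,
#' paired domain rows (concatenated across domains), and gap-padded unpaired
#' domain rows (domain order, input order within each domain). Exact
#' duplicates of earlier rows — identical identifier and residue string —
#' are dropped.
#'
#' @param full Full-length `foldrank_msa`.
#' @param domain_msas Per-domain `foldrank_msa` list, in segmentation order
#'   (may be empty).
#' @param segmentation A `domain_segmentation` matching `domain_msas`.
#' @return A `foldrank_msa` whose every row spans the full target length.
#' @export
build_domain_msa <- function(full, domain_msas, segmentation) {
  L <- segmentation$target_length
  if (nchar(full$seqs[1L]) != L) {
    stop("full-length MSA has ", nchar(full$seqs[1L]),
         " columns; segmentation expects ", L, call. = FALSE)
  }
  if (length(domain_msas) != 0L &&
      length(domain_msas) != nrow(segmentation$domains)) {
    stop("need one domain MSA per segmentation domain", call. = FALSE)
  }
  for (d in seq_along(domain_msas)) {
    dlen <- diff(segmentation$domains[d, ]) + 1L
    if (nchar(domain_msas[[d]]$seqs[1L]) != dlen) {
      stop("domain MSA ", d, " has ", nchar(domain_msas[[d]]$seqs[1L]),
           " columns; domain spans ", dlen, call. = FALSE)
    }
  }

  ids <- full$ids
  seqs <- full$seqs

  if (length(domain_msas) >= 2L) {
    pr <- pair_domain_alignments(domain_msas)
    if (nrow(pr$paired)) {
      ids <- c(ids, pr$paired$id)
      seqs <- c(seqs, do.call(paste0, pr$paired[-1L]))
    }
    for (d in seq_along(domain_msas)) {
      for (i in pr$unpaired[[d]]) {
        ids <- c(ids, domain_msas[[d]]$ids[i])
        seqs <- c(seqs, pad_unpaired(domain_msas[[d]]$seqs[i],
                                     segmentation$domains[d, ], L))
      }
    }
  } else if (length(domain_msas) == 1L) {
    m <- domain_msas[[1L]]
    for (i in seq_along(m$ids)[-1L]) {
      ids <- c(ids, m$ids[i])
      seqs <- c(seqs, pad_unpaired(m$seqs[i], segmentation$domains[1L, ], L))
    }
  }

  keep <- !duplicated(paste0(ids, "\r", seqs))
  new_msa(ids = ids[keep], seqs = seqs[keep], source_tag = full$source_tag)
}

#' Append profile-derived synthetic sequences to an MSA
#'
#' Emulates confidence-thresholded masked-residue replacement with the MSA's
#' own column profile: synthetic row k carries, at each position, the k-th
#' most frequent residue differing from the query when its frequency among
#' aligned (non-gap) residues exceeds `min_freq`, and the query residue
#' otherwise. The replacement predictor is pluggable via `profile_fn`.
#'
#' @param msa A `foldrank_msa`.
#' @param n_sequences Number of synthetic rows to append (default 2).
#' @param min_freq Minimum column frequency for a substitution (default 0.3).
#' @param profile_fn Optional function(column_characters) returning a named
#'   frequency vector; defaults to the empirical residue frequencies.
#' @return The MSA with `n_sequences` additional rows (ids `profile_syn_k`).
#' @export
augment_with_profile <- function(msa, n_sequences = 2, min_freq = 0.3,
                                 profile_fn = NULL) {
  if (n_sequences < 1) stop("n_sequences must be >= 1", call. = FALSE)
  q <- strsplit(msa$seqs[1L], "")[[1]]
  m <- do.call(rbind, strsplit(msa$seqs, ""))
  ids <- msa$ids; seqs <- msa$seqs
  for (k in seq_len(n_sequences)) {
    syn <- q
    for (cc in seq_along(q)) {
      col <- m[, cc]
      col <- col[col != "-"]
      freq <- if (is.null(profile_fn)) {
        table(col) / length(col)
      } else {
        profile_fn(col)
      }
      freq <- freq[names(freq) != q[cc]]
      freq <- sort(freq, decreasing = TRUE)  # ties resolved alphabetically
      if (length(freq) >= k && freq[k] > min_freq) {
        syn[cc] <- names(freq)[k]
      }
    }
    ids <- c(ids, paste0("profile_syn_", k))
    seqs <- c(seqs, paste0(syn, collapse = ""))
  }
  new_msa(ids = ids, seqs = seqs, source_tag = msa$source_tag)
}
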