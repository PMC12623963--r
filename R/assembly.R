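#' Declare a fragment model for assembly
#'
#' @param model A `structure_model` whose residue numbers lie, contiguously,
#'   inside `span` (full-length numbering).
#' @param span `c(start, end)` interval the fragment covers.
#' @return A `fragment_model`.
#' @export
fragment_model <- function(model, span) {
  span <- as.integer(span)
  ids <- model$residue_ids
  if (any(ids < span[1L] | ids > span[2L])) {
    stop("fragment residues outside declared span", call. = FALSE)
  }
  if (!identical(ids, seq(ids[1L], ids[length(ids)]))) {
    stop("fragment residues must be contiguous", call. = FALSE)
  }
  structure(list(model = model, span = span), class = "fragment_model")
}

#' Assemble overlapping fragment models into one full-length model
#'
#' Divide-and-conquer assembly: long targets that a predictor bends or
#' truncates can be predicted as overlapping regions and stitched back
#' together. The first fragment is fixed; each subsequent fragment is
#' rigidly superposed (Kabsch) onto the growing assembly over their shared
#' residues, and the overlap coordinates are taken from the earlier fragment
#' (or blended at the midpoint with `overlap = "blend"`). Per-junction
#' overlap RMSD after fitting is reported.
#'
#' @param fragments List of `fragment_model`, sorted by span start.
#' @param min_overlap Minimum shared residues per junction (default 20).
#' @param overlap `"first"` (earlier fragment wins) or `"blend"` (mean of
#'   the two copies).
#' @param model_id Identifier for the assembled model.
#' @return A `structure_model` covering the union of spans, with attribute
#'   `junction_rmsd` (one value per junction).
#' @export
assemble <- function(fragments, min_overlap = 20, overlap = c("first", "blend"),
                     model_id = "assembly") {
  overlap <- match.arg(overlap)
  stopifnot(length(fragments) >= 1L)
  starts <- vapply(fragments, function(f) f$span[1L], integer(1))
  if (is.unsorted(starts)) {
    stop("fragments must be sorted by span start", call. = FALSE)
  }
  cur_ids <- fragments[[1L]]$model$residue_ids
  cur_xyz <- fragments[[1L]]$model$ca_coords
  cur_seq <- strsplit(fragments[[1L]]$model$sequence, "")[[1]]
  junction_rmsd <- numeric(0)

  for (k in seq_along(fragments)[-1L]) {
    frag <- fragments[[k]]$model
    shared <- intersect(cur_ids, frag$residue_ids)
    if (length(shared) < min_overlap) {
      stop("assembly error at junction ", k - 1L, ": overlap of ",
           length(shared), " residues is below min_overlap = ", min_overlap,
           call. = FALSE)
    }
    sp <- kabsch_superpose(cur_xyz[match(shared, cur_ids), , drop = FALSE],
                           frag$ca_coords[match(shared, frag$residue_ids), ,
                                          drop = FALSE])
    junction_rmsd <- c(junction_rmsd, sp$rmsd)
    moved <- apply_superposition(sp, frag$ca_coords)
    if (overlap == "blend") {
      i_cur <- match(shared, cur_ids)
      i_frag <- match(shared, frag$residue_ids)
      cur_xyz[i_cur, ] <- (cur_xyz[i_cur, , drop = FALSE] +
                             moved[i_frag, , drop = FALSE]) / 2
    }
    new_i <- which(!frag$residue_ids %in% cur_ids)
    if (length(new_i)) {
      cur_ids <- c(cur_ids, frag$residue_ids[new_i])
      cur_xyz <- rbind(cur_xyz, moved[new_i, , drop = FALSE])
      cur_seq <- c(cur_seq, strsplit(frag$sequence, "")[[1]][new_i])
    }
  }

  o <- order(cur_ids)
  cur_ids <- cur_ids[o]
  if (!identical(cur_ids, seq(cur_ids[1L], cur_ids[length(cur_ids)]))) {
    stop("assembly error: fragments do not cover a contiguous interval",
         call. = FALSE)
  }
  out <- structure_model(model_id, cur_ids, cur_xyz[o, , drop = FALSE],
                         paste0(cur_seq[o], collapse = ""))
  attr(out, "junction_rmsd") <- junction_rmsd
  out
}
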