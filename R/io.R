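#' @useDynLib foldrank, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans rnorm runif sd setNames wilcox.test cor
#' @importFrom utils read.delim write.table head
NULL

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Split a FASTA/A3M file into header/sequence records, validating structure.
parse_fasta_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) & !grepl("^#", lines)]
  if (length(lines) == 0L) stop("parse error: empty file ", path, call. = FALSE)
  is_hdr <- startsWith(lines, ">")
  if (!is_hdr[1L]) {
    stop("parse error at line 1: expected '>' header, got: ", lines[1L], call. = FALSE)
  }
  rec_idx <- cumsum(is_hdr)
  headers <- sub("^>", "", lines[is_hdr])
  seqs <- vapply(split(lines[!is_hdr], rec_idx[!is_hdr]),
                 paste0, character(1), collapse = "")
  if (length(seqs) != length(headers)) {
    stop("parse error: header without sequence in ", path, call. = FALSE)
  }
  list(headers = headers, seqs = unname(seqs))
}

# Header token before the first whitespace; "/start-end" range suffix split off.
split_identifier <- function(header) {
  token <- sub("\\s.*$", "", header)
  desc <- sub("^\\S+\\s*", "", header)
  range <- NA_character_
  m <- regmatches(token, regexec("^(.*)/(\\d+-\\d+)$", token))[[1]]
  if (length(m) == 3L) {
    token <- m[2L]
    range <- m[3L]
  }
  if (!nzchar(token)) stop("parse error: empty identifier in header '", header, "'",
                           call. = FALSE)
  list(id = token, range = range, desc = desc)
}

#' Read an A3M / FASTA alignment
#'
#' Parses an alignment in the HH-suite A3M dialect: the first record is the
#' ungapped query; lowercase letters in subsequent rows are insertion states
#' relative to the query and are excluded from the match columns. Plain
#' aligned FASTA is the special case with no lowercase states.
#'
#' @param path Path to an A3M or aligned FASTA file.
#' @return An object of class `foldrank_msa`: a list with `ids`, `ranges`,
#'   `descs`, `seqs` (uppercase match-column rows, row 1 = query),
#'   `insertions` (per row, a list of `(after_col, segment)` records) and
#'   `source_tag`.
#' @export
read_a3m <- function(path) {
  rec <- parse_fasta_records(path)
  heads <- lapply(rec$headers, split_identifier)
  ids <- vapply(heads, `[[`, character(1), "id")
  ranges <- vapply(heads, `[[`, character(1), "range")
  descs <- vapply(heads, `[[`, character(1), "desc")

  query <- rec$seqs[1L]
  if (grepl("[a-z-]", query)) {
    stop("dialect error: query (first record '", ids[1L],
         "') must contain no lowercase or gap characters", call. = FALSE)
  }
  qlen <- nchar(query)

  seqs <- character(length(rec$seqs))
  insertions <- vector("list", length(rec$seqs))
  for (i in seq_along(rec$seqs)) {
    s <- rec$seqs[i]
    chars <- strsplit(s, "")[[1]]
    lower <- grepl("[a-z]", chars)
    match_cols <- paste0(chars[!lower], collapse = "")
    if (nchar(match_cols) != qlen) {
      stop("dialect error: row '", ids[i], "' has ", nchar(match_cols),
           " match columns; query has ", qlen, call. = FALSE)
    }
    ins <- list()
    if (any(lower)) {
      pos_in_match <- cumsum(!lower)  # match column preceding each char
      r <- rle(lower)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (k in which(r$values)) {
        after <- if (starts[k] == 1L) 0L else pos_in_match[starts[k] - 1L]
        ins[[length(ins) + 1L]] <- list(
          after_col = after,
          segment = paste0(chars[starts[k]:ends[k]], collapse = ""))
      }
    }
    seqs[i] <- toupper(match_cols)
    insertions[[i]] <- ins
  }
  new_msa(ids = ids, seqs = seqs, ranges = ranges, descs = descs,
          insertions = insertions)
}

#' @rdname read_a3m
#' @export
read_fasta <- read_a3m

new_msa <- function(ids, seqs, ranges = rep(NA_character_, length(ids)),
                    descs = rep("", length(ids)),
                    insertions = rep(list(list()), length(ids)),
                    source_tag = "other") {
  stopifnot(length(ids) == length(seqs))
  qlen <- nchar(seqs[1L])
  if (any(nchar(seqs) != qlen)) {
    stop("all rows must have match-column length ", qlen, call. = FALSE)
  }
  if (grepl("-", seqs[1L], fixed = TRUE)) {
    stop("query row must contain no gaps", call. = FALSE)
  }
  structure(list(ids = ids, ranges = ranges, descs = descs, seqs = seqs,
                 insertions = insertions, source_tag = source_tag),
            class = "foldrank_msa")
}

#' @export
print.foldrank_msa <- function(x, ...) {
  cat("foldrank_msa: ", length(x$ids), " rows x ", nchar(x$seqs[1L]),
      " match columns (query: ", x$ids[1L], ", source: ", x$source_tag, ")\n",
      sep = "")
  invisible(x)
}

#' @export
length.foldrank_msa <- function(x) length(x$ids)

#' Write an alignment in A3M
#'
#' Inverse of [read_a3m()]: insertion segments are re-interleaved (lowercase)
#' at their recorded positions, so a read/write round trip reproduces the
#' file's match columns, insertions and identifiers.
#'
#' @param msa A `foldrank_msa`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_a3m <- function(msa, path) {
  out <- character(2L * length(msa$ids))
  for (i in seq_along(msa$ids)) {
    id <- msa$ids[i]
    if (!is.na(msa$ranges[i])) id <- paste0(id, "/", msa$ranges[i])
    if (nzchar(msa$descs[i])) id <- paste(id, msa$descs[i])
    s <- msa$seqs[i]
    ins <- msa$insertions[[i]]
    if (length(ins)) {
      # insert from the rightmost position so earlier offsets stay valid
      ord <- order(vapply(ins, `[[`, integer(1), "after_col"), decreasing = TRUE)
      for (k in ord) {
        a <- ins[[k]]$after_col
        s <- paste0(substr(s, 1L, a), ins[[k]]$segment,
                    substr(s, a + 1L, nchar(s)))
      }
    }
    out[2L * i - 1L] <- paste0(">", id)
    out[2L * i] <- s
  }
  writeLines(out, path)
  invisible(path)
}

#' Read the CA trace of one chain from a PDB file
#'
#' Extracts CA atoms of the requested chain from ATOM records, ordered by
#' residue number. Alternate locations are resolved by highest occupancy,
#' then first seen; residues lacking a CA are skipped with a warning.
#' Insertion codes are rejected.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier (default `"A"`).
#' @param b_as_plddt If `TRUE`, interpret the B-factor column as per-residue
#'   plDDT (0-100).
#' @param generator Provenance tag: one of `"af2"`, `"af3"`, `"esmfold"`,
#'   `"other"`.
#' @param ranking_score Optional model-level ranking score to attach.
#' @return A `structure_model` (see [structure_model()]).
#' @export
read_pdb_chain <- function(path, chain = "A", b_as_plddt = FALSE,
                           generator = "other", ranking_score = NULL) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$chain == chain, , drop = FALSE]
  if (nrow(at) == 0L) {
    stop("lookup error: chain '", chain, "' not found in ", path, call. = FALSE)
  }
  if (any(!is.na(at$insert) & nzchar(at$insert))) {
    stop("insertion codes are not supported (chain ", chain, " in ", path, ")",
         call. = FALSE)
  }
  all_res <- sort(unique(at$resno))
  ca <- at[at$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(all_res, ca$resno)
  if (length(missing_ca)) {
    warning(length(missing_ca), " residue(s) without CA skipped (",
            paste(head(missing_ca, 5L), collapse = ","),
            if (length(missing_ca) > 5L) ",..." else "", ")", call. = FALSE)
  }
  # altloc: keep the highest-occupancy CA per residue, first seen on ties
  keep <- unlist(lapply(split(seq_len(nrow(ca)), ca$resno), function(ii) {
    occ <- ca$o[ii]
    occ[is.na(occ)] <- 1
    ii[which.max(occ)]
  }), use.names = FALSE)
  ca <- ca[sort(keep), , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  aa1 <- vapply(ca$resid, aa3to1, character(1))
  structure_model(
    model_id = sub("\\.(pdb|ent)$", "", basename(path)),
    residue_ids = ca$resno,
    ca_coords = cbind(ca$x, ca$y, ca$z),
    sequence = paste0(aa1, collapse = ""),
    plddt = if (b_as_plddt) ca$b else NULL,
    generator = generator,
    ranking_score = ranking_score)
}

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
            GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
            MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
            TYR = "Y", VAL = "V", MSE = "M", UNK = "X")

aa3to1 <- function(resid) {
  out <- AA3TO1[toupper(resid)]
  if (is.na(out)) "X" else unname(out)
}

AA1TO3 <- setNames(names(AA3TO1)[1:20], unname(AA3TO1)[1:20])

#' Construct a single-chain CA structure model
#'
#' @param model_id Model identifier (no whitespace).
#' @param residue_ids Strictly increasing 1-based residue numbers.
#' @param ca_coords Numeric matrix, one CA xyz row per residue (Angstrom).
#' @param sequence One-letter amino-acid string, same length as `residue_ids`.
#' @param plddt Optional per-residue confidence in \[0, 100\].
#' @param generator One of `"af2"`, `"af3"`, `"esmfold"`, `"other"`.
#' @param ranking_score Optional model-level score.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, residue_ids, ca_coords, sequence = NULL,
                            plddt = NULL, generator = "other",
                            ranking_score = NULL) {
  ca_coords <- as.matrix(ca_coords)
  n <- length(residue_ids)
  if (is.null(sequence)) sequence <- paste(rep("X", n), collapse = "")
  if (nrow(ca_coords) != n || nchar(sequence) != n) {
    stop("residue_ids, ca_coords and sequence lengths must agree", call. = FALSE)
  }
  if (ncol(ca_coords) != 3L || any(!is.finite(ca_coords))) {
    stop("ca_coords must be a finite n x 3 matrix", call. = FALSE)
  }
  if (n > 1L && any(diff(residue_ids) <= 0L)) {
    stop("residue_ids must be strictly increasing", call. = FALSE)
  }
  if (!is.null(plddt)) {
    if (length(plddt) != n) stop("plddt length mismatch", call. = FALSE)
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE)) {
      stop("plddt must lie in [0, 100]", call. = FALSE)
    }
  }
  generator <- match.arg(generator, c("af2", "af3", "esmfold", "other"))
  dimnames(ca_coords) <- NULL
  structure(list(model_id = model_id, residue_ids = as.integer(residue_ids),
                 ca_coords = ca_coords, sequence = sequence, plddt = plddt,
                 generator = generator, ranking_score = ranking_score),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model ", x$model_id, ": ", length(x$residue_ids),
      " residues [", x$residue_ids[1L], "-",
      x$residue_ids[length(x$residue_ids)], "], generator ", x$generator,
      "\n", sep = "")
  invisible(x)
}

#' Write a structure model as a CA-only PDB chain
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @param chain Chain identifier to write.
#' @return `path`, invisibly.
#' @export
write_pdb_chain <- function(model, path, chain = "A") {
  n <- length(model$residue_ids)
  aa <- strsplit(model$sequence, "")[[1]]
  res3 <- ifelse(aa %in% names(AA1TO3), AA1TO3[aa], "UNK")
  b <- if (!is.null(model$plddt)) model$plddt else rep(0, n)
  lines <- sprintf(
    "ATOM  %5d  CA  %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(n), res3, chain, model$residue_ids,
    model$ca_coords[, 1L], model$ca_coords[, 2L], model$ca_coords[, 3L],
    1.00, b)
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# Detect comma vs tab delimiter from the header line.
detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (grepl("\t", hdr)) "\t" else ","
}

#' Read a per-model score table
#'
#' Delimited text (comma or tab, auto-detected) with a header whose first
#' column is `model_id`; remaining columns are numeric QA scores. Missing
#' cells stay `NA` (absent), never zero.
#'
#' @param path Path to the table.
#' @return A `score_table`: a data frame with `model_id` plus numeric score
#'   columns.
#' @export
read_score_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  names(df)[1L] <- "model_id"
  if (anyDuplicated(df$model_id)) {
    stop("integrity error: duplicated model_id: ",
         paste(unique(df$model_id[duplicated(df$model_id)]), collapse = ", "),
         call. = FALSE)
  }
  for (j in seq_along(df)[-1L]) df[[j]] <- as.numeric(df[[j]])
  score_table(df)
}

#' @rdname read_score_table
#' @param df A data frame with a `model_id` first column.
#' @export
score_table <- function(df) {
  stopifnot(is.data.frame(df), names(df)[1L] == "model_id")
  if (anyDuplicated(df$model_id)) stop("duplicated model_id", call. = FALSE)
  if ("plddt_global" %in% names(df)) {
    bad <- !is.na(df$plddt_global) &
      (df$plddt_global < 0 | df$plddt_global > 100)
    if (any(bad)) stop("plddt_global must lie in [0, 100]", call. = FALSE)
  }
  class(df) <- c("score_table", "data.frame")
  df
}

#' Read a template-hit table
#'
#' Delimited text with header columns `template_id`, `target_start`,
#' `target_end`, `evalue`, `template_length`, `coverage`.
#'
#' @param path Path to the table.
#' @return A data frame of template hits.
#' @export
read_hit_table <- function(path) {
  df <- read.delim(path, sep = detect_sep(path), stringsAsFactors = FALSE)
  need <- c("template_id", "target_start", "target_end", "evalue",
            "template_length", "coverage")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("hit table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(df$target_start > df$target_end)) {
    stop("hit with target_start > target_end", call. = FALSE)
  }
  df
}

#' Read a per-residue disorder track
#'
#' Two-column delimited text: residue number, 0/1 flag (1 = disordered).
#'
#' @param path Path to the track.
#' @param target_length Expected number of residues.
#' @return A logical vector of length `target_length`.
#' @export
read_disorder_track <- function(path, target_length) {
  df <- read.delim(path, sep = detect_sep(path), header = FALSE,
                   stringsAsFactors = FALSE)
  if (suppressWarnings(is.na(as.integer(df[1L, 1L])))) {
    df <- df[-1L, , drop = FALSE]  # tolerate a header line
  }
  if (nrow(df) != target_length) {
    stop("disorder track has ", nrow(df), " rows; target length is ",
         target_length, call. = FALSE)
  }
  lab <- rep(FALSE, target_length)
  lab[as.integer(df[[1L]])] <- as.integer(df[[2L]]) == 1L
  lab
}

#' Read a predictor-by-domain evaluation matrix
#'
#' Rows are predictors, columns are evaluation domains; cells are GDT-TS
#' scores in \[0, 1\] with `NA` marking a missing submission.
#'
#' @param path Path to the delimited matrix (first column = predictor names).
#' @return A numeric matrix with predictor rownames and domain colnames.
#' @export
read_eval_table <- function(path) {
  df <- read.delim(path, sep = detect_sep(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1L]]
  if (any(m < 0 | m > 1, na.rm = TRUE)) {
    stop("GDT-TS values must lie in [0, 1]", call. = FALSE)
  }
  m
}

#' Write a numeric matrix (e.g. pairwise similarity) as delimited text
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
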