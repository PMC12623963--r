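# Small in-code fixture builders shared across test files.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# Minimal PDB text for a CA-only chain; coords is an n x 3 matrix.
toy_pdb <- function(coords, chain = "A", resno = seq_len(nrow(coords)),
                    occ = rep(1, nrow(coords)), altloc = rep("", nrow(coords)),
                    bfac = rep(0, nrow(coords)), elety = rep("CA", nrow(coords))) {
  lines <- sprintf(
    "ATOM  %5d  %-3s%1sALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           C",
    seq_len(nrow(coords)), elety, altloc, chain, resno,
    coords[, 1], coords[, 2], coords[, 3], occ, bfac)
  write_lines_tmp(c(lines, "TER", "END"), ".pdb")
}

toy_model <- function(coords, id = "m", resno = seq_len(nrow(coords)), ...) {
  structure_model(id, resno, coords, ...)
}

# A3M text from id/sequence pairs.
toy_a3m <- function(ids, seqs) {
  write_lines_tmp(as.vector(rbind(paste0(">", ids), seqs)), ".a3m")
}

toy_msa <- function(ids, seqs) new_msa_public(ids, seqs)

# new_msa is internal; rebuild through the A3M reader to stay on public API
new_msa_public <- function(ids, seqs) {
  read_a3m(toy_a3m(ids, seqs))
}

toy_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(template_id = r[["id"]] %||% "t",
               target_start = r[["start"]], target_end = r[["end"]],
               evalue = r[["evalue"]] %||% 1e-5,
               template_length = r[["tlen"]] %||%
                 ceiling((r[["end"]] - r[["start"]] + 1) / 0.9),
               coverage = r[["coverage"]] %||% 0.9)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rigid_move <- function(coords, angle = pi / 3, axis = c(0, 0, 1),
                       shift = c(10, -5, 3)) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3,
              byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  sweep(coords %*% t(R), 2, -shift)
}
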