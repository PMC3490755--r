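# Shared in-code fixtures: hand-written PDB snippets, PSSM text and small
# feature sets.

pdb_line <- function(serial, name, resname, chain, resno, x, y, z,
                     element = "C", record = "ATOM") {
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, sprintf(" %s", name), resname, chain, resno,
          x, y, z, element)
}

# 3 amino acids (chain A) + 2 ribonucleotides (chain B); residues 2 and 3
# have an atom within 5 A of the RNA, residue 1 does not.
toy_complex_lines <- function() {
  c(
    pdb_line(1, "CA", "ALA", "A", 1, 0.0, 20.0, 0.0),
    pdb_line(2, "CB", "ALA", "A", 1, 1.0, 20.5, 0.0),
    pdb_line(3, "CA", "GLY", "A", 2, 0.0, 4.9, 0.0),
    pdb_line(4, "CA", "VAL", "A", 3, 0.0, 3.0, 0.0),
    pdb_line(5, "CB", "VAL", "A", 3, 0.5, 3.5, 0.0),
    pdb_line(6, "P", "A", "B", 1, 0.0, 0.0, 0.0, element = "P"),
    pdb_line(7, "O2'", "G", "B", 2, 3.0, 0.0, 0.0, element = "O"),
    "END"
  )
}

write_toy_complex <- function(lines = toy_complex_lines(),
                              path = withr::local_tempfile(fileext = ".pdb",
                                                           .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}

# PSI-BLAST-style ASCII PSSM text for a given raw integer matrix
pssm_text <- function(raw, residues, with_percent = TRUE) {
  header <- c("", "Last position-specific scoring matrix computed",
              paste0("            ",
                     paste(sprintf("%3s", rep(rnaiface:::PSSM_COLUMNS, 2)),
                           collapse = "")))
  rows <- vapply(seq_len(nrow(raw)), function(i) {
    paste0(sprintf("%5d %s ", i, residues[i]),
           paste(sprintf("%3d", raw[i, ]), collapse = ""),
           if (with_percent) {
             paste0("  ", paste(sprintf("%4d", rep(7L, 20)), collapse = ""),
                    "  1.23 0.45")
           } else "")
  }, character(1))
  c(header, rows, "", "                      K         Lambda")
}

# rip_features from a plain matrix and labels
make_features <- function(x, labels, config = encoding_config()) {
  rnaiface:::new_rip_features(
    as.matrix(x),
    tibble::tibble(chain_key = "toy_A", position = seq_along(labels),
                   residue = "A", label = as.integer(labels)),
    config
  )
}

# labeled chain built directly (bypassing PDB parsing) for feature tests
make_chain <- function(residues, solved = rep(TRUE, length(residues)),
                       label = rep(0L, length(residues)),
                       centroids = NULL, cutoff = 5) {
  n <- length(residues)
  if (is.null(centroids)) {
    centroids <- cbind(3.8 * (seq_len(n) - 1), 0, 0)
  }
  tb <- tibble::tibble(
    position = seq_len(n), residue = residues, solved = solved,
    label = as.integer(label),
    min_rna_dist = NA_real_,
    auth_seq = ifelse(solved, as.character(seq_len(n)), NA_character_),
    surface = NA,
    cx = ifelse(solved, centroids[, 1], NA_real_),
    cy = ifelse(solved, centroids[, 2], NA_real_),
    cz = ifelse(solved, centroids[, 3], NA_real_)
  )
  rnaiface:::new_rip_chain(tb, pdb_id = "toy", chain_id = "A",
                           cutoff = cutoff)
}

random_pssm <- function(n, seed = 1, sigma = 2) {
  set.seed(seed)
  rnaiface:::new_rip_pssm(sample(rnaiface:::PSSM_COLUMNS, n, replace = TRUE),
                          matrix(round(rnorm(n * 20, 0, sigma)), n, 20))
}
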