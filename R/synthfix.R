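# Deterministic synthetic fixture generator: toy protein-RNA complexes with a
# planted interface patch, matching full-chain sequences, and PSI-BLAST-style
# PSSM files with class-conditional signal, so the whole pipeline runs with no
# external downloads.

#' Specification for the synthetic benchmark
#'
#' Geometry: the protein is a pseudo-backbone with one CA atom per residue at
#' 3.8 A spacing along x plus two jittered side atoms (jitter kept on the
#' side opposite the RNA); the RNA pseudo-strand carries one phosphate atom
#' per nucleotide, placed \code{d_near} A from each patch residue and
#' \code{d_far} A from everything else, so labeling at a cutoff between
#' \code{d_near} and \code{d_far} recovers the patch exactly. PSSM raw scores
#' are integer-rounded Normal(0, sigma^2) draws with \code{delta} added to
#' \code{k_signal} fixed columns at interface positions.
#'
#' @param n_chains Number of complexes (default 20).
#' @param length_range Protein chain length range (default 50..70, above the
#'   40-residue inclusion threshold).
#' @param patch Interface patch length in residues (default 8).
#' @param d_near Patch-to-RNA distance in A (default 4.0, inside the 5 A
#'   labeling cutoff).
#' @param d_far RNA distance from non-patch residues (default 12.0).
#' @param delta Mean shift planted on signal columns at interface positions
#'   (default 2).
#' @param sigma PSSM score noise standard deviation (default 1).
#' @param k_signal Number of PSSM columns carrying the shift (default 5).
#' @param unsolved_fraction Fraction of residues omitted from the coordinates
#'   (drawn from non-patch positions; present in the sequence, labeled
#'   non-interface). Default 0.
#' @param cutoff Labeling cutoff the geometry is built around (default 5).
#' @param seed Master seed; per-artifact seeds are derived by fixed offsets.
#' @return A \code{synthetic_spec} list.
#' @export
synthetic_spec <- function(n_chains = 20, length_range = c(50, 70), patch = 8,
                           d_near = 4.0, d_far = 12.0, delta = 2, sigma = 1,
                           k_signal = 5, unsolved_fraction = 0, cutoff = 5,
                           seed = 7) {
  stopifnot(d_near < cutoff, cutoff < d_far, delta >= 0, sigma > 0,
            unsolved_fraction >= 0, unsolved_fraction < 1,
            k_signal >= 1, k_signal <= 20, patch >= 1)
  structure(list(n_chains = n_chains, length_range = length_range,
                 patch = patch, d_near = d_near, d_far = d_far,
                 delta = delta, sigma = sigma, k_signal = k_signal,
                 unsolved_fraction = unsolved_fraction, cutoff = cutoff,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

derive_seed <- function(seed, index, stream) {
  as.integer((as.double(seed) * 7919 + index * 131 + stream) %% 2147483647)
}

#' Generate one synthetic protein-RNA complex
#'
#' @param spec A [synthetic_spec()].
#' @param chain_index Index of the complex (1-based); determines the derived
#'   seed and the identifier \code{SYN<index>}.
#' @return List with \code{pdb_text} (character vector of PDB lines),
#'   \code{sequence} (tibble \code{id}, \code{seq}; the full sequence
#'   including unsolved residues), \code{truth} (tibble \code{position},
#'   \code{residue}, \code{solved}, \code{label}) and \code{pdb_id}.
#' @export
gen_complex <- function(spec, chain_index = 1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_private_seed(derive_seed(spec$seed, chain_index, 1), {
    lens <- seq(spec$length_range[1], spec$length_range[2])
    len <- if (length(lens) == 1) lens else sample(lens, 1)
    if (spec$patch > len) stop("interface patch longer than the chain")
    residues <- sample(PSSM_COLUMNS, len, replace = TRUE)
    patch_start <- sample(seq_len(len - spec$patch + 1), 1)
    patch <- seq(patch_start, length.out = spec$patch)

    non_patch <- setdiff(seq_len(len), patch)
    n_unsolved <- round(spec$unsolved_fraction * len)
    if (n_unsolved > length(non_patch)) {
      stop("unsolved_fraction too large for the patch size")
    }
    unsolved <- sort(sample(non_patch, n_unsolved))
    solved <- setdiff(seq_len(len), unsolved)

    pdb_id <- sprintf("SYN%03d", chain_index)
    lines <- character(0)
    serial <- 0L
    emit <- function(name, resname, chain, resno, x, y, z, element) {
      serial <<- serial + 1L
      lines <<- c(lines, sprintf(
        "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, name, resname, chain, resno, x, y, z, 1, 0, element))
    }

    three <- names(AA_THREE_TO_ONE)[match(residues, AA_THREE_TO_ONE)]
    for (i in solved) {
      xi <- 3.8 * (i - 1)
      emit(" CA", three[i], "A", i, xi, 0, 0, "C")
      # side atoms jittered on +y, away from the RNA strand at -y
      emit(" CB", three[i], "A", i, xi + stats::runif(1, -0.3, 0.3),
           stats::runif(1, 0, 0.4), 1.2, "C")
      emit(" CG", three[i], "A", i, xi + stats::runif(1, -0.3, 0.3),
           stats::runif(1, 0, 0.4), -1.2, "C")
    }
    # RNA: one P atom per nucleotide; near atoms face the patch, far atoms
    # pad the strand to >= 5 nt
    rna_len <- max(spec$patch, 5)
    n_far <- rna_len - spec$patch
    far_x <- 3.8 * (setdiff(seq_len(len), patch)[seq_len(n_far)] - 1)
    rna_nt <- sample(c("A", "C", "G", "U"), rna_len, replace = TRUE)
    resno <- 0L
    for (xi in c(3.8 * (patch - 1), far_x)) {
      resno <- resno + 1L
      yy <- if (resno <= spec$patch) -spec$d_near else -spec$d_far
      emit(" P ", sprintf("%3s", rna_nt[resno]), "B", resno, xi, yy, 0, "P")
    }
    lines <- c(lines, "END")

    truth <- tibble::tibble(
      position = seq_len(len), residue = residues,
      solved = seq_len(len) %in% solved,
      label = as.integer(seq_len(len) %in% patch)
    )
    list(pdb_text = lines,
         sequence = tibble::tibble(id = paste0(pdb_id, "_A"),
                                   seq = paste(residues, collapse = "")),
         truth = truth, pdb_id = pdb_id)
  })
}

#' Generate a PSI-BLAST-style ASCII PSSM with planted class signal
#'
#' Raw log-odds scores are integer-rounded Normal(0, sigma^2) draws; at
#' interface positions \code{delta} is added to the first \code{k_signal}
#' columns before rounding. The text round-trips exactly through
#' [read_pssm()].
#'
#' @param residues Character vector of the chain's residues.
#' @param labels 0/1 interface labels, same length.
#' @param spec A [synthetic_spec()].
#' @param seed Seed for the score noise.
#' @return Character vector of file lines.
#' @export
gen_pssm <- function(residues, labels, spec, seed = 1) {
  stopifnot(length(residues) == length(labels))
  n <- length(residues)
  with_private_seed(seed, {
    raw <- matrix(stats::rnorm(n * 20, 0, spec$sigma), n, 20)
    raw[labels == 1L, seq_len(spec$k_signal)] <-
      raw[labels == 1L, seq_len(spec$k_signal)] + spec$delta
    raw <- round(raw)
    header <- c(
      "",
      paste("Last position-specific scoring matrix computed, weighted",
            "observed percentages rounded down, information per position,",
            "and relative weight of gapless real matches to pseudocounts"),
      paste0("            ",
             paste(sprintf("%3s", rep(PSSM_COLUMNS, 2)), collapse = ""))
    )
    rows <- vapply(seq_len(n), function(i) {
      paste0(sprintf("%5d %s ", i, residues[i]),
             paste(sprintf("%3d", raw[i, ]), collapse = ""),
             "  ",
             paste(sprintf("%4d", rep(0L, 20)), collapse = ""),
             sprintf("  %4.2f %4.2f", 0, 0))
    }, character(1))
    footer <- c("", "                      K         Lambda",
                "Standard Ungapped    0.1347     0.3177")
    c(header, rows, footer)
  })
}

#' Generate a complete synthetic benchmark directory
#'
#' Writes, for each chain, a PDB file and a PSSM file, plus one FASTA of all
#' full sequences and a truth TSV. Byte-identical across runs with the same
#' spec.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a manifest tibble: \code{chain_key}, \code{pdb_id},
#'   \code{pdb}, \code{pssm}, \code{length}, \code{n_interface},
#'   \code{n_unsolved}.
#' @export
gen_benchmark <- function(spec, dir) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  seqs <- list()
  truths <- list()
  for (i in seq_len(spec$n_chains)) {
    cx <- gen_complex(spec, i)
    pdb_path <- file.path(dir, paste0(cx$pdb_id, ".pdb"))
    writeLines(cx$pdb_text, pdb_path)
    key <- paste0(cx$pdb_id, "_A")
    pssm_path <- file.path(dir, paste0(key, ".pssm"))
    writeLines(gen_pssm(cx$truth$residue, cx$truth$label, spec,
                        seed = derive_seed(spec$seed, i, 2)),
               pssm_path)
    seqs[[i]] <- cx$sequence
    truths[[i]] <- dplyr::mutate(cx$truth, chain_key = key)
    rows[[i]] <- tibble::tibble(
      chain_key = key, pdb_id = cx$pdb_id,
      pdb = basename(pdb_path), pssm = basename(pssm_path),
      length = nrow(cx$truth), n_interface = sum(cx$truth$label),
      n_unsolved = sum(!cx$truth$solved)
    )
  }
  write_fasta(dplyr::bind_rows(seqs), file.path(dir, "sequences.fasta"))
  readr::write_tsv(dplyr::bind_rows(truths) |> dplyr::relocate("chain_key"),
                   file.path(dir, "truth.tsv"))
  manifest <- dplyr::bind_rows(rows)
  readr::write_tsv(manifest, file.path(dir, "manifest.tsv"))
  invisible(manifest)
}

#' Load a generated benchmark into labeled chains, profiles and a dataset
#'
#' Runs the regular pipeline (PDB parsing, interface labeling against the
#' full sequences, PSSM reading) over a [gen_benchmark()] directory.
#'
#' @param dir Benchmark directory.
#' @param cutoff Labeling cutoff in A (default 5).
#' @param variant Dataset variant, \code{"sequence"} or \code{"structure"}.
#' @return List with \code{chains} (list of \code{rip_chain}),
#'   \code{profiles} (named list of \code{rip_pssm}), \code{dataset}
#'   (\code{rip_dataset}) and \code{manifest}.
#' @export
load_benchmark <- function(dir, cutoff = 5, variant = "sequence") {
  manifest <- readr::read_tsv(file.path(dir, "manifest.tsv"),
                              show_col_types = FALSE, progress = FALSE)
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  chains <- list()
  profiles <- list()
  for (i in seq_len(nrow(manifest))) {
    cx <- read_complex(file.path(dir, manifest$pdb[i]),
                       pdb_id = manifest$pdb_id[i])
    fs <- seqs[seqs$id == manifest$chain_key[i], , drop = FALSE]
    ch <- label_interface(cx, "A", fs, cutoff = cutoff)
    chains[[chain_key(ch)]] <- ch
    profiles[[chain_key(ch)]] <- read_pssm(file.path(dir, manifest$pssm[i]))
  }
  list(chains = chains, profiles = profiles,
       dataset = make_dataset(chains, variant = variant),
       manifest = manifest)
}
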