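# Interface residue labeling by distance cutoff, sequence/structure dataset
# assembly, inclusion filters, solvent accessibility and the surface
# post-filter.

#' Minimum distance between a residue and a set of RNA atoms
#'
#' @param residue_atoms Data frame of atoms (needs \code{x,y,z}, and
#'   \code{is_heavy} when \code{atom_policy = "heavy"}).
#' @param rna_atoms Data frame of RNA atoms with the same columns.
#' @param atom_policy \code{"all"} uses every atom present in the file;
#'   \code{"heavy"} restricts both sides to non-hydrogen atoms.
#' @return Minimum Euclidean distance in Angstrom over all atom pairs.
#' @export
residue_min_distance <- function(residue_atoms, rna_atoms,
                                 atom_policy = c("all", "heavy")) {
  atom_policy <- match.arg(atom_policy)
  if (atom_policy == "heavy") {
    residue_atoms <- residue_atoms[residue_atoms$is_heavy, , drop = FALSE]
    rna_atoms <- rna_atoms[rna_atoms$is_heavy, , drop = FALSE]
  }
  if (nrow(residue_atoms) == 0 || nrow(rna_atoms) == 0) {
    stop("residue_min_distance: empty atom list")
  }
  a <- as.matrix(residue_atoms[, c("x", "y", "z")])
  b <- as.matrix(rna_atoms[, c("x", "y", "z")])
  sqrt(min_cross_dist2(a, b))
}

# minimum squared distance between rows of a and rows of b
min_cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  max(min(d2), 0)
}

# per-row minimum squared distance from rows of a to rows of b
rowmin_cross_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  pmax(apply(d2, 1, min), 0)
}

#' Label interface residues of a protein chain against the bound RNA
#'
#' A residue is an interface (RNA-binding) residue when at least one of its
#' atoms lies within \code{cutoff} Angstrom of any atom of any RNA chain in
#' the complex. Residues of the full sequence that are absent from the solved
#' coordinates are retained with \code{solved = FALSE} and labeled
#' non-interface.
#'
#' Solved residues are mapped onto the full sequence by exact substring match
#' of their 1-letter string; when that fails (e.g. internal unsolved spans) a
#' global identity alignment is used and at least 95\% of aligned solved
#' residues must agree.
#'
#' @param complex An \code{rip_complex}.
#' @param chain_id Protein chain to label.
#' @param full_seq Full-chain sequence: a string, or a one-row tibble from
#'   [read_fasta()].
#' @param cutoff Distance cutoff in Angstrom (default 5).
#' @param atom_policy Passed to [residue_min_distance()].
#' @return A \code{rip_chain}: tibble with one row per sequence position and
#'   columns \code{position}, \code{residue}, \code{solved}, \code{label}
#'   (0/1), \code{min_rna_dist}, \code{auth_seq}, \code{surface} (logical,
#'   \code{NA} until [flag_surface()]), centroid \code{cx,cy,cz}; attributes
#'   \code{pdb_id}, \code{chain_id}, \code{chain_key}, \code{cutoff},
#'   \code{atom_policy}.
#' @export
label_interface <- function(complex, chain_id, full_seq, cutoff = 5,
                            atom_policy = c("all", "heavy")) {
  stopifnot(inherits(complex, "rip_complex"))
  atom_policy <- match.arg(atom_policy)
  if (is.data.frame(full_seq)) {
    stopifnot(nrow(full_seq) == 1, "seq" %in% names(full_seq))
    full_seq <- full_seq$seq
  }
  full <- strsplit(toupper(full_seq), "")[[1]]
  n <- length(full)
  if (n == 0) stop("empty full sequence")

  atoms <- complex$atoms
  prot <- atoms[atoms$chain_id == chain_id & atoms$moltype == "protein", ,
                drop = FALSE]
  if (nrow(prot) == 0) {
    stop("no protein chain '", chain_id, "' in complex ", complex$pdb_id)
  }
  rna <- atoms[atoms$moltype == "rna", , drop = FALSE]
  if (atom_policy == "heavy") {
    prot_d <- prot[prot$is_heavy, , drop = FALSE]
    rna_d <- rna[rna$is_heavy, , drop = FALSE]
  } else {
    prot_d <- prot
    rna_d <- rna
  }
  if (nrow(rna_d) == 0) {
    stop("complex ", complex$pdb_id, " has no RNA atoms; cannot label")
  }

  # solved residues in chain order
  solved_tbl <- prot |>
    dplyr::group_by(.data$res_index) |>
    dplyr::summarise(auth_seq = .data$auth_seq[1],
                     one_letter = .data$one_letter[1], .groups = "drop") |>
    dplyr::arrange(.data$res_index)

  pos_map <- map_solved_positions(solved_tbl$one_letter, full)

  # min distance to RNA, per solved residue
  d2 <- rowmin_cross_dist2(as.matrix(prot_d[, c("x", "y", "z")]),
                           as.matrix(rna_d[, c("x", "y", "z")]))
  min_by_res <- tapply(d2, prot_d$res_index, min)
  min_dist <- sqrt(as.numeric(min_by_res[as.character(solved_tbl$res_index)]))

  # heavy-atom centroid per solved residue
  heavy <- prot[prot$is_heavy, , drop = FALSE]
  cent <- heavy |>
    dplyr::group_by(.data$res_index) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     cz = mean(.data$z), .groups = "drop")
  cent <- cent[match(solved_tbl$res_index, cent$res_index), , drop = FALSE]

  out <- tibble::tibble(
    position = seq_len(n),
    residue = full,
    solved = FALSE,
    label = 0L,
    min_rna_dist = NA_real_,
    auth_seq = NA_character_,
    surface = NA,
    cx = NA_real_, cy = NA_real_, cz = NA_real_
  )
  out$solved[pos_map] <- TRUE
  out$min_rna_dist[pos_map] <- min_dist
  out$label[pos_map] <- as.integer(min_dist <= cutoff)
  out$auth_seq[pos_map] <- solved_tbl$auth_seq
  out$cx[pos_map] <- cent$cx
  out$cy[pos_map] <- cent$cy
  out$cz[pos_map] <- cent$cz

  new_rip_chain(out, pdb_id = complex$pdb_id, chain_id = chain_id,
                cutoff = cutoff, atom_policy = atom_policy)
}

new_rip_chain <- function(tbl, pdb_id, chain_id, cutoff, atom_policy = "all") {
  structure(
    tbl,
    pdb_id = pdb_id, chain_id = chain_id,
    chain_key = paste0(pdb_id, "_", chain_id),
    cutoff = cutoff, atom_policy = atom_policy,
    class = c("rip_chain", class(tibble::as_tibble(tbl)))
  )
}

chain_key <- function(chain) attr(chain, "chain_key")

# Map solved residue letters onto positions of the full sequence.
# Exact unique substring first; otherwise global identity alignment
# (>= 95% identity over aligned solved residues required).
map_solved_positions <- function(solved_letters, full_chars) {
  k <- length(solved_letters)
  full <- paste(full_chars, collapse = "")
  s <- paste(solved_letters, collapse = "")
  if (k > length(full_chars)) {
    stop("solved residue string is longer than the full sequence")
  }
  hits <- gregexpr(s, full, fixed = TRUE)[[1]]
  if (length(hits) == 1 && hits[1] > 0) {
    return(seq.int(hits[1], length.out = k))
  }
  if (length(hits) > 1) {
    # ambiguous exact placement; fall through to alignment which picks the
    # first optimal placement deterministically
  }

  alpha <- AA_ALPHABET
  mat <- matrix(-1, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(mat) <- 2
  mat["X", ] <- 0
  mat[, "X"] <- 0
  aln <- Biostrings::pairwiseAlignment(
    pattern = s, subject = full, type = "global-local",
    substitutionMatrix = mat, gapOpening = 0, gapExtension = 1
  )
  pat <- strsplit(as.character(Biostrings::pattern(aln)), "")[[1]]
  sub <- strsplit(as.character(Biostrings::subject(aln)), "")[[1]]
  j0 <- Biostrings::start(Biostrings::subject(aln)) - 1L
  i <- 0L; j <- j0
  map <- integer(k)
  n_aligned <- 0L; n_match <- 0L
  for (t in seq_along(pat)) {
    pi <- pat[t] != "-"
    sj <- sub[t] != "-"
    if (sj) j <- j + 1L
    if (pi) {
      i <- i + 1L
      if (sj) {
        map[i] <- j
        n_aligned <- n_aligned + 1L
        if (pat[t] == sub[t] || pat[t] == "X" || sub[t] == "X") {
          n_match <- n_match + 1L
        }
      }
    }
  }
  if (any(map == 0L) || n_aligned == 0L || n_match / n_aligned < 0.95) {
    stop("cannot map solved residues onto the full sequence ",
         "(alignment identity ",
         if (n_aligned) round(100 * n_match / n_aligned, 1) else 0,
         "% over ", n_aligned, " aligned residues)")
  }
  map
}

#' Dataset inclusion filters
#'
#' A labeled chain is retained when its sequence has at least \code{min_len}
#' amino acids, carries at least \code{min_binding} RNA-binding (interface)
#' residues, and the longest RNA chain in its complex has at least
#' \code{min_rna} nucleotides. All three thresholds are inclusive.
#'
#' @param chain A \code{rip_chain} from [label_interface()].
#' @param rna_lengths Integer vector of RNA chain lengths (nucleotides) of the
#'   complex.
#' @param min_len,min_binding,min_rna Thresholds (defaults 40, 3, 5).
#' @return Logical scalar.
#' @export
passes_inclusion_filters <- function(chain, rna_lengths, min_len = 40,
                                     min_binding = 3, min_rna = 5) {
  nrow(chain) >= min_len &&
    sum(chain$label == 1L) >= min_binding &&
    length(rna_lengths) > 0 && max(rna_lengths) >= min_rna
}

#' Assemble a sequence- or structure-variant residue dataset
#'
#' The sequence variant keeps every residue of every chain (unsolved residues
#' are present, labeled non-interface); the structure variant keeps only
#' residues present in the solved coordinates. Interface counts are therefore
#' identical between variants built from the same chains.
#'
#' @param chains List of \code{rip_chain} objects labeled at a common cutoff.
#' @param variant \code{"sequence"} or \code{"structure"}.
#' @return A \code{rip_dataset}: tibble of residues with a \code{chain_key}
#'   column, plus attributes \code{variant}, \code{cutoff} and \code{counts}
#'   (named vector \code{n_interface}, \code{n_non_interface}).
#' @export
make_dataset <- function(chains, variant = c("sequence", "structure")) {
  variant <- match.arg(variant)
  if (inherits(chains, "rip_chain")) chains <- list(chains)
  stopifnot(length(chains) > 0,
            all(vapply(chains, inherits, logical(1), "rip_chain")))
  cutoffs <- vapply(chains, attr, numeric(1), "cutoff")
  if (length(unique(cutoffs)) != 1) {
    stop("chains were labeled with different cutoffs: ",
         paste(unique(cutoffs), collapse = ", "))
  }
  keys <- vapply(chains, chain_key, character(1))
  if (anyDuplicated(keys)) stop("duplicate chain keys in dataset")
  full_seqs <- stats::setNames(
    vapply(chains, function(ch) paste(ch$residue, collapse = ""),
           character(1)),
    keys
  )
  rows <- purrr::map(chains, function(ch) {
    tb <- tibble::as_tibble(ch)
    tb$chain_key <- chain_key(ch)
    if (variant == "structure") tb <- tb[tb$solved, , drop = FALSE]
    tb
  })
  tbl <- dplyr::bind_rows(rows) |>
    dplyr::relocate("chain_key")
  counts <- c(n_interface = sum(tbl$label == 1L),
              n_non_interface = sum(tbl$label == 0L))
  structure(tbl,
            variant = variant, cutoff = cutoffs[1], counts = counts,
            full_seqs = full_seqs,
            class = c("rip_dataset", class(tibble::as_tibble(tbl))))
}

#' Interface / non-interface counts of a dataset
#' @param dataset A \code{rip_dataset}.
#' @return Named integer vector \code{n_interface}, \code{n_non_interface}.
#' @export
dataset_counts <- function(dataset) attr(dataset, "counts")

# ---- Solvent accessibility --------------------------------------------------

VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               H = 1.20, D = 1.20, SE = 1.90, F = 1.47, CL = 1.75,
               BR = 1.85)
VDW_DEFAULT <- 1.70

# Theoretical maximum accessible surface areas per residue type (A^2),
# Tien et al.-style reference values used to express SASA in percent.
RSA_REF_MAX <- c(
  ALA = 129.0, ARG = 274.0, ASN = 195.0, ASP = 193.0, CYS = 167.0,
  GLN = 225.0, GLU = 223.0, GLY = 104.0, HIS = 224.0, ILE = 197.0,
  LEU = 201.0, LYS = 236.0, MET = 224.0, PHE = 240.0, PRO = 159.0,
  SER = 155.0, THR = 172.0, TRP = 285.0, TYR = 263.0, VAL = 174.0
)

# Deterministic unit sphere points (golden-section spiral).
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-residue relative solvent accessibility by sphere sampling
#'
#' Shrake-Rupley estimator: each heavy atom is expanded by the probe radius
#' and sampled with a deterministic spherical point set; a point is accessible
#' when it falls outside every other expanded atom. Residue SASA is the sum
#' over its heavy atoms, and relative accessibility is SASA divided by a fixed
#' per-residue-type theoretical maximum, in percent. The selected chain is
#' treated in isolation (accessibility of the unbound protein). This is a
#' built-in estimator with the NACCESS output conventions; numeric parity
#' with NACCESS is not promised, and precomputed \code{.rsa} tables (see
#' [read_rsa()]) take precedence when available.
#'
#' @param complex An \code{rip_complex}.
#' @param chain_id Protein chain.
#' @param probe Probe radius in Angstrom (default 1.4, water).
#' @param n_points Sphere sample points per atom (default 960).
#' @return Tibble with \code{chain_id}, \code{auth_seq}, \code{resname},
#'   \code{sasa} (absolute, A^2) and \code{rsa} (percent; \code{NA} for
#'   residue types without a reference maximum).
#' @export
compute_rsa <- function(complex, chain_id, probe = 1.4, n_points = 960) {
  stopifnot(inherits(complex, "rip_complex"))
  at <- complex$atoms
  at <- at[at$chain_id == chain_id & at$is_heavy, , drop = FALSE]
  if (nrow(at) == 0) stop("no heavy atoms for chain '", chain_id, "'")

  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- unname(VDW_RADII[at$element])
  rad[is.na(rad)] <- VDW_DEFAULT
  rext <- rad + probe
  pts <- sphere_points(n_points)

  atom_sasa <- vapply(seq_len(nrow(at)), function(i) {
    p <- sweep(pts * rext[i], 2, xyz[i, ], "+")
    # candidate occluders: expanded spheres that can reach atom i's surface
    dc <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ], "-")^2))
    nb <- which(dc < rext[i] + rext & seq_len(nrow(at)) != i)
    if (length(nb) == 0) {
      acc <- n_points
    } else {
      covered <- rep(FALSE, n_points)
      for (j in nb) {
        if (all(covered)) break
        d2 <- rowSums(sweep(p, 2, xyz[j, ], "-")^2)
        covered <- covered | d2 < rext[j]^2
      }
      acc <- sum(!covered)
    }
    4 * pi * rext[i]^2 * acc / n_points
  }, numeric(1))

  res <- tibble::tibble(res_index = at$res_index, auth_seq = at$auth_seq,
                        resname = at$resname, sasa = atom_sasa) |>
    dplyr::group_by(.data$res_index, .data$auth_seq, .data$resname) |>
    dplyr::summarise(sasa = sum(.data$sasa), .groups = "drop") |>
    dplyr::arrange(.data$res_index)
  ref <- unname(RSA_REF_MAX[res$resname])
  tibble::tibble(chain_id = chain_id, auth_seq = res$auth_seq,
                 resname = res$resname, sasa = res$sasa,
                 rsa = 100 * res$sasa / ref)
}

#' Flag surface residues of a labeled chain
#'
#' A solved residue is a surface residue when its relative accessibility is
#' strictly greater than \code{threshold} percent. Unsolved residues, and
#' solved residues missing from the RSA table, get \code{surface = NA}.
#'
#' @param chain A \code{rip_chain}.
#' @param rsa RSA tibble from [read_rsa()] or [compute_rsa()].
#' @param threshold Percent RSA above which a residue is surface (default 5;
#'   strict inequality).
#' @return The chain with its \code{surface} column filled in.
#' @export
flag_surface <- function(chain, rsa, threshold = 5) {
  stopifnot(inherits(chain, "rip_chain"))
  cid <- attr(chain, "chain_id")
  rsa <- rsa[is.na(rsa$chain_id) | rsa$chain_id == cid, , drop = FALSE]
  idx <- match(chain$auth_seq, rsa$auth_seq)
  val <- rsa$rsa[idx]
  surface <- ifelse(chain$solved, val > threshold, NA)
  miss <- chain$solved & is.na(val)
  if (any(miss)) {
    warning(sum(miss), " solved residue(s) missing from the RSA table; ",
            "surface left unknown")
  }
  chain$surface <- surface
  chain
}

#' Surface post-filter for predicted interface residues
#'
#' Residues predicted as interface but known not to be on the protein surface
#' are re-marked non-interface. Scores and all other rows are unchanged;
#' residues with unknown surface status are left untouched. The number of
#' predicted positives never increases.
#'
#' @param predictions Prediction tibble (see [write_predictions()]).
#' @param chain A \code{rip_chain} whose \code{surface} flags are set (see
#'   [flag_surface()]).
#' @return The filtered prediction tibble.
#' @export
surface_postfilter <- function(predictions, chain) {
  stopifnot(inherits(chain, "rip_chain"))
  predictions <- validate_predictions(predictions)
  surf <- chain$surface[match(predictions$position, chain$position)]
  drop <- predictions$pred == 1L & !is.na(surf) & !surf
  predictions$pred[drop] <- 0L
  predictions
}
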