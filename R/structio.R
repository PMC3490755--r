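# Readers and writers for the external formats: PDB coordinates, FASTA,
# PSI-BLAST ASCII PSSM, NACCESS-style RSA tables and prediction TSVs.

#' Read a protein-RNA complex from a PDB coordinate file
#'
#' Parses ATOM/HETATM records (fixed-column PDB dialect, via
#' \code{bio3d::read.pdb}) and partitions chains into protein and RNA by
#' residue-name vocabulary. Waters, ions and other unrecognised residues are
#' excluded. When several MODELs are present only the first is read; for
#' alternate locations the highest-occupancy conformer is kept, ties going to
#' altloc \code{"A"}.
#'
#' @param path Path to a PDB file.
#' @param pdb_id Identifier for the complex; defaults to the file stem.
#' @return An object of class \code{rip_complex}: a list with \code{pdb_id},
#'   an \code{atoms} tibble (one row per atom, with \code{chain_id},
#'   \code{moltype}, \code{resname}, \code{auth_seq}, \code{res_index},
#'   \code{one_letter}, \code{atom_name}, \code{element}, \code{is_heavy},
#'   \code{x}, \code{y}, \code{z}) and a \code{chains} summary tibble.
#'   A complex with no protein or no RNA chain is returned (with a warning);
#'   labeling requires both.
#' @seealso [label_interface()], [complex_chains()]
#' @export
read_complex <- function(path, pdb_id = NULL) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  if (is.null(pdb_id)) pdb_id <- sub("\\.(pdb|ent)$", "", basename(path))

  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) stop("failed to parse PDB file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- tibble::as_tibble(pdb$atom)
  if (nrow(at) == 0) {
    return(new_rip_complex(pdb_id, empty_atom_tibble()))
  }

  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  at$resid <- toupper(trimws(at$resid))

  # altloc: keep the highest-occupancy conformer per atom site, ties -> 'A'
  # (then first file order).
  at <- at |>
    dplyr::group_by(.data$chain, .data$resno, .data$insert, .data$resid,
                    .data$elety) |>
    dplyr::arrange(dplyr::desc(.data$o), .data$alt != "A",
                   .data$eleno, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$eleno)

  at <- at[!(at$resid %in% WATER_RESNAMES), , drop = FALSE]
  keep <- is_protein_resname(at$resid) | is_rna_resname(at$resid)
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) {
    warning("no protein or RNA residues found in '", path, "'")
    return(new_rip_complex(pdb_id, empty_atom_tibble()))
  }

  element <- toupper(trimws(at$elesy))
  miss <- is.na(element) | element == ""
  element[miss] <- element_from_atom_name(at$elety[miss])

  atoms <- tibble::tibble(
    chain_id  = at$chain,
    resname   = at$resid,
    auth_seq  = paste0(at$resno, trimws(at$insert)),
    atom_name = trimws(at$elety),
    element   = element,
    is_heavy  = !(element %in% c("H", "D")),
    serial    = at$eleno,
    x = at$x, y = at$y, z = at$z
  )

  # per-chain residue order = file order of first atom of each residue
  atoms <- atoms |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::mutate(res_index = match(.data$auth_seq, unique(.data$auth_seq))) |>
    dplyr::ungroup()

  # chain moltype by majority residue vocabulary
  res_tbl <- atoms |>
    dplyr::distinct(.data$chain_id, .data$res_index, .data$resname)
  chain_type <- res_tbl |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      n_protein = sum(is_protein_resname(.data$resname)),
      n_rna     = sum(is_rna_resname(.data$resname)),
      .groups = "drop"
    ) |>
    dplyr::mutate(moltype = ifelse(.data$n_protein >= .data$n_rna,
                                   "protein", "rna"))

  atoms <- atoms |>
    dplyr::left_join(chain_type[, c("chain_id", "moltype")], by = "chain_id") |>
    dplyr::mutate(
      one_letter = ifelse(.data$moltype == "protein",
                          aa_three_to_one(.data$resname),
                          rna_one_letter(.data$resname))
    ) |>
    dplyr::relocate("chain_id", "moltype", "resname", "auth_seq", "res_index",
                    "one_letter")

  cx <- new_rip_complex(pdb_id, atoms)
  ch <- complex_chains(cx)
  if (!any(ch$moltype == "protein") || !any(ch$moltype == "rna")) {
    warning("complex '", pdb_id,
            "' lacks a protein or an RNA chain; labeling will not be possible")
  }
  cx
}

empty_atom_tibble <- function() {
  tibble::tibble(
    chain_id = character(), moltype = character(), resname = character(),
    auth_seq = character(), res_index = integer(), one_letter = character(),
    atom_name = character(), element = character(), is_heavy = logical(),
    serial = integer(), x = double(), y = double(), z = double()
  )
}

new_rip_complex <- function(pdb_id, atoms) {
  structure(list(pdb_id = pdb_id, atoms = atoms), class = "rip_complex")
}

element_from_atom_name <- function(atom_name) {
  nm <- toupper(trimws(atom_name))
  # two-letter elements seen in nucleic/protein context
  two <- substr(nm, 1, 2)
  out <- ifelse(two %in% c("SE", "FE", "MG", "ZN", "MN", "BR", "CL"), two,
                substr(sub("^[0-9']*", "", nm), 1, 1))
  out[out == ""] <- "C"
  out
}

#' Summarise the chains of a parsed complex
#'
#' @param complex An \code{rip_complex} from [read_complex()].
#' @return Tibble with one row per chain: \code{chain_id}, \code{moltype},
#'   \code{n_residues}, \code{n_atoms}.
#' @export
complex_chains <- function(complex) {
  stopifnot(inherits(complex, "rip_complex"))
  complex$atoms |>
    dplyr::group_by(.data$chain_id, .data$moltype) |>
    dplyr::summarise(n_residues = dplyr::n_distinct(.data$res_index),
                     n_atoms = dplyr::n(), .groups = "drop")
}

#' @export
print.rip_complex <- function(x, ...) {
  ch <- complex_chains(x)
  cat("<rip_complex> ", x$pdb_id, ": ", nrow(ch), " chain(s), ",
      nrow(x$atoms), " atoms\n", sep = "")
  if (nrow(ch)) print(ch)
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return Tibble with columns \code{id} (first whitespace-delimited token of
#'   the header) and \code{seq} (uppercased; characters outside the 20
#'   amino-acid alphabet become \code{"X"}).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA file: ", path)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  seqs <- toupper(gsub("\\s", "", as.character(set)))
  seqs <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    ch[!(ch %in% PSSM_COLUMNS)] <- "X"
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
  if (any(!nzchar(seqs))) stop("FASTA record with empty sequence in ", path)
  tibble::tibble(id = ids, seq = seqs)
}

#' Write sequences to FASTA
#'
#' @param seqs Tibble with columns \code{id} and \code{seq}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  writeLines(paste0(">", seqs$id, "\n", seqs$seq), path)
  invisible(path)
}

#' Read a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Parses the classic ASCII PSSM produced by PSI-BLAST (header lines, one row
#' per sequence position carrying the position index, the query residue and 20
#' integer log-odds scores, then trailing statistics). Only the first block of
#' 20 score columns (the log-odds profile) is used; the weighted-percentage
#' block, when present, is ignored.
#'
#' @param path Path to an ASCII PSSM file.
#' @return An object of class \code{rip_pssm}: list with \code{residues}
#'   (character vector of query residues), \code{raw} (n x 20 numeric matrix
#'   of log-odds scores), \code{normalized} (elementwise logistic of
#'   \code{raw}, every value strictly in (0,1)) and \code{column_order}
#'   (the 20 amino-acid column labels).
#' @seealso [logistic_normalize()], [smooth_pssm()]
#' @export
read_pssm <- function(path) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  row_re <- "^\\s*([0-9]+)\\s+([A-Za-z])\\s+(-?[0-9].*)$"
  hits <- grepl(row_re, lines)
  if (!any(hits)) stop("no PSSM rows found in ", path)

  pos <- integer(0); res <- character(0); rows <- list()
  for (ln in lines[hits]) {
    m <- regmatches(ln, regexec(row_re, ln))[[1]]
    nums <- suppressWarnings(as.numeric(strsplit(trimws(m[4]), "\\s+")[[1]]))
    if (length(nums) < 20 || anyNA(nums[1:20])) {
      stop("malformed PSSM row (need 20 log-odds scores): ", trimws(ln))
    }
    pos <- c(pos, as.integer(m[2]))
    res <- c(res, toupper(m[3]))
    rows[[length(rows) + 1L]] <- nums[1:20]
  }
  if (!identical(pos, seq_along(pos))) {
    stop("PSSM positions are not consecutive from 1 in ", path)
  }
  raw <- do.call(rbind, rows)
  colnames(raw) <- PSSM_COLUMNS
  new_rip_pssm(res, raw)
}

new_rip_pssm <- function(residues, raw) {
  stopifnot(ncol(raw) == 20, nrow(raw) == length(residues))
  structure(
    list(residues = residues, raw = raw,
         normalized = logistic_normalize(raw),
         column_order = PSSM_COLUMNS),
    class = "rip_pssm"
  )
}

#' @export
print.rip_pssm <- function(x, ...) {
  cat("<rip_pssm> ", length(x$residues), " positions x 20 columns\n", sep = "")
  invisible(x)
}

#' Length of a PSSM profile
#' @param x An \code{rip_pssm}.
#' @param ... Unused.
#' @export
length.rip_pssm <- function(x) length(x$residues)

#' Read a NACCESS-style per-residue relative accessibility table
#'
#' Reads \code{RES} lines of a NACCESS \code{.rsa} file. The all-atoms
#' relative accessibility (the second numeric column of each \code{RES} line,
#' in percent) is retained.
#'
#' @param path Path to a \code{.rsa} file.
#' @return Tibble with columns \code{chain_id}, \code{auth_seq},
#'   \code{resname}, \code{rsa} (percent). Empty files yield an empty tibble.
#' @export
read_rsa <- function(path) {
  if (!file.exists(path)) stop("RSA file not found: ", path)
  lines <- grep("^RES\\s", readLines(path, warn = FALSE), value = TRUE)
  if (length(lines) == 0) {
    return(tibble::tibble(chain_id = character(), auth_seq = character(),
                          resname = character(), rsa = double()))
  }
  parse_one <- function(ln) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    # RES <resname> <chain> <number[ins]> <abs all> <rel all> ...
    if (length(toks) < 6) stop("malformed RSA line: ", ln)
    rel <- suppressWarnings(as.numeric(toks[6]))
    if (is.na(rel)) stop("missing relative accessibility column in: ", ln)
    tibble::tibble(chain_id = toks[3], auth_seq = toks[4],
                   resname = toupper(toks[2]), rsa = rel)
  }
  out <- dplyr::bind_rows(lapply(lines, parse_one))
  if (anyDuplicated(out[, c("chain_id", "auth_seq")])) {
    stop("duplicate (chain, residue) keys in RSA file ", path)
  }
  out
}

#' Write / read per-residue prediction tables
#'
#' Predictions are tab-separated with a header and one row per residue:
#' \code{chain_id}, \code{position} (1-based index in the full sequence),
#' \code{residue}, \code{score} (real-valued ranking score), \code{pred}
#' (0/1) and optional \code{label} (0/1 truth, \code{NA} when unknown).
#' \code{read_predictions(write_predictions(x, p))} recovers \code{x}.
#'
#' @param predictions Tibble with the columns above.
#' @param path File path.
#' @return \code{write_predictions} returns \code{path} invisibly;
#'   \code{read_predictions} returns the tibble.
#' @export
write_predictions <- function(predictions, path) {
  predictions <- validate_predictions(predictions)
  readr::write_tsv(predictions, path)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  tab <- readr::read_tsv(
    path,
    col_types = readr::cols(
      chain_id = readr::col_character(),
      position = readr::col_integer(),
      residue  = readr::col_character(),
      score    = readr::col_double(),
      pred     = readr::col_integer(),
      label    = readr::col_integer(),
      .default = readr::col_guess()
    ),
    progress = FALSE
  )
  validate_predictions(tab)
}

validate_predictions <- function(tab) {
  need <- c("chain_id", "position", "residue", "score", "pred")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("prediction table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (!"label" %in% names(tab)) tab$label <- NA_integer_
  if (!all(tab$pred %in% c(0L, 1L))) {
    stop("predicted labels must be 0 or 1")
  }
  if (!all(is.na(tab$label) | tab$label %in% c(0L, 1L))) {
    stop("true labels must be 0, 1 or NA")
  }
  if (anyDuplicated(tab[, c("chain_id", "position")])) {
    stop("duplicate (chain_id, position) rows in prediction table")
  }
  tibble::as_tibble(tab)[, c("chain_id", "position", "residue",
                             "score", "pred", "label")]
}
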