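# The six feature encodings: identity, PSSM and smoothed-PSSM channels over
# sequence or spatial-neighbor windows, plus logistic normalization, an
# optional auxiliary scalar channel and class balancing.

ENCODINGS <- c("IDSeq", "PSSMSeq", "SmoPSSMSeq", "IDStr", "PSSMStr",
               "SmoPSSMStr")

#' Logistic normalization of PSSM scores
#'
#' Maps a raw log-odds score x to y = 1 / (1 + e^(-x)). Strictly increasing,
#' numerically stable for extreme arguments (no overflow or NaN).
#'
#' @param x Numeric vector/matrix of raw scores.
#' @return Values in (0, 1), same shape as \code{x}.
#' @export
#' @examples
#' logistic_normalize(c(0, log(3)))  # 0.5, 0.75
logistic_normalize <- function(x) {
  y <- stats::plogis(x)
  if (is.matrix(x)) dim(y) <- dim(x)
  y
}

#' Smooth a PSSM over neighboring sequence positions
#'
#' Each position's 20 raw scores are replaced by the sum of raw scores over a
#' centered window of \code{w} positions (e.g. w = 5 sums positions i-2..i+2);
#' positions beyond the chain termini contribute 0. The normalized matrix is
#' recomputed from the smoothed raw scores.
#'
#' @param profile An \code{rip_pssm}.
#' @param w Odd smoothing window size (default 3; w = 1 is the identity).
#' @return A smoothed \code{rip_pssm}.
#' @export
smooth_pssm <- function(profile, w = 3) {
  stopifnot(inherits(profile, "rip_pssm"), w >= 1, w %% 2 == 1)
  if (w == 1) return(profile)
  n <- nrow(profile$raw)
  h <- (w - 1) / 2
  sm <- matrix(0, n, 20, dimnames = dimnames(profile$raw))
  for (off in -h:h) {
    src <- seq_len(n) + off
    ok <- src >= 1 & src <= n
    sm[ok, ] <- sm[ok, ] + profile$raw[src[ok], , drop = FALSE]
  }
  new_rip_pssm(profile$residues, sm)
}

#' Sequence window positions around a target residue
#'
#' @param chain_length Sequence length n.
#' @param position Target position p (1-based).
#' @param window_size Odd window size W.
#' @return Integer vector of length W: positions p-(W-1)/2 .. p+(W-1)/2, with
#'   \code{NA} marking out-of-range (padding) slots; the target sits at the
#'   center index.
#' @export
sequence_window <- function(chain_length, position, window_size = 25) {
  stopifnot(window_size >= 1, window_size %% 2 == 1,
            position >= 1, position <= chain_length)
  h <- (window_size - 1) / 2
  win <- seq.int(position - h, position + h)
  win[win < 1 | win > chain_length] <- NA_integer_
  as.integer(win)
}

#' Spatial neighbor index over the solved residues of a chain
#'
#' Residue centroids are the means of heavy-atom coordinates; the distance
#' between two residues is the distance between their centroids. For every
#' solved residue the other solved residues are listed in ascending centroid
#' distance, ties broken by ascending sequence position.
#'
#' @param chain A \code{rip_chain} (or structure-variant rows of one chain).
#' @return A \code{rip_spatial_index}: list with \code{positions} (solved
#'   positions with centroids) and \code{neighbors}, a list mapping each
#'   position (as character) to a tibble \code{position}, \code{dist}.
#' @export
build_spatial_index <- function(chain) {
  solved <- chain[chain$solved & !is.na(chain$cx), , drop = FALSE]
  n_dropped <- sum(chain$solved & is.na(chain$cx))
  if (n_dropped > 0) {
    warning(n_dropped, " solved residue(s) without heavy atoms excluded ",
            "from the spatial index")
  }
  if (nrow(solved) == 0) stop("no solved residues with coordinates")
  cent <- as.matrix(solved[, c("cx", "cy", "cz")])
  pos <- solved$position
  d <- as.matrix(stats::dist(cent))
  neighbors <- lapply(seq_along(pos), function(i) {
    o <- order(d[i, -i], pos[-i])
    tibble::tibble(position = pos[-i][o], dist = unname(d[i, -i][o]))
  })
  names(neighbors) <- as.character(pos)
  structure(list(positions = pos, neighbors = neighbors),
            class = "rip_spatial_index")
}

#' Spatial (structure-based) window around a solved residue
#'
#' @param index A \code{rip_spatial_index}.
#' @param position Solved target position.
#' @param window_size Total window size W: the target plus its W-1 nearest
#'   solved residues by centroid distance.
#' @return Integer vector of length W; target first, then neighbors by
#'   ascending distance, \code{NA}-padded when fewer than W-1 neighbors exist.
#' @export
spatial_window <- function(index, position, window_size = 25) {
  stopifnot(inherits(index, "rip_spatial_index"),
            window_size >= 1, window_size %% 2 == 1)
  key <- as.character(position)
  if (!key %in% names(index$neighbors)) {
    stop("position ", position, " is not a solved residue in the index")
  }
  nb <- index$neighbors[[key]]$position
  win <- c(position, utils::head(nb, window_size - 1))
  length(win) <- window_size  # NA padding
  as.integer(win)
}

#' Encoding configuration
#'
#' @param encoding One of \code{"IDSeq"}, \code{"PSSMSeq"},
#'   \code{"SmoPSSMSeq"}, \code{"IDStr"}, \code{"PSSMStr"},
#'   \code{"SmoPSSMStr"}.
#' @param window_size Odd window size W (default 25: the target and 12
#'   residues on either side, or the 24 spatially nearest residues).
#' @param smoothing_window Odd smoothing window w for the SmoPSSM variants
#'   (default 3).
#' @param aux Optional auxiliary per-residue scalar channel: a named list
#'   mapping chain keys to numeric vectors over full-sequence positions
#'   (e.g. externally predicted solvent accessibility). Appends one feature
#'   per window position.
#' @return An \code{encoding_config} list.
#' @export
encoding_config <- function(encoding = "PSSMSeq", window_size = 25,
                            smoothing_window = 3, aux = NULL) {
  encoding <- match.arg(encoding, ENCODINGS)
  stopifnot(window_size >= 1, window_size %% 2 == 1,
            smoothing_window >= 1, smoothing_window %% 2 == 1)
  structure(list(encoding = encoding, window_size = window_size,
                 smoothing_window = smoothing_window, aux = aux),
            class = "encoding_config")
}

encoding_is_id <- function(cfg) grepl("^ID", cfg$encoding)
encoding_is_spatial <- function(cfg) grepl("Str$", cfg$encoding)
encoding_is_smoothed <- function(cfg) grepl("^SmoPSSM", cfg$encoding)

#' Feature-vector length implied by a configuration
#'
#' W x 20 for PSSM channels, W x 21 for identity channels (20 amino acids
#' plus 'X' after one-hot binarization), plus W when the auxiliary channel is
#' active.
#'
#' @param config An \code{encoding_config}.
#' @return Integer feature count.
#' @export
feature_length <- function(config) {
  per <- if (encoding_is_id(config)) 21L else 20L
  n <- config$window_size * per
  if (!is.null(config$aux)) n <- n + config$window_size
  as.integer(n)
}

#' Encode one window into a feature vector
#'
#' Identity channels emit a 21-symbol one-hot per window position (padding
#' encodes as 'X'); PSSM channels emit the 20 logistic-normalized profile
#' values per position (padding encodes as 0.5, the logistic midpoint);
#' smoothed variants read the smoothed profile. The auxiliary channel, when
#' configured, appends one scalar per position (padding 0).
#'
#' @param residues Character vector: the chain's full-sequence residues.
#' @param profile An \code{rip_pssm} over the full sequence (already smoothed
#'   for SmoPSSM encodings), or \code{NULL} for identity encodings.
#' @param window Integer positions from [sequence_window()] or
#'   [spatial_window()] (\code{NA} = padding).
#' @param config An \code{encoding_config}.
#' @param aux_values Optional numeric vector of per-position auxiliary values.
#' @return Numeric feature vector of length [feature_length()].
#' @export
encode_instance <- function(residues, profile, window, config,
                            aux_values = NULL) {
  W <- config$window_size
  stopifnot(length(window) == W)
  if (encoding_is_id(config)) {
    letters <- residues[ifelse(is.na(window), 1L, window)]
    letters[is.na(window)] <- "X"
    letters[!(letters %in% AA_ALPHABET)] <- "X"
    block <- matrix(0, W, 21L)
    block[cbind(seq_len(W), match(letters, AA_ALPHABET))] <- 1
  } else {
    if (is.null(profile)) stop("PSSM encodings require a profile")
    if (length(profile$residues) != length(residues)) {
      stop("profile length (", length(profile$residues),
           ") does not match chain length (", length(residues), ")")
    }
    block <- profile$normalized[ifelse(is.na(window), 1L, window), ,
                                drop = FALSE]
    block[is.na(window), ] <- 0.5
  }
  feats <- as.vector(t(block))
  if (!is.null(config$aux)) {
    av <- if (is.null(aux_values)) rep(0, length(residues)) else aux_values
    a <- av[ifelse(is.na(window), 1L, window)]
    a[is.na(window) | is.na(a)] <- 0
    feats <- c(feats, a)
  }
  feats
}

#' Encode every residue of a dataset
#'
#' Sequence encodings window over the full chain sequence; spatial (Str)
#' encodings window over centroid-nearest solved residues and are defined
#' only for solved targets. One instance is emitted per dataset row (for
#' spatial encodings, per solved dataset row), so sequence encodings applied
#' to a structure-variant dataset use full-sequence windows but emit
#' instances only for solved residues.
#'
#' @param dataset A \code{rip_dataset} from [make_dataset()].
#' @param profiles Named list of \code{rip_pssm} objects keyed by chain key
#'   (required for PSSM/SmoPSSM encodings; profiles span the full sequence).
#' @param config An \code{encoding_config}.
#' @return An object of class \code{rip_features}: list with \code{x}
#'   (instances x features numeric matrix), \code{meta} (tibble
#'   \code{chain_key}, \code{position}, \code{residue}, \code{label}) and
#'   \code{config}.
#' @export
encode_dataset <- function(dataset, profiles = NULL, config) {
  stopifnot(inherits(dataset, "rip_dataset"),
            inherits(config, "encoding_config"))
  full_seqs <- attr(dataset, "full_seqs")
  keys <- unique(dataset$chain_key)
  need_pssm <- !encoding_is_id(config)
  spatial <- encoding_is_spatial(config)

  chunks <- lapply(keys, function(key) {
    rows <- dataset[dataset$chain_key == key, , drop = FALSE]
    residues <- strsplit(full_seqs[[key]], "")[[1]]
    prof <- NULL
    if (need_pssm) {
      prof <- profiles[[key]]
      if (is.null(prof)) stop("missing PSSM profile for chain ", key)
      if (encoding_is_smoothed(config)) {
        prof <- smooth_pssm(prof, config$smoothing_window)
      }
    }
    aux_values <- if (!is.null(config$aux)) config$aux[[key]] else NULL
    if (spatial) {
      rows <- rows[rows$solved, , drop = FALSE]
      idx <- build_spatial_index(rows)
      wins <- lapply(rows$position, spatial_window, index = idx,
                     window_size = config$window_size)
    } else {
      wins <- lapply(rows$position, sequence_window,
                     chain_length = length(residues),
                     window_size = config$window_size)
    }
    x <- t(vapply(wins, encode_instance, numeric(feature_length(config)),
                  residues = residues, profile = prof, config = config,
                  aux_values = aux_values))
    list(x = x,
         meta = tibble::tibble(chain_key = key, position = rows$position,
                               residue = rows$residue, label = rows$label))
  })

  new_rip_features(
    x = do.call(rbind, lapply(chunks, `[[`, "x")),
    meta = dplyr::bind_rows(lapply(chunks, `[[`, "meta")),
    config = config
  )
}

new_rip_features <- function(x, meta, config) {
  stopifnot(nrow(x) == nrow(meta))
  structure(list(x = x, meta = meta, config = config),
            class = "rip_features")
}

#' @export
print.rip_features <- function(x, ...) {
  cat("<rip_features> ", nrow(x$x), " instances x ", ncol(x$x),
      " features (", x$config$encoding, ", W=", x$config$window_size, ")\n",
      sep = "")
  invisible(x)
}

subset_features <- function(feats, idx) {
  new_rip_features(feats$x[idx, , drop = FALSE], feats$meta[idx, , drop = FALSE],
                   feats$config)
}

# run code under a private, seeded RNG stream without disturbing the caller's
with_private_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Balance classes by undersampling the majority class
#'
#' The minority class is kept whole; the majority class is sampled without
#' replacement down to the minority count with a seeded generator, and the
#' result is deterministically shuffled.
#'
#' @param features A \code{rip_features}.
#' @param seed Integer seed.
#' @return A balanced \code{rip_features}.
#' @export
undersample <- function(features, seed = 1) {
  stopifnot(inherits(features, "rip_features"))
  lab <- features$meta$label
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  if (n1 == 0 || n0 == 0) stop("undersample: both classes must be present")
  minority <- if (n1 <= n0) 1L else 0L
  keep_min <- which(lab == minority)
  maj <- which(lab != minority)
  idx <- with_private_seed(seed, {
    kept <- sample(maj, length(keep_min), replace = FALSE)
    sample(c(keep_min, kept))
  })
  subset_features(features, idx)
}
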