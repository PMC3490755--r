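# Interface labeling, dataset variants, inclusion filters, solvent
# accessibility and the surface post-filter.

atoms_at <- function(xyz, heavy = TRUE) {
  tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                 is_heavy = heavy)
}

test_that("residue_min_distance returns the closest atom pair", {
  res <- atoms_at(rbind(c(0, 0, 0)))
  rna <- atoms_at(rbind(c(0, 0, 4.9), c(0, 0, 9)))
  expect_equal(residue_min_distance(res, rna), 4.9)
  expect_equal(residue_min_distance(res, atoms_at(rbind(c(0, 0, 0)))), 0)
  expect_error(residue_min_distance(res, rna[0, ]), "empty")
})

test_that("residue_min_distance equals the exhaustive pairwise minimum", {
  set.seed(101)
  for (rep in 1:20) {
    a <- matrix(rnorm(9, sd = 5), 3)
    b <- matrix(rnorm(6, sd = 5), 2)
    brute <- min(apply(a, 1, function(p)
      apply(b, 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(residue_min_distance(atoms_at(a), atoms_at(b)), brute)
  }
})

test_that("heavy-only atom policy ignores hydrogens", {
  res <- tibble::tibble(x = c(0, 0), y = c(0, 0), z = c(4.9, 3.0),
                        is_heavy = c(TRUE, FALSE))
  rna <- atoms_at(rbind(c(0, 0, 0)))
  expect_equal(residue_min_distance(res, rna, atom_policy = "all"), 3.0)
  expect_equal(residue_min_distance(res, rna, atom_policy = "heavy"), 4.9)
})

test_that("label_interface labels exactly the residues within the cutoff", {
  cx <- read_complex(write_toy_complex())
  ch <- label_interface(cx, "A", "AGV", cutoff = 5)
  expect_equal(ch$label, c(0L, 1L, 1L))
  expect_true(all(ch$solved))
  expect_equal(ch$min_rna_dist[2], 4.9)
  # threshold semantics: nearest pair 4.9 > 3.5 (but residue 3 is at 3.0)
  ch35 <- label_interface(cx, "A", "AGV", cutoff = 3.5)
  expect_equal(ch35$label, c(0L, 0L, 1L))
  ch2 <- label_interface(cx, "A", "AGV", cutoff = 2)
  expect_equal(ch2$label, c(0L, 0L, 0L))
})

test_that("unsolved leading residues are retained and labeled non-interface", {
  cx <- read_complex(write_toy_complex())
  ch <- label_interface(cx, "A", "MKKWAGV", cutoff = 5)
  expect_equal(nrow(ch), 7)
  expect_equal(ch$solved, c(rep(FALSE, 4), rep(TRUE, 3)))
  expect_equal(ch$label, c(rep(0L, 4), 0L, 1L, 1L))
  expect_true(all(is.na(ch$min_rna_dist[1:4])))
})

test_that("labels are monotone in the cutoff", {
  spec <- synthetic_spec(n_chains = 1, length_range = c(45, 45), seed = 21)
  cxg <- gen_complex(spec, 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(cxg$pdb_text, path)
  cx <- read_complex(path)
  cuts <- c(3, 4.5, 6, 13)
  labs <- lapply(cuts, function(co)
    label_interface(cx, "A", cxg$sequence, cutoff = co)$label)
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(labs[[i]] <= labs[[i + 1]]))
  }
})

test_that("solved residues with internal gaps map back to the full sequence", {
  spec <- synthetic_spec(n_chains = 1, length_range = c(60, 60),
                         unsolved_fraction = 0.15, seed = 33)
  cxg <- gen_complex(spec, 1)
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(cxg$pdb_text, path)
  ch <- label_interface(read_complex(path), "A", cxg$sequence, cutoff = 5)
  expect_equal(sum(ch$solved), sum(cxg$truth$solved))
  expect_equal(ch$label, cxg$truth$label)
})

test_that("inclusion filters apply their inclusive thresholds", {
  mk <- function(len, n_int) {
    make_chain(rep("A", len),
               label = c(rep(1L, n_int), rep(0L, len - n_int)))
  }
  expect_false(passes_inclusion_filters(mk(39, 5), rna_lengths = 10))
  expect_true(passes_inclusion_filters(mk(40, 3), rna_lengths = 5))
  expect_false(passes_inclusion_filters(mk(200, 2), rna_lengths = 20))
  expect_false(passes_inclusion_filters(mk(50, 5), rna_lengths = 4))
})

test_that("dataset variants keep interface counts and drop unsolved negatives", {
  ch <- make_chain(rep("A", 10),
                   solved = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
                              TRUE, FALSE, TRUE),
                   label = c(0L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L, 0L))
  dseq <- make_dataset(list(ch), "sequence")
  dstr <- make_dataset(list(ch), "structure")
  expect_equal(dataset_counts(dseq), c(n_interface = 3, n_non_interface = 7))
  expect_equal(dataset_counts(dstr), c(n_interface = 3, n_non_interface = 5))
  expect_true(all(dstr$solved))
  # all-solved chain: variants identical
  ch2 <- make_chain(rep("G", 6), label = c(1L, 1L, 0L, 0L, 0L, 0L))
  expect_equal(nrow(make_dataset(list(ch2), "sequence")),
               nrow(make_dataset(list(ch2), "structure")))
})

test_that("interface counts agree across variants on random fixtures", {
  set.seed(7)
  for (rep in 1:10) {
    n <- sample(20:40, 1)
    ch <- make_chain(sample(rnaiface:::PSSM_COLUMNS, n, replace = TRUE),
                     solved = runif(n) > 0.2,
                     label = as.integer(runif(n) > 0.7))
    ch$label[!ch$solved] <- 0L  # unsolved residues are never interface
    dseq <- make_dataset(list(ch), "sequence")
    dstr <- make_dataset(list(ch), "structure")
    expect_equal(dataset_counts(dseq)[["n_interface"]],
                 sum(ch$label == 1L))
    expect_equal(dataset_counts(dstr)[["n_interface"]],
                 sum(ch$label == 1L))
    expect_equal(dataset_counts(dseq)[["n_non_interface"]] -
                   dataset_counts(dstr)[["n_non_interface"]],
                 sum(!ch$solved))
  }
})

test_that("chains labeled at different cutoffs cannot be mixed", {
  c1 <- make_chain(rep("A", 5), cutoff = 5)
  c2 <- make_chain(rep("A", 5), cutoff = 3.5)
  attr(c2, "chain_key") <- "toy2_A"
  expect_error(make_dataset(list(c1, c2)), "different cutoffs")
})

test_that("an isolated atom has the closed-form accessible surface", {
  lines <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             pdb_line(2, "P", "A", "B", 1, 100, 0, 0, element = "P"),
             "END")
  cx <- read_complex(write_toy_complex(lines))
  out <- compute_rsa(cx, "A", n_points = 960)
  r <- 1.70 + 1.4
  expect_equal(out$sasa[1], 4 * pi * r^2, tolerance = 1e-6)
})

test_that("a fully enclosed atom has (near) zero accessible surface", {
  # central CA caged by 14 neighbors on a 2.5 A shell
  dirs <- rbind(diag(3), -diag(3),
                cbind(c(1, 1, 1, 1, -1, -1, -1, -1), c(1, 1, -1, -1, 1, 1, -1, -1),
                      c(1, -1, 1, -1, 1, -1, 1, -1)) / sqrt(3))
  lines <- c(pdb_line(1, "CA", "GLY", "A", 1, 0, 0, 0),
             vapply(seq_len(nrow(dirs)), function(i)
               pdb_line(i + 1, "CB", "ALA", "A", i + 1,
                        2.5 * dirs[i, 1], 2.5 * dirs[i, 2], 2.5 * dirs[i, 3]),
               character(1)),
             pdb_line(20, "P", "A", "B", 1, 100, 0, 0, element = "P"),
             "END")
  cx <- read_complex(write_toy_complex(lines))
  out <- compute_rsa(cx, "A")
  expect_lt(out$sasa[out$resname == "GLY"], 1e-6)
})

test_that("default sampling matches a much denser sampling within 2%", {
  lines <- c(pdb_line(1, "CA", "ALA", "A", 1, 0, 0, 0),
             pdb_line(2, "CB", "ALA", "A", 1, 1.5, 0, 0),
             pdb_line(3, "CA", "GLY", "A", 2, 3.8, 0.5, 0.5),
             pdb_line(4, "P", "A", "B", 1, 100, 0, 0, element = "P"),
             "END")
  cx <- read_complex(write_toy_complex(lines))
  coarse <- compute_rsa(cx, "A", n_points = 960)
  fine <- compute_rsa(cx, "A", n_points = 10000)
  expect_equal(coarse$sasa, fine$sasa, tolerance = 0.02)
  expect_equal(coarse$rsa, fine$rsa, tolerance = 0.02)
})

test_that("surface flags use a strict >5% rule and NA for unsolved", {
  ch <- make_chain(c("A", "G", "V"), solved = c(TRUE, TRUE, FALSE))
  rsa <- tibble::tibble(chain_id = "A", auth_seq = c("1", "2"),
                        resname = c("ALA", "GLY"), rsa = c(5.0, 5.01))
  out <- flag_surface(ch, rsa, threshold = 5)
  expect_identical(out$surface, c(FALSE, TRUE, NA))
})

test_that("missing RSA for a solved residue warns and leaves surface unknown", {
  ch <- make_chain(c("A", "G"))
  rsa <- tibble::tibble(chain_id = "A", auth_seq = "1", resname = "ALA",
                        rsa = 50)
  expect_warning(out <- flag_surface(ch, rsa), "missing")
  expect_identical(out$surface, c(TRUE, NA))
})

test_that("the surface post-filter only demotes buried predicted positives", {
  ch <- make_chain(c("A", "G", "V", "K"))
  ch$surface <- c(FALSE, TRUE, FALSE, NA)
  preds <- tibble::tibble(
    chain_id = "toy_A", position = 1:4, residue = c("A", "G", "V", "K"),
    score = c(2, 1.5, -1, 0.5), pred = c(1L, 1L, 0L, 1L),
    label = c(1L, 1L, 0L, 0L)
  )
  out <- surface_postfilter(preds, ch)
  expect_equal(out$pred, c(0L, 1L, 0L, 1L))  # buried positive demoted only
  expect_equal(out$score, preds$score)       # scores untouched
  expect_lte(sum(out$pred), sum(preds$pred))
})

test_that("the post-filter never increases predicted positives", {
  set.seed(11)
  for (rep in 1:10) {
    n <- 20
    ch <- make_chain(rep("A", n))
    ch$surface <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
    preds <- tibble::tibble(chain_id = "toy_A", position = 1:n, residue = "A",
                            score = rnorm(n),
                            pred = sample(0:1, n, replace = TRUE),
                            label = sample(0:1, n, replace = TRUE))
    out <- surface_postfilter(preds, ch)
    expect_lte(sum(out$pred), sum(preds$pred))
    expect_true(all(out$pred[preds$pred == 0L] == 0L))
  }
})
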