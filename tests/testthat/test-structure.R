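test_that("the toy fixture round-trips through the PDB reader", {
  path <- toy_structure_file(4.4, 19.9)
  s <- read_pdb(path)
  expect_s3_class(s, "structure_model")
  expect_setequal(unique(s$chain), c("A", "B", "C"))
  expect_equal(nrow(s), 15)
  # coordinates survive the fixed-width format to printed precision
  expect_equal(s$y[s$chain == "B"], rep(4.4, 5), tolerance = 1e-9)
  expect_error(read_pdb(tempfile()), "not found")
})

test_that("only the first model of a multi-model file is read", {
  path <- tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL     1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL     2",
    "ATOM      2  CA  ALA A   1       9.000   9.000   9.000  1.00  0.00           C",
    "ENDMDL",
    "END"), path)
  s <- read_pdb(path)
  expect_equal(nrow(s), 1)
  expect_equal(s$x, 0)
})

test_that("contact annotation respects the inclusive 4.5 A cutoff", {
  near <- read_pdb(toy_structure_file(4.4, 19.9))
  hit <- contact_residues(near, "A", "B")
  expect_equal(nrow(hit), 5) # every facing residue pair sits at 4.4 A
  expect_equal(hit$min_distance, rep(4.4, 5), tolerance = 1e-9)

  exact <- read_pdb(toy_structure_file(4.5, 19.9))
  expect_equal(nrow(contact_residues(exact, "A", "B")), 5) # boundary counts

  far <- read_pdb(toy_structure_file(4.6, 19.9))
  expect_equal(nrow(contact_residues(far, "A", "B")), 0)
  # chain C is remote from the ligand chain
  expect_equal(nrow(contact_residues(near, "A", "C")), 0)
  expect_error(contact_residues(near, "Z", "B"), "Z")
})

test_that("contact detection matches a brute-force all-pairs oracle", {
  s <- read_pdb(toy_structure_file(4.45, 12))
  # independent O(n^2) scan over every ligand-atom / receptor-atom pair
  brute <- function(struct, lig, recs, cutoff) {
    out <- list()
    for (rc in recs) {
      rec <- struct[struct$chain == rc, ]
      for (rn in unique(struct$resno[struct$chain == lig])) {
        res <- struct[struct$chain == lig & struct$resno == rn, ]
        dmin <- Inf
        for (i in seq_len(nrow(res))) for (j in seq_len(nrow(rec))) {
          d <- sqrt(sum((unlist(res[i, c("x", "y", "z")]) -
                           unlist(rec[j, c("x", "y", "z")]))^2))
          dmin <- min(dmin, d)
        }
        if (dmin <= cutoff) {
          out[[length(out) + 1]] <- data.frame(resno = rn,
                                               partner_chain = rc,
                                               min_distance = dmin)
        }
      }
    }
    if (length(out)) do.call(rbind, out) else
      data.frame(resno = integer(0), partner_chain = character(0),
                 min_distance = numeric(0))
  }
  got <- contact_residues(s, "A", c("B", "C"))
  want <- brute(s, "A", c("B", "C"), 4.5)
  expect_equal(got$resno, want$resno)
  expect_equal(got$partner_chain, want$partner_chain)
  expect_equal(got$min_distance, want$min_distance, tolerance = 1e-9)
})

test_that("distances are invariant under rigid-body motion", {
  s <- read_pdb(toy_structure_file(4.4, 19.9))
  set.seed(5)
  rot <- qr.Q(qr(matrix(rnorm(9), 3))) # random orthogonal matrix
  shift <- rnorm(3, sd = 20)
  xyz <- as.matrix(s[, c("x", "y", "z")]) %*% rot
  moved <- s
  moved$x <- xyz[, 1] + shift[1]
  moved$y <- xyz[, 2] + shift[2]
  moved$z <- xyz[, 3] + shift[3]
  d0 <- c_terminal_distance(s, "B", "C")$distance
  d1 <- c_terminal_distance(moved, "B", "C")$distance
  expect_equal(d1, d0, tolerance = 1e-9)
  c0 <- contact_residues(s, "A", "B")
  c1 <- contact_residues(moved, "A", "B")
  expect_equal(c1$min_distance, c0$min_distance, tolerance = 1e-9)
})

test_that("C-terminal distances use the highest CA-bearing residues", {
  s <- read_pdb(toy_structure_file(4.4, 19.9))
  res <- c_terminal_distance(s, "B", "C")
  expect_equal(res$distance, 19.9, tolerance = 1e-6)
  expect_equal(res$resno_a, 5)
  expect_equal(res$resno_b, 5)
  expect_equal(c_terminal_distance(s, "B", "B")$distance, 0)
  expect_error(c_terminal_distance(s, "B", "Q"), "no CA")
})
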