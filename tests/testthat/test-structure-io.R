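test_that("PDB round trip preserves the atom table", {
  pp <- make_polymer_protein(3, "random", seed = 1)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pp$atoms, f)
  at <- read_structure(f)
  expect_equal(nrow(at), nrow(pp$atoms))
  expect_equal(at$name, pp$atoms$name)
  expect_equal(at$residue_index, pp$atoms$residue_index)
  expect_equal(at$residue_name, pp$atoms$residue_name)
  expect_equal(at$x, pp$atoms$x, tolerance = 1e-3)
  # all residues carry complete backbones
  for (r in 1:3) {
    expect_true(all(c("N", "CA", "C", "O") %in% at$name[at$residue_index == r]))
  }
})

test_that("only the first MODEL is read", {
  pp <- make_polymer_protein(3, "helix_like", seed = 2)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pp$atoms, f)
  body <- setdiff(readLines(f), "END")
  writeLines(c("MODEL     1", body, "ENDMDL",
               "MODEL     2", body, "ENDMDL", "END"), f)
  at <- read_structure(f)
  expect_equal(nrow(at), nrow(pp$atoms))
})

test_that("altloc keeps the highest occupancy, ties go to A", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, occ = 0.4, altloc = "A"),
    pdb_line(2, "N", "ALA", "A", 1, 1, 0, 0, occ = 0.6, altloc = "B"),
    pdb_line(3, "H", "ALA", "A", 1, 0, 1, 0),
    "END"), f)
  at <- read_structure(f)
  expect_equal(sum(at$name == "N"), 1L)
  expect_equal(at$x[at$name == "N"], 1)      # occupancy 0.6 conformer

  writeLines(c(
    pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0, occ = 0.5, altloc = "A"),
    pdb_line(2, "N", "ALA", "A", 1, 1, 0, 0, occ = 0.5, altloc = "B"),
    pdb_line(3, "H", "ALA", "A", 1, 0, 1, 0),
    "END"), f)
  at <- read_structure(f)
  expect_equal(at$x[at$name == "N"], 0)      # tie -> altloc A
})

test_that("HETATM records are dropped and insertion codes rejected", {
  f <- withr::local_tempfile(fileext = ".pdb")
  het <- sub("^ATOM  ", "HETATM", pdb_line(9, "O", "HOH", "A", 99, 5, 5, 5))
  writeLines(c(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "H", "ALA", "A", 1, 0, 1, 0), het, "END"), f)
  at <- read_structure(f)
  expect_false(any(at$residue_name == "HOH"))

  ins <- pdb_line(3, "CA", "ALA", "A", 1, 1, 1, 1)
  substr(ins, 27, 27) <- "A"                  # insertion code
  writeLines(c(pdb_line(1, "N", "ALA", "A", 1, 0, 0, 0),
               pdb_line(2, "H", "ALA", "A", 1, 0, 1, 0), ins, "END"), f)
  expect_error(read_structure(f), "insertion")
})

test_that("missing hydrogens on a standard residue is a hard error", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(pdb_line(1, "N", "GLY", "A", 1, 0, 0, 0),
               pdb_line(2, "CA", "GLY", "A", 1, 1.4, 0, 0),
               "END"), f)
  expect_error(read_structure(f), "hydrogens.*1")
})

test_that("relative SASA hits the exposed and buried limits", {
  pp3 <- make_polymer_protein(3, "random", seed = 1,
                              sequence = c("GLY", "GLY", "GLY"))
  pp <- list(atoms = pp3$atoms[pp3$atoms$residue_index == 2, ])
  pp$atoms$residue_index <- 1L
  free <- compute_relative_sasa(pp$atoms, n_points = 480)
  expect_gt(free$rel_sasa, 0.95)              # isolated residue ~ fully exposed

  # bury the residue inside a shell of dummy atoms
  shell_r <- 6
  pts <- mdcm:::sphere_points(200) * shell_r
  ctr <- colMeans(as.matrix(pp$atoms[, c("x", "y", "z")]))
  shell <- tibble::tibble(
    atom_id = max(pp$atoms$atom_id) + seq_len(200),
    name = "CA", element = "C", residue_index = 2L, residue_name = "GLY",
    chain = "A", x = pts[, 1] + ctr[1], y = pts[, 2] + ctr[2],
    z = pts[, 3] + ctr[3], bfactor = 0, occupancy = 1, serial = 0)
  both <- dplyr::bind_rows(pp$atoms, shell)
  buried <- compute_relative_sasa(both, n_points = 480)
  expect_lt(buried$rel_sasa[buried$residue_index == 1], 0.05)
})

test_that("SASA matches a double-resolution sphere oracle and is monotone", {
  pp <- make_polymer_protein(5, "sheet_like", seed = 3)
  coarse <- compute_relative_sasa(pp$atoms, n_points = 960)
  fine <- compute_relative_sasa(pp$atoms, n_points = 1920)
  expect_lt(max(abs(coarse$rel_sasa - fine$rel_sasa)), 0.03)

  # occluding atoms never increase accessibility
  occ <- pp$atoms[1, ]
  occ$atom_id <- max(pp$atoms$atom_id) + 1L
  occ$residue_index <- 6L
  occ$x <- mean(pp$atoms$x); occ$y <- mean(pp$atoms$y)
  occ$z <- mean(pp$atoms$z)
  with_occ <- compute_relative_sasa(dplyr::bind_rows(pp$atoms, occ),
                                    n_points = 960)
  expect_true(all(with_occ$rel_sasa[1:5] <= coarse$rel_sasa + 1e-12))
})

test_that("unknown residue types are reported", {
  at <- tibble::tibble(atom_id = 1, name = "X1", element = "C",
                       residue_index = 1, residue_name = "XYZ",
                       x = 0, y = 0, z = 0)
  expect_error(compute_relative_sasa(at), "XYZ")
})

test_that("tertile classes split ranks into near-equal contiguous groups", {
  expect_equal(as.character(tertile_classes(c(0.1, 0.5, 0.9))),
               c("buried", "moderate", "exposed"))

  tied <- tertile_classes(rep(0.3, 6))
  expect_equal(as.vector(table(tied)), c(2, 2, 2))
  expect_equal(as.character(tied),
               rep(c("buried", "moderate", "exposed"), each = 2))

  set.seed(7)
  v <- runif(130)
  cls <- tertile_classes(v)
  expect_equal(as.vector(table(cls)), c(44, 43, 43))
  # value ranges ordered buried < moderate < exposed (sort-based oracle)
  expect_lt(max(v[cls == "buried"]), min(v[cls == "moderate"]) + 1e-12)
  expect_lt(max(v[cls == "moderate"]), min(v[cls == "exposed"]) + 1e-12)

  # sizes differ by at most one for any length
  for (n in 3:12) {
    sz <- as.vector(table(tertile_classes(runif(n))))
    expect_lte(diff(range(sz)), 1)
  }
})

test_that("tabular artifacts round trip", {
  d <- withr::local_tempdir()
  ann <- tibble::tibble(residue_index = 1:4, rel_sasa = c(0.1, 0.4, 0.8, 0.2),
                        ss_class = c("helix", "helix", "coil", "strand"),
                        subdomain = c("alpha", "alpha", "alpha", "beta"))
  write_annotations(ann, file.path(d, "ann.tsv"))
  expect_equal(as.data.frame(read_annotations(file.path(d, "ann.tsv"))),
               as.data.frame(ann))

  fi <- tibble::tibble(residue_index = 1:5, FI = runif(5, -1, 1))
  write_fi_tsv(fi, file.path(d, "fi.tsv"))
  expect_equal(as.data.frame(read_fi_tsv(file.path(d, "fi.tsv"))),
               as.data.frame(fi), tolerance = 1e-12)

  cc <- matrix(runif(16, -1, 1), 4, 4)
  cc <- (cc + t(cc)) / 2
  dimnames(cc) <- list(1:4, 1:4)
  write_cc_tsv(cc, file.path(d, "cc.tsv"))
  expect_equal(read_cc_tsv(file.path(d, "cc.tsv")), cc, tolerance = 1e-12)

  meta <- list(seed = 3L, n_samples = 200L, grid = list(stride = 1L))
  write_run_metadata(meta, file.path(d, "meta.json"))
  back <- jsonlite::read_json(file.path(d, "meta.json"))
  expect_equal(back$seed, 3L)
  expect_equal(back$grid$stride, 1L)
})

test_that("annotation validation catches duplicates and bad classes", {
  d <- withr::local_tempdir()
  bad <- tibble::tibble(residue_index = c(1, 1),
                        ss_class = c("helix", "coil"),
                        subdomain = c("alpha", "alpha"))
  readr::write_tsv(bad, file.path(d, "bad.tsv"))
  expect_error(read_annotations(file.path(d, "bad.tsv")), "exactly once")
})

test_that("B-factor, H-bond and landscape tables round trip", {
  d <- withr::local_tempdir()
  bf <- tibble::tibble(residue_index = 1:6, bfactor = runif(6, 10, 40))
  write_bfactors_tsv(bf, file.path(d, "b.tsv"))
  expect_equal(as.data.frame(read_bfactors_tsv(file.path(d, "b.tsv"))),
               as.data.frame(bf), tolerance = 1e-12)

  pp <- make_polymer_protein(8, "helix_like", seed = 2)
  hb <- detect_hbonds(pp$atoms)
  write_hbonds_tsv(hb, file.path(d, "hb.tsv"))
  back <- readr::read_tsv(file.path(d, "hb.tsv"), show_col_types = FALSE)
  expect_equal(back$u_hb, hb$u_hb, tolerance = 1e-9)
  expect_equal(back$donor, hb$donor)

  net <- thermal_toy()
  L <- build_landscape(net, thermal_params(), T = 380,
                       config = dcm_ensemble_config(exhaustive_limit = Inf))
  write_landscape_tsv(L, file.path(d, "ls.tsv"))
  lsb <- readr::read_tsv(file.path(d, "ls.tsv"), show_col_types = FALSE)
  expect_equal(nrow(lsb), nrow(L$grid))
  expect_equal(lsb$free_energy, L$grid$free_energy, tolerance = 1e-9)
})

test_that("stratify supports a local exclusion window around the site", {
  set.seed(3)
  n <- 40
  ca <- matrix(rnorm(3 * n, sd = 10), n, 3)
  bins <- classify_bins(rnorm(n))
  classes <- rep(c("helix", "coil"), length.out = n)
  t0 <- stratify(bins, classes, 20L, ca)
  t2 <- stratify(bins, classes, 20L, ca, exclude_window = 2)
  expect_equal(sum(t0$count), n - 1L)
  expect_equal(sum(t2$count), n - 5L)
})
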