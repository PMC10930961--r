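test_that("residue centre of geometry is the unweighted atom mean", {
  one <- as_structure(tibble::tibble(chain = "A", resno = 1, resid = "GLY",
                                     elety = "CA", x = 1, y = 2, z = 3))
  expect_equal(unlist(residue_cog(one)[c("x", "y", "z")]),
               c(x = 1, y = 2, z = 3))
  two <- as_structure(tibble::tibble(chain = "A", resno = c(1, 1),
                                     resid = "GLY", elety = c("N", "C"),
                                     x = c(0, 2), y = 0, z = 0))
  expect_equal(residue_cog(two)$x, 1)
  atoms <- withr::with_seed(9, tibble::tibble(
    chain = "A", resno = 1, resid = "LYS", elety = paste0("A", 1:5),
    x = rnorm(5), y = rnorm(5), z = rnorm(5)))
  cog <- residue_cog(as_structure(atoms))
  expect_equal(c(cog$x, cog$y, cog$z),
               c(mean(atoms$x), mean(atoms$y), mean(atoms$z)))
})

test_that("planted pocket fixtures yield exactly the planted contact map", {
  g0 <- gen_peptide_pocket(4, 6, NULL, seed = 1)
  expect_equal(nrow(contact_map(g0$peptide, g0$domain)), 0)

  g <- gen_peptide_pocket(4, 3, rbind(c(1, 1), c(1, 3)), seed = 2)
  cm <- contact_map(g$peptide, g$domain)
  got <- sort(paste(cm$peptide_resno, cm$domain_resno - 300))
  expect_equal(got, sort(c("1 1", "1 3")))

  # 10-residue peptide with 7 residues given at least one planted contact
  planted <- cbind(c(1, 2, 3, 4, 7, 9, 10, 1), c(1, 2, 3, 4, 5, 6, 7, 2))
  g7 <- gen_peptide_pocket(8, 10, planted, seed = 3)
  s <- summarize_contact_table(contact_map(g7$peptide, g7$domain))
  expect_equal(s$contacting_residues, 7)
  # cross-check with the brute-force oracle
  bf <- brute_force_contacts(g7$peptide, g7$domain)
  expect_equal(nrow(bf), nrow(planted))
})

test_that("the 6.5-A boundary is inclusive and labels run back from the C-terminus", {
  pep <- as_structure(tibble::tibble(chain = "A", resno = 1:2, resid = "ALA",
                                     elety = "CA", x = c(0, 100), y = 0, z = 0))
  dom <- as_structure(tibble::tibble(chain = "B", resno = 301, resid = "LEU",
                                     elety = "CA", x = 6.5, y = 0, z = 0))
  cm <- contact_map(pep, dom)
  expect_equal(nrow(cm), 1)
  expect_equal(cm$peptide_position, "C-2")  # residue 1 of a 2-mer
  expect_equal(cm$domain_residue, "L301")
  # just past the cutoff: no contact
  dom2 <- dplyr::mutate(dom, x = 6.5001)
  expect_equal(nrow(contact_map(pep, as_structure(dom2))), 0)
})

test_that("grid-accelerated search equals brute force on random fixtures", {
  for (s in 1:25) {
    p <- random_structure(12, "A", box = 30, seed = s)
    d <- random_structure(60, "B", box = 30, seed = 1000 + s)
    cm <- contact_map(p, d)
    bf <- brute_force_contacts(p, d)
    got <- sort(paste(cm$peptide_resno, cm$domain_resno))
    want <- if (nrow(bf)) sort(paste(bf[, 1], d$resno[bf[, 2]])) else character(0)
    expect_equal(got, want)
    # swapped arguments give the mirrored pairs
    cm_swap <- contact_map(d, p)
    expect_equal(nrow(cm_swap), nrow(cm))
  }
})

test_that("the published contact listing summarises to 7 contacting residues", {
  m <- contact_table_to_map()
  s <- summarize_contact_table(m, n_peptide = 10)
  expect_equal(s$contacting_residues, 7)
  expect_equal(nchar(jam_tail_sequence()), 10)
  expect_equal(s$table$contacts[s$table$position == "C-5"], "-")
  # empty map and fully contacting map
  empty <- tibble::tibble(peptide_position = character(0),
                          domain_residue = character(0))
  expect_equal(summarize_contact_table(empty, n_peptide = 10)$contacting_residues, 0)
  full <- tibble::tibble(peptide_position = paste0("C-", 1:10),
                         domain_residue = "L321")
  expect_equal(summarize_contact_table(full, n_peptide = 10)$contacting_residues, 10)
})

test_that("hydropathy classification uses a strict threshold at 1", {
  tab <- jam_pdz2_contact_table()
  cls <- classify_hydropathy(tab)
  expect_equal(cls$class[cls$position == "C-1"], "hydrophobic")   # V, 0.9
  expect_equal(cls$class[cls$position == "C-8"], "hydrophilic")   # K, 1.3
  expect_equal(classify_hydropathy(tibble::tibble(parch = 1.0))$class,
               "hydrophilic")
  expect_error(classify_hydropathy(tibble::tibble(parch = 11)),
               class = "junctionmech_validation_error")
})

test_that("water contacts use the 0.315 nm cutoff converted once to 3.15 A", {
  st <- as_structure(tibble::tibble(chain = "A", resno = 1:2, resid = "SER",
                                    elety = "CA", x = c(0, 50), y = 0, z = 0))
  waters <- tibble::tibble(x = c(3.0, 2.0, -3.1, 4.0, 53.14, 53.16),
                           y = 0, z = 0)
  out <- count_water_contacts(st, waters)
  expect_equal(out$n_waters, c(3L, 1L))  # 3.16 A falls just outside
  expect_equal(count_water_contacts(st, waters[0, ])$n_waters, c(0L, 0L))
})

test_that("water counting matches a brute-force oracle on random frames", {
  for (s in 1:5) {
    st <- random_structure(15, seed = s)
    waters <- withr::with_seed(100 + s, tibble::tibble(
      x = runif(200, 0, 40), y = runif(200, 0, 40), z = runif(200, 0, 40)))
    got <- count_water_contacts(st, waters, cutoff_nm = 0.5)$n_waters
    want <- vapply(seq_len(15), function(i) {
      a <- st[st$resno == i, ]
      sum(vapply(seq_len(200), function(w) {
        min(sqrt((a$x - waters$x[w])^2 + (a$y - waters$y[w])^2 +
                   (a$z - waters$z[w])^2)) <= 5
      }, logical(1)))
    }, numeric(1))
    expect_equal(got, as.integer(want))
  }
})

test_that("structures survive a PDB round-trip", {
  g <- gen_peptide_pocket(3, 4, rbind(c(1, 1)), seed = 5)
  tmp <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(g$peptide, tmp)
  back <- read_pdb_structure(tmp)
  expect_equal(nrow(back), 4)
  expect_equal(back$x, g$peptide$x, tolerance = 1e-3)  # PDB has 3 decimals
  cm1 <- contact_map(g$peptide, g$domain)
  tmp2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb_structure(g$domain, tmp2)
  cm2 <- contact_map(back, read_pdb_structure(tmp2))
  expect_equal(cm2$domain_resno, cm1$domain_resno)
})
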