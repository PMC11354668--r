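test_that("contacts respect the distance cutoff with recorded min distance", {
  st <- pair_complex(4.0)
  ct <- find_contacts(st, contact_params(default_cutoff = 4.5))
  expect_equal(nrow(ct), 1)
  expect_equal(ct$min_distance, 4.0, tolerance = 1e-12)
  expect_identical(ct$receptor_resname, "GLU")
  expect_equal(nrow(find_contacts(st, contact_params(default_cutoff = 3.5))), 0)
})

test_that("an empty ligand interface yields zero rows, not an error", {
  cx <- make_toy_complex(complex_spec(seed = 3, planted_mode = "MODE1",
                                      contact_distance = 3))
  far <- cx$structure
  far$atoms$y[far$atoms$chain == "Z"] <- -250   # push ligand out of range
  expect_equal(nrow(find_contacts(far)), 0)
})

test_that("neighbor search equals the brute-force oracle on seeded toys", {
  for (seed in 1:20) {
    mode <- c("FAB", "MODE1", "MODE2", "MODE3")[(seed %% 4) + 1]
    cx <- make_toy_complex(complex_spec(seed = seed, planted_mode = mode))
    a <- find_contacts(cx$structure)
    b <- find_contacts_brute(cx$structure)
    expect_identical(a[, c("ligand_resnum", "receptor_chain", "receptor_resnum")],
                     b[, c("ligand_resnum", "receptor_chain", "receptor_resnum")])
    expect_true(all(abs(a$min_distance - b$min_distance) <= 1e-9))
  }
})

test_that("planted contacts are recovered exactly", {
  cx <- make_toy_complex(complex_spec(seed = 7, planted_mode = "MODE1"))
  ct <- find_contacts(cx$structure)
  got <- unique(ct[, c("receptor_chain", "receptor_resnum")])
  expect_setequal(paste(got$receptor_chain, got$receptor_resnum),
                  paste(cx$truth$chain, cx$truth$resnum))
})

test_that("enlarging the cutoff never removes a contact", {
  cx <- make_toy_complex(complex_spec(seed = 9, planted_mode = "MODE3"))
  key <- function(ct) paste(ct$ligand_resnum, ct$receptor_chain, ct$receptor_resnum)
  cuts <- c(3.2, 4.5, 6, 8)
  sets <- lapply(cuts, function(cc) key(find_contacts(cx$structure, contact_params(cc))))
  for (i in seq_len(length(cuts) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("per-class cutoffs apply to hydrogen-bond-capable atom pairs", {
  # N...N pair at 4.0 A: inside the 6.0 'other' cutoff? No - both atoms are
  # hbond-class, so the 3.5 A hbond cutoff governs and excludes it.
  txt <- paste(c(
    pdb_record("ATOM", 1, "N", "LYS", "B", 300, 0, 0, 0, element = "N"),
    pdb_record("HETATM", 2, "N1", "DG", "Z", 1, 0, 4, 0, element = "N"),
    "END"), collapse = "\n")
  st <- suppressWarnings(assign_regions(parse_complex(txt, "hb")))
  p <- contact_params(class_cutoffs = c(hbond = 3.5, other = 6.0))
  expect_equal(nrow(find_contacts(st, p)), 0)
  # a C...N pair at the same distance is 'other' class and qualifies at 6.0
  txt2 <- paste(c(
    pdb_record("ATOM", 1, "CA", "LYS", "B", 300, 0, 0, 0, element = "C"),
    pdb_record("HETATM", 2, "N1", "DG", "Z", 1, 0, 4, 0, element = "N"),
    "END"), collapse = "\n")
  st2 <- suppressWarnings(assign_regions(parse_complex(txt2, "hb2")))
  ct <- find_contacts(st2, p)
  expect_equal(nrow(ct), 1)
  expect_identical(ct$interaction_class, "other")
  expect_identical(find_contacts(st2, p), find_contacts_brute(st2, p))
})

test_that("binding frequency counts each site once per complex", {
  # complex where two nucleotides touch the same CH2 residue
  sites <- data.frame(chain = c("B", "B"), resnum = c(250, 250))
  cx_dup <- make_toy_complex(complex_spec(seed = 1, planted_mode = "MODE1",
                                          planted_contact_sites = sites,
                                          n_nucleotides = 4))
  ct <- find_contacts(cx_dup$structure)
  expect_equal(sum(ct$receptor_resnum == 250), 2)   # two raw contacts
  prof <- binding_frequency(list(ct), region_filter = "Fc")
  expect_equal(prof$count[prof$resnum == 250], 1)   # but one per complex
})

test_that("ensemble frequency matches a set-union oracle and ignores order", {
  set.seed(42)
  cxs <- lapply(1:10, function(s) {
    make_toy_complex(complex_spec(seed = 100 + s,
                                  planted_mode = sample(c("MODE1", "MODE3"), 1)))
  })
  cts <- lapply(cxs, function(cx) find_contacts(cx$structure))
  prof <- binding_frequency(cts, region_filter = "Fc")
  # independent oracle: per-complex site sets, tallied by hand
  site_sets <- lapply(cts, function(ct) {
    g <- region_group(ct$region)
    unique(paste(ct$receptor_chain, ct$receptor_resnum)[!is.na(g) & g == "Fc"])
  })
  tally <- table(unlist(site_sets))
  expect_equal(nrow(prof), length(tally))
  for (k in names(tally)) {
    row <- prof[paste(prof$chain, prof$resnum) == k, ]
    expect_equal(row$count, unname(as.integer(tally[k])))
    expect_equal(row$fraction, unname(as.integer(tally[k])) / 10)
  }
  prof_rev <- binding_frequency(rev(cts), region_filter = "Fc")
  expect_equal(prof, prof_rev)
  expect_error(binding_frequency(list()), "empty")
})

test_that("fraction example: a site contacted in 7 of 10 complexes is 0.7", {
  site <- data.frame(chain = "B", resnum = 300)
  alt <- data.frame(chain = "B", resnum = 350)
  cts <- lapply(1:10, function(i) {
    cx <- make_toy_complex(complex_spec(seed = i, planted_mode = "MODE1",
                                        planted_contact_sites = if (i <= 7) site else alt,
                                        n_nucleotides = 2))
    find_contacts(cx$structure)
  })
  prof <- binding_frequency(cts, region_filter = "Fc")
  expect_equal(prof$fraction[prof$resnum == 300], 0.7)
  expect_equal(prof$fraction[prof$resnum == 350], 0.3)
})

test_that("interface composition normalises each family to 100%", {
  mk <- function(resname, kind, n) {
    data.frame(ligand_resname = "DG", receptor_resname = resname,
               receptor_kind = kind, stringsAsFactors = FALSE)[rep(1, n), ]
  }
  ct <- rbind(mk("PRO", "amino_acid", 2), mk("GLU", "amino_acid", 1),
              mk("LYS", "amino_acid", 1), mk("NAG", "monosaccharide", 3),
              mk("MAN", "monosaccharide", 1))
  comp <- interface_composition(ct)
  aa <- comp[comp$family == "amino_acid", ]
  expect_equal(aa$share_pct[aa$unit == "PRO"], 50)
  expect_equal(aa$share_pct[aa$unit == "GLU"], 25)
  expect_equal(sum(aa$share_pct), 100)
  ms <- comp[comp$family == "monosaccharide", ]
  expect_equal(ms$share_pct[ms$unit == "NAG"], 75)
  expect_equal(sum(ms$share_pct), 100)
  expect_error(interface_composition(ct[0, ]), "zero contacts")
})
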