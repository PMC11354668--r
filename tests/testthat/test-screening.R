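classify_toy <- function(seed, mode, ...) {
  cx <- make_toy_complex(complex_spec(seed = seed, planted_mode = mode, ...))
  classify_binding_mode(cx$structure, find_contacts(cx$structure))
}

test_that("binding modes are classified per the region rules", {
  # all contacts in CH2 -> MODE1 / fc_bound
  sites <- data.frame(chain = "B", resnum = c(250, 300, 350))
  cx <- make_toy_complex(complex_spec(seed = 1, planted_mode = "MODE1",
                                      planted_contact_sites = sites,
                                      n_nucleotides = 5))
  rec <- classify_binding_mode(cx$structure, find_contacts(cx$structure))
  expect_identical(rec$mode, "MODE1")
  expect_true(rec$fc_bound)

  # hinge sites (heavy-chain 455-475 interval) -> MODE2
  hinge <- data.frame(chain = "B", resnum = c(458, 464, 470))
  cx2 <- make_toy_complex(complex_spec(seed = 2, planted_mode = "MODE2",
                                       planted_contact_sites = hinge,
                                       n_nucleotides = 5))
  rec2 <- classify_binding_mode(cx2$structure, find_contacts(cx2$structure))
  expect_identical(rec2$mode, "MODE2")
  expect_false(rec2$fc_bound)
})

test_that("MODE3 follows the majority-threshold rule on planted counts", {
  # 7 of 10 nucleotides on CH2/CH3, 3 on CL -> MODE3 by hand classification
  fc_sites <- data.frame(chain = "B", resnum = c(250, 300, 350, 370, 423, 450))
  fc_sites <- rbind(fc_sites, data.frame(chain = "D", resnum = 250))
  cl_sites <- data.frame(chain = "A", resnum = c(120, 160, 200))
  cx <- make_toy_complex(complex_spec(seed = 3, planted_mode = "MODE3",
                                      planted_contact_sites = rbind(fc_sites, cl_sites),
                                      n_nucleotides = 10))
  ct <- find_contacts(cx$structure)
  rec <- classify_binding_mode(cx$structure, ct)
  expect_identical(rec$mode, "MODE3")
  expect_equal(rec$frac_fc, 0.7)
  expect_equal(rec$frac_fab, 0.3)
  # with a threshold above the planted fraction the rule no longer fires
  rec_hi <- classify_binding_mode(cx$structure, ct, majority_threshold = 0.8)
  expect_identical(rec_hi$mode, "UNCLASSIFIED")
})

test_that("zero-contact ligands are UNCLASSIFIED with a warning", {
  cx <- make_toy_complex(complex_spec(seed = 4, planted_mode = "MODE1"))
  st <- cx$structure
  st$atoms$y[st$atoms$chain == "Z"] <- -250
  ct <- find_contacts(st)
  expect_warning(rec <- classify_binding_mode(st, ct), "zero contacts")
  expect_identical(rec$mode, "UNCLASSIFIED")
  expect_false(rec$fc_bound)
})

test_that("mode labels partition classified ligands and MODE1 implies pure Fc", {
  ens <- make_ensemble(24, seed = 5)
  recs <- do.call(rbind, lapply(ens$complexes, function(cx) {
    ct <- find_contacts(cx$structure)
    rec <- classify_binding_mode(cx$structure, ct)
    if (rec$mode == "MODE1") {
      expect_true(all(region_group(ct$region) == "Fc"))
    }
    rec
  }))
  expect_true(all(recs$mode %in% c("FAB", "MODE1", "MODE2", "MODE3")))
  # planted labels recovered for all unambiguous generator cases
  expect_identical(recs$mode, ens$poses$mode)
})

test_that("screen_fc_binders filters, ranks and breaks ties deterministically", {
  recs <- data.frame(
    ligand_id = c("L5", "L1", "L3", "L2", "L4"),
    mode = c("MODE1", "FAB", "MODE1", "MODE2", "MODE1"),
    fc_bound = c(TRUE, FALSE, TRUE, FALSE, TRUE),
    zdock_score = c(20.5, 33, 28.1, 25, 20.5),
    stringsAsFactors = FALSE
  )
  out <- screen_fc_binders(recs)
  expect_equal(nrow(out), 3)
  expect_identical(out$ligand_id, c("L3", "L4", "L5"))  # score desc, id tie-break
  expect_equal(attr(out, "n_total"), 5)

  none <- recs[recs$mode == "FAB", ]
  expect_equal(nrow(screen_fc_binders(none)), 0)
  expect_error(screen_fc_binders(recs[0, ]), "no screening records")
})

test_that("planted 49-of-140 MODE1 ensembles are recovered by screening", {
  props <- c(FAB = 31 / 140, MODE1 = 49 / 140, MODE2 = 25 / 140, MODE3 = 35 / 140)
  ens <- make_ensemble(140, mode_proportions = props, seed = 11)
  expect_equal(sum(ens$poses$mode == "MODE1"), 49)
  recs <- do.call(rbind, lapply(ens$complexes, function(cx) {
    classify_binding_mode(cx$structure, find_contacts(cx$structure))
  }))
  recs$zdock_score <- ens$poses$zdock_score[match(recs$ligand_id, ens$poses$ligand_id)]
  fc <- screen_fc_binders(recs)
  expect_equal(nrow(fc), 49)
  expect_true(all(diff(fc$zdock_score) <= 0))
})

test_that("mutation_report computes delta and site engagement", {
  ct_before <- data.frame(receptor_chain = "B", receptor_resnum = 423)
  ct_after <- data.frame(receptor_chain = "B", receptor_resnum = 423)
  before <- list(pose = list(ligand_id = "3HXQ", zdock_score = 32.78),
                 contacts = ct_before)
  after <- list(pose = list(ligand_id = "3HXQ", zdock_score = 29.1),
                contacts = ct_after)
  rep <- mutation_report(before, after, "B:423")
  expect_equal(rep$delta, 29.1 - 32.78)   # negative: lost favourability
  expect_true(rep$site_still_contacted)

  # identical poses -> delta 0
  rep0 <- mutation_report(before, before, "B:423")
  expect_equal(rep0$delta, 0)

  # site absent from the after-contacts
  after2 <- list(pose = list(ligand_id = "3HXQ", zdock_score = 29.1),
                 contacts = data.frame(receptor_chain = "B", receptor_resnum = 300))
  expect_false(mutation_report(before, after2, "B:423")$site_still_contacted)

  bad <- list(pose = list(ligand_id = "OTHER", zdock_score = 1), contacts = ct_after)
  expect_error(mutation_report(before, bad, "B:423"), "mismatched ligand ids")
})

test_that("pose tables round-trip through TSV", {
  poses <- data.frame(ligand_id = c("A1", "B2"), pose_rank = c(1L, 1L),
                      zdock_score = c(32.78, 17.18))
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write_pose_table(poses, f)
  expect_equal(read_pose_table(f), poses)
})
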